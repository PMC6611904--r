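#' @importFrom stats ppois phyper p.adjust ks.test rnorm rpois runif setNames
#' @importFrom utils read.delim write.table head
NULL

# All genomic intervals are 0-based half-open internally. TSS-relative
# coordinates (the user-facing promoter convention) have no position 0:
# the base immediately 5' of the TSS is -1, the TSS base itself is +1.
# Conversion happens only at the reporting boundary (motif module).

#' Construct a gene annotation
#'
#' An annotation is a data frame of gene models plus the chromosome sizes
#' they live on. Coordinates are 0-based half-open; strand is "+" or "-".
#' The TSS is `start` for a plus-strand gene and `end - 1` for a
#' minus-strand gene; the TES is the opposite boundary base.
#'
#' @param genes data.frame with columns gene_id, chrom, start, end, strand.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return A validated `cismark_annotation`: the gene data frame sorted by
#'   (chrom, start, gene_id), with `chrom_sizes` attached as an attribute.
#' @export
annotation <- function(genes, chrom_sizes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (length(chrom_sizes) == 0L || is.null(names(chrom_sizes)))
    stop("chrom_sizes must be a named vector of chromosome lengths")
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.character(genes$strand)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id: ", genes$gene_id[duplicated(genes$gene_id)][1L])
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (any(genes$start < 0L) || any(genes$start >= genes$end))
    stop("gene coordinates must satisfy 0 <= start < end")
  bad <- !(genes$chrom %in% names(chrom_sizes))
  if (any(bad)) stop("gene on unknown chromosome: ", genes$chrom[bad][1L])
  if (any(genes$end > chrom_sizes[genes$chrom]))
    stop("gene extends beyond chromosome end: ",
         genes$gene_id[genes$end > chrom_sizes[genes$chrom]][1L])
  ord <- order(genes$chrom, genes$start, genes$gene_id, method = "radix")
  genes <- genes[ord, c("gene_id", "chrom", "start", "end", "strand")]
  rownames(genes) <- NULL
  attr(genes, "chrom_sizes") <- setNames(as.integer(chrom_sizes), names(chrom_sizes))
  class(genes) <- c("cismark_annotation", "data.frame")
  genes
}

#' Chromosome sizes of an annotation or coverage track
#' @param x an annotation or coverage track.
#' @return Named integer vector of chromosome lengths.
#' @export
chrom_sizes <- function(x) attr(x, "chrom_sizes")

#' TSS and TES genomic positions (0-based base coordinates)
#'
#' @param genes an annotation or compatible gene data frame.
#' @return Integer vector of per-gene positions, named by gene_id.
#' @export
tss <- function(genes) {
  setNames(ifelse(genes$strand == "+", genes$start, genes$end - 1L),
           genes$gene_id)
}

#' @rdname tss
#' @export
tes <- function(genes) {
  setNames(ifelse(genes$strand == "+", genes$end - 1L, genes$start),
           genes$gene_id)
}

#' Read a multi-record FASTA into uppercase DNA strings
#'
#' Record ids are taken up to the first whitespace; sequences are
#' uppercased, IUPAC letters preserved.
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  setNames(toupper(as.character(ss)), ids)
}

#' Write sequences to FASTA
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "wb")  # LF endings on every platform
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con, sep = "\n")
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read gene models from BED6
#'
#' @param path BED6 file (chrom, start, end, name, score, strand); the
#'   score column is ignored.
#' @param chrom_sizes named vector of chromosome lengths used to validate
#'   gene extents.
#' @return A `cismark_annotation`.
#' @export
read_genes_bed <- function(path, chrom_sizes) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 6L))
    stop("line ", which(n < 6L)[1L], ": expected 6 BED columns")
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  for (i in seq_along(lines)) {
    if (is.na(start[i]) || is.na(end[i]) || start[i] >= end[i])
      stop("line ", i, ": invalid interval [", m[i, 2L], ", ", m[i, 3L], ")")
    if (!m[i, 6L] %in% c("+", "-"))
      stop("line ", i, ": unknown strand '", m[i, 6L], "'")
    if (!m[i, 1L] %in% names(chrom_sizes))
      stop("line ", i, ": unknown chromosome '", m[i, 1L], "'")
    if (end[i] > chrom_sizes[[m[i, 1L]]])
      stop("line ", i, ": gene extends beyond chromosome '", m[i, 1L], "'")
  }
  annotation(data.frame(gene_id = m[, 4L], chrom = m[, 1L],
                        start = start, end = end, strand = m[, 6L],
                        stringsAsFactors = FALSE),
             chrom_sizes)
}

#' Write an annotation as BED6
#' @param ann a `cismark_annotation`.
#' @param path output file.
#' @export
write_genes_bed <- function(ann, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     ann$chrom, ann$start, ann$end, ann$gene_id, ann$strand),
             con, sep = "\n")
  invisible(path)
}

#' Construct a coverage track
#'
#' A coverage track is a sorted, non-overlapping set of weighted intervals
#' (bedGraph semantics: value = per-base read depth) with a library size in
#' reads, computed as total coverage mass divided by the read length.
#'
#' @param intervals data.frame with columns chrom, start, end, value.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param read_length read length in bp used for library-size bookkeeping.
#' @return A `cismark_coverage` data frame with attributes `chrom_sizes`,
#'   `read_length`, `library_size`.
#' @export
coverage_track <- function(intervals, chrom_sizes, read_length = 50L) {
  stopifnot(is.data.frame(intervals),
            all(c("chrom", "start", "end", "value") %in% names(intervals)))
  intervals$chrom <- as.character(intervals$chrom)
  intervals$start <- as.integer(intervals$start)
  intervals$end <- as.integer(intervals$end)
  intervals$value <- as.numeric(intervals$value)
  if (any(intervals$value < 0)) stop("negative coverage value")
  if (any(intervals$start < 0L | intervals$start >= intervals$end))
    stop("invalid coverage interval")
  bad <- !(intervals$chrom %in% names(chrom_sizes))
  if (any(bad)) stop("coverage on unknown chromosome: ", intervals$chrom[bad][1L])
  if (any(intervals$end > chrom_sizes[intervals$chrom]))
    stop("coverage interval beyond chromosome end")
  ord <- order(intervals$chrom, intervals$start, method = "radix")
  intervals <- intervals[ord, c("chrom", "start", "end", "value")]
  # overlap check within chromosome
  by_chr <- split(seq_len(nrow(intervals)), intervals$chrom)
  for (idx in by_chr) {
    if (length(idx) > 1L &&
        any(intervals$start[idx][-1L] < intervals$end[idx][-length(idx)]))
      stop("overlapping intervals in coverage track")
  }
  # drop zero-value rows: they carry no mass and make round-trips canonical
  intervals <- intervals[intervals$value > 0, , drop = FALSE]
  rownames(intervals) <- NULL
  lib <- sum((intervals$end - intervals$start) * intervals$value) / read_length
  if (lib <= 0) stop("coverage track has zero total mass (library_size must be > 0)")
  attr(intervals, "chrom_sizes") <- setNames(as.integer(chrom_sizes), names(chrom_sizes))
  attr(intervals, "read_length") <- as.integer(read_length)
  attr(intervals, "library_size") <- lib
  class(intervals) <- c("cismark_coverage", "data.frame")
  intervals
}

#' Library size (reads) of a coverage track
#' @param track a `cismark_coverage`.
#' @return total coverage mass / read length.
#' @export
library_size <- function(track) attr(track, "library_size")

#' Read a 4-column bedGraph into a coverage track
#'
#' @inheritParams coverage_track
#' @param path bedGraph file.
#' @export
read_coverage_bedgraph <- function(path, chrom_sizes, read_length = 50L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L)
    stop("empty bedGraph: library_size must be > 0")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 4L)) stop("bedGraph line with fewer than 4 columns")
  m <- do.call(rbind, fields)
  val <- suppressWarnings(as.numeric(m[, 4L]))
  if (anyNA(val)) stop("non-numeric bedGraph value")
  coverage_track(data.frame(chrom = m[, 1L],
                            start = as.integer(m[, 2L]),
                            end = as.integer(m[, 3L]),
                            value = val, stringsAsFactors = FALSE),
                 chrom_sizes, read_length)
}

#' Write a coverage track as 4-column bedGraph
#' @param track a `cismark_coverage`.
#' @param path output file.
#' @export
write_coverage_bedgraph <- function(track, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                     format(track$value, trim = TRUE, scientific = FALSE,
                            drop0trailing = TRUE)),
             con, sep = "\n")
  invisible(path)
}

#' Per-base coverage of one chromosome as a numeric vector
#'
#' Expands the interval representation; used by the windowing and metagene
#' code, which need fast range sums (via cumulative sums).
#' @param track a `cismark_coverage`.
#' @param chrom chromosome name.
#' @return numeric vector of length `chrom_sizes(track)[chrom]`.
#' @export
per_base_coverage <- function(track, chrom) {
  len <- chrom_sizes(track)[[chrom]]
  delta <- numeric(len + 1L)
  rows <- track$chrom == chrom
  if (any(rows)) {
    s <- track$start[rows]; e <- track$end[rows]; v <- track$value[rows]
    # intervals are non-overlapping, so starts (and ends) are unique
    delta[s + 1L] <- delta[s + 1L] + v
    keep <- e < len
    delta[e[keep] + 1L] <- delta[e[keep] + 1L] - v[keep]
  }
  cumsum(delta[seq_len(len)])
}

#' Read a differential-expression table
#'
#' Expects a TSV with header columns gene_id, log2fc, q_value; log2fc is
#' mutant versus wild type, q_value the adjusted p.
#' @param path TSV file.
#' @return data.frame with one validated record per gene.
#' @export
read_deg_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "log2fc", "q_value") %in% names(d)))
  d$gene_id <- as.character(d$gene_id)
  if (anyDuplicated(d$gene_id))
    stop("duplicate gene_id in DEG table: ", d$gene_id[duplicated(d$gene_id)][1L])
  if (any(d$q_value < 0 | d$q_value > 1)) stop("q_value outside [0, 1]")
  d[, c("gene_id", "log2fc", "q_value")]
}

#' Write a data frame as a TSV with LF endings
#' @param d data.frame.
#' @param path output file.
#' @export
write_tsv <- function(d, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}
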