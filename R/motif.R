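# Promoter extraction and exact/IUPAC cis-element scanning.
#
# Reported coordinates follow the promoter convention: +1 is the TSS base,
# the base immediately 5' of it is -1, and there is no position 0. A hit
# whose 5'-most base lies 989 bp upstream of the TSS spans (-989, -983)
# for a 7-bp pattern.

#' Reverse complement of a DNA string
#'
#' @param seq character scalar of IUPAC DNA letters (case-insensitive).
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) return("")
  if (grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]", seq))
    stop("non-IUPAC character in sequence")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

#' Extract a gene's promoter sequence
#'
#' The promoter is the `upstream` bp immediately 5' of the TSS, truncated
#' at the chromosome edge. The returned sequence reads 5'-to-3' in the
#' gene's orientation (reverse-complemented for minus-strand genes), so
#' its last base is always the base at TSS-relative position -1.
#'
#' @param gene one-row gene data frame (gene_id, chrom, start, end, strand).
#' @param genome named character vector of chromosome sequences.
#' @param upstream promoter length in bp (default 2000).
#' @return list with `seq` (promoter, gene orientation), `start`/`end`
#'   (genomic 0-based half-open interval), `length` (actual bp) and
#'   `truncated` (TRUE when the chromosome edge cut the promoter short).
#' @export
extract_promoter <- function(gene, genome, upstream = 2000L) {
  if (!gene$chrom %in% names(genome))
    stop("chromosome missing from genome FASTA: ", gene$chrom)
  chrom_seq <- genome[[gene$chrom]]
  clen <- nchar(chrom_seq)
  if (gene$strand == "+") {
    g_start <- max(0L, gene$start - upstream)
    g_end <- gene$start
  } else {
    g_start <- gene$end
    g_end <- min(clen, gene$end + upstream)
  }
  n <- g_end - g_start
  s <- if (n > 0L) substr(chrom_seq, g_start + 1L, g_end) else ""
  if (gene$strand == "-" && n > 0L) s <- revcomp(s)
  list(seq = s, start = g_start, end = g_end, length = n,
       truncated = n < upstream)
}

#' Scan a promoter sequence for an exact or IUPAC pattern
#'
#' All occurrences (overlapping allowed) of `pattern` and, when
#' `both_strands`, of its reverse complement are reported with
#' TSS-relative inclusive coordinates. IUPAC ambiguity codes in the
#' pattern match their expansion sets; ambiguity letters in the subject
#' never match.
#'
#' @param promoter_seq promoter sequence in gene orientation (its last
#'   base sits at TSS-relative position -1).
#' @param pattern non-empty IUPAC DNA pattern.
#' @param both_strands also report reverse-complement matches
#'   (default TRUE).
#' @return data.frame with columns offset (0-based within the promoter),
#'   tss_start, tss_end (TSS-relative, inclusive, never 0),
#'   strand_of_match ("+" = pattern as given, "-" = reverse complement)
#'   and matched_seq; sorted by offset then strand.
#' @export
scan_pattern <- function(promoter_seq, pattern, both_strands = TRUE) {
  stopifnot(nzchar(pattern))
  u <- nchar(promoter_seq)
  empty <- data.frame(offset = integer(), tss_start = integer(),
                      tss_end = integer(), strand_of_match = character(),
                      matched_seq = character(), stringsAsFactors = FALSE)
  if (u < nchar(pattern)) return(empty)
  subj <- Biostrings::DNAString(toupper(promoter_seq))
  one_strand <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(toupper(pat)), subj,
                                  fixed = "subject")
    if (length(m) == 0L) return(empty)
    off <- BiocGenerics::start(m) - 1L  # 0-based promoter offset
    data.frame(offset = off,
               tss_start = off - u,            # -(u - off): no position 0
               tss_end = off - u + nchar(pat) - 1L,
               strand_of_match = strand,
               matched_seq = as.character(m),
               stringsAsFactors = FALSE)
  }
  hits <- one_strand(pattern, "+")
  if (both_strands) {
    rc <- revcomp(pattern)
    if (!identical(rc, toupper(pattern)))
      hits <- rbind(hits, one_strand(rc, "-"))
    else {
      # palindromic pattern: the reverse-complement scan would duplicate
      # every forward hit; report each occurrence once, on "+".
    }
  }
  hits <- hits[order(hits$offset, hits$strand_of_match), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Scan every gene's promoter for a cis-element
#'
#' A gene is included in the returned set iff its promoter (`upstream` bp
#' 5' of the TSS, gene orientation, truncated at chromosome edges)
#' contains at least one occurrence of the pattern (or of its reverse
#' complement when `both_strands`).
#'
#' @param ann a `cismark_annotation`.
#' @param genome named character vector of chromosome sequences.
#' @param pattern IUPAC DNA pattern (default the 7-bp element CGGAAAT).
#' @param upstream promoter length in bp (default 2000).
#' @param both_strands scan both orientations (default TRUE).
#' @return list with `gene_ids` (sorted character vector of genes with at
#'   least one hit) and `hits` (per-hit table: gene_id, chrom,
#'   genomic_start, genomic_end [0-based half-open], tss_start, tss_end
#'   [TSS-relative inclusive], strand_of_match, matched_seq), sorted by
#'   gene_id then tss_start.
#' @export
genes_with_element <- function(ann, genome, pattern = "CGGAAAT",
                               upstream = 2000L, both_strands = TRUE) {
  out <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    gene <- ann[i, ]
    prom <- extract_promoter(gene, genome, upstream)
    if (prom$length == 0L) next
    h <- scan_pattern(prom$seq, pattern, both_strands)
    if (nrow(h) == 0L) next
    len <- nchar(h$matched_seq)
    if (gene$strand == "+") {
      g_start <- prom$start + h$offset
    } else {
      # promoter offset counts 5'->3' in gene orientation, i.e. from the
      # genomic right edge of the promoter window leftwards
      g_start <- prom$end - h$offset - len
    }
    out[[i]] <- data.frame(gene_id = gene$gene_id, chrom = gene$chrom,
                           genomic_start = g_start, genomic_end = g_start + len,
                           tss_start = h$tss_start, tss_end = h$tss_end,
                           strand_of_match = h$strand_of_match,
                           matched_seq = h$matched_seq,
                           stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, out)
  if (is.null(hits))
    hits <- data.frame(gene_id = character(), chrom = character(),
                       genomic_start = integer(), genomic_end = integer(),
                       tss_start = integer(), tss_end = integer(),
                       strand_of_match = character(), matched_seq = character(),
                       stringsAsFactors = FALSE)
  hits <- hits[order(hits$gene_id, hits$tss_start, hits$strand_of_match), ,
               drop = FALSE]
  rownames(hits) <- NULL
  list(gene_ids = sort(unique(hits$gene_id)), hits = hits)
}
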