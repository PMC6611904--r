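# Scaled metagene profiles: 3-kb upstream flank (300 x 10-bp bins), gene
# body fitted to 300 equal-fraction bins, 3-kb downstream flank (300
# bins); 900 bins per gene, oriented so bin 1 is always 3 kb upstream of
# the TSS. Per-bin signal is an input-calibrated RPKM ratio.

#' Reads per kilobase per million mapped reads
#'
#' @param count read count in the region.
#' @param region_len_bp region length in bp (> 0).
#' @param library_size_reads total mapped reads (> 0).
#' @return count / ((region_len_bp / 1000) * (library_size_reads / 1e6)).
#' @export
rpkm <- function(count, region_len_bp, library_size_reads) {
  if (any(region_len_bp <= 0)) stop("region length must be > 0")
  if (any(library_size_reads <= 0)) stop("library size must be > 0")
  count / ((region_len_bp / 1000) * (library_size_reads / 1e6))
}

# Map each of L bases to one of `nbins` bins by cumulative rounding:
# base j (0-based) -> floor(j * nbins / L). Every base lands in exactly
# one bin; bins may be empty when L < nbins.
body_bin_of_base <- function(L, nbins = 300L) {
  pmin(as.integer(floor((seq_len(L) - 1) * nbins / L)), nbins - 1L) + 1L
}

# Sum of per-base coverage over bins defined by a base->bin map, plus the
# number of bases per bin. `cs` is c(0, cumsum(per-base coverage)).
bin_mass <- function(cs, from, bins, nbins) {
  # from: 0-based genomic start of base 1 of the mapped stretch
  L <- length(bins)
  mass <- numeric(nbins); nb <- integer(nbins)
  edges <- which(c(TRUE, diff(bins) != 0L))
  starts <- edges; ends <- c(edges[-1L] - 1L, L)
  for (k in seq_along(edges)) {
    b <- bins[starts[k]]
    mass[b] <- cs[from + ends[k] + 1L] - cs[from + starts[k]]
    nb[b] <- ends[k] - starts[k] + 1L
  }
  list(mass = mass, n = nb)
}

#' Metagene profile of one gene
#'
#' Computes the 900-bin profile: 300 upstream bins of
#' `upstream_bp / 300` bp, 300 equal-fraction gene-body bins, 300
#' downstream bins. Per bin, value = (rpkm_chip + c) / (rpkm_input + c)
#' with pseudocount `c`. Flank bins truncated by a chromosome edge, and
#' body bins left empty by a short gene, are NA (missing). Minus-strand
#' genes are flipped so bin 1 always lies 3 kb upstream of the TSS.
#'
#' @param chip,input `cismark_coverage` tracks.
#' @param gene one-row gene data frame.
#' @param upstream_bp,downstream_bp flank widths (default 3000).
#' @param nbins bins per segment (default 300).
#' @param pseudocount ratio stabilizer c (default 1.0).
#' @param chip_cs,input_cs optional precomputed coverage prefix sums for
#'   `gene$chrom` (`c(0, cumsum(per_base_coverage(track, chrom)))`), to
#'   amortize expansion across many genes.
#' @return numeric vector of length `3 * nbins`.
#' @export
gene_profile <- function(chip, input, gene, upstream_bp = 3000L,
                         downstream_bp = 3000L, nbins = 300L,
                         pseudocount = 1.0,
                         chip_cs = NULL, input_cs = NULL) {
  clen <- chrom_sizes(chip)[[gene$chrom]]
  if (gene$end - gene$start > clen) stop("gene longer than chromosome")
  if (is.null(chip_cs)) chip_cs <- c(0, cumsum(per_base_coverage(chip, gene$chrom)))
  if (is.null(input_cs)) input_cs <- c(0, cumsum(per_base_coverage(input, gene$chrom)))
  cs_chip <- chip_cs; cs_input <- input_cs
  rl_chip <- attr(chip, "read_length"); rl_input <- attr(input, "read_length")
  lib_chip <- library_size(chip); lib_input <- library_size(input)
  L <- gene$end - gene$start
  bw_up <- upstream_bp / nbins; bw_dn <- downstream_bp / nbins
  # flank bin edges in gene-oriented coordinates relative to the TSS:
  # upstream [-upstream_bp, 0), body [0, L), downstream [L, L + downstream_bp)
  b_idx <- seq_len(nbins) - 1
  a0 <- c(-upstream_bp + b_idx * bw_up, L + b_idx * bw_dn)
  a1 <- c(-upstream_bp + (b_idx + 1) * bw_up, L + (b_idx + 1) * bw_dn)
  # convert a gene-oriented interval [a, b) (0 = TSS base) to a genomic
  # interval: "+" -> [start + a, start + b); "-" -> [end - b, end - a)
  if (gene$strand == "+") { g0 <- gene$start + a0; g1 <- gene$start + a1 }
  else { g0 <- gene$end - a1; g1 <- gene$end - a0 }
  c0 <- pmax(0, pmin(g0, clen)); c1 <- pmax(0, pmin(g1, clen))
  full <- a1 - a0
  ok <- (c1 - c0) >= full & full > 0  # truncated at an edge -> missing
  r_ch <- rpkm((cs_chip[c1 + 1L] - cs_chip[c0 + 1L]) / rl_chip, full, lib_chip)
  r_in <- rpkm((cs_input[c1 + 1L] - cs_input[c0 + 1L]) / rl_input, full, lib_input)
  flank <- ifelse(ok, (r_ch + pseudocount) / (r_in + pseudocount), NA_real_)
  prof <- numeric(3L * nbins)
  prof[seq_len(nbins)] <- flank[seq_len(nbins)]
  prof[2L * nbins + seq_len(nbins)] <- flank[nbins + seq_len(nbins)]
  # body: equal-fraction bins via cumulative rounding over the L bases
  bins <- body_bin_of_base(L, nbins)
  if (gene$strand == "+") {
    bm_ch <- bin_mass(cs_chip, gene$start, bins, nbins)
    bm_in <- bin_mass(cs_input, gene$start, bins, nbins)
  } else {
    # gene-oriented base j sits at genomic end-1-j, so the genomic
    # left-to-right per-base bin map is the reversed gene-oriented map
    rbins <- rev(bins)
    bm_ch <- bin_mass(cs_chip, gene$start, rbins, nbins)
    bm_in <- bin_mass(cs_input, gene$start, rbins, nbins)
  }
  for (b in seq_len(nbins)) {
    if (bm_ch$n[b] == 0L) { prof[nbins + b] <- NA_real_; next }
    r_ch <- rpkm(bm_ch$mass[b] / rl_chip, bm_ch$n[b], lib_chip)
    r_in <- rpkm(bm_in$mass[b] / rl_input, bm_in$n[b], lib_input)
    prof[nbins + b] <- (r_ch + pseudocount) / (r_in + pseudocount)
  }
  prof
}

#' Metagene profiles for a set of genes, with the aggregate curve
#'
#' @param chip,input `cismark_coverage` tracks.
#' @param ann a `cismark_annotation` (>= 1 gene).
#' @param gene_ids optional subset of gene ids (default: all).
#' @param ... passed to [gene_profile()].
#' @return A `cismark_metagene` list: `matrix` (genes x 900, rownames =
#'   gene ids, input row order preserved), `aggregate` (per-bin mean over
#'   genes, NA bins excluded per bin), `gene_ids`, and `bin_scheme`.
#' @export
metagene_matrix <- function(chip, input, ann, gene_ids = NULL, ...) {
  if (is.null(gene_ids)) gene_ids <- ann$gene_id
  if (length(gene_ids) == 0L) stop("empty gene list")
  rows <- match(gene_ids, ann$gene_id)
  if (anyNA(rows)) stop("unknown gene id: ", gene_ids[is.na(rows)][1L])
  covs <- list()
  for (chrom in unique(ann$chrom[rows]))
    covs[[chrom]] <- list(chip = c(0, cumsum(per_base_coverage(chip, chrom))),
                          input = c(0, cumsum(per_base_coverage(input, chrom))))
  mat <- t(vapply(rows, function(i) {
    chrom <- ann$chrom[i]
    gene_profile(chip, input, ann[i, ],
                 chip_cs = covs[[chrom]]$chip,
                 input_cs = covs[[chrom]]$input, ...)
  }, numeric(900L)))
  rownames(mat) <- gene_ids
  structure(list(matrix = mat,
                 aggregate = colMeans(mat, na.rm = TRUE),
                 gene_ids = gene_ids,
                 bin_scheme = list(upstream_bp = 3000L, body_bins = 300L,
                                   downstream_bp = 3000L, bins = 900L)),
            class = "cismark_metagene")
}

#' Mean gene-body signal downstream of the TSS
#'
#' The per-gene scalar used for group comparisons: the mean over the 300
#' scaled gene-body bins (bins 301-600 of the 900-bin profile), NA bins
#' excluded.
#'
#' @param profile_row 900-bin numeric vector (or a matrix of rows).
#' @return numeric scalar (or vector, one per row); NA when the whole
#'   body is missing.
#' @export
tss_downstream_signal <- function(profile_row) {
  if (is.matrix(profile_row))
    return(apply(profile_row[, 301:600, drop = FALSE], 1L,
                 function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)))
  x <- profile_row[301:600]
  if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs evaluated at
#' the pooled sorted values; p is the standard two-sided asymptotic
#' Kolmogorov approximation.
#'
#' @param a,b numeric vectors (>= 2 finite values each).
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 finite values")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}
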