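test_that("rpkm follows its defining formula and scale invariance", {
  expect_equal(rpkm(1000, 1000, 1e6), 1000)
  expect_equal(rpkm(0, 500, 2e6), 0)
  expect_equal(rpkm(123, 700, 3e6), rpkm(246, 700, 6e6))
  expect_error(rpkm(1, 0, 1e6), "length")
  expect_error(rpkm(1, 100, 0), "library")
})

test_that("chip identical to input gives a flat profile of ones", {
  sizes <- c(chr1 = 20000L)
  tr <- uniform_track(sizes, value = 2)
  gene <- data.frame(gene_id = "g", chrom = "chr1", start = 8000L,
                     end = 10000L, strand = "+", stringsAsFactors = FALSE)
  prof <- gene_profile(tr, tr, gene)
  expect_length(prof, 900L)
  expect_equal(prof, rep(1, 900L))
})

test_that("5'-planted enrichment lands in the first half of the gene body", {
  cfg <- sim_config(n_genes = 1L, chrom_len = 1e5L,
                    gene_len_range = c(2000L, 2000L),
                    intergenic_len_range = c(10000L, 10000L),
                    enrich_fold = 8, depth = 20)
  ann <- simulate_annotation(cfg, seed = 50L)
  cov <- simulate_coverage(ann, ann$gene_id, cfg, seed = 51L)
  prof <- gene_profile(cov$chip, cov$input, ann[1L, ])
  body <- prof[301:600]
  # enrichment covers [TSS, TSS+1kb) = first half of the 2-kb body
  expect_lte(which.max(body), 150L)
  expect_gt(mean(body[1:150]), 2 * mean(body[151:300]))
})

test_that("body bin boundaries equal the cumulative-rounding partition", {
  L <- 1234L; nbins <- 300L
  bins <- cismark:::body_bin_of_base(L, nbins)
  # oracle: bin i (0-based) holds bases [ceil(i*L/n), ceil((i+1)*L/n))
  for (i in seq_len(nbins) - 1L) {
    lo <- ceiling(i * L / nbins); hi <- ceiling((i + 1L) * L / nbins)
    expect_identical(which(bins == i + 1L), seq_len(L)[(lo + 1L):hi],
                     info = paste("bin", i))
  }
  expect_equal(length(bins), L)
  expect_true(all(diff(bins) >= 0L))
  # short bodies leave some bins empty, never double-filled
  b40 <- cismark:::body_bin_of_base(40L, 300L)
  expect_equal(length(b40), 40L)
  expect_equal(anyDuplicated(b40), 0L)
})

test_that("minus-strand genes are orientation-flipped onto the same axis", {
  # asymmetric coverage: high on the left half of the chromosome
  sizes <- c(chr1 = 40000L)
  iv <- data.frame(chrom = "chr1", start = c(0L, 20000L),
                   end = c(20000L, 40000L), value = c(8, 1))
  chip <- coverage_track(iv, sizes)
  input <- uniform_track(sizes)
  gp <- data.frame(gene_id = "p", chrom = "chr1", start = 16000L,
                   end = 22000L, strand = "+", stringsAsFactors = FALSE)
  gm <- data.frame(gene_id = "m", chrom = "chr1", start = 16000L,
                   end = 22000L, strand = "-", stringsAsFactors = FALSE)
  pp <- gene_profile(chip, input, gp)
  pm <- gene_profile(chip, input, gm)
  # the plus gene sees high signal at its 5' end, the minus gene at its 3'
  expect_gt(mean(pp[301:400]), mean(pp[501:600]))
  expect_gt(mean(pm[501:600]), mean(pm[301:400]))
  # mirrored geometry: the minus profile is the reverse of the plus one
  expect_equal(pm, rev(pp), tolerance = 1e-9)
})

test_that("flank bins truncated by the chromosome edge are missing", {
  sizes <- c(chr1 = 6000L)
  tr <- uniform_track(sizes)
  gene <- data.frame(gene_id = "g", chrom = "chr1", start = 1000L,
                     end = 3000L, strand = "+", stringsAsFactors = FALSE)
  prof <- gene_profile(tr, tr, gene)
  # upstream flank needs 3 kb but only 1 kb exists: bins 1-200 missing
  expect_true(all(is.na(prof[1:200])))
  expect_true(all(prof[201:300] == 1))
  expect_true(all(prof[301:600] == 1))
})

test_that("the aggregate is the per-bin mean and matrices keep row order", {
  cfg <- sim_config(n_genes = 50L, chrom_len = 4e5L)
  d <- suppressWarnings(simulate_dataset(cfg, seed = 55L))
  mg <- metagene_matrix(d$chip, d$input, d$annotation)
  expect_equal(dim(mg$matrix), c(50L, 900L))
  expect_identical(rownames(mg$matrix), d$annotation$gene_id)
  # brute-force per-bin mean
  for (b in sample.int(900L, 25L)) {
    v <- mg$matrix[, b]
    expect_equal(mg$aggregate[b], mean(v[!is.na(v)]))
  }
  one <- metagene_matrix(d$chip, d$input, d$annotation,
                         gene_ids = d$annotation$gene_id[3L])
  expect_equal(unname(one$aggregate), unname(one$matrix[1L, ]))
  expect_error(metagene_matrix(d$chip, d$input, d$annotation,
                               gene_ids = character()), "empty")
})

test_that("tss_downstream_signal is the mean over the scaled gene body", {
  expect_equal(tss_downstream_signal(rep(1, 900L)), 1)
  v <- c(rep(0, 300L), rep(2, 300L), rep(0, 300L))
  expect_equal(tss_downstream_signal(v), 2)
  set.seed(60)
  for (i in 1:20) {
    x <- runif(900L)
    expect_equal(tss_downstream_signal(x), mean(x[301:600]))
  }
  x[301:600] <- NA
  expect_true(is.na(tss_downstream_signal(x)))
})

test_that("the KS statistic matches a brute ECDF scan and a permutation p", {
  expect_equal(ks_two_sample(c(1, 2, 3, 4), c(1, 2, 3, 4))$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3, 4), c(1, 2, 3, 4))$p, 1)
  expect_equal(ks_two_sample(c(1, 2, 3), c(4, 5, 6))$D, 1)
  expect_error(ks_two_sample(numeric(), c(1, 2)), "2 finite")

  set.seed(61)
  a <- rnorm(30); b <- rnorm(30, mean = 0.6)
  res <- ks_two_sample(a, b)
  expect_equal(res$D, naive_ks_D(a, b))
  # permutation reference for the p-value
  pooled <- c(a, b)
  perm <- vapply(seq_len(10000L), function(i) {
    idx <- sample.int(60L, 30L)
    naive_ks_D(pooled[idx], pooled[-idx])
  }, numeric(1L))
  p_perm <- mean(perm >= res$D - 1e-12)
  expect_lt(abs(res$p - p_perm), 0.02)
})

test_that("gene-body signal separates enriched from background genes", {
  cfg <- sim_config(n_genes = 100L, chrom_len = 8e5L, enrich_fold = 8,
                    depth = 20)
  ann <- simulate_annotation(cfg, seed = 63L)
  enriched <- sort(sample(ann$gene_id, 50L))
  cov <- simulate_coverage(ann, enriched, cfg, seed = 64L)
  mg <- metagene_matrix(cov$chip, cov$input, ann)
  sig <- tss_downstream_signal(mg$matrix)
  res <- ks_two_sample(sig[enriched], sig[setdiff(ann$gene_id, enriched)])
  expect_lt(res$p, 0.01)
})
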