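test_that("revcomp matches a lookup-table oracle and is an involution", {
  expect_identical(revcomp("CGGAAAT"), "ATTTCCG")
  expect_identical(revcomp(""), "")
  expect_error(revcomp("ACGX"), "IUPAC")
  set.seed(5)
  for (i in 1:200) {
    s <- random_dna(sample(1:40, 1))
    expect_identical(revcomp(s), naive_revcomp(s))
    expect_identical(revcomp(revcomp(s)), s)
  }
})

test_that("promoter extraction follows the 2-kb strand-aware convention", {
  genome <- c(chr1 = random_dna(6000))
  g_plus <- data.frame(gene_id = "p", chrom = "chr1", start = 5000L,
                       end = 5500L, strand = "+", stringsAsFactors = FALSE)
  pr <- extract_promoter(g_plus, genome)
  expect_equal(c(pr$start, pr$end, pr$length), c(3000, 5000, 2000))
  expect_false(pr$truncated)
  expect_identical(pr$seq, substr(genome[["chr1"]], 3001, 5000))

  # minus-strand gene near the right edge: truncated to 1 kb, sequence
  # reverse-complemented into gene orientation
  g_minus <- data.frame(gene_id = "m", chrom = "chr1", start = 4000L,
                        end = 5000L, strand = "-", stringsAsFactors = FALSE)
  pr <- extract_promoter(g_minus, genome)
  expect_equal(c(pr$start, pr$end, pr$length), c(5000, 6000, 1000))
  expect_true(pr$truncated)
  expect_identical(pr$seq, naive_revcomp(substr(genome[["chr1"]], 5001, 6000)))

  expect_error(extract_promoter(
    data.frame(gene_id = "x", chrom = "chrZ", start = 1L, end = 2L,
               strand = "+"), genome), "missing")
})

test_that("scanning the 9-bp element finds exactly one 7-bp core match", {
  h <- scan_pattern("TACGGAAAT", "CGGAAAT", both_strands = TRUE)
  expect_equal(nrow(h), 1L)
  expect_equal(nchar(h$matched_seq), 7L)
  expect_identical(h$matched_seq, "CGGAAAT")
})

test_that("TSS-relative coordinates have no zero and anchor -989..-983", {
  # place the pattern so its 5'-most base sits 989 bp upstream of the TSS
  u <- 2000L
  prom <- random_dna(u)
  off <- u - 989L  # 0-based promoter offset
  substr(prom, off + 1L, off + 7L) <- "CGGAAAT"
  h <- scan_pattern(prom, "CGGAAAT")
  row <- h[h$offset == off, ]
  expect_equal(row$tss_start, -989L)
  expect_equal(row$tss_end, -983L)
  # the base immediately 5' of the TSS is -1
  prom2 <- paste0(random_dna(100), "CGGAAAT")
  h2 <- scan_pattern(prom2, "CGGAAAT")
  expect_true(-1L %in% h2$tss_end)
  expect_false(any(h2$tss_start == 0L | h2$tss_end == 0L))
})

test_that("scan_pattern equals a naive all-positions substring search", {
  set.seed(13)
  pat <- "CGGAAAT"
  rc <- naive_revcomp(pat)
  for (i in 1:200) {
    s <- random_dna(2000)
    h <- scan_pattern(s, pat, both_strands = TRUE)
    fwd <- naive_find(s, pat)
    rev <- naive_find(s, rc)
    expect_identical(sort(h$offset[h$strand_of_match == "+"]), fwd)
    expect_identical(sort(h$offset[h$strand_of_match == "-"]), rev)
  }
  # overlapping occurrences are all reported
  h <- scan_pattern("AAAAAA", "AAA", both_strands = FALSE)
  expect_equal(h$offset, 0:3)
  # pattern longer than the sequence is an empty result, not an error
  expect_equal(nrow(scan_pattern("ACG", "ACGTACGT")), 0L)
})

test_that("IUPAC codes in the pattern match expansions; subject ambiguity never matches", {
  h <- scan_pattern("ACGT", "ANGT")
  expect_equal(nrow(h[h$strand_of_match == "+", ]), 1L)
  expect_equal(nrow(scan_pattern("ANGT", "ACGT", both_strands = FALSE)), 0L)
})

test_that("gene-level element calling recovers the planted truth exactly", {
  cfg <- sim_config(n_genes = 100L, chrom_len = 6e5L, element_rate = 0.1)
  ann <- simulate_annotation(cfg, seed = 21L)
  sq <- suppressWarnings(simulate_sequences(ann, cfg, seed = 22L))
  res <- genes_with_element(ann, sq$genome)
  expect_identical(res$gene_ids, sq$element_genes)
  # reported TSS-relative hit coordinates equal the planted coordinates
  planted <- sq$planted[order(sq$planted$gene_id), ]
  hits <- res$hits[match(planted$gene_id, res$hits$gene_id), ]
  expect_equal(hits$tss_start, planted$tss_start)
  expect_equal(hits$tss_end, planted$tss_end)
})

test_that("a planted minus-strand element appears in forward orientation in its promoter", {
  cfg <- sim_config(n_genes = 60L, chrom_len = 4e5L, element_rate = 0.5)
  ann <- simulate_annotation(cfg, seed = 31L)
  sq <- suppressWarnings(simulate_sequences(ann, cfg, seed = 32L))
  minus <- intersect(sq$element_genes, ann$gene_id[ann$strand == "-"])
  expect_gt(length(minus), 0L)
  genome <- sq$genome
  for (g in minus) {
    pr <- extract_promoter(ann[ann$gene_id == g, ], genome)
    expect_true(length(naive_find(pr$seq, "CGGAAAT")) >= 1L)
  }
})

test_that("element scanning is symmetric under genome mirroring", {
  cfg <- sim_config(n_genes = 40L, chrom_len = 3e5L, element_rate = 0.4)
  ann <- simulate_annotation(cfg, seed = 41L)
  sq <- suppressWarnings(simulate_sequences(ann, cfg, seed = 42L))
  clen <- chrom_sizes(ann)[["chr1"]]
  mirrored_genome <- c(chr1 = naive_revcomp(sq$genome[["chr1"]]))
  flipped <- annotation(data.frame(
    gene_id = ann$gene_id, chrom = ann$chrom,
    start = clen - ann$end, end = clen - ann$start,
    strand = ifelse(ann$strand == "+", "-", "+"),
    stringsAsFactors = FALSE), chrom_sizes(ann))
  a <- genes_with_element(ann, sq$genome)
  b <- genes_with_element(flipped, mirrored_genome)
  expect_identical(a$gene_ids, b$gene_ids)
})

test_that("degenerate motif inputs behave as specified", {
  # empty annotation -> empty set
  empty <- annotation(data.frame(gene_id = character(), chrom = character(),
                                 start = integer(), end = integer(),
                                 strand = character()), c(chr1 = 1000L))
  res <- genes_with_element(empty, c(chr1 = random_dna(1000)))
  expect_length(res$gene_ids, 0L)
  expect_equal(nrow(res$hits), 0L)
  # the long flowering-repressor element is found when a promoter carries it
  pat <- "CCAAATTTTAAGTTT"
  genome <- c(chr1 = random_dna(5000))
  substr(genome[["chr1"]], 3100, 3100 + nchar(pat) - 1L) <- pat
  ann <- annotation(data.frame(gene_id = "g1", chrom = "chr1", start = 4000L,
                               end = 4500L, strand = "+",
                               stringsAsFactors = FALSE), c(chr1 = 5000L))
  expect_identical(genes_with_element(ann, genome, pat)$gene_ids, "g1")
})
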