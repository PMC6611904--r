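test_that("down-regulation filtering uses strict fold and q thresholds", {
  deg <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    log2fc = c(-log2(1.5), -log2(1.5) - 1e-9, -1, -1, 2),
    q_value = c(0.01, 0.01, 0.01, 0.05, 0.001))
  # exactly 1.5-fold is excluded ("more than"); q = 0.05 is excluded
  expect_identical(filter_downregulated(deg), c("b", "c"))
})

test_that("overlap summaries reproduce the worked percentages and Venn counts", {
  a <- sprintf("x%03d", 1:132)
  b <- c(a[1:100], sprintf("y%03d", 1:500))
  s <- overlap_summary(list(candidates = a, enriched = b),
                       percent_of = "candidates")
  expect_equal(s$intersection_all, 100L)
  expect_equal(s$percent, 75.8)

  expect_equal(overlap_summary(list(A = c("p", "q"), B = c("r")))$intersection_all, 0L)
  expect_equal(overlap_summary(list(A = c("p", "q"), B = c("r")))$percent, 0)
  expect_error(overlap_summary(list(A = "p", B = "q"), percent_of = "C"),
               "unknown")

  # region counts match brute-force membership enumeration on random sets
  set.seed(70)
  universe <- sprintf("g%03d", 1:200)
  for (i in 1:10) {
    sets <- list(A = sample(universe, 80), B = sample(universe, 50),
                 C = sample(universe, 120))
    s3 <- overlap_summary(sets)
    for (region in names(s3$regions)) {
      parts <- strsplit(region, "&", fixed = TRUE)[[1]]
      inside <- setdiff(parts, parts[startsWith(parts, "!")])
      outside <- sub("^!", "", parts[startsWith(parts, "!")])
      n <- sum(vapply(universe, function(g)
        all(vapply(inside, function(s) g %in% sets[[s]], logical(1L))) &&
          !any(vapply(outside, function(s) g %in% sets[[s]], logical(1L))),
        logical(1L)))
      expect_equal(unname(s3$regions[region]), n, info = region)
    }
    expect_equal(sum(s3$regions), length(unique(unlist(sets))))
  }
})

test_that("hypergeometric tails match exhaustive subset enumeration", {
  expect_equal(hypergeom_tail(10, 4, 3, 0), 1)
  expect_equal(hypergeom_tail(10, 4, 3, 4), 0)
  expect_error(hypergeom_tail(5, 7, 2, 1), "bounds")
  # enumerate all C(N, k) subsets for small N
  for (case in list(c(10, 4, 3), c(8, 5, 4), c(6, 3, 2))) {
    N <- case[1]; K <- case[2]; k <- case[3]
    subsets <- utils::combn(N, k)
    marked <- seq_len(K)
    stat <- apply(subsets, 2L, function(s) sum(s %in% marked))
    for (obs in 0:(k + 1)) {
      expect_equal(hypergeom_tail(N, K, k, obs), mean(stat >= obs),
                   tolerance = 1e-12,
                   info = sprintf("N=%d K=%d k=%d obs=%d", N, K, k, obs))
    }
  }
})

test_that("the resampling null reports the worked exceedance arithmetic", {
  pool <- sprintf("g%04d", 1:1731)
  # construct a pool in which the observed count is never reached, then
  # check the derived fields directly on a seeded run
  res <- resample_null(pool, enriched_ids = pool[1:800], observed = 100L,
                       set_size = 132L, n_sets = 1000L, seed = 9L)
  expect_equal(res$empirical_percent, 100 * res$exceed_count / 1000)
  expect_equal(res$empirical_p_plus1, (res$exceed_count + 1) / 1001)
  expect_equal(res$N, 1731L)
  expect_true(all(res$null_counts >= 0 & res$null_counts <= 132))
  # observed 0 with tail ">=" qualifies every set
  res0 <- resample_null(pool, pool[1:10], observed = 0L, set_size = 5L,
                        n_sets = 200L, seed = 2L)
  expect_equal(res0$empirical_percent, 100)
  # reproducibility and seed sensitivity
  res_b <- resample_null(pool, pool[1:800], 100L, 132L, 1000L, seed = 9L)
  expect_identical(res$null_counts, res_b$null_counts)
  res_c <- resample_null(pool, pool[1:800], 100L, 132L, 1000L, seed = 10L)
  expect_false(identical(res$null_counts, res_c$null_counts))
  expect_error(resample_null(pool[1:5], pool[1:2], 1L, set_size = 10L),
               "pool")
})

test_that("the empirical tail agrees with the exact hypergeometric tail", {
  # N=6, K=3, k=2: exact tail enumerable over all C(6,2)=15 subsets
  pool <- letters[1:6]; marked <- letters[1:3]
  subsets <- utils::combn(6, 2)
  stat <- apply(subsets, 2L, function(s) sum(s %in% 1:3))
  B <- 20000L
  for (obs in 0:2) {
    exact <- mean(stat >= obs)
    res <- resample_null(pool, marked, observed = obs, set_size = 2L,
                         n_sets = B, seed = 77L)
    se <- sqrt(exact * (1 - exact) / B)
    expect_lt(abs(res$empirical_percent / 100 - exact), 3 * se + 1e-12)
    expect_equal(res$hypergeom_tail, exact, tolerance = 1e-12)
  }
})

test_that("empirical exceedance is non-increasing in the observed statistic", {
  pool <- sprintf("g%03d", 1:60)
  marked <- pool[1:25]
  pcts <- vapply(0:12, function(obs)
    resample_null(pool, marked, obs, set_size = 12L, n_sets = 2000L,
                  seed = 5L)$empirical_percent, numeric(1L))
  expect_true(all(diff(pcts) <= 0))
})

test_that("the integration analysis wires candidates, pool, and null together", {
  element <- sprintf("e%03d", 1:40)
  down <- c(element[1:20], sprintf("d%03d", 1:100))
  enriched <- c(element[1:15], sprintf("d%03d", 1:30))
  res <- run_integration(element, down, enriched, n_sets = 500L, seed = 4L)
  expect_identical(res$candidates, sort(element[1:20]))
  expect_equal(res$observed, 15L)
  expect_equal(res$resampling$N, 100L)   # pool = down \ element
  expect_equal(res$resampling$K, 30L)
  expect_equal(res$resampling$set_size, 20L)
  expect_equal(nrow(res$candidate_table), 20L)
  expect_equal(sum(res$candidate_table$enriched), 15L)

  # empty candidate set takes the warning path with no resampling
  expect_warning(res0 <- run_integration(c("zz1"), c("d001"), enriched,
                                         n_sets = 100L, seed = 1L),
                 "no candidate")
  expect_null(res0$resampling)
  expect_equal(res0$observed, 0L)
})
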