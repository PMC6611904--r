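# DEG filtering, gene-set intersection, and the resampling null testing
# whether element-containing down-regulated genes are preferentially
# H3K36me3-enriched, with its analytic hypergeometric comparator.

#' Select down-regulated genes from a DEG table
#'
#' Down-regulated means strictly more than `fold`-fold decrease
#' (log2fc < -log2(fold)) with adjusted p strictly below `q_max`.
#'
#' @param deg data.frame with gene_id, log2fc, q_value.
#' @param fold fold-change threshold (default 1.5).
#' @param q_max adjusted-p threshold (default 0.05).
#' @return Sorted character vector of gene ids.
#' @export
filter_downregulated <- function(deg, fold = 1.5, q_max = 0.05) {
  stopifnot(all(c("gene_id", "log2fc", "q_value") %in% names(deg)))
  sort(deg$gene_id[deg$log2fc < -log2(fold) & deg$q_value < q_max])
}

# round-half-up to one decimal, as percentages are conventionally printed
round_half_up1 <- function(x) floor(x * 10 + 0.5) / 10

#' Venn region counts and an intersection percentage for 2-3 gene sets
#'
#' @param sets named list of 2 or 3 character vectors (gene ids).
#' @param percent_of name of the set used as the denominator for the
#'   pairwise percentage (default: the first set).
#' @return list with `regions` (named counts, one per Venn region, names
#'   like "A&B" / "A_only"), `n` (per-set sizes), `intersection_all`
#'   (|A n B [n C]|) and `percent` (100 x intersection / |percent_of|,
#'   rounded half-up to one decimal).
#' @export
overlap_summary <- function(sets, percent_of = names(sets)[1L]) {
  stopifnot(is.list(sets), length(sets) %in% c(2L, 3L),
            !is.null(names(sets)))
  if (!percent_of %in% names(sets))
    stop("unknown denominator set: ", percent_of)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 0L)
    member <- matrix(logical(), 0L, length(sets), dimnames = list(NULL, names(sets)))
  combo_key <- function(m) paste(ifelse(m, names(sets), paste0("!", names(sets))),
                                 collapse = "&")
  key <- if (length(universe)) apply(member, 1L, combo_key) else character()
  all_keys <- apply(as.matrix(expand.grid(rep(list(c(TRUE, FALSE)),
                                              length(sets)))), 1L, combo_key)
  all_keys <- setdiff(all_keys, combo_key(rep(FALSE, length(sets))))
  regions <- table(factor(key, levels = all_keys))
  inter <- Reduce(intersect, sets)
  den <- length(sets[[percent_of]])
  num <- length(intersect(inter, sets[[percent_of]]))
  list(regions = c(regions),
       n = vapply(sets, length, integer(1L)),
       intersection_all = length(inter),
       percent = if (den > 0L) round_half_up1(100 * num / den) else NA_real_)
}

#' Upper hypergeometric tail
#'
#' P(X >= observed) for X ~ Hypergeometric(N, K, k): the probability that
#' a uniform draw of k genes from a pool of N containing K marked genes
#' contains at least `observed` marked genes.
#'
#' @param N pool size.
#' @param K marked genes in the pool.
#' @param k draw size.
#' @param observed threshold count.
#' @return probability in [0, 1].
#' @export
hypergeom_tail <- function(N, K, k, observed) {
  if (K < 0 || K > N || k < 0 || k > N) stop("invalid hypergeometric bounds")
  if (observed <= 0) return(1)
  if (observed > min(k, K)) return(0)
  phyper(observed - 1, K, N - K, k, lower.tail = FALSE)
}

#' Empirical exceedance of an observed statistic over a null sample
#'
#' The convention used throughout: the exceedance percentage is
#' 100 x (number of null sets whose statistic meets or exceeds the
#' observed value) / (number of sets), so 26 qualifying sets out of 1000
#' report 2.6. The (exceed + 1) / (B + 1) estimator is the standard
#' never-zero permutation p-value.
#'
#' @param null_counts integer vector of null statistics.
#' @param observed observed statistic.
#' @param tail "ge" counts null >= observed, "gt" counts null > observed.
#' @return list: exceed_count, empirical_percent, empirical_p_plus1.
#' @export
empirical_exceedance <- function(null_counts, observed, tail = c("ge", "gt")) {
  tail <- match.arg(tail)
  B <- length(null_counts)
  if (B == 0L) stop("empty null sample")
  exceed <- if (tail == "ge") sum(null_counts >= observed)
            else sum(null_counts > observed)
  list(exceed_count = exceed,
       empirical_percent = 100 * exceed / B,
       empirical_p_plus1 = (exceed + 1) / (B + 1))
}

#' Resampling null for gene-set enrichment
#'
#' Draws `n_sets` random sets of `set_size` genes, each uniformly without
#' replacement from `pool_ids` (independently across sets), counts the
#' enriched genes in each, and compares the null distribution with the
#' observed count. Reports the raw empirical exceedance percentage
#' (100 x exceed / n_sets), the (exceed + 1) / (n_sets + 1) p-value
#' estimator, and the analytic hypergeometric tail.
#'
#' @param pool_ids character vector: the resampling pool.
#' @param enriched_ids character vector: enriched genes; ids outside the
#'   pool are dropped with a warning.
#' @param observed observed enriched count in the real set.
#' @param set_size genes per resampled set (default 132).
#' @param n_sets number of sets (default 1000).
#' @param seed integer seed.
#' @param tail "ge" counts null sets with statistic >= observed;
#'   "gt" uses >.
#' @return A `cismark_resampling` list: N, K, set_size, n_sets, observed,
#'   null_counts, exceed_count, empirical_percent, empirical_p_plus1,
#'   hypergeom_tail, tail, seed.
#' @export
resample_null <- function(pool_ids, enriched_ids, observed, set_size = 132L,
                          n_sets = 1000L, seed = 1L, tail = c("ge", "gt")) {
  tail <- match.arg(tail)
  pool_ids <- unique(pool_ids)
  N <- length(pool_ids)
  if (set_size > N) stop("set_size exceeds pool size")
  extra <- setdiff(enriched_ids, pool_ids)
  if (length(extra) > 0L)
    warning(length(extra), " enriched ids outside the pool were dropped")
  marked <- pool_ids %in% enriched_ids
  K <- sum(marked)
  set.seed(seed)
  null_counts <- vapply(seq_len(n_sets), function(i)
    sum(marked[sample.int(N, set_size)]), integer(1L))
  emp <- empirical_exceedance(null_counts, observed, tail)
  structure(list(N = N, K = K, set_size = as.integer(set_size),
                 n_sets = as.integer(n_sets), observed = as.integer(observed),
                 null_counts = null_counts, exceed_count = emp$exceed_count,
                 empirical_percent = emp$empirical_percent,
                 empirical_p_plus1 = emp$empirical_p_plus1,
                 hypergeom_tail = hypergeom_tail(
                   N, K, set_size,
                   if (tail == "ge") observed else observed + 1L),
                 tail = tail, seed = as.integer(seed)),
            class = "cismark_resampling")
}

#' Element / down-regulation / H3K36me3 integration analysis
#'
#' Candidate direct targets are the element-containing down-regulated
#' genes; the observed statistic is how many of them are
#' H3K36me3-enriched. The null resamples sets of the same size from the
#' down-regulated genes that lack the element.
#'
#' @param element_set,down_set,enriched_set character vectors of gene ids
#'   over a common universe.
#' @param n_sets resampled sets (default 1000).
#' @param seed integer seed.
#' @param tail passed to [resample_null()].
#' @return list: candidates (element n down), observed (candidates n
#'   enriched, a count), overlap (an [overlap_summary()] of element/down
#'   and of candidates/enriched), resampling (a `cismark_resampling`, or
#'   NULL with a warning when there are no candidates or the pool is too
#'   small), candidate_table (per-candidate enrichment flags).
#' @export
run_integration <- function(element_set, down_set, enriched_set,
                            n_sets = 1000L, seed = 1L, tail = "ge") {
  element_set <- unique(element_set); down_set <- unique(down_set)
  enriched_set <- unique(enriched_set)
  candidates <- sort(intersect(element_set, down_set))
  observed <- length(intersect(candidates, enriched_set))
  pool <- sort(setdiff(down_set, element_set))
  overlap <- list(
    element_down = overlap_summary(list(element = element_set,
                                        down = down_set)),
    candidates_enriched = if (length(candidates) > 0L)
      overlap_summary(list(candidates = candidates,
                           enriched = enriched_set),
                      percent_of = "candidates") else NULL)
  resampling <- NULL
  if (length(candidates) == 0L) {
    warning("no candidate genes (element n down is empty); resampling skipped")
  } else if (length(candidates) > length(pool)) {
    warning("pool smaller than the candidate set; resampling skipped")
  } else {
    resampling <- resample_null(pool, intersect(enriched_set, pool), observed,
                                set_size = length(candidates),
                                n_sets = n_sets, seed = seed, tail = tail)
  }
  list(candidates = candidates, observed = observed, overlap = overlap,
       resampling = resampling,
       candidate_table = data.frame(
         gene_id = candidates,
         enriched = candidates %in% enriched_set,
         stringsAsFactors = FALSE))
}
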