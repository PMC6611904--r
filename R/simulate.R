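# Synthetic genome / coverage / DEG generator. Everything is deterministic
# under (config, seed); the truth sets it returns are exact so downstream
# modules can be scored for parameter recovery.

#' Simulation configuration
#'
#' Defaults describe the standard synthetic study: a 2-Mb chromosome with
#' 500 non-overlapping genes on random strands, the 7-bp element CGGAAAT
#' planted in 20% of promoters, ChIP enrichment of fold 8 over a
#' background of 20 reads per 200-bp window confined to the first 1 kb
#' downstream of the TSS of enriched genes, and a DEG table in which
#' element genes are down-regulated with probability 0.4 versus 0.15 for
#' the rest (so the non-element down-regulated pool stays larger than the
#' candidate set, as in real knockdown data). Intergenic gaps start at
#' 1.5 kb so a called island, including its bridged overhang, cannot
#' reach across a gap into a neighbouring gene's 1-kb upstream region.
#'
#' @param n_genes number of genes.
#' @param chrom_len chromosome length (bp).
#' @param gene_len_range min/max gene length (bp).
#' @param intergenic_len_range min/max gap between consecutive genes (bp).
#' @param pattern element to plant (IUPAC DNA).
#' @param element_rate probability a gene's promoter receives one element.
#' @param upstream promoter length used for planting and rejection (bp).
#' @param enrich_fold ChIP/input fold inside enriched regions (>= 1).
#' @param enrich_len enriched region length downstream of the anchor (bp).
#' @param enrich_anchor "tss" (5'-biased, plant at [TSS, TSS+L)) or "tes"
#'   (3'-biased, plant at (TES-L, TES]).
#' @param depth mean input reads per `window` bp window.
#' @param window simulation window size (bp) for Poisson counts.
#' @param read_length read length for library-size bookkeeping (bp).
#' @param p_down_element probability an element gene is down-regulated.
#' @param p_down_no_element probability a non-element gene is.
#' @param deg_q adjusted p assigned to true DEGs.
#' @param enriched_from "element" couples ChIP enrichment to the element
#'   truth set; "random" draws an independent enriched set.
#' @param enriched_rate used when `enriched_from = "random"`.
#' @param reject_spontaneous remove chance promoter occurrences of the
#'   pattern from the background sequence so the element truth set is
#'   exact (default TRUE).
#' @return A `cismark_sim_config` list.
#' @export
sim_config <- function(n_genes = 500L, chrom_len = 2e6L,
                       gene_len_range = c(500L, 3000L),
                       intergenic_len_range = c(1500L, 2700L),
                       pattern = "CGGAAAT", element_rate = 0.2,
                       upstream = 2000L,
                       enrich_fold = 8, enrich_len = 1000L,
                       enrich_anchor = c("tss", "tes"),
                       depth = 20, window = 200L, read_length = 50L,
                       p_down_element = 0.4, p_down_no_element = 0.15,
                       deg_q = 0.001,
                       enriched_from = c("element", "random"),
                       enriched_rate = 0.2,
                       reject_spontaneous = TRUE) {
  cfg <- list(n_genes = as.integer(n_genes), chrom_len = as.integer(chrom_len),
              gene_len_range = as.integer(gene_len_range),
              intergenic_len_range = as.integer(intergenic_len_range),
              pattern = toupper(pattern), element_rate = element_rate,
              upstream = as.integer(upstream),
              enrich_fold = enrich_fold, enrich_len = as.integer(enrich_len),
              enrich_anchor = match.arg(enrich_anchor),
              depth = depth, window = as.integer(window),
              read_length = as.integer(read_length),
              p_down_element = p_down_element,
              p_down_no_element = p_down_no_element,
              deg_q = deg_q, enriched_from = match.arg(enriched_from),
              enriched_rate = enriched_rate,
              reject_spontaneous = isTRUE(reject_spontaneous))
  probs <- c(cfg$element_rate, cfg$p_down_element, cfg$p_down_no_element,
             cfg$deg_q, cfg$enriched_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$enrich_fold < 1) stop("enrich_fold must be >= 1")
  if (cfg$depth <= 0) stop("depth must be > 0")
  if (cfg$n_genes < 0L) stop("n_genes must be >= 0")
  class(cfg) <- "cismark_sim_config"
  cfg
}

#' Simulate a non-overlapping gene annotation
#'
#' Genes are laid left to right with lengths and gaps drawn uniformly
#' from the configured ranges; strands are assigned uniformly at random.
#'
#' @param cfg a `cismark_sim_config`.
#' @param seed integer seed.
#' @return A `cismark_annotation` on chromosome "chr1".
#' @export
simulate_annotation <- function(cfg, seed = 1L) {
  set.seed(seed)
  sizes <- c(chr1 = cfg$chrom_len)
  if (cfg$n_genes == 0L)
    return(annotation(data.frame(gene_id = character(), chrom = character(),
                                 start = integer(), end = integer(),
                                 strand = character()), sizes))
  lens <- sample.int(cfg$gene_len_range[2L] - cfg$gene_len_range[1L] + 1L,
                     cfg$n_genes, replace = TRUE) + cfg$gene_len_range[1L] - 1L
  gaps <- sample.int(cfg$intergenic_len_range[2L] - cfg$intergenic_len_range[1L] + 1L,
                     cfg$n_genes, replace = TRUE) + cfg$intergenic_len_range[1L] - 1L
  starts <- cumsum(as.numeric(gaps)) + c(0, cumsum(as.numeric(lens)))[seq_len(cfg$n_genes)]
  ends <- starts + lens
  if (ends[cfg$n_genes] > cfg$chrom_len)
    stop("genes do not fit in chrom_len; increase chrom_len or reduce ",
         "n_genes / lengths / gaps")
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  annotation(data.frame(gene_id = ids, chrom = "chr1",
                        start = as.integer(starts), end = as.integer(ends),
                        strand = strand), sizes)
}

promoter_window <- function(gene, upstream, clen) {
  if (gene$strand == "+")
    c(max(0L, gene$start - upstream), gene$start)
  else
    c(gene$end, min(clen, gene$end + upstream))
}

#' Simulate chromosome sequences with planted promoter elements
#'
#' The background is uniform-random ACGT. With `reject_spontaneous`, any
#' chance occurrence of the pattern (either orientation) inside a promoter
#' window is mutated away, so the truth set is exactly the planted genes.
#' Each gene then receives, with probability `element_rate`, one copy of
#' the pattern at a uniform TSS-relative start in [-upstream, -8],
#' oriented with the gene, at a position that does not intersect any
#' other gene's promoter window (so scanning recovers the truth exactly).
#'
#' @param ann a `cismark_annotation`.
#' @param cfg a `cismark_sim_config`.
#' @param seed integer seed.
#' @return list with `genome` (named character vector), `element_genes`
#'   (character vector of planted gene ids) and `planted` (data.frame:
#'   gene_id, tss_start, tss_end of each planted copy).
#' @export
simulate_sequences <- function(ann, cfg, seed = 1L) {
  set.seed(seed)
  sizes <- chrom_sizes(ann)
  pat <- cfg$pattern
  plen <- nchar(pat)
  genome <- lapply(sizes, function(n)
    paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
  proms <- lapply(seq_len(nrow(ann)), function(i)
    promoter_window(ann[i, ], cfg$upstream, sizes[[ann$chrom[i]]]))
  prom_m <- if (nrow(ann) > 0L) do.call(rbind, proms) else
    matrix(integer(), 0L, 2L)
  if (cfg$reject_spontaneous && nrow(ann) > 0L) {
    rc <- revcomp(pat)
    pats <- unique(c(pat, rc))
    for (pass in 1:50) {
      dirty <- FALSE
      for (chrom in names(genome)) {
        wm <- prom_m[ann$chrom == chrom, , drop = FALSE]
        if (nrow(wm) == 0L) next
        subj <- Biostrings::DNAString(genome[[chrom]])
        occ0 <- sort(unique(unlist(lapply(pats, function(p)
          BiocGenerics::start(Biostrings::matchPattern(
            Biostrings::DNAString(p), subj, fixed = "subject")) - 1L))))
        for (p0 in occ0) {
          # only occurrences fully inside some promoter window are hits
          if (!any(wm[, 1L] <= p0 & p0 + plen <= wm[, 2L])) next
          dirty <- TRUE
          old <- substr(genome[[chrom]], p0 + 1L, p0 + 1L)
          substr(genome[[chrom]], p0 + 1L, p0 + 1L) <-
            sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        }
      }
      if (!dirty) break
    }
  }
  element_genes <- character()
  planted <- data.frame(gene_id = character(), tss_start = integer(),
                        tss_end = integer(), stringsAsFactors = FALSE)
  if (nrow(ann) > 0L && cfg$element_rate > 0) {
    pick <- runif(nrow(ann)) < cfg$element_rate
    for (i in which(pick)) {
      gene <- ann[i, ]
      w <- proms[[i]]
      u <- w[2L] - w[1L]
      if (u < plen + 1L) {
        warning("promoter of ", gene$gene_id,
                " too short to host the element; gene excluded from planting")
        next
      }
      # candidate TSS-relative starts: [-u, -8] and fully inside promoter
      cand <- seq(-u, min(-8L, -plen - 1L))
      cand <- cand[cand + plen - 1L <= -1L]
      ok <- FALSE
      for (try in seq_len(200L)) {
        t0 <- sample(cand, 1L)
        # genomic interval of the planted copy
        if (gene$strand == "+") {
          g0 <- gene$start + t0          # t0 negative: left of TSS
          gint <- c(g0, g0 + plen)
        } else {
          g1 <- gene$end - t0            # exclusive right edge
          gint <- c(g1 - plen, g1)
        }
        clash <- any(gint[1L] < prom_m[, 2L] & prom_m[, 1L] < gint[2L] &
                       ann$chrom == gene$chrom & seq_len(nrow(ann)) != i)
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok) {
        warning("no conflict-free planting position for ", gene$gene_id,
                "; gene excluded from planting")
        next
      }
      insert <- if (gene$strand == "+") pat else revcomp(pat)
      substr(genome[[gene$chrom]], gint[1L] + 1L, gint[2L]) <- insert
      element_genes <- c(element_genes, gene$gene_id)
      planted <- rbind(planted,
                       data.frame(gene_id = gene$gene_id, tss_start = t0,
                                  tss_end = t0 + plen - 1L,
                                  stringsAsFactors = FALSE))
    }
  }
  list(genome = unlist(genome), element_genes = sort(element_genes),
       planted = planted)
}

enriched_region <- function(gene, cfg, clen) {
  if (cfg$enrich_anchor == "tss") {
    if (gene$strand == "+") c(gene$start, min(clen, gene$start + cfg$enrich_len))
    else c(max(0L, gene$end - cfg$enrich_len), gene$end)
  } else {
    if (gene$strand == "+") c(max(0L, gene$end - cfg$enrich_len), gene$end)
    else c(gene$start, min(clen, gene$start + cfg$enrich_len))
  }
}

#' Simulate paired ChIP and input coverage with planted enrichment
#'
#' Input counts per `window`-bp window are Poisson(depth) everywhere;
#' ChIP counts are Poisson(depth) outside enriched regions and
#' Poisson(fold x depth) inside the strand-aware region of each enriched
#' gene (partially overlapping windows get a proportionally interpolated
#' rate). Counts are emitted as bedGraph-style coverage whose per-window
#' mass, divided by the read length, recovers the counts exactly.
#'
#' @param ann a `cismark_annotation`.
#' @param enriched_genes character vector of gene ids carrying enrichment.
#' @param cfg a `cismark_sim_config`.
#' @param seed integer seed.
#' @return list with `chip` and `input`, both `cismark_coverage`.
#' @export
simulate_coverage <- function(ann, enriched_genes, cfg, seed = 1L) {
  set.seed(seed)
  sizes <- chrom_sizes(ann)
  W <- cfg$window
  chip_l <- list(); input_l <- list()
  for (chrom in names(sizes)) {
    clen <- sizes[[chrom]]
    starts <- seq(0L, clen - 1L, by = W)
    ends <- pmin(starts + W, clen)
    wlen <- ends - starts
    frac <- numeric(length(starts))  # fraction of each window enriched
    rows <- which(ann$chrom == chrom & ann$gene_id %in% enriched_genes)
    for (i in rows) {
      r <- enriched_region(ann[i, ], cfg, clen)
      ov <- pmax(0L, pmin(ends, r[2L]) - pmax(starts, r[1L]))
      frac <- pmax(frac, ov / wlen)
    }
    lam_in <- cfg$depth * wlen / W
    lam_ch <- lam_in * (1 + (cfg$enrich_fold - 1) * frac)
    input_cnt <- rpois(length(starts), lam_in)
    chip_cnt <- rpois(length(starts), lam_ch)
    mk <- function(cnt) data.frame(chrom = chrom, start = starts, end = ends,
                                   value = cnt * cfg$read_length / wlen,
                                   stringsAsFactors = FALSE)
    input_l[[chrom]] <- mk(input_cnt)
    chip_l[[chrom]] <- mk(chip_cnt)
  }
  list(chip = coverage_track(do.call(rbind, chip_l), sizes, cfg$read_length),
       input = coverage_track(do.call(rbind, input_l), sizes, cfg$read_length))
}

#' Simulate a differential-expression table
#'
#' Each gene is a true down-regulated DEG (log2fc = -log2(U),
#' U ~ Uniform(1.5, 4); q = deg_q) with probability `p_down_element` if
#' it carries the element and `p_down_no_element` otherwise; remaining
#' genes get log2fc ~ Normal(0, 0.2) and q ~ Uniform(0.05, 1).
#'
#' @param ann a `cismark_annotation`.
#' @param element_genes character vector of element-carrying gene ids.
#' @param cfg a `cismark_sim_config`.
#' @param seed integer seed.
#' @return list with `deg` (data.frame gene_id, log2fc, q_value) and
#'   `down_genes` (character vector of true down-regulated ids).
#' @export
simulate_deg <- function(ann, element_genes, cfg, seed = 1L) {
  set.seed(seed)
  n <- nrow(ann)
  has_el <- ann$gene_id %in% element_genes
  p <- ifelse(has_el, cfg$p_down_element, cfg$p_down_no_element)
  down <- runif(n) < p
  log2fc <- numeric(n); q <- numeric(n)
  nd <- sum(down)
  if (nd > 0L) {
    log2fc[down] <- -log2(runif(nd, 1.5, 4))
    q[down] <- cfg$deg_q
  }
  if (nd < n) {
    log2fc[!down] <- rnorm(n - nd, 0, 0.2)
    q[!down] <- runif(n - nd, 0.05, 1)
  }
  list(deg = data.frame(gene_id = ann$gene_id, log2fc = log2fc, q_value = q,
                        stringsAsFactors = FALSE),
       down_genes = sort(ann$gene_id[down]))
}

#' Simulate a complete synthetic dataset
#'
#' Chains annotation, sequence, coverage and DEG simulation with
#' stage-derived seeds, returning the inputs of every downstream stage
#' plus the ground truth.
#'
#' @param cfg a `cismark_sim_config`.
#' @param seed master integer seed; per-stage seeds are derived with
#'   [derive_seed()].
#' @return list: annotation, genome, chip, input, deg (data.frame), and
#'   truth (list: element_genes, enriched_genes, down_genes, seed).
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = 1L) {
  ann <- simulate_annotation(cfg, derive_seed(seed, "annotation"))
  seqs <- simulate_sequences(ann, cfg, derive_seed(seed, "sequences"))
  if (cfg$enriched_from == "element") {
    enriched <- seqs$element_genes
  } else {
    set.seed(derive_seed(seed, "enriched"))
    enriched <- sort(ann$gene_id[runif(nrow(ann)) < cfg$enriched_rate])
  }
  cov <- simulate_coverage(ann, enriched, cfg, derive_seed(seed, "coverage"))
  deg <- simulate_deg(ann, seqs$element_genes, cfg, derive_seed(seed, "deg"))
  list(annotation = ann, genome = seqs$genome, chip = cov$chip,
       input = cov$input, deg = deg$deg,
       truth = list(element_genes = seqs$element_genes,
                    enriched_genes = enriched,
                    down_genes = deg$down_genes, seed = seed))
}
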