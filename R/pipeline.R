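# One seeded end-to-end run: simulate -> scan -> islands -> metagene ->
# integrate, with every stage's output written to one directory and a
# JSON manifest recording parameters, per-stage seeds and file digests.

#' Derive a per-stage seed from a master seed
#'
#' Stage seeds are `(seed * 7919 + hash(stage_name)) mod (2^31 - 1)`,
#' where hash is a small polynomial over the stage-name bytes. Stages are
#' therefore independently reproducible from the master seed alone.
#'
#' @param seed master integer seed.
#' @param stage stage name (character scalar).
#' @return integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483646 + 1)
}

#' Run the full synthetic analysis pipeline
#'
#' Simulates a dataset, scans promoters for the element, calls H3K36me3
#' islands and gene-level enrichment, builds the metagene profile of the
#' candidate genes versus the other enriched genes (compared with a
#' Kolmogorov-Smirnov test on the gene-body signal), and runs the
#' resampling integration analysis. All outputs (genome.fa, genes.bed,
#' chip.bedgraph, input.bedgraph, deg.tsv, truth.json, element_hits.tsv,
#' element_genes.txt, islands.tsv, gene_enrichment.tsv,
#' metagene_aggregate.tsv, integration.json, manifest.json) are written
#' under `out_dir`; deterministic stages reproduce byte-identically under
#' the same seed.
#'
#' @param out_dir output directory (created if missing).
#' @param cfg a [sim_config()].
#' @param seed master integer seed.
#' @param params an [island_params()].
#' @param n_sets resampled null sets (default 1000).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with every in-memory stage result plus
#'   `manifest`.
#' @export
run_pipeline <- function(out_dir, cfg = sim_config(), seed = 1L,
                         params = island_params(), n_sets = 1000L,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  tmp <- tempfile("cismark_run_")
  dir.create(tmp, recursive = TRUE)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp, recursive = TRUE), add = TRUE)

  say("simulate: ", cfg$n_genes, " genes on ", cfg$chrom_len, " bp")
  sim <- simulate_dataset(cfg, seed)
  write_fasta(sim$genome, file.path(tmp, "genome.fa"))
  write_genes_bed(sim$annotation, file.path(tmp, "genes.bed"))
  write_coverage_bedgraph(sim$chip, file.path(tmp, "chip.bedgraph"))
  write_coverage_bedgraph(sim$input, file.path(tmp, "input.bedgraph"))
  write_tsv(sim$deg, file.path(tmp, "deg.tsv"))
  jsonlite::write_json(sim$truth, file.path(tmp, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  say("scan: pattern ", cfg$pattern, ", ", cfg$upstream, " bp promoters")
  scan <- genes_with_element(sim$annotation, sim$genome, cfg$pattern,
                             upstream = cfg$upstream)
  write_tsv(scan$hits, file.path(tmp, "element_hits.tsv"))
  writeLines(scan$gene_ids, con <- file(file.path(tmp, "element_genes.txt"), "wb"))
  close(con)

  say("islands: W=", params$W, " G=", params$G, " fdr=", params$fdr)
  islands <- call_islands(sim$chip, sim$input, params)
  write_tsv(islands, file.path(tmp, "islands.tsv"))
  enrich <- call_gene_enrichment(sim$annotation, islands)
  write_tsv(enrich, file.path(tmp, "gene_enrichment.tsv"))
  enriched_ids <- enrich$gene_id[enrich$enriched]

  say("integrate: B=", n_sets)
  down <- filter_downregulated(sim$deg)
  integ <- run_integration(scan$gene_ids, down, enriched_ids,
                           n_sets = n_sets,
                           seed = derive_seed(seed, "resample"))

  say("metagene: candidates vs other enriched genes")
  metagene <- NULL; ks <- NULL
  cand_enr <- intersect(integ$candidates, enriched_ids)
  other_enr <- setdiff(enriched_ids, integ$candidates)
  if (length(enriched_ids) > 0L) {
    metagene <- metagene_matrix(sim$chip, sim$input, sim$annotation,
                                gene_ids = enriched_ids)
    write_tsv(data.frame(bin = seq_along(metagene$aggregate),
                         value = metagene$aggregate),
              file.path(tmp, "metagene_aggregate.tsv"))
    if (length(cand_enr) >= 2L && length(other_enr) >= 2L) {
      sig <- tss_downstream_signal(metagene$matrix)
      ks <- ks_two_sample(sig[cand_enr], sig[other_enr])
    }
  }

  report <- list(
    n_element_genes = length(scan$gene_ids),
    n_down_genes = length(down),
    n_candidates = length(integ$candidates),
    observed_enriched_candidates = integ$observed,
    n_enriched_genes = length(enriched_ids),
    n_significant_islands = sum(islands$significant),
    overlap_percent = if (!is.null(integ$overlap$candidates_enriched))
      integ$overlap$candidates_enriched$percent else NA,
    empirical_percent = if (!is.null(integ$resampling))
      integ$resampling$empirical_percent else NA,
    empirical_p_plus1 = if (!is.null(integ$resampling))
      integ$resampling$empirical_p_plus1 else NA,
    hypergeom_tail = if (!is.null(integ$resampling))
      integ$resampling$hypergeom_tail else NA,
    ks = ks)
  jsonlite::write_json(report, file.path(tmp, "integration.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  files <- sort(list.files(tmp))
  manifest <- list(
    package = "cismark",
    version = as.character(utils::packageVersion("cismark")),
    method = "sicer-like",
    seed = as.integer(seed),
    stage_seeds = sapply(c("annotation", "sequences", "coverage", "deg",
                           "resample"),
                         function(s) derive_seed(seed, s)),
    config = unclass(cfg),
    island_params = unclass(params),
    n_sets = as.integer(n_sets),
    outputs = files,
    md5 = as.list(tools::md5sum(file.path(tmp, files))),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  names(manifest$md5) <- files
  jsonlite::write_json(manifest, file.path(tmp, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # stage everything, then move into place so failures leave no partials
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (f in list.files(tmp))
    file.copy(file.path(tmp, f), file.path(out_dir, f), overwrite = TRUE)
  ok <- TRUE
  unlink(tmp, recursive = TRUE)
  say("done: ", length(files), " files in ", out_dir)
  invisible(list(sim = sim, scan = scan, islands = islands,
                 enrichment = enrich, integration = integ,
                 metagene = metagene, ks = ks, report = report,
                 manifest = manifest))
}
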