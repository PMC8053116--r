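# End-to-end orchestration: configuration, the two pipelines
# (ribo: simulate -> offsets -> pauses -> occupancy; coip: simulate ->
# enrich), and a manifest that makes every output regenerable.

#' Build and validate a run configuration
#'
#' All parameters of both pipelines in one validated object; the
#' configuration is serialized verbatim into the manifest of every run
#' directory. Validation happens here, before any computation.
#'
#' @param out_dir output directory (created).
#' @param seed global seed; per-stage seeds are fanned out deterministically
#'   with [fan_seed()].
#' @param pipeline "ribo", "coip" or "both".
#' @param n_transcripts,cds_length_range,total_reads,n_replicates footprint
#'   simulation size.
#' @param min_len,max_len inclusive read-length bounds (nt).
#' @param offset_fallback,offset_min_support offset estimation controls.
#' @param pause_window,pause_threshold,min_density pause scoring controls.
#' @param occupancy_site "E", "P", "A" or "all".
#' @param occupancy_weighting expectation weighting mode.
#' @param n_enriched,effect_log2,n_quant_background,quant_replicates,
#'   flagged_fraction quant simulation size.
#' @param width,downshift,min_valid enrichment controls.
#' @return a validated `run_config` list.
#' @export
ribo_config <- function(out_dir,
                        seed = 1L,
                        pipeline = c("both", "ribo", "coip"),
                        n_transcripts = 50L,
                        cds_length_range = c(100L, 300L),
                        total_reads = 50000L,
                        n_replicates = 3L,
                        min_len = 26L, max_len = 34L,
                        offset_fallback = 12L, offset_min_support = 50L,
                        pause_window = 25L, pause_threshold = 10,
                        min_density = 0.5,
                        occupancy_site = "A",
                        occupancy_weighting = "unweighted",
                        n_enriched = 10L, effect_log2 = 4,
                        n_quant_background = 300L, quant_replicates = 3L,
                        flagged_fraction = 0.05,
                        width = 0.3, downshift = 1.8, min_valid = 2L) {
  pipeline <- match.arg(pipeline)
  cfg <- as.list(environment())
  cfg <- cfg[sort(names(cfg))]
  .assert(cfg$pause_threshold >= 0, "pause_threshold must be >= 0")
  .assert(cfg$pause_window >= 1, "pause_window must be >= 1")
  .assert(cfg$min_density >= 0, "min_density must be >= 0")
  .assert(cfg$min_len >= 1 && cfg$max_len >= cfg$min_len,
          "need 1 <= min_len <= max_len")
  .assert(cfg$occupancy_site %in% c("E", "P", "A", "all"),
          "occupancy_site must be E, P, A or all")
  .assert(cfg$occupancy_weighting %in% c("unweighted", "read-weighted"),
          "bad occupancy_weighting")
  .assert(cfg$width > 0 && cfg$downshift >= 0, "bad imputation parameters")
  .assert(cfg$min_valid >= 1, "min_valid must be >= 1")
  .assert(cfg$n_replicates >= 1 && cfg$quant_replicates >= 2,
          "n_replicates >= 1 and quant_replicates >= 2 required")
  structure(cfg, class = "run_config")
}

.run_ribo <- function(cfg, paths) {
  tx <- generate_transcriptome(cfg$n_transcripts, cfg$cds_length_range,
                               seed = fan_seed(cfg$seed, "transcriptome"))
  write_transcriptome(tx, paths("transcriptome.fa"), paths("annotation.tsv"))
  sams <- character(cfg$n_replicates)
  for (r in seq_len(cfg$n_replicates)) {
    truth <- simulation_truth(tx, seed = fan_seed(cfg$seed, paste0("rep", r)))
    sim <- simulate_footprints(tx, truth, cfg$total_reads)
    sams[r] <- paths(sprintf("footprints_rep%d.sam", r))
    write_sam(sim$alignments, tx, sams[r])
    write_truth_json(sim, paths(sprintf("truth_rep%d.json", r)))
  }
  # reload through the I/O layer: the pipeline consumes its own files
  tx2 <- load_transcripts(paths("transcriptome.fa"), paths("annotation.tsv"))
  reps <- lapply(sams, load_alignments, min_len = cfg$min_len,
                 max_len = cfg$max_len, transcripts = tx2)
  names(reps) <- sprintf("rep%d", seq_along(reps))
  merged <- merge_replicates(reps)
  offsets <- estimate_offsets(merged, tx2, cfg$offset_fallback,
                              cfg$offset_min_support)
  write_tsv(offsets, paths("offsets.tsv"))
  write_tsv(frame_qc(merged, offsets, tx2), paths("frame_qc.tsv"))
  profiles <- build_profiles(merged, offsets, tx2, cfg$min_density)
  scores <- pause_scores_all(profiles, cfg$pause_window)
  calls <- call_pauses(scores, cfg$pause_threshold)
  write_tsv(calls, paths("pause_calls.tsv"))
  if (nrow(calls)) {
    write_tsv(rank_paused_codons(calls), paths("codon_ranking.tsv"))
  }
  sites <- if (cfg$occupancy_site == "all") c("E", "P", "A") else cfg$occupancy_site
  for (s in sites) {
    occ <- site_occupancy(merged, offsets, tx2, s, cfg$occupancy_weighting)
    write_tsv(occ$table, paths(sprintf("occupancy_%s.tsv", s)))
    write_tsv(occ$groups, paths(sprintf("occupancy_%s_groups.tsv", s)))
  }
  invisible(NULL)
}

.run_coip <- function(cfg, paths) {
  truth <- quant_sim_truth(n_enriched = cfg$n_enriched,
                           effect_log2 = cfg$effect_log2,
                           n_replicates_per_group = cfg$quant_replicates,
                           flagged_fraction = cfg$flagged_fraction,
                           seed = fan_seed(cfg$seed, "quant"))
  sim <- simulate_quant_table(truth, cfg$n_quant_background)
  write_quant_sim(sim, paths("quant_table.tsv"), paths("quant_truth.json"))
  res <- run_enrichment(sim$table, sim$groups, cfg$min_valid, cfg$width,
                        cfg$downshift, seed = fan_seed(cfg$seed, "impute"))
  write_tsv(res, paths("enrichment_results.tsv"))
  mask <- attr(res, "mask")
  write_tsv(cbind(protein_id = rownames(mask), as.data.frame(mask)),
            paths("imputation_mask.tsv"))
  invisible(NULL)
}

#' Run the configured pipeline(s)
#'
#' Writes all stage outputs plus `manifest.json` (package version,
#' configuration, per-file MD5 checksums — no timestamps, so identical
#' configurations reproduce byte-identical run directories).
#'
#' @param config a `run_config` from [ribo_config()].
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "run_config"), "config must come from ribo_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- function(f) file.path(config$out_dir, f)
  if (config$pipeline %in% c("both", "ribo")) .run_ribo(config, paths)
  if (config$pipeline %in% c("both", "coip")) .run_coip(config, paths)
  files <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- list(
    package = "ribopause",
    version = as.character(utils::packageVersion("ribopause")),
    config = unclass(config),
    checksums = as.list(tools::md5sum(file.path(config$out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, paths("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
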