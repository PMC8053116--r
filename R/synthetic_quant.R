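# Synthetic label-free proteomics quantification tables with known enriched
# proteins, replicate noise, intensity-dependent (left-censored) dropout and
# QC-flagged decoy rows.

#' Ground truth for a quantification-table simulation
#'
#' @param n_enriched number of truly enriched proteins.
#' @param effect_log2 true log2 enrichment (scalar recycled, or one value per
#'   enriched protein) applied in group 1.
#' @param n_replicates_per_group replicates per group (>= 2; the validity
#'   filter requires it).
#' @param sigma replicate standard deviation on the log2 scale.
#' @param baseline_mean,baseline_sd distribution of per-protein baseline
#'   log2 intensity across proteins. Defaults mimic typical LFQ ranges
#'   (log2 intensities ~ 20-30).
#' @param enriched_baseline_mean baseline mean for the enriched proteins
#'   (default: same as `baseline_mean`). Setting it below the dropout
#'   midpoint while the bait-side effect lifts it above models
#'   presence/absence interactors: quantified in the bait pull-down,
#'   censored in the control.
#' @param dropout logistic missing-not-at-random model: a protein value with
#'   true log2 intensity x is missing with probability
#'   `plogis((midpoint - x) / scale)`, non-increasing in x. Use
#'   `dropout_model(0)`-style helpers or NULL for no dropout.
#' @param flagged_fraction fraction of background rows carrying a QC flag
#'   (contaminant / reverse / only-identified-by-site, assigned round-robin).
#' @param seed integer seed.
#' @return an object of class `quant_sim_truth`.
#' @export
quant_sim_truth <- function(n_enriched = 10L,
                            effect_log2 = 4,
                            n_replicates_per_group = 3L,
                            sigma = 0.3,
                            baseline_mean = 25,
                            baseline_sd = 2,
                            enriched_baseline_mean = NULL,
                            dropout = dropout_model(),
                            flagged_fraction = 0,
                            seed = 1L) {
  .assert(n_replicates_per_group >= 2,
          "n_replicates_per_group must be >= 2 (validity filter needs it)")
  .assert(all(is.finite(effect_log2)), "effect sizes must be finite")
  .assert(flagged_fraction >= 0 && flagged_fraction < 1,
          "flagged_fraction must be in [0, 1)")
  if (!is.null(dropout)) {
    .assert(dropout$scale > 0, "dropout scale must be positive")
  }
  enriched <- if (n_enriched > 0) sprintf("HIT%03d", seq_len(n_enriched)) else character(0)
  structure(list(
    enriched_proteins = enriched,
    effect_log2 = stats::setNames(rep_len(effect_log2, n_enriched), enriched),
    dropout_model = dropout,
    n_replicates_per_group = as.integer(n_replicates_per_group),
    sigma = sigma,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    enriched_baseline_mean = enriched_baseline_mean %||% baseline_mean,
    flagged_fraction = flagged_fraction,
    seed = as.integer(seed)), class = "quant_sim_truth")
}

#' Logistic dropout model parameters
#'
#' Missingness probability `plogis((midpoint - x) / scale)` for true log2
#' intensity x: non-increasing in intensity, i.e. left-censored
#' missing-not-at-random, the regime the downshifted-normal imputation
#' presumes. `dropout_model(-Inf)` gives zero dropout everywhere.
#'
#' @param midpoint log2 intensity at which dropout probability is 0.5.
#' @param scale logistic scale (log2 units).
#' @export
dropout_model <- function(midpoint = 20, scale = 1) {
  list(midpoint = midpoint, scale = scale)
}

.dropout_prob <- function(x, model) {
  if (is.null(model)) return(rep(0, length(x)))
  stats::plogis((model$midpoint - x) / model$scale)
}

#' Simulate a protein quantification table
#'
#' Background proteins share equal group means; enriched proteins are
#' shifted by their true effect in group 1 ("bait"). Values are emitted on
#' the linear intensity scale with missing entries generated by the dropout
#' model; a configurable fraction of background rows carries a QC flag.
#'
#' @param truth a `quant_sim_truth`.
#' @param n_background_proteins number of unenriched proteins (>= 1).
#' @return list with `table` (data frame: protein_id, contaminant, reverse,
#'   only_identified_by_site, then one intensity column per sample),
#'   `groups` (named character vector sample -> group) and `truth`.
#' @export
simulate_quant_table <- function(truth, n_background_proteins) {
  .assert(inherits(truth, "quant_sim_truth"), "truth must be a quant_sim_truth")
  .assert(n_background_proteins >= 1, "n_background_proteins must be >= 1")
  set.seed(truth$seed)
  nrep <- truth$n_replicates_per_group
  ids <- c(truth$enriched_proteins,
           sprintf("BG%05d", seq_len(n_background_proteins)))
  n <- length(ids)
  baseline <- stats::rnorm(n, truth$baseline_mean, truth$baseline_sd)
  is_enriched <- ids %in% truth$enriched_proteins
  baseline[is_enriched] <- baseline[is_enriched] -
    truth$baseline_mean + truth$enriched_baseline_mean
  effect <- stats::setNames(rep(0, n), ids)
  effect[truth$enriched_proteins] <- truth$effect_log2
  samples <- c(sprintf("bait_%d", seq_len(nrep)),
               sprintf("control_%d", seq_len(nrep)))
  groups <- stats::setNames(rep(c("bait", "control"), each = nrep), samples)
  mat <- matrix(NA_real_, n, 2 * nrep, dimnames = list(ids, samples))
  for (j in seq_len(2 * nrep)) {
    mu <- baseline + if (groups[j] == "bait") effect else 0
    x <- stats::rnorm(n, mu, truth$sigma)
    miss <- stats::runif(n) < .dropout_prob(x, truth$dropout_model)
    x[miss] <- NA_real_
    mat[, j] <- 2^x
  }
  flags <- matrix(FALSE, n, 3,
                  dimnames = list(ids, c("contaminant", "reverse",
                                         "only_identified_by_site")))
  if (truth$flagged_fraction > 0) {
    bg_ids <- setdiff(ids, truth$enriched_proteins)
    n_flag <- round(truth$flagged_fraction * length(bg_ids))
    pick <- sample(bg_ids, n_flag)
    flags[cbind(match(pick, ids), 1L + (seq_along(pick) - 1L) %% 3L)] <- TRUE
  }
  tab <- data.frame(protein_id = ids,
                    contaminant = flags[, 1],
                    reverse = flags[, 2],
                    only_identified_by_site = flags[, 3],
                    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(mat))
  rownames(tab) <- NULL
  list(table = tab, groups = groups, truth = truth)
}

#' Serialize a quant simulation (table TSV + truth JSON)
#' @param sim result of [simulate_quant_table()].
#' @param table_path,truth_path output paths.
#' @export
write_quant_sim <- function(sim, table_path, truth_path) {
  write_tsv(sim$table, table_path)
  jsonlite::write_json(list(
    enriched_proteins = sim$truth$enriched_proteins,
    effect_log2 = as.list(sim$truth$effect_log2),
    dropout_model = sim$truth$dropout_model,
    n_replicates_per_group = sim$truth$n_replicates_per_group,
    sigma = sim$truth$sigma,
    flagged_fraction = sim$truth$flagged_fraction,
    groups = as.list(sim$groups),
    seed = sim$truth$seed),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(table = table_path, truth = truth_path))
}
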