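# Label-free co-IP interactome enrichment.
#
# Fixed pipeline order: QC flag filtering -> log2 transform + group
# validity filter -> left-shifted normal imputation -> per-protein
# two-group Student's t-test. Imputing before the validity filter would
# change results and is not expressible with these interfaces.

.FLAG_COLS <- c("contaminant", "reverse", "only_identified_by_site")

.flag_true <- function(x) {
  if (is.logical(x)) return(x & !is.na(x))
  x <- as.character(x)
  !is.na(x) & x %in% c("+", "TRUE", "true", "1", "yes")
}

.sample_cols <- function(table, groups) {
  .assert(all(names(groups) %in% names(table)),
          "group assignment names samples missing from the table: %s",
          paste(setdiff(names(groups), names(table)), collapse = ", "))
  .assert(length(unique(groups)) == 2, "exactly 2 groups required")
  names(groups)
}

#' Remove QC-flagged rows
#'
#' Drops rows flagged as potential contaminant, reverse (decoy) hit, or
#' only-identified-by-site. Flag columns may be logical or MaxQuant-style
#' "+" markers.
#'
#' @param table quant table with the three flag columns.
#' @return filtered table; removal tally in attribute `removed`.
#' @export
qc_filter <- function(table) {
  missing <- setdiff(.FLAG_COLS, names(table))
  .assert(length(missing) == 0, "missing flag column(s): %s",
          paste(missing, collapse = ", "))
  flagged <- Reduce(`|`, lapply(table[.FLAG_COLS], .flag_true))
  out <- table[!flagged, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(total = sum(flagged))
  out
}

#' log2 transform + group validity filter
#'
#' Intensities are log2-transformed (missing preserved); a protein is kept
#' iff it has at least `min_valid` quantified replicates in at least one
#' group. Proteins quantified in only one group survive — imputation later
#' fills the other group, which is how presence/absence interactors become
#' testable.
#'
#' @param table quant table (linear intensities).
#' @param groups named character vector: sample column -> group label
#'   (exactly 2 groups).
#' @param min_valid minimum quantified replicates in one group (default 2).
#' @return table with intensity columns on the log2 scale.
#' @export
log2_and_validity_filter <- function(table, groups, min_valid = 2L) {
  sc <- .sample_cols(table, groups)
  .assert(min_valid <= max(table(groups)),
          "min_valid exceeds the replicate count of every group")
  vals <- as.matrix(table[sc])
  .assert(all(is.na(vals) | vals > 0),
          "non-positive intensity found: upstream corruption")
  logv <- log2(vals)
  keep <- rep(FALSE, nrow(table))
  for (g in unique(groups)) {
    n_valid <- rowSums(!is.na(logv[, names(groups)[groups == g], drop = FALSE]))
    keep <- keep | n_valid >= min_valid
  }
  out <- table
  out[sc] <- logv
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- c(invalid = sum(!keep))
  attr(out, "scale") <- "log2"
  out
}

#' Impute missing values from a left-shifted normal distribution
#'
#' Column-wise (per sample): missing entries are drawn from
#' `Normal(mean - downshift * SD, (width * SD)^2)` using that column's
#' observed mean and SD, modeling below-detection-limit missingness. A
#' whole-matrix mode is available for sparse columns.
#'
#' @param table quant table on the log2 scale.
#' @param groups named sample -> group vector (identifies sample columns).
#' @param width imputation width as a fraction of the sample SD (default 0.3).
#' @param downshift center shift in multiples of the sample SD (default 1.8).
#' @param seed integer seed; same seed, same imputed values.
#' @param per_sample FALSE pools mean/SD over the whole matrix.
#' @return list: `table` (complete) and `mask` (logical matrix of imputed
#'   cells, proteins x samples).
#' @export
impute_missing <- function(table, groups, width = 0.3, downshift = 1.8,
                           seed = 1L, per_sample = TRUE) {
  sc <- .sample_cols(table, groups)
  vals <- as.matrix(table[sc])
  mask <- is.na(vals)
  set.seed(seed)
  if (per_sample) {
    for (j in seq_along(sc)) {
      obs <- vals[!mask[, j], j]
      if (!any(mask[, j])) next
      .assert(length(obs) >= 2,
              "sample %s has < 2 observed values: SD undefined", sc[j])
      mu <- mean(obs); s <- stats::sd(obs)
      vals[mask[, j], j] <- stats::rnorm(sum(mask[, j]),
                                         mu - downshift * s, width * s)
    }
  } else {
    obs <- vals[!mask]
    if (any(mask)) {
      .assert(length(obs) >= 2, "fewer than 2 observed values in the matrix")
      mu <- mean(obs); s <- stats::sd(obs)
      vals[mask] <- stats::rnorm(sum(mask), mu - downshift * s, width * s)
    }
  }
  out <- table
  out[sc] <- vals
  rownames(mask) <- table$protein_id
  list(table = out, mask = mask)
}

#' Per-protein two-group t-test
#'
#' Two-sided Student's (equal-variance) t-test per protein on log2 values;
#' Welch's test available via `var_equal = FALSE`. `log2_difference` is
#' group 1 mean minus group 2 mean, where group 1 is the first level in
#' `groups` order. Proteins with zero variance in both groups and equal
#' means get t = 0, p = 1 and a flag. No multiple-testing correction by
#' default; `adjust = "BH"` applies Benjamini-Hochberg.
#'
#' @param table complete quant table on the log2 scale (post-imputation).
#' @param groups named sample -> group vector.
#' @param var_equal Student's (TRUE, default) or Welch's (FALSE).
#' @param adjust "none" (default) or "BH".
#' @param mask optional imputation mask to report `n_imputed` per group.
#' @return data frame: protein_id, per-group means, log2_difference,
#'   t_statistic, p_value, neg_log10_p, degenerate flag (and n_imputed_*).
#' @export
enrichment_test <- function(table, groups, var_equal = TRUE,
                            adjust = c("none", "BH"), mask = NULL) {
  adjust <- match.arg(adjust)
  sc <- .sample_cols(table, groups)
  vals <- as.matrix(table[sc])
  .assert(!anyNA(vals), "table has missing values: impute first")
  lv <- unique(groups)
  x <- vals[, names(groups)[groups == lv[1]], drop = FALSE]
  y <- vals[, names(groups)[groups == lv[2]], drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  .assert(n1 >= 2 && n2 >= 2, "need >= 2 replicates per group")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m1 - m2) / se
  degenerate <- se == 0
  tstat[degenerate & m1 == m2] <- 0
  p <- 2 * stats::pt(-abs(tstat), df)
  p[degenerate & m1 == m2] <- 1
  p[degenerate & m1 != m2] <- .Machine$double.xmin  # infinite t, flagged; keeps p > 0
  if (adjust == "BH") p_adj <- stats::p.adjust(p, "BH")
  res <- data.frame(protein_id = table$protein_id,
                    stringsAsFactors = FALSE)
  res[[paste0("mean_log2_", lv[1])]] <- m1
  res[[paste0("mean_log2_", lv[2])]] <- m2
  res$log2_difference <- m1 - m2
  res$t_statistic <- tstat
  res$p_value <- p
  if (adjust == "BH") res$p_adjusted <- p_adj
  res$neg_log10_p <- -log10(pmax(p, .Machine$double.xmin))
  res$degenerate <- degenerate
  if (!is.null(mask)) {
    res[[paste0("n_imputed_", lv[1])]] <-
      rowSums(mask[, names(groups)[groups == lv[1]], drop = FALSE])
    res[[paste0("n_imputed_", lv[2])]] <-
      rowSums(mask[, names(groups)[groups == lv[2]], drop = FALSE])
  }
  res[order(res$p_value), , drop = FALSE] -> res
  rownames(res) <- NULL
  res
}

#' Run the whole enrichment workflow
#'
#' QC filter, log2 + validity filter, imputation, t-test — in that order.
#'
#' @param table raw quant table (linear intensities, flag columns).
#' @param groups named sample -> group vector.
#' @param min_valid validity threshold (default 2).
#' @param width,downshift imputation parameters (defaults 0.3 / 1.8).
#' @param seed imputation seed.
#' @param var_equal,adjust see [enrichment_test()].
#' @return result data frame from [enrichment_test()], with the imputation
#'   mask in attribute `mask`.
#' @export
run_enrichment <- function(table, groups, min_valid = 2L, width = 0.3,
                           downshift = 1.8, seed = 1L, var_equal = TRUE,
                           adjust = "none") {
  tab <- qc_filter(table)
  tab <- log2_and_validity_filter(tab, groups, min_valid)
  imp <- impute_missing(tab, groups, width, downshift, seed)
  res <- enrichment_test(imp$table, groups, var_equal, adjust, mask = imp$mask)
  attr(res, "mask") <- imp$mask
  res
}
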