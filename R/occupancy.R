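# Observed versus expected codon usage at the ribosomal E/P/A sites.
#
# All transcripts with reads contribute — no coverage filter here, unlike
# pause scoring. The expectation is the codon composition of the translated
# transcriptome over the same codon universe; a ratio of ~1 for a codon
# means ribosomes spend no excess time decoding it.

#' Observed codon counts at a ribosomal site
#'
#' @param alignments alignment data frame.
#' @param offsets offset table.
#' @param transcripts a `transcript_set`.
#' @param site one of "E", "P", "A".
#' @param exclude_edge_codons drop the first and last CDS codons from the
#'   counts (default TRUE: initiation/termination artifacts).
#' @param include_stops count stop-codon occupancy too (default FALSE).
#' @return named integer vector of counts over the codon universe, with an
#'   `excluded` attribute tallying out-of-CDS / edge / stop exclusions, and
#'   a `transcripts_with_reads` attribute.
#' @export
observed_site_usage <- function(alignments, offsets, transcripts,
                                site = c("A", "P", "E"),
                                exclude_edge_codons = TRUE,
                                include_stops = FALSE) {
  site <- match.arg(site)
  sites <- assign_sites(alignments, offsets, transcripts)
  idx <- switch(site, E = sites$e_index, P = sites$p_index, A = sites$a_index)
  in_cds <- switch(site, E = sites$e_in_cds, P = sites$p_in_cds,
                   A = sites$a_in_cds)
  nc <- n_codons(transcripts)
  n_out <- sum(!in_cds)
  tx <- sites$transcript_id[in_cds]
  idx <- idx[in_cds]
  n_edge <- 0L
  if (exclude_edge_codons) {
    edge <- idx == 0L | idx == nc[tx] - 1L
    n_edge <- sum(edge)
    tx <- tx[!edge]
    idx <- idx[!edge]
  }
  codons <- cds_codons(transcripts)
  idx_by_tx <- split(idx, tx)
  cod <- unlist(lapply(names(idx_by_tx), function(t) {
    codons[[t]][idx_by_tx[[t]] + 1L]
  }), use.names = FALSE)
  universe <- if (include_stops) ALL_CODONS else sense_codons()
  n_stop <- sum(!cod %in% universe)
  counts <- table(factor(cod[cod %in% universe], levels = universe))
  out <- stats::setNames(as.integer(counts), names(counts))
  attr(out, "excluded") <- c(out_of_cds = n_out, edge = n_edge,
                             stop_codon = n_stop)
  attr(out, "site") <- site
  attr(out, "transcripts_with_reads") <- unique(sites$transcript_id)
  out
}

#' Expected codon frequencies from transcriptome codon usage
#'
#' In `"unweighted"` mode every CDS codon of the restricted transcript set
#' counts once (duplicated ids are de-duplicated); in `"read-weighted"` mode
#' each transcript's codons are weighted by its mapped-read count.
#'
#' @param transcripts a `transcript_set`.
#' @param restrict_to transcript ids to include (default: all). The
#'   occupancy pipeline passes the transcripts that received reads.
#' @param weighting "unweighted" or "read-weighted".
#' @param read_counts named reads-per-transcript vector, required for
#'   read-weighted mode.
#' @param exclude_edge_codons drop first/last CDS codons (default TRUE, to
#'   mirror the observed counts).
#' @param include_stops include stop codons in the universe (default FALSE).
#' @return named numeric vector of frequencies summing to 1.
#' @export
expected_usage <- function(transcripts, restrict_to = NULL,
                           weighting = c("unweighted", "read-weighted"),
                           read_counts = NULL,
                           exclude_edge_codons = TRUE,
                           include_stops = FALSE) {
  weighting <- match.arg(weighting)
  ids <- unique(restrict_to %||% transcripts$id)
  .assert(length(ids) > 0, "empty transcript subset")
  .assert(all(ids %in% transcripts$id), "restrict_to contains unknown ids")
  universe <- if (include_stops) ALL_CODONS else sense_codons()
  codons <- cds_codons(transcripts)[ids]
  if (exclude_edge_codons) {
    codons <- lapply(codons, function(x) x[-c(1L, length(x))])
  }
  w <- if (weighting == "read-weighted") {
    .assert(!is.null(read_counts), "read-weighted mode needs read_counts")
    rc <- read_counts[ids]
    rc[is.na(rc)] <- 0
    rc
  } else {
    stats::setNames(rep(1, length(ids)), ids)
  }
  acc <- stats::setNames(rep(0, length(universe)), universe)
  for (id in ids) {
    cc <- table(factor(codons[[id]][codons[[id]] %in% universe],
                       levels = universe))
    acc <- acc + as.numeric(cc) * w[[id]]
  }
  .assert(sum(acc) > 0, "no codons left after restriction")
  acc / sum(acc)
}

#' Observed/expected codon occupancy
#'
#' @param observed named counts from [observed_site_usage()].
#' @param expected named frequencies from [expected_usage()].
#' @param codon_groups named list of codon sets summarized as the
#'   read-weighted mean of member ratios (defaults: Arg, Gln).
#' @return list of class `site_codon_usage`: `table` (codon,
#'   observed_count, observed_freq, expected_freq, ratio, group) and
#'   `groups` (group, ratio, observed_count). Codons with expected frequency
#'   0 get an NA (observed 0) or Inf (observed > 0) ratio, flagged, never an
#'   error.
#' @export
observed_over_expected <- function(observed, expected,
                                   codon_groups = codon_groups_default()) {
  .assert(setequal(names(observed), names(expected)),
          "observed and expected must cover the same codon set")
  expected <- expected[names(observed)]
  obs_freq <- observed / sum(observed)
  ratio <- ifelse(expected > 0, obs_freq / expected,
                  ifelse(observed > 0, Inf, NA_real_))
  grp <- rep(NA_character_, length(observed))
  for (g in names(codon_groups)) {
    grp[names(observed) %in% codon_groups[[g]]] <- g
  }
  tab <- data.frame(codon = names(observed),
                    observed_count = as.integer(observed),
                    observed_freq = as.numeric(obs_freq),
                    expected_freq = as.numeric(expected),
                    ratio = as.numeric(ratio),
                    group = grp,
                    stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(names(codon_groups), function(g) {
    sel <- tab$codon %in% codon_groups[[g]]
    w <- tab$observed_count[sel]
    data.frame(group = g,
               ratio = if (sum(w) > 0)
                 sum(tab$ratio[sel] * w) / sum(w) else NA_real_,
               observed_count = sum(w),
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, groups = groups,
                 site = attr(observed, "site") %||% NA_character_),
            class = "site_codon_usage")
}

#' @export
print.site_codon_usage <- function(x, ...) {
  cat(sprintf("site_codon_usage (%s site): %d codons, %d reads\n",
              x$site, nrow(x$table), sum(x$table$observed_count)))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' One-call occupancy analysis for a site
#'
#' Maps sites, restricts the expectation to transcripts with reads, and
#' returns observed/expected ratios.
#'
#' @inheritParams observed_site_usage
#' @param weighting expectation weighting mode (see [expected_usage()]).
#' @export
site_occupancy <- function(alignments, offsets, transcripts,
                           site = c("A", "P", "E"),
                           weighting = c("unweighted", "read-weighted"),
                           exclude_edge_codons = TRUE,
                           include_stops = FALSE) {
  site <- match.arg(site)
  weighting <- match.arg(weighting)
  obs <- observed_site_usage(alignments, offsets, transcripts, site,
                             exclude_edge_codons, include_stops)
  with_reads <- attr(obs, "transcripts_with_reads")
  rc <- NULL
  if (weighting == "read-weighted") {
    rc <- table(alignments$transcript_id)
    rc <- stats::setNames(as.numeric(rc), names(rc))
  }
  exp_f <- expected_usage(transcripts, restrict_to = with_reads,
                          weighting = weighting, read_counts = rc,
                          exclude_edge_codons = exclude_edge_codons,
                          include_stops = include_stops)
  observed_over_expected(obs, exp_f)
}
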