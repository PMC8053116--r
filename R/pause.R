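# Codon-resolution pause detection.
#
# Per transcript, P-site reads are binned per CDS codon; transcripts with a
# mean density >= 0.5 reads/codon (inclusive) are scored. The pause strength
# at codon i is a z-score against the local background, assuming a Poisson
# read distribution:
#
#     z_i = (d_i - max(bg_i)) / (max(bg_i) * 0.5)
#
# where bg_i are the counts over the flanking window (default 25 codons on
# each side, excluding codon i, truncated at the CDS edges) and max(bg) is
# floored at 1 read. Codons whose entire flanking window holds zero reads
# are not scorable. Calls are made at z >= 10 (inclusive).

#' Build per-codon P-site density profiles
#'
#' One profile per transcript whose mean density passes `min_mean_density`
#' (inclusive); other transcripts are excluded from pause scoring (the
#' occupancy analysis works directly from site assignments and applies no
#' such filter).
#'
#' @param alignments alignment data frame (replicates already merged).
#' @param offsets offset table.
#' @param transcripts a `transcript_set`.
#' @param min_mean_density minimum mean P-site reads per codon (default 0.5).
#' @return named list of `codon_density_profile` objects (transcript_id,
#'   counts, mean_density, n_codons, codons).
#' @export
build_profiles <- function(alignments, offsets, transcripts,
                           min_mean_density = 0.5) {
  if (nrow(alignments) == 0) {
    warning("empty alignment set: no profiles built", call. = FALSE)
    return(list())
  }
  sites <- assign_sites(alignments, offsets, transcripts)
  sites <- sites[sites$p_in_cds, , drop = FALSE]
  nc <- n_codons(transcripts)
  codons <- cds_codons(transcripts)
  by_tx <- split(sites$p_index, sites$transcript_id)
  profiles <- lapply(names(by_tx), function(id) {
    counts <- tabulate(by_tx[[id]] + 1L, nbins = nc[[id]])
    structure(list(transcript_id = id,
                   counts = counts,
                   mean_density = sum(counts) / nc[[id]],
                   n_codons = nc[[id]],
                   codons = codons[[id]]),
              class = "codon_density_profile")
  })
  names(profiles) <- names(by_tx)
  profiles[vapply(profiles, function(p) p$mean_density >= min_mean_density,
                  logical(1))]
}

# max over the flanking window (w codons each side, focal excluded,
# truncated at the vector edges), computed by shifting + pmax.
.flank_max <- function(counts, window) {
  n <- length(counts)
  m <- rep(-Inf, n)
  for (k in seq_len(min(window, n - 1))) {
    m <- pmax(m, c(counts[-seq_len(k)], rep(-Inf, k)))       # i + k
    m <- pmax(m, c(rep(-Inf, k), counts[seq_len(n - k)]))    # i - k
  }
  m
}

#' Pause z-scores for one density profile
#'
#' @param profile a `codon_density_profile`.
#' @param window flanking window half-width in codons (default 25). A window
#'   larger than the CDS degenerates to full-CDS-minus-focal background.
#' @param floor_value floor applied to max(background) to avoid division by
#'   zero (default 1 read).
#' @return data frame: transcript_id, codon_index (0-based), codon, count,
#'   background_max, z, scorable, is_edge (start or stop codon).
#' @export
pause_scores <- function(profile, window = 25L, floor_value = 1) {
  .assert(inherits(profile, "codon_density_profile"),
          "profile must come from build_profiles()")
  .assert(window >= 1, "window must be >= 1")
  counts <- profile$counts
  n <- profile$n_codons
  fm <- .flank_max(counts, window)
  scorable <- is.finite(fm) & fm > 0
  bg_max <- pmax(fm, floor_value)
  z <- (counts - bg_max) / (bg_max * 0.5)
  z[!scorable] <- NA_real_
  data.frame(transcript_id = profile$transcript_id,
             codon_index = seq_len(n) - 1L,
             codon = profile$codons,
             count = counts,
             background_max = ifelse(scorable, bg_max, NA_real_),
             z = z,
             scorable = scorable,
             is_edge = seq_len(n) %in% c(1L, n),
             stringsAsFactors = FALSE)
}

#' Score all profiles
#'
#' @param profiles list from [build_profiles()].
#' @inheritParams pause_scores
#' @return one data frame of per-codon scores across transcripts.
#' @export
pause_scores_all <- function(profiles, window = 25L, floor_value = 1) {
  out <- lapply(profiles, pause_scores, window = window,
                floor_value = floor_value)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res %||% data.frame()
}

#' Call pauses at a z threshold
#'
#' Retains exactly the scorable codons with `z >= threshold` (inclusive).
#' Start/stop codons remain callable but stay flagged via `is_edge`, since
#' initiation and termination peaks are not elongation pauses.
#'
#' @param scores score data frame from [pause_scores_all()].
#' @param threshold minimum pause score (default 10).
#' @export
call_pauses <- function(scores, threshold = 10) {
  if (nrow(scores) == 0) return(scores)
  out <- scores[scores$scorable & !is.na(scores$z) & scores$z >= threshold, ,
                drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank codon identities by pause frequency
#'
#' Counts calls per sense-codon identity and reports each identity's
#' fraction of all sense-codon calls; all 61 sense codons are listed (zeros
#' included), ordered by descending count with alphabetical tie-break.
#' Calls at stop codons (possible only at the terminal CDS codon) are
#' excluded from the ranking.
#'
#' @param calls data frame from [call_pauses()].
#' @return data frame: codon, n_pauses, fraction.
#' @export
rank_paused_codons <- function(calls) {
  sc <- sense_codons()
  if (nrow(calls) == 0) {
    warning("no pause calls: empty ranking", call. = FALSE)
    return(data.frame(codon = character(0), n_pauses = integer(0),
                      fraction = numeric(0)))
  }
  cod <- calls$codon[calls$codon %in% sc]
  counts <- table(factor(cod, levels = sc))
  out <- data.frame(codon = names(counts),
                    n_pauses = as.integer(counts),
                    fraction = as.numeric(counts) / sum(counts),
                    stringsAsFactors = FALSE)
  out[order(-out$n_pauses, out$codon), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Share of pause calls per codon group, across conditions
#'
#' For each named codon group (defaults: the 6 Arg and 2 Gln codons) and
#' each condition, reports the group's share of all pause calls — the
#' descriptive statistic used to compare pausing between conditions.
#'
#' @param condition_tables named list of ranking tables from
#'   [rank_paused_codons()], one per condition (>= 2).
#' @param codon_groups named list of codon sets.
#' @return data frame: group, condition, fraction, n_pauses.
#' @export
compare_pause_fractions <- function(condition_tables,
                                    codon_groups = codon_groups_default()) {
  .assert(length(condition_tables) >= 2, "need >= 2 conditions")
  sc <- sense_codons()
  for (g in names(codon_groups)) {
    bad <- setdiff(codon_groups[[g]], sc)
    .assert(length(bad) == 0, "unknown codon(s) in group %s: %s", g,
            paste(bad, collapse = ", "))
  }
  rows <- list()
  for (cond in names(condition_tables)) {
    tab <- condition_tables[[cond]]
    total <- sum(tab$n_pauses)
    for (g in names(codon_groups)) {
      sel <- tab$codon %in% codon_groups[[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, condition = cond,
        fraction = if (total > 0) sum(tab$n_pauses[sel]) / total else NA_real_,
        n_pauses = sum(tab$n_pauses[sel]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
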