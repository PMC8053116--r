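# P-site offset estimation and E/P/A-site codon assignment.
#
# The offset for a read length L is the distance from the 5' end to the
# first nucleotide of the P-site codon. It is estimated from reads whose 5'
# end lies upstream of an annotated start codon (initiating ribosomes carry
# the start codon in the P-site): for such reads cds_start - start is a
# direct observation of the offset. The per-length mode of these candidates,
# restricted to the plausible window [9, L-9], is taken; lengths with thin
# support fall back to a canonical 12 nt.

#' Estimate per-read-length P-site offsets
#'
#' @param alignments alignment data frame.
#' @param transcripts a `transcript_set`.
#' @param fallback offset used for lengths without a trustworthy estimate
#'   (default 12 nt, the canonical eukaryotic 5'->P-site distance).
#' @param min_support minimum number of start-proximal candidate reads per
#'   length before an estimate is trusted (default 50).
#' @return offset table: data frame (length, offset, support, source) with
#'   one row per read length present in `alignments`.
#' @export
estimate_offsets <- function(alignments, transcripts, fallback = 12L,
                             min_support = 50L) {
  lengths_present <- sort(unique(alignments$length))
  cds_start <- stats::setNames(transcripts$cds_start, transcripts$id)
  d <- cds_start[alignments$transcript_id] - alignments$start
  len <- alignments$length
  # start-proximal candidates within the plausible window [9, L - 9]
  cand <- !is.na(d) & d >= 9 & d <= len - 9 & d + len > 0
  tab <- data.frame(length = lengths_present,
                    offset = as.integer(fallback),
                    support = 0L,
                    source = "fallback",
                    stringsAsFactors = FALSE)
  for (k in seq_along(lengths_present)) {
    L <- lengths_present[k]
    dd <- d[cand & len == L]
    tab$support[k] <- length(dd)
    if (length(dd) >= min_support) {
      counts <- table(dd)
      best <- as.integer(names(counts)[counts == max(counts)])
      # tie on the mode broken toward the value closest to the fallback
      best <- best[order(abs(best - fallback), best)][1]
      tab$offset[k] <- best
      tab$source[k] <- "estimated"
    }
  }
  tab
}

.offset_lookup <- function(offsets, lengths) {
  m <- match(lengths, offsets$length)
  .assert(!anyNA(m), "no offset available for read length(s): %s",
          paste(unique(lengths[is.na(m)]), collapse = ", "))
  offsets$offset[m]
}

#' Assign E-, P- and A-site codons to footprints
#'
#' The P-site codon index within the CDS is
#' `floor((start + offset - cds_start) / 3)`; E = P - 1 and A = P + 1.
#' Sites whose index falls outside `[0, n_codons)` are flagged out-of-CDS.
#' The reading frame `(start + offset - cds_start) mod 3` is recorded for
#' periodicity QC; out-of-frame P-sites still map to the containing codon
#' via floor division.
#'
#' @param alignments alignment data frame.
#' @param offsets offset table from [estimate_offsets()] (or any data frame
#'   with `length` and `offset` columns).
#' @param transcripts a `transcript_set`.
#' @return data frame: transcript_id, p_index, e_index, a_index (0-based
#'   codon indices), p_in_cds / e_in_cds / a_in_cds flags, frame.
#' @export
assign_sites <- function(alignments, offsets, transcripts) {
  off <- .offset_lookup(offsets, alignments$length)
  cds_start <- stats::setNames(transcripts$cds_start, transcripts$id)
  nc <- n_codons(transcripts)
  .assert(all(alignments$transcript_id %in% transcripts$id),
          "alignments reference transcripts absent from the set")
  rel <- alignments$start + off - cds_start[alignments$transcript_id]
  p <- floor(rel / 3)
  n <- nc[alignments$transcript_id]
  res <- data.frame(transcript_id = alignments$transcript_id,
                    p_index = as.integer(p),
                    e_index = as.integer(p - 1),
                    a_index = as.integer(p + 1),
                    frame = as.integer(((rel %% 3) + 3) %% 3),
                    stringsAsFactors = FALSE)
  res$p_in_cds <- res$p_index >= 0 & res$p_index < n
  res$e_in_cds <- res$e_index >= 0 & res$e_index < n
  res$a_in_cds <- res$a_index >= 0 & res$a_index < n
  rownames(res) <- NULL
  res
}

#' Frame-periodicity QC per read length
#'
#' Fraction of in-CDS P-site assignments in each reading frame, per length.
#'
#' @inheritParams assign_sites
#' @return data frame: length, n, frame0, frame1, frame2.
#' @export
frame_qc <- function(alignments, offsets, transcripts) {
  sites <- assign_sites(alignments, offsets, transcripts)
  keep <- sites$p_in_cds
  len <- alignments$length[keep]
  fr <- sites$frame[keep]
  out <- lapply(sort(unique(len)), function(L) {
    f <- fr[len == L]
    data.frame(length = L, n = length(f),
               frame0 = mean(f == 0), frame1 = mean(f == 1),
               frame2 = mean(f == 2))
  })
  do.call(rbind, out)
}
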