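# Reading transcriptome-space alignments and applying the read-length
# selection of the footprinting protocol.

#' Load footprint alignments from a SAM/BAM file
#'
#' Retains primary, mapped, forward-strand alignments whose aligned
#' reference span lies within `[min_len, max_len]` (inclusive on both ends,
#' matching the 26-34 nt size-selection window). The effective length is the
#' reference span from the CIGAR, not the raw read length, so soft-clipped
#' bases do not count. SAM's 1-based positions are converted to 0-based at
#' this boundary. Discarded records are tallied by reason in the
#' `"discarded"` attribute.
#'
#' @param path SAM or BAM file of transcript-space alignments.
#' @param min_len,max_len inclusive length bounds in nt.
#' @param transcripts optional `transcript_set`; alignments to reference
#'   names absent from it are skipped (and counted).
#' @return data frame (transcript_id, start, length, flag) with attributes
#'   `discarded` (named integer) and `transcript_ids` (reference names from
#'   the header).
#' @export
load_alignments <- function(path, min_len = 26L, max_len = 34L,
                            transcripts = NULL) {
  .assert(min_len >= 1 && max_len >= min_len,
          "need 1 <= min_len <= max_len")
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    path
  } else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("flag", "rname", "pos", "cigar")))[[1]]
  hdr_ids <- names(Rsamtools::scanBamHeader(bam)[[1]]$targets)
  flag <- res$flag
  unmapped <- is.na(res$pos) | bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  reverse <- bitwAnd(flag, 16L) > 0L
  span <- rep(NA_integer_, length(flag))
  ok_cigar <- !is.na(res$cigar)
  span[ok_cigar] <- GenomicAlignments::cigarWidthAlongReferenceSpace(
    res$cigar[ok_cigar])
  out_of_range <- !unmapped & !is.na(span) & (span < min_len | span > max_len)
  unknown_ref <- rep(FALSE, length(flag))
  if (!is.null(transcripts)) {
    unknown_ref <- !unmapped & !(as.character(res$rname) %in% transcripts$id)
  }
  keep <- !unmapped & !secondary & !reverse & !out_of_range & !unknown_ref
  discarded <- c(unmapped = sum(unmapped),
                 secondary_or_supplementary = sum(secondary & !unmapped),
                 reverse_strand = sum(reverse & !unmapped & !secondary),
                 out_of_length_range = sum(out_of_range & !secondary & !reverse),
                 unknown_reference = sum(unknown_ref & !secondary & !reverse &
                                           !out_of_range))
  aln <- data.frame(transcript_id = as.character(res$rname)[keep],
                    start = res$pos[keep] - 1L,
                    length = span[keep],
                    flag = flag[keep],
                    stringsAsFactors = FALSE)
  attr(aln, "discarded") <- discarded
  attr(aln, "transcript_ids") <- hdr_ids
  aln
}

#' Apply the read-length filter to an in-memory alignment set
#'
#' Inclusive on both bounds; idempotent.
#'
#' @param alignments alignment data frame.
#' @param min_len,max_len inclusive bounds in nt.
#' @export
filter_lengths <- function(alignments, min_len = 26L, max_len = 34L) {
  out <- alignments[alignments$length >= min_len &
                      alignments$length <= max_len, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("discarded", "transcript_ids")) {
    attr(out, a) <- attr(alignments, a)
  }
  out
}

#' Merge replicate alignment sets
#'
#' Concatenates replicate alignments (the pause pipeline merges replicates
#' before offset calculation and P-site mapping). Per-replicate provenance
#' is kept in a `replicate` column and a read tally attribute. Sets aligned
#' against different transcript sets are a hard error.
#'
#' @param alignment_sets list of alignment data frames (named or not).
#' @return one alignment data frame with a `replicate` column and a
#'   `replicate_reads` attribute.
#' @export
merge_replicates <- function(alignment_sets) {
  .assert(is.list(alignment_sets) && length(alignment_sets) >= 1,
          "alignment_sets must be a non-empty list")
  ids <- lapply(alignment_sets, attr, "transcript_ids")
  known <- ids[!vapply(ids, is.null, logical(1))]
  if (length(known) > 1) {
    ref <- sort(known[[1]])
    same <- vapply(known, function(x) identical(sort(x), ref), logical(1))
    .assert(all(same), "replicates aligned to different transcript sets")
  }
  nm <- names(alignment_sets) %||% paste0("rep", seq_along(alignment_sets))
  nm[nm == ""] <- paste0("rep", which(nm == ""))
  pieces <- Map(function(a, n) {
    a$replicate <- rep(n, nrow(a))
    a
  }, alignment_sets, nm)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "replicate_reads") <- vapply(alignment_sets, nrow, integer(1))
  if (length(known)) attr(out, "transcript_ids") <- known[[1]]
  out
}
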