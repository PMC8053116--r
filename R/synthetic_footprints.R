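# Synthetic ribosome-profiling data: ground-truth transcriptomes and
# footprint alignments with known abundances, codon dwell times, injected
# pauses, read-length distribution and 5'->P-site offsets. Downstream stages
# are tested against the truth records these generators emit.

#' Generate a synthetic transcriptome
#'
#' Each transcript is a 5' UTR, a CDS starting with ATG and ending with a
#' single stop codon (no internal stops, guaranteed because internal codons
#' are drawn from the sense-codon usage vector), and a 3' UTR. UTRs default
#' to 50 nt so that footprints up to 34 nt whose P-site sits on the first or
#' last CDS codons remain fully mappable.
#'
#' @param n_transcripts number of transcripts.
#' @param cds_length_range integer vector of length 2: CDS length range in
#'   codons, start and stop codons included. Minimum 20.
#' @param codon_usage `"uniform"` or a named probability vector over the 61
#'   sense codons (must sum to 1, non-negative).
#' @param utr5_length,utr3_length UTR lengths in nt.
#' @param seed integer seed.
#' @return a `transcript_set`.
#' @export
generate_transcriptome <- function(n_transcripts,
                                   cds_length_range = c(100L, 300L),
                                   codon_usage = "uniform",
                                   utr5_length = 50L,
                                   utr3_length = 50L,
                                   seed = 1L) {
  .assert(n_transcripts >= 1, "n_transcripts must be >= 1")
  .assert(length(cds_length_range) == 2 && cds_length_range[1] >= 20,
          "cds_length_range must be two values with minimum >= 20 codons")
  usage <- .validate_codon_usage(codon_usage)
  set.seed(seed)
  len_choices <- seq(cds_length_range[1], cds_length_range[2])
  lens <- len_choices[sample.int(length(len_choices), n_transcripts,
                                 replace = TRUE)]
  sc <- names(usage)
  seqs <- vapply(lens, function(n_cod) {
    internal <- sample(sc, n_cod - 2L, replace = TRUE, prob = usage)
    stop_cd <- sample(stop_codons(), 1L)
    utr5 <- paste(sample(c("A", "C", "G", "T"), utr5_length, replace = TRUE),
                  collapse = "")
    utr3 <- paste(sample(c("A", "C", "G", "T"), utr3_length, replace = TRUE),
                  collapse = "")
    paste0(utr5, "ATG", paste(internal, collapse = ""), stop_cd, utr3)
  }, character(1))
  new_transcript_set(data.frame(
    id = sprintf("tx%04d", seq_len(n_transcripts)),
    sequence = seqs,
    cds_start = as.integer(utr5_length),
    cds_end = as.integer(utr5_length + 3L * lens),
    stringsAsFactors = FALSE))
}

#' Construct the ground-truth record for a footprint simulation
#'
#' @param transcripts a `transcript_set`.
#' @param abundances expected read count share per transcript (named, or NULL
#'   for equal abundances). Only relative values matter.
#' @param dwell_weights named relative dwell time per sense codon (strictly
#'   positive; NULL = all 1). Rescaled to mean 1.
#' @param injected_pauses data frame with columns `transcript_id`,
#'   `codon_index` (0-based, within the CDS) and `fold` (> 1), or NULL.
#' @param offset_by_length named numeric: read length -> true 5'->P-site
#'   offset in nt. Default 12 nt at every length 26-34.
#' @param length_distribution named probability vector over read lengths;
#'   default uniform over 26-34 nt, the size-selection window of the
#'   protocol being emulated.
#' @param site `"P"` (dwell acts on the P-site codon, default) or `"A"`
#'   (dwell acts on the A-site codon).
#' @param start_peak fold elevation of initiation (P-site on the start
#'   codon), emulating the initiation peak of real libraries; it is also
#'   what makes start-anchored offset estimation identifiable.
#' @param seed integer seed used by [simulate_footprints()].
#' @return an object of class `simulation_truth`.
#' @export
simulation_truth <- function(transcripts,
                             abundances = NULL,
                             dwell_weights = NULL,
                             injected_pauses = NULL,
                             offset_by_length = NULL,
                             length_distribution = NULL,
                             site = c("P", "A"),
                             start_peak = 5,
                             seed = 1L) {
  site <- match.arg(site)
  sc <- sense_codons()
  if (is.null(abundances)) {
    abundances <- stats::setNames(rep(1, nrow(transcripts)), transcripts$id)
  }
  .assert(all(transcripts$id %in% names(abundances)),
          "abundances must cover every transcript id")
  abundances <- abundances[transcripts$id]
  .assert(all(abundances >= 0) && sum(abundances) > 0,
          "abundances must be non-negative with positive sum")
  if (is.null(dwell_weights)) {
    dwell_weights <- stats::setNames(rep(1, length(sc)), sc)
  }
  .assert(all(sc %in% names(dwell_weights)),
          "dwell_weights must cover all 61 sense codons")
  dwell_weights <- dwell_weights[sc]
  .assert(all(dwell_weights > 0), "dwell weights must be strictly positive")
  dwell_weights <- dwell_weights / mean(dwell_weights)
  if (is.null(offset_by_length)) {
    offset_by_length <- stats::setNames(rep(12, 9), 26:34)
  }
  if (is.null(length_distribution)) {
    length_distribution <- stats::setNames(rep(1 / 9, 9), 26:34)
  }
  .assert(abs(sum(length_distribution) - 1) < 1e-8,
          "length_distribution must sum to 1")
  .assert(all(names(length_distribution) %in% names(offset_by_length)),
          "offset_by_length must cover the length_distribution support")
  if (!is.null(injected_pauses)) {
    .assert(all(c("transcript_id", "codon_index", "fold") %in%
                  names(injected_pauses)),
            "injected_pauses needs columns transcript_id, codon_index, fold")
    .assert(all(injected_pauses$fold > 1), "injected fold elevations must be > 1")
    nc <- n_codons(transcripts)
    .assert(all(injected_pauses$transcript_id %in% transcripts$id),
            "injected pause on unknown transcript")
    .assert(all(injected_pauses$codon_index >= 0 &
                  injected_pauses$codon_index <
                  nc[injected_pauses$transcript_id]),
            "injected pause codon_index outside its CDS")
  }
  structure(list(transcript_abundances = abundances,
                 dwell_weights = dwell_weights,
                 injected_pauses = injected_pauses,
                 offset_by_length = offset_by_length,
                 length_distribution = length_distribution,
                 site = site,
                 start_peak = start_peak,
                 seed = as.integer(seed)),
            class = "simulation_truth")
}

# Per-position sampling weights for the ribosome site codon on one transcript.
# In P mode the weight indexes the P-site codon (positions 0..n-2; the stop
# codon is never a P-site). In A mode it indexes the A-site codon a = p+1
# (so p ranges 0..n-3 and the A-site never sits on the stop).
.position_weights <- function(codons, truth, tx_id) {
  n <- length(codons)
  if (truth$site == "P") {
    idx <- seq_len(n - 1L)            # P-site codon positions 0..n-2 (1-based idx)
    w <- truth$dwell_weights[codons[idx]]
  } else {
    idx <- seq_len(n - 2L)            # P positions 0..n-3; weight by codon at p+1
    w <- truth$dwell_weights[codons[idx + 1L]]
  }
  w <- as.numeric(w)
  w[1L] <- w[1L] * truth$start_peak
  ip <- truth$injected_pauses
  if (!is.null(ip)) {
    ip <- ip[ip$transcript_id == tx_id, , drop = FALSE]
    for (k in seq_len(nrow(ip))) {
      j <- ip$codon_index[k]          # pause codon index (site codon)
      p_pos <- if (truth$site == "P") j else j - 1L
      if (p_pos >= 0 && p_pos < length(w)) {
        w[p_pos + 1L] <- w[p_pos + 1L] * ip$fold[k]
      }
    }
  }
  w
}

#' Simulate ribosome footprint alignments
#'
#' Per transcript, the read count is Poisson with mean proportional to its
#' abundance. Each read's P-site codon is drawn proportionally to the codon
#' dwell weights (times injected fold elevations), its length from the truth
#' length distribution, and its 5' end placed so that
#' `5' end + offset_by_length[len]` is the first nucleotide of the P-site
#' codon. Reads that would extend past either transcript end are resampled,
#' never truncated.
#'
#' @param transcripts a `transcript_set`.
#' @param truth a `simulation_truth`.
#' @param total_reads expected total read count across transcripts.
#' @return list with `alignments` (data frame: transcript_id, start, length,
#'   flag), `truth_counts` (named list: per-transcript integer vector of true
#'   P-site codon counts) and `truth`.
#' @export
simulate_footprints <- function(transcripts, truth, total_reads) {
  .assert(nrow(transcripts) > 0, "empty transcript list")
  .assert(inherits(truth, "simulation_truth"), "truth must be a simulation_truth")
  set.seed(truth$seed)
  ab <- truth$transcript_abundances / sum(truth$transcript_abundances)
  n_reads <- stats::rpois(nrow(transcripts), total_reads * ab)
  lens_support <- as.integer(names(truth$length_distribution))
  codons_all <- cds_codons(transcripts)
  nc <- n_codons(transcripts)
  out <- vector("list", nrow(transcripts))
  truth_counts <- vector("list", nrow(transcripts))
  names(truth_counts) <- transcripts$id
  for (i in seq_len(nrow(transcripts))) {
    id <- transcripts$id[i]
    m <- n_reads[i]
    truth_counts[[id]] <- integer(nc[[id]])
    if (m == 0) next
    w <- .position_weights(codons_all[[id]], truth, id)
    tx_len <- nchar(transcripts$sequence[i])
    cds_start <- transcripts$cds_start[i]
    pos <- sample.int(length(w), m, replace = TRUE, prob = w) - 1L  # P position
    len <- lens_support[sample.int(length(lens_support), m, replace = TRUE,
                                   prob = truth$length_distribution)]
    start <- cds_start + 3L * pos - as.integer(truth$offset_by_length[as.character(len)])
    bad <- start < 0L | start + len > tx_len
    tries <- 0L
    while (any(bad)) {
      tries <- tries + 1L
      .assert(tries <= 100, "cannot place reads on transcript %s; UTRs too short?", id)
      k <- sum(bad)
      pos[bad] <- sample.int(length(w), k, replace = TRUE, prob = w) - 1L
      len[bad] <- lens_support[sample.int(length(lens_support), k,
                                          replace = TRUE,
                                          prob = truth$length_distribution)]
      start[bad] <- cds_start + 3L * pos[bad] -
        as.integer(truth$offset_by_length[as.character(len[bad])])
      bad <- start < 0L | start + len > tx_len
    }
    truth_counts[[id]] <- tabulate(pos + 1L, nbins = nc[[id]])
    out[[i]] <- data.frame(transcript_id = id, start = start,
                           length = len, flag = 0L,
                           stringsAsFactors = FALSE)
  }
  aln <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(aln)) {
    aln <- data.frame(transcript_id = character(0), start = integer(0),
                      length = integer(0), flag = integer(0))
  }
  list(alignments = aln, truth_counts = truth_counts, truth = truth)
}

#' Write footprint alignments as a SAM file
#'
#' Emits a minimal transcript-space SAM (header with one `@SQ` line per
#' transcript, forward-strand records with fully-matching CIGAR). This is
#' the simulator's output contract; reading goes through Rsamtools.
#'
#' @param alignments alignment data frame (transcript_id, start 0-based,
#'   length, flag).
#' @param transcripts a `transcript_set` (for sequence lengths and read
#'   sequences).
#' @param path output SAM path.
#' @export
write_sam <- function(alignments, transcripts, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", transcripts$id,
                   nchar(transcripts$sequence)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(alignments)) {
    seq_by_id <- stats::setNames(transcripts$sequence, transcripts$id)
    rseq <- substr(rep(seq_by_id[alignments$transcript_id], 1),
                   alignments$start + 1L,
                   alignments$start + alignments$length)
    rec <- sprintf("read%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                   seq_len(nrow(alignments)),
                   alignments$flag,
                   alignments$transcript_id,
                   alignments$start + 1L,
                   alignments$length,
                   rseq,
                   strrep("I", alignments$length))
    writeLines(rec, con)
  }
  invisible(path)
}

#' Serialize / restore a simulation truth record (JSON)
#'
#' @param sim result of [simulate_footprints()] (or a bare
#'   `simulation_truth`).
#' @param path JSON path.
#' @export
write_truth_json <- function(sim, path) {
  truth <- if (inherits(sim, "simulation_truth")) sim else sim$truth
  obj <- list(
    transcript_abundances = as.list(truth$transcript_abundances),
    dwell_weights = as.list(truth$dwell_weights),
    injected_pauses = truth$injected_pauses,
    offset_by_length = as.list(truth$offset_by_length),
    length_distribution = as.list(truth$length_distribution),
    site = truth$site,
    start_peak = truth$start_peak,
    seed = truth$seed)
  if (!inherits(sim, "simulation_truth") && !is.null(sim$truth_counts)) {
    obj$truth_counts <- sim$truth_counts
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- structure(list(
    transcript_abundances = unlist(obj$transcript_abundances),
    dwell_weights = unlist(obj$dwell_weights),
    injected_pauses = obj$injected_pauses,
    offset_by_length = unlist(obj$offset_by_length),
    length_distribution = unlist(obj$length_distribution),
    site = obj$site,
    start_peak = obj$start_peak,
    seed = as.integer(obj$seed)), class = "simulation_truth")
  if (!is.null(obj$truth_counts)) {
    attr(truth, "truth_counts") <- lapply(obj$truth_counts, as.integer)
  }
  truth
}
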