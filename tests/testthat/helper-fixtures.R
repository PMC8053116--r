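# Shared fixture builders and independent oracles. Everything is generated
# in code; no binary fixtures.

# A hand-built transcript set: 10 nt UTRs, CDS given as codon strings.
tiny_transcripts <- function(cds_list, utr5 = 10L, utr3 = 40L) {
  seqs <- vapply(cds_list, function(cds) {
    paste0(strrep("AC", ceiling(utr5 / 2)) |> substr(1, utr5),
           paste(cds, collapse = ""),
           strrep("GT", ceiling(utr3 / 2)) |> substr(1, utr3))
  }, character(1))
  structure(data.frame(
    id = names(cds_list) %||% sprintf("t%d", seq_along(cds_list)),
    sequence = seqs,
    cds_start = utr5,
    cds_end = utr5 + vapply(cds_list, function(x) 3L * length(x), integer(1)),
    stringsAsFactors = FALSE),
    class = c("transcript_set", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Alignments placing the P-site of `n` reads on each requested codon of a
# transcript, assuming a fixed offset.
aln_at_codons <- function(transcripts, id, codon_index, n = 1L,
                          offset = 12L, length = 28L) {
  cds_start <- transcripts$cds_start[transcripts$id == id]
  data.frame(transcript_id = id,
             start = rep(cds_start + 3L * codon_index - offset, each = n),
             length = length, flag = 0L,
             stringsAsFactors = FALSE)
}

fixed_offset_table <- function(lengths = 26:34, offset = 12L) {
  data.frame(length = lengths, offset = offset,
             support = NA_integer_, source = "fixed",
             stringsAsFactors = FALSE)
}

# Independent naive oracle for the pause z-score: plain per-codon loop,
# no vectorization shared with the implementation.
naive_pause_z <- function(counts, window = 25L, floor_value = 1) {
  n <- length(counts)
  z <- rep(NA_real_, n)
  bg_max <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    flanks <- c(seq(max(1, i - window), i - 1),
                seq(i + 1, min(n, i + window)))
    flanks <- flanks[flanks >= 1 & flanks <= n & flanks != i]
    bg <- counts[flanks]
    if (all(bg == 0)) next
    m <- max(max(bg), floor_value)
    bg_max[i] <- m
    z[i] <- (counts[i] - m) / (m * 0.5)
  }
  list(z = z, bg_max = bg_max)
}

# Profile object straight from a counts vector (codons synthesized).
profile_from_counts <- function(counts, codons = NULL, id = "tx") {
  structure(list(transcript_id = id,
                 counts = as.integer(counts),
                 mean_density = sum(counts) / length(counts),
                 n_codons = length(counts),
                 codons = codons %||% rep("AAA", length(counts))),
            class = "codon_density_profile")
}

# Write a SAM file from raw record fields (for flag/CIGAR edge cases).
write_raw_sam <- function(path, sq, records) {
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq),
               records), path)
  path
}

# Quant-table fixture with explicit values; vals is a named list
# protein -> numeric vector over samples (NA = missing), linear scale.
quant_fixture <- function(vals, samples, flags = NULL) {
  tab <- data.frame(protein_id = names(vals),
                    contaminant = FALSE, reverse = FALSE,
                    only_identified_by_site = FALSE,
                    stringsAsFactors = FALSE)
  m <- do.call(rbind, vals)
  colnames(m) <- samples
  if (!is.null(flags)) for (f in names(flags)) tab[[f]] <- flags[[f]]
  cbind(tab, as.data.frame(m, row.names = NULL))
}
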