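# Transcript container: a data frame (one row per transcript) carrying the
# sequence and the CDS window in 0-based half-open transcript coordinates.

new_transcript_set <- function(df) {
  structure(df, class = c("transcript_set", "data.frame"))
}

#' Number of CDS codons per transcript
#' @param transcripts a `transcript_set`.
#' @return integer vector named by transcript id.
#' @export
n_codons <- function(transcripts) {
  stats::setNames(as.integer((transcripts$cds_end - transcripts$cds_start) / 3),
                  transcripts$id)
}

#' CDS codon triplets per transcript
#' @param transcripts a `transcript_set`.
#' @return named list of codon character vectors.
#' @export
cds_codons <- function(transcripts) {
  out <- lapply(seq_len(nrow(transcripts)), function(i) {
    split_codons(substr(transcripts$sequence[i],
                        transcripts$cds_start[i] + 1,
                        transcripts$cds_end[i]))
  })
  stats::setNames(out, transcripts$id)
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts, %d-%d CDS codons\n",
              nrow(x),
              if (nrow(x)) min(n_codons(x)) else 0L,
              if (nrow(x)) max(n_codons(x)) else 0L))
  invisible(x)
}

#' Load transcripts from FASTA plus a CDS annotation table
#'
#' The annotation is tab-delimited with columns `transcript_id`, `cds_start`,
#' `cds_end` (0-based, half-open, transcript coordinates). Records whose CDS
#' is malformed (length not divisible by 3, or window outside the sequence)
#' are skipped with a warning; annotation ids missing from the FASTA are a
#' hard error.
#'
#' @param fasta_path transcriptome FASTA.
#' @param annotation_path CDS annotation TSV.
#' @return a `transcript_set`.
#' @export
load_transcripts <- function(fasta_path, annotation_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  .assert(all(c("transcript_id", "cds_start", "cds_end") %in% names(ann)),
          "annotation must have columns transcript_id, cds_start, cds_end")
  missing <- setdiff(ann$transcript_id, names(seqs))
  .assert(length(missing) == 0,
          "annotation references ids absent from FASTA: %s",
          paste(missing, collapse = ", "))
  seq_chr <- as.character(seqs[ann$transcript_id])
  len <- nchar(seq_chr)
  bad_div <- (ann$cds_end - ann$cds_start) %% 3 != 0
  bad_win <- ann$cds_start < 0 | ann$cds_end > len | ann$cds_end <= ann$cds_start
  bad <- bad_div | bad_win
  if (any(bad)) {
    warning(sprintf("skipping %d transcript(s) with malformed CDS: %s",
                    sum(bad), paste(ann$transcript_id[bad], collapse = ", ")),
            call. = FALSE)
  }
  keep <- !bad
  new_transcript_set(data.frame(
    id = ann$transcript_id[keep],
    sequence = seq_chr[keep],
    cds_start = as.integer(ann$cds_start[keep]),
    cds_end = as.integer(ann$cds_end[keep]),
    stringsAsFactors = FALSE))
}

#' Write a transcript set as FASTA + annotation TSV
#'
#' @param transcripts a `transcript_set`.
#' @param fasta_path,annotation_path output paths.
#' @export
write_transcriptome <- function(transcripts, fasta_path, annotation_path) {
  seqs <- Biostrings::DNAStringSet(stats::setNames(transcripts$sequence,
                                                   transcripts$id))
  Biostrings::writeXStringSet(seqs, fasta_path)
  write_tsv(data.frame(transcript_id = transcripts$id,
                       cds_start = transcripts$cds_start,
                       cds_end = transcripts$cds_end),
            annotation_path)
  invisible(c(fasta = fasta_path, annotation = annotation_path))
}
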