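# Codon vocabulary: the 64 DNA triplets, the 3 stops, the 61 sense codons,
# and the codon groups reported in the occupancy/pause-fraction summaries.

ALL_CODONS <- sort(apply(expand.grid(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T")), 1, paste0,
                         collapse = ""))

#' Stop codons (standard genetic code)
#' @return character vector of the 3 stop triplets.
#' @export
stop_codons <- function() c("TAA", "TAG", "TGA")

#' The 61 sense codons of the standard genetic code
#' @return sorted character vector of length 61.
#' @export
sense_codons <- function() setdiff(ALL_CODONS, stop_codons())

#' Built-in codon groups: the six arginine and two glutamine codons
#'
#' These are the codon identities decoded by ArgRS and GlnRS, the two
#' synthetases whose anchoring to the multi-tRNA synthetase complex the
#' analysis interrogates.
#'
#' @return named list of codon character vectors.
#' @export
codon_groups_default <- function() {
  list(Arg = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
       Gln = c("CAA", "CAG"))
}

#' Split a nucleotide string into codons
#' @param seq nucleotide string, length divisible by 3.
#' @return character vector of triplets.
#' @export
split_codons <- function(seq) {
  n <- nchar(seq)
  .assert(n %% 3 == 0, "sequence length %d is not divisible by 3", n)
  if (n == 0) return(character(0))
  substring(seq, seq(1, n, by = 3), seq(3, n, by = 3))
}

.validate_codon_usage <- function(codon_usage) {
  sc <- sense_codons()
  if (identical(codon_usage, "uniform")) {
    return(stats::setNames(rep(1 / length(sc), length(sc)), sc))
  }
  .assert(is.numeric(codon_usage) && !is.null(names(codon_usage)),
          "codon_usage must be 'uniform' or a named numeric vector")
  .assert(all(names(codon_usage) %in% sc),
          "codon_usage contains non-sense codons: %s",
          paste(setdiff(names(codon_usage), sc), collapse = ", "))
  u <- stats::setNames(rep(0, length(sc)), sc)
  u[names(codon_usage)] <- codon_usage
  .assert(all(u >= 0), "codon_usage has negative entries")
  .assert(abs(sum(u) - 1) < 1e-8,
          "codon_usage must sum to 1 over sense codons (got %.6f)", sum(u))
  u
}
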