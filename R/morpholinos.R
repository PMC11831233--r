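#' Antisense poly(A)-mask morpholino sequences for the GPI locus
#'
#' The two antisense morpholino oligos used to sterically block poly(A)
#' sites of the glycolysis gene GPI: a 25-mer against the canonical
#' poly(A) site in the annotated 3' UTR and a 28-mer against the extended
#' (downstream) poly(A) site. Because the oligos are antisense, the
#' poly(A)-signal hexamer they cover appears in their reverse complement;
#' see [scan_pas_hexamer()].
#'
#' @return Named character vector with elements `canonical_pas_25mer`
#'   and `extended_pas_28mer` (5'->3').
#' @export
gpi_pam_morpholinos <- function() {
  c(canonical_pas_25mer = "ACCTCCTCCGTGGCATCTTTATTTT",
    extended_pas_28mer = "AGTTTTTAATTTTTAGAGAAACACACCA")
}

#' Reverse complement of a DNA sequence string
#'
#' @param seq Character vector of DNA sequences.
#' @return Reverse-complemented sequences.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
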