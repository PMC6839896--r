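#' Vertebrate mitochondrial genetic code
#'
#' Returns the vertebrate mitochondrial genetic code (NCBI translation table
#' 2): AGA/AGG are stop codons, ATA translates to Met and TGA to Trp. Stops
#' are reported as \code{"*"}.
#'
#' @return A list with \code{code} (named character vector mapping all 64 DNA
#'   codons to one-letter amino acids), \code{starts} (initiation codons,
#'   translated as Met when they open a reading frame) and \code{stops}.
#' @examples
#' gc <- mito_genetic_code()
#' gc$code[c("ATA", "TGA", "AGA")]
#' @export
mito_genetic_code <- function() {
  code <- Biostrings::getGeneticCode("2")
  starts <- c("ATG", attr(code, "alt_init_codons"))
  list(code = setNames(as.character(code), names(code)),
       starts = starts,
       stops = names(code)[code == "*"])
}

#' Translate a single DNA codon under the vertebrate mitochondrial code
#'
#' @param codon three-letter DNA codon (A/C/G/T).
#' @param as_start translate initiation codons (e.g. GTG, ATT) as Met; used
#'   for the first codon of a coding sequence.
#' @return One-letter amino acid; \code{"*"} for a stop codon.
#' @export
translate_codon <- function(codon, as_start = FALSE) {
  gc <- mito_genetic_code()
  codon <- toupper(codon)
  if (!codon %in% names(gc$code)) stop("not a DNA codon: ", codon)
  if (as_start && codon %in% gc$starts) return("M")
  unname(gc$code[codon])
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#' @param x character scalar over A/C/G/T/N.
#' @return Reverse-complemented character scalar.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
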