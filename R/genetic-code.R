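#' The standard nuclear genetic code as a tibble
#'
#' Returns one row per sense codon (61 rows) with its amino acid
#' (three-letter code), one-letter code, and the degeneracy (fold) class of
#' the amino acid. Fold classes partition the 20 amino acids as: onefold
#' (Met, Trp), ninefold twofold, threefold (Ile), five fourfold and three
#' sixfold (Leu, Ser, Arg). Stop codons are available through
#' [stop_codons()].
#'
#' @return A tibble with columns `codon`, `aa` (one-letter), `aa3`
#'   (three-letter) and `fold` (integer degeneracy of the amino acid).
#' @export
#' @examples
#' genetic_code()
genetic_code <- function() {
  .codonsel_code
}

#' Stop codons of the standard genetic code
#'
#' @return Character vector of the three stop codons.
#' @export
stop_codons <- function() {
  c("TAA", "TAG", "TGA")
}

# Built once at load from Biostrings' standard code table.
.build_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa1 <- unname(gc)
  sense <- aa1 != "*"
  codons <- codons[sense]
  aa1 <- aa1[sense]
  aa3_map <- c(
    A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
    E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
    M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
    Y = "Tyr", V = "Val"
  )
  fold <- table(aa1)[aa1]
  tibble::tibble(
    codon = codons,
    aa = aa1,
    aa3 = unname(aa3_map[aa1]),
    fold = as.integer(fold)
  )
}

#' Translate codons to one-letter amino acids
#'
#' Stop codons translate to `"*"`; codons containing `N` or `-` (or anything
#' outside `A`, `C`, `G`, `T`) translate to `NA`.
#'
#' @param codons Character vector of three-letter codon strings.
#' @return Character vector of one-letter amino-acid codes.
#' @export
translate_codons <- function(codons) {
  out <- .codonsel_trans[codons]
  out[is.na(names(out)) | !(codons %in% names(.codonsel_trans))] <- NA_character_
  unname(out)
}

#' Split in-frame sequences into codons
#'
#' @param x Character vector of nucleotide sequences, each with length
#'   divisible by 3.
#' @return A list of character vectors of codons, one per input sequence.
#' @export
split_codons <- function(x) {
  nc <- nchar(x)
  if (any(nc %% 3L != 0L)) {
    stop("sequence length not divisible by 3", call. = FALSE)
  }
  lapply(x, function(s) {
    n <- nchar(s) / 3L
    substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  })
}

.codonsel_code <- .build_code()
.codonsel_trans <- {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(unname(gc), names(gc))
}
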