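#' Nei-Gojobori synonymous and nonsynonymous site counts
#'
#' For each codon, every position contributes `s/3` synonymous sites, where
#' `s` is the number of the three possible single-base changes at that
#' position that leave the amino acid unchanged, and the complement to
#' nonsynonymous sites; the two always sum to 3 per codon. Changes to stop
#' codons count as nonsynonymous. Codons containing `N` or gaps, and stop
#' codons, are skipped.
#'
#' @param x Character vector of in-frame sequences, or a vector of codons
#'   when `codons = TRUE`.
#' @param codons If `TRUE`, `x` is already a vector of codon strings.
#' @return A one-row tibble with `syn_sites`, `nonsyn_sites` and
#'   `n_codons` (codons actually counted).
#' @export
#' @examples
#' codon_site_counts("TTT") # 1/3 synonymous
codon_site_counts <- function(x, codons = FALSE) {
  if (!codons) {
    x <- unlist(split_codons(x), use.names = FALSE)
  }
  tab <- .ng_sites()
  use <- x %in% rownames(tab)
  syn <- sum(tab[x[use], "syn"])
  tibble::tibble(
    syn_sites = syn,
    nonsyn_sites = 3 * sum(use) - syn,
    n_codons = sum(use)
  )
}

# per-codon NG86 synonymous site fractions, memoised
.ng_env <- new.env(parent = emptyenv())
.ng_sites <- function() {
  if (!is.null(.ng_env$tab)) {
    return(.ng_env$tab)
  }
  code <- genetic_code()
  bases <- c("A", "C", "G", "T")
  syn <- vapply(code$codon, function(cd) {
    aa <- translate_codons(cd)
    ch <- strsplit(cd, "", fixed = TRUE)[[1]]
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, ch[pos])) {
        mut <- ch
        mut[pos] <- b
        if (identical(translate_codons(paste(mut, collapse = "")), aa)) s <- s + 1
      }
    }
    s / 3
  }, numeric(1))
  tab <- cbind(syn = syn, nonsyn = 3 - syn)
  rownames(tab) <- code$codon
  .ng_env$tab <- tab
  tab
}

#' Per-haplotype synonymous/nonsynonymous site totals for an alignment
#'
#' Counts Nei-Gojobori sites for each haplotype and averages over
#' haplotypes, the usual denominator for per-site polymorphism statistics.
#'
#' @param aln A `haplotype_alignment`.
#' @return A one-row tibble with mean `syn_sites` and `nonsyn_sites`.
#' @export
alignment_site_counts <- function(aln) {
  per_hap <- purrr::map_dfr(aln$sequences, codon_site_counts)
  tibble::tibble(
    syn_sites = mean(per_hap$syn_sites),
    nonsyn_sites = mean(per_hap$nonsyn_sites)
  )
}
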