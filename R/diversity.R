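#' Synonymous nucleotide diversity (pi_S)
#'
#' Mean pairwise synonymous differences per synonymous site. Differences
#' are counted per nucleotide column between each pair of haplotypes;
#' columns with `N` or `-` in either member of a pair are skipped. A
#' difference is synonymous when substituting one haplotype's base into the
#' other's codon leaves the amino acid unchanged. The pairwise mean
#' (equivalently, the sample-size-corrected heterozygosity sum) is divided
#' by the haplotype-averaged Nei-Gojobori synonymous site count.
#'
#' @param aln A `haplotype_alignment`.
#' @return pi_S per synonymous site, or `NA` when the alignment has zero
#'   synonymous sites.
#' @export
pi_synonymous <- function(aln) {
  sites <- alignment_site_counts(aln)$syn_sites
  if (!is.finite(sites) || sites <= 0) {
    return(NA_real_)
  }
  m <- alignment_matrix(aln)
  n <- nrow(m)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + .pair_syn_diffs(m[i, ], m[j, ])
    }
  }
  (total / choose(n, 2)) / sites
}

# synonymous differences between two haplotype rows (codon-aware)
.pair_syn_diffs <- function(a, b) {
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  diff_pos <- which(a != b & ok)
  if (length(diff_pos) == 0L) {
    return(0)
  }
  d <- 0
  for (pos in diff_pos) {
    ci <- (pos - 1L) %/% 3L
    idx <- (ci * 3L + 1L):(ci * 3L + 3L)
    ca <- paste(a[idx], collapse = "")
    cb <- paste(b[idx], collapse = "")
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    swapped <- a[idx]
    swapped[pos - ci * 3L] <- b[pos]
    if (identical(
      translate_codons(ca),
      translate_codons(paste(swapped, collapse = ""))
    )) {
      d <- d + 1
    }
  }
  d
}

#' Watterson's estimator of theta per site
#'
#' `theta_W = S / (a_n * sites)` with `a_n = sum(1/i, i = 1..n-1)`.
#'
#' @param S Number of segregating sites.
#' @param n Number of sampled haplotypes (>= 2).
#' @param sites Number of sites surveyed (> 0; may be fractional, e.g.
#'   Nei-Gojobori synonymous sites).
#' @return theta_W per site.
#' @export
#' @examples
#' watterson_theta(5, 10, 100)
watterson_theta <- function(S, n, sites) {
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  if (sites <= 0) stop("sites must be > 0", call. = FALSE)
  a_n <- sum(1 / seq_len(n - 1))
  S / (a_n * sites)
}

#' Tajima's D
#'
#' Computed either from a `haplotype_alignment` (all sites, pairwise
#' differences skipping ambiguous columns) or from supplied summary
#' statistics `S` (segregating sites), `pi_total` (mean pairwise
#' differences, not per site) and `n`.
#'
#' @param aln Optional `haplotype_alignment`.
#' @param S,pi_total,n Summary statistics, used when `aln` is `NULL`.
#' @return Tajima's D, or `NA` when `S = 0`.
#' @export
tajimas_d <- function(aln = NULL, S = NULL, pi_total = NULL, n = NULL) {
  if (!is.null(aln)) {
    m <- alignment_matrix(aln)
    n <- nrow(m)
    good <- apply(m, 2, function(col) all(col %in% c("A", "C", "G", "T")))
    mm <- m[, good, drop = FALSE]
    S <- sum(apply(mm, 2, function(col) length(unique(col)) > 1))
    pairs <- utils::combn(n, 2)
    pi_total <- mean(apply(pairs, 2, function(p) sum(mm[p[1], ] != mm[p[2], ])))
  }
  if (S == 0) {
    return(NA_real_)
  }
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}
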