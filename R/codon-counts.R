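#' Tally codon usage from in-frame sequences
#'
#' Counts occurrences of each sense codon across one or more in-frame coding
#' sequences. Codons containing `N` or gap characters, and stop codons, are
#' excluded from the tally (stop codons are reported via the
#' `n_stop_excluded` attribute).
#'
#' @param x Character vector of in-frame nucleotide sequences, or a list of
#'   codon vectors as returned by [split_codons()].
#' @param id Optional identifier recorded in the `gene_id` column
#'   (default `"pooled"`).
#' @return A tibble with columns `gene_id`, `codon`, `aa`, `fold`, `count`;
#'   one row per sense codon (zero counts included).
#' @export
#' @examples
#' count_codons("ATGAAGAAATTC")
count_codons <- function(x, id = "pooled") {
  if (is.character(x)) x <- split_codons(x)
  codons <- unlist(x, use.names = FALSE)
  if (length(codons) == 0L) stop("no codons to tally", call. = FALSE)
  code <- genetic_code()
  valid <- codons %in% code$codon
  n_stop <- sum(codons %in% stop_codons())
  tab <- table(factor(codons[valid], levels = code$codon))
  out <- dplyr::mutate(code, gene_id = id, count = as.integer(tab[.data$codon]))
  out <- dplyr::select(out, "gene_id", "codon", "aa", "fold", "count")
  attr(out, "n_stop_excluded") <- n_stop
  attr(out, "n_ambiguous_excluded") <- sum(!valid) - n_stop
  out
}

#' Identify major codons from pooled codon counts
#'
#' For every amino acid with two or more synonymous codons, computes the
#' usage fraction of each codon and marks the most frequent one as the major
#' codon. Ties are broken by lexicographic codon order and flagged. Onefold
#' amino acids (Met, Trp) receive no major/minor assignment. A heterogeneity
#' G-test against equal synonymous-codon usage (see
#' [g_test_heterogeneity()]) is attached per amino acid.
#'
#' @param counts A codon-count tibble from [count_codons()], or any data
#'   frame with columns `codon` and `count`.
#' @return A tibble with one row per sense codon of each amino acid with
#'   >= 2 synonymous codons: `aa`, `codon`, `count`, `fraction`, `is_major`,
#'   `tie`, and per-amino-acid `G`, `df`, `p_value` (`NA` for amino acids
#'   with zero observations, which are kept and flagged via `no_data`).
#' @export
#' @examples
#' major_codons(count_codons(c("AAAAAGAAG", "AAGAAGAAA")))
major_codons <- function(counts) {
  stopifnot(is.data.frame(counts), all(c("codon", "count") %in% names(counts)))
  if (nrow(counts) == 0L || sum(counts$count) == 0) {
    stop("empty codon counts", call. = FALSE)
  }
  if (any(counts$codon %in% stop_codons())) {
    stop("codon counts contain stop codons", call. = FALSE)
  }
  code <- genetic_code()
  tbl <- dplyr::left_join(
    dplyr::select(code, "codon", "aa", "fold"),
    dplyr::select(counts, "codon", "count"),
    by = "codon"
  )
  tbl$count[is.na(tbl$count)] <- 0L
  tbl <- dplyr::filter(tbl, .data$fold >= 2L)
  tbl <- dplyr::arrange(tbl, .data$aa, .data$codon)
  tbl <- dplyr::group_by(tbl, .data$aa)
  tbl <- dplyr::mutate(
    tbl,
    no_data = sum(.data$count) == 0L,
    fraction = ifelse(.data$no_data, NA_real_, .data$count / sum(.data$count)),
    # which.max on codon-sorted rows gives the lexicographic tie-break
    is_major = !.data$no_data & seq_along(.data$count) == which.max(.data$count),
    tie = !.data$no_data & sum(.data$count == max(.data$count)) > 1L
  )
  g <- dplyr::summarise(
    tbl,
    G = if (sum(.data$count) > 0) g_test_heterogeneity(.data$count)$G else NA_real_,
    df = dplyr::n() - 1L,
    p_value = if (sum(.data$count) > 0) {
      g_test_heterogeneity(.data$count)$p_value
    } else {
      NA_real_
    }
  )
  out <- dplyr::left_join(dplyr::ungroup(tbl), g, by = "aa")
  dplyr::arrange(out, .data$aa, .data$codon)
}

#' G-test for heterogeneity of synonymous codon usage
#'
#' Tests the observed counts of the synonymous codons of one amino acid
#' against the equal-usage expectation. `G = 2 * sum(O * ln(O / E))` with
#' `E = total / k` and the convention `0 * ln(0) = 0`; degrees of freedom
#' `k - 1`; p-value from the chi-squared distribution.
#'
#' @param counts Non-negative integer vector of synonymous-codon counts for
#'   a single amino acid (length >= 2).
#' @return A list with elements `G`, `df` and `p_value`.
#' @export
#' @examples
#' g_test_heterogeneity(c(100, 300))
g_test_heterogeneity <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) {
    stop("heterogeneity G-test requires >= 2 synonymous codons", call. = FALSE)
  }
  if (any(counts < 0)) stop("negative codon counts", call. = FALSE)
  total <- sum(counts)
  if (total < 1) stop("total codon count must be >= 1", call. = FALSE)
  e <- total / length(counts)
  terms <- ifelse(counts > 0, counts * log(counts / e), 0)
  g <- 2 * sum(terms)
  df <- length(counts) - 1L
  list(G = g, df = df, p_value = stats::pchisq(g, df, lower.tail = FALSE))
}

#' Nucleotide composition of sequences
#'
#' Base fractions and %GC over one or more sequences; `N` and `-` are
#' excluded from denominators. With `frame_aware = TRUE` the sequences are
#' treated as in-frame coding sequence and GC3 (the fraction of third codon
#' positions that are G or C) is also reported.
#'
#' @param x Character vector of nucleotide sequences.
#' @param frame_aware If `TRUE`, require length divisible by 3 and compute
#'   GC3.
#' @return A one-row tibble with `frac_a`, `frac_t`, `frac_c`, `frac_g`,
#'   `pct_gc` and (frame-aware only) `gc3`.
#' @export
#' @examples
#' nucleotide_composition("ATGGCC", frame_aware = TRUE)
nucleotide_composition <- function(x, frame_aware = FALSE) {
  if (length(x) == 0L || all(nchar(x) == 0L)) {
    stop("empty sequence input", call. = FALSE)
  }
  if (frame_aware && any(nchar(x) %% 3L != 0L)) {
    stop("frame-aware composition requires lengths divisible by 3", call. = FALSE)
  }
  chars <- strsplit(toupper(paste(x, collapse = "")), "", fixed = TRUE)[[1]]
  use <- chars %in% c("A", "C", "G", "T")
  n <- sum(use)
  if (n == 0L) stop("no unambiguous bases in input", call. = FALSE)
  tab <- table(factor(chars[use], levels = c("A", "C", "G", "T")))
  fr <- as.numeric(tab) / n
  out <- tibble::tibble(
    frac_a = fr[1], frac_c = fr[2], frac_g = fr[3], frac_t = fr[4],
    pct_gc = 100 * (fr[2] + fr[3])
  )
  if (frame_aware) {
    third <- unlist(lapply(x, function(s) {
      ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
      ch[seq(3L, length(ch), by = 3L)]
    }))
    third <- third[third %in% c("A", "C", "G", "T")]
    out$gc3 <- mean(third %in% c("G", "C"))
  }
  out
}
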