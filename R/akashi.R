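# codon matrix (haplotypes x codon columns) for an alignment
.codon_matrix <- function(m) {
  L <- ncol(m) %/% 3L
  idx <- 3L * (seq_len(L) - 1L)
  matrix(
    paste0(m[, idx + 1L], m[, idx + 2L], m[, idx + 3L]),
    nrow = nrow(m)
  )
}

#' Classify codon columns as conserved or variable
#'
#' Conservation is judged at the amino-acid level per codon column:
#' `conserved` when the ingroup amino acid is monomorphic and equals the
#' outgroup amino acid, `variable` when the ingroup amino acid is
#' polymorphic, `excluded` when the ingroup is monomorphic but differs from
#' the outgroup (a fixed difference, uninformative for the accuracy test)
#' or when too few codons are called. A nucleotide-level mode
#' (`level = "nucleotide"`) instead requires the full codon to be
#' monomorphic and to match the outgroup codon.
#'
#' @param aln A `haplotype_alignment` with an outgroup.
#' @param level `"amino_acid"` (default) or `"nucleotide"`.
#' @return A tibble with `codon_index` (0-based), `status`
#'   (`conserved`/`variable`/`excluded`) and `aa` (the majority ingroup
#'   amino acid at classified columns).
#' @export
codon_site_conservation <- function(aln, level = c("amino_acid", "nucleotide")) {
  level <- match.arg(level)
  if (is.null(aln$outgroup)) {
    stop("conservation classification requires an outgroup", call. = FALSE)
  }
  m <- alignment_matrix(aln)
  cods <- .codon_matrix(m)
  out_cods <- .codon_matrix(matrix(strsplit(aln$outgroup, "", fixed = TRUE)[[1]], nrow = 1))
  L <- ncol(cods)
  aa_map <- .codonsel_trans
  status <- character(L)
  aa_out <- rep(NA_character_, L)
  for (ci in seq_len(L)) {
    cc <- cods[, ci]
    cc <- cc[!grepl("[^ACGT]", cc)]
    oc <- out_cods[1, ci]
    status[ci] <- "excluded"
    if (length(cc) < 2L || grepl("[^ACGT]", oc)) next
    aas <- unname(aa_map[cc])
    out_aa <- unname(aa_map[oc])
    if (anyNA(aas) || is.na(out_aa) || out_aa == "*" || any(aas == "*")) next
    if (level == "amino_acid") {
      if (length(unique(aas)) > 1L) {
        status[ci] <- "variable"
        aa_out[ci] <- names(which.max(table(aas)))
      } else if (aas[1] == out_aa) {
        status[ci] <- "conserved"
        aa_out[ci] <- aas[1]
      }
    } else {
      if (length(unique(cc)) > 1L) {
        status[ci] <- "variable"
        aa_out[ci] <- names(which.max(table(aas)))
      } else if (cc[1] == oc) {
        status[ci] <- "conserved"
        aa_out[ci] <- aas[1]
      }
    }
  }
  tibble::tibble(codon_index = seq_len(L) - 1L, status = status, aa = aa_out)
}

#' Build Akashi 2x2 contingency strata
#'
#' For each amino acid (Met and Trp skipped), tallies codon occurrences at
#' conserved and variable columns into the four cells of Akashi's test:
#' `a` (major codon, conserved site), `b` (major, variable), `c` (minor,
#' conserved), `d` (minor, variable). By default every haplotype's codon is
#' counted (sample size weights the strata); with
#' `per_column = TRUE` a single majority codon per column is counted
#' instead.
#'
#' @param aln A `haplotype_alignment` with an outgroup.
#' @param majors Major-codon table.
#' @param conservation Optional precomputed [codon_site_conservation()]
#'   table.
#' @param per_column Count one (majority) codon per column instead of one
#'   per haplotype.
#' @return A tibble with one stratum per amino acid: `aa`, `a`, `b`, `c`,
#'   `d`, `n_k`.
#' @export
akashi_strata <- function(aln, majors, conservation = NULL, per_column = FALSE) {
  if (is.null(conservation)) conservation <- codon_site_conservation(aln)
  m <- alignment_matrix(aln)
  cods <- .codon_matrix(m)
  major_of <- stats::setNames(majors$is_major, majors$codon)
  aa_of <- stats::setNames(majors$aa, majors$codon)
  status_col <- conservation$status[col(cods)]
  cod_vec <- as.vector(cods)
  status_vec <- as.vector(status_col)
  keep <- status_vec != "excluded" & cod_vec %in% names(major_of)
  if (per_column) {
    # reduce each column to its majority codon
    df <- tibble::tibble(
      col = as.vector(col(cods))[keep],
      codon = cod_vec[keep], status = status_vec[keep]
    )
    df <- dplyr::slice_max(
      dplyr::group_by(
        dplyr::count(df, .data$col, .data$codon, .data$status),
        .data$col
      ),
      .data$n,
      n = 1, with_ties = FALSE
    )
    cod_vec <- df$codon
    status_vec <- df$status
    keep <- rep(TRUE, length(cod_vec))
  }
  cod_use <- cod_vec[keep]
  st_use <- status_vec[keep]
  if (length(cod_use) == 0L) {
    return(tibble::tibble(
      aa = character(), a = numeric(), b = numeric(),
      c = numeric(), d = numeric(), n_k = numeric()
    ))
  }
  tab <- table(
    aa = aa_of[cod_use],
    major = major_of[cod_use],
    conserved = st_use == "conserved"
  )
  cell <- function(mj, cons) {
    out <- stats::setNames(rep(0, dim(tab)[1]), dimnames(tab)$aa)
    mj_c <- as.character(mj)
    cons_c <- as.character(cons)
    if (mj_c %in% dimnames(tab)$major && cons_c %in% dimnames(tab)$conserved) {
      out[] <- tab[, mj_c, cons_c]
    }
    out
  }
  out <- tibble::tibble(
    aa = dimnames(tab)$aa,
    a = as.numeric(cell(TRUE, TRUE)),
    b = as.numeric(cell(TRUE, FALSE)),
    c = as.numeric(cell(FALSE, TRUE)),
    d = as.numeric(cell(FALSE, FALSE))
  )
  dplyr::mutate(out, n_k = .data$a + .data$b + .data$c + .data$d)
}

#' Akashi's odds ratio psi for one stratum
#'
#' `psi = (a * d) / (b * c)`, the association between major codons and
#' conserved amino-acid sites. With `haldane = TRUE`, 0.5 is added to every
#' cell when any cell is zero (Haldane-Anscombe correction); otherwise a
#' zero `b * c` yields `NA`.
#'
#' @param a,b,c,d Cell counts (major/conserved, major/variable,
#'   minor/conserved, minor/variable).
#' @param haldane Apply the +0.5 correction to zero-celled tables.
#' @return The odds ratio, or `NA` when undefined.
#' @export
#' @examples
#' psi(10, 5, 2, 4)
psi <- function(a, b, c, d, haldane = FALSE) {
  if (min(a, b, c, d) < 0) stop("negative cell counts", call. = FALSE)
  if (haldane && any(c(a, b, c, d) == 0)) {
    a <- a + 0.5
    b <- b + 0.5
    c <- c + 0.5
    d <- d + 0.5
  }
  if (b * c == 0) {
    return(NA_real_)
  }
  (a * d) / (b * c)
}

#' Mantel-Haenszel pooled odds ratio over amino-acid strata
#'
#' `psi_MH = sum(a_k d_k / n_k) / sum(b_k c_k / n_k)`; strata with
#' `n_k = 0` are skipped.
#'
#' @param strata Tibble of strata from [akashi_strata()] (columns `a`, `b`,
#'   `c`, `d`, `n_k`).
#' @return The pooled odds ratio, or `NA` when the denominator is zero.
#' @export
psi_mh <- function(strata) {
  s <- dplyr::filter(strata, .data$n_k > 0)
  if (nrow(s) == 0L) {
    return(NA_real_)
  }
  num <- sum(s$a * s$d / s$n_k)
  den <- sum(s$b * s$c / s$n_k)
  if (den == 0) {
    return(NA_real_)
  }
  num / den
}

#' Gene-level Akashi test across a set of alignments
#'
#' @param alns List of `haplotype_alignment`s (each with an outgroup).
#' @param majors Major-codon table.
#' @param per_column Passed to [akashi_strata()].
#' @return A tibble with one row per gene (`gene_id`, `psi_mh`) and the
#'   long-format strata as attribute `strata`.
#' @export
akashi_test <- function(alns, majors, per_column = FALSE) {
  if (inherits(alns, "haplotype_alignment")) alns <- list(alns)
  strata_all <- purrr::map_dfr(alns, function(a) {
    s <- akashi_strata(a, majors, per_column = per_column)
    s$gene_id <- a$gene_id
    s
  })
  res <- dplyr::summarise(
    dplyr::group_by(strata_all, .data$gene_id),
    psi_mh = psi_mh(dplyr::pick(dplyr::everything())),
    .groups = "drop"
  )
  attr(res, "strata") <- strata_all
  res
}
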