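#' Effective number of codons (ENC)
#'
#' Wright's nondirectional codon-bias statistic. For every amino acid with
#' at least two observed codons, the codon homozygosity is estimated as
#' `F = (n * sum(p^2) - 1) / (n - 1)` where `n` is the number of codons
#' observed for that amino acid and `p` the within-amino-acid usage
#' fractions. Homozygosities are averaged within each degeneracy class and
#' combined as `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, clamped to
#' `[20, 61]`.
#'
#' Missing-class handling: if the threefold class (Ile) has no estimable
#' homozygosity, `F3` is imputed as the mean of `F2` and `F4`; if a two-,
#' four- or sixfold class is wholly missing its term is dropped and the
#' result rescaled so that unbiased usage still maps to 61.
#'
#' @param counts Codon-count tibble for one gene ([count_codons()]), or any
#'   data frame with `codon` and `count` columns.
#' @return ENC as a single number in `[20, 61]`.
#' @export
#' @examples
#' enc(count_codons(strrep("AAAAAGGAAGAG", 10)))
enc <- function(counts) {
  tbl <- .join_code(counts)
  tbl <- dplyr::filter(tbl, .data$fold >= 2L)
  per_aa <- dplyr::summarise(
    dplyr::group_by(tbl, .data$aa, .data$fold),
    n = sum(.data$count),
    f_hat = {
      n <- sum(.data$count)
      if (n >= 2) {
        p <- .data$count / n
        (n * sum(p^2) - 1) / (n - 1)
      } else {
        NA_real_
      }
    },
    .groups = "drop"
  )
  if (all(is.na(per_aa$f_hat))) {
    stop("ENC undefined: no amino acid with >= 2 observed codons", call. = FALSE)
  }
  class_mean <- function(k) {
    v <- per_aa$f_hat[per_aa$fold == k]
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  f2 <- class_mean(2L)
  f3 <- class_mean(3L)
  f4 <- class_mean(4L)
  f6 <- class_mean(6L)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- mean(c(f2, f4))
  mult <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  kk <- c(`2` = 2, `3` = 3, `4` = 4, `6` = 6)
  fbar <- c(`2` = f2, `3` = f3, `4` = f4, `6` = f6)
  present <- !is.na(fbar) & fbar > 0
  raw <- 2 + sum(mult[present] / fbar[present])
  # rescale so that uniform usage (F = 1/k per class) still maps to 61
  attainable <- 2 + sum(mult[present] * kk[present])
  out <- raw * 61 / attainable
  min(61, max(20, out))
}

#' Frequency of optimal codons (Fop)
#'
#' The fraction of a gene's codons that are the major codon of their amino
#' acid, among codons of amino acids that have a defined major codon.
#' Onefold amino acids (Met, Trp) are excluded.
#'
#' @param counts Codon-count tibble for one gene.
#' @param majors Major-codon table from [major_codons()] (typically computed
#'   on pooled counts).
#' @return Fop in `[0, 1]`, or `NA` if the gene contains no codon of an
#'   amino acid with a defined major codon.
#' @export
fop <- function(counts, majors) {
  mj <- dplyr::filter(majors, !.data$no_data)
  eligible <- dplyr::filter(counts, .data$codon %in% mj$codon)
  denom <- sum(eligible$count)
  if (denom == 0) {
    return(NA_real_)
  }
  major_set <- mj$codon[mj$is_major]
  sum(eligible$count[eligible$codon %in% major_set]) / denom
}

#' Codon adaptation index (CAI)
#'
#' Relative adaptiveness weights `w = f / max(f)` are computed within each
#' amino acid from a reference codon-usage table; the CAI of a gene is the
#' geometric mean of the weights of its codons, excluding Met, Trp and stop
#' codons. Codons unobserved in the reference receive a floor weight.
#'
#' @param counts Codon-count tibble for one gene.
#' @param reference Codon-count tibble for the reference set (for example
#'   pooled counts of the most biased genes; see [cai_reference()]).
#' @param w_floor Weight assigned to codons with zero reference frequency
#'   (default 0.01).
#' @return CAI in `(0, 1]`.
#' @export
cai <- function(counts, reference, w_floor = 0.01) {
  if (!is.data.frame(reference) || sum(reference$count) == 0) {
    stop("empty CAI reference counts", call. = FALSE)
  }
  ref <- .join_code(reference)
  ref <- dplyr::filter(ref, .data$fold >= 2L)
  ref <- dplyr::mutate(
    dplyr::group_by(ref, .data$aa),
    w = if (max(.data$count) > 0) .data$count / max(.data$count) else 0
  )
  ref <- dplyr::ungroup(ref)
  ref$w[ref$w <= 0] <- w_floor
  gene <- .join_code(counts)
  gene <- dplyr::filter(gene, .data$fold >= 2L, .data$count > 0)
  gene <- dplyr::left_join(gene, dplyr::select(ref, "codon", "w"), by = "codon")
  present <- dplyr::filter(gene, !is.na(.data$w))
  aa_gene <- unique(gene$aa)
  aa_ref <- unique(ref$aa[ref$count > 0])
  if (!all(aa_gene %in% aa_ref)) {
    stop("reference does not cover all amino acids present in gene", call. = FALSE)
  }
  exp(sum(present$count * log(present$w)) / sum(present$count))
}

#' Default CAI reference: pooled counts of the most biased genes
#'
#' Pools the codon counts of the genes in the top decile of Fop, the usual
#' stand-in for a curated set of highly expressed genes.
#'
#' @param gene_counts A codon-count tibble covering several genes (rows with
#'   `gene_id`, `codon`, `count`).
#' @param majors Major-codon table used to score Fop per gene.
#' @param top Fraction of genes (by Fop) pooled into the reference
#'   (default 0.1).
#' @return A pooled codon-count tibble usable as the `reference` of [cai()].
#' @export
cai_reference <- function(gene_counts, majors, top = 0.1) {
  per_gene <- dplyr::group_split(dplyr::group_by(gene_counts, .data$gene_id))
  fops <- vapply(per_gene, fop, numeric(1), majors = majors)
  keep <- fops >= stats::quantile(fops, 1 - top, na.rm = TRUE, names = FALSE)
  keep[is.na(keep)] <- FALSE
  pooled <- dplyr::bind_rows(per_gene[keep])
  dplyr::summarise(
    dplyr::group_by(pooled, .data$codon),
    count = sum(.data$count), .groups = "drop"
  )
}

#' Amino-acid-composition randomization test for codon bias
#'
#' Tests whether a gene's ENC could be explained by its amino-acid
#' composition alone. Each replicate redraws every codon uniformly among the
#' synonymous codons of its amino acid (amino-acid sequence preserved,
#' codon preference destroyed) and re-evaluates ENC. The p-value is the
#' fraction of replicates at least as biased as the observed gene
#' (`ENC_replicate <= ENC_observed`); genes with `p > cutoff` are flagged
#' for exclusion, since their observed bias is indistinguishable from a
#' compositional artefact.
#'
#' @param counts Codon-count tibble for one gene.
#' @param replicates Number of randomized replicates (default 1000).
#' @param seed Integer seed for the replicate draws (required).
#' @param cutoff Flagging threshold on the p-value (default 0.05).
#' @return A list with `p_value`, `flag` (`TRUE` when the gene should be
#'   excluded downstream) and `enc_observed`.
#' @export
aa_composition_test <- function(counts, replicates = 1000, seed, cutoff = 0.05) {
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  tbl <- .join_code(counts)
  enc_obs <- tryCatch(enc(tbl), error = function(e) NA_real_)
  aa_tot <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(tbl, .data$fold >= 2L), .data$aa),
    n = sum(.data$count), k = dplyr::n(), .groups = "drop"
  )
  aa_tot <- dplyr::filter(aa_tot, .data$n > 0)
  code <- genetic_code()
  withr_seed <- .with_seed(seed)
  on.exit(withr_seed(), add = TRUE)
  enc_rep <- vapply(seq_len(replicates), function(r) {
    rep_counts <- lapply(seq_len(nrow(aa_tot)), function(i) {
      k <- aa_tot$k[i]
      stats::rmultinom(1, aa_tot$n[i], rep(1 / k, k))[, 1]
    })
    codons <- unlist(lapply(seq_len(nrow(aa_tot)), function(i) {
      code$codon[code$aa == aa_tot$aa[i]]
    }))
    sim <- tibble::tibble(codon = codons, count = unlist(rep_counts))
    tryCatch(enc(sim), error = function(e) NA_real_)
  }, numeric(1))
  if (is.na(enc_obs) || all(is.na(enc_rep))) {
    return(list(p_value = 1, flag = TRUE, enc_observed = enc_obs))
  }
  p <- mean(enc_rep <= enc_obs, na.rm = TRUE)
  list(p_value = p, flag = p > cutoff, enc_observed = enc_obs)
}

#' Gene-level codon-bias scores
#'
#' Computes ENC, Fop and CAI (and optionally the amino-acid-composition
#' randomization test) for every gene in a codon-count table.
#'
#' @param gene_counts Codon-count tibble covering several genes.
#' @param majors Major-codon table ([major_codons()]); defaults to the one
#'   computed from the pooled counts of `gene_counts`.
#' @param reference CAI reference counts; defaults to [cai_reference()] on
#'   the input.
#' @param composition_test If `TRUE`, run [aa_composition_test()] per gene.
#' @param replicates,seed,cutoff Passed to [aa_composition_test()].
#' @return A tibble with one row per gene: `gene_id`, `enc`, `fop`, `cai`,
#'   and when requested `comp_p`, `comp_flag`.
#' @export
codon_bias_scores <- function(gene_counts, majors = NULL, reference = NULL,
                              composition_test = FALSE, replicates = 1000,
                              seed = NULL, cutoff = 0.05) {
  if (is.null(majors)) {
    pooled <- dplyr::summarise(
      dplyr::group_by(gene_counts, .data$codon),
      count = sum(.data$count), .groups = "drop"
    )
    majors <- major_codons(pooled)
  }
  if (is.null(reference)) reference <- cai_reference(gene_counts, majors)
  per_gene <- dplyr::group_split(dplyr::group_by(gene_counts, .data$gene_id))
  ids <- vapply(per_gene, function(g) g$gene_id[1], character(1))
  out <- purrr::map2_dfr(per_gene, seq_along(per_gene), function(g, i) {
    row <- tibble::tibble(
      gene_id = g$gene_id[1],
      enc = tryCatch(enc(g), error = function(e) NA_real_),
      fop = fop(g, majors),
      cai = tryCatch(cai(g, reference), error = function(e) NA_real_)
    )
    if (composition_test) {
      ct <- aa_composition_test(g,
        replicates = replicates,
        seed = seed + i, cutoff = cutoff
      )
      row$comp_p <- ct$p_value
      row$comp_flag <- ct$flag
    }
    row
  })
  out[order(match(out$gene_id, ids)), ]
}

# join arbitrary codon/count frames against the code table
.join_code <- function(counts) {
  stopifnot(is.data.frame(counts), all(c("codon", "count") %in% names(counts)))
  code <- genetic_code()
  tbl <- dplyr::left_join(
    dplyr::select(code, "codon", "aa", "fold"),
    dplyr::select(counts, "codon", "count"),
    by = "codon"
  )
  tbl$count[is.na(tbl$count)] <- 0L
  tbl
}

# evaluate fn under a local RNG seed, restoring the caller's RNG state
.with_seed <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }
}
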