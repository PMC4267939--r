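#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the study design the analysis targets: 47 haplotypes
#' across five gene arrangements, GC-ending major codons favoured by weak
#' selection against a mutational bias toward A/T, and a recent one-step
#' population expansion. The default selection/mutation/demography values
#' are the total-dataset preferred-SFS estimates (`gamma = 0.788`,
#' `kappa = 2.23`, `g = 3.7`, `tau = 0.026`, `theta01 = 0.005`).
#'
#' @param n_genes Number of genes (default 200).
#' @param n_haplotypes Named integer vector of haplotypes per arrangement
#'   (default `c(AR = 15, ST = 8, PP = 9, TL = 8, CH = 7)`).
#' @param codons_per_gene Codons per gene (default 300).
#' @param params A [selection_params()] for synonymous sites, or a list of
#'   them (one per gene class, recycled across genes in order).
#' @param theta_nonsyn Scaled mutation rate at nonsynonymous sites
#'   (default 0.001; selection on nonsynonymous variants is not modelled
#'   beyond this reduced rate).
#' @param divergence Expected substitutions per site on the outgroup
#'   lineage (default 0.03; applied to the ancestral state only).
#' @param breakpoints Two-column data frame (`start`, `end`) of inversion
#'   breakpoint intervals on the reference coordinate system; defaults to
#'   the first and last third-chromosome breakpoint intervals.
#' @param chrom_length Chromosome length for gene placement (default 2e7).
#' @param rho_meanlog,rho_sdlog Log-normal parameters for per-gene
#'   population recombination rates (defaults give a long-tailed
#'   distribution with mean about 0.05/bp).
#' @param seed Integer seed (mandatory).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200, n_haplotypes = c(AR = 15, ST = 8, PP = 9, TL = 8, CH = 7),
                       codons_per_gene = 300,
                       params = selection_params(0.005, 0.005 * 2.23,
                         gamma = 0.788, g = 3.7, tau = 0.026
                       ),
                       theta_nonsyn = 0.001, divergence = 0.03,
                       breakpoints = NULL, chrom_length = 2e7,
                       rho_meanlog = log(0.03), rho_sdlog = 1, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  if (n_genes < 1 || codons_per_gene < 1 || any(n_haplotypes < 1)) {
    stop("all sizes must be >= 1", call. = FALSE)
  }
  if (divergence < 0 || divergence > 0.2) {
    stop("divergence must be in [0, 0.2]", call. = FALSE)
  }
  if (inherits(params, "selection_params")) params <- list(params)
  if (is.null(breakpoints)) {
    breakpoints <- data.frame(
      start = c(2496966, 17722064),
      end = c(2502362, 17725256)
    )
  }
  structure(
    list(
      n_genes = n_genes, n_haplotypes = n_haplotypes,
      codons_per_gene = codons_per_gene, params = params,
      theta_nonsyn = theta_nonsyn, divergence = divergence,
      breakpoints = breakpoints, chrom_length = chrom_length,
      rho_meanlog = rho_meanlog, rho_sdlog = rho_sdlog, seed = seed
    ),
    class = "sim_config"
  )
}

#' Simulate a site frequency spectrum from the model
#'
#' Draws `n_sites` sites multinomially from the expected SFS of the model,
#' or returns the real-valued expected counts with `n_sites = "expected"`.
#'
#' @param params A [selection_params()].
#' @param n Sample size.
#' @param n_sites Number of sites, or `"expected"` for expected counts.
#' @param seed Integer seed.
#' @param focal Focal-state label recorded on the result.
#' @return An [new_sfs()] object.
#' @export
simulate_sfs <- function(params, n, n_sites, seed = NULL, focal = "major") {
  p <- expected_sfs(params, n)
  if (identical(n_sites, "expected")) {
    return(new_sfs(p, n, focal = focal))
  }
  if (n_sites < 1) stop("n_sites must be >= 1", call. = FALSE)
  if (is.null(seed)) stop("a seed is required for multinomial draws", call. = FALSE)
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  counts <- stats::rmultinom(1, n_sites, p)[, 1]
  new_sfs(counts, n, focal = focal)
}

# major/minor codon pair used at synonymous sites of each amino acid:
# GC-ending state (focal, favoured when gamma > 0) vs its AT-ending
# third-position transition partner.
.sim_codon_pairs <- function() {
  if (!is.null(.ng_env$pairs)) {
    return(.ng_env$pairs)
  }
  ts <- c(G = "A", C = "T")
  code <- genetic_code()
  elig <- code[code$fold >= 2L & substr(code$codon, 3, 3) %in% c("G", "C"), ]
  pairs <- purrr::map_dfr(seq_len(nrow(elig)), function(i) {
    cd <- elig$codon[i]
    b3 <- substr(cd, 3, 3)
    partner <- paste0(substr(cd, 1, 2), ts[[b3]])
    if (!identical(translate_codons(partner), elig$aa[i])) {
      return(NULL)
    }
    tibble::tibble(aa = elig$aa[i], gc_codon = cd, at_codon = partner)
  })
  # one pair per amino acid: the lexicographically first GC codon
  pairs <- dplyr::slice_min(dplyr::group_by(pairs, .data$aa), .data$gc_codon,
    n = 1, with_ties = FALSE
  )
  .ng_env$pairs <- dplyr::ungroup(pairs)
  .ng_env$pairs
}

#' Simulate haplotype alignments under the model
#'
#' For every gene, each codon is assigned an amino acid; at synonymous
#' (third) positions the gene's two-allele system is the amino acid's
#' GC-ending codon (focal state, favoured when `gamma > 0`) versus its
#' AT-ending transition partner. The focal-state carrier count of the `n`
#' pooled haplotypes is drawn from the model's expected SFS (stationary or
#' post-expansion), which is the exact sampling distribution for unlinked
#' sites. First/second codon positions carry rare nonsynonymous variation
#' at rate `theta_nonsyn`. The outgroup copies the ancestral state and
#' accumulates divergence on its own lineage only.
#'
#' @param cfg A [sim_config()].
#' @return A named list of `haplotype_alignment`s (plus attribute
#'   `truth`: tibble of per-gene generating parameters).
#' @export
simulate_alignments <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  restore <- .with_seed(cfg$seed)
  on.exit(restore(), add = TRUE)
  n <- sum(cfg$n_haplotypes)
  arr <- rep(names(cfg$n_haplotypes), cfg$n_haplotypes)
  pairs <- .sim_codon_pairs()
  param_idx <- rep_len(seq_along(cfg$params), cfg$n_genes)
  freq_cache <- lapply(cfg$params, .site_freq_dist)
  ann <- simulate_annotations(cfg)
  a_n <- sum(1 / seq_len(n - 1))
  alns <- vector("list", cfg$n_genes)
  for (gidx in seq_len(cfg$n_genes)) {
    fd <- freq_cache[[param_idx[gidx]]]
    nc <- cfg$codons_per_gene
    aa_rows <- sample.int(nrow(pairs), nc, replace = TRUE)
    gc_cod <- pairs$gc_codon[aa_rows]
    at_cod <- pairs$at_codon[aa_rows]
    # focal-state population frequency per codon, then binomial sampling
    x <- sample(fd$x, nc, replace = TRUE, prob = fd$p)
    i_gc <- stats::rbinom(nc, n, x)
    # outgroup lineage: allele drawn at the split, plus own-lineage divergence
    out_gc <- stats::rbinom(nc, 1, x) == 1L
    flip <- stats::runif(nc) < cfg$divergence
    out_gc <- xor(out_gc, flip)
    hapmat <- matrix("", nrow = n, ncol = nc)
    for (ci in seq_len(nc)) {
      col <- rep(at_cod[ci], n)
      if (i_gc[ci] > 0) col[sample.int(n, i_gc[ci])] <- gc_cod[ci]
      # nonsynonymous variation at position 1: transition to another codon
      if (stats::runif(1) < cfg$theta_nonsyn * a_n) {
        mut <- .transition_pos1(gc_cod[ci])
        if (!is.na(mut)) {
          k <- min(1 + stats::rgeom(1, 0.5), n - 1)
          hit <- sample.int(n, k)
          col[hit] <- paste0(substr(mut, 1, 1), substr(col[hit], 2, 3))
        }
      }
      hapmat[, ci] <- col
    }
    out_cods <- ifelse(out_gc, gc_cod, at_cod)
    seqs <- apply(hapmat, 1, paste, collapse = "")
    names(seqs) <- paste0("strain", seq_len(n))
    gene_id <- sprintf("gene%04d", gidx)
    alns[[gidx]] <- haplotype_alignment(
      seqs,
      outgroup = paste(out_cods, collapse = ""),
      gene_id = gene_id, arrangement = arr,
      start = ann$start[gidx], end = ann$end[gidx]
    )
  }
  names(alns) <- sprintf("gene%04d", seq_len(cfg$n_genes))
  attr(alns, "truth") <- tibble::tibble(
    gene_id = names(alns),
    param_class = param_idx,
    gamma = vapply(cfg$params, function(p) p$gamma, numeric(1))[param_idx],
    kappa = vapply(cfg$params, function(p) p$kappa, numeric(1))[param_idx]
  )
  alns
}

# Discrete approximation of the focal-allele frequency density (stationary,
# or evolved to tau after the expansion), on the finite-volume grid.
.site_freq_dist <- function(params, K = 256L) {
  g <- params$g
  tau <- params$tau
  if (g == 1 || tau == 0 || is.infinite(tau)) {
    eff <- if (is.infinite(tau) && g != 1) {
      selection_params(g * params$theta01, g * params$theta10, g * params$gamma)
    } else {
      params
    }
    sol <- .fv_system(
      eff$theta01, eff$theta10, eff$gamma,
      eff$theta01, eff$theta10, eff$gamma,
      n = 2, K = K
    )
    return(list(x = sol$xbar, p = sol$wnorm))
  }
  new_p <- selection_params(g * params$theta01, g * params$theta10, g * params$gamma)
  sol <- .fv_system(
    new_p$theta01, new_p$theta10, new_p$gamma,
    params$theta01, params$theta10, params$gamma,
    n = 2, K = K
  )
  u <- pmax(cn_propagate(sol$w, sol$off, sol$u0, tau), 0)
  p <- sol$wnorm * u
  list(x = sol$xbar, p = p / sum(p))
}

# transition partner at codon position 1 that changes the amino acid
.transition_pos1 <- function(cod) {
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  mut <- paste0(ts[[substr(cod, 1, 1)]], substr(cod, 2, 3))
  aa <- translate_codons(mut)
  if (is.na(aa) || aa == "*" || identical(aa, translate_codons(cod))) {
    return(NA_character_)
  }
  mut
}

#' Simulate gene annotations: coordinates and recombination rates
#'
#' Gene intervals are laid out sorted and non-overlapping along the
#' chromosome; per-gene population recombination rates are drawn from a
#' long-tailed log-normal; region labels follow the breakpoint
#' configuration (proximal before the first breakpoint interval, inverted
#' within [first start, last end], distal after).
#'
#' @param cfg A [sim_config()].
#' @return A tibble with `gene_id`, `start`, `end` (0-based half-open),
#'   `rho`, `region`.
#' @export
simulate_annotations <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  restore <- .with_seed(cfg$seed + 1L)
  on.exit(restore(), add = TRUE)
  len <- 3L * cfg$codons_per_gene
  gap <- max(1, floor((cfg$chrom_length - cfg$n_genes * len) / (cfg$n_genes + 1)))
  starts <- gap + (0:(cfg$n_genes - 1)) * (len + gap)
  ann <- tibble::tibble(
    gene_id = sprintf("gene%04d", seq_len(cfg$n_genes)),
    start = starts, end = starts + len,
    rho = stats::rlnorm(cfg$n_genes, cfg$rho_meanlog, cfg$rho_sdlog)
  )
  ann$region <- assign_region(ann, cfg$breakpoints, cfg$chrom_length)$region
  ann
}
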