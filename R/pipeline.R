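#' Quality-control filter for variant/site records
#'
#' Applies the ingest thresholds to a site table: minimum SNP quality
#' (default: drop quality < 30), minimum coverage (drop coverage < 2),
#' removal of heterozygous calls (isochromosomal data should be homozygous)
#' and exclusion of genes whose mean coverage exceeds the upper quantile
#' bound (default 0.99), a signature of collapsed paralogs. Each enabled
#' filter requires its column; every dropped record is tallied by reason.
#'
#' @param sites A data frame of site records; recognised columns:
#'   `quality`, `coverage`, `genotype` (`"het"` marks heterozygotes),
#'   `gene_id`.
#' @param min_quality Quality threshold (sites strictly below are dropped;
#'   `NULL` disables).
#' @param min_coverage Coverage threshold (sites strictly below are
#'   dropped; `NULL` disables).
#' @param drop_heterozygous Drop rows with `genotype == "het"`.
#' @param coverage_quantile Upper quantile bound for per-gene mean
#'   coverage (`NULL` disables).
#' @return The filtered tibble, with an `exclusions` attribute (named
#'   per-reason counts) and `excluded_genes` attribute.
#' @export
qc_filter_sites <- function(sites, min_quality = 30, min_coverage = 2,
                            drop_heterozygous = TRUE, coverage_quantile = 0.99) {
  sites <- tibble::as_tibble(sites)
  excl <- c(quality = 0L, coverage = 0L, heterozygous = 0L, gene_coverage = 0L)
  need <- function(col, filt) {
    if (!col %in% names(sites)) {
      stop("filter '", filt, "' enabled but column '", col, "' missing", call. = FALSE)
    }
  }
  keep <- rep(TRUE, nrow(sites))
  if (!is.null(min_quality)) {
    need("quality", "min_quality")
    bad <- sites$quality < min_quality
    excl["quality"] <- sum(bad & keep)
    keep <- keep & !bad
  }
  if (!is.null(min_coverage)) {
    need("coverage", "min_coverage")
    bad <- sites$coverage < min_coverage
    excl["coverage"] <- sum(bad & keep)
    keep <- keep & !bad
  }
  if (drop_heterozygous) {
    need("genotype", "drop_heterozygous")
    bad <- sites$genotype == "het"
    excl["heterozygous"] <- sum(bad & keep)
    keep <- keep & !bad
  }
  out <- sites[keep, ]
  excluded_genes <- character()
  if (!is.null(coverage_quantile)) {
    need("coverage", "coverage_quantile")
    need("gene_id", "coverage_quantile")
    gene_cov <- dplyr::summarise(
      dplyr::group_by(out, .data$gene_id),
      mean_cov = mean(.data$coverage), .groups = "drop"
    )
    bound <- stats::quantile(gene_cov$mean_cov, coverage_quantile, names = FALSE)
    excluded_genes <- gene_cov$gene_id[gene_cov$mean_cov > bound]
    drop <- out$gene_id %in% excluded_genes
    excl["gene_coverage"] <- sum(drop)
    out <- out[!drop, ]
  }
  attr(out, "exclusions") <- excl
  attr(out, "excluded_genes") <- excluded_genes
  out
}

#' Assign genes to proximal / inverted / distal chromosome regions
#'
#' Region boundaries derive from the breakpoint intervals: proximal is
#' `[0, first breakpoint start)`, inverted `[first start, last end]`,
#' distal `(last end, chromosome end]`. A gene is labelled by its midpoint;
#' genes whose span overlaps a breakpoint interval are flagged.
#'
#' @param genes Data frame with `gene_id`, `start`, `end` (0-based
#'   half-open).
#' @param breakpoints Data frame of breakpoint intervals (`start`, `end`),
#'   on the same coordinate system.
#' @param chrom_length Chromosome length (for bounds checking).
#' @return The input tibble with added `region`
#'   (`proximal`/`inverted`/`distal`) and `overlaps_breakpoint` columns.
#' @export
assign_region <- function(genes, breakpoints, chrom_length = Inf) {
  genes <- tibble::as_tibble(genes)
  if (any(genes$start < 0 | genes$end > chrom_length | genes$start >= genes$end)) {
    stop("gene coordinates outside chromosome bounds", call. = FALSE)
  }
  first_start <- min(breakpoints$start)
  last_end <- max(breakpoints$end)
  mid <- (genes$start + genes$end) / 2
  genes$region <- dplyr::case_when(
    mid < first_start ~ "proximal",
    mid <= last_end ~ "inverted",
    TRUE ~ "distal"
  )
  genes$overlaps_breakpoint <- purrr::map_lgl(seq_len(nrow(genes)), function(i) {
    any(genes$start[i] < breakpoints$end & genes$end[i] > breakpoints$start)
  })
  genes
}

#' Bin genes by quantiles of a covariate
#'
#' Partitions values into `k` equal-size bins at type-7 quantile
#' boundaries (`scheme = "quantile"`), or into classes of fixed percentile
#' width (`scheme = "percentile"`, e.g. `width = 0.05` for 20 classes).
#' Values tied at a boundary go to the lower bin.
#'
#' @param values Numeric vector (one per gene).
#' @param k Number of quantile bins (default 4).
#' @param scheme `"quantile"` or `"percentile"`.
#' @param width Percentile width for `scheme = "percentile"`.
#' @return Integer vector of bin labels (1 = lowest values).
#' @export
bin_genes <- function(values, k = 4, scheme = c("quantile", "percentile"),
                      width = 0.05) {
  scheme <- match.arg(scheme)
  if (scheme == "percentile") k <- round(1 / width)
  if (length(values) < k) stop("fewer genes than bins", call. = FALSE)
  qs <- stats::quantile(values, probs = seq(0, 1, length.out = k + 1),
    type = 7, names = FALSE
  )
  if (anyDuplicated(qs[-c(1, k + 1)])) {
    stop("degenerate quantile boundaries (ties across bins)", call. = FALSE)
  }
  # right-closed intervals put boundary ties in the lower bin
  bins <- findInterval(values, qs[-c(1, k + 1)], left.open = FALSE) + 1L
  # findInterval is left-open on the vector: values equal to a boundary
  # land above; shift them down
  for (b in seq_len(k - 1)) {
    bins[values == qs[b + 1]] <- b
  }
  as.integer(bins)
}

#' Run the full synthetic-data analysis and emit report tables
#'
#' Orchestrates the pipeline on a configured synthetic dataset: simulates
#' alignments and annotations, identifies major codons, computes bias
#' scores and composition, polymorphism and diversity statistics, the
#' Akashi test, SFS model fits with likelihood-ratio tests, and regional /
#' binned summaries. All randomness derives from the configuration seed,
#' so identical configurations give identical outputs.
#'
#' @param cfg A [sim_config()].
#' @param fit_models Fit the SFS selection models (slowest step; default
#'   `TRUE`).
#' @param n_starts Optimizer starts per model fit.
#' @param out_dir Optional directory: every table is also written as TSV.
#' @return A named list of tibbles: `major_codons`, `bias_summary`,
#'   `composition`, `diversity`, `region_summary`, `per_aa_rates`,
#'   `akashi`, `model_fits`, `binned_gamma`, `fop_by_rho`.
#' @export
run_report <- function(cfg, fit_models = TRUE, n_starts = 12, out_dir = NULL) {
  alns <- simulate_alignments(cfg)
  ann <- simulate_annotations(cfg)
  gene_counts <- purrr::map_dfr(alns, function(a) {
    count_codons(unname(a$sequences), id = a$gene_id)
  })
  pooled <- dplyr::summarise(
    dplyr::group_by(gene_counts, .data$codon),
    count = sum(.data$count), .groups = "drop"
  )
  majors <- major_codons(pooled)
  bias <- codon_bias_scores(gene_counts, majors = majors)
  comp <- nucleotide_composition(
    unlist(lapply(alns, function(a) unname(a$sequences))),
    frame_aware = TRUE
  )
  diversity <- purrr::map_dfr(alns, function(a) {
    sc <- alignment_site_counts(a)
    tibble::tibble(
      gene_id = a$gene_id,
      pi_s = pi_synonymous(a),
      syn_sites = sc$syn_sites,
      nonsyn_sites = sc$nonsyn_sites,
      tajimas_d = tajimas_d(a)
    )
  })
  ann2 <- dplyr::left_join(ann,
    dplyr::select(diversity, "gene_id", "pi_s"),
    by = "gene_id"
  )
  ann2 <- dplyr::left_join(ann2, dplyr::select(bias, "gene_id", "fop"), by = "gene_id")
  region_summary <- dplyr::summarise(
    dplyr::group_by(ann2, .data$region),
    n_genes = dplyr::n(),
    rho = mean(.data$rho),
    pi_s = mean(.data$pi_s, na.rm = TRUE),
    rho_over_pi_s = ifelse(.data$pi_s > 0, .data$rho / .data$pi_s, NA_real_),
    fop = mean(.data$fop, na.rm = TRUE),
    .groups = "drop"
  )
  rates <- per_aa_polymorphism(alns, majors)
  akashi <- akashi_test(alns, majors)
  model_fits <- NULL
  binned <- NULL
  if (fit_models) {
    sfs <- site_frequency_spectrum(alns, majors, focal = "major")
    f_l1 <- fit_sfs_model(sfs, model = "L1", n_starts = n_starts, seed = cfg$seed)
    f_l0 <- fit_sfs_model(sfs, model = "L0", n_starts = n_starts, seed = cfg$seed)
    f_ns <- fit_sfs_model(sfs, model = "NS", n_starts = n_starts, seed = cfg$seed)
    model_fits <- dplyr::bind_rows(
      dplyr::mutate(glance(f_l1),
        gamma = f_l1$params$gamma, kappa = f_l1$params$kappa,
        g = f_l1$params$g, tau = f_l1$params$tau
      ),
      dplyr::mutate(glance(f_l0),
        gamma = f_l0$params$gamma, kappa = f_l0$params$kappa,
        g = NA_real_, tau = NA_real_
      ),
      dplyr::mutate(glance(f_ns),
        gamma = 0, kappa = f_ns$params$kappa,
        g = f_ns$params$g, tau = f_ns$params$tau
      )
    )
    model_fits$chisq_vs_L1 <- c(
      NA,
      lrt(f_l1, f_l0)$chisq,
      lrt(f_l1, f_ns)$chisq
    )
    fop_vec <- stats::setNames(bias$fop, bias$gene_id)
    binned <- fit_binned(alns, fop_vec, majors,
      k = 4, model = "L0",
      n_starts = max(4, n_starts %/% 2), seed = cfg$seed, boot = 0
    )
  }
  # 5% classes when the gene set is large enough, else coarser
  n_classes <- min(20L, max(2L, nrow(ann2) %/% 3L))
  rho_bins <- bin_genes(ann2$rho, scheme = "percentile", width = 1 / n_classes)
  fop_by_rho <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(ann2, rho_class = rho_bins), .data$rho_class),
    n_genes = dplyr::n(), fop = mean(.data$fop, na.rm = TRUE),
    .groups = "drop"
  )
  out <- list(
    major_codons = majors,
    bias_summary = bias,
    composition = comp,
    diversity = diversity,
    region_summary = region_summary,
    per_aa_rates = rates$per_aa,
    directional_rates = rates$directional,
    akashi = akashi,
    model_fits = model_fits,
    binned_gamma = binned,
    fop_by_rho = fop_by_rho
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      if (!is.null(out[[nm]])) {
        utils::write.table(out[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
          sep = "\t", row.names = FALSE, quote = FALSE
        )
      }
    }
  }
  out
}
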