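#' Classify and polarize segregating sites in a coding alignment
#'
#' Walks every nucleotide column of an in-frame haplotype alignment and
#' classifies the segregating ones. Haplotypes with `N`/`-` anywhere in the
#' affected codon are dropped for that site. Biallelic sites are polarized
#' against the outgroup (ancestral = the outgroup base when it matches one
#' of the two segregating alleles), classified as synonymous or
#' nonsynonymous, as preferred (minor -> major codon) or unpreferred
#' (major -> minor) when synonymous and polarized, as transition or
#' transversion, and by GC direction (`GC->AT`, `AT->GC`, or
#' `GC-conservative`). Sites that cannot be classified are returned with an
#' exclusion `reason` (`multiallelic`, `codon_context`, `too_few_calls`).
#'
#' Codon context must be unambiguous: all haplotypes carrying a given
#' allele must share the same codon at the site's codon column.
#'
#' @param aln A `haplotype_alignment` (outgroup optional; without one, all
#'   sites are `unpolarized`).
#' @param majors Major-codon table from [major_codons()].
#' @return A tibble with one row per segregating site: `gene_id`, `column`
#'   (0-based), `codon_index` (0-based), `codon_pos` (1-3), `allele1`,
#'   `allele2`, `ancestral`, `derived`, `derived_count`, `n_called`,
#'   `count1`, `count2` (carriers of each allele),
#'   `codon1`, `codon2`, `aa1`, `aa2`, `synonymous`, `polarity`
#'   (`preferred`/`unpreferred`/`unpolarized`/`not_applicable`),
#'   `transition`, `gc_direction`, `reason` (`NA` for classified sites).
#' @export
classify_mutations <- function(aln, majors) {
  m <- alignment_matrix(aln)
  n <- nrow(m)
  L <- ncol(m)
  out_bases <- if (!is.null(aln$outgroup)) {
    strsplit(aln$outgroup, "", fixed = TRUE)[[1]]
  } else {
    rep(NA_character_, L)
  }
  major_set <- majors$codon[majors$is_major]
  minor_set <- majors$codon[!majors$is_major & !majors$no_data]
  acgt <- c("A", "C", "G", "T")
  rows <- list()
  for (col in seq_len(L)) {
    ci <- (col - 1L) %/% 3L
    idx <- (ci * 3L + 1L):(ci * 3L + 3L)
    cods <- apply(m[, idx, drop = FALSE], 1, paste, collapse = "")
    called <- !grepl("[^ACGT]", cods)
    if (sum(called) < 2L) next
    bases <- m[called, col]
    alle <- sort(unique(bases))
    if (length(alle) < 2L) next
    base_row <- tibble::tibble(
      gene_id = aln$gene_id, column = col - 1L, codon_index = ci,
      codon_pos = col - ci * 3L,
      allele1 = alle[1], allele2 = if (length(alle) >= 2) alle[2] else NA,
      ancestral = NA_character_, derived = NA_character_,
      derived_count = NA_integer_, n_called = sum(called),
      count1 = sum(bases == alle[1]),
      count2 = sum(bases == alle[2]),
      codon1 = NA_character_, codon2 = NA_character_,
      aa1 = NA_character_, aa2 = NA_character_,
      synonymous = NA, polarity = NA_character_,
      transition = NA, gc_direction = NA_character_,
      reason = NA_character_
    )
    if (length(alle) > 2L) {
      base_row$reason <- "multiallelic"
      rows[[length(rows) + 1L]] <- base_row
      next
    }
    cod1 <- unique(cods[called][bases == alle[1]])
    cod2 <- unique(cods[called][bases == alle[2]])
    if (length(cod1) != 1L || length(cod2) != 1L) {
      base_row$reason <- "codon_context"
      rows[[length(rows) + 1L]] <- base_row
      next
    }
    aa1 <- translate_codons(cod1)
    aa2 <- translate_codons(cod2)
    base_row$codon1 <- cod1
    base_row$codon2 <- cod2
    base_row$aa1 <- aa1
    base_row$aa2 <- aa2
    base_row$synonymous <- identical(aa1, aa2) && aa1 != "*"
    anc <- out_bases[col]
    polarized <- !is.na(anc) && anc %in% alle
    ts_pairs <- c(AG = TRUE, GA = TRUE, CT = TRUE, TC = TRUE)
    pr <- paste0(alle[1], alle[2])
    base_row$transition <- isTRUE(ts_pairs[pr])
    if (polarized) {
      der <- setdiff(alle, anc)
      base_row$ancestral <- anc
      base_row$derived <- der
      base_row$derived_count <- sum(bases == der)
      gc <- c("G", "C")
      base_row$gc_direction <- if (anc %in% gc && !(der %in% gc)) {
        "GC->AT"
      } else if (!(anc %in% gc) && der %in% gc) {
        "AT->GC"
      } else {
        "GC-conservative"
      }
      anc_cod <- if (anc == alle[1]) cod1 else cod2
      der_cod <- if (anc == alle[1]) cod2 else cod1
      if (base_row$synonymous && der_cod %in% major_set && anc_cod %in% minor_set) {
        base_row$polarity <- "preferred"
      } else if (base_row$synonymous && der_cod %in% minor_set && anc_cod %in% major_set) {
        base_row$polarity <- "unpreferred"
      } else {
        base_row$polarity <- "not_applicable"
      }
    } else {
      base_row$polarity <- "unpolarized"
    }
    rows[[length(rows) + 1L]] <- base_row
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      gene_id = character(), column = integer(), codon_index = integer(),
      codon_pos = integer(), allele1 = character(), allele2 = character(),
      ancestral = character(), derived = character(),
      derived_count = integer(), n_called = integer(),
      count1 = integer(), count2 = integer(),
      codon1 = character(), codon2 = character(), aa1 = character(),
      aa2 = character(), synonymous = logical(), polarity = character(),
      transition = logical(), gc_direction = character(), reason = character()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Per-amino-acid rates of synonymous and nonsynonymous polymorphism
#'
#' Watterson's theta per synonymous site and per nonsynonymous site,
#' estimated separately for each amino acid, and (from polarized
#' third-position transitions) per mutation direction (`GC->AT` vs
#' `AT->GC`). Site denominators are Nei-Gojobori fractional counts averaged
#' over haplotypes and partitioned by the amino acid of each haplotype's
#' codon; segregating sites are assigned to the amino acid of the ancestral
#' codon when polarized, else of the majority-allele codon. Stop codons and
#' the onefold amino acids Met and Trp are not considered.
#'
#' @param alns List of `haplotype_alignment`s with a common sample size.
#' @param majors Major-codon table.
#' @param transitions_only If `TRUE`, restrict the per-amino-acid
#'   synonymous counts to third-position transitions.
#' @return A list with `per_aa` (tibble: `aa`, `theta_syn`, `theta_nonsyn`)
#'   and `directional` (tibble: `direction`, `S`, `sites`, `theta`; plus the
#'   ratio as attribute `gc_at_ratio`).
#' @export
per_aa_polymorphism <- function(alns, majors, transitions_only = FALSE) {
  if (inherits(alns, "haplotype_alignment")) alns <- list(alns)
  n <- length(alns[[1]]$sequences)
  if (!all(vapply(alns, function(a) length(a$sequences), integer(1)) == n)) {
    stop("all alignments must share the same number of haplotypes", call. = FALSE)
  }
  a_n <- sum(1 / seq_len(n - 1))
  code <- genetic_code()
  ng <- .ng_sites()
  aa_keep <- setdiff(unique(code$aa), c("M", "W"))
  syn_sites <- stats::setNames(numeric(length(aa_keep)), aa_keep)
  nonsyn_sites <- syn_sites
  dir_sites <- c(`GC->AT` = 0, `AT->GC` = 0)
  s_syn <- syn_sites
  s_nonsyn <- syn_sites
  dir_s <- c(`GC->AT` = 0, `AT->GC` = 0)
  ts3_syn <- .third_transition_syn()
  for (aln in alns) {
    for (seq in aln$sequences) {
      cods <- split_codons(seq)[[1]]
      cods <- cods[cods %in% rownames(ng)]
      aas <- translate_codons(cods)
      keep <- aas %in% aa_keep
      cods <- cods[keep]
      aas <- aas[keep]
      ssum <- tapply(ng[cods, "syn"], aas, sum)
      nsum <- tapply(ng[cods, "nonsyn"], aas, sum)
      syn_sites[names(ssum)] <- syn_sites[names(ssum)] + ssum / n
      nonsyn_sites[names(nsum)] <- nonsyn_sites[names(nsum)] + nsum / n
      elig <- cods[ts3_syn[cods]]
      third <- substr(elig, 3, 3)
      gc3 <- third %in% c("G", "C")
      dir_sites["GC->AT"] <- dir_sites["GC->AT"] + sum(gc3) / n
      dir_sites["AT->GC"] <- dir_sites["AT->GC"] + sum(!gc3) / n
    }
    cls <- classify_mutations(aln, majors)
    cls <- dplyr::filter(cls, is.na(.data$reason))
    if (nrow(cls) > 0) {
      anc_cod <- ifelse(!is.na(cls$ancestral),
        ifelse(cls$ancestral == cls$allele1, cls$codon1, cls$codon2),
        # majority-allele codon when unpolarized
        ifelse(cls$count1 >= cls$count2, cls$codon1, cls$codon2)
      )
      aa_site <- translate_codons(anc_cod)
      use <- aa_site %in% aa_keep
      syn_use <- use & cls$synonymous
      if (transitions_only) syn_use <- syn_use & cls$transition & cls$codon_pos == 3L
      tab_s <- table(aa_site[syn_use])
      s_syn[names(tab_s)] <- s_syn[names(tab_s)] + tab_s
      tab_n <- table(aa_site[use & !cls$synonymous])
      s_nonsyn[names(tab_n)] <- s_nonsyn[names(tab_n)] + tab_n
      dsites <- dplyr::filter(
        cls, .data$synonymous, .data$transition, .data$codon_pos == 3L,
        .data$gc_direction %in% names(dir_s)
      )
      if (nrow(dsites) > 0) {
        td <- table(dsites$gc_direction)
        dir_s[names(td)] <- dir_s[names(td)] + td
      }
    }
  }
  per_aa <- tibble::tibble(
    aa = aa_keep,
    syn_sites = syn_sites,
    nonsyn_sites = nonsyn_sites,
    s_syn = as.numeric(s_syn),
    s_nonsyn = as.numeric(s_nonsyn),
    theta_syn = ifelse(syn_sites > 0, s_syn / (a_n * syn_sites), NA_real_),
    theta_nonsyn = ifelse(nonsyn_sites > 0, s_nonsyn / (a_n * nonsyn_sites), NA_real_)
  )
  directional <- tibble::tibble(
    direction = names(dir_s),
    S = as.numeric(dir_s),
    sites = as.numeric(dir_sites),
    theta = ifelse(dir_sites > 0, dir_s / (a_n * dir_sites), NA_real_)
  )
  ratio <- directional$theta[1] / directional$theta[2]
  attr(directional, "gc_at_ratio") <- ratio
  list(per_aa = per_aa, directional = directional)
}

# codons whose third-position transition is synonymous, memoised
.third_transition_syn <- function() {
  if (!is.null(.ng_env$ts3)) {
    return(.ng_env$ts3)
  }
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  code <- genetic_code()
  res <- vapply(code$codon, function(cd) {
    b3 <- substr(cd, 3, 3)
    mut <- paste0(substr(cd, 1, 2), ts[b3])
    identical(translate_codons(mut), translate_codons(cd))
  }, logical(1))
  names(res) <- code$codon
  .ng_env$ts3 <- res
  res
}
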