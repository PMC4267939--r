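test_that("Nei-Gojobori site counts match single-base enumeration", {
  # Met: no synonymous change possible
  expect_equal(codon_site_counts("ATG")$syn_sites, 0)
  expect_equal(codon_site_counts("ATG")$nonsyn_sites, 3)
  # Phe TTT: only TTT->TTC synonymous among the 9 changes
  expect_equal(codon_site_counts("TTT")$syn_sites, 1 / 3)
  expect_equal(codon_site_counts("TTT")$nonsyn_sites, 8 / 3)
  # Leu CTG: fourfold third position plus the CTG->TTG first-position path
  expect_equal(codon_site_counts("CTG")$syn_sites, 4 / 3)
  expect_equal(codon_site_counts("CTG")$nonsyn_sites, 5 / 3)
  expect_error(codon_site_counts("ATGA"), "divisible")
})

test_that("syn + nonsyn sites sum to 3 for every sense codon", {
  code <- genetic_code()
  for (cd in code$codon) {
    cs <- codon_site_counts(cd)
    expect_equal(cs$syn_sites + cs$nonsyn_sites, 3)
  }
  # stop codons and ambiguous codons are skipped
  expect_equal(codon_site_counts("TAA")$n_codons, 0L)
  expect_equal(codon_site_counts("ATGNNNTAA")$n_codons, 1L)
})

test_that("pi_S matches hand and brute-force values", {
  # identical sequences -> 0
  aln0 <- make_aln(c(a = "AAGGAC", b = "AAGGAC"))
  expect_equal(pi_synonymous(aln0), 0)
  # n = 2, one synonymous third-position difference
  aln1 <- make_aln(c(a = "AAAGACAAGTTCGGCGGA", b = "AAGGACAAGTTCGGCGGA"))
  sites <- alignment_site_counts(aln1)$syn_sites
  expect_equal(pi_synonymous(aln1), 1 / sites)
  # 4 haplotypes: equals brute-force mean over all 6 pairs
  seqs <- c(
    a = "AAAGACCTG", b = "AAGGACCTG", c = "AAGGATCTG", d = "AAAGATCTA"
  )
  aln4 <- make_aln(seqs)
  pairs <- combn(4, 2)
  brute <- mean(apply(pairs, 2, function(p) {
    s1 <- strsplit(seqs[p[1]], "")[[1]]
    s2 <- strsplit(seqs[p[2]], "")[[1]]
    d <- 0
    for (pos in which(s1 != s2)) {
      ci <- (pos - 1) %/% 3
      c1 <- paste(s1[(ci * 3 + 1):(ci * 3 + 3)], collapse = "")
      sw <- s1[(ci * 3 + 1):(ci * 3 + 3)]
      sw[pos - ci * 3] <- s2[pos]
      if (translate_codons(c1) == translate_codons(paste(sw, collapse = ""))) d <- d + 1
    }
    d
  }))
  expect_equal(pi_synonymous(aln4), brute / alignment_site_counts(aln4)$syn_sites)
})

test_that("Watterson's theta follows S / (a_n * sites)", {
  expect_equal(watterson_theta(0, 10, 100), 0)
  expect_equal(watterson_theta(5, 10, 100), 5 / (sum(1 / 1:9) * 100))
  expect_equal(watterson_theta(5, 10, 100), 0.01767, tolerance = 1e-3)
  expect_equal(watterson_theta(3, 2, 30), 0.1) # a_1 = 1
  expect_error(watterson_theta(5, 10, 0), "> 0")
  expect_error(watterson_theta(5, 1, 10), ">= 2")
})

test_that("Tajima's D matches the published-constant oracle", {
  expect_true(is.na(tajimas_d(S = 0, pi_total = 0, n = 10)))
  # D = 0 when pi equals S/a1
  a1 <- sum(1 / 1:9)
  expect_equal(tajimas_d(S = 5, pi_total = 5 / a1, n = 10), 0)
  # toy alignment against the straight-line oracle
  set.seed(2)
  cfg <- sim_config(
    n_genes = 1, n_haplotypes = c(A = 5, B = 5),
    codons_per_gene = 200, seed = 31
  )
  aln <- simulate_alignments(cfg)[[1]]
  m <- alignment_matrix(aln)
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  pairs <- combn(nrow(m), 2)
  pi_tot <- mean(apply(pairs, 2, function(p) sum(m[p[1], ] != m[p[2], ])))
  if (S > 0) {
    expect_equal(tajimas_d(aln), tajima_oracle(S, pi_tot, nrow(m)))
  }
})

test_that("mutation classification polarizes against the outgroup", {
  mj <- major_codons(tibble::tibble(
    codon = c("AAA", "AAG", "GAT", "GAC"),
    count = c(100L, 300L, 100L, 300L)
  ))
  # AAG -> AAA with ancestral AAG: synonymous, unpreferred, ts, GC->AT
  aln <- make_aln(c(a = "AAG", b = "AAA", c = "AAG"), outgroup = "AAG")
  cls <- classify_mutations(aln, mj)
  expect_equal(nrow(cls), 1L)
  expect_true(cls$synonymous)
  expect_equal(cls$polarity, "unpreferred")
  expect_true(cls$transition)
  expect_equal(cls$gc_direction, "GC->AT")
  expect_equal(cls$derived_count, 1L)
  # reverse polarization: preferred
  aln2 <- make_aln(c(a = "AAG", b = "AAA", c = "AAA"), outgroup = "AAA")
  cls2 <- classify_mutations(aln2, mj)
  expect_equal(cls2$polarity, "preferred")
  expect_equal(cls2$gc_direction, "AT->GC")
  # outgroup matches neither allele -> unpolarized
  aln3 <- make_aln(c(a = "AAG", b = "AAA"), outgroup = "AAC")
  expect_equal(classify_mutations(aln3, mj)$polarity, "unpolarized")
  # triallelic -> excluded with reason
  aln4 <- make_aln(c(a = "AAA", b = "AAC", c = "AAG"), outgroup = "AAA")
  expect_equal(classify_mutations(aln4, mj)$reason, "multiallelic")
})

test_that("per-amino-acid rates: no polymorphism gives zero, Met/Trp excluded", {
  mj <- major_codons(tibble::tibble(
    codon = c("AAA", "AAG"), count = c(1L, 3L)
  ))
  aln <- make_aln(c(a = "AAGATGTGG", b = "AAGATGTGG", c = "AAGATGTGG"),
    outgroup = "AAGATGTGG"
  )
  rates <- per_aa_polymorphism(aln, mj)
  expect_true(all(rates$per_aa$theta_syn == 0 | is.na(rates$per_aa$theta_syn)))
  expect_false("M" %in% rates$per_aa$aa)
  expect_false("W" %in% rates$per_aa$aa)
  # Lys sites present, Met/Trp contribute nothing
  expect_gt(rates$per_aa$syn_sites[rates$per_aa$aa == "K"], 0)
})

test_that("SFS construction places sites by focal-state carrier count", {
  mj <- major_codons(tibble::tibble(
    codon = c("AAA", "AAG", "GAT", "GAC"),
    count = c(100L, 300L, 100L, 300L)
  ))
  # 4 haplotypes: one column 3 major / 1 minor, one all-major column,
  # one all-minor column
  aln <- make_aln(c(
    a = "AAGGACAAA", b = "AAGGACAAA", c = "AAGGACAAA", d = "AAAGACAAA"
  ))
  sfs <- site_frequency_spectrum(aln, mj, focal = "major")
  expect_s3_class(sfs, "sfs")
  expect_equal(attr(sfs, "n"), 4L)
  expect_equal(sfs$count[sfs$i == 3], 1) # 3 major carriers
  expect_equal(sfs$count[sfs$i == 4], 1) # monomorphic major
  expect_equal(sfs$count[sfs$i == 0], 1) # monomorphic minor
  expect_equal(sum(sfs$count), 3)
})

test_that("major- and minor-focal spectra are mirror images", {
  set.seed(5)
  cfg <- sim_config(
    n_genes = 4, n_haplotypes = c(A = 4, B = 4),
    codons_per_gene = 150, seed = 13
  )
  alns <- simulate_alignments(cfg)
  counts <- purrr::map_dfr(alns, function(a) count_codons(unname(a$sequences), id = a$gene_id))
  pooled <- dplyr::summarise(dplyr::group_by(counts, .data$codon),
    count = sum(.data$count), .groups = "drop"
  )
  mj <- major_codons(pooled)
  s_major <- site_frequency_spectrum(alns, mj, focal = "major")
  s_minor <- site_frequency_spectrum(alns, mj, focal = "minor")
  expect_equal(s_major$count, rev(s_minor$count))
})

test_that("sites segregating two minor codons are excluded with a reason", {
  pooled <- tibble::tibble(
    codon = c("GCT", "GCC", "GCA", "GCG"),
    count = c(10L, 70L, 10L, 10L)
  )
  mj <- major_codons(pooled)
  aln <- make_aln(c(a = "GCT", b = "GCA", c = "GCT"))
  sfs <- site_frequency_spectrum(aln, mj)
  expect_equal(sum(sfs$count), 0)
  expect_equal(attr(sfs, "excluded")[["two_minor"]], 1L)
})

test_that("FASTA round trip preserves alignment and outgroup", {
  aln <- make_aln(c(s1 = "AAGGAC", s2 = "AAAGAC"),
    outgroup = "AAGGAT",
    gene_id = "g1", arrangement = c("AR", "ST")
  )
  path <- tempfile(fileext = ".fasta")
  write_haplotype_alignment(aln, path)
  back <- read_haplotype_alignment(path, gene_id = "g1")
  expect_equal(unname(back$sequences), unname(aln$sequences))
  expect_equal(back$outgroup, aln$outgroup)
  expect_equal(back$arrangement, aln$arrangement)
  unlink(path)
})

test_that("neutral symmetric data give Tajima's D near zero on average", {
  cfg <- sim_config(
    n_genes = 40, n_haplotypes = c(A = 6, B = 6),
    codons_per_gene = 200,
    params = selection_params(0.02, 0.02, gamma = 0),
    seed = 88
  )
  alns <- simulate_alignments(cfg)
  d <- vapply(alns, function(a) tajimas_d(a), numeric(1))
  expect_lt(abs(mean(d, na.rm = TRUE)), 0.35)
})
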