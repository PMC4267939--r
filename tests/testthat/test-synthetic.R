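test_that("simulated SFS is deterministic and converges to the model", {
  pr <- selection_params(0.01, 0.01, 0)
  s1 <- simulate_sfs(pr, 10, 5e4, seed = 3)
  s2 <- simulate_sfs(pr, 10, 5e4, seed = 3)
  expect_identical(s1$count, s2$count)
  # expected mode returns real-valued expected counts
  se <- simulate_sfs(pr, 10, "expected")
  expect_equal(sum(se$count), 1, tolerance = 1e-9)
  # law of large numbers toward the expected spectrum
  big <- simulate_sfs(pr, 10, 1e6, seed = 4)
  p <- expected_sfs(pr, 10)
  expect_lt(total_variation(big$count / sum(big$count), p), 0.005)
  # symmetric neutral spectrum is symmetric within binomial noise
  mid <- big$count[2:10]
  expect_true(all(abs(mid - rev(mid)) <
    3 * sqrt(1e6 * (p[2:10] + rev(p[2:10])))))
  expect_error(simulate_sfs(pr, 10, 0, seed = 1), ">= 1")
})

test_that("alignment simulation is seed-deterministic and well formed", {
  cfg <- sim_config(
    n_genes = 3, n_haplotypes = c(AR = 3, ST = 2),
    codons_per_gene = 50, seed = 9
  )
  a1 <- simulate_alignments(cfg)
  a2 <- simulate_alignments(cfg)
  expect_identical(
    lapply(a1, function(x) x$sequences),
    lapply(a2, function(x) x$sequences)
  )
  aln <- a1[[1]]
  expect_s3_class(aln, "haplotype_alignment")
  expect_equal(length(aln$sequences), 5L)
  expect_equal(nchar(aln$sequences[[1]]), 150L)
  expect_equal(nchar(aln$outgroup), 150L)
  expect_setequal(unique(aln$arrangement), c("AR", "ST"))
  # byte-identical FASTA under the same seed
  p1 <- tempfile(fileext = ".fa")
  p2 <- tempfile(fileext = ".fa")
  write_haplotype_alignment(a1[[1]], p1)
  write_haplotype_alignment(a2[[1]], p2)
  expect_identical(readLines(p1), readLines(p2))
  unlink(c(p1, p2))
})

test_that("strong GC selection drives Fop and GC3 up; neutrality leaves GC3 at 1/2", {
  cfg_sel <- sim_config(
    n_genes = 5, n_haplotypes = c(A = 5, B = 5),
    codons_per_gene = 300,
    params = selection_params(0.01, 0.01, gamma = 6),
    seed = 15
  )
  alns <- simulate_alignments(cfg_sel)
  seqs <- unlist(lapply(alns, function(a) unname(a$sequences)))
  gc3 <- nucleotide_composition(seqs, frame_aware = TRUE)$gc3
  expect_gt(gc3, 0.9)
  cfg_neu <- sim_config(
    n_genes = 5, n_haplotypes = c(A = 5, B = 5),
    codons_per_gene = 300,
    params = selection_params(0.01, 0.01, gamma = 0),
    seed = 16
  )
  alns_n <- simulate_alignments(cfg_neu)
  seqs_n <- unlist(lapply(alns_n, function(a) unname(a$sequences)))
  gc3_n <- nucleotide_composition(seqs_n, frame_aware = TRUE)$gc3
  expect_lt(abs(gc3_n - 0.5), 0.05)
})

test_that("GC-favouring selection makes GC-ending codons major", {
  cfg <- sim_config(
    n_genes = 10, n_haplotypes = c(A = 6, B = 6),
    codons_per_gene = 300,
    params = selection_params(0.01, 0.01, gamma = 1.5),
    seed = 23
  )
  alns <- simulate_alignments(cfg)
  counts <- purrr::map_dfr(alns, function(a) count_codons(unname(a$sequences), id = a$gene_id))
  pooled <- dplyr::summarise(dplyr::group_by(counts, .data$codon),
    count = sum(.data$count), .groups = "drop"
  )
  mj <- major_codons(pooled)
  observed <- mj[mj$is_major & !mj$no_data, ]
  third <- substr(observed$codon, 3, 3)
  expect_gte(mean(third %in% c("G", "C")), 0.9)
})

test_that("annotations are sorted, non-overlapping and regionally consistent", {
  cfg <- sim_config(n_genes = 30, codons_per_gene = 100, seed = 41)
  ann <- simulate_annotations(cfg)
  expect_equal(nrow(ann), 30L)
  expect_true(all(diff(ann$start) > 0))
  expect_true(all(ann$start[-1] >= ann$end[-nrow(ann)]))
  expect_true(all(ann$rho >= 0))
  mid <- (ann$start + ann$end) / 2
  first_bp <- min(cfg$breakpoints$start)
  last_bp <- max(cfg$breakpoints$end)
  expect_true(all(ann$region[mid < first_bp] == "proximal"))
  expect_true(all(ann$region[mid >= first_bp & mid <= last_bp] == "inverted"))
  expect_true(all(ann$region[mid > last_bp] == "distal"))
  # deterministic under the seed
  expect_identical(ann, simulate_annotations(cfg))
})
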