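test_that("genetic code partitions codons and degeneracy classes correctly", {
  code <- genetic_code()
  expect_equal(nrow(code), 61L)
  expect_equal(length(stop_codons()), 3L)
  folds <- dplyr::distinct(code, .data$aa, .data$fold)
  expect_equal(sum(folds$fold == 1), 2L) # Met, Trp
  expect_equal(sum(folds$fold == 2), 9L)
  expect_equal(sum(folds$fold == 3), 1L) # Ile
  expect_equal(sum(folds$fold == 4), 5L)
  expect_equal(sum(folds$fold == 6), 3L) # Leu, Ser, Arg
  expect_setequal(folds$aa[folds$fold == 1], c("M", "W"))
})

test_that("major codons follow usage, with lexicographic ties flagged", {
  # Lys usage as on the third chromosome: AAG is major
  lys <- tibble::tibble(codon = c("AAA", "AAG"), count = c(2652L, 7348L))
  mj <- major_codons(lys)
  lys_rows <- mj[mj$aa == "K", ]
  expect_equal(lys_rows$codon[lys_rows$is_major], "AAG")
  expect_equal(lys_rows$fraction[lys_rows$codon == "AAG"], 0.7348)
  expect_false(any(lys_rows$tie))

  # Asp tie resolves to GAC lexicographically and is flagged
  asp <- tibble::tibble(codon = c("GAT", "GAC"), count = c(50L, 50L))
  mj2 <- major_codons(asp)
  asp_rows <- mj2[mj2$aa == "D", ]
  expect_equal(asp_rows$codon[asp_rows$is_major], "GAC")
  expect_true(all(asp_rows$tie))

  # Leu counts proportional to observed genome usage give CTG
  leu <- tibble::tibble(
    codon = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
    count = c(296L, 1476L, 758L, 1938L, 724L, 4809L)
  )
  mj3 <- major_codons(leu)
  leu_rows <- mj3[mj3$aa == "L", ]
  expect_equal(leu_rows$codon[leu_rows$is_major], "CTG")

  # onefold amino acids never appear
  met <- major_codons(tibble::tibble(codon = "AAA", count = 5L))
  expect_false("M" %in% met$aa)
  expect_false("W" %in% met$aa)
})

test_that("major_codons rejects empty and stop-containing input", {
  expect_error(major_codons(tibble::tibble(codon = character(), count = integer())))
  expect_error(
    major_codons(tibble::tibble(codon = "TAA", count = 3L)),
    "stop"
  )
})

test_that("heterogeneity G-test matches direct evaluation", {
  expect_equal(g_test_heterogeneity(c(100, 100))$G, 0)
  expect_equal(
    g_test_heterogeneity(c(100, 300))$G,
    2 * (100 * log(100 / 200) + 300 * log(300 / 200))
  )
  # 0 * ln 0 convention
  expect_equal(g_test_heterogeneity(c(0, 200))$G, 2 * 200 * log(2))
  expect_equal(g_test_heterogeneity(c(10, 20, 30))$df, 2L)
  expect_error(g_test_heterogeneity(c(5)), ">= 2")
  expect_error(g_test_heterogeneity(c(-1, 5)), "negative")
})

test_that("G is label-permutation invariant and zero iff counts equal", {
  set.seed(42)
  for (r in 1:20) {
    k <- sample(2:6, 1)
    cnt <- sample(0:50, k, replace = TRUE)
    if (sum(cnt) == 0) cnt[1] <- 1
    g1 <- g_test_heterogeneity(cnt)$G
    g2 <- g_test_heterogeneity(sample(cnt))$G
    expect_equal(g1, g2)
    expect_gte(g1, 0)
    if (length(unique(cnt)) > 1) expect_gt(g1, 0)
  }
})

test_that("uniform random counts make each codon major at rate ~ 1/k", {
  set.seed(7)
  k <- 4 # Gly codons
  hits <- integer(k)
  n_rep <- 400
  gly <- genetic_code()$codon[genetic_code()$aa == "G"]
  for (r in seq_len(n_rep)) {
    cnt <- stats::rmultinom(1, 60, rep(1 / k, k))[, 1]
    mj <- major_codons(tibble::tibble(codon = gly, count = cnt))
    hits <- hits + (mj$is_major[match(gly, mj$codon)])
  }
  # binomial tolerance around 1/4
  expect_true(all(abs(hits / n_rep - 1 / k) < 4 * sqrt(0.25 * 0.75 / n_rep)))
})

test_that("nucleotide composition handles GC extremes, GC3 and errors", {
  expect_equal(nucleotide_composition("GCGC")$pct_gc, 100)
  expect_equal(nucleotide_composition("ATAT")$pct_gc, 0)
  expect_equal(nucleotide_composition("ATGGCC", frame_aware = TRUE)$gc3, 1.0)
  comp <- nucleotide_composition(c("ATGNNC", "A-GCTA"))
  expect_equal(comp$frac_a + comp$frac_c + comp$frac_g + comp$frac_t, 1)
  expect_error(nucleotide_composition(character()), "empty")
  expect_error(nucleotide_composition("ATGC", frame_aware = TRUE), "divisible")
})

test_that("usage fractions sum to one within every amino acid", {
  set.seed(11)
  code <- genetic_code()
  cnt <- tibble::tibble(codon = code$codon, count = rpois(61, 40) + 1L)
  mj <- major_codons(cnt)
  sums <- tapply(mj$fraction, mj$aa, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # exactly one major per amino acid
  n_major <- tapply(mj$is_major, mj$aa, sum)
  expect_true(all(n_major == 1))
})
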