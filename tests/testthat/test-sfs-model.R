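test_that("equilibrium SFS matches its analytic anchors", {
  # n = 2 symmetric neutral case
  p <- expected_sfs_equilibrium(selection_params(0.01, 0.01, 0), 2)
  expect_equal(p[2], 0.0098, tolerance = 1e-3)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # symmetry when gamma = 0 and theta01 = theta10
  p10 <- expected_sfs_equilibrium(selection_params(0.02, 0.02, 0), 10)
  expect_equal(p10, rev(p10))
  # strong positive selection pushes all mass to fixation of the focal state
  p_str <- expected_sfs_equilibrium(selection_params(0.01, 0.01, 40), 10)
  expect_gt(p_str[11], 0.99)
})

test_that("focal-state relabeling duality holds", {
  set.seed(4)
  for (r in 1:8) {
    t01 <- runif(1, 1e-3, 0.05)
    t10 <- runif(1, 1e-3, 0.05)
    gam <- runif(1, -4, 4)
    n <- sample(4:30, 1)
    a <- expected_sfs_equilibrium(selection_params(t01, t10, gam), n)
    b <- rev(expected_sfs_equilibrium(selection_params(t10, t01, -gam), n))
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("expansion model reduces to equilibrium when g = 1 or tau = 0", {
  pr <- selection_params(0.01, 0.02, 0.5, g = 1, tau = 0.3)
  eq <- expected_sfs_equilibrium(pr, 20)
  expect_lt(total_variation(expected_sfs_expansion(pr, 20), eq), 1e-8)
  pr0 <- selection_params(0.01, 0.02, 0.5, g = 4, tau = 0)
  expect_lt(total_variation(expected_sfs_expansion(pr0, 20), eq), 1e-8)
})

test_that("expansion model relaxes to the rescaled equilibrium", {
  # mutation rates of order one so the diffusion genuinely relaxes by tau = 10
  pr <- selection_params(0.8, 1.2, 1.5, g = 2, tau = 10)
  p_lim <- expected_sfs_expansion(pr, 12)
  p_eq <- expected_sfs_equilibrium(selection_params(1.6, 2.4, 3.0), 12)
  expect_lt(total_variation(p_lim, p_eq), 1e-4)
})

test_that("expansion SFS matches the Wright-Fisher matrix oracle", {
  p <- expected_sfs_expansion(selection_params(0.01, 0.01, 1, g = 4, tau = 0.1), 10)
  p_or <- wf_expansion_sfs(0.01, 0.01, 1, g = 4, tau = 0.1, n = 10)
  expect_lt(total_variation(p, p_or), 5e-3)
  expect_equal(sum(p), 1, tolerance = 1e-10)
  expect_true(all(p >= 0))
})

test_that("multinomial SFS log-likelihood follows its contract", {
  # direct evaluation
  expect_equal(
    sfs_loglik(c(2, 1, 1), c(0.5, 0.25, 0.25)),
    2 * log(0.5) + 2 * log(0.25)
  )
  # all counts in one class
  expect_equal(sfs_loglik(c(0, 7, 0), c(0.2, 0.5, 0.3)), 7 * log(0.5))
  # Gibbs inequality: the data proportions maximise the likelihood
  cnt <- c(5, 3, 2)
  p_hat <- cnt / sum(cnt)
  set.seed(6)
  for (r in 1:20) {
    q <- stats::runif(3)
    q <- q / sum(q)
    expect_lte(sfs_loglik(cnt, q), sfs_loglik(cnt, p_hat) + 1e-12)
  }
  # zero probability on an occupied class
  expect_identical(sfs_loglik(c(1, 0), c(0, 1)), -Inf)
  expect_error(sfs_loglik(c(1, 2), c(1)), "length")
})

test_that("parameter validation rejects impossible values", {
  expect_error(selection_params(-0.1, 0.01), "> 0")
  expect_error(selection_params(0.01, 0.01, g = 0), "> 0")
  expect_error(selection_params(0.01, 0.01, tau = -1), ">= 0")
  expect_equal(selection_params(0.005, 0.01)$kappa, 2)
  expect_error(expected_sfs_equilibrium(selection_params(0.01, 0.01), 1), ">= 2")
})

test_that("nested models respect the likelihood ordering", {
  pr <- selection_params(0.01, 0.02, 0.8, g = 3, tau = 0.1)
  counts <- expected_sfs(pr, 12) * 5e4
  f_l1 <- fit_sfs_model(counts, model = "L1", n_starts = 2, seed = 3, grid_size = 96)
  f_l0 <- fit_sfs_model(counts, model = "L0", n_starts = 6, seed = 3)
  f_ns <- fit_sfs_model(counts, model = "NS", n_starts = 2, seed = 3, grid_size = 96)
  expect_gte(f_l1$loglik, f_l0$loglik - 1e-6)
  expect_gte(f_l1$loglik, f_ns$loglik - 1e-6)
  out <- lrt(f_l1, f_l0)
  expect_gte(out$chisq, 0)
  expect_equal(out$df, 2)
})

test_that("symmetric neutral data yield gamma ~ 0 and kappa ~ 1", {
  pr <- selection_params(0.01, 0.01, 0)
  counts <- expected_sfs(pr, 12) * 1e6
  f <- fit_sfs_model(counts, model = "L0", n_starts = 8, seed = 11)
  expect_lt(abs(f$params$gamma), 0.05)
  expect_lt(abs(f$params$kappa - 1), 0.05)
})

test_that("LRT arithmetic and failure modes", {
  expect_equal(lrt(-100, -110, df = 2)$chisq, 20)
  expect_equal(lrt(-100, -100, df = 2)$p_value, 1)
  expect_error(lrt(-110, -100, df = 2), "optimizer failure")
})

test_that("tidy and glance expose fit results in broom style", {
  counts <- expected_sfs(selection_params(0.01, 0.02, 0.5), 8) * 1e4
  f <- fit_sfs_model(counts, model = "L0", n_starts = 4, seed = 2)
  td <- tidy(f)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_true("kappa" %in% td$term)
  gl <- glance(f)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$model, "L0")
})

test_that("binned fits partition genes and recover an increasing gamma trend", {
  gammas <- c(0.3, 2.0)
  cfg <- sim_config(
    n_genes = 40, n_haplotypes = c(A = 5, B = 5),
    codons_per_gene = 250,
    params = lapply(gammas, function(g) selection_params(0.01, 0.02, g)),
    seed = 71
  )
  alns <- simulate_alignments(cfg)
  counts <- purrr::map_dfr(alns, function(a) {
    count_codons(unname(a$sequences), id = a$gene_id)
  })
  pooled <- dplyr::summarise(dplyr::group_by(counts, .data$codon),
    count = sum(.data$count), .groups = "drop"
  )
  mj <- major_codons(pooled)
  scores <- codon_bias_scores(counts, majors = mj)
  fops <- stats::setNames(scores$fop, scores$gene_id)
  res <- fit_binned(alns, fops, mj,
    k = 2, model = "L0", n_starts = 4,
    seed = 5, boot = 10
  )
  expect_equal(nrow(res), 2L)
  expect_equal(res$n_genes, c(20L, 20L))
  # high-Fop bin is enriched for the high-gamma class
  expect_gt(res$gamma[2], res$gamma[1])
  expect_true(all(res$gamma_lo <= res$gamma & res$gamma <= res$gamma_hi,
    na.rm = TRUE
  ))
})
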