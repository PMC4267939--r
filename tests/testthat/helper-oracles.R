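# Independent oracles used across the suite. These deliberately avoid the
# package's own computational routes.

# Equilibrium sampling probabilities by adaptive quadrature of the
# stationary density against the binomial kernel. Endpoint classes use a
# power substitution (u = x^A on the left, u = (1-x)^B on the right) that
# absorbs the algebraic boundary singularities; interior classes are
# smooth and integrated directly.
quad_equilibrium_sfs <- function(t01, t10, gam, n) {
  raw <- sapply(0:n, function(i) {
    A <- i + t01
    B <- n - i + t10
    v <- if (i >= 1 && i <= n - 1) {
      stats::integrate(function(x) x^(A - 1) * (1 - x)^(B - 1) * exp(gam * x),
        0, 1,
        rel.tol = 1e-11
      )$value
    } else {
      left <- stats::integrate(
        function(u) (1 - u^(1 / A))^(B - 1) * exp(gam * u^(1 / A)) / A,
        0, 0.5^A,
        rel.tol = 1e-11
      )$value
      right <- stats::integrate(
        function(u) (1 - u^(1 / B))^(A - 1) * exp(gam * (1 - u^(1 / B))) / B,
        0, 0.5^B,
        rel.tol = 1e-11
      )$value
      left + right
    }
    choose(n, i) * v
  })
  raw / sum(raw)
}

# Wright-Fisher binomial-transition-matrix oracle for the one-step
# expansion model: the chain has 2N = C copies; per-generation selection
# and mutation rates are the g-rescaled diffusion parameters divided by
# 2C; the initial state is the diffusion equilibrium sampled into C
# copies, and the chain is iterated for round(tau * C) generations before
# binomial subsampling to n.
wf_expansion_sfs <- function(t01, t10, gam, g, tau, n, C = 400) {
  mu01 <- g * t01 / (2 * C)
  mu10 <- g * t10 / (2 * C)
  s <- g * gam / (2 * C)
  x <- (0:C) / C
  xs <- x + s * x * (1 - x)
  xstar <- pmin(pmax(xs * (1 - mu10) + (1 - xs) * mu01, 0), 1)
  P <- t(sapply(xstar, function(m) stats::dbinom(0:C, C, m)))
  v <- expected_sfs_equilibrium(selection_params(t01, t10, gam), C)
  for (k in seq_len(round(tau * C))) v <- as.vector(v %*% P)
  sapply(0:n, function(i) sum(v * stats::dbinom(i, n, x)))
}

total_variation <- function(a, b) 0.5 * sum(abs(a - b))

# straight-line evaluation of Tajima's published constants from (S, pi, n)
tajima_oracle <- function(S, pi_total, n) {
  a1 <- sum(1 / 1:(n - 1))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_total - S / a1) /
    sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# small deterministic alignment builder for unit tests
make_aln <- function(seqs, outgroup = NULL, ...) {
  haplotype_alignment(seqs, outgroup = outgroup, ...)
}
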