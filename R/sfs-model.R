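#' Selection/mutation/demography parameters for the SFS model
#'
#' Container for the parameters of the reversible two-allele
#' mutation-selection-drift model: `theta01 = 4*Ne*mu01` (scaled mutation
#' rate toward the focal allele), `theta10 = 4*Ne*mu10` (away from it),
#' `gamma = 4*Ne*s` (selection on the focal allele; positive favours it),
#' and for the one-step expansion `g = Ne_after / Ne_before` and
#' `tau = T / (2*Ne_after)` (time since the size change). The mutational
#' bias is `kappa = theta10 / theta01`.
#'
#' @param theta01,theta10 Scaled mutation rates (> 0).
#' @param gamma Scaled selection coefficient on the focal allele.
#' @param g Post/pre expansion effective-size ratio (> 0; 1 = no change).
#' @param tau Time since the size change in units of `2*Ne_after`
#'   generations (>= 0).
#' @return A list of class `selection_params` (with derived `kappa`).
#' @export
selection_params <- function(theta01, theta10, gamma = 0, g = 1, tau = Inf) {
  if (theta01 <= 0 || theta10 <= 0) stop("theta01, theta10 must be > 0", call. = FALSE)
  if (g <= 0) stop("g must be > 0", call. = FALSE)
  if (tau < 0) stop("tau must be >= 0", call. = FALSE)
  structure(
    list(
      theta01 = theta01, theta10 = theta10, gamma = gamma,
      g = g, tau = tau, kappa = theta10 / theta01
    ),
    class = "selection_params"
  )
}

# log of Kummer's confluent hypergeometric 1F1(a; b; z), a,b > 0.
# For z < 0 the Kummer transform 1F1(a;b;z) = e^z 1F1(b-a;b;-z) keeps all
# series terms positive; overflow is avoided by rescaling with a tracked
# log offset.
.log1f1 <- function(a, b, z) {
  if (z < 0) {
    return(z + .log1f1(b - a, b, -z))
  }
  if (z == 0) {
    return(0)
  }
  term <- 1
  total <- 1
  shift <- 0
  k <- 0
  repeat {
    term <- term * (a + k) * z / ((b + k) * (k + 1))
    total <- total + term
    k <- k + 1
    if (total > 1e280) {
      total <- total * 1e-280
      term <- term * 1e-280
      shift <- shift + 280 * log(10)
    }
    if ((term < total * 1e-17 && k > z) || k > 1e6) break
  }
  log(total) + shift
}

#' Expected site frequency spectrum at mutation-selection-drift equilibrium
#'
#' Under Wright's stationary density for the focal-allele frequency,
#' `phi(x) propto x^(theta01-1) * (1-x)^(theta10-1) * exp(gamma*x)`,
#' the probability that a site shows `i` of `n` sampled haplotypes carrying
#' the focal allele has the closed form
#' `p_i propto choose(n,i) * Beta(i+theta01, n-i+theta10) *
#'  1F1(i+theta01; n+theta01+theta10; gamma)`,
#' normalised over `i = 0..n`. Computed in log space with a
#' positive-series evaluation of the confluent hypergeometric function.
#'
#' @param params A [selection_params()] (fields `g`, `tau` are ignored).
#' @param n Sample size (>= 2).
#' @return Numeric vector `p_0..p_n` summing to 1.
#' @export
#' @examples
#' expected_sfs_equilibrium(selection_params(0.01, 0.01, gamma = 0), n = 2)
expected_sfs_equilibrium <- function(params, n) {
  stopifnot(inherits(params, "selection_params"))
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  i <- 0:n
  a <- i + params$theta01
  b <- n + params$theta01 + params$theta10
  lh <- vapply(a, function(ai) .log1f1(ai, b, params$gamma), numeric(1))
  lp <- lchoose(n, i) + lbeta(a, n - i + params$theta10) + lh
  if (any(!is.finite(lp))) {
    stop(
      "non-finite hypergeometric evaluation at theta01=", params$theta01,
      " theta10=", params$theta10, " gamma=", params$gamma,
      call. = FALSE
    )
  }
  p <- exp(lp - max(lp))
  p / sum(p)
}

#' Expected site frequency spectrum after a one-step population expansion
#'
#' The allele-frequency density starts at the equilibrium for
#' `(theta01, theta10, gamma)`; at the size change all scaled parameters
#' become `g` times larger, and the density is evolved under the
#' Wright-Fisher diffusion with the rescaled parameters for `tau` time
#' units (`2*Ne_after` generations each) before being integrated against
#' the binomial sampling kernel.
#'
#' Numerically, the forward equation is discretised in the self-adjoint
#' form `phi * du/dt = d/dx (V*phi/2 * du/dx)` (with `f = phi*u` and `phi`
#' the post-change stationary density), as a zero-flux finite-volume system
#' on a Chebyshev-clustered grid whose cell masses are computed by
#' singularity-absorbing quadrature; the semi-discrete system is advanced
#' by Crank-Nicolson time stepping on a geometric time-step ramp
#' (implicit-Euler start), with tridiagonal Thomas solves in compiled code.
#' The rescaled stationary density is an exact fixed point of the scheme,
#' so the `tau -> Inf` limit reproduces the closed form. `g = 1` (or
#' `tau = 0`, `tau = Inf`) short-circuits to the appropriate equilibrium.
#'
#' @param params A [selection_params()] with finite `g` and `tau`.
#' @param n Sample size (>= 2).
#' @param grid_size Number of finite-volume cells (default 192).
#' @return Numeric vector `p_0..p_n` summing to 1.
#' @export
expected_sfs_expansion <- function(params, n, grid_size = 192L) {
  stopifnot(inherits(params, "selection_params"))
  if (n < 2) stop("n must be >= 2", call. = FALSE)
  g <- params$g
  tau <- params$tau
  if (g == 1 || tau == 0) {
    return(expected_sfs_equilibrium(params, n))
  }
  new_p <- selection_params(g * params$theta01, g * params$theta10, g * params$gamma)
  if (is.infinite(tau)) {
    return(expected_sfs_equilibrium(new_p, n))
  }
  p <- expansion_sfs_cpp(
    a_new = new_p$theta01, b_new = new_p$theta10, c_new = new_p$gamma,
    a_old = params$theta01, b_old = params$theta10, c_old = params$gamma,
    n = as.integer(n), K = as.integer(grid_size), tau = tau
  )
  if (any(!is.finite(p)) || any(p < -1e-8)) {
    stop("non-convergent expansion solve; parameter report: g=", g, " tau=", tau,
      call. = FALSE
    )
  }
  p[p < 0] <- 0
  p / sum(p)
}

#' Expected SFS under any model variant
#'
#' Dispatches to the equilibrium or expansion form depending on `g`/`tau`.
#'
#' @inheritParams expected_sfs_expansion
#' @export
expected_sfs <- function(params, n, grid_size = 192L) {
  if (params$g == 1 || params$tau == 0 || is.infinite(params$tau)) {
    expected_sfs_equilibrium(params, n)
  } else {
    expected_sfs_expansion(params, n, grid_size = grid_size)
  }
}

# Finite-volume discretisation of the diffusion in self-adjoint form.
# Returns the symmetrised eigensystem, initial condition u0 (old/new
# density ratio per cell) and the binomial moment matrix mapping u to the
# sampled SFS. All phi evaluations are done in a common log scale.
.fv_system <- function(a_new, b_new, c_new, a_old, b_old, c_old, n, K) {
  edges <- (1 - cos(pi * (0:K) / K)) / 2
  # 7-point Gauss-Legendre nodes/weights on [0, 1]
  gl <- .gl7()
  # quadrature nodes per cell; first/last cells use a power transform that
  # absorbs the x^(a-1) / (1-x)^(b-1) boundary singularities
  lo <- edges[seq_len(K)]
  hi <- edges[seq_len(K) + 1L]
  h <- hi - lo
  lgw <- log(gl$w)
  # interior cells, fully vectorised (rows 1 and K overwritten below)
  qx <- outer(h, gl$x) + lo
  lqx <- log(qx)
  l1qx <- log1p(-qx)
  lhmat <- log(h) + matrix(lgw, K, 7L, byrow = TRUE)
  ljac_new <- lhmat + (a_new - 1) * lqx + (b_new - 1) * l1qx + c_new * qx
  ljac_old <- lhmat + (a_old - 1) * lqx + (b_old - 1) * l1qx + c_old * qx
  # first cell: x = hi * t^(1/a) absorbs the x^(a-1) singularity
  t <- gl$x
  x1 <- hi[1] * t^(1 / a_new)
  qx[1, ] <- x1
  lqx[1, ] <- log(hi[1]) + log(t) / a_new
  l1qx[1, ] <- log1p(-x1)
  ljac_new[1, ] <- lgw + a_new * log(hi[1]) - log(a_new) +
    (b_new - 1) * l1qx[1, ] + c_new * x1
  xo <- hi[1] * t^(1 / a_old)
  ljac_old[1, ] <- lgw + a_old * log(hi[1]) - log(a_old) +
    (b_old - 1) * log1p(-xo) + c_old * xo
  # last cell: 1 - x = (1 - lo) * t^(1/b) absorbs the (1-x)^(b-1) singularity
  wid <- 1 - lo[K]
  one_minus <- wid * t^(1 / b_new)
  qx[K, ] <- 1 - one_minus
  lqx[K, ] <- log1p(-one_minus)
  l1qx[K, ] <- log(wid) + log(t) / b_new
  ljac_new[K, ] <- lgw + b_new * log(wid) - log(b_new) +
    (a_new - 1) * lqx[K, ] + c_new * qx[K, ]
  om_o <- wid * t^(1 / b_old)
  ljac_old[K, ] <- lgw + b_old * log(wid) - log(b_old) +
    (a_old - 1) * log1p(-om_o) + c_old * (1 - om_o)
  shift_new <- max(ljac_new)
  wq_new <- exp(ljac_new - shift_new) # K x 7 effective weights, common scale
  shift_old <- max(ljac_old)
  wq_old <- exp(ljac_old - shift_old)
  w_cell <- rowSums(wq_new)
  v_cell <- rowSums(wq_old)
  u0 <- (v_cell / sum(v_cell)) / (w_cell / sum(w_cell))
  # cell centroids under the new-parameter weight
  xbar <- rowSums(wq_new * qx) / w_cell
  # interface diffusion coefficients D = x(1-x)/2 * phi_new(x) at edges,
  # same log scale as the cell masses
  e_int <- edges[2:K]
  lD <- log(e_int * (1 - e_int) / 2) +
    (a_new - 1) * log(e_int) + (b_new - 1) * log1p(-e_int) + c_new * e_int -
    shift_new
  D <- exp(lD)
  dx <- diff(xbar)
  off <- D / dx # flux coupling between neighbouring cells
  # binomial sampling moments per cell: m[i+1, j] = int_cell C(n,i) x^i (1-x)^(n-i) phi_new
  i <- 0:n
  lc <- lchoose(n, i)
  lw <- outer(i, as.vector(lqx)) + outer(n - i, as.vector(l1qx)) + lc
  contrib <- exp(lw) * rep(as.vector(wq_new), each = n + 1L)
  dim(contrib) <- c((n + 1L) * K, 7L)
  M <- matrix(rowSums(contrib), n + 1L, K)
  M <- M / sum(w_cell) # so that M %*% 1 = equilibrium SFS (normalised)
  list(
    w = w_cell, off = off,
    u0 = u0, moments = M, xbar = xbar, wnorm = w_cell / sum(w_cell)
  )
}

# 7-point Gauss-Legendre rule on [0, 1], memoised
.gl7 <- function() {
  if (!is.null(.ng_env$gl7)) {
    return(.ng_env$gl7)
  }
  x <- c(
    -0.9491079123427585, -0.7415311855993945, -0.4058451513773972, 0,
    0.4058451513773972, 0.7415311855993945, 0.9491079123427585
  )
  w <- c(
    0.1294849661688697, 0.2797053914892766, 0.3818300505051189,
    0.4179591836734694, 0.3818300505051189, 0.2797053914892766,
    0.1294849661688697
  )
  out <- list(x = (x + 1) / 2, w = w / 2)
  .ng_env$gl7 <- out
  out
}

#' Multinomial log-likelihood of an SFS under class probabilities
#'
#' `lnL = sum_i c_i * log(p_i)` up to a data-only constant. A class with
#' observations but zero probability yields `-Inf`.
#'
#' @param sfs An [new_sfs()] object or a numeric count vector `c_0..c_n`.
#' @param p Probability vector of matching length.
#' @return The log-likelihood.
#' @export
sfs_loglik <- function(sfs, p) {
  counts <- if (inherits(sfs, "sfs")) sfs$count else as.numeric(sfs)
  if (length(p) != length(counts)) {
    stop("probability vector length must equal n + 1", call. = FALSE)
  }
  use <- counts > 0
  if (any(p[use] <= 0)) {
    return(-Inf)
  }
  sum(counts[use] * log(p[use]))
}
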