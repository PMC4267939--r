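#' Fit the mutation-selection-drift SFS model by maximum likelihood
#'
#' Fits the multinomial likelihood of an observed site frequency spectrum
#' under one of three nested model variants:
#' * `L1` - full model: mutation (`theta01`, `theta10`), selection
#'   (`gamma`) and a one-step population expansion (`g`, `tau`);
#' * `L0` - equilibrium model: `g` fixed at 1, `tau` dropped;
#' * `NS` - no-selection model: `gamma` fixed at 0, expansion retained.
#'
#' The likelihood surface is searched by multi-start local optimization on
#' log-transformed positive parameters (`gamma` untransformed): each start
#' alternates the bounded PORT quasi-Newton routine ([stats::nlminb()])
#' with Nelder-Mead until neither improves by `restart_tol`. Starts are
#' drawn log-uniform from a seeded generator; for the expansion models one
#' additional set of informed starts is derived from a fast equilibrium
#' (`L0`) fit crossed with a small grid of (`g`, `tau`) values and a short
#' profile over the mutational-bias ratio, and the winner is refined by a
#' scan along `kappa` (see `kappa_refine`).
#'
#' @param sfs An [new_sfs()] object or count vector `c_0..c_n`.
#' @param model `"L1"`, `"L0"` or `"NS"`.
#' @param n_starts Number of random starts (default 50).
#' @param seed Integer seed for the start draws (required).
#' @param fixed Named list pinning parameters (e.g. `list(gamma = 0)`).
#' @param grid_size Frequency-grid size passed to
#'   [expected_sfs_expansion()].
#' @param maxit Nelder-Mead iteration cap per start.
#' @param restart_tol Log-likelihood improvement below which polishing
#'   restarts stop.
#' @param informed_starts Add the equilibrium-seeded start grid (default
#'   `TRUE`; ignored for `L0`).
#' @param start Optional named vector of free-parameter values used as an
#'   additional start.
#' @param screen Rank candidate starts by their initial likelihood and run
#'   local optimization only from the best `max(5, n_starts)` of them
#'   (default `FALSE`; screening saves time but can drop the start that
#'   leads to the global basin).
#' @param kappa_refine After the multistart, refine the winner by a scan
#'   along the mutational-bias ratio `kappa = theta10/theta01` (the
#'   direction along which the expansion likelihood can hold competing
#'   optima): stepped `kappa` values are grafted onto the incumbent's
#'   remaining parameters, re-optimized, and the best point fully
#'   polished. Default `TRUE`; applies when both rates are free.
#' @return An object of class `sfs_fit`: list with `model`, `loglik`,
#'   `params` ([selection_params()]), `estimates` (tibble), `n`, `n_starts`,
#'   `starts` (per-start diagnostics tibble), `seed`, `convergence`.
#' @export
fit_sfs_model <- function(sfs, model = c("L1", "L0", "NS"), n_starts = 50,
                          seed, fixed = list(), grid_size = 192L,
                          maxit = 2000L, restart_tol = 1e-6,
                          informed_starts = TRUE, start = NULL,
                          kappa_refine = TRUE, screen = FALSE) {
  model <- match.arg(model)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  counts <- if (inherits(sfs, "sfs")) sfs$count else as.numeric(sfs)
  n <- length(counts) - 1L
  if (n < 2 || sum(counts) <= 0) stop("SFS is empty or too small", call. = FALSE)
  if (model == "NS") fixed$gamma <- 0
  if (model == "L0") {
    fixed$g <- 1
    fixed$tau <- Inf
  }
  free <- setdiff(c("theta01", "theta10", "gamma", "g", "tau"), names(fixed))
  if (model == "L0") free <- setdiff(free, c("g", "tau"))
  lower <- c(theta01 = 1e-5, theta10 = 1e-5, gamma = -50, g = 0.02, tau = 1e-5)
  upper <- c(theta01 = 1, theta10 = 1, gamma = 50, g = 50, tau = 50)
  to_opt <- function(v) {
    pos <- names(v) != "gamma"
    v[pos] <- log(v[pos])
    v
  }
  from_opt <- function(z) {
    pos <- names(z) != "gamma"
    z[pos] <- exp(z[pos])
    z
  }
  nll_full <- function(full) {
    if (any(full[free] < lower[free] - 1e-12) ||
      any(full[free] > upper[free] + 1e-12)) {
      return(1e12)
    }
    p <- tryCatch(
      expected_sfs(
        selection_params(
          full[["theta01"]], full[["theta10"]], full[["gamma"]],
          full[["g"]], full[["tau"]]
        ),
        n,
        grid_size = grid_size
      ),
      error = function(e) NULL
    )
    if (is.null(p)) {
      return(1e12)
    }
    ll <- sfs_loglik(counts, p)
    if (!is.finite(ll)) {
      return(1e12)
    }
    -ll
  }
  nll <- function(z) {
    v <- from_opt(stats::setNames(z, free))
    full <- c(v, unlist(fixed))[c("theta01", "theta10", "gamma", "g", "tau")]
    nll_full(full)
  }
  restore <- .with_seed(seed)
  on.exit(restore(), add = TRUE)
  draw_start <- function() {
    v <- c(
      theta01 = exp(stats::runif(1, log(5e-4), log(0.1))),
      theta10 = exp(stats::runif(1, log(5e-4), log(0.1))),
      gamma = stats::runif(1, -5, 5),
      g = exp(stats::runif(1, log(0.2), log(30))),
      tau = exp(stats::runif(1, log(0.005), log(2)))
    )
    v[free]
  }
  starts <- lapply(seq_len(max(0, n_starts)), function(i) draw_start())
  if (!is.null(start)) starts <- c(list(start[free]), starts)
  if (length(starts) == 0L) starts <- list(draw_start())
  if (informed_starts && model != "L0") {
    eq <- fit_sfs_model(counts,
      model = "L0", n_starts = 8, seed = seed + 1L,
      maxit = maxit, informed_starts = FALSE, kappa_refine = FALSE
    )
    base <- c(
      theta01 = eq$params$theta01, theta10 = eq$params$theta10,
      gamma = eq$params$gamma
    )
    for (gg in c(1.5, 4, 16)) {
      for (tt in c(0.01, 0.1, 0.5)) {
        v <- c(base, g = gg, tau = tt)
        starts[[length(starts) + 1L]] <- v[free]
      }
    }
    if (all(c("theta01", "theta10") %in% free)) {
      # mutational-bias profile: the likelihood can hold competing optima
      # that differ mainly in kappa, so sweep kappa on a fixed grid with
      # theta10 = kappa * theta01 pinned, optimize the rest briefly, and
      # seed the main search from the best profile points
      theta_sum <- eq$params$theta01 + eq$params$theta10
      gam0 <- if ("gamma" %in% free) eq$params$gamma else fixed$gamma
      kappas <- exp(seq(log(0.05), log(20), length.out = 7))
      prof_free <- setdiff(free, "theta10")
      prof <- lapply(kappas, function(kap) {
        st <- c(
          theta01 = theta_sum / (1 + kap), gamma = gam0,
          g = 4, tau = 0.1
        )[prof_free]
        z <- to_opt(st)
        o <- stats::nlminb(z, function(zz) {
          v <- from_opt(stats::setNames(zz, prof_free))
          full <- c(v, unlist(fixed))
          full[["theta10"]] <- kap * full[["theta01"]]
          nll_full(full[c("theta01", "theta10", "gamma", "g", "tau")])
        }, control = list(iter.max = 150, eval.max = 600, rel.tol = 1e-9))
        o$value <- o$objective
        v <- from_opt(stats::setNames(o$par, prof_free))
        full <- c(v, unlist(fixed))
        full[["theta10"]] <- kap * full[["theta01"]]
        list(value = o$value, par = full[free])
      })
      ord <- order(vapply(prof, function(p) p$value, numeric(1)))
      for (k in ord[1:2]) {
        starts[[length(starts) + 1L]] <- prof[[k]]$par
      }
    }
  }
  zlower <- to_opt(lower[free])
  zupper <- to_opt(upper[free])
  # screened multistart: rank all candidate starts by their initial
  # likelihood and optimize locally only from the most promising ones
  if (screen && length(starts) > max(5L, n_starts)) {
    v0 <- vapply(starts, function(s) nll(to_opt(s)), numeric(1))
    keep_n <- min(length(starts), max(5L, n_starts))
    starts <- starts[order(v0)[seq_len(keep_n)]]
  }
  runs <- purrr::map_dfr(seq_along(starts), function(si) {
    z <- to_opt(starts[[si]])
    pol <- .polish_alternate(z, nll, maxit, zlower, zupper,
      tol = max(restart_tol, 1e-5), max_rounds = 3L
    )
    est <- from_opt(stats::setNames(pol$par, free))
    tibble::tibble(
      start = si, loglik = -pol$value, convergence = 0L,
      par = list(est)
    )
  })
  ok <- runs$loglik > -1e11
  if (!any(ok)) stop("all optimizer starts failed to converge", call. = FALSE)
  top <- which.max(runs$loglik)
  est <- runs$par[[top]]
  best_ll <- runs$loglik[top]
  if (kappa_refine && model != "L0" &&
    all(c("theta01", "theta10") %in% free)) {
    ref <- .kappa_continuation(
      est, unlist(fixed), free, nll_full, from_opt, to_opt,
      zlower, zupper,
      maxit = maxit
    )
    if (-ref$value > best_ll + 1e-9) {
      est <- ref$par
      best_ll <- -ref$value
      runs <- dplyr::bind_rows(runs, tibble::tibble(
        start = length(starts) + 1L, loglik = best_ll,
        convergence = 0L, par = list(est)
      ))
      top <- nrow(runs)
    }
  }
  full <- c(est, unlist(fixed))[c("theta01", "theta10", "gamma", "g", "tau")]
  params <- selection_params(
    full[["theta01"]], full[["theta10"]], full[["gamma"]],
    full[["g"]], full[["tau"]]
  )
  structure(
    list(
      model = model,
      loglik = runs$loglik[top],
      params = params,
      estimates = tibble::tibble(
        term = c("theta01", "theta10", "gamma", "g", "tau", "kappa"),
        estimate = c(
          params$theta01, params$theta10, params$gamma, params$g,
          params$tau, params$kappa
        ),
        fixed = c(
          c("theta01", "theta10", "gamma", "g", "tau") %in% names(fixed),
          FALSE
        )
      ),
      n = n, sites = sum(counts), counts = counts,
      n_starts = length(starts), starts = dplyr::select(runs, -"par"),
      seed = seed,
      convergence = runs$convergence[top] == 0
    ),
    class = "sfs_fit"
  )
}

# Alternate Nelder-Mead and PORT (nlminb) polishing until neither improves:
# the two methods stall at different points in the long curved valleys of
# the expansion likelihood, so the alternation ratchets down further than
# either alone.
.polish_alternate <- function(z, fn, maxit, zlower, zupper, tol = 1e-6,
                              value0 = NULL, max_rounds = 4L) {
  val <- if (is.null(value0)) fn(z) else value0
  for (round in seq_len(max_rounds)) {
    o1 <- tryCatch(
      stats::nlminb(z, fn,
        lower = zlower, upper = zupper,
        control = list(iter.max = 300, eval.max = 1500, rel.tol = 1e-10)
      ),
      error = function(e) NULL
    )
    if (!is.null(o1) && o1$objective < val) {
      z <- o1$par
      gain_port <- val - o1$objective
      val <- o1$objective
    } else {
      gain_port <- 0
    }
    o2 <- stats::optim(z, fn,
      method = "Nelder-Mead",
      control = list(maxit = min(maxit, 800L), reltol = 1e-10)
    )
    if (o2$value < val) {
      gain_nm <- val - o2$value
      z <- o2$par
      val <- o2$value
    } else {
      gain_nm <- 0
    }
    if (gain_port + gain_nm < tol) break
  }
  list(par = z, value = val)
}

# Refinement along kappa = theta10/theta01: the expansion likelihood can
# hold competing optima that differ mainly in the mutational-bias ratio,
# connected by a long curved valley. Scan stepped kappa values grafted onto
# the incumbent's remaining parameters with a bounded quasi-Newton solve,
# then fully polish the best point.
.kappa_continuation <- function(est, fixed_vec, free, nll_full, from_opt,
                                to_opt, zlower, zupper, maxit = 2000L) {
  order5 <- c("theta01", "theta10", "gamma", "g", "tau")
  fn <- function(zz) {
    v <- from_opt(stats::setNames(zz, free))
    nll_full(c(v, fixed_vec)[order5])
  }
  kap0 <- est[["theta10"]] / est[["theta01"]]
  kaps <- kap0 * exp(seq(-0.3, 0.3, by = 0.05))
  best <- list(value = fn(to_opt(est)), par = to_opt(est))
  for (kap in kaps) {
    graft <- est
    graft[["theta10"]] <- kap * graft[["theta01"]]
    z <- to_opt(graft)
    o <- tryCatch(
      stats::nlminb(z, fn,
        lower = zlower, upper = zupper,
        control = list(iter.max = 150, eval.max = 600, rel.tol = 1e-10)
      ),
      error = function(e) NULL
    )
    if (!is.null(o) && o$objective < best$value) {
      best <- list(value = o$objective, par = o$par)
    }
  }
  pol <- .polish_alternate(best$par, fn, maxit, zlower, zupper,
    value0 = best$value
  )
  list(value = pol$value, par = from_opt(stats::setNames(pol$par, free)))
}

#' @export
print.sfs_fit <- function(x, ...) {
  cat(
    "<sfs_fit>", x$model, " lnL =", format(x$loglik, digits = 10),
    " n =", x$n, " sites =", x$sites, "\n"
  )
  cat(
    " gamma =", signif(x$params$gamma, 4),
    " kappa =", signif(x$params$kappa, 4),
    " theta01 =", signif(x$params$theta01, 4),
    if (x$model != "L0") {
      paste(
        " g =", signif(x$params$g, 4),
        " tau =", signif(x$params$tau, 4)
      )
    } else {
      ""
    }, "\n"
  )
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an SFS model fit
#'
#' @param x An `sfs_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` and `fixed`.
#' @method tidy sfs_fit
#' @export
tidy.sfs_fit <- function(x, ...) {
  x$estimates
}

#' One-row summary of an SFS model fit
#'
#' @param x An `sfs_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `model`, `logLik`, `n`, `sites`,
#'   `n_starts`, `converged`.
#' @method glance sfs_fit
#' @export
glance.sfs_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model, logLik = x$loglik, n = x$n, sites = x$sites,
    n_starts = x$n_starts, converged = x$convergence
  )
}

#' Likelihood-ratio test between nested SFS model fits
#'
#' `chisq = 2 * (lnL_full - lnL_reduced)` compared against a chi-squared
#' distribution with `df` degrees of freedom.
#'
#' @param full,reduced Fitted models ([fit_sfs_model()]) or bare
#'   log-likelihood values.
#' @param df Difference in free parameters (default: inferred from the
#'   model ids, `L1` = 5, `NS` = 4, `L0` = 3).
#' @return A tibble with `chisq`, `df`, `p_value`.
#' @export
#' @examples
#' lrt(-1643574, -1647996, df = 2)
lrt <- function(full, reduced, df = NULL) {
  ll_f <- if (inherits(full, "sfs_fit")) full$loglik else as.numeric(full)
  ll_r <- if (inherits(reduced, "sfs_fit")) reduced$loglik else as.numeric(reduced)
  if (is.null(df)) {
    k <- c(L1 = 5, NS = 4, L0 = 3)
    if (inherits(full, "sfs_fit") && inherits(reduced, "sfs_fit")) {
      df <- k[[full$model]] - k[[reduced$model]]
    } else {
      stop("df must be given when passing bare log-likelihoods", call. = FALSE)
    }
  }
  if (ll_f < ll_r - 1e-8) {
    stop("full-model lnL below reduced-model lnL: optimizer failure", call. = FALSE)
  }
  chisq <- 2 * max(0, ll_f - ll_r)
  tibble::tibble(
    chisq = chisq, df = df,
    p_value = stats::pchisq(chisq, df, lower.tail = FALSE)
  )
}

#' Fit the selection model within covariate bins of genes
#'
#' Genes are partitioned into `k` equal-size bins at the quantile
#' boundaries of a covariate (codon bias `Fop`, recombination rate `rho`,
#' ...), one pooled SFS is built per bin, and the selection model is fitted
#' per bin. Confidence intervals come from a site-level bootstrap: SFS
#' counts are resampled multinomially (sites with replacement) and refitted
#' from the bin's point estimate.
#'
#' @param alns Named list of `haplotype_alignment`s (names = gene ids).
#' @param covariate Named numeric vector of the binning covariate per gene.
#' @param majors Major-codon table.
#' @param k Number of bins (default 4, quartiles).
#' @param model Model variant fitted per bin (default `"L1"`).
#' @param focal Focal state of the SFS (`"major"` or `"minor"`).
#' @param n_starts,seed,... Passed to [fit_sfs_model()].
#' @param boot Number of bootstrap replicates for the CI (default 200; 0
#'   skips the CI).
#' @param conf Confidence level (default 0.95).
#' @return A tibble with one row per bin: `bin`, `n_genes`, `sites`,
#'   `gamma`, `kappa`, `gamma_lo`, `gamma_hi`, `loglik`.
#' @export
fit_binned <- function(alns, covariate, majors, k = 4, model = "L1",
                       focal = "major", n_starts = 20, seed = 1,
                       boot = 200, conf = 0.95, ...) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (length(alns) < k) stop("fewer genes than bins", call. = FALSE)
  ids <- names(alns)
  cov <- covariate[ids]
  if (any(is.na(cov))) stop("every gene needs a covariate value", call. = FALSE)
  bins <- bin_genes(cov, k = k)
  purrr::map_dfr(seq_len(k), function(b) {
    sub <- alns[bins == b]
    sfs <- site_frequency_spectrum(sub, majors, focal = focal)
    if (sum(sfs$count[-c(1, length(sfs$count))]) == 0) {
      return(tibble::tibble(
        bin = b, n_genes = length(sub), sites = sum(sfs$count),
        gamma = NA_real_, kappa = NA_real_, gamma_lo = NA_real_,
        gamma_hi = NA_real_, loglik = NA_real_
      ))
    }
    fit <- fit_sfs_model(sfs,
      model = model, n_starts = n_starts,
      seed = seed + b, ...
    )
    lo <- hi <- NA_real_
    if (boot > 0) {
      restore <- .with_seed(seed + 1000L + b)
      on.exit(restore(), add = TRUE)
      tot <- sum(sfs$count)
      probs <- sfs$count / tot
      gammas <- vapply(seq_len(boot), function(r) {
        bs <- stats::rmultinom(1, tot, probs)[, 1]
        point <- c(
          theta01 = fit$params$theta01, theta10 = fit$params$theta10,
          gamma = fit$params$gamma, g = fit$params$g, tau = fit$params$tau
        )
        f <- tryCatch(
          fit_sfs_model(bs,
            model = model, n_starts = 0, seed = seed + r,
            informed_starts = FALSE, start = point, ...
          ),
          error = function(e) NULL
        )
        if (is.null(f)) NA_real_ else f$params$gamma
      }, numeric(1))
      qs <- stats::quantile(gammas, c((1 - conf) / 2, 1 - (1 - conf) / 2),
        na.rm = TRUE, names = FALSE
      )
      lo <- qs[1]
      hi <- qs[2]
    }
    tibble::tibble(
      bin = b, n_genes = length(sub), sites = sum(sfs$count),
      gamma = fit$params$gamma, kappa = fit$params$kappa,
      gamma_lo = lo, gamma_hi = hi, loglik = fit$loglik
    )
  })
}
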