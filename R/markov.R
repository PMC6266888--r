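# Censored first-order Markov likelihood (Eqs of the model: GPD exceedance
# margins, logistic lag-1 dependence, Markov factorization
# m(x1) * prod f(x_t, x_{t-1}) / m(x_{t-1}) per independent site chain) and
# its numerical maximization.

as_chain_list <- function(ds) {
  if (inherits(ds, "em_dataset")) {
    if (attr(ds, "scale") != "original") return(dataset_segments(ds))
    stop("dataset is on the original scale; call negate() first")
  }
  if (is.list(ds)) return(lapply(ds, as.numeric))
  list(as.numeric(ds))
}

#' Negative log-likelihood of the Markov-extremes model
#'
#' The censored likelihood over all independent site chains: exceedances of
#' `u` contribute the GPD density (scaled by the exceedance rate), censored
#' observations contribute the mass `1 - lambda_u`, and adjacent months are
#' coupled through the censored bivariate logistic density, following the
#' first-order Markov factorization.  Support violations yield a large
#' finite penalty rather than an exception, so optimizers can recover.
#'
#' @param par parameter vector `c(sigma, xi, alpha)`.
#' @param ds an `em_dataset` on the negated scale, a list of numeric chain
#'   vectors, or a single numeric vector.
#' @param u threshold on the negated scale.
#' @param lambda exceedance rate; default the empirical fraction above `u`.
#' @param paper_literal see [to_frechet()].
#' @return The negative log-likelihood (scalar).
#' @export
markov_nll <- function(par, ds, u, lambda = NULL, paper_literal = FALSE) {
  chains <- as_chain_list(ds)
  x <- unlist(chains, use.names = FALSE)
  lambda <- lambda %||% mean(x > u)
  cpp_markov_nll(as.numeric(par), chains, u, lambda, paper_literal)
}

#' Fit the Markov-extremes model
#'
#' Maximizes the censored Markov likelihood over `(sigma, xi, alpha)` by
#' BFGS on an unconstrained parameterization (`log sigma`; a scaled logit
#' for `alpha`), starting from the independent POT fit with `alpha = 0.8`
#' and falling back to a small grid of `alpha` starts if needed.  The
#' parameter covariance is the inverse of a numerically differenced Hessian
#' at the optimum (natural scale).
#'
#' @param ds an `em_dataset` on the negated scale (or list of chains).
#' @param u threshold on the negated scale.
#' @param start optional `c(sigma, xi, alpha)` start.
#' @param alpha_fixed freeze `alpha` (e.g. at 1 for the independence
#'   submodel) and optimize `(sigma, xi)` only.
#' @param lambda exceedance rate; default empirical.
#' @param paper_literal see [to_frechet()].
#' @param multi_start try a grid of `alpha` starts and keep the best
#'   optimum (default); disable for speed inside bootstrap loops.
#' @param hessian compute the covariance (disable inside bootstrap loops).
#' @param reltol optimizer relative tolerance on the objective.
#' @return An object of class `"markov_fit"`: fitted [gpd_tail()],
#'   `alpha`, standard errors `se` (named `sigma`, `xi`, `alpha`),
#'   covariance `cov`, `loglik`, `n_effective` (exceedance count),
#'   `converged`, `cov_ok`, and a `settings` record.
#' @export
fit_markov <- function(ds, u, start = NULL, alpha_fixed = NULL,
                       lambda = NULL, paper_literal = FALSE,
                       multi_start = TRUE, hessian = TRUE, reltol = 1e-12) {
  chains <- as_chain_list(ds)
  x <- unlist(chains, use.names = FALSE)
  n_exc <- sum(x > u)
  if (n_exc < 2) stop("need at least 2 exceedances above u")
  lambda <- lambda %||% (n_exc / length(x))
  eps <- 1e-3

  to_alpha <- function(a) eps + (1 - eps) * stats::plogis(a)
  from_alpha <- function(alpha) stats::qlogis((alpha - eps) / (1 - eps))
  nll_free <- function(th) {
    cpp_markov_nll(c(exp(th[1]), th[2], to_alpha(th[3])), chains, u,
                   lambda, paper_literal)
  }
  nll_fixed <- function(th) {
    cpp_markov_nll(c(exp(th[1]), th[2], alpha_fixed), chains, u,
                   lambda, paper_literal)
  }

  if (is.null(start)) {
    pot <- tryCatch(fit_pot(x, u), error = function(e) NULL)
    base <- if (is.null(pot)) c(stats::sd(x[x > u] - u), -0.1)
            else c(pot$tail$sigma, pot$tail$xi)
    # moment-style start for alpha from the empirical lag-1 tail
    # dependence at the threshold: chi = 2 - 2^alpha
    joint <- unlist(lapply(chains, function(ch)
      if (length(ch) > 1) ch[-1] > u & ch[-length(ch)] > u else logical(0)))
    chi0 <- if (length(joint)) mean(joint) / lambda else lambda
    alpha0 <- min(max(log2(2 - min(max(chi0, 0), 0.99)), 0.05), 0.95)
    start <- c(base, alpha0)
  }
  # keep starts strictly inside the feasible box so finite differences
  # never straddle the penalty region
  start[2] <- min(max(start[2], -0.985), 4.9)
  if (length(start) >= 3) start[3] <- min(max(start[3], 0.02), 0.98)
  alpha_grid <- if (!is.null(alpha_fixed)) numeric(0)
                else if (multi_start) c(0.2, 0.5, 0.8, 0.95) else numeric(0)
  starts <- c(list(start),
              lapply(alpha_grid, function(a) c(start[1], start[2], a)))

  best <- NULL
  traces <- character(0)
  fn <- if (is.null(alpha_fixed)) nll_free else nll_fixed
  for (s0 in starts) {
    th0 <- if (is.null(alpha_fixed)) c(log(s0[1]), s0[2], from_alpha(s0[3]))
           else c(log(s0[1]), s0[2])
    opt <- tryCatch(
      optim(th0, fn, method = "BFGS",
            control = list(reltol = reltol, maxit = 1000, ndeps = rep(1e-5, length(th0)))),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e9) {
      # BFGS stranded on the infeasibility plateau: recover with a
      # simplex pass, then polish
      nm <- tryCatch(
        optim(th0, fn, method = "Nelder-Mead",
              control = list(reltol = 1e-10, maxit = 2000)),
        error = function(e) NULL)
      if (!is.null(nm) && is.finite(nm$value) && nm$value < 1e9)
        opt <- tryCatch(
          optim(nm$par, fn, method = "BFGS",
                control = list(reltol = reltol, maxit = 1000, ndeps = rep(1e-5, length(th0)))),
          error = function(e) nm)
    }
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e9) {
      traces <- c(traces, sprintf("start (%s): failed or infeasible",
                                  paste(signif(s0, 3), collapse = ", ")))
      next
    }
    ok <- opt$convergence == 0
    traces <- c(traces, sprintf("start (%s): nll %.6f, convergence %d",
                                paste(signif(s0, 3), collapse = ", "),
                                opt$value, opt$convergence))
    if (ok && (is.null(best) || opt$value < best$value - 1e-9)) best <- opt
    if (!multi_start && ok) break
  }
  if (is.null(best))
    stop("Markov fit did not converge from any start:\n",
         paste(traces, collapse = "\n"))
  # restart from the optimum: a fresh BFGS pass (reset Hessian
  # approximation) tightens the stationarity of the returned point
  polish <- tryCatch(
    optim(best$par, fn, method = "BFGS",
          control = list(reltol = reltol, maxit = 500, ndeps = rep(1e-5, length(best$par)))),
    error = function(e) NULL)
  if (!is.null(polish) && polish$convergence == 0 &&
      polish$value <= best$value) best <- polish

  sigma <- exp(best$par[1]); xi <- best$par[2]
  alpha <- if (is.null(alpha_fixed)) to_alpha(best$par[3]) else alpha_fixed

  se <- c(sigma = NA_real_, xi = NA_real_, alpha = NA_real_)
  cov <- NULL; cov_ok <- FALSE
  if (hessian) {
    nat <- function(p) cpp_markov_nll(p, chains, u, lambda, paper_literal)
    if (is.null(alpha_fixed)) {
      H <- tryCatch(optimHess(c(sigma, xi, alpha), nat), error = function(e) NULL)
      free <- 1:3
    } else {
      H <- tryCatch(optimHess(c(sigma, xi), function(p) nat(c(p, alpha_fixed))),
                    error = function(e) NULL)
      free <- 1:2
    }
    cov <- matrix(NA_real_, 3, 3, dimnames = list(names(se), names(se)))
    if (!is.null(H)) {
      Hi <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Hi) && all(diag(Hi) > 0)) {
        cov[free, free] <- Hi
        se[free] <- sqrt(diag(Hi))
        cov_ok <- TRUE
      }
    }
    if (!cov_ok)
      warning("Hessian not positive definite; covariance flagged unreliable")
  }

  structure(list(
    tail = gpd_tail(u, sigma, xi, lambda_u = lambda),
    alpha = alpha, se = se, cov = cov, loglik = -best$value,
    n_effective = n_exc, n_total = length(x),
    converged = TRUE, cov_ok = cov_ok,
    settings = list(start = start, alpha_fixed = alpha_fixed,
                    optimizer = "BFGS", reltol = reltol,
                    multi_start = multi_start,
                    paper_literal = paper_literal, trace = traces)),
    class = "markov_fit")
}

#' @export
print.markov_fit <- function(x, ...) {
  cat("Extreme-Markov fit:", x$n_effective, "effective observations (of",
      x$n_total, ") above u =", format(x$tail$u), "\n")
  cat(sprintf("  sigma = %.4g (se %.3g)\n  xi    = %.4g (se %.3g)\n",
              x$tail$sigma, x$se["sigma"], x$tail$xi, x$se["xi"]))
  cat(sprintf("  alpha = %.4g (se %.3g)%s\n", x$alpha, x$se["alpha"],
              if (!is.null(x$settings$alpha_fixed)) "  [fixed]" else ""))
  cat("  log-likelihood:", format(x$loglik),
      "  lambda_u:", format(x$tail$lambda_u), "\n")
  if (!x$cov_ok) cat("  (covariance unreliable)\n")
  invisible(x)
}
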