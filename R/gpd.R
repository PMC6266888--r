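#' Generalized Pareto tail model on the negated scale
#'
#' Container for the marginal exceedance model: threshold `u`, GPD scale
#' `sigma` and shape `xi`, and the exceedance rate `lambda_u` (the marginal
#' probability of exceeding `u`, estimated empirically as the sample
#' fraction of exceedances).  `lambda_u` is not part of the conditional GPD
#' itself but is needed for return levels and for a non-degenerate marginal
#' transform at the threshold.
#'
#' @param u threshold on the negated scale (for minima of concentrations,
#'   the negative of the concentration threshold).
#' @param sigma GPD scale, `> 0`.
#' @param xi GPD shape; `xi < 0` gives a bounded tail with upper endpoint
#'   `u - sigma/xi`.
#' @param lambda_u exceedance rate in `(0, 1]`.
#' @return An object of class `"gpd_tail"`.
#' @examples
#' gpd_tail(u = -1.0, sigma = 0.34, xi = -0.48, lambda_u = 0.1)
#' @export
gpd_tail <- function(u, sigma, xi, lambda_u = 1) {
  stopifnot(is.finite(u), is.finite(sigma), is.finite(xi), is.finite(lambda_u))
  if (sigma <= 0) stop("sigma must be > 0")
  if (lambda_u <= 0 || lambda_u > 1) stop("lambda_u must be in (0, 1]")
  structure(list(u = u, sigma = sigma, xi = xi, lambda_u = lambda_u),
            class = "gpd_tail")
}

#' @export
print.gpd_tail <- function(x, ...) {
  cat("GPD tail (negated scale): u =", format(x$u),
      " sigma =", format(x$sigma), " xi =", format(x$xi),
      " lambda_u =", format(x$lambda_u), "\n")
  if (x$xi < 0)
    cat("  bounded support: (", format(x$u), ",",
        format(x$u - x$sigma / x$xi), "]\n")
  invisible(x)
}

#' Upper endpoint of a GPD tail
#' @param tail a [gpd_tail()].
#' @return `u - sigma/xi` when `xi < 0`, otherwise `Inf`.
#' @export
gpd_support_upper <- function(tail) {
  if (tail$xi < 0) tail$u - tail$sigma / tail$xi else Inf
}

#' Conditional GPD distribution function
#'
#' `H(y) = 1 - [1 + xi (y - u)/sigma]^{-1/xi}` for `y >= u`, with the
#' exponential limit `1 - exp(-(y - u)/sigma)` on an explicit `xi = 0`
#' branch.  Values beyond a bounded upper endpoint are clamped to 1.
#'
#' @param y values on the negated scale, `>= u`.
#' @param tail a [gpd_tail()].
#' @return Probabilities `H(y)`.
#' @export
gpd_cdf <- function(y, tail) {
  if (any(y < tail$u)) stop("gpd_cdf is conditional on exceedance: y >= u")
  a <- (y - tail$u) / tail$sigma
  if (abs(tail$xi) < 1e-8) return(1 - exp(-a))
  w <- 1 + tail$xi * a
  ifelse(w <= 0, 1, 1 - w^(-1 / tail$xi))
}

#' Conditional GPD density
#' @inheritParams gpd_cdf
#' @param log return the log density?
#' @return Density values; 0 outside the support.
#' @export
gpd_pdf <- function(y, tail, log = FALSE) {
  a <- (y - tail$u) / tail$sigma
  if (abs(tail$xi) < 1e-8) {
    ld <- ifelse(a < 0, -Inf, -log(tail$sigma) - a)
  } else {
    w <- 1 + tail$xi * a
    ld <- ifelse(a < 0 | w <= 0, -Inf,
                 -log(tail$sigma) - (1 / tail$xi + 1) * log(pmax(w, 1e-300)))
  }
  if (log) ld else exp(ld)
}

#' Conditional GPD quantile
#'
#' Inverse of [gpd_cdf()]: returns `q` with `H(q) = p`, i.e.
#' `q = u + (sigma/xi) ((1-p)^{-xi} - 1)` (`xi != 0`) or
#' `q = u - sigma log(1-p)` (`xi = 0`).  `q -> u` as `p -> 0`.
#'
#' @param p probabilities in `(0, 1)`.
#' @inheritParams gpd_cdf
#' @export
gpd_quantile <- function(p, tail) {
  if (any(p <= 0 | p >= 1)) stop("p must be in (0, 1)")
  if (abs(tail$xi) < 1e-8) return(tail$u - tail$sigma * log(1 - p))
  tail$u + tail$sigma / tail$xi * ((1 - p)^(-tail$xi) - 1)
}

#' Draw from the conditional GPD
#' @param n number of draws.
#' @inheritParams gpd_cdf
#' @export
rgpd_tail <- function(n, tail) gpd_quantile(runif(n), tail)

#' Mean residual life table for threshold selection
#'
#' Mean excess `e(u) = mean(y - u | y > u)` over a grid of candidate
#' thresholds, with normal-approximation 95% confidence bounds
#' `e(u) +/- 1.96 sd/sqrt(n_u)`.  Under a GPD with shape `xi`, `e(u)` is
#' linear in `u` with slope `xi/(1-xi)`, so the plot should be roughly
#' linear above a valid threshold.
#'
#' @param ds an `em_dataset` on the negated scale, or a numeric vector.
#' @param thresholds candidate thresholds; default an equispaced grid from
#'   the median to just below the maximum.
#' @param conf confidence level for the bounds.
#' @param min_exceed minimum exceedance count required for a confidence
#'   bound (rows with fewer get `NA` bounds).
#' @return A data frame with columns `u`, `n_exceed`, `mean_excess`,
#'   `ci_low`, `ci_high`.
#' @export
mean_residual_life <- function(ds, thresholds = NULL, conf = 0.95,
                               min_exceed = 5) {
  x <- if (inherits(ds, "em_dataset")) dataset_values(ds) else as.numeric(ds)
  stopifnot(length(x) >= 2)
  if (is.null(thresholds))
    thresholds <- seq(stats::median(x), sort(x, decreasing = TRUE)[2],
                      length.out = 30)
  drop <- thresholds >= max(x)
  if (any(drop)) {
    warning(sum(drop), " grid point(s) at or above the sample maximum excluded")
    thresholds <- thresholds[!drop]
  }
  zc <- qnorm(1 - (1 - conf) / 2)
  rows <- lapply(thresholds, function(u) {
    e <- x[x > u] - u
    n <- length(e)
    se <- if (n >= min_exceed) sd(e) / sqrt(n) else NA_real_
    data.frame(u = u, n_exceed = n, mean_excess = mean(e),
               ci_low = mean(e) - zc * se, ci_high = mean(e) + zc * se)
  })
  do.call(rbind, rows)
}

# log survival log(1 - H(y)) for y >= u, safe deep in the tail where
# 1 - gpd_cdf() would round to zero
gpd_logsurv <- function(y, tail) {
  a <- (y - tail$u) / tail$sigma
  if (abs(tail$xi) < 1e-8) return(-a)
  w <- 1 + tail$xi * a
  ifelse(w <= 0, -Inf, -log1p(tail$xi * a) / tail$xi)
}

# independent GPD negative log-likelihood over exceedances (vectorised)
pot_nll <- function(par, y, u) {
  sigma <- exp(par[1]); xi <- par[2]
  if (xi <= -0.99 || xi > 5) return(1e10)
  a <- (y - u) / sigma
  if (abs(xi) < 1e-8) return(length(y) * log(sigma) + sum(a))
  w <- 1 + xi * a
  if (any(w <= 0)) return(1e10)
  length(y) * log(sigma) + (1 / xi + 1) * sum(log(w))
}

#' Independent peaks-over-threshold (POT) fit
#'
#' Maximum-likelihood GPD fit to all exceedances of `u`, pooled across
#' sites, under the classical assumption of independent exceedances.
#' Standard errors come from the inverse observed information.  This is
#' both the baseline comparator and the `alpha = 1` special case of the
#' Markov-extremes model.
#'
#' @param ds an `em_dataset` on the negated scale, or a numeric vector.
#' @param u threshold on the negated scale.
#' @param start optional `c(sigma, xi)` start.
#' @return An object of class `"pot_fit"`: a list with the fitted
#'   [gpd_tail()] (`tail`), standard errors, log-likelihood and exceedance
#'   count.
#' @export
fit_pot <- function(ds, u, start = NULL) {
  x <- if (inherits(ds, "em_dataset")) dataset_values(ds) else as.numeric(ds)
  y <- x[x > u]
  if (length(y) < 2) stop("need at least 2 exceedances above u")
  if (sd(y) == 0) stop("degenerate exceedances: all values equal")
  if (is.null(start)) {
    m <- mean(y - u); v <- stats::var(y - u)
    xi0 <- max(min(0.5 * (1 - m^2 / v), 0.4), -0.6)  # moment start
    sig0 <- m * (1 - xi0)
    # keep the start inside the support constraint sigma > -xi * max(y - u)
    if (xi0 < 0) sig0 <- max(sig0, 1.05 * abs(xi0) * max(y - u))
    start <- c(sig0, xi0)
  }
  if (pot_nll(c(log(start[1]), start[2]), y, u) >= 1e9)
    start <- c(mean(y - u), 0.1)
  opt <- optim(c(log(start[1]), start[2]), pot_nll, y = y, u = u,
               method = "BFGS", control = list(reltol = 1e-12, maxit = 500, ndeps = c(1e-5, 1e-5)))
  # restart once: a fresh BFGS pass from the optimum tightens the gradient
  opt2 <- optim(opt$par, pot_nll, y = y, u = u, method = "BFGS",
                control = list(reltol = 1e-12, maxit = 500,
                               ndeps = c(1e-5, 1e-5)))
  if (opt2$value <= opt$value) opt <- opt2
  if (opt$convergence != 0)
    stop("POT fit did not converge: optim code ", opt$convergence,
         " (", opt$message %||% "no message", ")")
  sigma <- exp(opt$par[1]); xi <- opt$par[2]
  nll_nat <- function(p) pot_nll(c(log(p[1]), p[2]), y, u)
  H <- optimHess(c(sigma, xi), nll_nat)
  cov <- tryCatch(solve(H), error = function(e) matrix(NA_real_, 2, 2))
  se <- sqrt(pmax(diag(cov), 0))
  structure(list(
    tail = gpd_tail(u, sigma, xi, lambda_u = length(y) / length(x)),
    se_sigma = se[1], se_xi = se[2], cov = cov,
    loglik = -opt$value, n_exceed = length(y), n_total = length(x)),
    class = "pot_fit")
}

#' @export
print.pot_fit <- function(x, ...) {
  cat("Independent POT fit:", x$n_exceed, "exceedances of u =",
      format(x$tail$u), "\n")
  cat(sprintf("  sigma = %.4g (se %.3g)   xi = %.4g (se %.3g)\n",
              x$tail$sigma, x$se_sigma, x$tail$xi, x$se_xi))
  cat("  log-likelihood:", format(x$loglik),
      "  lambda_u:", format(x$tail$lambda_u), "\n")
  invisible(x)
}
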