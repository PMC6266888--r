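# Serial-dependence screening and GPD goodness-of-fit arrays: sample
# autocorrelation with 95% bounds, probability and quantile plots with
# envelopes, and return-level curves with delta-method bands.

#' Sample autocorrelation with confidence bounds
#'
#' Standard sample autocorrelation (biased denominator, as in
#' [stats::acf()]) of one site series, with the usual white-noise
#' `+/- 1.96/sqrt(n)` bounds.  Significant lag-1 (and only lag-1)
#' coefficients motivate the first-order Markov model.
#'
#' @param series a series element of an `em_dataset`, or a numeric vector.
#' @param max_lag largest lag.
#' @return An object of class `"acf_result"`: data frame `lags`/
#'   `coefficients` plus `conf_bound` and `n`.
#' @export
series_acf <- function(series, max_lag = 24) {
  x <- if (is.list(series)) series$values else as.numeric(series)
  n <- length(x)
  if (n <= max_lag + 1) stop("series too short for max_lag = ", max_lag)
  if (sd(x) == 0) stop("constant series: autocorrelation undefined")
  a <- acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
  structure(list(lags = 0:max_lag,
                 coefficients = as.numeric(a$acf),
                 conf_bound = 1.96 / sqrt(n), n = n),
            class = "acf_result")
}

#' @export
print.acf_result <- function(x, ...) {
  sig <- which(abs(x$coefficients[-1]) > x$conf_bound)
  cat("ACF over lags 0..", max(x$lags), " (n = ", x$n, "); bound +/-",
      format(round(x$conf_bound, 3)), "\n", sep = "")
  cat("  significant lags:", if (length(sig)) paste(sig, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Model diagnostic arrays: PP, QQ and return levels
#'
#' Pools exceedances across sites (sorted; invariant to site order) and
#' builds the three classical GPD diagnostics with Weibull plotting
#' positions `i/(n+1)`:
#' * PP: empirical position vs fitted `H`; the band on the empirical axis
#'   is the exact beta order-statistic interval.
#' * QQ: fitted quantile vs empirical order statistic; the band is either
#'   a simulation envelope of order statistics from the fitted GPD
#'   (default; calibrated so ~95% of points fall inside when the model is
#'   true) or a delta-method band from the parameter covariance.
#' * Return levels: `z_m` solving `lambda_u (1 - H(z_m)) = 1/m` over a
#'   grid of return periods `m` (in months, pooled across sites), with
#'   delta-method 95% bands combining the parameter covariance and the
#'   binomial variance of `lambda_u`.  At `m = 1/lambda_u`, `z_m = u`.
#'
#' @param fit a converged [fit_markov()] or [fit_pot()] result.
#' @param ds the `em_dataset` (negated scale) behind the fit.
#' @param m_grid return periods (months); default log-spaced from just
#'   above `1/lambda_u` to 1000.
#' @param qq_band `"envelope"` or `"delta"`.
#' @param n_env envelope replicates.
#' @param conf band confidence level.
#' @return An object of class `"em_diagnostics"`: data frames `pp`, `qq`,
#'   `return_levels`.
#' @export
diagnostic_arrays <- function(fit, ds, m_grid = NULL,
                              qq_band = c("envelope", "delta"),
                              n_env = 1000, conf = 0.95) {
  qq_band <- match.arg(qq_band)
  tail <- tail_of(fit)
  x <- if (inherits(ds, "em_dataset")) dataset_values(ds) else as.numeric(ds)
  y <- sort(x[x > tail$u])
  n <- length(y)
  if (n < 5) stop("need at least 5 exceedances for diagnostics")
  cov_ok <- !inherits(fit, "markov_fit") || isTRUE(fit$cov_ok)
  if (!cov_ok) warning("unreliable covariance: delta-method bands suppressed")
  zc <- qnorm(1 - (1 - conf) / 2)
  pp_pos <- seq_len(n) / (n + 1)

  pp <- data.frame(p_empirical = pp_pos, p_model = gpd_cdf(y, tail),
                   lo = stats::qbeta((1 - conf) / 2, seq_len(n), n + 1 - seq_len(n)),
                   hi = stats::qbeta(1 - (1 - conf) / 2, seq_len(n), n + 1 - seq_len(n)))

  q_model <- gpd_quantile(pp_pos, tail)
  if (qq_band == "envelope") {
    sims <- matrix(rgpd_tail(n * n_env, tail), nrow = n)
    sims <- apply(sims, 2, sort)
    qlo <- apply(sims, 1, quantile, probs = (1 - conf) / 2)
    qhi <- apply(sims, 1, quantile, probs = 1 - (1 - conf) / 2)
  } else if (cov_ok) {
    sdq <- quantile_delta_sd(pp_pos, tail, param_cov(fit))
    qlo <- q_model - zc * sdq; qhi <- q_model + zc * sdq
  } else {
    qlo <- qhi <- rep(NA_real_, n)
  }
  qq <- data.frame(q_model = q_model, q_empirical = y, lo = qlo, hi = qhi)

  m_grid <- m_grid %||% exp(seq(log(1 / tail$lambda_u * 1.01), log(1000),
                                length.out = 50))
  if (any(m_grid * tail$lambda_u < 1)) stop("return periods must exceed 1/lambda_u")
  level <- return_level(m_grid, tail)
  if (cov_ok) {
    sdr <- return_level_delta_sd(m_grid, tail, param_cov(fit),
                                 n_total = total_count(fit, x))
    rlo <- level - zc * sdr; rhi <- level + zc * sdr
  } else rlo <- rhi <- rep(NA_real_, length(m_grid))
  rl <- data.frame(m = m_grid, level = level, lo = rlo, hi = rhi)

  structure(list(pp = pp, qq = qq, return_levels = rl,
                 n_exceed = n, conf = conf), class = "em_diagnostics")
}

#' Return level on the negated scale
#'
#' The value exceeded on average once per `m` observations:
#' `z_m = u + (sigma/xi) ((m lambda_u)^xi - 1)`.
#'
#' @param m return periods in observations (months).
#' @param tail a [gpd_tail()].
#' @export
return_level <- function(m, tail) {
  stopifnot(all(m * tail$lambda_u >= 1))
  if (abs(tail$xi) < 1e-8) return(tail$u + tail$sigma * log(m * tail$lambda_u))
  tail$u + tail$sigma / tail$xi * ((m * tail$lambda_u)^tail$xi - 1)
}

param_cov <- function(fit) {
  if (inherits(fit, "markov_fit")) fit$cov[1:2, 1:2]
  else if (inherits(fit, "pot_fit")) fit$cov
  else matrix(0, 2, 2)
}

total_count <- function(fit, x) {
  if (!is.null(fit$n_total)) fit$n_total else length(x)
}

# delta-method sd of the conditional quantile in (sigma, xi)
quantile_delta_sd <- function(p, tail, cov2) {
  s <- tail$sigma; xi <- tail$xi
  if (abs(xi) < 1e-8) {
    g_s <- -log(1 - p); g_xi <- s * log(1 - p)^2 / 2
  } else {
    b <- (1 - p)^(-xi)
    g_s <- (b - 1) / xi
    g_xi <- s * (-(b - 1) / xi^2 + b * (-log(1 - p)) / xi)
  }
  vapply(seq_along(p), function(i) {
    g <- c(g_s[i], g_xi[i])
    sqrt(max(drop(t(g) %*% cov2 %*% g), 0))
  }, numeric(1))
}

# delta-method sd of the return level in (lambda, sigma, xi); lambda gets
# its binomial variance and is taken independent of (sigma, xi)
return_level_delta_sd <- function(m, tail, cov2, n_total) {
  s <- tail$sigma; xi <- tail$xi; lam <- tail$lambda_u
  ml <- m * lam
  if (abs(xi) < 1e-8) {
    g_s <- log(ml); g_xi <- s * log(ml)^2 / 2; g_lam <- s / lam
  } else {
    b <- ml^xi
    g_s <- (b - 1) / xi
    g_xi <- s * (-(b - 1) / xi^2 + b * log(ml) / xi)
    g_lam <- s * m * ml^(xi - 1)
  }
  v_lam <- lam * (1 - lam) / n_total
  vapply(seq_along(m), function(i) {
    g <- c(g_s[i], g_xi[i])
    sqrt(max(drop(t(g) %*% cov2 %*% g) + g_lam[i]^2 * v_lam, 0))
  }, numeric(1))
}

#' Plot the diagnostic panels
#'
#' Base-graphics PP, QQ and return-level panels from
#' [diagnostic_arrays()].
#'
#' @param x an `"em_diagnostics"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.em_diagnostics <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(op))
  with(x$pp, {
    plot(p_model, p_empirical, xlab = "model", ylab = "empirical",
         main = "Probability plot", ...)
    graphics::abline(0, 1)
    graphics::lines(p_model, lo, lty = 3); graphics::lines(p_model, hi, lty = 3)
  })
  with(x$qq, {
    plot(q_model, q_empirical, xlab = "model", ylab = "empirical",
         main = "Quantile plot", ...)
    graphics::abline(0, 1)
    graphics::lines(q_model, lo, lty = 3); graphics::lines(q_model, hi, lty = 3)
  })
  with(x$return_levels, {
    plot(m, level, type = "l", log = "x", xlab = "return period (months)",
         ylab = "return level", main = "Return level plot", ...)
    graphics::lines(m, lo, lty = 3); graphics::lines(m, hi, lty = 3)
  })
  invisible(x)
}

#' Export diagnostic arrays as CSV files
#' @param x an `"em_diagnostics"` object.
#' @param dir output directory (created if needed).
#' @return Paths of the three CSV files, invisibly.
#' @export
write_diagnostics <- function(x, dir) {
  stopifnot(inherits(x, "em_diagnostics"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("pp.csv", "qq.csv", "return_levels.csv"))
  write.csv(x$pp, paths[1], row.names = FALSE)
  write.csv(x$qq, paths[2], row.names = FALSE)
  write.csv(x$return_levels, paths[3], row.names = FALSE)
  invisible(paths)
}
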