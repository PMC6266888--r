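#' Marginal transform to the standard Frechet scale
#'
#' Maps an observation on the negated scale to the standard Frechet scale
#' through `z = -1/log F(x)`, where the marginal cdf is
#' `F(x) = 1 - lambda_u [1 + xi (x - u)/sigma]^{-1/xi}` for `x >= u` and
#' censored observations (`x < u`) map to the threshold's Frechet value
#' `-1/log(1 - lambda_u)`.  With `paper_literal = TRUE` the exceedance rate
#' is dropped from the above-threshold transform (`F(x) = H(x)`), matching
#' the transform as commonly printed; this makes the threshold map to
#' Frechet value 0 and is offered for comparison only.
#'
#' @param x values on the negated scale.
#' @param tail a [gpd_tail()] with `lambda_u` set.
#' @param paper_literal drop `lambda_u` from the above-threshold transform.
#' @return Positive values on the standard Frechet scale
#'   (`P(Z <= z) = exp(-1/z)`).
#' @seealso [from_frechet()]
#' @export
to_frechet <- function(x, tail, paper_literal = FALSE) {
  lam_t <- if (paper_literal) 1 else tail$lambda_u
  below <- x < tail$u
  lf <- numeric(length(x))
  if (any(below)) {
    if (tail$lambda_u >= 1)
      stop("censored values need lambda_u < 1 for a finite threshold image")
    lf[below] <- log1p(-tail$lambda_u)
  }
  if (any(!below)) {
    if (any(x[!below] < tail$u)) stop("x must be >= u on the exceedance branch")
    surv <- lam_t * exp(gpd_logsurv(x[!below], tail))
    if (any(surv >= 1 | surv < 0)) stop("marginal cdf outside (0, 1)")
    lf[!below] <- log1p(-surv)
  }
  if (any(lf >= 0)) stop("marginal cdf reached 1; cannot map to Frechet scale")
  -1 / lf
}

#' Inverse of the Frechet marginal transform
#'
#' Defined on the exceedance branch (`z` above the threshold image); the
#' censored branch is not invertible pointwise.
#'
#' @param z standard-Frechet values.
#' @inheritParams to_frechet
#' @export
from_frechet <- function(z, tail, paper_literal = FALSE) {
  lam_t <- if (paper_literal) 1 else tail$lambda_u
  stopifnot(all(z > 0))
  s <- -expm1(-1 / z) / lam_t  # conditional survival 1 - H(x)
  if (any(s > 1 + 1e-12))
    stop("z below the threshold image; censored branch not invertible")
  s <- pmin(s, 1)
  # invert through the survival function: accurate deep in the tail
  if (abs(tail$xi) < 1e-8) return(tail$u - tail$sigma * log(s))
  tail$u + tail$sigma / tail$xi * (s^(-tail$xi) - 1)
}

#' Bivariate logistic extreme-value distribution function
#'
#' `F(z1, z2) = exp[-(z1^{-1/alpha} + z2^{-1/alpha})^alpha]` on the
#' standard Frechet scale.  `alpha = 1` is independence (the product of the
#' Frechet marginals); `alpha -> 0` is complete dependence.
#'
#' @param z1,z2 positive values on the standard Frechet scale.
#' @param alpha dependence parameter in `(0, 1]`.
#' @export
logistic_joint_cdf <- function(z1, z2, alpha) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  stopifnot(all(z1 > 0), all(z2 > 0))
  exp(-(z1^(-1 / alpha) + z2^(-1 / alpha))^alpha)
}

#' Tail-dependence coefficient of the logistic model
#'
#' The limiting conditional probability that one variable is extreme given
#' the other is; for the logistic family `chi = 2 - 2^alpha`
#' (0 at independence, 1 at complete dependence).
#'
#' @param alpha dependence parameter in `(0, 1]`.
#' @export
chi_logistic <- function(alpha) {
  if (any(alpha <= 0 | alpha > 1)) stop("alpha must be in (0, 1]")
  2 - 2^alpha
}

# region classifier used by the censored density
pair_region <- function(x_t, x_prev, u) {
  if (x_t > u && x_prev > u) "both-above"
  else if (x_t > u) "first-above"
  else if (x_prev > u) "second-above"
  else "both-below"
}

#' Censored pair density of the logistic Markov-extremes model
#'
#' The four-region joint contribution of a lag-1 pair on the negated
#' observation scale: the full mixed-partial density when both values
#' exceed the threshold, the partial derivative of the joint cdf in the
#' uncensored argument when only one does, and the probability mass
#' `F(u, u) = (1 - lambda_u)^{2^alpha}` when both are censored.  This is
#' the R reference implementation of the term assembled (in compiled code)
#' into the Markov likelihood.
#'
#' @param x_t,x_prev the pair on the negated scale (scalars).
#' @param tail a [gpd_tail()] with `lambda_u < 1`.
#' @param alpha logistic dependence parameter in `(0, 1]`.
#' @param log return the log contribution?
#' @param paper_literal see [to_frechet()].
#' @return The density (or mass, for the both-below region) contribution.
#' @export
censored_pair_density <- function(x_t, x_prev, tail, alpha, log = FALSE,
                                  paper_literal = FALSE) {
  stopifnot(length(x_t) == 1, length(x_prev) == 1)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  if (tail$lambda_u >= 1) stop("censored model needs lambda_u < 1")
  u <- tail$u
  region <- pair_region(x_t, x_prev, u)
  lam_t <- if (paper_literal) 1 else tail$lambda_u

  # per-exceedance pieces: log z, z^{-1/alpha}, log Jacobian dz/dx
  piece <- function(x) {
    z <- to_frechet(x, tail, paper_literal)
    logz <- log(z)
    logF <- -1 / z
    logJ <- log(lam_t) + gpd_pdf(x, tail, log = TRUE) + 2 * logz - logF
    list(logz = logz, t = exp(-logz / alpha), logJ = logJ)
  }
  t_u <- (-1 / log1p(-tail$lambda_u))^(-1 / alpha)

  ld <- switch(region,
    "both-above" = {
      a <- piece(x_t); b <- piece(x_prev)
      s <- a$t + b$t
      V <- s^alpha
      -V - (1 / alpha + 1) * (a$logz + b$logz) + (alpha - 2) * log(s) +
        log(V + (1 - alpha) / alpha) + a$logJ + b$logJ
    },
    "first-above" = {
      a <- piece(x_t)
      s <- a$t + t_u
      (alpha - 1) * log(s) - (1 / alpha + 1) * a$logz - s^alpha + a$logJ
    },
    "second-above" = {
      a <- piece(x_prev)
      s <- a$t + t_u
      (alpha - 1) * log(s) - (1 / alpha + 1) * a$logz - s^alpha + a$logJ
    },
    "both-below" = 2^alpha * log1p(-tail$lambda_u)
  )
  if (log) ld else exp(ld)
}
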