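test_that("Frechet transform closed forms and round trip", {
  # censored values map to the threshold image -1/log(1 - lambda_u)
  tl <- gpd_tail(0, 1, -0.3, lambda_u = 1 - exp(-1))
  expect_equal(to_frechet(-5, tl), 1, tolerance = 1e-12)
  tl2 <- gpd_tail(0, 1, -0.3, lambda_u = 0.5)
  expect_equal(to_frechet(-5, tl2), -1 / log(0.5), tolerance = 1e-12)

  # literal transform (lambda_u dropped): H(x) = 0.9 maps to -1/log(0.9)
  x9 <- gpd_quantile(0.9, tl2)
  expect_equal(to_frechet(x9, tl2, paper_literal = TRUE), -1 / log(0.9),
               tolerance = 1e-10)

  # strictly increasing, and invertible to < 1e-9 across the support
  tl3 <- gpd_tail(-1, 0.4, -0.35, lambda_u = 0.15)
  x <- seq(-1, gpd_support_upper(tl3) - 1e-9, length.out = 200)
  z <- to_frechet(x, tl3)
  expect_true(all(diff(z) > 0))
  expect_lt(max(abs(from_frechet(z, tl3) - x)), 1e-9)
})

test_that("logistic joint cdf: limits, symmetry, bounds, monotonicity", {
  expect_equal(logistic_joint_cdf(1, 1, 1), exp(-2), tolerance = 1e-12)
  expect_equal(logistic_joint_cdf(1, 1, 0.5), exp(-sqrt(2)),
               tolerance = 1e-12)
  expect_error(logistic_joint_cdf(1, 1, 1.2), "alpha")

  zs <- c(0.3, 1, 4, 20)
  for (a in c(0.2, 0.5, 1)) {
    for (z1 in zs) for (z2 in zs) {
      F12 <- logistic_joint_cdf(z1, z2, a)
      expect_equal(F12, logistic_joint_cdf(z2, z1, a))
      F1 <- exp(-1 / z1); F2 <- exp(-1 / z2)
      expect_gte(F12, max(0, F1 + F2 - 1) - 1e-12)  # Frechet-Hoeffding
      expect_lte(F12, min(F1, F2) + 1e-12)
    }
    # marginal consistency as the other argument grows
    expect_equal(logistic_joint_cdf(1, 1e12, a), exp(-1), tolerance = 1e-9)
  }
  # complete-dependence limit and monotonicity in alpha on the diagonal
  expect_equal(logistic_joint_cdf(1, 1, 1e-8), exp(-1), tolerance = 1e-6)
  vals <- sapply(c(0.1, 0.4, 0.7, 1), function(a)
    logistic_joint_cdf(1, 1, a))
  expect_true(all(diff(vals) < 0))
})

test_that("tail-dependence coefficient closed form", {
  expect_equal(chi_logistic(1), 0)
  expect_equal(chi_logistic(0.5), 2 - sqrt(2), tolerance = 1e-12)
  expect_equal(chi_logistic(0.17), 2 - 2^0.17, tolerance = 1e-12)
})

test_that("censored pair density: independence factorization and mass", {
  # both censored at alpha = 1: mass (1 - lambda)^2
  tl <- gpd_tail(-1, 0.5, -0.3, lambda_u = 0.1)
  expect_equal(censored_pair_density(-2, -3, tl, 1), 0.81, tolerance = 1e-12)
  # general both-below mass (1 - lambda)^(2^alpha)
  expect_equal(censored_pair_density(-2, -3, tl, 0.5), 0.9^(2^0.5),
               tolerance = 1e-12)

  # alpha = 1 factorizes into marginal censored densities
  tl2 <- gpd_tail(-1, 0.5, -0.3, lambda_u = 0.2)
  for (xs in list(c(-0.8, -0.5), c(-0.95, -0.2), c(-0.5, -1.7))) {
    d <- censored_pair_density(xs[1], xs[2], tl2, 1)
    m <- function(x) if (x > tl2$u) 0.2 * gpd_pdf(x, tl2) else 0.8
    expect_equal(d, m(xs[1]) * m(xs[2]), tolerance = 1e-8)
  }
})

test_that("analytic mixed partial matches numerical differentiation", {
  tl <- gpd_tail(-1, 0.5, -0.3, lambda_u = 0.2)
  Fxy <- function(x1, x2, a)
    logistic_joint_cdf(to_frechet(x1, tl), to_frechet(x2, tl), a)
  h <- 2e-4
  for (a in c(0.3, 0.6, 1)) {
    for (xs in list(c(-0.7, -0.4), c(-0.9, -0.85), c(-0.3, -0.6))) {
      num <- (Fxy(xs[1] + h, xs[2] + h, a) - Fxy(xs[1] + h, xs[2] - h, a) -
              Fxy(xs[1] - h, xs[2] + h, a) + Fxy(xs[1] - h, xs[2] - h, a)) /
             (4 * h^2)
      ana <- censored_pair_density(xs[1], xs[2], tl, a)
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
})

test_that("four censored regions sum to one by quadrature (spot check)", {
  tl <- gpd_tail(-1, 0.5, -0.5, lambda_u = 0.2)
  expect_equal(censored_total_probability(tl, 0.5), 1, tolerance = 1e-4)
})
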