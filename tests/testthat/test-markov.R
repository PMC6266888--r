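test_that("hand-computed likelihood values", {
  # single chain of length 2, both censored: -log F(u,u)
  for (a in c(0.5, 0.8, 1)) {
    lam <- 0.2
    nll <- markov_nll(c(0.5, -0.3, a), list(c(-2, -3)), u = -1, lambda = lam)
    expect_equal(nll, -2^a * log1p(-lam), tolerance = 1e-10)
  }
})

test_that("compiled likelihood agrees with the R-level composition", {
  tl <- gpd_tail(-1, 0.5, -0.3, lambda_u = 0.2)
  ds <- simulate_chain(2, 60, tl, 0.5, seed = 99)
  chains <- extmarkov:::dataset_segments(ds)
  lam <- 0.2
  for (a in c(0.3, 0.7, 1)) {
    nll_cpp <- markov_nll(c(0.5, -0.3, a), ds, -1, lambda = lam)
    logm <- function(x) if (x > -1) log(lam) + gpd_pdf(x, tl, log = TRUE)
                        else log1p(-lam)
    ll <- 0
    for (ch in chains) {
      ll <- ll + logm(ch[1])
      for (t in 2:length(ch))
        ll <- ll + censored_pair_density(ch[t], ch[t - 1], tl, a, log = TRUE) -
          logm(ch[t - 1])
    }
    expect_equal(nll_cpp, -ll, tolerance = 1e-9)
  }
})

test_that("alpha = 1 likelihood factorizes into the censored GPD likelihood", {
  tl <- gpd_tail(-1, 0.34, -0.48, lambda_u = 0.15)
  ds <- simulate_chain(2, 100, tl, 1, seed = 9)
  x <- extmarkov:::dataset_values(ds)
  lam <- mean(x > -1)
  tl_hat <- gpd_tail(-1, 0.3, -0.4, lam)
  nll_m <- markov_nll(c(0.3, -0.4, 1), ds, -1, lambda = lam)
  nll_i <- -sum(ifelse(x > -1, log(lam) + gpd_pdf(x, tl_hat, log = TRUE),
                       log1p(-lam)))
  expect_equal(nll_m, nll_i, tolerance = 1e-8)
})

test_that("likelihood prefers the generating dependence over independence", {
  tl <- gpd_tail(-1, 0.5, -0.3, lambda_u = 0.2)
  ds <- simulate_chain(4, 144, tl, 0.5, seed = 21)
  nll_true <- markov_nll(c(0.5, -0.3, 0.5), ds, -1)
  nll_indep <- markov_nll(c(0.5, -0.3, 1), ds, -1)
  expect_lt(nll_true, nll_indep)
})

test_that("site order does not change the likelihood or the fit", {
  fx <- make_fixture("TN", seed = 5, n_sites = 4, chain_length = 72)
  chains <- extmarkov:::dataset_segments(fx$dataset)
  perm <- chains[c(3, 1, 4, 2)]
  p0 <- c(0.23, -0.27, 0.78)
  expect_equal(markov_nll(p0, chains, -1, lambda = 0.112),
               markov_nll(p0, perm, -1, lambda = 0.112), tolerance = 1e-12)
  f1 <- fit_markov(chains, -1, multi_start = FALSE, hessian = FALSE)
  f2 <- fit_markov(perm, -1, multi_start = FALSE, hessian = FALSE)
  expect_equal(f1$tail$sigma, f2$tail$sigma, tolerance = 1e-6)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-6)
})

test_that("support violations penalize rather than throw", {
  nll <- markov_nll(c(0.01, -0.9, 0.5), list(c(-0.5, 5, -2)), -1,
                    lambda = 0.3)
  expect_true(is.finite(nll))
  expect_gte(nll, 1e9)
})

test_that("the returned optimum is stationary and recovers truth", {
  fx <- make_fixture("TN", seed = 3)
  f <- fit_markov(fx$dataset, -1)
  expect_true(f$converged)
  expect_true(f$cov_ok)
  expect_equal(unname(f$se), unname(sqrt(diag(f$cov))), tolerance = 1e-10)
  expect_equal(f$n_effective,
               sum(extmarkov:::dataset_values(fx$dataset) > -1))
  g <- nll_num_grad(c(f$tail$sigma, f$tail$xi, f$alpha), fx$dataset, -1,
                    f$tail$lambda_u)
  expect_lt(max(abs(g)), 1e-3)
  # truth within ~3 SE for this seed
  expect_lt(abs(f$tail$sigma - 0.23), 3 * f$se["sigma"])
  expect_lt(abs(f$tail$xi + 0.27), 3 * f$se["xi"])
  expect_lt(abs(f$alpha - 0.78), 3 * f$se["alpha"])
})

test_that("independent data push alpha to the boundary", {
  tl <- gpd_tail(-1, 0.34, -0.48, lambda_u = 0.15)
  ds <- simulate_chain(4, 144, tl, alpha = 1, seed = 17)
  f <- fit_markov(ds, -1, hessian = FALSE)
  expect_gt(f$alpha, 0.9)
  # likelihood-ratio statistic against the alpha = 1 submodel is small
  f1 <- fit_markov(ds, -1, alpha_fixed = 1, hessian = FALSE)
  lr <- 2 * (f$loglik - f1$loglik)
  expect_gte(lr, -1e-6)
  expect_lt(lr, qchisq(0.99, df = 1))
})

test_that("Markov standard errors beat POT on dependent data", {
  fx <- make_fixture("TN", seed = 11)
  f <- fit_markov(fx$dataset, -1)
  p <- fit_pot(extmarkov:::dataset_values(fx$dataset), -1)
  expect_lt(f$se["sigma"], p$se_sigma)
  expect_lt(f$se["xi"], p$se_xi)
})
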