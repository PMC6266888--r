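# shared helpers: small CSV fixtures written on the fly, quick fits

write_obs_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# a tiny two-site monthly table on the original concentration scale
tiny_obs_df <- function(n = 24, sites = c("S1", "S2"), variable = "TN",
                        seed = 42) {
  set.seed(seed)
  months <- format(seq(as.Date("2000-01-01"), by = "month", length.out = n),
                   "%Y-%m")
  do.call(rbind, lapply(sites, function(s)
    data.frame(site = s, date = months, variable = variable,
               value = round(exp(rnorm(n, 0.5, 0.4)), 3))))
}

# central-difference gradient of the Markov nll in natural parameters
nll_num_grad <- function(par, ds, u, lambda) {
  vapply(seq_along(par), function(j) {
    e <- 1e-5 * max(abs(par[j]), 1e-2)
    pp <- par; pm <- par
    pp[j] <- pp[j] + e; pm[j] <- pm[j] - e
    (markov_nll(pp, ds, u, lambda = lambda) -
       markov_nll(pm, ds, u, lambda = lambda)) / (2 * e)
  }, numeric(1))
}

# total probability of the four censored regions by quadrature
censored_total_probability <- function(tail, alpha) {
  u <- tail$u
  up <- if (tail$xi < 0) gpd_support_upper(tail)
        else gpd_quantile(1 - 1e-8, tail)
  f2 <- function(a, b) censored_pair_density(a, b, tail, alpha)
  inner <- function(a)
    integrate(function(x2) sapply(x2, function(b) f2(a, b)), u, up,
              rel.tol = 1e-9)$value
  dbl <- integrate(function(x1) sapply(x1, inner), u, up,
                   rel.tol = 1e-7)$value
  one <- integrate(function(x) sapply(x, function(a) f2(a, u - 1)), u, up,
                   rel.tol = 1e-9)$value
  two <- integrate(function(x) sapply(x, function(a) f2(u - 1, a)), u, up,
                   rel.tol = 1e-9)$value
  dbl + one + two + censored_pair_density(u - 1, u - 2, tail, alpha)
}
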