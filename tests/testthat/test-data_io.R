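test_that("reading is lossless and order-insensitive", {
  df <- tiny_obs_df(n = 24)
  path <- write_obs_csv(df)
  ds <- read_observations(path, "TN", quiet = TRUE)
  expect_s3_class(ds, "em_dataset")
  expect_named(ds$series, c("S1", "S2"))
  expect_length(ds$series$S1$values, 24)

  shuffled <- write_obs_csv(df[sample(nrow(df)), ])
  ds2 <- read_observations(shuffled, "TN", quiet = TRUE)
  expect_equal(ds, ds2)

  # write -> read round trip preserves (site, date, value)
  back <- write_obs_csv(NULL, tempfile(fileext = ".csv"))
  write_observations(ds, back)
  ds3 <- read_observations(back, "TN", quiet = TRUE)
  expect_equal(lapply(ds$series, `[[`, "values"),
               lapply(ds3$series, `[[`, "values"))
  expect_equal(lapply(ds$series, `[[`, "dates"),
               lapply(ds3$series, `[[`, "dates"))
})

test_that("malformed inputs are rejected with informative errors", {
  df <- tiny_obs_df(n = 12)
  no_col <- df[, c("site", "date", "value")]
  expect_error(read_observations(write_obs_csv(no_col), "TN", quiet = TRUE),
               "missing column")

  bad <- df
  bad$value <- as.character(bad$value)
  bad$value[5] <- "oops"
  expect_error(read_observations(write_obs_csv(bad), "TN", quiet = TRUE),
               "line\\(s\\): 6")  # header is line 1

  expect_error(read_observations(write_obs_csv(df), "TP", quiet = TRUE),
               "empty dataset")

  single <- df[1, ]
  expect_error(read_observations(write_obs_csv(single), "TN", quiet = TRUE),
               "shorter than 2")

  dup <- rbind(df, df[1, ])
  expect_error(read_observations(write_obs_csv(dup), "TN", quiet = TRUE),
               "duplicate month")
})

test_that("negation is an involution that flips the scale attribute", {
  ds <- read_observations(write_obs_csv(tiny_obs_df()), "TN", quiet = TRUE)
  nds <- negate(ds)
  expect_identical(attr(nds, "scale"), "negated")
  expect_equal(nds$series$S1$values, -ds$series$S1$values)
  expect_equal(negate(nds), ds)

  zero <- ds
  zero$series <- lapply(zero$series, function(s) { s$values[] <- 0; s })
  expect_equal(negate(zero)$series$S1$values, zero$series$S1$values)
})

test_that("calendar gaps split series into separate Markov segments", {
  df <- tiny_obs_df(n = 24, sites = "S1")
  df <- df[-13, ]  # knock out one month
  ds <- read_observations(write_obs_csv(df), "TN", quiet = TRUE)
  segs <- extmarkov:::dataset_segments(ds)
  expect_length(segs, 2)
  expect_equal(lengths(segs), c(12L, 11L))
})

test_that("reports round-trip and refuse unconverged fits", {
  fx <- make_fixture("TN", seed = 2, n_sites = 2, chain_length = 60)
  fit <- fit_markov(fx$dataset, -1)
  q <- structure(list(p = 0.25, value = 0.7, ci_low = 0.6, ci_high = 0.8,
                      n_boot = 200L, n_failed = 0L, seed = 1L,
                      kind = "parametric", conf = 0.95),
                 class = "quantile_estimate")
  path <- tempfile(fileext = ".json")
  write_report(fit, q, path, extra = list(variable = "TN"))
  rep <- read_report(path)
  expect_equal(rep$parameters$sigma, fit$tail$sigma)
  expect_equal(rep$parameters$alpha, fit$alpha)
  expect_equal(rep$quantile$ci_low, 0.6)
  expect_equal(rep$n_effective, fit$n_effective)

  # byte-identical modulo the timestamp line
  path2 <- tempfile(fileext = ".json")
  write_report(fit, q, path2, extra = list(variable = "TN"))
  strip <- function(p) grep("timestamp", readLines(p), value = TRUE,
                            invert = TRUE)
  expect_identical(strip(path), strip(path2))

  bad <- fit
  bad$converged <- FALSE
  expect_error(write_report(bad, q, tempfile()), "converge")
})
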