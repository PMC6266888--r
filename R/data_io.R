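# Monitoring tables: long CSV (site,date,variable,value) in, JSON reports
# out, and the negation convention that turns a minima problem into a
# maxima one.

new_em_dataset <- function(series, variable, scale = "original") {
  stopifnot(scale %in% c("original", "negated"))
  structure(list(variable = variable, series = series),
            class = "em_dataset", scale = scale)
}

#' Read monitoring observations from a long-format CSV
#'
#' Expects a UTF-8 CSV with header columns `site,date,variable,value`;
#' dates are `YYYY-MM` or `YYYY-MM-DD` (day of month ignored; observations
#' are stored at month resolution).  One time-sorted series per site is
#' returned; rows for other variables are ignored.  Calendar gaps are
#' allowed and later split a series into separate Markov segments, since
#' the likelihood couples adjacent months only.
#'
#' @param path CSV file path.
#' @param variable which variable to keep (e.g. `"TN"`).
#' @param quiet suppress the parsed-row message.
#' @return An object of class `"em_dataset"` (attribute `scale =
#'   "original"`): a list with the variable name and one series per site,
#'   each holding `site_id`, month-resolution `dates` and `values`.
#' @export
read_observations <- function(path, variable, quiet = FALSE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("site", "date", "variable", "value")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("input format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  df$.line <- seq_len(nrow(df)) + 1L  # header is line 1
  df <- df[df$variable == variable, , drop = FALSE]
  if (nrow(df) == 0) stop("empty dataset: no rows for variable '", variable, "'")

  val <- suppressWarnings(as.numeric(df$value))
  if (anyNA(val))
    stop("non-numeric value(s) at line(s): ",
         paste(df$.line[is.na(val)], collapse = ", "))
  if (any(!is.finite(val)))
    stop("non-finite value(s) at line(s): ",
         paste(df$.line[!is.finite(val)], collapse = ", "))
  if (any(val < 0))
    warning("negative concentration(s) on the original scale at line(s): ",
            paste(df$.line[val < 0], collapse = ", "))
  df$value <- val

  months <- parse_year_month(df$date)
  if (anyNA(months))
    stop("unparseable date(s) at line(s): ",
         paste(df$.line[is.na(months)], collapse = ", "))

  series <- lapply(split(seq_len(nrow(df)), df$site), function(idx) {
    o <- idx[order(months[idx])]
    m <- months[o]
    if (anyDuplicated(m))
      stop("duplicate month(s) for site '", df$site[o][1], "'")
    list(site_id = as.character(df$site[o][1]),
         dates = month_to_date(m), values = df$value[o])
  })
  short <- vapply(series, function(s) length(s$values) < 2, logical(1))
  if (any(short))
    stop("series shorter than 2 observations for site(s): ",
         paste(names(series)[short], collapse = ", "))
  if (!quiet)
    message("parsed ", nrow(df), " rows of '", variable, "' across ",
            length(series), " site(s)")
  new_em_dataset(series[order(names(series))], variable)
}

# "YYYY-MM" or "YYYY-MM-DD" -> integer month index (year*12 + month-1)
parse_year_month <- function(x) {
  m <- regmatches(x, regexec("^\\s*(\\d{4})-(\\d{2})(-\\d{2})?\\s*$", x))
  vapply(m, function(g) {
    if (length(g) == 0) return(NA_integer_)
    mo <- as.integer(g[3])
    if (mo < 1 || mo > 12) return(NA_integer_)
    as.integer(g[2]) * 12L + mo - 1L
  }, integer(1))
}

month_to_date <- function(m) {
  as.Date(sprintf("%04d-%02d-01", m %/% 12L, m %% 12L + 1L))
}

#' @export
print.em_dataset <- function(x, ...) {
  n <- vapply(x$series, function(s) length(s$values), integer(1))
  cat("em_dataset:", x$variable, "on the", attr(x, "scale"), "scale;",
      length(x$series), "site(s),", sum(n), "observations\n")
  for (s in x$series)
    cat("  ", s$site_id, ": ", length(s$values), " months from ",
        format(s$dates[1], "%Y-%m"), "\n", sep = "")
  invisible(x)
}

#' Negate a dataset (minima -> maxima convention)
#'
#' Sign-flips every value and toggles the `scale` attribute between
#' `"original"` and `"negated"`.  Negation is an involution:
#' `negate(negate(ds))` restores the input.
#'
#' @param ds an `em_dataset`.
#' @export
negate <- function(ds) {
  stopifnot(inherits(ds, "em_dataset"))
  out <- ds
  out$series <- lapply(ds$series, function(s) { s$values <- -s$values; s })
  attr(out, "scale") <- if (attr(ds, "scale") == "original") "negated"
                        else "original"
  out
}

#' Write a dataset back to the long CSV dialect
#'
#' Always writes original-scale concentrations (negated datasets are
#' flipped back first), so a write/read round trip is lossless for the
#' `(site, date, value)` triples.
#'
#' @param ds an `em_dataset`.
#' @param path output CSV path.
#' @export
write_observations <- function(ds, path) {
  if (attr(ds, "scale") == "negated") ds <- negate(ds)
  rows <- do.call(rbind, lapply(ds$series, function(s) {
    data.frame(site = s$site_id, date = format(s$dates, "%Y-%m"),
               variable = ds$variable, value = s$values)
  }))
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# all values pooled across sites
dataset_values <- function(ds) {
  unlist(lapply(ds$series, `[[`, "values"), use.names = FALSE)
}

# split each site series into contiguous monthly segments (transition terms
# are only formed between consecutive months); returns a list of numeric
# vectors
dataset_segments <- function(ds) {
  segs <- lapply(ds$series, function(s) {
    m <- as.integer(format(s$dates, "%Y")) * 12L +
      as.integer(format(s$dates, "%m")) - 1L
    brk <- cumsum(c(0L, diff(m) != 1L))
    unname(split(s$values, brk))
  })
  unlist(segs, recursive = FALSE, use.names = FALSE)
}

#' Write a fitted-model report to JSON
#'
#' Machine-readable record of a converged Markov-extremes fit and its
#' reference-condition quantile: parameters with standard errors, the
#' parameter covariance, exceedance counts, the quantile with its bootstrap
#' interval, and the settings (including the seed) needed to reproduce the
#' run.  Round-trippable through [read_report()].
#'
#' @param fit a converged [fit_markov()] result.
#' @param q a [bootstrap_ci()] result (class `"quantile_estimate"`), or
#'   `NULL` for a parameters-only report.
#' @param path output JSON path.
#' @param extra optional named list merged into the report (e.g. variable
#'   name, input file).
#' @export
write_report <- function(fit, q = NULL, path, extra = list()) {
  stopifnot(inherits(fit, "markov_fit"))
  if (!isTRUE(fit$converged)) stop("refusing to write report: fit did not converge")
  rep <- c(extra, list(
    model = "extreme-markov",
    package_version = as.character(utils::packageVersion("extmarkov")),
    threshold = fit$tail$u,
    lambda_u = fit$tail$lambda_u,
    parameters = list(sigma = fit$tail$sigma, xi = fit$tail$xi,
                      alpha = fit$alpha),
    se = as.list(fit$se),
    cov = fit$cov,
    loglik = fit$loglik,
    n_effective = fit$n_effective,
    converged = fit$converged,
    settings = fit$settings
  ))
  if (!is.null(q)) {
    stopifnot(inherits(q, "quantile_estimate"))
    rep$quantile <- list(p = q$p, value = q$value, ci_low = q$ci_low,
                         ci_high = q$ci_high, n_boot = q$n_boot,
                         n_failed = q$n_failed, seed = q$seed, kind = q$kind)
  }
  rep$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#' @param path report path.
#' @return The report as a list; the covariance is restored as a matrix.
#' @export
read_report <- function(path) {
  rep <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(rep$cov)) rep$cov <- as.matrix(rep$cov)
  rep
}
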