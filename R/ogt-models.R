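#' Linear model of a composition metric against optimum growth temperature
#'
#' Ordinary least squares. The default orientation, `metric_on_ogt`, regresses
#' the metric on optimum growth temperature (OGT on the x axis, as such
#' comparative plots are drawn); `ogt_on_metric` regresses the other way for
#' direct OGT prediction.
#'
#' @param x Predictor values (OGT in deg C for `metric_on_ogt`).
#' @param y Response values (the metric for `metric_on_ogt`).
#' @param metric_name Label carried through summaries.
#' @param orientation `"metric_on_ogt"` (default) or `"ogt_on_metric"`.
#' @return An `ogt_lm`: list with `metric_name`, `slope`, `intercept`, `r`
#'   (Pearson), `n`, `orientation`, `source = "fitted"`, and the underlying
#'   `lm` fit.
#' @export
fit_linear_model <- function(x, y, metric_name = "metric",
                             orientation = c("metric_on_ogt", "ogt_on_metric")) {
  orientation <- match.arg(orientation)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) abort("need at least 2 complete points to fit")
  if (length(unique(x)) < 2) abort("degenerate predictor: all x values equal")
  fit <- lm(y ~ x)
  structure(
    list(metric_name = metric_name,
         slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         orientation = orientation,
         r = if (length(unique(y)) < 2) NA_real_ else cor(x, y),
         n = length(x),
         source = "fitted",
         fit = fit),
    class = "ogt_lm")
}

#' Define a literature regression line
#'
#' Wraps published slope/intercept coefficients (for example regression lines
#' fitted on large prokaryote panels in earlier comparative studies) in the
#' same `ogt_lm` container as [fit_linear_model()] so prediction and residual
#' scoring treat fitted and published lines identically.
#'
#' @param metric_name Metric label.
#' @param slope,intercept Published coefficients.
#' @param orientation See [fit_linear_model()].
#' @return An `ogt_lm` with `source = "literature"`.
#' @export
literature_model <- function(metric_name, slope, intercept,
                             orientation = c("metric_on_ogt", "ogt_on_metric")) {
  orientation <- match.arg(orientation)
  structure(
    list(metric_name = metric_name, slope = slope, intercept = intercept,
         orientation = orientation, r = NA_real_, n = NA_integer_,
         source = "literature", fit = NULL),
    class = "ogt_lm")
}

#' @export
print.ogt_lm <- function(x, ...) {
  cat(sprintf("<ogt_lm> %s (%s, %s): slope %.6g, intercept %.6g, r %.3f, n %s\n",
              x$metric_name, x$orientation, x$source, x$slope, x$intercept,
              x$r, x$n %||% NA))
  invisible(x)
}

#' @export
tidy.ogt_lm <- function(x, ...) {
  tibble(metric = x$metric_name, orientation = x$orientation,
         source = x$source, slope = x$slope, intercept = x$intercept,
         r = x$r, n = as.integer(x$n))
}

#' @export
glance.ogt_lm <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(r = x$r, r.squared = x$r^2, sigma = NA_real_,
                  p.value = NA_real_, n = as.integer(x$n)))
  }
  s <- summary(x$fit)
  tibble(r = x$r, r.squared = s$r.squared, sigma = s$sigma,
         p.value = unname(coef(s)[2, 4]), n = as.integer(x$n))
}

#' Predict optimum growth temperature from a metric value
#'
#' Inverts a `metric_on_ogt` line (`ogt = (metric - intercept) / slope`) or
#' applies an `ogt_on_metric` line directly.
#'
#' @param model An `ogt_lm`.
#' @param metric_value Metric value(s).
#' @return Predicted OGT(s) in deg C.
#' @export
predict_ogt <- function(model, metric_value) {
  stopifnot(inherits(model, "ogt_lm"))
  if (model$orientation == "ogt_on_metric")
    return(model$intercept + model$slope * metric_value)
  if (model$slope == 0)
    abort("metric_on_ogt model with zero slope cannot be inverted to predict OGT")
  (metric_value - model$intercept) / model$slope
}

#' Residual of an observation from an OGT regression line
#'
#' For the default `metric_on_ogt` orientation this is the observed metric
#' minus the line's prediction at the observed OGT: positive residuals mean
#' the metric is higher than the organism's growth temperature predicts.
#' Large residuals flag genomes whose composition is out of step with their
#' growth temperature (for example thermophile-like proteomes retained in a
#' mesophile).
#'
#' @param model An `ogt_lm`.
#' @param metric_value Observed metric value(s).
#' @param ogt_observed Observed OGT(s), deg C.
#' @return Signed residual(s), in metric units.
#' @export
ogt_residual <- function(model, metric_value, ogt_observed) {
  stopifnot(inherits(model, "ogt_lm"))
  if (model$orientation == "metric_on_ogt") {
    metric_value - (model$intercept + model$slope * ogt_observed)
  } else {
    # line predicts OGT; residual kept in metric units via inversion
    metric_value - (ogt_observed - model$intercept) / model$slope
  }
}

#' Correlation between a metric and optimum growth temperature
#'
#' Pearson or Spearman correlation with a two-sided test, on pairwise-complete
#' rows.
#'
#' @param table Data frame with an `ogt_observed` (or `ogt_c`) column and the
#'   metric column.
#' @param metric_name Column to correlate with OGT.
#' @param method `"pearson"` or `"spearman"`.
#' @return One-row tibble: `metric`, `method`, `estimate`, `p_value`, `n`,
#'   `n_dropped`.
#' @export
correlate_metric_ogt <- function(table, metric_name,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ogt_col <- intersect(c("ogt_observed", "ogt_c"), names(table))[1]
  if (is.na(ogt_col)) abort("table needs an ogt_observed or ogt_c column")
  if (!metric_name %in% names(table))
    abort(paste0("no such metric column: ", metric_name))
  x <- table[[ogt_col]]; y <- table[[metric_name]]
  ok <- stats::complete.cases(x, y)
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    warn(sprintf("%d row(s) dropped for missing values in %s", n_dropped, metric_name))
  if (sum(ok) < 3) abort("need at least 3 complete rows")
  ct <- suppressWarnings(cor.test(x[ok], y[ok], method = method,
                                  alternative = "two.sided", exact = FALSE))
  tibble(metric = metric_name, method = method,
         estimate = unname(ct$estimate), p_value = ct$p.value,
         n = sum(ok), n_dropped = n_dropped)
}

#' Read a flat key=value regression-line config
#'
#' Lines of the form `<metric>.slope=...`, `<metric>.intercept=...`,
#' optionally `<metric>.orientation=...`; `#` comments and blank lines are
#' ignored. Used to supply published regression coefficients that the user
#' transcribes from the literature.
#'
#' @param path Config file.
#' @return Named list of [literature_model()] objects, one per metric.
#' @export
read_model_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2)) abort("config lines must be key=value")
  keys <- trimws(map_chr(kv, 1)); vals <- trimws(map_chr(kv, 2))
  parts <- strsplit(keys, ".", fixed = TRUE)
  if (any(lengths(parts) != 2)) abort("config keys must be <metric>.<field>")
  metrics <- unique(map_chr(parts, 1))
  out <- map(metrics, function(mtr) {
    get <- function(f, default = NA) {
      hit <- which(keys == paste0(mtr, ".", f))
      if (length(hit)) vals[hit[1]] else default
    }
    slope <- as.numeric(get("slope"))
    intercept <- as.numeric(get("intercept"))
    if (is.na(slope) || is.na(intercept))
      abort(paste0("config metric '", mtr, "' needs slope and intercept"))
    literature_model(mtr, slope, intercept,
                     orientation = get("orientation", "metric_on_ogt"))
  })
  setNames(out, metrics)
}
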