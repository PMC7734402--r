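#' Compare thermal profiles against optimum growth temperatures
#'
#' For each metric: Pearson (and optionally Spearman) correlation with OGT,
#' an OLS line fitted across species, per-species residuals from the fitted
#' line, and — when literature regression lines are supplied — residuals from
#' those published lines as well. Species whose residual magnitude exceeds
#' `flag_sd` fitted residual standard deviations are flagged as off-line
#' (composition out of step with growth temperature).
#'
#' @param profiles A `thermal_profile` tibble (one row per genome/species).
#' @param meta Optional tibble with `species_id`/`genome_id` and `ogt_c`
#'   columns supplying OGTs not already in `profiles$ogt_observed`.
#' @param metrics Metric columns to analyse (defaults to the standard
#'   profile metrics present and non-constant).
#' @param literature Optional named list of [literature_model()]s (or a
#'   config path for [read_model_config()]), keyed by metric.
#' @param methods Correlation methods to report.
#' @param flag_sd Residual flagging threshold, in fitted residual SDs.
#' @return A `thermal_comparison`: list with tibbles `correlations`,
#'   `models`, `residuals`, plus `fits` (the `ogt_lm` objects).
#' @export
compare_profiles <- function(profiles, meta = NULL,
                             metrics = NULL, literature = NULL,
                             methods = c("pearson"), flag_sd = 2) {
  tab <- as_tibble(profiles)
  if (!is.null(meta)) {
    meta <- as_tibble(meta)
    idcol <- intersect(c("species_id", "genome_id"), names(meta))[1]
    if (is.na(idcol)) abort("meta needs a species_id or genome_id column")
    ogtcol <- intersect(c("ogt_c", "ogt_observed"), names(meta))[1]
    if (is.na(ogtcol)) abort("meta needs an ogt_c or ogt_observed column")
    m <- match(tab$genome_id, meta[[idcol]])
    supplied <- meta[[ogtcol]][m]
    if (!"ogt_observed" %in% names(tab)) tab$ogt_observed <- NA_real_
    tab$ogt_observed <- ifelse(is.na(tab$ogt_observed), supplied, tab$ogt_observed)
  }
  if (!"ogt_observed" %in% names(tab) || sum(!is.na(tab$ogt_observed)) < 3)
    abort("need at least 3 species with an observed OGT")

  default_metrics <- c("gc_genome", "gc_16s", "genome_size", "cvp_bias",
                       "ivywrel", "at3_fraction", "rrna_operon_count")
  metrics <- metrics %||% intersect(default_metrics, names(tab))
  if (is.character(literature)) literature <- read_model_config(literature)

  keep <- map_lgl(metrics, function(mtr) {
    vals <- tab[[mtr]][!is.na(tab[[mtr]]) & !is.na(tab$ogt_observed)]
    ok <- length(vals) >= 3 && length(unique(vals)) >= 2
    if (!ok) warn(sprintf("metric '%s' skipped: constant or too few complete rows", mtr))
    ok
  })
  metrics <- metrics[keep]
  if (length(metrics) == 0) abort("no analysable metrics")

  fits <- map(metrics, function(mtr)
    fit_linear_model(tab$ogt_observed, tab[[mtr]], metric_name = mtr))
  names(fits) <- metrics

  correlations <- bind_rows(map(metrics, function(mtr)
    bind_rows(map(methods, function(me)
      suppressWarnings(correlate_metric_ogt(tab, mtr, method = me))))))

  models <- bind_rows(map(fits, tidy))

  residuals <- bind_rows(map(metrics, function(mtr) {
    fit <- fits[[mtr]]
    ok <- !is.na(tab[[mtr]]) & !is.na(tab$ogt_observed)
    res <- ogt_residual(fit, tab[[mtr]][ok], tab$ogt_observed[ok])
    rsd <- sd(res)
    out <- tibble(genome_id = tab$genome_id[ok], metric = mtr,
                  value = tab[[mtr]][ok], ogt_observed = tab$ogt_observed[ok],
                  residual_fitted = res,
                  off_line = if (rsd > 0) abs(res) > flag_sd * rsd else FALSE)
    if (!is.null(literature) && mtr %in% names(literature)) {
      lit <- literature[[mtr]]
      out$residual_literature <- ogt_residual(lit, out$value, out$ogt_observed)
    } else {
      out$residual_literature <- NA_real_
    }
    out
  }))

  structure(list(correlations = correlations, models = models,
                 residuals = residuals, fits = fits, table = tab,
                 flag_sd = flag_sd),
            class = "thermal_comparison")
}

#' @export
print.thermal_comparison <- function(x, ...) {
  cat(sprintf("<thermal_comparison> %d metric(s) across %d species\n",
              length(x$fits), nrow(x$table)))
  print(x$models)
  flagged <- filter(x$residuals, .data$off_line)
  if (nrow(flagged) > 0) {
    cat(sprintf("off-line species (>|%.1f| SD):\n", x$flag_sd))
    print(select(flagged, "genome_id", "metric", "residual_fitted"))
  }
  invisible(x)
}

#' @export
tidy.thermal_comparison <- function(x, ...) x$models

#' @export
glance.thermal_comparison <- function(x, ...) {
  tibble(n_species = nrow(x$table), n_metrics = length(x$fits),
         n_off_line = sum(x$residuals$off_line))
}

#' Write the tables of a thermal comparison
#'
#' Emits `models.tsv`, `correlations.tsv` and `residuals.tsv` with fixed
#' float formatting, so identical inputs give byte-identical outputs.
#'
#' @param comparison A `thermal_comparison`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_comparison <- function(comparison, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.6g", x))
  w <- function(df, name) {
    df <- mutate(df, dplyr::across(dplyr::where(is.numeric), num))
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  w(comparison$models, "models.tsv")
  w(comparison$correlations, "correlations.tsv")
  # residual sign convention: observed metric minus line prediction at the
  # species' observed OGT (positive = metric above the line)
  w(comparison$residuals, "residuals.tsv")
  invisible(dir)
}
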