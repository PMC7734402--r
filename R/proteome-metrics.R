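#' Amino-acid composition of a proteome
#'
#' Residue frequencies over the 20 canonical amino acids. `pooled` mode tallies
#' residues across all proteins (each residue weighs equally, so long proteins
#' dominate); `per_protein_mean` averages per-protein frequency vectors
#' (each protein weighs equally). X/U/B/Z residues are excluded from both
#' numerator and denominator; flagged proteins are excluded entirely.
#'
#' @param proteins A `protein_set` (see [protein_set()],
#'   [extract_and_translate_cds()]) or a character vector of residue strings.
#' @param mode `"pooled"` (default) or `"per_protein_mean"`.
#' @return An `aa_composition`: list with `frequencies` (named 20-vector
#'   summing to 1), `n_residues`, `n_proteins`, `mode`.
#' @export
aa_composition <- function(proteins, mode = c("pooled", "per_protein_mean")) {
  mode <- match.arg(mode)
  if (is.character(proteins)) proteins <- protein_set(proteins)
  usable <- usable_proteins(proteins)
  if (nrow(usable) == 0) abort("no unflagged proteins to summarise")
  mat <- residue_count_matrix(usable$residues)
  n_res <- sum(mat)
  if (n_res == 0) abort("proteins contain no canonical residues")
  freqs <- if (mode == "pooled") {
    colSums(mat) / n_res
  } else {
    rs <- rowSums(mat)
    keep <- rs > 0
    colMeans(mat[keep, , drop = FALSE] / rs[keep])
  }
  structure(list(frequencies = freqs, n_residues = n_res,
                 n_proteins = nrow(usable), mode = mode),
            class = "aa_composition")
}

# proteins x 20 matrix of canonical residue counts (X/U/B/Z dropped)
residue_count_matrix <- function(residues) {
  chars <- strsplit(residues, "", fixed = TRUE)
  t(vapply(chars, function(cc) {
    tab <- table(factor(cc, levels = AA_CANONICAL))
    as.numeric(tab)
  }, numeric(20)))  |>
    (\(m) {colnames(m) <- AA_CANONICAL; m})()
}

#' @export
print.aa_composition <- function(x, ...) {
  cat(sprintf("<aa_composition> %s over %d residues in %d protein(s)\n",
              x$mode, x$n_residues, x$n_proteins))
  print(round(x$frequencies, 4))
  invisible(x)
}

#' @export
tidy.aa_composition <- function(x, ...) {
  tibble(residue = names(x$frequencies), frequency = unname(x$frequencies))
}

#' CvP bias
#'
#' Percentage-point difference between charged (D, E, K, R) and polar
#' (N, Q, S, T) residue fractions: `100 * (fD+fE+fK+fR - (fN+fQ+fS+fT))`.
#' Higher values track thermophily. Histidine is not counted as charged.
#'
#' @param comp An [aa_composition()] (or anything it accepts).
#' @param charged,polar Residue sets, overridable.
#' @return CvP bias in percentage points, in `[-100, 100]`.
#' @export
cvp_bias <- function(comp, charged = AA_CHARGED, polar = AA_POLAR) {
  comp <- as_composition(comp)
  f <- comp$frequencies
  100 * (sum(f[charged]) - sum(f[polar]))
}

#' IVYWREL fraction
#'
#' Fraction of residues that are Ile, Val, Tyr, Trp, Arg, Glu or Leu; across
#' prokaryotes this fraction rises roughly linearly with optimum growth
#' temperature.
#'
#' @inheritParams cvp_bias
#' @param members Residue set, overridable.
#' @return Fraction in `[0, 1]`.
#' @export
ivywrel_fraction <- function(comp, members = AA_IVYWREL) {
  comp <- as_composition(comp)
  sum(comp$frequencies[members])
}

as_composition <- function(x) {
  if (inherits(x, "aa_composition")) return(x)
  aa_composition(x)
}

#' Count transmembrane helices by sliding-window hydropathy
#'
#' Hydropathy surrogate for dedicated TM-topology predictors: a helix is
#' called for every maximal run of positions whose sliding-window mean
#' hydropathy reaches `threshold`; runs separated by fewer than
#' `min_separation` residues merge into one. Proteins shorter than the window
#' return 0. Supplied TM counts from an external predictor can bypass this
#' entirely (see [filter_soluble()]).
#'
#' @param residues One amino-acid string.
#' @param scale Named per-residue hydropathy scale (default Kyte-Doolittle;
#'   U scored as C, other non-scale letters as 0).
#' @param window Sliding window length in residues (odd, >= 7).
#' @param threshold Window-mean hydropathy at or above which a position is
#'   membrane-like.
#' @param min_separation Runs closer than this merge.
#' @return Non-negative integer helix count.
#' @export
count_tm_helices <- function(residues, scale = KYTE_DOOLITTLE, window = 19,
                             threshold = 1.6, min_separation = 10) {
  stopifnot(window %% 2 == 1, window >= 7)
  n <- nchar(residues)
  if (n < window) return(0L)
  h <- scale[strsplit(toupper(residues), "")[[1]]]
  h[is.na(h)] <- 0
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 2))
  means <- means[!is.na(means)]
  hot <- means >= threshold
  if (!any(hot)) return(0L)
  r <- rle(hot)
  # merge hot runs separated by short cold gaps
  if (length(r$lengths) > 2) {
    inner_cold <- which(!r$values)
    inner_cold <- inner_cold[inner_cold > 1 & inner_cold < length(r$values)]
    r$values[inner_cold[r$lengths[inner_cold] < min_separation]] <- TRUE
    hot <- inverse.rle(r)
    r <- rle(hot)
  }
  sum(r$values)
}

#' Filter a proteome to its putatively soluble proteins
#'
#' Keeps proteins with fewer than `max_helices_exclusive` predicted
#' transmembrane helices (default: fewer than 2), the membrane filter applied
#' before computing CvP and IVYWREL. Counts must already be present — either
#' from [add_tm_helix_counts()] or an external predictor's table.
#'
#' @param proteins A `protein_set` with `tm_helix_count` set on every
#'   unflagged protein.
#' @param max_helices_exclusive Exclusive upper bound on helix count.
#' @return The filtered `protein_set` (flagged proteins are retained;
#'   filtering applies to usable proteins only). Idempotent.
#' @export
filter_soluble <- function(proteins, max_helices_exclusive = 2) {
  usable <- is.na(proteins$flag)
  if (any(usable & is.na(proteins$tm_helix_count)))
    abort(paste("tm_helix_count unset on some proteins;",
                "run add_tm_helix_counts() or supply an external TM table"))
  out <- proteins[!usable | proteins$tm_helix_count < max_helices_exclusive, ]
  class(out) <- class(proteins)
  out
}

#' Attach TM helix counts to a protein set
#'
#' Either computes the hydropathy surrogate per protein or joins counts from
#' an external predictor's table.
#'
#' @param proteins A `protein_set`.
#' @param external Optional tibble/data.frame with columns `id` and
#'   `tm_helix_count` (e.g. parsed output of a TM-topology predictor).
#'   Proteins missing from the table get the surrogate count.
#' @param ... Passed to [count_tm_helices()].
#' @return The `protein_set` with `tm_helix_count` filled in.
#' @export
add_tm_helix_counts <- function(proteins, external = NULL, ...) {
  counts <- proteins$tm_helix_count
  if (!is.null(external)) {
    stopifnot(all(c("id", "tm_helix_count") %in% names(external)))
    m <- match(proteins$id, external$id)
    counts <- as.integer(external$tm_helix_count[m])
  }
  need <- which(is.na(counts) & is.na(proteins$flag))
  dots <- list(...)
  counts[need] <- map_int(proteins$residues[need], function(r)
    as.integer(do.call(count_tm_helices, c(list(r), dots))))
  proteins$tm_helix_count <- counts
  proteins
}

#' Read an external per-protein TM-count table
#'
#' TSV with columns `id` and `tm_helix_count`.
#'
#' @param path Input file.
#' @return Tibble.
#' @export
read_tm_table <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("id", "tm_helix_count") %in% names(tab)))
    abort("TM table needs columns id and tm_helix_count")
  as_tibble(tab)
}
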