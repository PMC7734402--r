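#' Thermal-signature profile of one genome
#'
#' Runs the full per-genome pipeline: CDS extraction and translation,
#' membrane-protein filtering, composition indices (CvP bias, IVYWREL),
#' whole-genome G+C, codon third-position composition, and rRNA operon
#' statistics (copy count and minimum pairwise 16S identity). Deterministic
#' for a fixed input.
#'
#' @param genome A [genome_record()] or path to a GenBank file.
#' @param tm_mode `"surrogate"` (hydropathy heuristic), `"external"`
#'   (counts from `external_tm`), or `"none"` (skip the membrane filter).
#' @param external_tm Tibble with `id`, `tm_helix_count` when
#'   `tm_mode = "external"`.
#' @param composition_mode Passed to [aa_composition()].
#' @param max_helices_exclusive Membrane filter bound (keep < this many
#'   helices).
#' @param ogt_observed Optional known optimum growth temperature (deg C),
#'   carried through to the profile row.
#' @param ... Hydropathy surrogate parameters for [count_tm_helices()].
#' @return A `thermal_profile`: one-row tibble with columns `genome_id`,
#'   `genome_size`, `gc_genome`, `gc_16s`, `cvp_bias`, `ivywrel`,
#'   `at3_fraction`, `rrna_operon_count`, `min_16s_copy_identity`,
#'   `n_proteins`, `n_proteins_used`, `ogt_observed`.
#' @export
proteome_thermal_profile <- function(genome,
                                     tm_mode = c("surrogate", "external", "none"),
                                     external_tm = NULL,
                                     composition_mode = "pooled",
                                     max_helices_exclusive = 2,
                                     ogt_observed = NA_real_, ...) {
  tm_mode <- match.arg(tm_mode)
  if (is.character(genome)) genome <- read_genome(genome)
  stopifnot(inherits(genome, "genome_record"))

  with_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      abort(sprintf("[%s] %s", stage, conditionMessage(e))))
  }

  proteins <- with_stage("translate", extract_and_translate_cds(genome))
  filtered <- with_stage("tm_filter", switch(tm_mode,
    surrogate = filter_soluble(add_tm_helix_counts(proteins, ...),
                               max_helices_exclusive),
    external = filter_soluble(add_tm_helix_counts(proteins, external = external_tm),
                              max_helices_exclusive),
    none = proteins))
  comp <- with_stage("composition", aa_composition(filtered, mode = composition_mode))

  cds_nt <- with_stage("codon_usage", {
    cds <- filter(genome$features, .data$kind == "CDS")
    seqs <- map_chr(seq_len(nrow(cds)), ~feature_sequence(genome, cds[.x, ]))
    suppressWarnings(codon_usage(seqs[nchar(seqs) %% 3 == 0]))
  })

  rrna <- with_stage("rrna", rrna_stats(genome))

  out <- tibble(
    genome_id = genome$id,
    genome_size = genome_length(genome),
    gc_genome = gc_content(genome),
    gc_16s = rrna$gc_16s,
    cvp_bias = cvp_bias(comp),
    ivywrel = ivywrel_fraction(comp),
    at3_fraction = cds_nt$at3_fraction,
    rrna_operon_count = rrna$count,
    min_16s_copy_identity = rrna$min_identity,
    n_proteins = nrow(proteins),
    n_proteins_used = comp$n_proteins,
    ogt_observed = ogt_observed
  )
  class(out) <- c("thermal_profile", class(out))
  out
}

# count of 16S copies, their mean G+C, and minimum pairwise percent identity
rrna_stats <- function(genome) {
  copies <- extract_rrna_copies(genome, "16S")
  n <- length(copies)
  if (n == 0) return(list(count = 0L, gc_16s = NA_real_, min_identity = NA_real_))
  gc <- mean(map_dbl(copies, gc_content))
  min_id <- NA_real_
  if (n >= 2) {
    pairs <- utils::combn(n, 2)
    ids <- map_dbl(seq_len(ncol(pairs)), function(k) {
      percent_identity(global_align(copies[[pairs[1, k]]], copies[[pairs[2, k]]]))
    })
    min_id <- min(ids)
  }
  list(count = as.integer(n), gc_16s = gc, min_identity = min_id)
}

#' Profile several genomes, isolating per-genome failures
#'
#' @param genomes List of [genome_record()] objects and/or file paths
#'   (GenBank), optionally named.
#' @param ... Passed to [proteome_thermal_profile()].
#' @return A `thermal_profile` tibble, one row per genome. A genome whose
#'   profiling fails contributes a row of NAs (id preserved) and a warning
#'   naming the failed stage; `attr(, "n_failed")` counts failures.
#' @export
profile_genomes <- function(genomes, ...) {
  if (inherits(genomes, "genome_record") || is.character(genomes) && length(genomes) == 1)
    genomes <- list(genomes)
  rows <- imap(genomes, function(g, nm) {
    id <- if (is.character(g)) g else g$id
    tryCatch(proteome_thermal_profile(g, ...), error = function(e) {
      warn(sprintf("genome '%s' failed: %s", id, conditionMessage(e)))
      tibble(genome_id = as.character(id), genome_size = NA_integer_,
             gc_genome = NA_real_, gc_16s = NA_real_, cvp_bias = NA_real_,
             ivywrel = NA_real_, at3_fraction = NA_real_,
             rrna_operon_count = NA_integer_, min_16s_copy_identity = NA_real_,
             n_proteins = NA_integer_, n_proteins_used = NA_integer_,
             ogt_observed = NA_real_)
    })
  })
  out <- bind_rows(rows)
  failed <- is.na(out$genome_size)
  # degenerate partial failures keep their genome-level fields where possible
  attr(out, "n_failed") <- sum(failed)
  class(out) <- c("thermal_profile", class(out))
  out
}

#' Write thermal profiles as a TSV
#'
#' Fixed formatting: G+C as mol% with one decimal, indices with four
#' decimals, so re-runs produce byte-identical tables.
#'
#' @param profiles A `thermal_profile` tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  fmt <- profiles |>
    mutate(
      gc_genome = sprintf("%.1f", 100 * .data$gc_genome),
      gc_16s = sprintf("%.1f", 100 * .data$gc_16s),
      cvp_bias = sprintf("%.4f", .data$cvp_bias),
      ivywrel = sprintf("%.4f", .data$ivywrel),
      at3_fraction = sprintf("%.4f", .data$at3_fraction),
      min_16s_copy_identity = sprintf("%.4f", .data$min_16s_copy_identity)
    )
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a thermal-profile TSV back
#'
#' Reverses the fixed formatting of [write_profiles()] (mol% back to
#' fractions).
#'
#' @param path TSV written by [write_profiles()].
#' @return A `thermal_profile` tibble.
#' @export
read_profiles <- function(path) {
  tab <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  tab$gc_genome <- suppressWarnings(as.numeric(tab$gc_genome)) / 100
  tab$gc_16s <- suppressWarnings(as.numeric(tab$gc_16s)) / 100
  class(tab) <- c("thermal_profile", class(tab))
  tab
}
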