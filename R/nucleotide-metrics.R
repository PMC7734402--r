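#' G+C content of a nucleotide sequence
#'
#' `(G + C) / (A + C + G + T)`. IUPAC ambiguity symbols are excluded from both
#' numerator and denominator, so `"ATNNGC"` counts 2 of 4 unambiguous bases.
#'
#' @param sequence Nucleotide string or [genome_record()].
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(sequence) {
  if (inherits(sequence, "genome_record")) sequence <- sequence$sequence
  counts <- base_counts(sequence)
  denom <- sum(counts)
  if (denom == 0) abort("G+C undefined: no unambiguous bases in sequence")
  unname((counts["G"] + counts["C"]) / denom)
}

base_counts <- function(sequence) {
  v <- Biostrings::letterFrequency(Biostrings::DNAString(toupper(sequence)),
                                   letters = c("A", "C", "G", "T"))
  setNames(as.numeric(v), c("A", "C", "G", "T"))
}

#' Windowed G+C profile
#'
#' Scans the genome in fixed windows (default: non-overlapping 10-kb windows).
#' For linear genomes a shorter tail is emitted as its own window, which makes
#' the length-weighted mean of the window values equal the whole-genome G+C
#' exactly. For circular genomes the final window wraps past the origin to
#' full window length (so the wrapped bases are counted twice in a weighted
#' mean unless the length is a multiple of the step).
#'
#' @param genome A [genome_record()] or plain sequence string (treated as
#'   linear).
#' @param window,step Window and step size in bases.
#' @return A `gc_profile`: tibble with `window_start` (0-based), `window_end`
#'   (half-open; may exceed the length for a wrapped circular window),
#'   `n_bases`, `gc`; attributes `window`, `step`, `whole_genome_gc`,
#'   `genome_id`, `topology`.
#' @export
windowed_gc <- function(genome, window = 10000, step = window) {
  if (is.character(genome)) genome <- genome_record("seq", genome, topology = "linear")
  stopifnot(inherits(genome, "genome_record"), window >= 1, step >= 1)
  len <- genome_length(genome)
  if (window > len) {
    warn("window exceeds genome length; emitting a single whole-genome window")
    window <- len
    step <- len
  }
  starts <- seq(0L, len - 1L, by = as.integer(step))
  seqs <- map_chr(starts, function(s) {
    e <- s + window
    if (e <= len) return(substr(genome$sequence, s + 1, e))
    if (genome$topology == "circular") {
      paste0(substr(genome$sequence, s + 1, len),
             substr(genome$sequence, 1, e - len))
    } else {
      substr(genome$sequence, s + 1, len)
    }
  })
  out <- tibble(
    window_start = starts,
    window_end = starts + nchar(seqs),
    n_bases = nchar(seqs),
    gc = map_dbl(seqs, gc_content)
  )
  structure(out,
            class = c("gc_profile", class(out)),
            window = window, step = step,
            whole_genome_gc = gc_content(genome$sequence),
            genome_id = genome$id, topology = genome$topology)
}

#' @export
print.gc_profile <- function(x, ...) {
  cat(sprintf("<gc_profile> %s (%s): %d windows of %d bp; whole-genome G+C %.1f mol%%\n",
              attr(x, "genome_id"), attr(x, "topology"), nrow(x),
              attr(x, "window"), 100 * attr(x, "whole_genome_gc")))
  NextMethod()
}

#' Codon usage and third-position composition
#'
#' Counts all 64 codons over a set of in-frame CDS nucleotide sequences.
#' Codons containing ambiguity symbols are excluded everywhere; stop codons
#' are counted but excluded from the third-position (AT3/GC3) fractions,
#' which are defined over sense codons only. Records whose length is not a
#' multiple of 3 are skipped with a warning.
#'
#' @param cds_sequences Character vector of in-frame CDS nucleotide strings.
#' @param code_table NCBI genetic-code table number (default 11).
#' @return A `codon_usage_table`: list with `counts` (named 64-vector),
#'   `per_aa_fractions` (tibble `aa`, `codon`, `count`, `fraction`),
#'   `at3_fraction`, `gc3_fraction`, `n_codons`, `n_stop`, `n_skipped`.
#' @export
codon_usage <- function(cds_sequences, code_table = 11) {
  gc_code <- Biostrings::getGeneticCode(as.character(code_table))
  codons64 <- names(gc_code)
  bad <- nchar(cds_sequences) %% 3 != 0
  if (any(bad)) {
    warn(sprintf("%d CDS record(s) skipped: length not a multiple of 3", sum(bad)))
    cds_sequences <- cds_sequences[!bad]
  }
  if (length(cds_sequences) == 0) abort("no usable in-frame CDS sequences")
  all_codons <- unlist(map(toupper(cds_sequences), function(s) {
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }))
  all_codons <- all_codons[grepl("^[ACGT]{3}$", all_codons)]  # drop ambiguous
  counts <- table(factor(all_codons, levels = codons64))
  counts <- setNames(as.integer(counts), codons64)

  is_stop <- gc_code == "*"
  sense <- counts[!is_stop]
  third <- substr(names(sense), 3, 3)
  n_sense <- sum(sense)
  at3 <- if (n_sense > 0) sum(sense[third %in% c("A", "T")]) / n_sense else NA_real_

  aa <- gc_code[!is_stop]
  per_aa <- tibble(aa = unname(aa), codon = names(aa), count = unname(sense)) |>
    group_by(.data$aa) |>
    mutate(fraction = if (sum(.data$count) > 0) .data$count / sum(.data$count) else NA_real_) |>
    dplyr::ungroup()

  structure(
    list(counts = counts, per_aa_fractions = per_aa,
         at3_fraction = at3, gc3_fraction = 1 - at3,
         n_codons = sum(counts), n_stop = sum(counts[is_stop]),
         n_skipped = sum(bad)),
    class = "codon_usage_table"
  )
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf("<codon_usage_table> %d codons (%d stop); AT3 %.3f, GC3 %.3f\n",
              x$n_codons, x$n_stop, x$at3_fraction, x$gc3_fraction))
  invisible(x)
}

#' @export
tidy.codon_usage_table <- function(x, ...) {
  x$per_aa_fractions
}

#' Write a windowed G+C profile as TSV
#'
#' Columns `genome_id`, `window_start`, `gc`; fixed four-decimal formatting
#' for reproducible diffs.
#'
#' @param profile A `gc_profile` from [windowed_gc()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gc_profile <- function(profile, path) {
  out <- tibble(genome_id = attr(profile, "genome_id"),
                window_start = profile$window_start,
                gc = sprintf("%.4f", profile$gc))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
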