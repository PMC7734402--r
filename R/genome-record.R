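#' Genome record objects
#'
#' A `genome_record` bundles one replicon's nucleotide sequence with its typed,
#' located features. Coordinates are held 0-based half-open internally
#' (converted once, on read, from the 1-based inclusive GenBank convention);
#' a feature may span several intervals (GenBank `join()` locations), stored
#' as a two-column integer matrix with one row per interval.
#'
#' @param id Accession or other identifier.
#' @param sequence Nucleotide string (IUPAC letters; uppercased on entry).
#' @param topology `"circular"` or `"linear"`.
#' @param features Tibble with columns `kind` (one of `CDS`, `rRNA_16S`,
#'   `rRNA_23S`, `rRNA_5S`, `other`), `strand` (`"+"`/`"-"`), `locus_tag`,
#'   `product`, and `intervals` (list column of 0-based half-open
#'   `[start, end)` matrices).
#'
#' @return An object of class `genome_record`.
#' @examples
#' g <- genome_record("toy", "ATGAAATAAGGG",
#'                    features = feature_tibble("CDS", 0L, 9L, "+"))
#' genome_length(g)
#' @export
genome_record <- function(id, sequence, topology = c("circular", "linear"),
                          features = empty_features()) {
  topology <- match.arg(topology)
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) abort("genome sequence must have length > 0")
  if (grepl("[^ACGTRYSWKMBDHVN]", sequence))
    abort("sequence contains non-IUPAC characters")
  features <- validate_features(features, nchar(sequence))
  structure(
    list(id = as.character(id), sequence = sequence, topology = topology,
         features = features),
    class = "genome_record"
  )
}

#' @rdname genome_record
#' @param x A `genome_record`.
#' @export
genome_length <- function(x) {
  stopifnot(inherits(x, "genome_record"))
  nchar(x$sequence)
}

empty_features <- function() {
  tibble(kind = character(), strand = character(),
         locus_tag = character(), product = character(),
         intervals = list())
}

#' Build a one-interval-per-row feature table
#'
#' Convenience constructor for simple (single-interval) features.
#'
#' @param kind,start,end,strand,locus_tag,product Parallel vectors; `start`
#'   and `end` are 0-based half-open.
#' @return A feature tibble suitable for [genome_record()].
#' @export
feature_tibble <- function(kind, start, end, strand = "+",
                           locus_tag = NA_character_, product = NA_character_) {
  n <- length(kind)
  tibble(
    kind = as.character(kind),
    strand = rep_len(strand, n),
    locus_tag = rep_len(as.character(locus_tag), n),
    product = rep_len(as.character(product), n),
    intervals = map2(as.integer(start), as.integer(end),
                     ~cbind(start = .x, end = .y))
  )
}

FEATURE_KINDS <- c("CDS", "rRNA_16S", "rRNA_23S", "rRNA_5S", "other")

validate_features <- function(features, genome_len) {
  features <- as_tibble(features)
  needed <- c("kind", "strand", "locus_tag", "product", "intervals")
  missing <- setdiff(needed, names(features))
  if ("intervals" %in% missing) abort("features need an 'intervals' column")
  for (col in setdiff(missing, "intervals"))
    features[[col]] <- if (col %in% c("kind", "strand")) "other" else NA_character_
  features <- features[needed]
  bad <- !features$kind %in% FEATURE_KINDS
  features$kind[bad] <- "other"
  for (iv in features$intervals) {
    if (!is.matrix(iv) || ncol(iv) != 2 || nrow(iv) < 1)
      abort("each feature needs a non-empty 2-column interval matrix")
    if (any(iv[, 1] >= iv[, 2]))
      abort("feature intervals must satisfy start < end")
    if (any(iv < 0) || any(iv[, 2] > genome_len))
      abort("feature intervals fall outside [0, genome length)")
  }
  features
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %s, %d feature(s)\n",
              x$id, format(genome_length(x), big.mark = ","), x$topology,
              nrow(x$features)))
  if (nrow(x$features) > 0)
    print(table(x$features$kind))
  invisible(x)
}

#' Extract the spliced, strand-normalized sequence of one feature
#'
#' Concatenates the feature's intervals in order, then reverse-complements
#' the result for minus-strand features, so the returned string reads in the
#' gene's sense. Features that span the circular origin are represented as
#' two intervals and come out contiguous.
#'
#' @param genome A [genome_record()].
#' @param feature_row One row of `genome$features` (a list or 1-row tibble).
#' @return Nucleotide string.
#' @export
feature_sequence <- function(genome, feature_row) {
  iv <- if (is.data.frame(feature_row)) feature_row$intervals[[1]] else feature_row$intervals
  strand <- if (is.data.frame(feature_row)) feature_row$strand[1] else feature_row$strand
  parts <- apply(iv, 1, function(r) substr(genome$sequence, r[1] + 1, r[2]))
  s <- paste(parts, collapse = "")
  if (identical(strand, "-")) s <- revcomp(s)
  s
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
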