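#' Extract and translate CDS features
#'
#' Pulls every CDS feature out of a genome, reverse-complements minus-strand
#' features, and translates with the bacterial/archaeal genetic code (NCBI
#' table 11 by default; alternative initiators become Met). Problem CDS are
#' kept in the table but flagged, and flagged proteins are excluded from all
#' composition statistics downstream:
#'
#' * `length_not_multiple_of_3` — frame cannot be trusted, not translated;
#' * `internal_stop` — in-frame stop before the final codon;
#' * `high_ambiguity` — more than `max_x_fraction` of residues translated
#'   from ambiguous codons (X).
#'
#' @param genome A [genome_record()] with at least one CDS feature.
#' @param code_table NCBI genetic-code table number (default 11).
#' @param max_x_fraction Proteins with a higher fraction of X residues are
#'   flagged (default 0.05).
#' @return A `protein_set`: tibble with columns `id`, `residues`, `length`,
#'   `tm_helix_count` (NA until counted), `flag` (NA when usable).
#' @export
extract_and_translate_cds <- function(genome, code_table = 11,
                                      max_x_fraction = 0.05) {
  stopifnot(inherits(genome, "genome_record"))
  cds <- filter(genome$features, .data$kind == "CDS")
  if (nrow(cds) == 0) abort("genome has no CDS features")
  gc_code <- Biostrings::getGeneticCode(as.character(code_table))

  rows <- map(seq_len(nrow(cds)), function(i) {
    row <- cds[i, ]
    id <- row$locus_tag
    if (is.na(id)) id <- sprintf("cds_%04d", i)
    nt <- feature_sequence(genome, row)
    if (nchar(nt) %% 3 != 0)
      return(tibble(id = id, residues = NA_character_, length = NA_integer_,
                    tm_helix_count = NA_integer_,
                    flag = "length_not_multiple_of_3"))
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(nt), genetic.code = gc_code, if.fuzzy.codon = "solve"))
    if (endsWith(aa, "*")) aa <- substr(aa, 1, nchar(aa) - 1)
    flag <- NA_character_
    if (grepl("\\*", aa)) flag <- "internal_stop"
    else if (nchar(aa) == 0) flag <- "empty_translation"
    else {
      nx <- lengths(regmatches(aa, gregexpr("X", aa, fixed = TRUE)))
      if (nx / nchar(aa) > max_x_fraction) flag <- "high_ambiguity"
    }
    tibble(id = id, residues = aa, length = nchar(aa),
           tm_helix_count = NA_integer_, flag = flag)
  })
  out <- bind_rows(rows)
  class(out) <- c("protein_set", class(out))
  out
}

#' Usable (unflagged) proteins of a protein set
#' @param proteins A `protein_set` tibble.
#' @return The unflagged rows.
#' @export
usable_proteins <- function(proteins) {
  filter(proteins, is.na(.data$flag))
}

#' Construct a protein set from residue strings
#'
#' @param residues Character vector of amino-acid strings.
#' @param id Optional ids (defaults to `p0001`, ...).
#' @param tm_helix_count Optional per-protein transmembrane helix counts.
#' @return A `protein_set` tibble.
#' @export
protein_set <- function(residues, id = NULL,
                        tm_helix_count = NA_integer_) {
  residues <- toupper(residues)
  if (any(nchar(residues) < 1)) abort("proteins must have length >= 1")
  if (any(grepl("[^ACDEFGHIKLMNPQRSTVWYXUBZ]", residues)))
    abort("residues outside the 20 canonical letters plus X/U/B/Z")
  id <- id %||% sprintf("p%04d", seq_along(residues))
  out <- tibble(id = id, residues = residues, length = nchar(residues),
                tm_helix_count = as.integer(rep_len(tm_helix_count, length(residues))),
                flag = NA_character_)
  class(out) <- c("protein_set", class(out))
  out
}

#' Extract rRNA gene copies
#'
#' Returns the sequences of all rRNA features of the requested subtype,
#' strand-normalized to the gene's sense. An empty result is allowed.
#'
#' @param genome A [genome_record()].
#' @param kind `"16S"`, `"23S"` or `"5S"` (or a full kind name like
#'   `"rRNA_16S"`).
#' @return Named character vector of gene sequences (may be empty).
#' @export
extract_rrna_copies <- function(genome, kind = "16S") {
  stopifnot(inherits(genome, "genome_record"))
  kind <- if (grepl("^rRNA_", kind)) kind else paste0("rRNA_", kind)
  hits <- filter(genome$features, .data$kind == !!kind)
  if (nrow(hits) == 0) return(setNames(character(0), character(0)))
  seqs <- map_chr(seq_len(nrow(hits)), ~feature_sequence(genome, hits[.x, ]))
  nm <- hits$locus_tag
  nm[is.na(nm)] <- sprintf("%s_copy%d", kind, which(is.na(nm)))
  setNames(seqs, nm)
}
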