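#' Read a FASTA file into a tibble
#'
#' Thin wrapper over [Biostrings::readBStringSet()] returning a tibble so the
#' result drops straight into a pipe. Sequences are uppercased; record order
#' is preserved. Duplicate ids are kept (with a warning) since downstream
#' metrics operate positionally.
#'
#' @param path FASTA file.
#' @return Tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort(paste0("not FASTA-formatted: ", conditionMessage(e))))
  if (length(set) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0))
    abort(paste0("zero-length sequence under header(s): ",
                 paste(ids[nchar(seqs) == 0], collapse = ", ")))
  if (anyDuplicated(ids))
    warn(paste0("duplicate FASTA ids kept: ",
                paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  tibble(id = ids, sequence = unname(seqs))
}

#' Write sequences to FASTA
#'
#' @param x Tibble with `id` and `sequence` columns (as from [read_fasta()]),
#'   or a named character vector.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  if (is.data.frame(x)) x <- setNames(x$sequence, x$id)
  stopifnot(!is.null(names(x)))
  lines <- unlist(map2(names(x), unname(x), function(id, s) {
    c(paste0(">", id),
      substring(s, seq(1, nchar(s), width), pmin(seq(1, nchar(s), width) + width - 1, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}
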