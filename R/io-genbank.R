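#' Read an annotated genome
#'
#' Reads one replicon plus its features from either a GenBank flat file or a
#' FASTA file with an optional tab-separated feature table alongside. GenBank
#' 1-based inclusive locations are converted to the package's 0-based
#' half-open convention; `join()` locations become multi-interval features;
#' rRNA features are classified 16S/23S/5S by a case-insensitive substring
#' match on the product qualifier.
#'
#' The feature-table dialect has columns `kind`, `start`, `end`, `strand`,
#' `product` (optional `locus_tag`), with `start`/`end` 1-based inclusive;
#' multi-interval features carry comma-separated coordinate lists.
#'
#' @param path Input file.
#' @param format `"genbank"` or `"fasta+table"`.
#' @param feature_table Path of the feature TSV for `"fasta+table"`; defaults
#'   to `path` with a `.features.tsv` extension. Missing table: the genome is
#'   returned featureless, with a warning.
#' @param rrna_patterns Named list mapping kinds to product-qualifier
#'   substrings, overriding the 16S/23S/5S defaults.
#' @return A [genome_record()].
#' @export
read_genome <- function(path, format = c("genbank", "fasta+table"),
                        feature_table = NULL, rrna_patterns = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "genbank") {
    read_genbank(path, rrna_patterns = rrna_patterns)
  } else {
    fa <- read_fasta(path)
    if (nrow(fa) > 1) warn("multiple FASTA records; using the first replicon")
    if (is.null(feature_table))
      feature_table <- paste0(sub("\\.(fa|fasta|fna)$", "", path), ".features.tsv")
    if (!file.exists(feature_table)) {
      warn(paste0("no feature table found at ", feature_table,
                  "; returning a featureless genome"))
      return(genome_record(fa$id[1], fa$sequence[1], topology = "linear"))
    }
    feats <- read_feature_table(feature_table)
    genome_record(fa$id[1], fa$sequence[1], topology = "linear", features = feats)
  }
}

DEFAULT_RRNA_PATTERNS <- list(rRNA_16S = "16S", rRNA_23S = "23S", rRNA_5S = "5S")

classify_rrna <- function(product, patterns = NULL) {
  patterns <- patterns %||% DEFAULT_RRNA_PATTERNS
  for (kind in names(patterns)) {
    if (!is.na(product) && grepl(patterns[[kind]], product, ignore.case = TRUE))
      return(kind)
  }
  "other"
}

read_genbank <- function(path, rrna_patterns = NULL) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) abort("not a GenBank flat file: no LOCUS line")
  topology <- if (grepl("\\bcircular\\b", locus[1], ignore.case = TRUE))
    "circular" else "linear"
  id <- strsplit(trimws(sub("^LOCUS\\s+", "", locus[1])), "\\s+")[[1]][1]
  acc <- grep("^ACCESSION\\s+\\S", lines, value = TRUE)
  if (length(acc) > 0) {
    acc_id <- strsplit(trimws(sub("^ACCESSION", "", acc[1])), "\\s+")[[1]][1]
    if (nzchar(acc_id)) id <- acc_id
  }

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0) abort("GenBank record has no ORIGIN section")
  end <- grep("^//", lines)
  end <- if (length(end)) end[end > ori[1]][1] else length(lines) + 1
  seq_lines <- lines[(ori[1] + 1):(end - 1)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  fstart <- grep("^FEATURES", lines)
  features <- empty_features()
  if (length(fstart) > 0) {
    flines <- lines[(fstart[1] + 1):(ori[1] - 1)]
    features <- parse_genbank_features(flines, nchar(sequence), rrna_patterns)
  }
  genome_record(id, sequence, topology = topology, features = features)
}

parse_genbank_features <- function(fl, genome_len, rrna_patterns = NULL) {
  # Feature keys start at column 6; qualifier/continuation lines at column 22.
  is_key <- grepl("^ {5}\\S", fl)
  idx <- which(is_key)
  if (length(idx) == 0) return(empty_features())
  rows <- map(seq_along(idx), function(i) {
    from <- idx[i]
    to <- if (i < length(idx)) idx[i + 1] - 1 else length(fl)
    block <- fl[from:to]
    key <- sub("^ {5}(\\S+).*", "\\1", block[1])
    # location may continue over lines until the first qualifier
    qual_at <- grep("^\\s+/", block)
    loc_end <- if (length(qual_at)) qual_at[1] - 1 else length(block)
    loc <- gsub("\\s", "", paste(c(sub("^ {5}\\S+\\s*", "", block[1]),
                                   trimws(block[seq_len(loc_end)][-1])), collapse = ""))
    quals <- parse_qualifiers(block[seq_len(length(block)) >= (loc_end + 1)])
    list(key = key, location = loc, quals = quals)
  })
  rows <- rows[!map_chr(rows, "key") %in% c("source")]
  if (length(rows) == 0) return(empty_features())
  parsed <- map(rows, function(r) {
    loc <- tryCatch(parse_genbank_location(r$location),
                    error = function(e) {
                      abort(sprintf("unparseable location for locus tag '%s': %s",
                                    r$quals[["locus_tag"]] %||% "<unknown>",
                                    r$location))
                    })
    product <- r$quals[["product"]] %||% NA_character_
    kind <- switch(r$key,
      CDS = "CDS",
      rRNA = classify_rrna(product, rrna_patterns),
      "other")
    tibble(kind = kind,
           strand = if (loc$complement) "-" else "+",
           locus_tag = r$quals[["locus_tag"]] %||% NA_character_,
           product = product,
           intervals = list(loc$intervals))
  })
  validate_features(bind_rows(parsed), genome_len)
}

parse_qualifiers <- function(block) {
  qual_at <- grep("^\\s+/", block)
  out <- list()
  for (i in qual_at) {
    line <- trimws(block[i])
    m <- regmatches(line, regexec("^/([A-Za-z_0-9]+)(=(.*))?$", line))[[1]]
    if (length(m) == 0) next
    key <- m[2]
    val <- gsub('^"|"$', "", m[4])
    # continuation lines (no leading /) extend the previous value
    j <- i + 1
    while (j <= length(block) && !grepl("^\\s+/", block[j]) && nzchar(trimws(block[j]))) {
      val <- paste(val, trimws(block[j]))
      j <- j + 1
    }
    val <- gsub('"$', "", val)
    out[[key]] <- val
  }
  out
}

# GenBank location grammar subset: N, N..M, complement(...), join(...),
# order(...), partial markers < and >. Returns 0-based half-open intervals.
parse_genbank_location <- function(loc) {
  complement <- FALSE
  x <- loc
  repeat {
    if (grepl("^complement\\(.*\\)$", x)) {
      complement <- !complement
      x <- sub("^complement\\((.*)\\)$", "\\1", x)
    } else if (grepl("^(join|order)\\(.*\\)$", x)) {
      x <- sub("^(join|order)\\((.*)\\)$", "\\2", x)
    } else break
  }
  parts <- strsplit(x, ",")[[1]]
  iv <- map(parts, function(p) {
    p <- gsub("[<>]", "", p)
    p <- sub("^complement\\((.*)\\)$", "\\1", p)  # rare per-segment form
    if (grepl("^[0-9]+$", p)) {
      a <- as.integer(p); b <- a
    } else if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "\\.\\.")[[1]])
      a <- ab[1]; b <- ab[2]
    } else stop("bad location segment: ", p)
    c(a - 1L, b)  # 1-based inclusive -> 0-based half-open
  })
  m <- do.call(rbind, iv)
  colnames(m) <- c("start", "end")
  list(intervals = m, complement = complement)
}

#' Read/write the FASTA + feature-table genome representation
#'
#' `write_genome()` writes a genome as a FASTA file plus a tab-separated
#' feature table (`<path>.features.tsv`); `read_feature_table()` reads the
#' table back. The pair round-trips a [genome_record()] exactly (topology is
#' recorded in the FASTA header).
#'
#' @param genome A [genome_record()].
#' @param path FASTA output path.
#' @return `write_genome()` returns `path` invisibly.
#' @export
write_genome <- function(genome, path) {
  write_fasta(setNames(genome$sequence, paste0(genome$id, " topology=", genome$topology)),
              path)
  tab <- genome$features |>
    mutate(
      start = map_chr(.data$intervals, ~paste(.x[, 1] + 1L, collapse = ",")),
      end = map_chr(.data$intervals, ~paste(.x[, 2], collapse = ","))
    ) |>
    select("kind", "start", "end", "strand", "locus_tag", "product")
  write.table(tab, paste0(sub("\\.(fa|fasta|fna)$", "", path), ".features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genome
#' @param table_path Feature-table TSV path.
#' @export
read_feature_table <- function(table_path) {
  tab <- read.delim(table_path, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", colClasses = "character")
  needed <- c("kind", "start", "end")
  if (!all(needed %in% names(tab)))
    abort("feature table needs at least kind/start/end columns")
  tibble(
    kind = tab$kind,
    strand = if ("strand" %in% names(tab)) tab$strand else "+",
    locus_tag = if ("locus_tag" %in% names(tab)) tab$locus_tag else NA_character_,
    product = if ("product" %in% names(tab)) tab$product else NA_character_,
    intervals = map2(tab$start, tab$end, function(s, e) {
      a <- as.integer(strsplit(s, ",")[[1]]) - 1L
      b <- as.integer(strsplit(e, ",")[[1]])
      if (length(a) != length(b) || anyNA(a) || anyNA(b))
        abort("malformed start/end interval lists in feature table")
      cbind(start = a, end = b)
    })
  )
}

#' Re-read a genome written by [write_genome()]
#'
#' @inheritParams write_genome
#' @return A [genome_record()].
#' @export
read_genome_fasta_table <- function(path) {
  fa <- read_fasta(path)
  hdr <- names(Biostrings::readBStringSet(path))[1]
  topo <- if (grepl("topology=circular", hdr)) "circular" else "linear"
  feats <- read_feature_table(paste0(sub("\\.(fa|fasta|fna)$", "", path), ".features.tsv"))
  genome_record(fa$id[1], fa$sequence[1], topology = topo, features = feats)
}
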