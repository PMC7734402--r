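# Synthetic mini-genome used to exercise the GenBank reader. The segments are
# laid out so that feature extraction has known answers (two MK proteins on
# opposite strands, a spliced MEEG protein, two rRNA genes, one frame-broken
# CDS).

mini_segments <- c(
  cds_plus   = "ATGAAATAA",                # 1..9, translates to MK
  cds_minus  = "TTATTTCAT",                # complement(10..18) -> MK
  join_a     = "ATGGAAGAA",                # join(19..27,31..36) -> MEEG
  filler1    = "CCC",                      # 28..30
  join_b     = "GGGTAA",                   # 31..36
  filler2    = "ACG",                      # 37..39
  rrna16     = "ACGTACGTACGTACGTACGTA",    # 40..60
  rrna23     = "GGGGCCCCAAAATTTTGGCC",     # 61..80
  filler3    = "TTTT",                     # 81..84
  cds_broken = "ATGAAAATAA",               # 85..94, length 10 (not codon-sized)
  filler4    = "ACGTACGTACGTACGTACGTACGTAC"  # 95..120
)

mini_sequence <- function() paste(mini_segments, collapse = "")

mini_genbank_text <- function() {
  seq <- tolower(mini_sequence())
  stopifnot(nchar(seq) == 120)
  origin <- vapply(seq(1, nchar(seq), 60), function(s) {
    chunk <- substr(seq, s, min(s + 59, nchar(seq)))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(1, nchar(chunk), 10) + 9, nchar(chunk)))
    sprintf("%9d %s", s, paste(blocks, collapse = " "))
  }, "")
  c(
    "LOCUS       SYN0001              120 bp    DNA     circular BCT 01-JAN-2020",
    "DEFINITION  synthetic mini genome for parser tests.",
    "ACCESSION   SYN0001",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    '                     /organism="synthetic construct"',
    "     CDS             1..9",
    '                     /locus_tag="mini_0001"',
    '                     /product="toy protein MK"',
    "     CDS             complement(10..18)",
    '                     /locus_tag="mini_0002"',
    '                     /product="toy protein MK, minus strand"',
    "     CDS             join(19..27,31..36)",
    '                     /locus_tag="mini_0003"',
    '                     /product="spliced toy protein MEEG"',
    "     rRNA            40..60",
    '                     /locus_tag="mini_r16"',
    '                     /product="16S ribosomal RNA"',
    "     rRNA            complement(61..80)",
    '                     /locus_tag="mini_r23"',
    '                     /product="23S ribosomal RNA"',
    "     CDS             85..94",
    '                     /locus_tag="mini_0004"',
    '                     /product="frame-broken CDS"',
    "ORIGIN",
    origin,
    "//"
  )
}

write_mini_genbank <- function(path = withr::local_tempfile(fileext = ".gbk",
                                                            .local_envir = parent.frame())) {
  writeLines(mini_genbank_text(), path)
  path
}
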