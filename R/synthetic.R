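#' Specification for a synthetic genome
#'
#' Defaults emulate, at desk scale, a low-G+C circular chromosome carrying
#' several near-identical rRNA operon copies: 100 kb at 25.8% G+C with 60 CDS
#' and 6 rRNA (16S-like) genes diverged from a common template by 0.1%
#' per-site substitution.
#'
#' @param length Genome length in bases.
#' @param gc_target Target G+C fraction in (0, 1).
#' @param n_cds Number of CDS features.
#' @param cds_length_range Min/max CDS length in bases (rounded to codons).
#' @param rrn_copies Number of 16S-like rRNA gene copies (>= 0).
#' @param rrn_divergence Per-site substitution probability applied
#'   independently to each copy of the template.
#' @param cvp_target,ivywrel_target Composition targets for the translations
#'   of the embedded CDS (see [solve_composition()]).
#' @param topology `"circular"` or `"linear"`.
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return A `genome_spec` list.
#' @export
genome_spec <- function(length = 100000, gc_target = 0.258, n_cds = 60,
                        cds_length_range = c(300, 900), rrn_copies = 6,
                        rrn_divergence = 0.001,
                        cvp_target = 0, ivywrel_target = 0.40,
                        topology = c("circular", "linear"), seed = 1) {
  topology <- match.arg(topology)
  stopifnot(gc_target > 0, gc_target < 1, rrn_copies >= 0, length >= 1000,
            rrn_divergence >= 0, rrn_divergence < 1,
            cds_length_range[1] >= 60, cds_length_range[2] >= cds_length_range[1])
  spec <- structure(list(length = as.integer(length), gc_target = gc_target,
                         n_cds = as.integer(n_cds),
                         cds_length_range = as.integer(cds_length_range),
                         rrn_copies = as.integer(rrn_copies),
                         rrn_divergence = rrn_divergence,
                         cvp_target = cvp_target,
                         ivywrel_target = ivywrel_target,
                         polar_mass = 0.17,
                         topology = topology, seed = as.integer(seed)),
                    class = "genome_spec")
  solve_composition(spec)  # composition feasibility check
  spec
}

# Fixed packaged 1,500-base 16S-like template (structural stand-in, not a
# biological sequence); deterministic and independent of any genome spec.
rrna_template <- function(length = 1500, gc = 0.5) {
  withr::with_seed(20200918, {
    paste(sample(c("A", "T", "G", "C"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
          collapse = "")
  })
}

# Synonymous-codon sampling weights per amino acid: within each family,
# codons are weighted by independent base probabilities at G+C level t, which
# skews third positions toward A/T in low-G+C genomes.
synonymous_codon_weights <- function(t, code_table = 11) {
  gcode <- Biostrings::getGeneticCode(as.character(code_table))
  sense <- gcode[gcode != "*"]
  pb <- c(A = (1 - t) / 2, C = t / 2, G = t / 2, T = (1 - t) / 2)
  w <- vapply(strsplit(names(sense), ""), function(cc) prod(pb[cc]), 0)
  split(setNames(w, names(sense)), unname(sense)) |>
    map(~.x / sum(.x))
}

# Pick the weighting level t whose expected CDS G+C (under the given residue
# composition) is closest to gc_target. The achievable range is bounded by
# the amino-acid composition, so t saturates when the target lies outside it.
solve_codon_weighting <- function(f_aa, gc_target, code_table = 11) {
  gcode <- Biostrings::getGeneticCode(as.character(code_table))
  gc3 <- setNames(
    vapply(strsplit(names(gcode), ""), function(cc) sum(cc %in% c("G", "C")), 0),
    names(gcode))
  exp_gc <- function(t) {
    w <- synonymous_codon_weights(t, code_table)
    per_aa <- map_dbl(w, ~sum(.x * gc3[names(.x)]) / 3)
    sum(f_aa * per_aa[names(f_aa)])
  }
  lo <- 1e-4; hi <- 1 - 1e-4
  if (exp_gc(lo) >= gc_target) return(lo)
  if (exp_gc(hi) <= gc_target) return(hi)
  uniroot(function(t) exp_gc(t) - gc_target, c(lo, hi), tol = 1e-9)$root
}

#' Generate a synthetic genome with known ground truth
#'
#' Background bases are i.i.d., with their G+C probability compensating the
#' realized composition of the embedded features so the whole genome hits
#' `gc_target` in expectation. CDS are placed without overlap on both strands
#' with a valid start (ATG) and stop and no internal stops; their residues
#' are drawn from the composition solved for the spec's CvP/IVYWREL targets
#' and back-translated through synonymous codons weighted toward the genome's
#' base composition (so low-G+C genomes use A/T third positions). rRNA gene
#' copies derive from one fixed template by independent per-site substitution
#' at `rrn_divergence`. Output is byte-identical for identical specs.
#'
#' @param spec A [genome_spec()].
#' @return A [genome_record()] with CDS and rRNA_16S features.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  withr::with_seed(spec$seed, generate_genome_impl(spec))
}

generate_genome_impl <- function(spec) {
  L <- spec$length
  tmpl <- rrna_template()
  rrn_len <- nchar(tmpl)

  # CDS lengths in codons (start + interior + stop)
  n_codons <- floor(runif(spec$n_cds,
                          spec$cds_length_range[1] / 3,
                          spec$cds_length_range[2] / 3 + 1))
  cds_lens <- as.integer(n_codons * 3)
  feat_lens <- c(cds_lens, rep(rrn_len, spec$rrn_copies))
  n_feat <- length(feat_lens)
  total_feat <- sum(feat_lens)
  if (total_feat > 0.9 * L)
    abort(sprintf("infeasible packing: %d feature bases exceed 90%% of the %d-bp genome",
                  total_feat, L))

  # CDS: protein-first back-translation. Residues are drawn from the solved
  # composition, then each residue picks a synonymous codon weighted by the
  # genome's base composition (AT-skewed third positions in low-G+C genomes).
  f_aa <- solve_composition(spec)
  syn <- synonymous_codon_weights(solve_codon_weighting(f_aa, spec$gc_target))
  stops <- c("TAA", "TAG", "TGA")
  pb <- c(A = (1 - spec$gc_target) / 2, C = spec$gc_target / 2,
          G = spec$gc_target / 2, T = (1 - spec$gc_target) / 2)
  stop_w <- vapply(strsplit(stops, ""), function(cc) prod(pb[cc]), 0)
  stop_w <- stop_w / sum(stop_w)
  cds_seqs <- map_chr(seq_len(spec$n_cds), function(i) {
    k <- cds_lens[i] / 3 - 2
    aa <- sample(AA_CANONICAL, k, replace = TRUE, prob = f_aa)
    codons <- map_chr(aa, function(a) {
      wt <- syn[[a]]
      sample(names(wt), 1, prob = wt)
    })
    paste0("ATG", paste(codons, collapse = ""), sample(stops, 1, prob = stop_w))
  })
  tmpl_chars <- strsplit(tmpl, "")[[1]]
  rrn_seqs <- map_chr(seq_len(spec$rrn_copies), function(i) {
    mut <- runif(rrn_len) < spec$rrn_divergence
    cc <- tmpl_chars
    if (any(mut)) {
      cc[mut] <- map_chr(cc[mut], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1))
    }
    paste(cc, collapse = "")
  })
  feat_seqs <- c(cds_seqs, rrn_seqs)
  feat_kind <- c(rep("CDS", spec$n_cds), rep("rRNA_16S", spec$rrn_copies))
  strands <- sample(c("+", "-"), n_feat, replace = TRUE)

  # background base probability compensates the realized G+C of the feature
  # sequences, so the genome hits gc_target in expectation
  L_bg <- L - total_feat
  gc_feat <- sum(map_dbl(feat_seqs, ~sum(strsplit(.x, "")[[1]] %in% c("G", "C"))))
  t_bg <- (L * spec$gc_target - gc_feat) / L_bg
  if (t_bg <= 0 || t_bg >= 1)
    abort(sprintf(paste0("infeasible G+C compensation: embedded features leave a ",
                         "background G+C of %.3f"), t_bg))
  bg <- sample(c("A", "T", "G", "C"), L, replace = TRUE,
               prob = c((1 - t_bg) / 2, (1 - t_bg) / 2, t_bg / 2, t_bg / 2))

  # feature placement: random order, random gaps (stick-breaking)
  ord <- sample.int(n_feat)
  cuts <- sort(sample.int(L_bg + 1, n_feat, replace = TRUE) - 1L)
  gaps <- c(cuts[1], diff(cuts))
  starts <- integer(n_feat)
  pos <- 0L
  for (k in seq_len(n_feat)) {
    pos <- pos + gaps[k]
    starts[k] <- pos
    pos <- pos + feat_lens[ord[k]]
  }

  for (k in seq_len(n_feat)) {
    f <- ord[k]
    s <- feat_seqs[f]
    if (strands[f] == "-") s <- revcomp(s)
    idx <- starts[k] + seq_len(feat_lens[f])
    bg[idx] <- strsplit(s, "")[[1]]
  }

  placed_start <- integer(n_feat)
  placed_start[ord] <- starts
  features <- tibble(
    kind = feat_kind,
    strand = strands,
    locus_tag = c(sprintf("cds_%04d", seq_len(spec$n_cds)),
                  if (spec$rrn_copies > 0) sprintf("rrn16S_%02d", seq_len(spec$rrn_copies))),
    product = ifelse(feat_kind == "CDS", "hypothetical protein",
                     "16S ribosomal RNA"),
    intervals = map2(placed_start, placed_start + feat_lens,
                     ~cbind(start = as.integer(.x), end = as.integer(.y)))
  )
  genome_record(sprintf("synthetic_seed%d", spec$seed),
                paste(bg, collapse = ""),
                topology = spec$topology, features = features)
}

#' Specification for a synthetic proteome
#'
#' @param n_proteins Number of proteins.
#' @param length_range Min/max protein length in residues.
#' @param cvp_target Target CvP bias in percentage points.
#' @param ivywrel_target Target IVYWREL fraction.
#' @param tm_protein_fraction Fraction of proteins given one >= 25-residue
#'   hydrophobic insert (membrane-like proteins).
#' @param polar_mass Baseline total frequency of the polar set (N, Q, S, T);
#'   raised automatically when a negative CvP target requires it.
#' @param seed Integer seed.
#' @return A `proteome_spec` list.
#' @export
proteome_spec <- function(n_proteins = 500, length_range = c(100, 500),
                          cvp_target = 0, ivywrel_target = 0.40,
                          tm_protein_fraction = 0, polar_mass = 0.17,
                          seed = 1) {
  stopifnot(n_proteins >= 1, length_range[1] >= 30,
            cvp_target >= -100, cvp_target <= 100,
            ivywrel_target >= 0, ivywrel_target <= 1,
            tm_protein_fraction >= 0, tm_protein_fraction <= 1)
  spec <- structure(list(n_proteins = as.integer(n_proteins),
                         length_range = as.integer(length_range),
                         cvp_target = cvp_target,
                         ivywrel_target = ivywrel_target,
                         tm_protein_fraction = tm_protein_fraction,
                         polar_mass = polar_mass, seed = as.integer(seed)),
                    class = "proteome_spec")
  solve_composition(spec)  # feasibility check at construction time
  spec
}

#' Solve a residue composition meeting CvP and IVYWREL targets
#'
#' Mass is split evenly inside each residue group (charged D/E/K/R, polar
#' N/Q/S/T, the IVYWREL-only residues I/V/Y/W/L, and the remainder), so the
#' targets are met in expectation by i.i.d. sampling. Because E and R sit in
#' both the charged and IVYWREL sets, an even within-group split makes some
#' target pairs jointly infeasible (e.g. CvP +100 with IVYWREL 0); the error
#' names the binding constraint.
#'
#' @param spec A `proteome_spec` (or list with the same fields).
#' @return Named frequency vector over the 20 canonical residues, summing
#'   to 1.
#' @export
solve_composition <- function(spec) {
  v <- spec$cvp_target / 100
  p <- max(spec$polar_mass, -v)          # ensure charged mass >= 0
  ch <- p + v                             # charged mass: CvP = 100 (ch - p)
  w <- spec$ivywrel_target
  if (ch > 1)
    abort("infeasible: charged mass above 1 (cvp_target too high for polar_mass)")
  extra_ivywrel <- w - ch / 2             # E and R carry half the charged mass
  if (extra_ivywrel < -1e-12)
    abort(sprintf(paste0("infeasible: ivywrel_target %.3f is below the %.3f share ",
                         "already implied by E and R in the charged set"),
                  w, ch / 2))
  extra_ivywrel <- max(extra_ivywrel, 0)
  rest <- 1 - ch - p - extra_ivywrel
  if (rest < -1e-12)
    abort(sprintf("infeasible: residue masses sum to %.3f > 1 (binding constraint: remainder)",
                  ch + p + extra_ivywrel))
  rest <- max(rest, 0)
  f <- setNames(numeric(20), AA_CANONICAL)
  f[AA_CHARGED] <- ch / 4
  f[AA_POLAR] <- p / 4
  ivy_only <- setdiff(AA_IVYWREL, AA_CHARGED)   # I V Y W L
  f[ivy_only] <- f[ivy_only] + extra_ivywrel / 5
  others <- setdiff(AA_CANONICAL, c(AA_CHARGED, AA_POLAR, ivy_only))
  f[others] <- rest / length(others)
  f / sum(f)
}

#' Generate a synthetic proteome with known composition targets
#'
#' Residues are drawn i.i.d. from the composition solved by
#' [solve_composition()], so measured CvP and IVYWREL converge on their
#' targets; a `tm_protein_fraction` share of proteins receives a multi-pass
#' membrane insert — two 25-residue hydrophobic (Leu/Ile/Val/Phe) stretches
#' separated by a 40-residue polar linker — so the hydropathy surrogate calls
#' two transmembrane helices and the default soluble filter (< 2 helices)
#' removes them.
#'
#' @param spec A [proteome_spec()].
#' @return A `protein_set` tibble; `attr(, "composition")` holds the solved
#'   ground-truth frequencies and `attr(, "tm_ids")` the inserted-protein ids.
#' @export
generate_proteome <- function(spec) {
  stopifnot(inherits(spec, "proteome_spec"))
  f <- solve_composition(spec)
  withr::with_seed(spec$seed, {
    lens <- floor(runif(spec$n_proteins, spec$length_range[1],
                        spec$length_range[2] + 1))
    residues <- map_chr(lens, function(n)
      paste(sample(AA_CANONICAL, n, replace = TRUE, prob = f), collapse = ""))
    n_tm <- round(spec$tm_protein_fraction * spec$n_proteins)
    tm_idx <- if (n_tm > 0) sample.int(spec$n_proteins, n_tm) else integer(0)
    for (i in tm_idx) {
      helix <- function() paste(sample(c("L", "I", "V", "F"), 25, replace = TRUE,
                                       prob = c(0.5, 0.2, 0.2, 0.1)), collapse = "")
      linker <- paste(sample(c("N", "S", "T", "G"), 40, replace = TRUE), collapse = "")
      insert <- paste0(helix(), linker, helix())
      at <- sample.int(nchar(residues[i]) - 1, 1)
      residues[i] <- paste0(substr(residues[i], 1, at), insert,
                            substr(residues[i], at + 1, nchar(residues[i])))
    }
    out <- protein_set(residues)
    attr(out, "composition") <- f
    attr(out, "tm_ids") <- out$id[tm_idx]
    out
  })
}

#' Generate a synthetic species table with a known metric-OGT line
#'
#' Optimum growth temperatures are uniform on `ogt_range`; the metric is
#' `intercept + slope * OGT + N(0, noise_sd)`. The noiseless truth is kept in
#' `metric_true`.
#'
#' @param n_species Number of species (>= 3).
#' @param slope,intercept Ground-truth line (metric on OGT).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param ogt_range OGT range in deg C.
#' @param seed Integer seed.
#' @param metric_name Name used for the metric column.
#' @return Tibble `species_id`, `ogt_observed`, `<metric_name>`,
#'   `metric_true`; attributes `slope`, `intercept`, `noise_sd`.
#' @export
generate_species_table <- function(n_species = 20, slope = -0.002,
                                   intercept = 0.65, noise_sd = 0.005,
                                   ogt_range = c(20, 100), seed = 1,
                                   metric_name = "metric") {
  if (n_species < 3) abort("need n_species >= 3")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  withr::with_seed(seed, {
    ogt <- runif(n_species, ogt_range[1], ogt_range[2])
    true <- intercept + slope * ogt
    obs <- true + rnorm(n_species, 0, noise_sd)
    out <- tibble(species_id = sprintf("sp%03d", seq_len(n_species)),
                  ogt_observed = ogt, metric_true = true)
    out[[metric_name]] <- obs
    out <- out[c("species_id", "ogt_observed", metric_name, "metric_true")]
    attr(out, "slope") <- slope
    attr(out, "intercept") <- intercept
    attr(out, "noise_sd") <- noise_sd
    out
  })
}
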