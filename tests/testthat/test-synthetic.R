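test_that("generators are pure functions of their specs", {
  s <- genome_spec(length = 20000, n_cds = 8, rrn_copies = 3, seed = 42)
  g1 <- generate_genome(s); g2 <- generate_genome(s)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$features, g2$features)

  p1 <- generate_proteome(proteome_spec(n_proteins = 20, seed = 9))
  p2 <- generate_proteome(proteome_spec(n_proteins = 20, seed = 9))
  expect_identical(p1$residues, p2$residues)

  t1 <- generate_species_table(seed = 5); t2 <- generate_species_table(seed = 5)
  expect_identical(t1, t2)

  # the generator must not disturb the caller's RNG stream
  withr::with_seed(1, {
    before <- runif(1)
  })
  withr::with_seed(1, {
    invisible(generate_genome(s))
    expect_identical(runif(1), before)
  })
})

test_that("generated genomes hit their G+C target within binomial tolerance", {
  for (gct in c(0.258, 0.45)) {
    g <- generate_genome(genome_spec(length = 100000, gc_target = gct, seed = 17))
    expect_equal(gc_content(g), gct, tolerance = 0.005 / gct)
  }
})

test_that("rRNA copies are extractable and near-identical at low divergence", {
  g <- generate_genome(genome_spec(length = 60000, rrn_copies = 6,
                                   rrn_divergence = 0.001, n_cds = 5, seed = 2))
  copies <- extract_rrna_copies(g, "16S")
  expect_length(copies, 6)
  prof_id <- proteome_thermal_profile(g)$min_16s_copy_identity
  expect_gte(prof_id, 99.5)
})

test_that("generated CDS translate cleanly and pass the io invariants", {
  g <- generate_genome(genome_spec(length = 40000, n_cds = 30, seed = 13))
  prot <- extract_and_translate_cds(g)
  expect_true(all(is.na(prot$flag)))
  expect_true(all(substr(prot$residues, 1, 1) == "M"))
  expect_false(any(grepl("\\*", prot$residues)))
})

test_that("infeasible genome packing raises a capacity error", {
  expect_error(generate_genome(genome_spec(length = 1000, n_cds = 10,
                                           cds_length_range = c(300, 300),
                                           rrn_copies = 0, seed = 1)),
               "infeasible packing")
})

test_that("proteome targets are met in expectation", {
  ps <- generate_proteome(proteome_spec(n_proteins = 500,
                                        length_range = c(300, 300),
                                        cvp_target = 0, ivywrel_target = 0.40,
                                        seed = 4))
  comp <- aa_composition(ps)
  expect_equal(cvp_bias(comp), 0, tolerance = 1)            # +/- 1 point
  expect_equal(ivywrel_fraction(comp), 0.40, tolerance = 0.01 / 0.40)
})

test_that("tm_protein_fraction controls how many proteins the filter removes", {
  ps <- generate_proteome(proteome_spec(n_proteins = 300,
                                        length_range = c(200, 400),
                                        tm_protein_fraction = 0.3, seed = 7))
  counted <- add_tm_helix_counts(ps)
  kept <- filter_soluble(counted)
  removed <- 1 - nrow(kept) / nrow(ps)
  expect_equal(removed, 0.3, tolerance = 0.25)  # approximate by construction
  expect_true(all(attr(ps, "tm_ids") %in% setdiff(ps$id, kept$id)))
})

test_that("jointly infeasible composition targets raise the binding constraint", {
  expect_error(proteome_spec(cvp_target = 100, ivywrel_target = 0),
               "infeasible")
  # with no polar mass the E/R overlap itself is binding
  expect_error(proteome_spec(cvp_target = 100, ivywrel_target = 0, polar_mass = 0),
               "E and R")
  f <- solve_composition(proteome_spec(cvp_target = 15, ivywrel_target = 0.45))
  expect_equal(sum(f), 1)
  expect_equal(100 * (sum(f[c("D","E","K","R")]) - sum(f[c("N","Q","S","T")])), 15)
  expect_equal(sum(f[c("I","V","Y","W","R","E","L")]), 0.45)
})

test_that("species tables have exact structure in the noiseless limit", {
  tab <- generate_species_table(n_species = 10, slope = -0.002, intercept = 0.65,
                                noise_sd = 0, seed = 3)
  m <- fit_linear_model(tab$ogt_observed, tab$metric)
  expect_equal(m$slope, -0.002, tolerance = 1e-12)
  expect_equal(m$intercept, 0.65, tolerance = 1e-12)
  expect_identical(tab$metric, tab$metric_true)
  expect_error(generate_species_table(n_species = 2), "n_species")
  expect_error(generate_species_table(noise_sd = -1), "noise_sd")
})

test_that("pipeline recovery grid: G+C and operon count round-trip", {
  for (gct in c(0.3, 0.5)) {
    for (rrn in c(2L, 5L)) {
      g <- generate_genome(genome_spec(length = 50000, gc_target = gct,
                                       n_cds = 15, rrn_copies = rrn,
                                       seed = 100 + rrn))
      prof <- proteome_thermal_profile(g, tm_mode = "none")
      expect_equal(prof$gc_genome, gct, tolerance = 0.005 / gct)
      expect_identical(prof$rrna_operon_count, rrn)
    }
  }
})
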