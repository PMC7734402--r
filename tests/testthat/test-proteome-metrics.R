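test_that("aa_composition handles modes and excludes non-canonical residues", {
  c1 <- aa_composition("AAAA")
  expect_equal(unname(c1$frequencies["A"]), 1.0)
  expect_equal(sum(c1$frequencies), 1.0)

  c2 <- aa_composition(c("DEKR", "NQST"))
  expect_true(all(abs(c2$frequencies[c("D","E","K","R","N","Q","S","T")] - 0.125) < 1e-12))

  pooled <- aa_composition(c("AA", "CCCCCC"), mode = "pooled")
  per <- aa_composition(c("AA", "CCCCCC"), mode = "per_protein_mean")
  expect_equal(unname(pooled$frequencies["A"]), 0.25)
  expect_equal(unname(per$frequencies["A"]), 0.5)

  cx <- aa_composition("AAXX")
  expect_equal(unname(cx$frequencies["A"]), 1.0)
  expect_equal(cx$n_residues, 2)
})

test_that("CvP and IVYWREL match hand tallies on constructed proteins", {
  expect_equal(cvp_bias(aa_composition("DEKR")), 100.0)
  expect_equal(cvp_bias(aa_composition("NQST")), -100.0)
  expect_equal(cvp_bias(aa_composition("DENQGG")), 0.0)
  expect_equal(ivywrel_fraction(aa_composition("IVYWREL")), 1.0)
  expect_equal(ivywrel_fraction(aa_composition("GAST")), 0.0)
  expect_equal(ivywrel_fraction(aa_composition("LIVING")), 4 / 6)
})

test_that("indices agree with a brute-force residue tally on random proteomes", {
  withr::with_seed(101, {
    for (i in 1:10) {
      prots <- replicate(20, random_protein(sample(30:200, 1)))
      comp <- aa_composition(prots, mode = "pooled")
      oracle <- tally_indices(prots)
      expect_equal(cvp_bias(comp), oracle$cvp, tolerance = 1e-12)
      expect_equal(ivywrel_fraction(comp), oracle$ivywrel, tolerance = 1e-12)
    }
  })
})

test_that("indices are invariant under permutation and whole-set duplication", {
  withr::with_seed(11, {
    prots <- replicate(15, random_protein(80))
    comp <- aa_composition(prots)
    expect_equal(cvp_bias(aa_composition(sample(prots))), cvp_bias(comp))
    expect_equal(cvp_bias(aa_composition(c(prots, prots))), cvp_bias(comp))
    expect_equal(ivywrel_fraction(aa_composition(c(prots, prots))),
                 ivywrel_fraction(comp))
    expect_true(cvp_bias(comp) >= -100 && cvp_bias(comp) <= 100)
    expect_true(ivywrel_fraction(comp) >= 0 && ivywrel_fraction(comp) <= 1)
  })
})

test_that("removing an index-neutral protein only rescales the denominator", {
  prots <- c("DDEE", "KKRR", "GGAAMM")  # third protein has no charged/polar residues
  with_it <- cvp_bias(aa_composition(prots))
  oracle <- tally_indices(prots)
  expect_equal(with_it, oracle$cvp)
  without <- cvp_bias(aa_composition(prots[1:2]))
  expect_equal(without, tally_indices(prots[1:2])$cvp)
  expect_equal(with_it, 100 * 8 / 14)
  expect_equal(without, 100.0)
})

test_that("hydropathy surrogate counts helix runs as specified", {
  expect_equal(count_tm_helices(strrep("L", 30)), 1L)   # all windows hot
  expect_equal(count_tm_helices(strrep("D", 30)), 0L)   # all cold
  expect_equal(count_tm_helices(strrep("L", 10)), 0L)   # shorter than window
  # two hydrophobic stretches separated by a long polar linker
  two <- paste0(strrep("L", 25), strrep("N", 40), strrep("L", 25))
  expect_equal(count_tm_helices(two), 2L)
  # short gap: runs merge
  one <- paste0(strrep("L", 25), strrep("N", 3), strrep("L", 25))
  expect_equal(count_tm_helices(one), 1L)
})

test_that("filter_soluble keeps counts below the bound and is idempotent", {
  ps <- protein_set(rep(strrep("A", 50), 4), tm_helix_count = c(0L, 1L, 2L, 3L))
  kept <- filter_soluble(ps)
  expect_equal(kept$tm_helix_count, c(0L, 1L))
  expect_equal(filter_soluble(kept), kept)
  expect_equal(nrow(filter_soluble(ps, max_helices_exclusive = 0)), 0)
  all0 <- protein_set(rep(strrep("A", 50), 3), tm_helix_count = 0L)
  expect_equal(nrow(filter_soluble(all0)), 3)

  unset <- protein_set("AAAA")
  expect_error(filter_soluble(unset), "tm_helix_count unset")
})

test_that("external TM tables bypass the surrogate", {
  ps <- protein_set(c(strrep("L", 40), strrep("D", 40)), id = c("a", "b"))
  ext <- tibble::tibble(id = c("a", "b"), tm_helix_count = c(0L, 5L))
  got <- add_tm_helix_counts(ps, external = ext)
  expect_equal(got$tm_helix_count, c(0L, 5L))  # surrogate would say c(1, 0)
  kept <- filter_soluble(got)
  expect_equal(kept$id, "a")
})

test_that("full profile of a synthetic genome satisfies its invariants", {
  prof <- proteome_thermal_profile(generate_genome(genome_spec(
    length = 40000, n_cds = 25, seed = 1)))
  expect_true(prof$gc_genome > 0 && prof$gc_genome < 1)
  expect_true(prof$ivywrel >= 0 && prof$ivywrel <= 1)
  expect_true(prof$cvp_bias >= -100 && prof$cvp_bias <= 100)
  expect_true(prof$at3_fraction >= 0 && prof$at3_fraction <= 1)
  expect_equal(prof$rrna_operon_count, 6L)
  expect_true(prof$min_16s_copy_identity > 99)
  expect_identical(
    prof,
    proteome_thermal_profile(generate_genome(genome_spec(
      length = 40000, n_cds = 25, seed = 1))))  # deterministic
})

test_that("proteome generated to a CvP target round-trips through the index", {
  ps <- generate_proteome(proteome_spec(n_proteins = 500,
                                        length_range = c(300, 300),
                                        cvp_target = 10, seed = 3))
  expect_equal(cvp_bias(aa_composition(ps)), 10, tolerance = 0.5 / 10)
})
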