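test_that("global alignment identities on small cases", {
  expect_equal(global_align("ACGT", "ACGT")$identity_pct, 100.0)
  expect_equal(global_align("ACGT", "ACGA")$identity_pct, 75.0)
  expect_error(global_align("", "ACGT"), "empty")
})

test_that("alignment score matches an independent DP oracle", {
  withr::with_seed(77, {
    for (i in 1:8) {
      a <- random_dna(sample(40:200, 1))
      b <- random_dna(sample(40:200, 1))
      pair <- global_align(a, b)
      expect_equal(pair$score, dp_align_score(a, b))
      # the reported alignment realizes the reported score
      ca <- strsplit(pair$a_gapped, "")[[1]]
      cb <- strsplit(pair$b_gapped, "")[[1]]
      sub <- sum(ifelse(ca != "-" & cb != "-", ifelse(ca == cb, 1, -1), 0))
      gaps <- rle(ca == "-"); go_a <- sum(gaps$values); ge_a <- sum(ca == "-")
      gaps <- rle(cb == "-"); go_b <- sum(gaps$values); ge_b <- sum(cb == "-")
      expect_equal(sub - 5 * (go_a + go_b) - (ge_a + ge_b), pair$score)
    }
  })
})

test_that("percent identity: symmetry, gap modes, substitution arithmetic", {
  s <- strrep("ACGT", 375)  # identical 1500-mers
  expect_equal(percent_identity(global_align(s, s)), 100.0)

  one_sub <- paste0("T", substr(s, 2, 1000))
  expect_equal(percent_identity(c(substr(s, 1, 1000), one_sub)), 99.9)

  withr::with_seed(9, {
    a <- random_dna(300); b <- random_dna(300)
    expect_equal(global_align(a, b)$identity_pct, global_align(b, a)$identity_pct)
  })

  pair <- list("AC-GT", "ACNGA")
  expect_equal(percent_identity(pair), 75)                       # gap+N columns dropped
  expect_equal(percent_identity(pair, "include_gaps"), 60)       # counted as mismatch
  expect_error(percent_identity(c("--", "AA")), "zero compared")
})

test_that("distance matrices: p-distance, JC closed form, saturation error", {
  seqs <- c(a = "AAAAAAAA", b = "AAAAAAAA", c = "AAAAAAAA")
  d0 <- distance_matrix(seqs)
  expect_true(all(d0 == 0))

  seqs2 <- c(a = strrep("A", 100),
             b = paste0(strrep("C", 25), strrep("A", 75)),  # p = 0.25
             c = strrep("A", 100))
  jc <- distance_matrix(seqs2, model = "jukes_cantor")
  expect_equal(jc["a", "b"], -0.75 * log(1 - 4 * 0.25 / 3))
  expect_equal(jc["a", "c"], 0)
  expect_true(isSymmetric(jc))
  expect_true(all(diag(jc) == 0))

  sat <- c(a = strrep("A", 100), b = strrep("C", 100), c = strrep("A", 100))
  expect_error(distance_matrix(sat, model = "jukes_cantor"), "saturation.*a.*b")

  # pairwise gap deletion: gap columns only drop out for pairs touching them
  gapped <- c(a = "A-AAA", b = "ACAAA", c = "ACAAC")
  p <- distance_matrix(gapped)
  expect_equal(p["a", "b"], 0)
  expect_equal(p["b", "c"], 0.2)

  expect_error(distance_matrix(seqs[1:2]), "at least 3")
  expect_error(distance_matrix(c(a = "AC", b = "ACGT", c = "ACGT")), "same")
})

test_that("JC distance exceeds p-distance and matches ape on random alignments", {
  withr::with_seed(31, {
    base <- random_dna(600)
    seqs <- vapply(1:5, function(i) {
      cc <- strsplit(base, "")[[1]]
      mut <- runif(600) < 0.1
      cc[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
      paste(cc, collapse = "")
    }, "")
    names(seqs) <- paste0("s", 1:5)
    p <- distance_matrix(seqs, "p_distance")
    jc <- distance_matrix(seqs, "jukes_cantor")
    off <- upper.tri(p)
    expect_true(all(jc[off] >= p[off]))

    bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(seqs), "")))
    expect_equal(unname(p), unname(as.matrix(ape::dist.dna(bin, "raw"))),
                 tolerance = 1e-12)
    expect_equal(unname(jc), unname(as.matrix(ape::dist.dna(bin, "JC69"))),
                 tolerance = 1e-12)
  })
})

test_that("3-taxon NJ reproduces the closed-form branch lengths", {
  m <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(m)
  expect_equal(ape::Ntip(tr), 3)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), 1)  # (3+4-5)/2
  expect_equal(unname(bl["b"]), 2)  # (3+5-4)/2
  expect_equal(unname(bl["c"]), 3)  # (4+5-3)/2
})

test_that("NJ recovers additive matrices exactly (path-length oracle)", {
  withr::with_seed(55, {
    for (i in 1:20) {
      m <- random_additive_matrix(sample(4:12, 1))
      tr <- neighbor_joining(m)
      got <- ape::cophenetic.phylo(tr)[rownames(m), colnames(m)]
      expect_equal(unname(got), unname(m), tolerance = 1e-10)
    }
  })
})

test_that("NJ topology agrees with an independent implementation", {
  withr::with_seed(60, {
    for (i in 1:5) {
      m <- random_additive_matrix(8)
      mine <- neighbor_joining(m)
      theirs <- ape::nj(as.dist(m))
      expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(theirs)), 0,
                   ignore_attr = TRUE)
    }
  })
})

test_that("NJ is deterministic on tie-rich (star-like) matrices and validates input", {
  m <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(m) <- 0
  t1 <- neighbor_joining(m)
  t2 <- neighbor_joining(m)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length >= 0))

  bad <- m; bad[1, 2] <- 2
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("newick round-trips preserve path-length matrices", {
  withr::with_seed(8, {
    m <- random_additive_matrix(20)
    tr <- neighbor_joining(m)
    f <- withr::local_tempfile(fileext = ".nwk")
    write_newick(tr, f)
    back <- read_newick(f)
    expect_equal(ape::cophenetic.phylo(back)[rownames(m), colnames(m)],
                 ape::cophenetic.phylo(tr)[rownames(m), colnames(m)],
                 tolerance = 1e-12)
  })

  # metacharacter labels survive quoting
  tr3 <- neighbor_joining(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3, 3,
                                 dimnames = list(c("a b", "c(d)", "e"),
                                                 c("a b", "c(d)", "e"))))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr3, f)
  expect_setequal(read_newick(f)$tip.label, c("a b", "c(d)", "e"))
})

test_that("bootstrap support is high for well-separated clades", {
  withr::with_seed(14, {
    # two clearly distinct clades of near-identical sequences
    a <- random_dna(400); b <- random_dna(400)
    mut <- function(s, k) {
      cc <- strsplit(s, "")[[1]]
      at <- sample(length(cc), k)
      cc[at] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      paste(cc, collapse = "")
    }
    seqs <- c(a1 = mut(a, 4), a2 = mut(a, 4), a3 = mut(a, 4),
              b1 = mut(b, 4), b2 = mut(b, 4), b3 = mut(b, 4))
    tr <- build_nj_tree(seqs, model = "p_distance", n_replicates = 50, seed = 2)
    expect_s3_class(tr, "phylo")
    expect_true(any(as.numeric(tr$node.label) >= 90, na.rm = TRUE))
    # same seed, same supports
    tr2 <- build_nj_tree(seqs, model = "p_distance", n_replicates = 50, seed = 2)
    expect_equal(tr$node.label, tr2$node.label)
  })
})

test_that("16S copies of a synthetic genome are nearly identical", {
  g <- generate_genome(genome_spec(length = 60000, rrn_copies = 6,
                                   rrn_divergence = 0.001, n_cds = 10, seed = 6))
  copies <- extract_rrna_copies(g, "16S")
  expect_length(copies, 6)
  pairs <- combn(6, 2)
  ids <- apply(pairs, 2, function(k)
    percent_identity(global_align(copies[[k[1]]], copies[[k[2]]])))
  expect_gte(min(ids), 99.5)
})
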