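# Independent oracles used by the tests. These deliberately avoid the package
# implementations: alignment scoring by a direct Gotoh DP, composition by a
# raw residue tally, additive matrices from random trees via path lengths.

# Affine-gap global alignment score: a gap of length L costs open + L * ext.
dp_align_score <- function(a, b, match = 1, mismatch = -1,
                           gap_open = 5, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in a gap in b (up)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in a gap in a (left)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + i * gap_extend)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + j * gap_extend)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# CvP and IVYWREL by raw character tally over a pooled residue string.
tally_indices <- function(residues) {
  cc <- strsplit(paste(residues, collapse = ""), "")[[1]]
  cc <- cc[cc %in% c("A","C","D","E","F","G","H","I","K","L",
                     "M","N","P","Q","R","S","T","V","W","Y")]
  n <- length(cc)
  list(
    cvp = 100 * (sum(cc %in% c("D","E","K","R")) - sum(cc %in% c("N","Q","S","T"))) / n,
    ivywrel = sum(cc %in% c("I","V","Y","W","R","E","L")) / n
  )
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A","T","G","C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

random_protein <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               n, replace = TRUE), collapse = "")
}

# Additive distance matrix: leaf-to-leaf path lengths of a random tree.
random_additive_matrix <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.05, 1))
  ape::cophenetic.phylo(tr)
}
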