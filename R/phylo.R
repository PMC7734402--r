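#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment via [Biostrings::pairwiseAlignment()].
#' A gap of length L costs `gap_open + L * gap_extend`. `N` scores 0 against
#' everything (neither match nor mismatch).
#'
#' @param a,b Nucleotide strings (non-empty).
#' @param match,mismatch,gap_open,gap_extend Scoring scheme; penalties are
#'   given as positive costs.
#' @return An `aligned_pair`: list with `a_gapped`, `b_gapped`, `score`,
#'   `identity_pct` (gap/N columns excluded).
#' @export
global_align <- function(a, b, match = 1, mismatch = -1,
                         gap_open = 5, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) abort("cannot align an empty sequence")
  letters <- c("A", "C", "G", "T", "N")
  sm <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(sm) <- match
  sm["N", ] <- 0; sm[, "N"] <- 0
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = "global", substitutionMatrix = sm,
    gapOpening = gap_open, gapExtension = gap_extend)
  pair <- structure(
    list(a_gapped = as.character(Biostrings::alignedPattern(pa)),
         b_gapped = as.character(Biostrings::alignedSubject(pa)),
         score = Biostrings::score(pa)),
    class = "aligned_pair")
  pair$identity_pct <- percent_identity(pair)
  pair
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat(sprintf("<aligned_pair> score %.1f, identity %.2f%%, %d columns\n",
              x$score, x$identity_pct, nchar(x$a_gapped)))
  invisible(x)
}

#' Percent identity of an aligned pair
#'
#' Matches over compared columns, times 100. By default columns containing a
#' gap or `N` in either row are excluded from the comparison
#' (`exclude_gap_columns`); `include_gaps` counts them as mismatches.
#'
#' @param pair An `aligned_pair` from [global_align()], or a length-2
#'   character vector of equal-length gapped sequences.
#' @param gap_mode `"exclude_gap_columns"` (default) or `"include_gaps"`.
#' @return Percent in `[0, 100]`.
#' @export
percent_identity <- function(pair, gap_mode = c("exclude_gap_columns", "include_gaps")) {
  gap_mode <- match.arg(gap_mode)
  if (inherits(pair, "aligned_pair")) {
    a <- pair$a_gapped; b <- pair$b_gapped
  } else {
    a <- pair[[1]]; b <- pair[[2]]
  }
  if (nchar(a) != nchar(b)) abort("gapped sequences differ in length")
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  special <- ca %in% c("-", "N") | cb %in% c("-", "N")
  if (gap_mode == "exclude_gap_columns") {
    ca <- ca[!special]; cb <- cb[!special]
    if (length(ca) == 0) abort("percent identity undefined: zero compared columns")
    100 * mean(ca == cb)
  } else {
    if (length(ca) == 0) abort("percent identity undefined: zero columns")
    100 * mean(ca == cb & !special)
  }
}

#' Pairwise distance matrix from aligned sequences
#'
#' p-distance is the proportion of differing sites over compared columns,
#' with pairwise gap deletion (columns holding a gap, `N` or other ambiguity
#' in either sequence of the pair are dropped for that pair only). The
#' Jukes-Cantor correction `d = -(3/4) ln(1 - 4p/3)` converts p to expected
#' substitutions per site; it saturates at `p >= 3/4`, which raises a
#' per-pair error naming the offending labels.
#'
#' @param aligned_seqs Named character vector (or tibble with `id`,
#'   `sequence`) of equal-length gapped sequences; at least 3.
#' @param model `"p_distance"` or `"jukes_cantor"`.
#' @return Symmetric numeric matrix with zero diagonal and the sequence names
#'   as dimnames.
#' @export
distance_matrix <- function(aligned_seqs, model = c("p_distance", "jukes_cantor")) {
  model <- match.arg(model)
  if (is.data.frame(aligned_seqs))
    aligned_seqs <- setNames(aligned_seqs$sequence, aligned_seqs$id)
  n <- length(aligned_seqs)
  if (n < 3) abort("need at least 3 sequences")
  if (length(unique(nchar(aligned_seqs))) != 1)
    abort("aligned sequences must all have the same (gapped) length")
  labels <- names(aligned_seqs) %||% paste0("seq", seq_len(n))
  chars <- map(toupper(aligned_seqs), ~strsplit(.x, "")[[1]])
  good <- map(chars, ~.x %in% c("A", "C", "G", "T"))
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- good[[i]] & good[[j]]
      if (!any(ok)) abort(sprintf("no comparable columns between %s and %s",
                                  labels[i], labels[j]))
      p <- mean(chars[[i]][ok] != chars[[j]][ok])
      if (model == "jukes_cantor") {
        if (p >= 0.75)
          abort(sprintf("Jukes-Cantor saturation (p = %.3f >= 0.75) between %s and %s",
                        p, labels[i], labels[j]))
        p <- -0.75 * log(1 - 4 * p / 3)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on a symmetric distance matrix: at each step the
#' pair minimizing `Q(i,j) = (r-2) d(i,j) - R_i - R_j` is joined (ties broken
#' deterministically on the lowest label-index pair). Negative estimated
#' branch lengths are clamped to 0 with the deficit transferred to the sister
#' branch. Returns an unrooted binary tree.
#'
#' @param m Symmetric numeric matrix with zero diagonal (labels as dimnames),
#'   or a `dist`.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
neighbor_joining <- function(m) {
  if (inherits(m, "dist")) m <- as.matrix(m)
  if (!isSymmetric(unname(m), tol = 1e-8)) abort("distance matrix is not symmetric")
  if (any(diag(m) != 0)) abort("distance matrix diagonal must be zero")
  n <- nrow(m)
  if (n < 3) abort("need at least 3 taxa")
  labels <- rownames(m) %||% paste0("t", seq_len(n))

  fmt <- function(x) sprintf("%.17g", max(x, 0))
  # node representations as newick fragments; 'order' = creation index for ties
  node <- as.list(newick_quote(labels))
  ord <- seq_len(n)
  D <- m
  active <- seq_len(n)

  while (length(active) > 3) {
    r <- length(active)
    Dm <- D[active, active, drop = FALSE]
    R <- rowSums(Dm)
    Q <- (r - 2) * Dm - outer(R, R, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    # deterministic tie-break: lowest creation-order pair
    key <- cbind(pmin(ord[active][best[, 1]], ord[active][best[, 2]]),
                 pmax(ord[active][best[, 1]], ord[active][best[, 2]]))
    pick <- order(key[, 1], key[, 2])[1]
    i <- best[pick, 1]; j <- best[pick, 2]
    if (ord[active][i] > ord[active][j]) { tmp <- i; i <- j; j <- tmp }
    ai <- active[i]; aj <- active[j]

    dij <- D[ai, aj]
    bi <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- dij - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    bi <- max(bi, 0); bj <- max(bj, 0)

    new_node <- sprintf("(%s:%s,%s:%s)", node[[ai]], fmt(bi), node[[aj]], fmt(bj))
    others <- setdiff(active, c(ai, aj))
    dnew <- (D[ai, others] + D[aj, others] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    k <- nrow(D)
    D[k, others] <- dnew; D[others, k] <- dnew
    node[[k]] <- new_node
    ord[k] <- min(ord[ai], ord[aj])
    active <- c(others, k)
  }

  a <- active[order(ord[active])]
  dab <- D[a[1], a[2]]; dac <- D[a[1], a[3]]; dbc <- D[a[2], a[3]]
  ba <- (dab + dac - dbc) / 2
  bb <- (dab + dbc - dac) / 2
  bc <- (dac + dbc - dab) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 node[[a[1]]], fmt(ba), node[[a[2]]], fmt(bb), node[[a[3]]], fmt(bc))
  tr <- ape::read.tree(text = nwk)
  tr$tip.label <- newick_unquote(tr$tip.label)
  tr
}

newick_quote <- function(x) {
  meta <- grepl("[(),:;\\[\\]\\s']", x, perl = TRUE)
  x[meta] <- paste0("'", gsub("'", "''", x[meta]), "'")
  x
}

newick_unquote <- function(x) {
  q <- grepl("^'.*'$", x)
  x[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", x[q]))
  x
}

#' Read and write newick trees
#'
#' `write_newick()` serializes with branch lengths at full precision, quoting
#' labels that contain newick metacharacters; `read_newick()` reads a newick
#' file back, removing such quoting, so a written tree re-reads identically.
#'
#' @param tree A `phylo` object.
#' @param path File path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()` a
#'   `phylo`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  quote_lab <- newick_quote
  n_tip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  node_lab <- tree$node.label %||% rep("", tree$Nnode)
  ser <- function(node) {
    if (node <= n_tip) return(quote_lab(tree$tip.label[node]))
    e <- kids[[as.character(node)]]
    parts <- vapply(e, function(k) {
      sub <- ser(tree$edge[k, 2])
      if (!is.null(tree$edge.length))
        sub <- paste0(sub, ":", sprintf("%.17g", tree$edge.length[k]))
      sub
    }, "")
    lab <- node_lab[node - n_tip]
    paste0("(", paste(parts, collapse = ","), ")",
           if (!is.na(lab) && nzchar(lab)) quote_lab(as.character(lab)) else "")
  }
  writeLines(paste0(ser(n_tip + 1L), ";"), path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  tr$tip.label <- newick_unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- newick_unquote(tr$node.label)
  tr
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the NJ tree from an alignment, then resamples alignment columns
#' with replacement `n_replicates` times; internal-node labels carry the
#' proportion of replicates recovering each clade (0-100).
#'
#' @param aligned_seqs Named character vector (or `id`/`sequence` tibble) of
#'   equal-length aligned sequences.
#' @param model Distance model, see [distance_matrix()].
#' @param n_replicates Bootstrap replicate count (default 100).
#' @param seed RNG seed for the resampling.
#' @return A `phylo` with `node.label` holding bootstrap percentages.
#' @export
build_nj_tree <- function(aligned_seqs, model = "jukes_cantor",
                          n_replicates = 100, seed = 1) {
  if (is.data.frame(aligned_seqs))
    aligned_seqs <- setNames(aligned_seqs$sequence, aligned_seqs$id)
  main <- neighbor_joining(distance_matrix(aligned_seqs, model = model))
  if (n_replicates > 0) {
    chars <- do.call(rbind, strsplit(toupper(aligned_seqs), ""))
    L <- ncol(chars)
    boots <- withr::with_seed(seed, map(seq_len(n_replicates), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      rs <- setNames(apply(chars[, cols, drop = FALSE], 1, paste, collapse = ""),
                     names(aligned_seqs))
      tryCatch(neighbor_joining(distance_matrix(rs, model = model)),
               error = function(e) NULL)
    }))
    boots <- boots[!map_lgl(boots, is.null)]
    if (length(boots) > 0) {
      counts <- ape::prop.clades(main, boots, rooted = FALSE)
      counts[is.na(counts)] <- 0
      main$node.label <- round(100 * counts / length(boots))
    }
  }
  main
}
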