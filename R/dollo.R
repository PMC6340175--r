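#' Root a tree on an outgroup taxon
#'
#' Convenience wrapper giving the rooted direction that Dollo scoring needs
#' (the ancestral state at the root is "insertion absent", i.e. the
#' reference genome's state).
#'
#' @param tree a `phylo` object.
#' @param outgroup tip label to root on.
#' @return A rooted `phylo`.
#' @export
root_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup '", outgroup, "' is not a tip of the tree")
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Dollo parsimony score of a tree
#'
#' Scores a rooted tree against a binary presence-absence matrix under the
#' Dollo model: each character (insertion locus) is gained exactly once
#' (0 to 1) and may be lost any number of times; the root state is fixed to
#' absent. The single gain is placed on the stem of the most recent common
#' ancestor of the present taxa and losses are counted as the minimal
#' number of maximal all-absent subtrees inside the gain clade. Missing
#' states are free: they are resolved (via dynamic programming) to
#' whichever state minimizes the number of losses.
#'
#' @param tree rooted `phylo`; every matrix taxon must be a tip. Tips absent
#'   from the matrix are treated as all-missing.
#' @param x a [pa_matrix()].
#' @return Object of class `dollo_score`: list with `total_steps`,
#'   `per_character_steps`, and `min_steps` (one step per character with at
#'   least one present taxon, the Dollo minimum).
#' @export
dollo_score <- function(tree, x) {
  stopifnot(inherits(tree, "phylo"), inherits(x, "pa_matrix"))
  if (!ape::is.rooted(tree)) stop("Dollo scoring needs a rooted tree")
  miss <- setdiff(x$taxa, tree$tip.label)
  if (length(miss) > 0)
    stop("matrix taxa absent from tree: ", paste(miss, collapse = ", "))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  L <- ncol(x$states)
  big <- 1e9

  st <- matrix(NA_integer_, ntip, L)
  in_mat <- tree$tip.label %in% x$taxa
  st[in_mat, ] <- x$states[tree$tip.label[in_mat], , drop = FALSE]

  # c1[v,]: min losses below v given v carries the insertion (no gains below)
  # c0[v,]: 0 if the subtree of v can be all-absent, else "infinite"
  # s1[v,]: number of determinately-present leaves below v
  c1 <- matrix(0, ntip + nnode, L)
  c0 <- matrix(0, ntip + nnode, L)
  s1 <- matrix(0, ntip + nnode, L)
  is0 <- !is.na(st) & st == 0L
  is1 <- !is.na(st) & st == 1L
  c1[seq_len(ntip), ][is0] <- big
  c0[seq_len(ntip), ][is1] <- big
  s1[seq_len(ntip), ][is1] <- 1

  edge <- stats::na.omit(ape::reorder.phylo(tree, "postorder")$edge)
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; v <- edge[k, 2]
    c1[p, ] <- pmin(c1[p, ] + pmin(c1[v, ], 1 + c0[v, ]), big)
    c0[p, ] <- pmin(c0[p, ] + c0[v, ], big)
    s1[p, ] <- s1[p, ] + s1[v, ]
  }

  tot1 <- colSums(is1)
  # gain may sit on the stem of any node whose subtree contains all present
  # taxa; the minimum is attained at (or below cost of) their MRCA
  best <- rep(big, L)
  for (v in seq_len(ntip + nnode)) {
    m <- s1[v, ] == tot1
    best[m] <- pmin(best[m], c1[v, m])
  }
  steps <- as.integer(1 + best)
  steps[tot1 == 0] <- 0L
  structure(list(total_steps = sum(steps),
                 per_character_steps = steps,
                 min_steps = sum(tot1 > 0)),
            class = "dollo_score")
}

#' @export
print.dollo_score <- function(x, ...) {
  cat(sprintf("Dollo parsimony score: %d steps over %d characters (min %d)\n",
              x$total_steps, length(x$per_character_steps), x$min_steps))
  invisible(x)
}

#' Consistency index of a tree on a presence-absence matrix
#'
#' CI = (sum of per-character minimum steps) / (observed tree length under
#' Dollo parsimony). Every character with at least one present taxon has a
#' Dollo minimum of one step (its single gain), so CI = 1 means every
#' insertion pattern maps to a clade of the tree (no homoplasy, i.e. no
#' excess losses). Characters present in every taxon always take exactly
#' one step; `include_constant = FALSE` excludes them from both sums.
#'
#' @param tree rooted `phylo`.
#' @param x a [pa_matrix()].
#' @param include_constant count all-present characters (default `TRUE`).
#' @return CI in (0, 1].
#' @export
consistency_index <- function(tree, x, include_constant = TRUE) {
  stopifnot(inherits(x, "pa_matrix"))
  sc <- dollo_score(tree, x)
  keep <- rep(TRUE, ncol(x$states))
  if (!include_constant)
    keep <- colSums(x$states == 0L, na.rm = TRUE) > 0
  tot <- sum(sc$per_character_steps[keep])
  mn <- sum(sc$per_character_steps[keep] > 0)
  if (tot == 0) stop("no variable characters: tree length is zero")
  mn / tot
}
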