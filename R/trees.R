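# Tree reconstruction from presence-absence matrices: heuristic Dollo
# parsimony search, neighbor-joining, and bootstrap support.

ANC_LABEL <- ".ANC"

unit_lengths <- function(tree) {
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

# all trees obtained by attaching `tip` to each edge except the outgroup's
# terminal edge (the outgroup position defines the root and stays fixed)
attach_candidates <- function(tree, tip, outgroup) {
  og_node <- match(outgroup, tree$tip.label)
  keep <- tree$edge[, 2] != og_node
  lapply(which(keep), function(k) {
    unit_lengths(suppressWarnings(
      phytools::bind.tip(tree, tip, where = tree$edge[k, 2],
                         position = 0.5 * tree$edge.length[k])))
  })
}

# score a (possibly partial, during stepwise addition) tree on the
# submatrix of the taxa it carries
score_rooted <- function(tree, x) {
  tips <- intersect(x$taxa, tree$tip.label)
  dollo_score(tree, pa_matrix(x$states[tips, , drop = FALSE],
                              x$het[tips, , drop = FALSE]))$total_steps
}

reroot_og <- function(tree, outgroup) {
  unit_lengths(ape::root(ape::unroot(tree), outgroup = outgroup,
                         resolve.root = TRUE))
}

# neighborhood for hill climbing: NNI rearrangements, optionally plus
# tip-prune-and-regraft (an SPR subset), all re-rooted on the outgroup
swap_neighbors <- function(tree, outgroup, swap) {
  un <- ape::unroot(tree)
  nbs <- lapply(phangorn::nni(un), reroot_og, outgroup = outgroup)
  if (swap == "spr") {
    for (tip in setdiff(tree$tip.label, outgroup)) {
      base <- ape::drop.tip(tree, tip)
      if (is.null(base) || length(base$tip.label) < 3) next
      base <- reroot_og(base, outgroup)
      nbs <- c(nbs, attach_candidates(base, tip, outgroup))
    }
  }
  nbs
}

#' Heuristic Dollo parsimony tree search
#'
#' Random-addition starting trees followed by hill-climbing branch swapping
#' (NNI, optionally plus tip-regrafting SPR moves), scored under
#' [dollo_score()]. The Dollo direction requires a root: either a named
#' outgroup taxon, or (default) an implicit all-absent ancestor -- a
#' pseudo-taxon carrying no insertions, which represents the reference
#' genome and is removed from the returned tree.
#'
#' @param x a [pa_matrix()] with at least 4 taxa.
#' @param outgroup optional tip name to root on; `NULL` uses the implicit
#'   all-absent ancestor.
#' @param n_addition_reps number of random-addition replicates.
#' @param swap `"nni"` or `"spr"` (NNI plus tip regrafts).
#' @param seed optional integer; the search is deterministic given a seed.
#' @return List of class `dollo_search`: `tree` (rooted `phylo`),
#'   `score` (a `dollo_score` on the returned tree), `n_addition_reps`.
#' @export
dollo_search <- function(x, outgroup = NULL, n_addition_reps = 10,
                         swap = c("nni", "spr"), seed = NULL) {
  stopifnot(inherits(x, "pa_matrix"))
  if (nrow(x$states) < 4) stop("need at least 4 taxa for a tree search")
  swap <- match.arg(swap)
  implicit <- is.null(outgroup)
  if (implicit) {
    outgroup <- ANC_LABEL
    states <- rbind(x$states,
                    matrix(0L, 1, ncol(x$states),
                           dimnames = list(ANC_LABEL, x$loci_ids)))
    x <- pa_matrix(states)
  }
  if (!outgroup %in% x$taxa) stop("outgroup not among matrix taxa")
  ingroup <- setdiff(x$taxa, outgroup)
  if (length(ingroup) < 3) stop("need at least 4 taxa for a tree search")

  run <- function() {
    best_tree <- NULL
    best_score <- Inf
    for (rep in seq_len(n_addition_reps)) {
      ord <- sample(ingroup)
      tree <- unit_lengths(ape::read.tree(text = sprintf(
        "((%s,%s),%s);", ord[1], ord[2], outgroup)))
      for (tip in ord[-(1:2)]) {
        cand <- attach_candidates(tree, tip, outgroup)
        sc <- vapply(cand, score_rooted, numeric(1), x = x)
        tree <- cand[[which.min(sc)]]
      }
      cur <- score_rooted(tree, x)
      repeat {
        nbs <- swap_neighbors(tree, outgroup, swap)
        sc <- vapply(nbs, score_rooted, numeric(1), x = x)
        if (min(sc) < cur) {
          cur <- min(sc)
          tree <- nbs[[which.min(sc)]]
        } else break
      }
      if (cur < best_score) {
        best_score <- cur
        best_tree <- tree
      }
    }
    best_tree
  }
  tree <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (implicit) {
    tree <- ape::drop.tip(tree, ANC_LABEL)
    x <- pa_matrix(x$states[ingroup, , drop = FALSE],
                   x$het[ingroup, , drop = FALSE])
  }
  structure(list(tree = tree, score = dollo_score(tree, x),
                 n_addition_reps = n_addition_reps, swap = swap),
            class = "dollo_search")
}

#' @export
print.dollo_search <- function(x, ...) {
  cat(sprintf("Dollo heuristic search (%d addition reps, %s swaps)\n",
              x$n_addition_reps, toupper(x$swap)))
  print(x$score)
  invisible(x)
}

#' Mean-character-difference distance matrix
#'
#' Proportion of characters differing between each pair of taxa, over the
#' characters non-missing in both (pairwise deletion).
#'
#' @param x a [pa_matrix()].
#' @return A symmetric taxa x taxa distance matrix.
#' @export
mean_character_distance <- function(x) {
  stopifnot(inherits(x, "pa_matrix"))
  p1 <- (!is.na(x$states) & x$states == 1L) + 0
  p0 <- (!is.na(x$states) & x$states == 0L) + 0
  shared <- (p1 + p0) %*% t(p1 + p0)
  mism <- p1 %*% t(p0) + p0 %*% t(p1)
  off <- shared[upper.tri(shared)]
  if (any(off == 0))
    stop("a taxon pair shares no non-missing characters; distance undefined")
  d <- mism / shared
  dimnames(d) <- list(x$taxa, x$taxa)
  d
}

#' Neighbor-joining tree from a presence-absence matrix
#'
#' Classic Saitou-Nei NJ on mean character differences (the standard-data
#' default of common parsimony software). Negative branch lengths are
#' clamped to zero.
#'
#' @param x a [pa_matrix()] with at least 3 taxa.
#' @return An unrooted `phylo` with branch lengths in expected differences
#'   per character.
#' @export
nj_tree <- function(x) {
  stopifnot(inherits(x, "pa_matrix"))
  if (nrow(x$states) < 3) stop("need at least 3 taxa for neighbor-joining")
  phy <- ape::nj(mean_character_distance(x))
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' Bootstrap support for a presence-absence phylogeny
#'
#' Characters (loci) are resampled with replacement; a tree is built per
#' replicate with the chosen method, and the support of each internal
#' branch of the point-estimate tree is the fraction of replicate trees
#' containing the same bipartition.
#'
#' @param x a [pa_matrix()].
#' @param method `"nj"` or `"dollo"`.
#' @param n_reps number of bootstrap replicates.
#' @param seed optional integer seed (resampling and any search are
#'   deterministic given it).
#' @param outgroup passed to [dollo_search()] when `method = "dollo"`.
#' @param addition_reps random-addition replicates per bootstrap tree
#'   (Dollo only; small values suffice at few taxa).
#' @return The unrooted point-estimate `phylo` with per-internal-node
#'   support fractions in `node.label` (NA for the root).
#' @export
bootstrap_support <- function(x, method = c("nj", "dollo"), n_reps = 100,
                              seed = NULL, outgroup = NULL,
                              addition_reps = 3) {
  stopifnot(inherits(x, "pa_matrix"), n_reps >= 1)
  method <- match.arg(method)
  build <- function(mat, sd) {
    if (method == "nj") nj_tree(mat)
    else dollo_search(mat, outgroup = outgroup,
                      n_addition_reps = addition_reps, seed = sd)$tree
  }
  run <- function() {
    point <- build(x, 0L)
    boots <- lapply(seq_len(n_reps), function(i) {
      idx <- sample.int(ncol(x$states), replace = TRUE)
      build(pa_matrix(x$states[, idx, drop = FALSE],
                      x$het[, idx, drop = FALSE]), i)
    })
    un <- ape::unroot(point)
    cnt <- ape::prop.clades(un, lapply(boots, ape::unroot), rooted = FALSE)
    un$node.label <- cnt / n_reps
    un
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
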