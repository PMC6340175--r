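# Mapping insertion loci onto a dated species tree and estimating
# per-branch insertion rates and heterozygosity fractions.

#' A dated species tree
#'
#' Wraps a rooted, ultrametric `phylo` whose branch lengths are in years,
#' deriving node ages (years before present). The stem above the root (used
#' for insertions shared by all species) can be supplied via `stem_years`
#' or the tree's `root.edge`.
#'
#' @param phy rooted ultrametric `phylo`, branch lengths in years, or a
#'   path/string parseable by [ape::read.tree()].
#' @param stem_years optional duration of the root stem branch in years.
#' @return Object of class `dated_tree`: `phy`, `node_ages` (named by node
#'   number), `stem_years`.
#' @export
dated_tree <- function(phy, stem_years = NULL) {
  if (is.character(phy))
    phy <- if (file.exists(phy)) ape::read.tree(phy)
           else ape::read.tree(text = phy)
  stopifnot(inherits(phy, "phylo"))
  if (!ape::is.rooted(phy)) stop("dated tree must be rooted")
  if (is.null(phy$edge.length)) stop("dated tree needs branch lengths (years)")
  if (any(phy$edge.length <= 0)) stop("branch durations must be positive")
  ntip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  if (diff(range(depth[seq_len(ntip)])) > 1e-6 * max(depth))
    stop("tree is not ultrametric: tip ages differ")
  ages <- max(depth[seq_len(ntip)]) - depth
  ages[seq_len(ntip)] <- 0
  if (is.null(stem_years) && !is.null(phy$root.edge))
    stem_years <- phy$root.edge
  structure(list(phy = phy,
                 node_ages = stats::setNames(ages, seq_along(ages)),
                 stem_years = stem_years),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("Dated tree: %d tips, root age %.3g years\n",
              length(x$phy$tip.label),
              x$node_ages[length(x$phy$tip.label) + 1]))
  invisible(x)
}

node_clade_label <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) phy$tip.label[node]
  else if (node == ntip + 1L) paste(sort(phy$tip.label), collapse = "+")
  else paste(sort(ape::extract.clade(phy, node)$tip.label), collapse = "+")
}

#' Assign insertion loci to branches of a dated species tree
#'
#' Congruent loci (presence set equal to a clade) map to that clade's stem
#' branch. Species-tree incongruent loci are interpreted as incomplete
#' lineage sorting and map to the stem of the most recent common ancestor
#' of the affected species. Loci present in every species map to the root
#' stem. Missing species states are treated as absent for the purpose of
#' the presence set (the affected loci are flagged).
#'
#' @param x species-level [pa_matrix()]; taxa must equal the tree's tips.
#' @param tree a [dated_tree()].
#' @return data.frame of class `branch_assignment`: `locus`, `node` (the
#'   child node of the assigned stem branch; `"root"` for the root stem),
#'   `branch` (clade label), `congruent`, `n_missing` per locus.
#' @export
assign_branches <- function(x, tree) {
  stopifnot(inherits(x, "pa_matrix"), inherits(tree, "dated_tree"))
  phy <- tree$phy
  extra <- setdiff(x$taxa, phy$tip.label)
  if (length(extra) > 0)
    stop("matrix taxa not in tree: ", paste(extra, collapse = ", "))
  ntip <- length(phy$tip.label)
  root <- ntip + 1L
  clades <- lapply(seq_len(ntip + phy$Nnode), function(nd)
    if (nd <= ntip) phy$tip.label[nd]
    else ape::extract.clade(phy, nd)$tip.label)
  nodes <- integer(ncol(x$states))
  congr <- logical(ncol(x$states))
  nmiss <- colSums(is.na(x$states))
  for (j in seq_len(ncol(x$states))) {
    pres <- x$taxa[!is.na(x$states[, j]) & x$states[, j] == 1L]
    if (length(pres) == 0) stop("locus ", x$loci_ids[j], ": empty presence set")
    nd <- if (length(pres) == 1) match(pres, phy$tip.label)
          else ape::getMRCA(phy, pres)
    nodes[j] <- nd
    congr[j] <- setequal(clades[[nd]], pres)
  }
  out <- data.frame(locus = x$loci_ids,
                    node = ifelse(nodes == root, "root", nodes),
                    branch = vapply(nodes, function(nd)
                      if (nd == root) "root" else node_clade_label(phy, nd),
                      character(1)),
                    congruent = congr,
                    n_missing = as.integer(nmiss),
                    stringsAsFactors = FALSE)
  class(out) <- c("branch_assignment", "data.frame")
  out
}

#' Rate parameters
#'
#' @param generation_time_years mean generation time g in years
#'   (default 24.4, the mean over extant baleen whales).
#' @return Object of class `rate_params`.
#' @export
rate_params <- function(generation_time_years = 24.4) {
  stopifnot(generation_time_years > 0)
  structure(list(generation_time_years = generation_time_years),
            class = "rate_params")
}

#' Per-branch insertion counts, heterozygosity fractions and rates
#'
#' For each branch: `n_insertions` loci assigned to it, branch duration
#' `branch_years` (b), and the insertion rate per generation
#' mu = n / (b / g), i.e. insertions divided by the number of generations
#' the branch spans. The heterozygosity fraction is, per branch, the
#' fraction of its loci that are unfixed -- heterozygous in at least one
#' carrier individual (`het_mode = "locus"`, default) or the fraction of
#' heterozygous genotype calls among present calls (`het_mode = "call"`,
#' requires an individual-level matrix in `het`).
#'
#' @param assignment a [assign_branches()] result.
#' @param tree the [dated_tree()] used for the assignment.
#' @param params a [rate_params()].
#' @param het either a named per-locus logical vector (any carrier
#'   individual heterozygous; see `attr(collapsed, "het_any")`), or an
#'   individual-level [pa_matrix()] for `het_mode = "call"`, or `NULL` to
#'   skip heterozygosity.
#' @param het_mode `"locus"` or `"call"`.
#' @return data.frame of class `rate_table`: `branch`, `n_insertions`,
#'   `branch_years`, `rate_per_generation`, `het_fraction` (NA where no
#'   insertions), `congruent_fraction`.
#' @export
branch_rates <- function(assignment, tree, params = rate_params(),
                         het = NULL, het_mode = c("locus", "call")) {
  stopifnot(inherits(assignment, "branch_assignment"),
            inherits(tree, "dated_tree"), inherits(params, "rate_params"))
  het_mode <- match.arg(het_mode)
  phy <- tree$phy
  g <- params$generation_time_years
  child <- phy$edge[, 2]
  branch_ids <- c(as.character(child), "root")
  labels <- c(vapply(child, node_clade_label, character(1), phy = phy), "root")
  years <- c(phy$edge.length,
             if (is.null(tree$stem_years)) NA_real_ else tree$stem_years)
  if (any(years <= 0, na.rm = TRUE)) stop("branch durations must be positive")
  het_frac <- function(loci) {
    if (is.null(het) || length(loci) == 0) return(NA_real_)
    if (het_mode == "locus") {
      v <- het[loci]
      if (anyNA(v)) stop("het vector does not cover all assigned loci")
      mean(v)
    } else {
      stopifnot(inherits(het, "pa_matrix"))
      j <- match(loci, het$loci_ids)
      if (anyNA(j)) stop("het matrix does not cover all assigned loci")
      pres <- sum(het$states[, j, drop = FALSE] == 1L, na.rm = TRUE)
      if (pres == 0) NA_real_ else sum(het$het[, j, drop = FALSE]) / pres
    }
  }
  rows <- lapply(seq_along(branch_ids), function(k) {
    loci <- assignment$locus[assignment$node == branch_ids[k]]
    n <- length(loci)
    b <- years[k]
    data.frame(branch = labels[k],
               n_insertions = n,
               branch_years = b,
               rate_per_generation = if (is.na(b)) NA_real_ else n / (b / g),
               het_fraction = het_frac(loci),
               congruent_fraction = if (n == 0) NA_real_ else
                 mean(assignment$congruent[assignment$node == branch_ids[k]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (sum(out$n_insertions) != nrow(assignment))
    stop("internal error: assigned loci not conserved across branches")
  class(out) <- c("rate_table", "data.frame")
  out
}
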