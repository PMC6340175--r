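# Conflict quantification: species collapsing, exclusive synapomorphy
# intersections, conflicting-triple extraction, and count-based polytomy /
# asymmetry tests on retroposon insertion counts.

#' Read a sample-to-species map
#'
#' Two-column TSV (`sample<TAB>species`, no header required; a header line
#' `sample species` is tolerated).
#'
#' @param path TSV path.
#' @return Named character vector: `map[sample] == species`.
#' @export
read_species_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("sample", "species"))
  if (identical(tolower(df$sample[1]), "sample")) df <- df[-1, , drop = FALSE]
  stats::setNames(df$species, df$sample)
}

#' Collapse individuals to species
#'
#' Under `rule = "all"` a species is scored present at a locus only when
#' every individual of the species carries the insertion (the conservative
#' rule for multi-individual species), absent when every individual lacks
#' it; mixed presence within a species scores the species absent for that
#' locus, and the number of loci affected is reported as a diagnostic.
#' Under `rule = "any"` one carrier individual suffices. Missing genotypes
#' propagate: a species state that cannot be decided from the non-missing
#' individuals becomes missing. Loci left without any present species are
#' dropped (diagnostic `n_dropped_absent`).
#'
#' A species-level het flag is kept: `TRUE` where the species is present
#' and at least one of its individuals was heterozygous.
#'
#' @param x individual-level [pa_matrix()].
#' @param species_map named character vector (see [read_species_map()])
#'   covering every matrix taxon.
#' @param rule `"all"` or `"any"`.
#' @return Species-level [pa_matrix()] with attributes `diagnostics`
#'   (named counts) and `het_any` (per-locus logical: any carrier
#'   individual heterozygous).
#' @export
collapse_to_species <- function(x, species_map, rule = c("all", "any")) {
  stopifnot(inherits(x, "pa_matrix"))
  rule <- match.arg(rule)
  unmapped <- setdiff(x$taxa, names(species_map))
  if (length(unmapped) > 0)
    stop("taxa missing from species map: ", paste(unmapped, collapse = ", "))
  sp <- species_map[x$taxa]
  species <- unique(sp)
  L <- ncol(x$states)
  states <- matrix(NA_integer_, length(species), L,
                   dimnames = list(species, x$loci_ids))
  het <- matrix(FALSE, length(species), L, dimnames = dimnames(states))
  n_mixed <- 0L
  for (s in species) {
    rows <- x$states[sp == s, , drop = FALSE]
    hrows <- x$het[sp == s, , drop = FALSE]
    n1 <- colSums(rows == 1L, na.rm = TRUE)
    n0 <- colSums(rows == 0L, na.rm = TRUE)
    nna <- colSums(is.na(rows))
    if (rule == "all") {
      st <- rep(NA_integer_, L)
      st[n0 > 0] <- 0L                      # any absent individual: not "all"
      st[n1 > 0 & n0 == 0 & nna > 0] <- NA  # unverifiable unanimity
      st[n1 > 0 & n0 == 0 & nna == 0] <- 1L
      st[n1 == 0 & n0 > 0 & nna == 0] <- 0L
      n_mixed <- n_mixed + sum(n1 > 0 & n0 > 0)
    } else {
      st <- rep(NA_integer_, L)
      st[n1 > 0] <- 1L
      st[n1 == 0 & nna == 0 & n0 > 0] <- 0L
    }
    states[s, ] <- st
    het[s, ] <- st == 1L & !is.na(st) & colSums(hrows) > 0
  }
  present_any <- colSums(states == 1L, na.rm = TRUE) > 0
  het_any <- colSums(het) > 0
  out <- pa_matrix(states[, present_any, drop = FALSE],
                   het[, present_any, drop = FALSE])
  attr(out, "diagnostics") <- c(n_mixed_species_loci = n_mixed,
                                n_dropped_absent = sum(!present_any))
  attr(out, "het_any") <- stats::setNames(het_any[present_any],
                                          colnames(states)[present_any])
  out
}

#' Exclusive intersection counts of insertion presence sets
#'
#' UpSet-style "distinct" tally: each locus contributes one count to the
#' entry of its exact presence set (the set of taxa carrying the
#' insertion). Every such synapomorphic insertion is a phylogenetic signal
#' for the common ancestry of the taxa carrying it. Loci with a missing
#' species state are skipped and reported in the diagnostics.
#'
#' @param x a (typically species-collapsed) [pa_matrix()].
#' @return data.frame of class `intersection_table` with columns `subset`
#'   (comma-joined sorted taxon names), `n_taxa`, and `count`, sorted by
#'   decreasing count; attribute `n_skipped_missing` gives skipped loci.
#' @export
intersection_counts <- function(x) {
  stopifnot(inherits(x, "pa_matrix"))
  has_na <- colSums(is.na(x$states)) > 0
  st <- x$states[, !has_na, drop = FALSE]
  keys <- apply(st == 1L, 2, function(p)
    paste(sort(x$taxa[p]), collapse = ","))
  keys <- keys[keys != ""]
  tab <- sort(table(keys), decreasing = TRUE)
  out <- data.frame(subset = names(tab),
                    n_taxa = lengths(strsplit(names(tab), ",", fixed = TRUE)),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_skipped_missing") <- sum(has_na)
  class(out) <- c("intersection_table", "data.frame")
  out
}

canonical_subset <- function(taxa) paste(sort(unique(taxa)), collapse = ",")

#' Look up the count of one exclusive intersection
#'
#' @param table an [intersection_counts()] result.
#' @param taxa character vector of taxon names (order-insensitive).
#' @return Integer count (0 when the subset never occurs).
#' @export
intersection_count <- function(table, taxa) {
  i <- match(canonical_subset(taxa), table$subset)
  if (is.na(i)) 0L else table$count[i]
}

#' Export an UpSetR-compatible membership matrix
#'
#' @param table an [intersection_counts()] result.
#' @return data.frame with one 0/1 membership column per taxon plus a
#'   `count` column; suitable for `UpSetR::upset(..., count.col)` -style
#'   plotting or TSV export.
#' @export
as_upset_matrix <- function(table) {
  taxa <- sort(unique(unlist(strsplit(table$subset, ",", fixed = TRUE))))
  memb <- vapply(taxa, function(t)
    as.integer(vapply(strsplit(table$subset, ",", fixed = TRUE),
                      function(s) t %in% s, logical(1))),
    integer(nrow(table)))
  cbind(as.data.frame(memb), count = table$count)
}

# two rooted clades conflict iff they overlap and neither contains the other
sets_incompatible <- function(a, b) {
  length(intersect(a, b)) > 0 &&
    length(setdiff(a, b)) > 0 && length(setdiff(b, a)) > 0
}

#' Extract the three conflicting counts around a focal node
#'
#' The three subsets must be the three alternative sister-groupings around
#' one focal branching (pairwise incompatible clades). Counts are read
#' from the intersection table (0 when absent) and sorted decreasingly.
#'
#' @param table an [intersection_counts()] result.
#' @param hypothesis_sets list of three character vectors of taxon names.
#' @return Object of class `conflict_triple`: `counts` (n1 >= n2 >= n3)
#'   and `labels` (canonical subset strings, in count order).
#' @export
conflict_triple <- function(table, hypothesis_sets) {
  stopifnot(is.list(hypothesis_sets), length(hypothesis_sets) == 3)
  for (i in 1:2) for (j in (i + 1):3)
    if (!sets_incompatible(hypothesis_sets[[i]], hypothesis_sets[[j]]))
      stop("hypothesis subsets must be pairwise incompatible ",
           "(overlapping, neither nested nor disjoint)")
  labels <- vapply(hypothesis_sets, canonical_subset, character(1))
  counts <- vapply(hypothesis_sets, function(s)
    intersection_count(table, s), integer(1))
  ord <- order(counts, decreasing = TRUE)
  structure(list(counts = counts[ord], labels = labels[ord]),
            class = "conflict_triple")
}

#' @export
print.conflict_triple <- function(x, ...) {
  cat("Conflicting-signal triple:\n")
  for (i in 1:3)
    cat(sprintf("  %5d  {%s}\n", x$counts[i], x$labels[i]))
  invisible(x)
}

as_triple_counts <- function(triple) {
  if (inherits(triple, "conflict_triple")) triple$counts
  else sort(as.numeric(triple), decreasing = TRUE)
}

# exact P(max multinomial(n, 1/3) count >= c) by inclusion-exclusion
p_max_trinomial <- function(c, n) {
  if (c <= ceiling(n / 3)) return(1)
  a <- c:n
  t1 <- sum(stats::dbinom(a, n, 1 / 3))
  t2 <- sum(stats::dbinom(a, n, 1 / 3) *
              stats::pbinom(c - 1, n - a, 0.5, lower.tail = FALSE))
  # all three counts >= c is impossible here since c > n/3
  min(1, max(0, 3 * t1 - 3 * t2))
}

#' Count-based polytomy (bifurcation) test
#'
#' Null hypothesis: the focal branching is a hard polytomy, so each of the
#' three resolutions is equally likely (probability 1/3) for every
#' tree-relevant insertion. Two tail probabilities are returned:
#'
#' * `p_value` -- the one-sided exact binomial tail P(X >= n1) with
#'   X ~ Binomial(n, 1/3) and n1 the largest of the three counts. This is
#'   the convention used in published retroposon bifurcation tests and is
#'   reported for comparability; because it conditions on the largest
#'   count it is anti-conservative as a decision rule.
#' * `p_max` -- the exact tail P(max count >= n1) under the trinomial null
#'   (inclusion-exclusion), which is a calibrated p-value: rejecting when
#'   `p_max <= alpha` has type-I error at most alpha.
#'
#' A Monte-Carlo trinomial mode estimates both tails by simulation and
#' serves as an independent check of the closed forms.
#'
#' @param triple a [conflict_triple()] or numeric vector of three counts.
#' @param method `"exact"` or `"montecarlo"`.
#' @param n_reps Monte-Carlo replicates.
#' @param seed optional seed for the Monte-Carlo mode.
#' @return Object of class `retro_test` with `statistic` (n1), `p_value`,
#'   `p_max`, `method`, `n_total`.
#' @export
polytomy_test <- function(triple, method = c("exact", "montecarlo"),
                          n_reps = 1e6, seed = NULL) {
  method <- match.arg(method)
  cnt <- as_triple_counts(triple)
  n <- sum(cnt)
  if (n < 1) stop("all counts are zero")
  n1 <- cnt[1]
  if (method == "exact") {
    p <- stats::pbinom(n1 - 1, n, 1 / 3, lower.tail = FALSE)
    pm <- p_max_trinomial(n1, n)
  } else {
    draw <- function() {
      sims <- stats::rmultinom(n_reps, n, rep(1 / 3, 3))
      c(mean(sims[1, ] >= n1),
        mean(apply(sims, 2, max) >= n1))
    }
    est <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    p <- est[1]; pm <- est[2]
  }
  structure(list(statistic = n1, p_value = p, p_max = pm,
                 method = paste0("trinomial polytomy test (", method, ")"),
                 n_total = n),
            class = "retro_test")
}

#' Asymmetry (ILS vs introgression) test on the two minority counts
#'
#' Under pure incomplete lineage sorting the two species-tree-incongruent
#' resolutions are equally likely, so their counts n2 and n3 follow a
#' symmetric binomial. A significant two-sided departure indicates a
#' directional process such as introgression.
#'
#' @param n2,n3 the two minority counts.
#' @return Object of class `retro_test` (exact two-sided binomial test,
#'   success probability 0.5).
#' @export
asymmetry_test <- function(n2, n3) {
  if (n2 + n3 < 1) stop("both counts are zero")
  bt <- stats::binom.test(n2, n2 + n3, p = 0.5)
  structure(list(statistic = n2, p_value = bt$p.value, p_max = NULL,
                 method = "exact binomial asymmetry test (two-sided, p = 0.5)",
                 n_total = n2 + n3),
            class = "retro_test")
}

#' @export
print.retro_test <- function(x, ...) {
  cat(x$method, "\n", sep = "")
  cat(sprintf("  statistic = %d of n = %d, p = %.4g",
              x$statistic, x$n_total, x$p_value))
  if (!is.null(x$p_max))
    cat(sprintf(" (calibrated max-count tail p = %.4g)", x$p_max))
  cat("\n")
  invisible(x)
}
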