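# Independent brute-force oracles and small fixture builders shared by the
# test files. The oracles deliberately use exhaustive enumeration, not the
# package's algorithms.

# Exhaustive Dollo oracle: minimum steps over all assignments of internal
# nodes (and missing leaves) to {0,1}, with an implicit all-absent
# ancestor above the root (so a gain may sit on the root stem) and at
# most one 0->1 gain in total; steps = gains + losses.
dollo_oracle <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  a0 <- rep(NA_integer_, nn)
  a0[seq_len(ntip)] <- states[tree$tip.label]
  free <- which(is.na(a0))
  k <- length(free)
  grid <- as.matrix(expand.grid(rep(list(0:1), k)))
  best <- Inf
  for (r in seq_len(max(1, nrow(grid)))) {
    a <- a0
    if (k > 0) a[free] <- grid[r, ]
    pa <- a[tree$edge[, 1]]; ch <- a[tree$edge[, 2]]
    gains <- sum(pa == 0 & ch == 1) + (a[root] == 1)  # stem gain counts
    losses <- sum(pa == 1 & ch == 0)
    if (gains <= 1) best <- min(best, gains + losses)
  }
  best
}

# Brute-force maximum bipartite matching size under a distance window
# (recursion over truth points; each may take any unused call or none).
match_oracle_size <- function(truth_pos, call_pos, window) {
  nt <- length(truth_pos); nc <- length(call_pos)
  rec <- function(i, used) {
    if (i > nt) return(0L)
    best <- rec(i + 1L, used)
    for (j in seq_len(nc)) {
      if (!used[j] && abs(truth_pos[i] - call_pos[j]) <= window) {
        used[j] <- TRUE
        best <- max(best, 1L + rec(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  rec(1L, logical(nc))
}

# random rooted binary tree with unit branch lengths on the given tips
random_rooted_tree <- function(tips) {
  phy <- ape::rtree(length(tips), tip.label = sample(tips))
  phy$edge.length <- rep(1, nrow(phy$edge))
  phy
}

# random presence-absence matrix (taxa x nchar) with presence/absence and
# a sprinkling of missing states; every column keeps >= 1 present taxon
random_pa <- function(taxa, nchar, p_missing = 0.1) {
  n <- length(taxa)
  st <- matrix(sample(0:1, n * nchar, replace = TRUE), n,
               dimnames = list(taxa, paste0("L", seq_len(nchar))))
  st[sample(length(st), round(p_missing * length(st)))] <- NA_integer_
  for (j in seq_len(nchar))
    if (!any(st[, j] == 1L, na.rm = TRUE)) st[sample(n, 1), j] <- 1L
  pa_matrix(st)
}

# write a small VCF file from a genotype-string matrix; returns the path
write_test_vcf <- function(gt_strings, samples, chrom = "scaf1",
                           pos = NULL, filter = "PASS",
                           path = tempfile(fileext = ".vcf")) {
  gt_strings <- matrix(gt_strings, ncol = length(samples))
  n <- nrow(gt_strings)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (length(filter) == 1) filter <- rep(filter, n)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(n), function(i)
    paste(c(chrom, pos[i], ".", "N", "<INS:ME:CHR2>", ".", filter[i], ".",
            "GT", gt_strings[i, ]), collapse = "\t"), character(1))
  writeLines(c(header, body), path)
  path
}
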