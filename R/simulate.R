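# Synthetic insertion data under the multispecies coalescent: gene trees
# sampled within a species tree (producing ILS-incongruent patterns and
# unfixed heterozygous insertions), coverage-dependent detection noise,
# and reference spiking for caller benchmarks.

#' Species tree for coalescent simulation
#'
#' @param phy rooted ultrametric `phylo` (or newick string) with branch
#'   lengths in generations.
#' @param Ne diploid effective population size: a scalar, or a vector with
#'   one entry per edge of `phy` (aligned with `phy$edge` rows).
#' @param samples_per_species named integer vector of diploid individuals
#'   sampled per species (default 1 each).
#' @param root_Ne population size of the ancestral (above-root) population
#'   (default: `Ne` of the first edge).
#' @param ploidy 2 (diploid, default) or 1 (haploid sampling; useful for
#'   theory checks with one lineage per species).
#' @return Object of class `sim_species_tree`.
#' @export
sim_species_tree <- function(phy, Ne, samples_per_species = NULL,
                             root_Ne = NULL, ploidy = 2) {
  if (is.character(phy)) phy <- ape::read.tree(text = phy)
  stopifnot(inherits(phy, "phylo"), ape::is.rooted(phy))
  if (is.null(phy$edge.length)) stop("species tree needs branch lengths")
  if (any(phy$edge.length <= 0)) stop("branch durations must be positive")
  if (length(Ne) == 1) Ne <- rep(Ne, nrow(phy$edge))
  if (length(Ne) != nrow(phy$edge)) stop("Ne must be scalar or per-edge")
  if (any(Ne <= 0)) stop("Ne must be positive")
  if (is.null(root_Ne)) root_Ne <- Ne[1]
  if (is.null(samples_per_species))
    samples_per_species <- stats::setNames(rep(1L, length(phy$tip.label)),
                                           phy$tip.label)
  if (!setequal(names(samples_per_species), phy$tip.label))
    stop("samples_per_species must be named by the tree's tips")
  if (any(samples_per_species < 1)) stop("need >= 1 sample per species")
  stopifnot(ploidy %in% c(1, 2))
  structure(list(phy = phy, Ne = Ne, root_Ne = root_Ne,
                 samples_per_species = samples_per_species[phy$tip.label],
                 ploidy = ploidy),
            class = "sim_species_tree")
}

#' @export
print.sim_species_tree <- function(x, ...) {
  cat(sprintf("Coalescent species tree: %d species, %d diploid samples, Ne %s\n",
              length(x$phy$tip.label), sum(x$samples_per_species),
              paste(unique(x$Ne), collapse = "/")))
  invisible(x)
}

#' Individual sample names of a simulation tree
#' @param sptree a [sim_species_tree()].
#' @return character vector like `"speciesA_1"`.
#' @export
sim_sample_names <- function(sptree) {
  unlist(lapply(names(sptree$samples_per_species), function(s)
    paste(s, seq_len(sptree$samples_per_species[s]), sep = "_")),
    use.names = FALSE)
}

# Simulate one gene tree under the MSC; returns segments (descendant
# haplotype sets, durations, species-tree edge labels) and, if tag
# haplotypes are given, the first-coalescing tag pair.
sim_gene_tree <- function(sptree, clade_labels, tags = NULL) {
  phy <- sptree$phy
  ntip <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  ages <- max(depth[seq_len(ntip)]) - depth
  ages[seq_len(ntip)] <- 0
  hap_of <- hap_index(sptree)

  seg_set <- list(); seg_dur <- numeric(0); seg_edge <- character(0)
  seg_t0 <- numeric(0)
  first_pair <- NULL

  record <- function(set, t0, t1, lab) {
    if (t1 > t0) {
      seg_set[[length(seg_set) + 1]] <<- set
      seg_dur[length(seg_dur) + 1] <<- t1 - t0
      seg_t0[length(seg_t0) + 1] <<- t0
      seg_edge[length(seg_edge) + 1] <<- lab
    }
  }

  # coalesce `pool` (list of set=, t=) within [t0, t1] (t1 may be Inf)
  evolve <- function(pool, t0, t1, Ne, lab) {
    t <- t0
    repeat {
      k <- length(pool)
      if (k <= 1) break
      wait <- stats::rexp(1, rate = k * (k - 1) / 2 / (2 * Ne))
      if (t + wait > t1) break
      t <- t + wait
      ij <- sample.int(k, 2)
      a <- pool[[ij[1]]]; b <- pool[[ij[2]]]
      record(a$set, a$t, t, lab)
      record(b$set, b$t, t, lab)
      if (!is.null(tags) && is.null(first_pair)) {
        ta <- intersect(a$set, tags); tb <- intersect(b$set, tags)
        if (length(ta) >= 1 && length(tb) >= 1)
          first_pair <<- sort(c(match(ta[1], tags), match(tb[1], tags)))
      }
      pool <- c(pool[-ij], list(list(set = sort(c(a$set, b$set)), t = t)))
    }
    if (is.finite(t1)) {
      pool <- lapply(pool, function(l) {
        record(l$set, l$t, t1, lab)
        list(set = l$set, t = t1)
      })
    }
    pool
  }

  pools <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) {
    sp <- phy$tip.label[i]
    pools[[i]] <- lapply(unlist(hap_of[[sp]], use.names = FALSE),
                         function(h) list(set = h, t = 0))
  }
  edge <- ape::reorder.phylo(phy, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; v <- edge[k, 2]
    lab <- clade_labels[[v]]
    out <- evolve(pools[[v]], ages[v], ages[p], sptree$Ne[k], lab)
    pools[[p]] <- c(pools[[p]], out)
  }
  root <- ntip + 1L
  evolve(pools[[root]], ages[root], Inf, sptree$root_Ne, "root")
  list(seg_set = seg_set, seg_dur = seg_dur, seg_t0 = seg_t0,
       seg_edge = seg_edge, first_pair = first_pair)
}

hap_index <- function(sptree) {
  n <- sptree$samples_per_species
  counts <- n * sptree$ploidy
  ends <- cumsum(counts)
  starts <- ends - counts + 1
  out <- lapply(seq_along(n), function(i) {
    haps <- starts[i]:ends[i]
    split(haps, rep(seq_len(n[i]), each = sptree$ploidy))
  })
  stats::setNames(out, names(n))
}

#' Simulate an insertion presence-absence data set under the MSC
#'
#' For each locus a gene tree of all sampled haplotypes is drawn under the
#' standard multispecies coalescent (pairwise coalescence rate 1/(2 Ne)
#' per generation within each species-tree branch), and a single insertion
#' event is placed uniformly at random on the gene tree in proportion to
#' branch length. The insertion is carried by the descendant haplotypes,
#' giving diploid genotypes (including unfixed, heterozygous insertions)
#' and, when the gene tree is discordant with the species tree,
#' tree-incongruent presence patterns.
#'
#' Two sampling modes: `n_loci` draws exactly that many loci (one
#' insertion per gene tree); alternatively `rate` gives a per-generation
#' insertion probability per gene-tree lineage, with `n_gene_trees`
#' independent genealogies each receiving Poisson(rate x tree length)
#' insertions -- the mode used for insertion-rate recovery experiments.
#'
#' @param sptree a [sim_species_tree()].
#' @param n_loci number of loci (one per gene tree), or `NULL`.
#' @param rate per-generation, per-lineage insertion probability (used
#'   with `n_gene_trees`).
#' @param n_gene_trees number of genealogies for `rate` mode.
#' @param seed optional integer; simulation is deterministic given it.
#' @param edge_weights optional named numeric multipliers of insertion
#'   placement weight per species-tree branch label (clade labels as in
#'   [assign_branches()]; `"root"` for the ancestral branch) for
#'   branch-specific burst experiments.
#' @param triplet optional character vector of 3 species names; the
#'   gene-tree resolution of one tagged haplotype per species is recorded
#'   (`"12"`, `"13"`, `"23"` for which pair coalesces first).
#' @return Object of class `sim_truth`: `call_set` (true genotypes as an
#'   [mei_call_set()]), `matrix` (its [pa_matrix()]), and per-locus truth
#'   columns in `loci_info` (`origin_edge`, `insertion_time`, `congruent`,
#'   `triplet_resolution`).
#' @export
simulate_insertion_matrix <- function(sptree, n_loci = NULL, rate = NULL,
                                      n_gene_trees = NULL, seed = NULL,
                                      edge_weights = NULL, triplet = NULL) {
  stopifnot(inherits(sptree, "sim_species_tree"))
  if (is.null(n_loci) == is.null(rate))
    stop("give exactly one of n_loci or rate")
  if (!is.null(rate) && is.null(n_gene_trees))
    stop("rate mode needs n_gene_trees")
  phy <- sptree$phy
  ntip <- length(phy$tip.label)
  clade_labels <- lapply(seq_len(ntip + phy$Nnode), function(nd)
    node_clade_label(phy, nd))
  clades <- lapply(seq_len(ntip + phy$Nnode), function(nd)
    if (nd <= ntip) phy$tip.label[nd]
    else ape::extract.clade(phy, nd)$tip.label)
  hap_of <- hap_index(sptree)
  samples <- sim_sample_names(sptree)
  hap_sample <- rep(seq_along(samples), each = sptree$ploidy)
  sp_of_hap <- rep(names(sptree$samples_per_species),
                   sptree$samples_per_species * sptree$ploidy)
  tags <- if (is.null(triplet)) NULL else {
    if (length(triplet) != 3 || !all(triplet %in% phy$tip.label))
      stop("triplet must name three species of the tree")
    vapply(triplet, function(s) hap_of[[s]][[1]][1], numeric(1))
  }
  weight_of <- function(lab) {
    if (is.null(edge_weights)) 1
    else if (lab %in% names(edge_weights)) edge_weights[[lab]] else 1
  }

  run <- function() {
    geno <- list(); origin <- character(0); itime <- numeric(0)
    congr <- logical(0); trip <- character(0)
    place <- function(gt, idx) {
      set <- gt$seg_set[[idx]]
      t <- gt$seg_t0[idx] + stats::runif(1) * gt$seg_dur[idx]
      g <- tabulate(hap_sample[set], nbins = length(samples))
      sp_pres <- unique(sp_of_hap[set])
      is_clade <- any(vapply(clades, function(cl)
        setequal(cl, sp_pres), logical(1)))
      geno[[length(geno) + 1]] <<- g
      origin[length(origin) + 1] <<- gt$seg_edge[idx]
      itime[length(itime) + 1] <<- t
      congr[length(congr) + 1] <<- is_clade
      trip[length(trip) + 1] <<- if (is.null(gt$first_pair)) NA_character_
        else paste(gt$first_pair, collapse = "")
    }
    n_trees <- if (!is.null(n_loci)) n_loci else n_gene_trees
    if (n_trees < 1) stop("need at least one locus/gene tree")
    for (i in seq_len(n_trees)) {
      gt <- sim_gene_tree(sptree, clade_labels, tags)
      if (length(gt$seg_dur) == 0) next  # single-haplotype degenerate tree
      w <- gt$seg_dur * vapply(gt$seg_edge, weight_of, numeric(1))
      if (!is.null(n_loci)) {
        place(gt, sample.int(length(w), 1, prob = w))
      } else {
        n_ins <- stats::rpois(1, rate * sum(w))
        for (k in seq_len(n_ins))
          place(gt, sample.int(length(w), 1, prob = w))
      }
    }
    pos <- sort(sample.int(10 * length(geno) + 1000, length(geno)))
    list(geno = geno, origin = origin, itime = itime,
         congr = congr, trip = trip, pos = pos)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  n <- length(res$geno)
  if (n == 0) stop("no loci simulated")
  gmat <- do.call(rbind, res$geno)
  colnames(gmat) <- samples
  pos <- res$pos
  loci <- data.frame(chrom = "sim", pos = pos, te_family = "SINE_sim",
                     filter = "PASS", stringsAsFactors = FALSE)
  calls <- mei_call_set(loci, gmat)
  stopifnot(all(rowSums(gmat >= 1) >= 1))  # every locus has a carrier
  structure(list(call_set = calls,
                 matrix = build_matrix(calls),
                 loci_info = data.frame(
                   locus = locus_ids(calls),
                   origin_edge = res$origin,
                   insertion_time = res$itime,
                   congruent = res$congr,
                   triplet_resolution = res$trip,
                   stringsAsFactors = FALSE),
                 sptree = sptree),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulated insertion truth set: %d loci, %d samples\n",
              nrow(x$loci_info), length(x$call_set$samples)))
  cat(sprintf("  species-tree congruent: %.1f%%\n",
              100 * mean(x$loci_info$congruent)))
  invisible(x)
}

#' Logistic detection-sensitivity curve
#'
#' Returns TPR as a function of sequencing coverage, calibrated so that
#' `tpr(calibrate_cov) == calibrate_tpr` (default: 0.99 at 5X, the
#' empirical sensitivity plateau of short-read MEI callers).
#'
#' @param calibrate_cov,calibrate_tpr calibration point.
#' @param slope logistic slope per coverage unit.
#' @return function(coverage) -> detection probability.
#' @export
make_tpr_curve <- function(calibrate_cov = 5, calibrate_tpr = 0.99,
                           slope = 1.5) {
  mid <- calibrate_cov - stats::qlogis(calibrate_tpr) / slope
  function(coverage) stats::plogis(slope * (coverage - mid))
}

#' Apply coverage-dependent detection noise to a truth set
#'
#' Emulates an MEI caller: each present genotype (het or hom) is detected
#' with probability TPR(coverage of the sample); undetected genotypes are
#' reported absent (or missing); detected genotypes are miscalled to the
#' other present state with rates `het_to_hom` and `hom_to_het` (default
#' 0.08 each, i.e. 92% of called insertions correctly genotyped); a
#' background `missing_rate` and an absent-site false-positive rate
#' `fp_rate` are optional.
#'
#' @param truth a [simulate_insertion_matrix()] result, or an
#'   [mei_call_set()] of true genotypes.
#' @param coverage scalar or per-sample named vector of sequencing depth.
#' @param tpr_curve function(coverage) -> detection probability
#'   (default [make_tpr_curve()]).
#' @param het_to_hom probability a detected het is called homozygous.
#' @param hom_to_het probability a detected homozygote is called het.
#' @param undetected `"absent"` (0/0) or `"missing"` (./.).
#' @param missing_rate background per-call missing probability.
#' @param fp_rate probability an absent genotype is called heterozygous.
#' @param seed optional integer seed.
#' @return An [mei_call_set()] of noisy calls (same loci as the truth).
#' @export
apply_detection_noise <- function(truth, coverage = 5, tpr_curve = NULL,
                                  het_to_hom = 0.08, hom_to_het = 0.08,
                                  undetected = c("absent", "missing"),
                                  missing_rate = 0, fp_rate = 0,
                                  seed = NULL) {
  calls <- if (inherits(truth, "sim_truth")) truth$call_set else truth
  stopifnot(inherits(calls, "mei_call_set"))
  undetected <- match.arg(undetected)
  if (is.null(tpr_curve)) tpr_curve <- make_tpr_curve()
  samples <- calls$samples
  if (length(coverage) == 1)
    coverage <- stats::setNames(rep(coverage, length(samples)), samples)
  if (!all(samples %in% names(coverage)))
    stop("coverage must be named for every sample")
  run <- function() {
    g <- calls$genotypes
    miss_code <- if (undetected == "absent") 0L else NA_integer_
    for (s in samples) {
      tpr <- tpr_curve(coverage[[s]])
      col <- g[, s]
      pres <- !is.na(col) & col >= 1L
      det <- pres & stats::runif(length(col)) < tpr
      col[pres & !det] <- miss_code
      was_het <- det & col == 1L
      was_hom <- det & col == 2L
      col[was_het & stats::runif(length(col)) < het_to_hom] <- 2L
      col[was_hom & stats::runif(length(col)) < hom_to_het] <- 1L
      if (fp_rate > 0) {
        fp <- !is.na(col) & col == 0L & stats::runif(length(col)) < fp_rate
        col[fp] <- 1L
      }
      if (missing_rate > 0)
        col[stats::runif(length(col)) < missing_rate] <- NA_integer_
      g[, s] <- col
    }
    g
  }
  g <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  mei_call_set(calls$loci, g)
}

#' Spike element insertions into a reference coordinate system
#'
#' Samples insertion positions uniformly without collision (minimum
#' spacing) on a linear reference, returning the truth positions on the
#' original coordinates plus the induced coordinate-shift map for the
#' spiked sequence. Optionally emits the spiked FASTA when sequences are
#' provided.
#'
#' @param genome_length reference length in bp.
#' @param n_insertions number of elements to integrate.
#' @param element_length length of the inserted element (bp).
#' @param min_spacing minimum distance between insertion points (bp).
#' @param seed optional integer seed (same seed, same positions).
#' @param sequence optional reference sequence (single character string).
#' @param element_sequence element sequence (required with `sequence`).
#' @param fasta_path optional output path for the spiked FASTA.
#' @return Object of class `spike_truth`: `positions` (sorted, original
#'   coordinates), `spiked_positions` (same points on the spiked
#'   coordinates), `element_length`, `genome_length`.
#' @export
spike_reference <- function(genome_length, n_insertions,
                            element_length = 300, min_spacing = 500,
                            seed = NULL, sequence = NULL,
                            element_sequence = NULL, fasta_path = NULL) {
  stopifnot(genome_length >= 1, n_insertions >= 0)
  if (n_insertions * min_spacing > genome_length)
    stop("n_insertions too large for genome_length at this min_spacing")
  draw <- function() {
    if (n_insertions == 0) return(integer(0))
    span <- genome_length - (n_insertions - 1) * min_spacing
    base <- sort(sample.int(span, n_insertions))
    base + (seq_len(n_insertions) - 1) * min_spacing
  }
  pos <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  spiked <- pos + (seq_along(pos) - 1) * element_length
  out <- structure(list(positions = as.integer(pos),
                        spiked_positions = as.integer(spiked),
                        element_length = element_length,
                        genome_length = genome_length),
                   class = "spike_truth")
  if (!is.null(sequence)) {
    if (is.null(element_sequence))
      stop("element_sequence required to build a spiked sequence")
    pieces <- character(0)
    prev <- 1
    for (p in pos) {
      pieces <- c(pieces, substr(sequence, prev, p), element_sequence)
      prev <- p + 1
    }
    pieces <- c(pieces, substr(sequence, prev, nchar(sequence)))
    out$spiked_sequence <- paste(pieces, collapse = "")
    if (!is.null(fasta_path))
      writeLines(c(">spiked", out$spiked_sequence), fasta_path)
  }
  out
}

#' Write spiked truth positions as BED
#'
#' BED uses 0-based half-open coordinates; the 1-based insertion point p
#' becomes the interval `[p-1, p)`.
#'
#' @param truth a [spike_reference()] result.
#' @param path output path.
#' @param chrom contig name.
#' @return `path`, invisibly.
#' @export
write_spike_bed <- function(truth, path, chrom = "ref") {
  stopifnot(inherits(truth, "spike_truth"))
  df <- data.frame(chrom = chrom, start = truth$positions - 1L,
                   end = truth$positions)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
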