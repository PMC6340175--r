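quartet_tree <- function(t_internal, Ne, ploidy = 1) {
  nw <- sprintf("(((A:1000,B:1000):%d,C:%d):2000,D:%d);",
                t_internal, 1000 + t_internal, 3000 + t_internal)
  sim_species_tree(nw, Ne = Ne,
                   samples_per_species = c(A = 1, B = 1, C = 1, D = 1),
                   ploidy = ploidy)
}

test_that("simulation is deterministic given a seed", {
  st <- quartet_tree(500, 200, ploidy = 2)
  a <- simulate_insertion_matrix(st, n_loci = 50, seed = 99)
  b <- simulate_insertion_matrix(st, n_loci = 50, seed = 99)
  expect_identical(a$call_set$genotypes, b$call_set$genotypes)
  expect_identical(a$loci_info, b$loci_info)
})

test_that("every simulated locus has at least one carrier", {
  st <- quartet_tree(500, 500, ploidy = 2)
  truth <- simulate_insertion_matrix(st, n_loci = 200, seed = 31)
  expect_true(all(rowSums(truth$call_set$genotypes >= 1) >= 1))
  expect_equal(ncol(truth$matrix$states), 200)
})

test_that("the no-ILS limit yields only species-tree congruent loci", {
  st <- quartet_tree(2000, Ne = 0.5, ploidy = 2)
  truth <- simulate_insertion_matrix(st, n_loci = 300, seed = 32)
  expect_true(all(truth$loci_info$congruent))
})

test_that("a single diploid individual yields only het or hom present loci", {
  st <- sim_species_tree("(A:5000);", Ne = 100,
                         samples_per_species = c(A = 1))
  truth <- simulate_insertion_matrix(st, n_loci = 100, seed = 33)
  g <- truth$call_set$genotypes[, "A_1"]
  expect_true(all(g %in% c(1L, 2L)))
  expect_true(any(g == 1L))   # unfixed insertions exist below the coalescence
})

test_that("quartet gene-tree incongruence matches coalescent theory", {
  t_int <- 2000; Ne <- 2000          # T = t / (2 Ne) = 0.5
  st <- quartet_tree(t_int, Ne, ploidy = 1)
  truth <- simulate_insertion_matrix(st, n_loci = 3000, seed = 34,
                                     triplet = c("A", "B", "C"))
  frac <- mean(truth$loci_info$triplet_resolution != "12")
  theo <- (2 / 3) * exp(-t_int / (2 * Ne))
  se <- sqrt(theo * (1 - theo) / 3000)
  expect_lt(abs(frac - theo), 3 * se)
  # the two incongruent resolutions are symmetric
  inc <- truth$loci_info$triplet_resolution
  n13 <- sum(inc == "13"); n23 <- sum(inc == "23")
  expect_gt(asymmetry_test(n13, n23)$p_value, 0.001)
})

test_that("incongruence decreases with internal branch length and grows with Ne", {
  fr <- function(t_int, Ne, seed) {
    st <- quartet_tree(t_int, Ne, ploidy = 1)
    truth <- simulate_insertion_matrix(st, n_loci = 1200, seed = seed,
                                       triplet = c("A", "B", "C"))
    mean(truth$loci_info$triplet_resolution != "12")
  }
  expect_gt(fr(200, 2000, 35), fr(4000, 2000, 36))   # longer branch, less ILS
  expect_gt(fr(1000, 4000, 37), fr(1000, 400, 38))   # larger Ne, more ILS
})

test_that("detection noise obeys its limiting cases and calibration", {
  st <- quartet_tree(1000, 100, ploidy = 2)
  truth <- simulate_insertion_matrix(st, n_loci = 400, seed = 39)
  perfect <- apply_detection_noise(truth, tpr_curve = function(c) 1,
                                   het_to_hom = 0, hom_to_het = 0, seed = 1)
  expect_identical(perfect$genotypes, truth$call_set$genotypes)
  blind <- apply_detection_noise(truth, tpr_curve = function(c) 0,
                                 seed = 1)
  expect_true(all(blind$genotypes == 0L))
  blind_na <- apply_detection_noise(truth, tpr_curve = function(c) 0,
                                    undetected = "missing", seed = 1)
  expect_true(all(is.na(blind_na$genotypes[truth$call_set$genotypes >= 1])))
  # default logistic curve detects 99% at 5X
  curve <- make_tpr_curve()
  expect_equal(curve(5), 0.99)
  noisy <- apply_detection_noise(truth, coverage = 5,
                                 het_to_hom = 0, hom_to_het = 0, seed = 2)
  pres <- truth$call_set$genotypes >= 1
  det <- mean(noisy$genotypes[pres] >= 1)
  n <- sum(pres)
  expect_lt(abs(det - 0.99), 3 * sqrt(0.99 * 0.01 / n))
})

test_that("reference spiking is deterministic, spaced, sorted, and bounded", {
  sp <- spike_reference(5e6, 200, seed = 7)
  expect_length(sp$positions, 200)
  expect_false(is.unsorted(sp$positions, strictly = TRUE))
  expect_true(all(diff(sp$positions) >= 500))
  sp2 <- spike_reference(5e6, 200, seed = 7)
  expect_identical(sp$positions, sp2$positions)
  expect_identical(spike_reference(1e4, 0, seed = 1)$positions, integer(0))
  expect_error(spike_reference(1e4, 100, min_spacing = 500), "too large")
  # coordinate shift: i-th point moves down by (i-1) element lengths
  expect_equal(sp$spiked_positions - sp$positions,
               (seq_len(200) - 1) * sp$element_length)
})

test_that("spiked sequences contain the element at each position", {
  ref <- paste(rep("A", 1000), collapse = "")
  sp <- spike_reference(1000, 3, element_length = 4, min_spacing = 100,
                        seed = 8, sequence = ref, element_sequence = "CGCG")
  expect_equal(nchar(sp$spiked_sequence), 1000 + 3 * 4)
  for (p in sp$spiked_positions)
    expect_equal(substr(sp$spiked_sequence, p + 1, p + 4), "CGCG")
})

test_that("branch-specific placement weights shift insertion origins", {
  st <- quartet_tree(2000, 50, ploidy = 2)
  base <- simulate_insertion_matrix(st, n_loci = 400, seed = 40)
  burst <- simulate_insertion_matrix(st, n_loci = 400, seed = 40,
                                     edge_weights = c("A+B" = 25))
  expect_gt(sum(burst$loci_info$origin_edge == "A+B"),
            sum(base$loci_info$origin_edge == "A+B"))
})
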