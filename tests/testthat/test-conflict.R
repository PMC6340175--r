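make_pa <- function(st, taxa) {
  dimnames(st) <- list(taxa, paste0("L", seq_len(ncol(st))))
  pa_matrix(st)
}

test_that("species collapsing follows the all/any rules", {
  taxa <- c("gray_A", "gray_B", "sei_1")
  map <- c(gray_A = "gray", gray_B = "gray", sei_1 = "sei")
  st <- rbind(c(1L, 1L, 0L, 1L),
              c(1L, 0L, 0L, 1L),
              c(0L, 1L, 1L, 0L))
  x <- make_pa(st, taxa)
  all_m <- collapse_to_species(x, map, rule = "all")
  any_m <- collapse_to_species(x, map, rule = "any")
  # locus 1: unanimous gray -> present under both rules
  expect_equal(all_m$states["gray", "L1"], 1L)
  expect_equal(any_m$states["gray", "L1"], 1L)
  # locus 2: mixed gray -> absent under all, present under any
  expect_equal(all_m$states["gray", "L2"], 0L)
  expect_equal(any_m$states["gray", "L2"], 1L)
  # single-individual species behaves as identity
  expect_equal(unname(all_m$states["sei", ]), unname(x$states["sei_1", ]))
  expect_equal(unname(any_m$states["sei", ]), unname(x$states["sei_1", ]))
  expect_equal(attr(all_m, "diagnostics")[["n_mixed_species_loci"]], 1)
})

test_that("mixed loci stay when another species is unanimously present", {
  taxa <- c("g1", "g2", "s1")
  map <- c(g1 = "G", g2 = "G", s1 = "S")
  st <- rbind(c(1L), c(0L), c(1L))
  x <- make_pa(st, taxa)
  m <- collapse_to_species(x, map, rule = "all")
  expect_equal(unname(m$states[, 1]), c(0L, 1L)[match(c("G", "S"), rownames(m$states))])
})

test_that("missing genotypes make species states undecidable", {
  taxa <- c("g1", "g2", "s1")
  map <- c(g1 = "G", g2 = "G", s1 = "S")
  x <- make_pa(rbind(c(1L, 1L), c(NA, 1L), c(1L, 0L)), taxa)
  m <- collapse_to_species(x, map, rule = "all")
  expect_true(is.na(m$states["G", "L1"]))   # unanimity unverifiable
  expect_equal(m$states["G", "L2"], 1L)
  # a locus whose only possible carrier is undecidable is dropped
  x2 <- make_pa(rbind(c(1L), c(NA), c(0L)), taxa)
  m2 <- collapse_to_species(x2, map, rule = "all")
  expect_equal(ncol(m2$states), 0L)
  expect_equal(attr(m2, "diagnostics")[["n_dropped_absent"]], 1L)
})

test_that("species het flag records any heterozygous carrier individual", {
  taxa <- c("g1", "g2")
  map <- c(g1 = "G", g2 = "G")
  st <- rbind(c(1L, 1L), c(1L, 1L))
  het <- rbind(c(TRUE, FALSE), c(FALSE, FALSE))
  dimnames(st) <- dimnames(het) <- list(taxa, c("L1", "L2"))
  m <- collapse_to_species(pa_matrix(st, het), map, rule = "all")
  expect_equal(unname(attr(m, "het_any")), c(TRUE, FALSE))
})

test_that("intersection counts form an exclusive partition of counted loci", {
  taxa <- c("A", "B", "C")
  st <- cbind(c(1L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L),
              c(1L, NA, 0L), c(1L, 1L, 1L))
  tab <- intersection_counts(make_pa(st, taxa))
  expect_equal(intersection_count(tab, "A"), 2L)
  expect_equal(intersection_count(tab, c("B", "A")), 1L)
  expect_equal(intersection_count(tab, c("A", "B", "C")), 1L)
  expect_equal(intersection_count(tab, "C"), 0L)
  expect_equal(sum(tab$count), 4L)              # locus with NA skipped
  expect_equal(attr(tab, "n_skipped_missing"), 1L)
  # fuzz: counts always partition the fully-observed loci
  set.seed(20)
  for (rep in 1:5) {
    x <- random_pa(letters[1:4], 30, p_missing = 0.1)
    tab <- intersection_counts(x)
    full <- sum(colSums(is.na(x$states)) == 0)
    expect_equal(sum(tab$count), full)
  }
})

test_that("upset export encodes memberships consistently", {
  taxa <- c("A", "B")
  tab <- intersection_counts(make_pa(cbind(c(1L, 1L), c(1L, 0L)), taxa))
  um <- as_upset_matrix(tab)
  expect_equal(sort(colnames(um)), sort(c("A", "B", "count")))
  expect_equal(sum(um$count), 2)
})

test_that("conflict triples read counts, default to zero, and sort canonically", {
  taxa <- c("A", "B", "C", "D")
  st <- cbind(c(1L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L))
  tab <- intersection_counts(make_pa(st, taxa))
  sets <- list(c("A", "B"), c("A", "C"), c("B", "C"))
  tri <- conflict_triple(tab, sets)
  expect_equal(tri$counts, c(2L, 1L, 0L))
  expect_equal(tri$labels, c("A,B", "A,C", "B,C"))
  # permuting the hypothesis order leaves the canonical result unchanged
  tri2 <- conflict_triple(tab, sets[c(3, 1, 2)])
  expect_equal(tri2$counts, tri$counts)
  expect_equal(tri2$labels, tri$labels)
  expect_error(conflict_triple(tab, list(c("A", "B"), c("A", "B", "C"),
                                         c("B", "C"))), "incompatible")
  expect_error(conflict_triple(tab, list(c("A", "B"), c("C", "D"),
                                         c("B", "C"))), "incompatible")
})

test_that("polytomy test matches closed forms and extreme cases", {
  pt <- polytomy_test(c(300, 0, 0))
  expect_lt(pt$p_value, 1e-10)
  pt2 <- polytomy_test(c(334, 333, 333))
  expect_equal(pt2$p_value,
               pbinom(333, 1000, 1 / 3, lower.tail = FALSE))
  expect_gt(pt2$p_value, 0.4); expect_lt(pt2$p_value, 0.6)
  expect_error(polytomy_test(c(0, 0, 0)), "zero")
})

test_that("Monte-Carlo and exact polytomy tails agree within 3 MC SE", {
  ex <- polytomy_test(c(120, 100, 80))
  mc <- polytomy_test(c(120, 100, 80), method = "montecarlo",
                      n_reps = 2e5, seed = 5)
  se <- sqrt(ex$p_value * (1 - ex$p_value) / 2e5)
  expect_lt(abs(mc$p_value - ex$p_value), 3 * se)
  se_max <- sqrt(ex$p_max * (1 - ex$p_max) / 2e5)
  expect_lt(abs(mc$p_max - ex$p_max), 3 * se_max)
})

test_that("the polytomy p decreases monotonically in the lead count", {
  n <- 900
  p <- vapply(seq(310, 400, by = 10), function(n1) {
    rest <- n - n1
    polytomy_test(c(n1, ceiling(rest / 2), floor(rest / 2)))$p_value
  }, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("the calibrated decision rule controls type-I error under the null", {
  set.seed(30)
  n <- 500
  sims <- stats::rmultinom(4000, n, rep(1 / 3, 3))
  maxima <- apply(sims, 2, max)
  pm <- vapply(sort(unique(maxima)), retrophylo:::p_max_trinomial,
               numeric(1), n = n)
  names(pm) <- sort(unique(maxima))
  rej <- mean(pm[as.character(maxima)] <= 0.05)
  expect_lte(rej, 0.06)
})

test_that("asymmetry test matches its closed forms", {
  expect_equal(asymmetry_test(100, 100)$p_value, 1)
  expect_equal(asymmetry_test(50, 0)$p_value, 2 * 0.5^50)
  a <- asymmetry_test(465, 444)
  expect_gt(a$p_value, 0.4); expect_lt(a$p_value, 0.6)
  expect_error(asymmetry_test(0, 0), "zero")
})
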