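test_that("VCF records map to the four genotype states", {
  path <- write_test_vcf(rbind(c("0/1", "1/1"),
                               c("0/0", "./."),
                               c("1|1", "0/1")),
                         samples = c("s1", "s2"))
  calls <- read_mei_vcf(path)
  expect_equal(nrow(calls$loci), 3)
  expect_equal(calls$samples, c("s1", "s2"))
  expect_equal(unname(calls$genotypes),
               matrix(c(1L, 2L, 0L, NA, 2L, 1L), 3, byrow = TRUE))
  expect_equal(calls$loci$te_family, rep("CHR2", 3))
})

test_that("half-calls are conservatively missing; multi-allelic is present", {
  expect_equal(retrophylo:::gt_to_code(c("./1", "1/.", ".", "1/2", "2/2", "0|1")),
               c(NA, NA, NA, 2L, 2L, 1L))
})

test_that("a header-only VCF yields an empty call set", {
  path <- write_test_vcf(matrix(character(0), ncol = 2), c("s1", "s2"))
  calls <- read_mei_vcf(path)
  expect_s3_class(calls, "mei_call_set")
  expect_equal(nrow(calls$loci), 0)
  expect_equal(calls$samples, c("s1", "s2"))
})

test_that("filtering keeps requested FILTER values, preserves order, and is idempotent", {
  path <- write_test_vcf(matrix("0/1", 10, 1), "s1",
                         filter = rep(c("PASS", "lc_region", "PASS", "ac0",
                                        "PASS"), 2))
  calls <- read_mei_vcf(path)
  kept <- filter_calls(calls)
  expect_equal(nrow(kept$loci), 6)
  expect_equal(kept$loci$pos, sort(kept$loci$pos))
  expect_identical(filter_calls(kept), kept)
  all_filters <- unique(calls$loci$filter)
  expect_identical(filter_calls(calls, all_filters), calls)
  expect_equal(nrow(filter_calls(calls, "nosuch")$loci), 0)
})

test_that("matrix construction maps genotypes, flags hets, drops empty columns", {
  path <- write_test_vcf(rbind(c("0/1", "1/1", "0/0"),
                               c("0/0", "0/0", "0/0"),
                               c("./.", "1/1", "0/1")),
                         samples = c("a", "b", "c"), pos = c(5L, 9L, 13L))
  m <- build_matrix(read_mei_vcf(path))
  expect_equal(dim(m$states), c(3, 2))          # all-absent locus dropped
  expect_equal(m$loci_ids, c("scaf1:5", "scaf1:13"))
  expect_equal(unname(m$states[, 1]), c(1L, 1L, 0L))
  expect_equal(unname(m$het[, 1]), c(TRUE, FALSE, FALSE))
  expect_equal(unname(m$states[, 2]), c(NA, 1L, 1L))
  expect_error(mei_call_set(
    data.frame(chrom = "c", pos = 1L, te_family = "x", filter = "PASS"),
    matrix(1L, 1, 0, dimnames = list(NULL, character(0)))),
    "sample")
})

test_that("per-sample counts follow the call/het semantics", {
  path <- write_test_vcf(rbind(c("0/1", "./."),
                               c("1/1", "./.")),
                         samples = c("s1", "allmiss"))
  counts <- per_sample_counts(read_mei_vcf(path), total = TRUE)
  expect_equal(counts$n_calls, c(2L, 0L, 2L))
  expect_equal(counts$n_het, c(1L, 0L, 1L))
  expect_true(all(counts$n_het <= counts$n_calls))
})

test_that("call totals equal present-cell totals of the matrix", {
  set.seed(41)
  for (rep in 1:5) {
    g <- matrix(sample(c(0:2, NA), 40, replace = TRUE), 10,
                dimnames = list(NULL, c("w", "x", "y", "z")))
    g[1, ] <- 2L  # keep at least one locus present
    cs <- mei_call_set(data.frame(chrom = "c", pos = 1:10 * 10L,
                                  te_family = "CHR2", filter = "PASS"), g)
    m <- build_matrix(cs)
    expect_equal(sum(per_sample_counts(cs)$n_calls),
                 sum(m$states == 1L, na.rm = TRUE))
  }
})

test_that("matrix survives a VCF round trip (fuzzed)", {
  set.seed(42)
  for (rep in 1:5) {
    taxa <- c("s1", "s2", "s3")
    g <- matrix(sample(c(0:2, NA), 30, replace = TRUE,
                       prob = c(.4, .25, .25, .1)), 10,
                dimnames = list(NULL, taxa))
    g[cbind(1:10, sample(3, 10, TRUE))] <- 2L
    cs <- mei_call_set(data.frame(chrom = "c", pos = sort(sample(1e5, 10)),
                                  te_family = "CHR2", filter = "PASS"), g)
    path <- tempfile(fileext = ".vcf")
    write_mei_vcf(cs, path)
    m2 <- build_matrix(read_mei_vcf(path))
    expect_identical(m2$states, build_matrix(cs)$states)
    expect_identical(m2$het, build_matrix(cs)$het)
  }
})

test_that("NEXUS round trip preserves states, taxa order and missing cells", {
  set.seed(43)
  m <- random_pa(c("Blue", "Fin", "Gray"), 12)
  path <- tempfile(fileext = ".nex")
  write_nexus(m, path)
  lines <- readLines(path)
  expect_true(any(grepl("NTAX=3 NCHAR=12", lines)))
  expect_true(any(grepl("SYMBOLS=\"01\"", lines)))
  m2 <- read_nexus(path, loci_ids = m$loci_ids)
  expect_identical(m2$states, m$states)
  expect_identical(rownames(m2$states), rownames(m$states))
})

test_that("het flags survive the sidecar round trip", {
  st <- matrix(c(1L, 1L, 0L, 1L), 2, dimnames = list(c("a", "b"),
                                                     c("l1", "l2")))
  het <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, dimnames = dimnames(st))
  m <- pa_matrix(st, het)
  nex <- tempfile(); sidecar <- tempfile()
  write_nexus(m, nex)
  write_het_sidecar(m, sidecar)
  m2 <- read_het_sidecar(read_nexus(nex, loci_ids = m$loci_ids), sidecar)
  expect_identical(m2$het, m$het)
})

test_that("pa_matrix enforces its invariants", {
  st <- matrix(c(0L, 1L), 1, dimnames = list("a", c("l1", "l2")))
  bad_het <- matrix(c(TRUE, FALSE), 1, dimnames = dimnames(st))
  expect_error(pa_matrix(st, bad_het), "het")
  expect_error(pa_matrix(matrix(2L, 1, 1, dimnames = list("a", "l1"))),
               "0, 1 or NA")
})
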