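#' Genotype codes used throughout the package
#'
#' Diploid MEI genotypes are stored as integer codes: `0` = insertion absent
#' (0/0), `1` = heterozygous (0/1), `2` = homozygous present (1/1),
#' `NA` = missing (./.). Half-calls such as `./1` are conservatively mapped
#' to missing.
#'
#' @name genotype-codes
#' @keywords internal
NULL

#' Construct an MEI call set
#'
#' An `mei_call_set` holds the loci (coordinates, element family, FILTER
#' status) and a loci x samples genotype-code matrix as parsed from a
#' mobile-element-insertion VCF.
#'
#' @param loci data.frame with columns `chrom`, `pos`, `te_family`, `filter`.
#' @param genotypes integer matrix (loci x samples) of genotype codes
#'   (see [genotype-codes]); column names are the sample names.
#' @return An object of class `mei_call_set`.
#' @export
mei_call_set <- function(loci, genotypes) {
  stopifnot(is.data.frame(loci),
            all(c("chrom", "pos", "te_family", "filter") %in% names(loci)))
  genotypes <- as.matrix(genotypes)
  if (nrow(loci) != nrow(genotypes))
    stop("genotype table must have one row per locus")
  if (is.null(colnames(genotypes)) || anyDuplicated(colnames(genotypes)))
    stop("sample names must be present and unique")
  if (nrow(loci) > 0) {
    if (any(loci$pos < 1)) stop("VCF positions are 1-based; pos must be >= 1")
    key <- paste(loci$chrom, loci$pos)
    if (anyDuplicated(key)) stop("duplicated (chrom, pos) in call set")
  }
  structure(list(loci = loci, samples = colnames(genotypes),
                 genotypes = genotypes),
            class = "mei_call_set")
}

#' @export
print.mei_call_set <- function(x, ...) {
  cat(sprintf("MEI call set: %d loci x %d samples\n",
              nrow(x$loci), length(x$samples)))
  if (nrow(x$loci) > 0) {
    tab <- table(x$loci$filter)
    cat("  FILTER: ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Locus identifiers ("chrom:pos") of a call set
#' @param calls an `mei_call_set`.
#' @return character vector.
#' @export
locus_ids <- function(calls) {
  paste(calls$loci$chrom, calls$loci$pos, sep = ":")
}

# Map a vector of VCF GT strings to genotype codes. Phased separators are
# treated as unphased; any non-zero allele index counts as presence; any
# "." allele makes the call missing.
gt_to_code <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & !grepl(".", gt, fixed = TRUE)
  if (any(ok)) {
    alt <- vapply(strsplit(gt[ok], "/", fixed = TRUE),
                  function(a) sum(a != "0"), integer(1))
    out[ok] <- pmin(alt, 2L)
  }
  out
}

#' Read a mobile-element-insertion VCF into a call set
#'
#' Parses a VCF 4.x file (plain or bgzipped) produced by an MEI genotyper
#' such as MELT-Split. One call-set row is created per VCF record; GT
#' strings are mapped to the four genotype states (absent, heterozygous,
#' homozygous present, missing). The element family is taken from a
#' `<INS:ME:FAMILY>` ALT allele when present, otherwise from the raw ALT.
#'
#' @param path path to the VCF file.
#' @return An [mei_call_set()].
#' @export
read_mei_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  fix <- vcf@fix
  if (nrow(fix) == 0) {
    samples <- colnames(vcf@gt)
    samples <- samples[samples != "FORMAT"]
    if (length(samples) == 0) stop("VCF has no sample columns")
    gt <- matrix(integer(0), nrow = 0, ncol = length(samples),
                 dimnames = list(NULL, samples))
    loci <- data.frame(chrom = character(0), pos = integer(0),
                       te_family = character(0), filter = character(0),
                       stringsAsFactors = FALSE)
    return(mei_call_set(loci, gt))
  }
  if (ncol(vcf@gt) < 2) stop("VCF has no sample columns")
  if (!all(grepl("(^|:)GT(:|$)", vcf@gt[, "FORMAT"])))
    stop("GT field absent from FORMAT in at least one record")
  gts <- vcfR::extract.gt(vcf, element = "GT")
  codes <- apply(gts, 2, gt_to_code)
  if (is.null(dim(codes)))
    codes <- matrix(codes, nrow = nrow(fix),
                    dimnames = list(NULL, colnames(gts)))
  alt <- fix[, "ALT"]
  fam <- ifelse(grepl("^<INS:ME:(.+)>$", alt),
                sub("^<INS:ME:(.+)>$", "\\1", alt), alt)
  loci <- data.frame(chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     te_family = fam,
                     filter = ifelse(is.na(fix[, "FILTER"]), ".",
                                     fix[, "FILTER"]),
                     stringsAsFactors = FALSE)
  mei_call_set(loci, codes)
}

#' Filter a call set by FILTER status
#'
#' Retains only loci whose VCF FILTER field is one of `keep_filters`
#' (default `"PASS"`), preserving locus order. Idempotent.
#'
#' @param calls an [mei_call_set()].
#' @param keep_filters character vector of FILTER values to keep.
#' @return A filtered `mei_call_set` (possibly with zero loci).
#' @export
filter_calls <- function(calls, keep_filters = "PASS") {
  stopifnot(inherits(calls, "mei_call_set"))
  keep <- calls$loci$filter %in% keep_filters
  mei_call_set(calls$loci[keep, , drop = FALSE],
               calls$genotypes[keep, , drop = FALSE])
}

#' Construct a presence-absence matrix object
#'
#' @param states integer matrix (taxa x loci) with values 0, 1 and `NA`
#'   (missing); dimnames give taxa and locus identifiers.
#' @param het logical matrix of the same shape, `TRUE` where the underlying
#'   genotype was heterozygous (implies `states == 1`).
#' @return An object of class `pa_matrix`.
#' @export
pa_matrix <- function(states, het = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (is.null(het))
    het <- matrix(FALSE, nrow(states), ncol(states), dimnames = dimnames(states))
  het <- as.matrix(het)
  stopifnot(identical(dim(states), dim(het)))
  if (is.null(rownames(states)) || anyDuplicated(rownames(states)))
    stop("taxa names must be present and unique")
  if (any(het & !(states == 1L), na.rm = TRUE) || any(het & is.na(states)))
    stop("het flags are only valid where state == 1")
  if (!all(states %in% c(0L, 1L, NA)))
    stop("states must be 0, 1 or NA")
  structure(list(states = states, het = het,
                 taxa = rownames(states), loci_ids = colnames(states)),
            class = "pa_matrix")
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat(sprintf("Presence-absence matrix: %d taxa x %d loci\n",
              nrow(x$states), ncol(x$states)))
  cat(sprintf("  present cells: %d, het-flagged: %d, missing: %d\n",
              sum(x$states == 1L, na.rm = TRUE), sum(x$het),
              sum(is.na(x$states))))
  invisible(x)
}

#' @export
dim.pa_matrix <- function(x) dim(x$states)

#' Build a presence-absence matrix from a call set
#'
#' A taxon carries state 1 at a locus iff its genotype contains at least one
#' alternate allele, 0 iff homozygous reference, `?` (NA) iff missing.
#' Heterozygous calls are flagged in a parallel logical matrix. Loci with no
#' present taxon at all are dropped (they carry no insertion signal against
#' the reference); all-present loci are kept, as they are synapomorphies of
#' the whole ingroup relative to the reference genome.
#'
#' @param calls a (typically filtered) [mei_call_set()].
#' @return A [pa_matrix()] with `loci_ids` of the form `"chrom:pos"`.
#' @export
build_matrix <- function(calls) {
  stopifnot(inherits(calls, "mei_call_set"))
  if (length(calls$samples) == 0) stop("call set has zero samples")
  code <- t(calls$genotypes)           # taxa x loci
  colnames(code) <- locus_ids(calls)
  states <- ifelse(is.na(code), NA_integer_, as.integer(code >= 1L))
  het <- !is.na(code) & code == 1L
  keep <- colSums(states == 1L, na.rm = TRUE) > 0
  pa_matrix(states[, keep, drop = FALSE], het[, keep, drop = FALSE])
}

#' Per-sample call and heterozygosity counts
#'
#' For each sample, counts loci carrying at least one alternate allele
#' (`n_calls`) and heterozygous loci (`n_het`). These are the per-sample
#' summary semantics of an MEI genotyping run: summing `n_calls` over
#' samples gives the total number of genotyped insertion calls, which
#' exceeds the number of unique loci whenever insertions are shared.
#'
#' @param calls an [mei_call_set()].
#' @param total append a `"Total"` row of column sums.
#' @return data.frame with columns `sample`, `n_calls`, `n_het`.
#' @export
per_sample_counts <- function(calls, total = FALSE) {
  stopifnot(inherits(calls, "mei_call_set"))
  g <- calls$genotypes
  out <- data.frame(sample = calls$samples,
                    n_calls = as.integer(colSums(g >= 1L, na.rm = TRUE)),
                    n_het = as.integer(colSums(g == 1L, na.rm = TRUE)),
                    stringsAsFactors = FALSE)
  if (total)
    out <- rbind(out, data.frame(sample = "Total",
                                 n_calls = sum(out$n_calls),
                                 n_het = sum(out$n_het)))
  out
}

#' Write a call set as a minimal VCF 4.2 file
#'
#' Serializes an [mei_call_set()] (e.g. simulated data) so it can be fed to
#' any VCF-consuming tool, including [read_mei_vcf()].
#'
#' @param calls an `mei_call_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mei_vcf <- function(calls, path) {
  stopifnot(inherits(calls, "mei_call_set"))
  gt_str <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##source=retrophylo",
              "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
              "##ALT=<ID=INS:ME,Description=\"Mobile element insertion\">",
              "##FILTER=<ID=PASS,Description=\"All filters passed\">",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", calls$samples), collapse = "\t"))
  n <- nrow(calls$loci)
  body <- character(0)
  if (n > 0) {
    gtxt <- matrix(gt_str[as.character(calls$genotypes)],
                   nrow = n, ncol = length(calls$samples))
    gtxt[is.na(gtxt)] <- "./."
    body <- paste(calls$loci$chrom, calls$loci$pos, ".", "N",
                  paste0("<INS:ME:", calls$loci$te_family, ">"), ".",
                  calls$loci$filter, "SVTYPE=INS", "GT",
                  apply(gtxt, 1, paste, collapse = "\t"), sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}
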