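#' Write a presence-absence matrix as a NEXUS DATA block
#'
#' Standard-datatype NEXUS with `SYMBOLS="01"` and `MISSING=?`, the dialect
#' accepted by PAUP*, MrBayes and SplitsTree for binary insertion data.
#' Heterozygosity flags cannot be encoded in binary symbols; use
#' [write_het_sidecar()] to preserve them.
#'
#' @param x a [pa_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nexus <- function(x, path) {
  stopifnot(inherits(x, "pa_matrix"))
  if (ncol(x$states) == 0) stop("matrix has no loci")
  chr <- x$states
  txt <- matrix("?", nrow(chr), ncol(chr))
  txt[!is.na(chr)] <- as.character(chr[!is.na(chr)])
  rows <- apply(txt, 1, paste, collapse = "")
  # NEXUS tokens must not contain whitespace
  taxa <- gsub("[[:space:]]+", "_", x$taxa)
  lines <- c("#NEXUS",
             "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(chr), ncol(chr)),
             "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=? INTERLEAVE=NO;",
             "  MATRIX",
             sprintf("    %-*s %s", max(nchar(taxa)), taxa, rows),
             "  ;",
             "END;")
  writeLines(lines, path)
  invisible(path)
}

#' Read a NEXUS presence-absence matrix
#'
#' Parses a standard-datatype NEXUS DATA block (as written by
#' [write_nexus()] or compatible tools). Heterozygosity flags are not part
#' of NEXUS; supply them via [read_het_sidecar()] if needed.
#'
#' @param path NEXUS file path.
#' @param loci_ids optional character vector of locus identifiers
#'   (defaults to `"chr1" ... "chrN"`).
#' @return A [pa_matrix()] (all het flags `FALSE`).
#' @export
read_nexus <- function(path, loci_ids = NULL) {
  dat <- tryCatch(ape::read.nexus.data(path),
                  error = function(e) stop("malformed NEXUS '", path,
                                           "' (DATA/MATRIX block): ",
                                           conditionMessage(e), call. = FALSE))
  states <- do.call(rbind, lapply(dat, function(v) {
    out <- suppressWarnings(as.integer(v))
    out[v %in% c("?", "-")] <- NA_integer_
    if (any(is.na(out) & !(v %in% c("?", "-"))))
      stop("non-binary symbol in NEXUS matrix")
    out
  }))
  rownames(states) <- names(dat)
  colnames(states) <- if (is.null(loci_ids))
    paste0("chr", seq_len(ncol(states))) else loci_ids
  pa_matrix(states)
}

#' Write / read the heterozygosity sidecar
#'
#' TSV with columns `locus`, `taxon`, `het`; one row per het-flagged cell.
#' This preserves the genotype-level heterozygosity that the binary NEXUS
#' encoding discards and that branch-dynamics analyses need.
#'
#' @param x a [pa_matrix()].
#' @param path sidecar path.
#' @return `path` invisibly for the writer; for the reader, `x` with het
#'   flags restored.
#' @export
write_het_sidecar <- function(x, path) {
  stopifnot(inherits(x, "pa_matrix"))
  idx <- which(x$het, arr.ind = TRUE)
  df <- data.frame(locus = x$loci_ids[idx[, 2]],
                   taxon = x$taxa[idx[, 1]],
                   het = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_het_sidecar
#' @export
read_het_sidecar <- function(x, path) {
  stopifnot(inherits(x, "pa_matrix"))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  het <- matrix(FALSE, nrow(x$states), ncol(x$states),
                dimnames = dimnames(x$states))
  if (nrow(df) > 0) {
    i <- match(df$taxon, x$taxa)
    j <- match(df$locus, x$loci_ids)
    if (anyNA(i) || anyNA(j))
      stop("sidecar refers to taxa/loci absent from the matrix")
    het[cbind(i, j)] <- df$het
  }
  pa_matrix(x$states, het)
}
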