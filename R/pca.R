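#' Principal component analysis of insertion genotypes
#'
#' Decomposes the individuals x loci dosage matrix (0/1/2 alternate-allele
#' counts; `mode = "binary"` uses presence 0/1 instead). Missing genotypes
#' are mean-imputed per locus; loci invariant after imputation are dropped.
#' Columns are centered per locus; `scale = TRUE` additionally divides by
#' the per-locus standard deviation. The sign of each component is fixed so
#' that its largest-magnitude loading is positive.
#'
#' @param obj an [mei_call_set()] (dosage or binary mode) or a
#'   [pa_matrix()] (binary only).
#' @param n_components number of components to return.
#' @param scale variance-scale loci (default `FALSE`).
#' @param mode `"dosage"` or `"binary"`.
#' @return Object of class `mei_pca`: `coordinates` (taxa x components),
#'   `explained_fraction` (non-increasing, sums to <= 1), `loadings`.
#' @export
mei_pca <- function(obj, n_components = 10, scale = FALSE,
                    mode = c("dosage", "binary")) {
  mode <- match.arg(mode)
  if (inherits(obj, "mei_call_set")) {
    d <- t(obj$genotypes)                       # taxa x loci
    if (mode == "binary") d <- ifelse(is.na(d), NA, as.numeric(d >= 1))
  } else if (inherits(obj, "pa_matrix")) {
    d <- obj$states
  } else stop("obj must be an mei_call_set or pa_matrix")
  d <- matrix(as.numeric(d), nrow(d), dimnames = dimnames(d))
  if (nrow(d) < 2 || ncol(d) < 2) stop("need >= 2 taxa and >= 2 loci")
  mu <- colMeans(d, na.rm = TRUE)
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- mu[j]
  keep <- apply(d, 2, stats::var) > 0
  if (!any(keep)) stop("matrix is constant: no variable loci after imputation")
  d <- d[, keep, drop = FALSE]
  pc <- stats::prcomp(d, center = TRUE, scale. = scale)
  total_var <- sum(pc$sdev^2)
  k <- min(n_components, sum(pc$sdev > 1e-12))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    if (load[which.max(abs(load[, i])), i] < 0) {
      load[, i] <- -load[, i]
      coords[, i] <- -coords[, i]
    }
  }
  structure(list(coordinates = coords,
                 explained_fraction = pc$sdev[seq_len(k)]^2 / total_var,
                 loadings = load),
            class = "mei_pca")
}

#' @export
print.mei_pca <- function(x, ...) {
  cat(sprintf("MEI genotype PCA: %d taxa, %d components\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("  explained: ",
      paste(sprintf("%.1f%%", 100 * x$explained_fraction), collapse = " "),
      "\n", sep = "")
  invisible(x)
}
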