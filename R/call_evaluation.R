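# Benchmarking called insertion positions/genotypes against a truth set:
# windowed one-to-one matching and sensitivity/precision metrics.

#' Match called positions to truth positions within a window
#'
#' Greedy nearest-neighbour one-to-one matching: candidate pairs with
#' |call - truth| <= `window_bp` are accepted in order of increasing
#' distance (ties broken by lower truth then call coordinate), each truth
#' and call position used at most once. Greedy matching attains the
#' optimal number of matches whenever truth positions are separated by
#' more than twice the window, which the spiking generator's minimum
#' spacing guarantees.
#'
#' @param truth_pos,call_pos integer vectors on the same coordinate system.
#' @param window_bp maximum accepted breakpoint offset (default 50 bp).
#' @return data.frame of class `call_matching` with columns `truth_idx`,
#'   `call_idx`, `distance`; attributes `n_truth`, `n_calls`.
#' @export
match_calls <- function(truth_pos, call_pos, window_bp = 50) {
  if (window_bp < 0) stop("window_bp must be non-negative")
  nt <- length(truth_pos); nc <- length(call_pos)
  pairs <- NULL
  if (nt > 0 && nc > 0) {
    d <- abs(outer(truth_pos, call_pos, "-"))
    ok <- which(d <= window_bp, arr.ind = TRUE)
    if (nrow(ok) > 0) {
      ord <- order(d[ok], truth_pos[ok[, 1]], call_pos[ok[, 2]])
      ok <- ok[ord, , drop = FALSE]
      used_t <- logical(nt); used_c <- logical(nc)
      keep <- logical(nrow(ok))
      for (k in seq_len(nrow(ok))) {
        i <- ok[k, 1]; j <- ok[k, 2]
        if (!used_t[i] && !used_c[j]) {
          used_t[i] <- used_c[j] <- TRUE
          keep[k] <- TRUE
        }
      }
      ok <- ok[keep, , drop = FALSE]
      pairs <- data.frame(truth_idx = ok[, 1], call_idx = ok[, 2],
                          distance = d[ok])
    }
  }
  if (is.null(pairs))
    pairs <- data.frame(truth_idx = integer(0), call_idx = integer(0),
                        distance = numeric(0))
  attr(pairs, "n_truth") <- nt
  attr(pairs, "n_calls") <- nc
  class(pairs) <- c("call_matching", "data.frame")
  pairs
}

#' Detection and genotyping metrics from a matching
#'
#' * `detr` -- detection rate (sensitivity): matched truth / all truth.
#' * `fnr` -- 1 - detr.
#' * `tpr` -- fraction of calls matching a truth site. Note this follows
#'   the benchmarking convention of MEI-caller assessments, where TPR is
#'   computed *from the detected calls*, i.e. it is a precision; the
#'   unambiguous aliases `sensitivity` and `precision` are also returned.
#' * `fpr` -- 1 - tpr (fraction of calls not matching any truth site).
#' * `genotype_concordance` -- fraction of matched pairs with identical
#'   genotype codes (only defined when genotypes are supplied).
#'
#' @param matching a [match_calls()] result.
#' @param truth_gt,called_gt optional genotype-code vectors parallel to the
#'   truth and call position vectors.
#' @return Object of class `eval_metrics` (a one-row data.frame).
#' @export
compute_metrics <- function(matching, truth_gt = NULL, called_gt = NULL) {
  stopifnot(inherits(matching, "call_matching"))
  nt <- attr(matching, "n_truth"); nc <- attr(matching, "n_calls")
  if (nt == 0) stop("empty truth set: detection rate undefined")
  nm <- nrow(matching)
  conc <- NA_real_
  if (!is.null(truth_gt) && !is.null(called_gt) && nm > 0)
    conc <- mean(truth_gt[matching$truth_idx] ==
                   called_gt[matching$call_idx])
  out <- data.frame(n_truth = nt, n_calls = nc, n_matched = nm,
                    detr = nm / nt,
                    fnr = 1 - nm / nt,
                    tpr = if (nc == 0) NA_real_ else nm / nc,
                    fpr = if (nc == 0) NA_real_ else 1 - nm / nc,
                    genotype_concordance = conc)
  out$sensitivity <- out$detr
  out$precision <- out$tpr
  class(out) <- c("eval_metrics", "data.frame")
  out
}

#' Aggregate evaluation metrics across replicates
#'
#' @param metrics_list list of [compute_metrics()] rows.
#' @return data.frame with one row per replicate plus `mean` and `sd`
#'   aggregate rows.
#' @export
aggregate_metrics <- function(metrics_list) {
  stopifnot(length(metrics_list) >= 1)
  df <- do.call(rbind, lapply(metrics_list, as.data.frame))
  df$replicate <- as.character(seq_len(nrow(df)))
  num <- vapply(df, is.numeric, logical(1))
  mean_row <- df[1, ]
  mean_row[num] <- as.list(colMeans(df[, num, drop = FALSE], na.rm = TRUE))
  mean_row$replicate <- "mean"
  sd_row <- df[1, ]
  sd_row[num] <- as.list(apply(df[, num, drop = FALSE], 2, stats::sd,
                               na.rm = TRUE))
  sd_row$replicate <- "sd"
  rbind(df, mean_row, sd_row)
}
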