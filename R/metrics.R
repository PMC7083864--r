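#' Match predicted to ground-truth centroids
#'
#' Greedy one-to-one nearest-neighbor matching: candidate (prediction, truth)
#' pairs within `radius` are visited in order of increasing distance (ties by
#' prediction index, then truth index) and accepted when both endpoints are
#' still unmatched. Matched predictions are true positives; leftover
#' predictions are false positives, leftover truths false negatives.
#'
#' @param predicted,truth matrices (or data frames) with columns `row`, `col`
#'   (or two unnamed columns), one centroid per row.
#' @param radius maximal matching distance in pixels (> 0). Default 25 px at
#'   20x / 1024x1024 scale.
#' @return list with `counts` (list `TP`, `FP`, `FN`) and `pairs` (data frame
#'   `pred`, `truth`, `dist` of accepted matches).
#' @export
match_detections <- function(predicted, truth, radius = 25) {
  if (radius <= 0) stop("radius must be positive")
  as_pts <- function(x) {
    if (is.null(x) || length(x) == 0)
      return(matrix(numeric(0), 0, 2))
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x[, 1:2, drop = FALSE]
  }
  p <- as_pts(predicted); t <- as_pts(truth)
  np <- nrow(p); nt <- nrow(t)
  pairs <- data.frame(pred = integer(0), truth = integer(0),
                      dist = numeric(0))
  if (np > 0 && nt > 0) {
    d <- sqrt(outer(p[, 1], t[, 1], `-`)^2 + outer(p[, 2], t[, 2], `-`)^2)
    cand <- which(d <= radius, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(d[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      pused <- logical(np); tused <- logical(nt)
      for (i in seq_len(nrow(cand))) {
        pi <- cand[i, 1]; ti <- cand[i, 2]
        if (pused[pi] || tused[ti]) next
        pused[pi] <- TRUE; tused[ti] <- TRUE
        pairs <- rbind(pairs, data.frame(pred = pi, truth = ti,
                                         dist = d[pi, ti]))
      }
    }
  }
  tp <- nrow(pairs)
  list(counts = confusion_counts(tp, np - tp, nt - tp), pairs = pairs)
}

confusion_counts <- function(TP, FP, FN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  structure(list(TP = as.integer(TP), FP = as.integer(FP),
                 FN = as.integer(FN)), class = "confusion_counts")
}

#' Sensitivity, precision and Dice's coefficient from confusion counts
#'
#' `S = TP / (TP + FN)`, `P = TP / (TP + FP)`,
#' `DC = 2 TP / (2 TP + FP + FN)` (the harmonic mean of S and P). A ratio with
#' zero denominator is reported as `NaN` with the corresponding
#' `undefined` flag set, never silently 0.
#'
#' @param counts list with fields `TP`, `FP`, `FN` (e.g. from
#'   [match_detections()]), all zero is a degenerate input and an error.
#' @param level `"cell"` or `"pixel"` (annotation only).
#' @return an object of class `metrics_report`: list with `counts`, `S`, `P`,
#'   `DC`, `level`, `undefined` (named logical vector).
#' @export
compute_metrics <- function(counts, level = c("cell", "pixel")) {
  level <- match.arg(level)
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN
  stopifnot(TP >= 0, FP >= 0, FN >= 0)
  if (TP + FP + FN == 0)
    stop("degenerate input: all confusion counts are zero")
  ratio <- function(num, den) if (den > 0) num / den else NaN
  S <- ratio(TP, TP + FN)
  P <- ratio(TP, TP + FP)
  DC <- ratio(2 * TP, 2 * TP + FP + FN)
  structure(list(counts = confusion_counts(TP, FP, FN),
                 S = S, P = P, DC = DC, level = level,
                 undefined = c(S = is.nan(S), P = is.nan(P),
                               DC = is.nan(DC))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%s-level metrics: TP=%d FP=%d FN=%d | S=%.3f P=%.3f DC=%.3f\n",
              x$level, x$counts$TP, x$counts$FP, x$counts$FN,
              x$S, x$P, x$DC))
  invisible(x)
}

#' Pixel-level metrics between two binary masks
#'
#' @param predicted_mask,truth_mask binary (logical or 0/1) matrices of equal
#'   shape.
#' @return a [compute_metrics()] report with `level = "pixel"`.
#' @export
pixel_metrics <- function(predicted_mask, truth_mask) {
  if (!identical(dim(predicted_mask), dim(truth_mask)))
    stop("mask shapes differ")
  p <- predicted_mask != 0; t <- truth_mask != 0
  compute_metrics(confusion_counts(sum(p & t), sum(p & !t), sum(!p & t)),
                  level = "pixel")
}

#' Weighted average of metric reports
#'
#' Component-wise weighted arithmetic mean of S, P and DC across reports
#' (e.g. a 1/3 weight on the development image set and a 2/3 weight on an
#' independent set, rewarding generalization).
#'
#' @param reports list of [compute_metrics()] reports.
#' @param weights numeric weights summing to 1 (tolerance 1e-9).
#' @return list with weighted `S`, `P`, `DC`.
#' @export
weighted_average_metrics <- function(reports, weights) {
  if (length(reports) != length(weights))
    stop("reports and weights lengths differ")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  agg <- function(f) sum(vapply(reports, `[[`, numeric(1), f) * weights)
  list(S = agg("S"), P = agg("P"), DC = agg("DC"))
}
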