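# Accuracy evaluation of scanner-derived against field measurements.

#' Evaluate extraction accuracy against field measurements
#'
#' Compares field values y to extracted values y-hat with the six standard
#' agreement metrics: R2 about the 1:1 line (1 - SSE/SST, not a refitted
#' regression), RMSE with divisor n, relative RMSE as a percentage of the
#' field mean, MAE, bias = mean(y - yhat) (positive means the extraction
#' underestimates), and bias as a percentage of the field mean.
#'
#' @param y field measurements (DBH in cm or height in m).
#' @param yhat extracted values, same length and units.
#' @param variable optional tag ("dbh" or "height") carried into the output.
#' @return one-row data.frame: `variable`, `n`, `R2`, `RMSE`, `rRMSE`,
#'   `MAE`, `bias`, `biasPct`.
#' @examples
#' evaluateAccuracy(c(10, 20, 30), c(12, 18, 33))
#' @export
evaluateAccuracy <- function(y, yhat, variable = NA_character_) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (any(is.na(y)) || any(is.na(yhat))) stop("missing values in pairs")
  n <- length(y)
  if (n < 2) stop("need at least 2 pairs")
  ybar <- mean(y)
  if (ybar == 0) stop("zero field mean: relative metrics undefined")
  sse <- sum((y - yhat)^2)
  sst <- sum((y - ybar)^2)
  rmse <- sqrt(sse / n)
  bias <- mean(y - yhat)
  data.frame(variable = variable, n = n,
             R2 = 1 - sse / sst,
             RMSE = rmse,
             rRMSE = 100 * rmse / ybar,
             MAE = mean(abs(y - yhat)),
             bias = bias,
             biasPct = 100 * bias / ybar,
             stringsAsFactors = FALSE)
}

#' Evaluate a paired measurement table
#'
#' Convenience wrapper over [evaluateAccuracy()] for tables produced by
#' [generatePairedMeasurements()] or assembled from two tree tables.
#'
#' @param pairs data.frame with columns `dbh_field`, `dbh_est`,
#'   `height_field`, `height_est` (either pair may be absent).
#' @return data.frame with one row per variable present.
#' @export
evaluatePairs <- function(pairs) {
  out <- list()
  if (all(c("dbh_field", "dbh_est") %in% names(pairs)))
    out$dbh <- evaluateAccuracy(pairs$dbh_field, pairs$dbh_est, "dbh")
  if (all(c("height_field", "height_est") %in% names(pairs)))
    out$height <- evaluateAccuracy(pairs$height_field, pairs$height_est,
                                   "height")
  if (length(out) == 0) stop("no recognised measurement pairs")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Match field and scanner-derived trees by stem position
#'
#' Pairs each field tree with the nearest extracted stem within a distance
#' cap, for surveys without shared tags. Greedy one-to-one matching in
#' order of increasing distance.
#'
#' @param field,bls data.frames with columns `tree_id`, `x`, `y`, `dbh`,
#'   `height`.
#' @param maxDist maximum pairing distance (m).
#' @return data.frame of matched pairs: `tree_id` (field id), `bls_id`,
#'   `distance`, `dbh_field`, `dbh_est`, `height_field`, `height_est`.
#' @export
matchStems <- function(field, bls, maxDist = 1) {
  stopifnot(nrow(field) > 0, nrow(bls) > 0)
  d <- outer(field$x, bls$x, "-")^2 + outer(field$y, bls$y, "-")^2
  d <- sqrt(d)
  cand <- which(d <= maxDist, arr.ind = TRUE)
  if (nrow(cand) == 0) return(data.frame())
  cand <- cand[order(d[cand]), , drop = FALSE]
  usedF <- logical(nrow(field)); usedB <- logical(nrow(bls))
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    fi <- cand[i, 1]; bi <- cand[i, 2]
    if (usedF[fi] || usedB[bi]) next
    usedF[fi] <- TRUE; usedB[bi] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      tree_id = field$tree_id[fi], bls_id = bls$tree_id[bi],
      distance = d[fi, bi],
      dbh_field = field$dbh[fi], dbh_est = bls$dbh[bi],
      height_field = field$height[fi], height_est = bls$height[bi],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
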