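# CASP-style evaluation: top-L/k precision per sequence-separation regime,
# probability-bin precision, and contact prediction depth.

# Eligible upper-triangle pairs for a regime set, excluding pairs the
# native map marks `ignored` (when a native map is given).
eligible_pairs <- function(L, regimes, native = NULL) {
  idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1L], j = idx[, 2L])
  df <- df[classify_range(df$i, df$j) %in% regimes, , drop = FALSE]
  if (!is.null(native)) {
    st <- native$states[cbind(df$i, df$j)]
    df <- df[st != .STATE_IGNORED, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

# Rank eligible pairs by descending probability, ties by ascending (i, j).
rank_predictions <- function(pred, regimes = c("medium", "long"),
                             native = NULL) {
  p <- as_prob_matrix(pred)
  df <- eligible_pairs(nrow(p), regimes, native)
  df$p <- p[cbind(df$i, df$j)]
  df <- df[order(-df$p, df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Precision of the top L/k contact predictions
#'
#' Ranks eligible pairs (upper triangle, requested regimes, not `ignored`)
#' by predicted probability (ties broken by ascending i, then j), takes
#' the top ceiling(L/k) pairs, and reports the fraction that are native
#' contacts. Targets with no native contact in the requested regimes score
#' 0. If fewer eligible pairs exist than ceiling(L/k), all are taken and
#' the denominator is the number taken.
#'
#' @param pred Symmetric probability matrix or `prediction_map`.
#' @param native A [contact_map()] of the native structure.
#' @param k Divisor of the list length (1, 2, 5, 10 in the standard
#'   evaluation).
#' @param regimes Character vector of regimes (default medium + long).
#' @return Precision in \[0, 1\].
#' @export
top_k_precision <- function(pred, native, k = 5,
                            regimes = c("medium", "long")) {
  stopifnot(inherits(native, "contact_map"), k >= 1)
  p <- as_prob_matrix(pred)
  L <- native$length
  if (nrow(p) != L)
    stop("prediction (", nrow(p), ") and native map (", L,
         ") have different lengths")
  ranked <- rank_predictions(p, regimes, native)
  if (!nrow(ranked)) return(0)
  truth <- native$states[cbind(ranked$i, ranked$j)]
  if (!any(truth == .STATE_CONTACT)) return(0)
  n_take <- min(ceiling(L / k), nrow(ranked))
  sum(truth[seq_len(n_take)] == .STATE_CONTACT) / n_take
}

#' Precision of positive predictions within probability bins
#'
#' Positive predictions (P > `cutoff`) among eligible, resolved pairs are
#' binned by their probability; each bin reports its count and precision.
#' Empty bins report `NA` precision (undefined, not 0).
#'
#' @param pred Prediction matrix or `prediction_map`.
#' @param native A [contact_map()].
#' @param edges Ascending bin edges within \[0.5, 1\]; bin b is
#'   (edges\[b\], edges\[b+1\]\].
#' @param regimes Regimes considered (default all non-local).
#' @param cutoff Positive-prediction cutoff (default the first edge).
#' @return Data frame with columns `bin_lo`, `bin_hi`, `n`, `n_correct`,
#'   `precision`.
#' @export
precision_by_probability_bin <- function(pred, native,
                                         edges = seq(0.5, 1, by = 0.1),
                                         regimes = c("short", "medium", "long"),
                                         cutoff = edges[1L]) {
  stopifnot(inherits(native, "contact_map"))
  if (is.unsorted(edges, strictly = TRUE))
    stop("bin edges must be strictly ascending")
  if (any(edges <= 0 | edges > 1)) stop("bin edges must lie in (0, 1]")
  ranked <- rank_predictions(pred, regimes, native)
  pos <- ranked[ranked$p > cutoff, , drop = FALSE]
  truth <- native$states[cbind(pos$i, pos$j)] == .STATE_CONTACT
  nb <- length(edges) - 1L
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1L],
                    n = integer(nb), n_correct = integer(nb),
                    precision = NA_real_)
  if (nrow(pos)) {
    bin <- findInterval(pos$p, edges, left.open = TRUE,
                        rightmost.closed = FALSE)
    bin[pos$p > edges[length(edges)]] <- nb   # clamp overflow into last bin
    for (b in seq_len(nb)) {
      sel <- bin == b
      out$n[b] <- sum(sel)
      out$n_correct[b] <- sum(truth[sel])
      if (out$n[b] > 0) out$precision[b] <- out$n_correct[b] / out$n[b]
    }
  }
  out
}

#' Precision of predictions above a probability cutoff
#'
#' @param pred Prediction matrix or `prediction_map`.
#' @param native A [contact_map()].
#' @param cutoff Probability cutoff (strict).
#' @param regimes Regimes considered.
#' @return List with `n`, `n_correct` and `precision` (`NA` when there is
#'   no positive prediction).
#' @export
positive_precision <- function(pred, native, cutoff = 0.5,
                               regimes = c("short", "medium", "long")) {
  stopifnot(inherits(native, "contact_map"))
  ranked <- rank_predictions(pred, regimes, native)
  pos <- ranked[ranked$p > cutoff, , drop = FALSE]
  n <- nrow(pos)
  nc <- if (n) sum(native$states[cbind(pos$i, pos$j)] == .STATE_CONTACT) else 0L
  list(n = n, n_correct = nc, precision = if (n) nc / n else NA_real_)
}

#' Contact prediction depth
#'
#' D = (number of eligible pairs predicted above the confidence cutoff)
#' divided by the target length L.
#'
#' @param pred Prediction matrix or `prediction_map`.
#' @param cutoff Confidence cutoff (default 0.8, strict).
#' @param regimes Regimes considered (default medium + long).
#' @param native Optional [contact_map()] whose `ignored` pairs are
#'   excluded.
#' @return Non-negative number D.
#' @export
prediction_depth <- function(pred, cutoff = 0.8,
                             regimes = c("medium", "long"), native = NULL) {
  p <- as_prob_matrix(pred)
  L <- nrow(p)
  if (L < 1L) stop("empty prediction map")
  ranked <- rank_predictions(p, regimes, native)
  sum(ranked$p > cutoff) / L
}

#' Per-target evaluation report
#'
#' Computes top-L/k precision for each k and regime set, the prediction
#' depth, and positive-prediction precision.
#'
#' @param pred Prediction matrix or `prediction_map`.
#' @param native A [contact_map()].
#' @param ks Divisors for the top-L/k lists.
#' @param regime_sets Named list of regime vectors.
#' @param depth_cutoff Confidence cutoff for the depth (default 0.8).
#' @return Data frame of class `eval_report` with one row per
#'   (regime set, k) plus attributes `depth` and `positive`.
#' @export
evaluate_contacts <- function(pred, native, ks = c(1, 2, 5, 10),
                              regime_sets = list(
                                short = "short", medium = "medium",
                                long = "long",
                                medium_long = c("medium", "long"),
                                nonlocal = c("short", "medium", "long")),
                              depth_cutoff = 0.8) {
  rows <- do.call(rbind, lapply(names(regime_sets), function(rs) {
    data.frame(regimes = rs, k = ks,
               precision = vapply(ks, function(k)
                 top_k_precision(pred, native, k, regime_sets[[rs]]),
                 numeric(1L)))
  }))
  attr(rows, "depth") <- prediction_depth(pred, cutoff = depth_cutoff,
                                          native = native)
  attr(rows, "positive") <- positive_precision(pred, native)
  class(rows) <- c("eval_report", class(rows))
  rows
}

#' Write a per-target evaluation report as TSV
#'
#' @param report An [evaluate_contacts()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_eval_tsv <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Aggregate evaluation reports
#'
#' @param reports List of [evaluate_contacts()] results.
#' @return List (JSON-ready) with mean and median precision per
#'   (regime set, k) and mean depth.
#' @export
aggregate_eval <- function(reports) {
  stopifnot(length(reports) >= 1L)
  key <- paste(reports[[1L]]$regimes, reports[[1L]]$k, sep = "_L/")
  mat <- vapply(reports, function(r) r$precision,
                numeric(nrow(reports[[1L]])))
  mat <- matrix(mat, nrow = nrow(reports[[1L]]))
  list(n_targets = length(reports),
       mean = setNames(rowMeans(mat), key),
       median = setNames(apply(mat, 1L, stats::median), key),
       mean_depth = mean(vapply(reports, function(r) attr(r, "depth"),
                                numeric(1L))))
}
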