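# Contact-pattern analysis: density clustering of contact-map points,
# cluster/contact coverage of a prediction, coverage differences between
# two predictors, and the proximity of false positives to native clusters.

#' Cluster contact-map points into contact patterns
#'
#' Runs HDBSCAN (Euclidean metric on the (i, j) index coordinates,
#' `min_samples = min_cluster_size`) on the upper-triangle contact points;
#' points in no cluster are noise. Clusters of packed secondary-structure
#' element pairs appear as dense point groups on the map.
#'
#' @param x A [contact_map()], or a data frame with columns `i`, `j`
#'   (upper triangle, deduplicated).
#' @param min_cluster_size Minimum contacts per cluster (default 3).
#' @param regimes Regimes retained before clustering when `x` is a
#'   contact map (default medium + long). Ignored for data-frame input.
#' @return An object of class `cluster_set`: list with `points` (data
#'   frame `i`, `j`, `cluster`, `is_noise`; `cluster` 0 = noise),
#'   `n_clusters`, `n_noise`, `clusters` (list of per-cluster data
#'   frames), `min_cluster_size`, `regimes`.
#' @export
cluster_contacts <- function(x, min_cluster_size = 3L,
                             regimes = c("medium", "long")) {
  if (inherits(x, "contact_map")) {
    pts <- contact_pairs(x, regimes = regimes)
  } else {
    pts <- as.data.frame(x)[, c("i", "j")]
    if (any(pts$i >= pts$j)) stop("points must be upper-triangle (i < j)")
    if (anyDuplicated(pts)) stop("points must be deduplicated")
    regimes <- NULL
  }
  if (nrow(pts) == 0L) {
    labels <- integer(0L)
  } else {
    labels <- hdbscan_points(as.matrix(pts), min_cluster_size = min_cluster_size)
  }
  pts$cluster <- as.integer(labels)
  pts$is_noise <- pts$cluster == 0L
  k <- if (nrow(pts)) max(pts$cluster) else 0L
  structure(list(points = pts,
                 n_clusters = k,
                 n_noise = sum(pts$is_noise),
                 clusters = if (k) split(pts[!pts$is_noise, c("i", "j")],
                                         pts$cluster[!pts$is_noise])
                            else list(),
                 min_cluster_size = as.integer(min_cluster_size),
                 regimes = regimes),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d points: %d clusters, %d noise\n",
              nrow(x$points), x$n_clusters, x$n_noise))
  invisible(x)
}

#' Write cluster assignments as TSV
#'
#' @param cset A [cluster_contacts()] result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cluster_tsv <- function(cset, path) {
  df <- cset$points
  names(df) <- c("i", "j", "cluster_id", "is_noise")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# predicted pairs as a normalized data frame (i < j)
as_pair_df <- function(predicted) {
  if (inherits(predicted, "prediction_map") || is.matrix(predicted))
    predicted <- positive_predictions(predicted)
  df <- as.data.frame(predicted)
  stopifnot(all(c("i", "j") %in% names(df)))
  sw <- df$i > df$j
  tmp <- df$i[sw]; df$i[sw] <- df$j[sw]; df$j[sw] <- tmp
  unique(df[, c("i", "j")])
}

pair_key <- function(df) paste(df$i, df$j)

#' Which native clusters are hit by a prediction
#'
#' A native cluster is hit when at least one correctly predicted contact
#' (a predicted pair that is a member of the cluster) lies in it.
#'
#' @param cset Native [cluster_contacts()] result.
#' @param predicted Predicted positive pairs: a data frame with `i`, `j`,
#'   or a prediction map (positives at P > 0.5).
#' @return Logical vector of length `n_clusters`.
#' @export
cluster_hits <- function(cset, predicted) {
  stopifnot(inherits(cset, "cluster_set"))
  pred_keys <- pair_key(as_pair_df(predicted))
  vapply(cset$clusters, function(cl) any(pair_key(cl) %in% pred_keys),
         logical(1L))
}

#' Coverage statistics of a prediction over native contact clusters
#'
#' Cluster coverage: number of native clusters hit divided by the total
#' number of native clusters. Contact coverage: number of correctly
#' predicted contacts inside the clusters divided by all native contacts
#' inside the clusters. With no native cluster both are undefined and
#' reported as `NA`.
#'
#' @param cset Native [cluster_contacts()] result.
#' @param predicted Predicted positive pairs (see [cluster_hits()]).
#' @return An object of class `coverage_stats`: list with
#'   `cluster_coverage`, `contact_coverage`, `n_clusters`, `n_hit`,
#'   `n_in_cluster_contacts`, `n_in_cluster_predicted`, and a `basis`
#'   fingerprint of the native cluster set.
#' @export
coverage_stats <- function(cset, predicted) {
  stopifnot(inherits(cset, "cluster_set"))
  pred <- as_pair_df(predicted)
  if (cset$n_clusters == 0L) {
    out <- list(cluster_coverage = NA_real_, contact_coverage = NA_real_,
                n_clusters = 0L, n_hit = 0L, n_in_cluster_contacts = 0L,
                n_in_cluster_predicted = 0L, basis = cluster_basis(cset))
    class(out) <- "coverage_stats"
    return(out)
  }
  hits <- cluster_hits(cset, pred)
  members <- do.call(rbind, cset$clusters)
  pred_keys <- pair_key(pred)
  n_in <- nrow(members)
  n_pred_in <- sum(pair_key(members) %in% pred_keys)
  out <- list(cluster_coverage = sum(hits) / cset$n_clusters,
              contact_coverage = n_pred_in / n_in,
              n_clusters = cset$n_clusters, n_hit = sum(hits),
              n_in_cluster_contacts = n_in,
              n_in_cluster_predicted = n_pred_in,
              basis = cluster_basis(cset))
  class(out) <- "coverage_stats"
  out
}

# fingerprint of a native cluster set so coverage differences can verify
# they share the same basis
cluster_basis <- function(cset) {
  pts <- cset$points
  paste(cset$n_clusters, nrow(pts), sum(pts$i * 131 + pts$j), sep = ":")
}

#' @export
print.coverage_stats <- function(x, ...) {
  cat(sprintf(
    "<coverage_stats> cluster coverage %s (%d/%d), contact coverage %s (%d/%d)\n",
    format(x$cluster_coverage, digits = 3L), x$n_hit, x$n_clusters,
    format(x$contact_coverage, digits = 3L), x$n_in_cluster_predicted,
    x$n_in_cluster_contacts))
  invisible(x)
}

#' Signed coverage difference between two predictors
#'
#' Element-wise difference (a - b) of cluster and contact coverage; both
#' statistics must have been computed against the same native cluster
#' set.
#'
#' @param a,b [coverage_stats()] of the two predictors.
#' @return List with `cluster_coverage` and `contact_coverage`
#'   differences, each in \[-1, 1\].
#' @export
delta_coverage <- function(a, b) {
  stopifnot(inherits(a, "coverage_stats"), inherits(b, "coverage_stats"))
  if (!identical(a$basis, b$basis))
    stop("coverage statistics were computed against different native cluster sets")
  list(cluster_coverage = a$cluster_coverage - b$cluster_coverage,
       contact_coverage = a$contact_coverage - b$contact_coverage)
}

#' Fraction of false positives near native clusters
#'
#' A false positive is "near" a native cluster when its Chebyshev distance
#' in index space to some cluster member is at most `shift` (so a
#' two-residue shift means both indices within +/-2). With no false
#' positives the fraction is undefined (`NA`).
#'
#' @param false_positives Data frame with `i`, `j` of false-positive
#'   predictions.
#' @param cset Native [cluster_contacts()] result.
#' @param shift Maximum residue shift (default 2).
#' @return Fraction in \[0, 1\], or `NA`.
#' @export
fp_proximity_fraction <- function(false_positives, cset, shift = 2L) {
  stopifnot(inherits(cset, "cluster_set"), shift >= 0L)
  fp <- as_pair_df(false_positives)
  if (nrow(fp) == 0L) return(NA_real_)
  if (cset$n_clusters == 0L) return(0)
  members <- do.call(rbind, cset$clusters)
  near <- vapply(seq_len(nrow(fp)), function(k) {
    any(pmax(abs(members$i - fp$i[k]), abs(members$j - fp$j[k])) <= shift)
  }, logical(1L))
  mean(near)
}

#' Compare two predictors on one native cluster set
#'
#' The reference predictor contributes its positive predictions
#' (P > `cutoff`); the comparison predictor is truncated to the same
#' number of its top-ranked pairs, so both are judged on equally sized
#' prediction lists. Reports coverage statistics for both, their signed
#' difference, and each predictor's false-positive proximity fraction.
#'
#' @param pred_ref,pred_cmp Prediction maps (matrix or `prediction_map`).
#' @param native Native [contact_map()].
#' @param regimes Regimes analyzed (default medium + long).
#' @param cutoff Positive cutoff for the reference (default 0.5).
#' @param min_cluster_size Minimum cluster size (default 3).
#' @param shift Residue shift for the proximity fraction (default 2).
#' @return List with `clusters` (native [cluster_contacts()]), `ref` and
#'   `cmp` (each: pairs, [coverage_stats()], `fp_proximity`), and
#'   `delta` ([delta_coverage()]).
#' @export
compare_predictors <- function(pred_ref, pred_cmp, native,
                               regimes = c("medium", "long"), cutoff = 0.5,
                               min_cluster_size = 3L, shift = 2L) {
  stopifnot(inherits(native, "contact_map"))
  cset <- cluster_contacts(native, min_cluster_size = min_cluster_size,
                           regimes = regimes)
  ranked_ref <- rank_predictions(pred_ref, regimes, native)
  pos_ref <- ranked_ref[ranked_ref$p > cutoff, c("i", "j"), drop = FALSE]
  n_ref <- nrow(pos_ref)
  ranked_cmp <- rank_predictions(pred_cmp, regimes, native)
  pos_cmp <- head(ranked_cmp, n_ref)[, c("i", "j"), drop = FALSE]

  native_keys <- pair_key(contact_pairs(native, regimes = regimes))
  side <- function(pos) {
    tp <- pos[pair_key(pos) %in% native_keys, , drop = FALSE]
    fp <- pos[!(pair_key(pos) %in% native_keys), , drop = FALSE]
    list(pairs = pos, n_positive = nrow(pos), n_correct = nrow(tp),
         coverage = coverage_stats(cset, pos),
         fp_proximity = fp_proximity_fraction(fp, cset, shift = shift))
  }
  ref <- side(pos_ref)
  cmp <- side(pos_cmp)
  list(clusters = cset, ref = ref, cmp = cmp,
       delta = delta_coverage(ref$coverage, cmp$coverage))
}
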