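# Two 6-point blobs plus two far singletons; the expected partition was
# frozen from an independent reference HDBSCAN run (min_cluster_size =
# min_samples = 3, Euclidean metric) on these exact coordinates.
blob_fixture <- function() {
  b1 <- cbind(10 + c(0, 1.1, 0.3, 1.7, 0.9, 0.2),
              40 + c(0, 0.4, 1.2, 0.8, 1.9, 2.3))
  b2 <- cbind(30 + c(0, 0.7, 1.3, 0.2, 1.9, 1.1),
              15 + c(0, 1.5, 0.3, 2.1, 0.9, 1.7))
  rbind(b1, b2, c(50, 50), c(2, 2))
}

test_that("density clustering recovers blobs, noise, and the single-cluster case", {
  lab <- hdbscan_points(blob_fixture(), 3L, 3L)
  expect_identical(as.integer(lab), c(rep(1L, 6L), rep(2L, 6L), 0L, 0L))
  # three adjacent collinear points, nothing else: one cluster, no noise
  lab3 <- hdbscan_points(cbind(1:3, 0), 3L)
  expect_identical(as.integer(lab3), rep(1L, 3L))
  # fewer points than the minimum cluster size: all noise
  expect_identical(as.integer(hdbscan_points(cbind(1:2, 0), 3L)),
                   c(0L, 0L))
  # determinism for fixed input
  expect_identical(hdbscan_points(blob_fixture(), 3L),
                   hdbscan_points(blob_fixture(), 3L))
})

test_that("cluster sizes plus noise conserve the input point count", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(3:60, 1L)
    pts <- unique(cbind(sample.int(50L, n, TRUE), sample.int(50L, n, TRUE)))
    lab <- hdbscan_points(pts, 3L)
    expect_identical(length(lab), nrow(pts))
    expect_identical(sum(lab == 0L) + sum(table(lab[lab > 0L])), nrow(pts))
    if (any(lab > 0L))
      expect_true(all(table(lab[lab > 0L]) >= 3L))
  }
})

test_that("contact clustering restricts to regimes and reports conservation", {
  tgt <- generate_target(L = 55L, seed = 31L, features = FALSE)
  cset <- cluster_contacts(tgt$labels, regimes = c("medium", "long"))
  ml <- contact_pairs(tgt$labels, c("medium", "long"))
  expect_identical(nrow(cset$points), nrow(ml))
  expect_identical(sum(!cset$points$is_noise) + cset$n_noise,
                   nrow(cset$points))
  if (cset$n_clusters > 0L)
    expect_true(all(vapply(cset$clusters, nrow, integer(1L)) >= 3L))
  # clustering the native map against itself: full coverage
  cov_self <- coverage_stats(cset, ml)
  expect_equal(cov_self$cluster_coverage, 1)
  expect_equal(cov_self$contact_coverage, 1)
})

test_that("cluster hits and coverage match a hand-built counting oracle", {
  # two clusters: 4 points near (5, 20), 3 points near (30, 45); 1 noise
  pts <- data.frame(i = c(5L, 5L, 6L, 7L, 30L, 31L, 31L, 60L),
                    j = c(20L, 21L, 20L, 22L, 45L, 45L, 46L, 90L))
  cset <- cluster_contacts(pts)
  expect_identical(cset$n_clusters, 2L)
  expect_identical(cset$n_noise, 1L)
  # prediction hits only the first cluster (2 of its 4 points)
  pred <- data.frame(i = c(5L, 6L, 9L), j = c(20L, 20L, 40L))
  hits <- cluster_hits(cset, pred)
  expect_identical(sum(hits), 1L)
  cov <- coverage_stats(cset, pred)
  expect_equal(cov$cluster_coverage, 1 / 2)
  expect_equal(cov$contact_coverage, 2 / 7)
  # empty predictions: no hits
  none <- coverage_stats(cset, data.frame(i = integer(0L), j = integer(0L)))
  expect_equal(none$cluster_coverage, 0)
  expect_equal(none$contact_coverage, 0)
  # membership-scan oracle on random predictions
  set.seed(12)
  for (rep in 1:5) {
    rnd <- data.frame(i = sample.int(35L, 6L), j = 36L + sample.int(12L, 6L))
    manual <- vapply(cset$clusters, function(cl)
      any(pkey(cl) %in% pkey(rnd)), logical(1L))
    expect_identical(cluster_hits(cset, rnd), manual)
  }
})

test_that("coverage differences are antisymmetric and need a shared basis", {
  pts <- data.frame(i = c(5L, 5L, 6L, 30L, 31L, 31L),
                    j = c(20L, 21L, 20L, 45L, 45L, 46L))
  cset <- cluster_contacts(pts)
  a <- coverage_stats(cset, pts[1:3, ])
  b <- coverage_stats(cset, pts[4:6, ])
  d <- delta_coverage(a, b)
  dr <- delta_coverage(b, a)
  expect_equal(d$cluster_coverage, -dr$cluster_coverage)
  expect_equal(d$contact_coverage, -dr$contact_coverage)
  expect_equal(delta_coverage(a, a)$contact_coverage, 0)
  other <- cluster_contacts(pts[1:5, ])
  expect_error(delta_coverage(a, coverage_stats(other, pts)),
               "different native cluster sets")
  # no native clusters: undefined coverage, reported as missing
  sparse <- cluster_contacts(data.frame(i = c(1L, 20L), j = c(10L, 40L)))
  expect_identical(sparse$n_clusters, 0L)
  cov0 <- coverage_stats(sparse, pts)
  expect_true(is.na(cov0$cluster_coverage) && is.na(cov0$contact_coverage))
})

test_that("false-positive proximity uses the Chebyshev shift and matches a scan", {
  pts <- data.frame(i = c(5L, 5L, 6L, 7L), j = c(20L, 21L, 20L, 22L))
  cset <- cluster_contacts(pts)
  # false positives sitting exactly on cluster members: fraction 1 at shift 0
  members <- do.call(rbind, cset$clusters)
  expect_equal(fp_proximity_fraction(members, cset, shift = 0L), 1)
  # no false positives: undefined
  expect_true(is.na(fp_proximity_fraction(
    data.frame(i = integer(0L), j = integer(0L)), cset)))
  set.seed(9)
  for (rep in 1:5) {
    fp <- data.frame(i = sample.int(30L, 8L, TRUE),
                     j = 31L + sample.int(20L, 8L, TRUE))
    fp <- unique(fp)
    members <- do.call(rbind, cset$clusters)
    manual <- mean(vapply(seq_len(nrow(fp)), function(k)
      any(abs(members$i - fp$i[k]) <= 2L & abs(members$j - fp$j[k]) <= 2L),
      logical(1L)))
    expect_equal(fp_proximity_fraction(fp, cset, shift = 2L), manual)
  }
})

test_that("predictor comparison truncates the rival to equal list length", {
  tgt <- generate_target(L = 50L, seed = 41L, features = FALSE)
  native <- tgt$labels
  L <- native$length
  good <- (native$states == 1L) * 0.9
  set.seed(4)
  noise <- random_pred(L, 44L) * 0.6
  cmp <- compare_predictors(good, noise, native)
  expect_identical(cmp$cmp$n_positive, cmp$ref$n_positive)
  expect_gte(cmp$delta$contact_coverage, 0)
  expect_true(cmp$ref$coverage$cluster_coverage == 1)
})
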