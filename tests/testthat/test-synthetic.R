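test_that("toy folds have the expected contact structure", {
  # a single unpacked helix has no medium/long-range contacts
  single <- generate_toy_fold(n_helices = 1L, n_strands = 0L, seed = 3L)
  map1 <- extract_native_contacts(single$coords)
  expect_identical(nrow(contact_pairs(map1, c("medium", "long"))), 0L)
  # two packed helices produce at least one contact cluster of size >= 3
  two <- generate_toy_fold(n_helices = 2L, n_strands = 0L, seed = 3L)
  map2 <- extract_native_contacts(two$coords)
  cset <- cluster_contacts(map2, regimes = c("medium", "long"))
  expect_gte(cset$n_clusters, 1L)
  expect_true(all(vapply(cset$clusters, nrow, integer(1L)) >= 3L))
  # determinism: same seed, bit-identical coordinates
  again <- generate_toy_fold(n_helices = 2L, n_strands = 0L, seed = 3L)
  expect_identical(two$ca, again$ca)
  expect_identical(two$sequence, again$sequence)
  expect_error(generate_toy_fold(n_helices = 2L, packing = 2), "packing")
})

test_that("alignment covariation tracks contacts only when switched on", {
  tgt <- generate_target(L = 45L, seed = 51L, features = FALSE)
  contacts <- contact_pairs(tgt$labels, c("medium", "long"))
  mean_mi <- function(strength, depth = 300L) {
    aln <- generate_covarying_msa(tgt$record, contacts, depth = depth,
                                  covariation_strength = strength,
                                  seed = 99L)
    mi <- compute_mutual_information(aln)
    up <- which(upper.tri(mi) & abs(row(mi) - col(mi)) >= 6, arr.ind = TRUE)
    on <- pkey(data.frame(i = up[, 1L], j = up[, 2L])) %in% pkey(contacts)
    c(ct = mean(mi[up][on]), bg = mean(mi[up][!on]))
  }
  off <- mean_mi(0)
  expect_lt(abs(off["ct"] - off["bg"]), 0.15)
  on <- mean_mi(0.9, depth = 500L)
  expect_gt(on["ct"], on["bg"] + 0.3)
  # determinism
  a1 <- generate_covarying_msa(tgt$record, contacts, depth = 50L, seed = 5L)
  a2 <- generate_covarying_msa(tgt$record, contacts, depth = 50L, seed = 5L)
  expect_identical(a1$seqs, a2$seqs)
  expect_error(generate_covarying_msa(tgt$record, contacts,
                                      mutation_rate = 1.2), "mutation_rate")
})

test_that("datasets have unique ids, disjoint splits, and sparse labels", {
  ds <- generate_dataset(10L, seed = 77L, depth = 30L, features = FALSE)
  ids <- c(names(ds$train), names(ds$validation))
  expect_length(unique(ids), 10L)
  expect_length(intersect(names(ds$train), names(ds$validation)), 0L)
  Ls <- vapply(c(ds$train, ds$validation), function(t) t$record$length,
               integer(1L))
  expect_true(all(Ls >= 25L & Ls <= 95L))   # near the configured 40-80 band
  # class imbalance: non-local contacts are a few percent of non-local pairs
  fracs <- vapply(c(ds$train, ds$validation), function(t) {
    L <- t$record$length
    nl <- sum(upper.tri(diag(L)) & abs(row(diag(L)) - col(diag(L))) >= 6)
    nrow(contact_pairs(t$labels, c("short", "medium", "long"))) / nl
  }, numeric(1L))
  expect_true(all(fracs > 0.002 & fracs < 0.2))
  expect_error(generate_dataset(1L), "at least 2")
})

test_that("synthetic targets exercise the ignored label class", {
  tgt <- generate_target(L = 40L, seed = 61L, missing_prob = 0.1,
                         depth = 30L, features = FALSE)
  expect_true(any(tgt$labels$states == 2L))
  expect_true(any(!tgt$coords$resolved))
})

test_that("the synthetic writers and real readers agree end to end", {
  tgt <- generate_target(L = 40L, seed = 71L, depth = 25L, features = FALSE)
  d <- tempfile(); dir.create(d)
  faf <- file.path(d, "t.fasta"); write_fasta_record(tgt$record, faf)
  expect_identical(read_fasta_record(faf)$sequence, tgt$record$sequence)
  msaf <- file.path(d, "t.afa"); write_msa(tgt$aln, msaf)
  expect_identical(read_msa(msaf)$seqs, tgt$aln$seqs)
  matf <- file.path(d, "t.mat"); write_ccmpred(tgt$coev, matf)
  expect_equal(read_ccmpred(matf, L = tgt$record$length), tgt$coev,
               tolerance = 1e-5)
})
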