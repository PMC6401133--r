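test_that("native-contact extraction matches a naive all-pairs distance loop", {
  for (seed in 1:20) {
    set.seed(seed)
    L <- sample(5:50, 1L)
    xyz <- matrix(rnorm(L * 3L, sd = 6), L, 3L)
    thr <- runif(1L, 4, 10)
    map <- extract_native_contacts(residue_coords(xyz), threshold = thr)
    naive <- matrix(0L, L, L)
    for (i in seq_len(L)) for (j in seq_len(L)) {
      if (i != j && sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < thr)
        naive[i, j] <- 1L
    }
    expect_identical(map$states, naive)
  }
})

test_that("contact maps are symmetric with a non-contact diagonal and ignored missing residues", {
  set.seed(42)
  xyz <- matrix(rnorm(30 * 3L, sd = 5), 30L, 3L)
  resolved <- rep(TRUE, 30L); resolved[c(4L, 17L)] <- FALSE
  map <- extract_native_contacts(residue_coords(xyz, resolved = resolved))
  expect_identical(map$states, t(map$states))
  expect_true(all(diag(map$states) == 0L))
  expect_true(all(map$states[4L, -4L] == 2L))
  expect_true(all(map$states[-17L, 17L] == 2L))
  # two residues 10 A apart are not in contact at the 8 A threshold
  far <- extract_native_contacts(residue_coords(rbind(c(0, 0, 0), c(10, 0, 0))))
  expect_identical(far$states[1L, 2L], 0L)
  # strictly-below comparison at the threshold itself
  at8 <- extract_native_contacts(residue_coords(rbind(c(0, 0, 0), c(8, 0, 0))))
  expect_identical(at8$states[1L, 2L], 0L)
})

test_that("degenerate coordinate input is rejected", {
  expect_error(residue_coords(matrix(numeric(0L), 0L, 3L)), "empty")
  expect_error(residue_coords(matrix(0, 3L, 3L), sequence = "AC"),
               "does not match")
  expect_error(extract_native_contacts(residue_coords(matrix(0, 2L, 3L)),
                                       threshold = -1), "positive")
})

test_that("sequence-separation regimes partition every separation once", {
  L <- 60L
  for (s in 1:(L - 1L)) {
    reg <- classify_range(1L, 1L + s)
    expected <- if (s <= 5) "local" else if (s <= 11) "short"
                else if (s <= 23) "medium" else "long"
    expect_identical(reg, expected)
  }
  expect_identical(classify_range(1L, 7L), "short")
  expect_identical(classify_range(1L, 13L), "medium")
  expect_identical(classify_range(1L, 25L), "long")
  expect_identical(classify_range(10L, 5L), "local")
  expect_error(classify_range(3L, 3L), "i != j")
})

test_that("positive predictions use a strict cutoff and match exhaustive scan", {
  p0 <- matrix(0, 8L, 8L)
  expect_identical(nrow(positive_predictions(p0)), 0L)
  p1 <- p0; p1[2L, 5L] <- p1[5L, 2L] <- 0.51
  pos <- positive_predictions(p1, 0.5)
  expect_identical(pos$i, 2L); expect_identical(pos$j, 5L)
  p2 <- p0; p2[3L, 6L] <- p2[6L, 3L] <- 0.5
  expect_identical(nrow(positive_predictions(p2, 0.5)), 0L)
  for (seed in 1:10) {
    p <- random_pred(20L, seed)
    pos <- positive_predictions(p, 0.7)
    manual <- NULL
    for (i in 1:19) for (j in (i + 1L):20L)
      if (p[i, j] > 0.7) manual <- rbind(manual, c(i, j))
    expect_identical(nrow(pos), if (is.null(manual)) 0L else nrow(manual))
    if (!is.null(manual))
      expect_setequal(pkey(pos), paste(manual[, 1L], manual[, 2L]))
  }
  asym <- matrix(runif(16L), 4L, 4L)
  expect_error(positive_predictions(asym), "symmetric")
})

test_that("a minimal PDB round-trips through the structure reader", {
  fold <- generate_toy_fold(n_helices = 2L, n_strands = 1L, seed = 5L)
  f <- tempfile(fileext = ".pdb")
  write_pdb_minimal(fold$ca, fold$cb, fold$sequence, f)
  coords <- read_structure(f)
  L <- nchar(fold$sequence)
  expect_identical(coords$length, L)
  expect_identical(coords$sequence, fold$sequence)
  aa <- strsplit(fold$sequence, "")[[1]]
  # contact atom: CB, except glycines (CA fallback)
  gly <- which(aa == "G")
  expect_true(length(gly) >= 1L)   # generator plants glycines
  expect_equal(coords$contact_atom[gly, , drop = FALSE],
               fold$ca[gly, , drop = FALSE], tolerance = 1e-3,
               ignore_attr = TRUE)
  ngl <- setdiff(seq_len(L), gly)
  expect_equal(coords$contact_atom[ngl, , drop = FALSE],
               fold$cb[ngl, , drop = FALSE], tolerance = 1e-3,
               ignore_attr = TRUE)
  # extraction through the file equals extraction from memory
  expect_identical(extract_native_contacts(coords)$states,
                   extract_native_contacts(fold$coords)$states)
})

test_that("RR records round-trip and use 1-based i j 0 8 p lines", {
  p <- random_pred(15L, 3L)
  f <- tempfile(fileext = ".rr")
  write_rr(p, f, cutoff = 0.6)
  lines <- readLines(f)
  expect_true(all(grepl("^\\d+ \\d+ 0 8 0\\.\\d+$", lines)))
  back <- read_rr(f, 15L)
  kept <- p * (p > 0.6)
  expect_equal(back, kept, tolerance = 1e-5)
  expect_error(read_rr(f, 4L), "out of range")
})
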