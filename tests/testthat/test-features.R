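aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aln <- function(depth, width, seed, gap_frac = 0) {
  set.seed(seed)
  letters_pool <- c(aa20, if (gap_frac > 0) "-")
  probs <- c(rep((1 - gap_frac) / 20, 20L), if (gap_frac > 0) gap_frac)
  m <- matrix(sample(letters_pool, depth * width, TRUE, prob = probs),
              depth, width)
  m[1L, ] <- sample(aa20, width, TRUE)   # ungapped target row
  alignment(apply(m, 1L, paste, collapse = ""))
}

test_that("profiles are one-hot for a single sequence and match naive counting", {
  one <- alignment("ACDG")
  prof <- compute_profile(one, pseudocount = 0)
  expect_equal(unname(prof[1L, "A"]), 1)
  expect_equal(unname(prof[3L, "D"]), 1)
  expect_equal(rowSums(prof), rep(1, 4L))
  # column entirely A
  allA <- alignment(c("AC", "AC", "AD"))
  expect_equal(unname(compute_profile(allA, pseudocount = 0)[1L, "A"]), 1)
  # naive per-column counting oracle on a random 50-row x 30-column alignment
  aln <- random_aln(50L, 30L, seed = 9L, gap_frac = 0.1)
  prof <- compute_profile(aln, pseudocount = 0)
  for (col in c(1L, 7L, 30L)) {
    cnt <- table(factor(aln$seqs[, col], levels = aa20))
    expect_equal(prof[col, ], as.numeric(cnt) / sum(cnt),
                 ignore_attr = TRUE)
  }
  prof1 <- compute_profile(aln, pseudocount = 1)
  expect_equal(rowSums(prof1), rep(1, 30L), tolerance = 1e-9)
})

test_that("mutual information has its closed-form and oracle values", {
  # identical sequences: no variation, MI = 0 everywhere
  same <- alignment(rep("ACDEF", 10L))
  expect_true(all(compute_mutual_information(same, pseudocount = 0) == 0))
  # perfect covariation over a uniform two-letter alphabet: MI = ln 2
  pair <- alignment(c("AA", "AA", "CC", "CC"))
  mi <- compute_mutual_information(pair, pseudocount = 0)
  expect_equal(mi[1L, 2L], log(2), tolerance = 1e-12)
  # direct summation oracle over all 400 letter pairs
  aln <- random_aln(40L, 8L, seed = 4L)
  mi <- compute_mutual_information(aln, pseudocount = 0)
  for (ij in list(c(1L, 2L), c(3L, 8L))) {
    i <- ij[1L]; j <- ij[2L]
    joint <- matrix(0, 20L, 20L, dimnames = list(aa20, aa20))
    for (r in seq_len(aln$depth))
      joint[aln$seqs[r, i], aln$seqs[r, j]] <-
        joint[aln$seqs[r, i], aln$seqs[r, j]] + 1
    f <- joint / sum(joint)
    fi <- rowSums(f); fj <- colSums(f)
    s <- 0
    for (a in 1:20) for (b in 1:20)
      if (f[a, b] > 0) s <- s + f[a, b] * log(f[a, b] / (fi[a] * fj[b]))
    expect_equal(mi[i, j], unname(s), tolerance = 1e-12)
  }
  expect_identical(mi, t(mi))
  expect_true(all(mi >= -1e-12))
  expect_true(all(diag(mi) == 0))
})

test_that("coevolution matrices are symmetrized on read and errors are located", {
  f <- tempfile()
  writeLines(c("0 0.4 0", "0.2 0 0", "0 0 0"), f)
  M <- read_ccmpred(f)
  expect_equal(M[1L, 2L], 0.3)
  expect_equal(M[2L, 1L], 0.3)
  expect_true(all(diag(M) == 0))
  writeLines(c("0 1", "0 1 2"), f)
  expect_error(read_ccmpred(f), "row 2")
  writeLines(c("0 x", "1 0"), f)
  expect_error(read_ccmpred(f), "row 1, column 2")
  writeLines(c("0 1", "1 0"), f)
  expect_error(read_ccmpred(f, L = 5L), "sequence length")
  # synthetic-module round trip: write then read is exact after symmetrization
  set.seed(2)
  A <- matrix(round(runif(25L), 6L), 5L, 5L)
  write_ccmpred(A, f)
  expect_equal(read_ccmpred(f), {
    S <- (A + t(A)) / 2; diag(S) <- 0; S
  }, tolerance = 1e-12)
})

test_that("pair potentials favor observed contact pairs and stay symmetric", {
  # corpus where only A-A pairs are ever in contact
  st <- matrix(0L, 4L, 4L); st[1L, 2L] <- st[2L, 1L] <- 1L
  corpus <- list(list(sequence = "AACD", map = contact_map(st)))
  U <- derive_pair_potential(corpus, smoothing = 0.01)
  expect_identical(which(U == min(U), arr.ind = TRUE)[1L, ],
                   c(row = 1L, col = 1L))
  expect_identical(unclass(U), t(unclass(U)))
  expect_true(all(is.finite(U)))
  expect_error(derive_pair_potential(
    list(list(sequence = "AC", map = contact_map(matrix(0L, 2L, 2L))))),
    "no contacts")
  # uniform random contacts over uniform composition: U ~ 0 as corpus grows
  set.seed(7)
  big <- lapply(1:150, function(k) {
    L <- 50L
    seq <- paste(sample(aa20, L, TRUE), collapse = "")
    st <- matrix(0L, L, L)
    idx <- which(upper.tri(st), arr.ind = TRUE)
    sel <- idx[sample.int(nrow(idx), 300L), , drop = FALSE]
    st[sel] <- 1L; st[sel[, 2:1]] <- 1L
    list(sequence = seq, map = contact_map(st))
  })
  Ubig <- derive_pair_potential(big)
  expect_lt(max(abs(Ubig)), 0.5)
  expect_lt(mean(abs(Ubig)), 0.1)
})

test_that("the assembled tensor has 51 channels with the documented layout", {
  tgt <- protein_record("t", "ACDEFGHIKLMN")
  L <- tgt$length
  set.seed(11)
  prof <- matrix(runif(L * 20L), L, 20L); prof <- prof / rowSums(prof)
  ss3 <- matrix(runif(L * 3L), L, 3L); ss3 <- ss3 / rowSums(ss3)
  acc <- runif(L)
  coev <- random_pred(L, 1L); mi <- random_pred(L, 2L)
  U <- matrix(rnorm(400L), 20L, 20L, dimnames = list(aa20, aa20))
  U <- (U + t(U)) / 2
  T <- assemble_features(tgt, prof, ss3, acc, coev, mi, U)
  expect_identical(dim(T), c(L, L, 51L))
  # 2D channels symmetric
  for (ch in 49:51) expect_identical(T[, , ch], t(T[, , ch]))
  # concatenated 1D blocks: i-block of (i,j) equals j-block of (j,i)
  for (k in 1:20) expect_identical(T[, , k], t(T[, , 20L + k]))
  for (k in 1:3) expect_identical(T[, , 40L + k], t(T[, , 43L + k]))
  expect_identical(T[, , 47L], t(T[, , 48L]))
  # pair potential channel is U(seq[i], seq[j])
  expect_equal(T[1L, 3L, 51L], U["A", "D"])
  # L = 2 edge case
  t2 <- protein_record("t2", "AC")
  T2 <- assemble_features(t2, prof[1:2, ], ss3[1:2, ], acc[1:2],
                          coev[1:2, 1:2], mi[1:2, 1:2], U)
  expect_identical(dim(T2), c(2L, 2L, 51L))
  # errors name the offending feature
  expect_error(assemble_features(tgt, prof[-1L, ], ss3, acc, coev, mi, U),
               "profile")
  expect_error(assemble_features(tgt, prof, ss3, acc[-1L], coev, mi, U),
               "acc")
  # assembly is deterministic
  expect_identical(T, assemble_features(tgt, prof, ss3, acc, coev, mi, U))
})

test_that("A3M lowercase inserts are dropped and ragged alignments rejected", {
  f <- tempfile(fileext = ".a3m")
  writeLines(c(">t", "ACDEF", ">h1", "AcCDEF", ">h2", "A-DEF"), f)
  aln <- read_msa(f)
  expect_identical(aln$depth, 3L)
  expect_identical(aln$width, 5L)
  expect_identical(paste(aln$seqs[2L, ], collapse = ""), "ACDEF")
  f2 <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDEF", ">b", "ACD"), f2)
  expect_error(read_msa(f2), "width")
})

test_that("PSI-BLAST ASCII PSSMs parse into normalized profiles", {
  f <- tempfile()
  hdr <- paste(c("", "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               collapse = "  ")
  set.seed(3)
  rows <- vapply(1:4, function(r)
    paste(c(sprintf("%d %s", r, c("A", "C", "D", "E")[r]),
            sprintf("%d", sample(-5:8, 20L, TRUE))), collapse = "  "),
    character(1L))
  writeLines(c("", "Last position-specific scoring matrix computed", hdr,
               rows), f)
  ps <- read_pssm(f)
  expect_identical(dim(ps$profile), c(4L, 20L))
  expect_equal(rowSums(ps$profile), rep(1, 4L), tolerance = 1e-9)
  expect_identical(ps$sequence, "ACDE")
})
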