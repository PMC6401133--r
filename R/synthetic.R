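# Synthetic targets: toy folds built from ideal secondary-structure
# segments, multiple sequence alignments whose column covariation tracks
# the fold's contacts, fabricated coevolution matrices, and packaged
# train/validation datasets. All generators are deterministic given their
# seed.

#' Generate a toy fold from packed secondary-structure segments
#'
#' Ideal helices (rise 1.5 A/residue, 100 degrees/residue, radius 2.3 A)
#' and extended strands (rise 3.3 A/residue) are laid out as antiparallel
#' rods spaced `packing` Angstrom apart and joined by short loops. Packed
#' neighboring segments produce the clustered medium/long-range contact
#' patterns typical of real folds; a single unpacked segment produces
#' none. Every residue gets a pseudo C-beta at a fixed offset from its
#' C-alpha, except glycines (inserted at random) which exercise the
#' C-alpha fallback.
#'
#' @param n_helices,n_strands Segment counts (total >= 1).
#' @param packing Axis-to-axis spacing of neighboring segments in
#'   Angstrom (default 9); must be >= 4 when more than one segment is
#'   packed.
#' @param seed Integer seed.
#' @param helix_len,strand_len Residues per segment.
#' @param loop_len Residues per connecting loop.
#' @param glycine_prob Per-residue probability of inserting a glycine.
#' @return List with `ca`, `cb` (L x 3; `cb` rows are `NA` for glycine),
#'   `sequence`, `ss` (per-residue H/E/C labels), and `coords` (a
#'   [residue_coords()] whose contact atom is the C-beta, C-alpha for
#'   glycine).
#' @export
generate_toy_fold <- function(n_helices = 2L, n_strands = 1L, packing = 9,
                              seed = 1L, helix_len = 12L, strand_len = 7L,
                              loop_len = 3L, glycine_prob = 0.08) {
  n_seg <- n_helices + n_strands
  if (n_seg < 1L) stop("need at least one segment")
  if (n_seg > 1L && packing < 4)
    stop("impossible packing: segments ", packing,
         " A apart would interpenetrate (need >= 4 A)")
  set.seed(seed)
  kinds <- sample(c(rep("H", n_helices), rep("E", n_strands)))
  seg_len <- ifelse(kinds == "H", helix_len, strand_len)
  span <- max(ifelse(kinds == "H", helix_len * 1.5, strand_len * 3.3))

  ca <- NULL; cb_dir <- NULL; ss <- character(0L)
  for (s in seq_len(n_seg)) {
    x0 <- (s - 1L) * packing
    up <- s %% 2L == 1L          # antiparallel arrangement
    n <- seg_len[s]
    z0 <- runif(1L, 0, max(0.1, span - n * if (kinds[s] == "H") 1.5 else 3.3))
    if (kinds[s] == "H") {
      k <- seq_len(n) - 1L
      theta <- (k * 100 + runif(1L, 0, 360)) * pi / 180
      z <- z0 + 1.5 * k
      if (!up) z <- (z0 + 1.5 * (n - 1L)) - 1.5 * k
      pts <- cbind(x0 + 2.3 * cos(theta), 2.3 * sin(theta), z)
      dirs <- cbind(cos(theta), sin(theta), 0)
    } else {
      k <- seq_len(n) - 1L
      z <- z0 + 3.3 * k
      if (!up) z <- (z0 + 3.3 * (n - 1L)) - 3.3 * k
      side <- rep_len(c(1, -1), n)
      pts <- cbind(x0 + 0.6 * side, 0.4 * side, z)
      dirs <- cbind(side, 0, 0)
    }
    ss_seg <- rep(kinds[s], n)
    if (s > 1L) {   # connecting loop
      a <- ca[nrow(ca), ]; b <- pts[1L, ]
      tt <- seq_len(loop_len) / (loop_len + 1L)
      loop <- cbind(a[1L] + (b[1L] - a[1L]) * tt,
                    a[2L] + (b[2L] - a[2L]) * tt + 4 * sin(pi * tt),
                    a[3L] + (b[3L] - a[3L]) * tt)
      ca <- rbind(ca, loop)
      cb_dir <- rbind(cb_dir, matrix(rep(c(0, 1, 0), loop_len),
                                     ncol = 3L, byrow = TRUE))
      ss <- c(ss, rep("C", loop_len))
    }
    ca <- rbind(ca, pts)
    cb_dir <- rbind(cb_dir, dirs)
    ss <- c(ss, ss_seg)
  }
  L <- nrow(ca)
  aa <- sample(setdiff(.AA20, "G"), L, replace = TRUE)
  aa[runif(L) < glycine_prob] <- "G"
  cb <- ca + 1.6 * cb_dir
  cb[aa == "G", ] <- NA_real_
  contact_atom <- cb
  contact_atom[aa == "G", ] <- ca[aa == "G", ]
  sequence <- paste(aa, collapse = "")
  list(ca = ca, cb = cb, sequence = sequence, ss = ss,
       coords = residue_coords(contact_atom, sidechain_com = contact_atom,
                               resolved = rep(TRUE, L),
                               sequence = sequence))
}

#' Generate an alignment whose covariation tracks a contact set
#'
#' Row 1 is the target. In every other row, each contact pair (restricted
#' to a one-to-one column matching, so a column covaries with at most one
#' partner) mutates jointly with probability `covariation_strength`: the
#' first column receives a random amino acid and the second the image of
#' that amino acid under a pair-specific random permutation. All other
#' columns (and contact columns in rows without a joint mutation) mutate
#' independently with probability `mutation_rate`.
#'
#' @param target A [protein_record()].
#' @param contacts Data frame with columns `i`, `j` of contacting pairs.
#' @param depth Number of alignment rows N (>= 2).
#' @param mutation_rate Background per-column mutation probability.
#' @param covariation_strength Joint-mutation probability in \[0, 1\].
#' @param seed Integer seed.
#' @return An [alignment()] of `depth` rows.
#' @export
generate_covarying_msa <- function(target, contacts, depth = 200L,
                                   mutation_rate = 0.35,
                                   covariation_strength = 0.9, seed = 1L) {
  stopifnot(inherits(target, "protein_record"), depth >= 2L)
  if (mutation_rate < 0 || mutation_rate > 1)
    stop("mutation_rate must lie in [0, 1]")
  if (covariation_strength < 0 || covariation_strength > 1)
    stop("covariation_strength must lie in [0, 1]")
  set.seed(seed)
  L <- target$length
  tgt <- strsplit(target$sequence, "")[[1]]
  contacts <- as.data.frame(contacts)
  # one-to-one matching: a column covaries with at most one partner
  used <- logical(L)
  pairs <- list()
  perms <- list()
  if (nrow(contacts)) {
    for (r in seq_len(nrow(contacts))) {
      i <- contacts$i[r]; j <- contacts$j[r]
      if (!used[i] && !used[j]) {
        used[i] <- used[j] <- TRUE
        pairs[[length(pairs) + 1L]] <- c(i, j)
        perms[[length(perms) + 1L]] <- sample.int(20L)
      }
    }
  }
  rows <- matrix(rep(tgt, depth), nrow = depth, byrow = TRUE)
  for (n in 2:depth) {
    row <- tgt
    mut <- runif(L) < mutation_rate
    row[mut] <- .AA20[sample.int(20L, sum(mut), replace = TRUE)]
    for (k in seq_along(pairs)) {
      if (runif(1L) < covariation_strength) {
        a <- sample.int(20L, 1L)
        row[pairs[[k]][1L]] <- .AA20[a]
        row[pairs[[k]][2L]] <- .AA20[perms[[k]][a]]
      }
    }
    rows[n, ] <- row
  }
  alignment(apply(rows, 1L, paste, collapse = ""),
            ids = c(target$id, sprintf("%s_hom%03d", target$id, 2:depth)))
}

#' Fabricate a coevolution score matrix from an alignment
#'
#' A stand-in for an external coevolutionary analysis: the alignment's
#' mutual information normalized to \[0, 1\], plus Gaussian noise,
#' symmetrized with a zeroed diagonal and clamped at 0.
#'
#' @param aln An [alignment()].
#' @param noise_sd Standard deviation of the additive noise.
#' @param seed Integer seed.
#' @return L x L coevolution score matrix.
#' @export
generate_coevolution <- function(aln, noise_sd = 0.05, seed = 1L) {
  set.seed(seed)
  mi <- compute_mutual_information(aln)
  mx <- max(mi)
  if (mx > 0) mi <- mi / mx
  L <- nrow(mi)
  noise <- matrix(rnorm(L * L, sd = noise_sd), L, L)
  out <- mi + (noise + t(noise)) / 2
  out[out < 0] <- 0
  diag(out) <- 0
  out
}

#' Generate one synthetic target with all its inputs
#'
#' Builds a toy fold, extracts the native contact labels, simulates a
#' covarying alignment, fabricates the coevolution matrix, noisy 3-state
#' secondary-structure probabilities and a burial-based accessibility
#' track, and (optionally) assembles the 51-channel feature tensor.
#'
#' @param L Approximate target length; segment counts are chosen to land
#'   within ~15 residues of it (`NULL` to pass segment counts directly).
#' @param seed Integer seed.
#' @param n_helices,n_strands Segment counts when `L` is `NULL`.
#' @param depth Alignment depth.
#' @param mutation_rate,covariation_strength See
#'   [generate_covarying_msa()].
#' @param missing_prob Per-residue probability of flagging a residue as
#'   missing from the "structure" (exercises the `ignored` label class).
#' @param potential Optional pair-potential table for the feature tensor.
#' @param features Assemble the feature tensor (default TRUE).
#' @param id Target id.
#' @return List with `id`, `record`, `fold`, `coords`, `labels` (a
#'   [contact_map()]), `aln`, `coev`, `ss3`, `acc`, `ss_labels` and
#'   (optionally) `features`.
#' @export
generate_target <- function(L = 50L, seed = 1L, n_helices = NULL,
                            n_strands = NULL, depth = 200L,
                            mutation_rate = 0.35,
                            covariation_strength = 0.9,
                            missing_prob = 0, potential = NULL,
                            features = TRUE, id = NULL) {
  set.seed(seed)
  if (is.null(n_helices)) {
    # greedily pick a segment mix whose length is close to L
    per_h <- 12L + 3L; per_e <- 7L + 3L
    n_helices <- max(1L, round(L / (2L * per_h)))
    rem <- L - n_helices * per_h
    n_strands <- max(0L, round(rem / per_e))
  }
  if (is.null(id)) id <- sprintf("synth_%06d", seed)
  fold <- generate_toy_fold(n_helices = n_helices, n_strands = n_strands,
                            seed = seed)
  record <- protein_record(id, fold$sequence)
  Ln <- record$length
  coords <- fold$coords
  if (missing_prob > 0) {
    drop <- runif(Ln) < missing_prob
    coords$resolved[drop] <- FALSE
  }
  labels <- extract_native_contacts(coords)
  nonlocal <- contact_pairs(labels, regimes = c("short", "medium", "long"))
  aln <- generate_covarying_msa(record, nonlocal, depth = depth,
                                mutation_rate = mutation_rate,
                                covariation_strength = covariation_strength,
                                seed = seed + 7L)
  coev <- generate_coevolution(aln, seed = seed + 13L)
  set.seed(seed + 17L)
  onehot <- matrix(0, Ln, 3L)
  onehot[cbind(seq_len(Ln), match(fold$ss, c("H", "E", "C")))] <- 1
  ss3 <- onehot * 0.8 + 0.2 / 3 + matrix(runif(Ln * 3L, 0, 0.05), Ln, 3L)
  ss3 <- ss3 / rowSums(ss3)
  burial <- sqrt(rowSums(sweep(fold$ca, 2L, colMeans(fold$ca))^2))
  acc <- (burial - min(burial)) / max(1e-9, diff(range(burial)))
  acc <- pmin(1, pmax(0, acc + rnorm(Ln, sd = 0.05)))
  out <- list(id = id, record = record, fold = fold, coords = coords,
              labels = labels, aln = aln, coev = coev, ss3 = ss3, acc = acc,
              ss_labels = fold$ss)
  if (features)
    out$features <- assemble_features(
      record, compute_profile(aln), ss3, acc, coev,
      compute_mutual_information(aln),
      if (is.null(potential))
        structure(matrix(0, 20L, 20L, dimnames = list(.AA20, .AA20)),
                  class = c("pair_potential", "matrix"))
      else potential)
  out
}

#' Generate a synthetic train/validation dataset
#'
#' @param n_targets Total targets (>= 2).
#' @param L_range Target length range (approximate; default 40-80).
#' @param seed Integer root seed.
#' @param validation_fraction Fraction held out for validation.
#' @param ... Passed to [generate_target()].
#' @return List with `train` and `validation` (named lists of targets,
#'   ids disjoint) and `manifest` (seed, sizes, ids, length range).
#' @export
generate_dataset <- function(n_targets, L_range = c(40L, 80L), seed = 1L,
                             validation_fraction = 0.2, ...) {
  if (n_targets < 2L) stop("need at least 2 targets to split")
  n_val <- max(1L, round(n_targets * validation_fraction))
  if (n_val >= n_targets)
    stop("validation fraction leaves no training targets")
  set.seed(seed)
  Ls <- sample(seq(L_range[1L], L_range[2L]), n_targets, replace = TRUE)
  targets <- lapply(seq_len(n_targets), function(k) {
    generate_target(L = Ls[k], seed = seed + 1000L * k,
                    id = sprintf("synth_%03d", k), ...)
  })
  names(targets) <- vapply(targets, `[[`, character(1L), "id")
  set.seed(seed + 1L)
  val_ids <- sample(names(targets), n_val)
  manifest <- list(seed = seed, n_targets = n_targets,
                   L_range = as.integer(L_range),
                   train_ids = setdiff(names(targets), val_ids),
                   validation_ids = val_ids)
  list(train = targets[manifest$train_ids],
       validation = targets[val_ids],
       manifest = manifest)
}
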