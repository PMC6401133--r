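# Per-pair feature assembly: sequence profiles, mutual information,
# coevolution couplings, a contact pair potential, and the 51-channel
# L x L feature tensor fed to the contact network.
#
# Channel layout of the tensor (third dimension):
#   1-20   profile of residue i        21-40  profile of residue j
#   41-43  3-state secondary structure of i   44-46  of j
#   47     relative solvent accessibility of i  48  of j
#   49     coevolution coupling score (2D)
#   50     mutual information (2D)
#   51     contact pair potential U(seq[i], seq[j]) (2D)

.FEATURE_CHANNELS <- 51L

# integer codes: 1..20 amino acids (alphabetical), 0 gap/unknown
aln_codes <- function(aln) {
  m <- match(aln$seqs, .AA20)
  m[is.na(m)] <- 0L
  matrix(m, nrow = aln$depth)
}

#' Positional frequency profile of an alignment
#'
#' Per-column amino-acid frequencies over the 20-letter alphabet with an
#' additive pseudocount. Gaps (and letters outside the alphabet) are
#' excluded from the normalization, so rows sum to 1. A column with no
#' countable letters and zero pseudocount falls back to the uniform row.
#'
#' @param aln An [alignment()].
#' @param pseudocount Additive pseudocount per amino acid (default 1).
#' @return L x 20 matrix of probabilities (columns in alphabetical
#'   one-letter order); rows sum to 1.
#' @export
compute_profile <- function(aln, pseudocount = 1) {
  stopifnot(inherits(aln, "alignment"))
  if (aln$depth < 1L) stop("empty alignment")
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  codes <- aln_codes(aln)
  L <- aln$width
  prof <- matrix(0, L, 20L, dimnames = list(NULL, .AA20))
  for (l in seq_len(L)) {
    cnt <- tabulate(codes[, l], nbins = 20L) + pseudocount
    tot <- sum(cnt)
    prof[l, ] <- if (tot > 0) cnt / tot else rep(1 / 20, 20L)
  }
  prof
}

#' Mutual information between alignment columns
#'
#' MI(i, j) = sum_ab f_ij(a,b) log( f_ij(a,b) / (f_i(a) f_j(b)) ) over the
#' 20 x 20 amino-acid pairs, with a uniform additive pseudocount on the
#' joint counts and natural logarithms. Rows where either column holds a
#' gap or unknown letter are excluded from that pair's counts. No average
#' product correction is applied. The diagonal is 0.
#'
#' @param aln An [alignment()].
#' @param pseudocount Additive pseudocount per joint cell (default 1/400,
#'   i.e. one total pseudo-observation spread uniformly).
#' @return L x L symmetric matrix; nonnegative up to numerical tolerance.
#' @export
compute_mutual_information <- function(aln, pseudocount = 1 / 400) {
  stopifnot(inherits(aln, "alignment"))
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  codes <- aln_codes(aln)
  L <- aln$width
  MI <- matrix(0, L, L)
  if (L < 2L) return(MI)
  for (i in seq_len(L - 1L)) {
    ci <- codes[, i]
    for (j in (i + 1L):L) {
      cj <- codes[, j]
      sel <- ci > 0L & cj > 0L
      if (!any(sel) && pseudocount == 0) next
      joint <- tabulate((ci[sel] - 1L) * 20L + cj[sel], nbins = 400L) +
        pseudocount
      tot <- sum(joint)
      if (tot <= 0) next
      f <- joint / tot
      fm <- matrix(f, 20L, 20L, byrow = TRUE)   # rows: letter of i
      fi <- rowSums(fm)
      fj <- colSums(fm)
      pos <- fm > 0
      ev <- outer(fi, fj)
      MI[i, j] <- MI[j, i] <- sum(fm[pos] * log(fm[pos] / ev[pos]))
    }
  }
  MI
}

#' Derive a contact pair potential from a structure corpus
#'
#' A symmetric 20 x 20 table of contact pseudo-energies
#' U(a, b) = -log( P_obs(a, b | contact) / P_exp(a, b) ), where P_obs is
#' the additively smoothed frequency of amino-acid pairs among contacts in
#' the corpus and P_exp is the product of corpus amino-acid compositions.
#' Frequently contacting pairs therefore receive low (favorable) energies.
#'
#' @param corpus List of entries, each a list with `sequence` (string) and
#'   `map` (a [contact_map()]).
#' @param smoothing Additive smoothing per ordered pair cell (default 1).
#' @return An object of class `pair_potential`: a symmetric 20 x 20 matrix
#'   with amino-acid dimnames.
#' @export
derive_pair_potential <- function(corpus, smoothing = 1) {
  stopifnot(is.list(corpus), length(corpus) >= 1L)
  counts <- matrix(0, 20L, 20L, dimnames = list(.AA20, .AA20))
  comp <- setNames(numeric(20L), .AA20)
  n_contacts <- 0L
  for (entry in corpus) {
    seq <- strsplit(toupper(entry$sequence), "")[[1]]
    tab <- table(factor(seq, levels = .AA20))
    comp <- comp + as.numeric(tab)
    prs <- contact_pairs(entry$map)
    if (!nrow(prs)) next
    a <- seq[prs$i]; b <- seq[prs$j]
    keep <- a %in% .AA20 & b %in% .AA20
    a <- a[keep]; b <- b[keep]
    n_contacts <- n_contacts + length(a)
    for (k in seq_along(a)) {
      counts[a[k], b[k]] <- counts[a[k], b[k]] + 1
      counts[b[k], a[k]] <- counts[b[k], a[k]] + 1
    }
  }
  if (n_contacts == 0L) stop("no contacts in the corpus")
  if (sum(comp) == 0) stop("no standard amino acids in the corpus")
  counts <- counts + smoothing
  p_obs <- counts / sum(counts)
  compf <- comp / sum(comp)
  p_exp <- outer(compf, compf)
  U <- matrix(0, 20L, 20L, dimnames = list(.AA20, .AA20))
  seen <- p_exp > 0
  # amino acids absent from the corpus carry no information: U stays 0
  U[seen] <- -log(p_obs[seen] / p_exp[seen])
  U <- (U + t(U)) / 2
  structure(U, class = c("pair_potential", "matrix"))
}

#' Build the 51-channel per-pair feature tensor
#'
#' Concatenates the 1D tracks (profile, 3-state secondary structure,
#' solvent accessibility) of both residues of every pair with the three 2D
#' features (coevolution couplings, mutual information, pair potential)
#' into an L x L x 51 tensor.
#'
#' Sequence letters outside the 20-letter alphabet contribute the uniform
#' profile row (when the supplied profile row is degenerate) and the mean
#' potential.
#'
#' @param target A [protein_record()].
#' @param profile L x 20 profile (see [compute_profile()]).
#' @param ss3 L x 3 secondary-structure probabilities (helix, strand,
#'   coil).
#' @param acc Length-L relative solvent accessibility in \[0, 1\].
#' @param coev L x L coevolution score matrix.
#' @param mi L x L mutual-information matrix.
#' @param potential A [derive_pair_potential()] table (or any symmetric
#'   20 x 20 matrix with amino-acid dimnames).
#' @return L x L x 51 numeric array with a `channels` attribute describing
#'   the layout.
#' @export
assemble_features <- function(target, profile, ss3, acc, coev, mi,
                              potential) {
  stopifnot(inherits(target, "protein_record"))
  L <- target$length
  chk <- function(x, nr, nc, name) {
    x <- as.matrix(x)
    if (nrow(x) != nr || ncol(x) != nc)
      stop(sprintf("feature '%s' is %d x %d, expected %d x %d",
                   name, nrow(x), ncol(x), nr, nc))
    x
  }
  profile <- chk(profile, L, 20L, "profile")
  ss3 <- chk(ss3, L, 3L, "ss3")
  acc <- as.numeric(acc)
  if (length(acc) != L)
    stop(sprintf("feature 'acc' has length %d, expected %d", length(acc), L))
  coev <- chk(coev, L, L, "coev")
  mi <- chk(mi, L, L, "mi")
  potential <- chk(unclass(potential), 20L, 20L, "potential")

  seq <- strsplit(target$sequence, "")[[1]]
  ai <- match(seq, .AA20)                 # NA for X
  mean_u <- mean(potential)
  Useq <- matrix(mean_u, L, L)
  known <- which(!is.na(ai))
  if (length(known))
    Useq[known, known] <- potential[cbind(
      rep(ai[known], times = length(known)),
      rep(ai[known], each = length(known)))]

  T <- array(0, dim = c(L, L, .FEATURE_CHANNELS))
  for (k in 1:20) {
    T[, , k] <- matrix(profile[, k], L, L)          # residue i, constant in j
    T[, , 20L + k] <- matrix(profile[, k], L, L, byrow = TRUE)  # residue j
  }
  for (k in 1:3) {
    T[, , 40L + k] <- matrix(ss3[, k], L, L)
    T[, , 43L + k] <- matrix(ss3[, k], L, L, byrow = TRUE)
  }
  T[, , 47L] <- matrix(acc, L, L)
  T[, , 48L] <- matrix(acc, L, L, byrow = TRUE)
  T[, , 49L] <- (coev + t(coev)) / 2
  T[, , 50L] <- (mi + t(mi)) / 2
  T[, , 51L] <- Useq
  attr(T, "channels") <- feature_channel_layout()
  T
}

#' Describe the feature-tensor channel layout
#'
#' @return Data frame with columns `channel`, `name`, `kind`.
#' @export
feature_channel_layout <- function() {
  data.frame(
    channel = 1:.FEATURE_CHANNELS,
    name = c(paste0("profile_i_", .AA20), paste0("profile_j_", .AA20),
             paste0("ss_i_", c("H", "E", "C")), paste0("ss_j_", c("H", "E", "C")),
             "acc_i", "acc_j", "coevolution", "mutual_information",
             "pair_potential"),
    kind = c(rep("1D_i", 20L), rep("1D_j", 20L), rep("1D_i", 3L),
             rep("1D_j", 3L), "1D_i", "1D_j", rep("2D", 3L)),
    stringsAsFactors = FALSE
  )
}

#' Build the feature tensor for a target from its raw inputs
#'
#' Convenience wrapper chaining [compute_profile()],
#' [compute_mutual_information()] and [assemble_features()].
#'
#' @param target A [protein_record()].
#' @param aln An [alignment()] whose first row is the target.
#' @param coev L x L coevolution matrix (e.g. [read_ccmpred()]); `NULL`
#'   substitutes a zero matrix.
#' @param ss3 L x 3 secondary-structure probabilities; `NULL` substitutes
#'   the uninformative uniform track.
#' @param acc Length-L accessibility scalar track; `NULL` substitutes 0.5.
#' @param potential Pair-potential table; `NULL` substitutes zeros.
#' @param pseudocount Profile/MI pseudocount.
#' @return L x L x 51 feature tensor.
#' @export
featurize_target <- function(target, aln, coev = NULL, ss3 = NULL,
                             acc = NULL, potential = NULL, pseudocount = 1) {
  L <- target$length
  if (aln$width != L)
    stop("alignment width (", aln$width, ") does not match target length (",
         L, ")")
  if (is.null(coev)) coev <- matrix(0, L, L)
  if (is.null(ss3)) ss3 <- matrix(1 / 3, L, 3L)
  if (is.null(acc)) acc <- rep(0.5, L)
  if (is.null(potential))
    potential <- structure(matrix(0, 20L, 20L, dimnames = list(.AA20, .AA20)),
                           class = c("pair_potential", "matrix"))
  prof <- compute_profile(aln, pseudocount = pseudocount)
  mi <- compute_mutual_information(aln)
  assemble_features(target, prof, ss3, acc, coev, mi, potential)
}
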