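# Core domain types: protein records, residue coordinates, ternary contact
# maps, and sequence-separation regimes.

#' Protein sequence record
#'
#' A minimal container for a target sequence. Sequences use the 20-letter
#' amino-acid alphabet plus `X` for unknown residues.
#'
#' @param id Target identifier.
#' @param sequence Amino-acid string.
#' @return An object of class `protein_record` with fields `id`, `sequence`
#'   and `length`.
#' @examples
#' protein_record("t1", "MKVLA")
#' @export
protein_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("sequence must contain at least one residue")
  bad <- setdiff(unique(strsplit(sequence, "")[[1]]), c(.AA20, "X"))
  if (length(bad))
    stop("sequence contains letters outside the amino-acid alphabet: ",
         paste(bad, collapse = ", "))
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (L = %d)\n", x$id, x$length))
  invisible(x)
}

#' Per-residue coordinates for contact extraction
#'
#' Holds, for every residue of a chain, the contact-atom coordinate (C-beta,
#' or C-alpha for glycine and for residues lacking a C-beta), the side-chain
#' center of mass (used as the restraint anchor), and a resolved/missing
#' mask. Missing residues are flagged, never silently zero-filled.
#'
#' @param contact_atom L x 3 numeric matrix of contact-atom coordinates
#'   (Angstrom). Rows of unresolved residues may contain `NA`.
#' @param sidechain_com L x 3 numeric matrix of side-chain center-of-mass
#'   coordinates; defaults to `contact_atom`.
#' @param resolved Logical vector of length L; `FALSE` marks missing
#'   residues.
#' @param sequence Optional amino-acid string of length L.
#' @return An object of class `residue_coords`.
#' @export
residue_coords <- function(contact_atom, sidechain_com = contact_atom,
                           resolved = NULL, sequence = NULL) {
  contact_atom <- as.matrix(contact_atom)
  sidechain_com <- as.matrix(sidechain_com)
  if (ncol(contact_atom) != 3L || ncol(sidechain_com) != 3L)
    stop("coordinates must be L x 3 matrices")
  L <- nrow(contact_atom)
  if (L < 1L) stop("empty coordinate set")
  if (nrow(sidechain_com) != L)
    stop("contact_atom and sidechain_com disagree in length")
  if (is.null(resolved)) resolved <- !apply(is.na(contact_atom), 1L, any)
  stopifnot(is.logical(resolved), length(resolved) == L)
  if (!is.null(sequence)) {
    if (nchar(sequence) != L)
      stop("sequence length (", nchar(sequence),
           ") does not match coordinate count (", L, ")")
  }
  structure(list(contact_atom = contact_atom, sidechain_com = sidechain_com,
                 resolved = resolved, sequence = sequence, length = L),
            class = "residue_coords")
}

#' @export
print.residue_coords <- function(x, ...) {
  cat(sprintf("<residue_coords> L = %d (%d resolved, %d missing)\n",
              x$length, sum(x$resolved), sum(!x$resolved)))
  invisible(x)
}

#' Ternary residue-residue contact map
#'
#' An L x L symmetric matrix over the states `non-contact`, `contact` and
#' `ignored` (integer codes 0, 1, 2). `ignored` marks pairs involving
#' residues missing from the structure; the diagonal is `non-contact`.
#'
#' @param states L x L integer matrix of state codes, or a logical matrix
#'   (`TRUE` = contact).
#' @param threshold Distance threshold (Angstrom) the map was derived with.
#' @return An object of class `contact_map`: a list with elements `states`,
#'   `threshold` and `length`.
#' @export
contact_map <- function(states, threshold = 8.0) {
  if (is.logical(states)) states <- states * 1L
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (nrow(states) != ncol(states)) stop("contact map must be square")
  if (!all(states %in% c(.STATE_NONCONTACT, .STATE_CONTACT, .STATE_IGNORED)))
    stop("contact map states must be 0 (non-contact), 1 (contact) or 2 (ignored)")
  if (!identical(states, t(states))) stop("contact map must be symmetric")
  diag(states) <- .STATE_NONCONTACT
  structure(list(states = states, threshold = threshold,
                 length = nrow(states)),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  up <- upper.tri(x$states)
  cat(sprintf(
    "<contact_map> L = %d, threshold %.1f A: %d contacts, %d ignored pairs (i<j)\n",
    x$length, x$threshold, sum(x$states[up] == .STATE_CONTACT),
    sum(x$states[up] == .STATE_IGNORED)))
  invisible(x)
}

#' Contact pairs of a contact map
#'
#' @param map A [contact_map()].
#' @param regimes Optional character vector of regimes (see
#'   [classify_range()]) to restrict the pairs to.
#' @return A data frame with 1-based columns `i`, `j` (`i < j`).
#' @export
contact_pairs <- function(map, regimes = NULL) {
  stopifnot(inherits(map, "contact_map"))
  idx <- which(upper.tri(map$states) & map$states == .STATE_CONTACT,
               arr.ind = TRUE)
  out <- data.frame(i = idx[, 1L], j = idx[, 2L])
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(regimes)) {
    keep <- classify_range(out$i, out$j) %in% regimes
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Extract native contacts from residue coordinates
#'
#' A pair (i, j) is a contact when both residues are resolved and the
#' Euclidean distance between their contact atoms (C-beta; C-alpha for
#' glycine) is strictly below `threshold`. Pairs involving a missing residue
#' are `ignored`; the diagonal is `non-contact`.
#'
#' @param coords A [residue_coords()] object.
#' @param threshold Contact distance threshold in Angstrom (default 8.0).
#' @return A [contact_map()].
#' @examples
#' xyz <- cbind(c(0, 3, 20), 0, 0)
#' m <- extract_native_contacts(residue_coords(xyz))
#' m$states
#' @export
extract_native_contacts <- function(coords, threshold = 8.0) {
  stopifnot(inherits(coords, "residue_coords"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number")
  L <- coords$length
  xyz <- coords$contact_atom
  xyz[!coords$resolved, ] <- NA_real_
  d <- as.matrix(dist(xyz))
  states <- matrix(.STATE_NONCONTACT, L, L)
  states[!is.na(d) & d < threshold] <- .STATE_CONTACT
  miss <- !coords$resolved
  states[miss, ] <- .STATE_IGNORED
  states[, miss] <- .STATE_IGNORED
  diag(states) <- .STATE_NONCONTACT
  contact_map(states, threshold = threshold)
}

#' Classify the sequence-separation regime of residue pairs
#'
#' Non-local separations are split into `short` \[6, 11\], `medium`
#' \[12, 23\] and `long` \[24, Inf); separations 1-5 are `local` and are
#' excluded from non-local evaluation.
#'
#' @param i,j 1-based residue indices (vectorized; `i != j`).
#' @return Character vector in `c("local", "short", "medium", "long")`.
#' @examples
#' classify_range(1, 7)    # short
#' classify_range(1, 13)   # medium
#' classify_range(1, 25)   # long
#' @export
classify_range <- function(i, j) {
  if (any(i == j)) stop("classify_range requires i != j")
  s <- abs(i - j)
  out <- character(length(s))
  out[s >= 1 & s <= 5] <- "local"
  out[s >= 6 & s <= 11] <- "short"
  out[s >= 12 & s <= 23] <- "medium"
  out[s >= 24] <- "long"
  out
}

#' Positive contact predictions
#'
#' Upper-triangle pairs whose predicted contact probability strictly exceeds
#' the cutoff.
#'
#' @param pred Symmetric L x L matrix of contact probabilities (or a
#'   `prediction_map`).
#' @param cutoff Probability cutoff in (0, 1); strictly greater-than
#'   (default 0.5).
#' @return Data frame with columns `i`, `j`, `p`, sorted by descending `p`
#'   (ties by ascending `i`, then `j`).
#' @export
positive_predictions <- function(pred, cutoff = 0.5) {
  pred <- as_prob_matrix(pred)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0 || cutoff >= 1)
    stop("cutoff must lie in (0, 1)")
  idx <- which(upper.tri(pred) & pred > cutoff, arr.ind = TRUE)
  out <- data.frame(i = idx[, 1L], j = idx[, 2L], p = pred[idx])
  out <- out[order(-out$p, out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Coerce a prediction to a plain symmetric probability matrix; errors on
# asymmetric input.
as_prob_matrix <- function(pred) {
  if (inherits(pred, "prediction_map")) pred <- pred$p
  pred <- as.matrix(pred)
  if (nrow(pred) != ncol(pred)) stop("prediction map must be square")
  if (!isTRUE(all.equal(pred, t(pred), tolerance = 1e-8,
                        check.attributes = FALSE)))
    stop("prediction map must be symmetric")
  if (any(pred < -1e-12 | pred > 1 + 1e-12))
    stop("probabilities must lie in [0, 1]")
  unname(pred)
}
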