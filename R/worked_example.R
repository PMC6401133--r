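# End-to-end native-contact pattern analysis of a single structure:
# extract contacts under the C-beta < 8 A rule and cluster the
# medium/long-range pairs.

#' Contact-pattern summary of a structure
#'
#' Reads a PDB file, extracts native contacts (C-beta, C-alpha for
#' glycine, strict 8 A threshold), restricts to medium/long-range pairs
#' (|i - j| >= 12) and clusters them with HDBSCAN.
#'
#' @param pdb_path Path to a PDB file.
#' @param chain Chain identifier (`NULL`: first polymer chain).
#' @param threshold Contact threshold in Angstrom (default 8.0).
#' @param min_cluster_size Minimum contacts per cluster (default 3).
#' @return List with `length`, `n_medium_long_contacts`, `n_clusters`,
#'   `n_noise`, the [cluster_contacts()] result (`clusters`) and the
#'   native [contact_map()] (`map`).
#' @export
worked_example <- function(pdb_path, chain = NULL, threshold = 8.0,
                           min_cluster_size = 3L) {
  coords <- read_structure(pdb_path, chain = chain)
  map <- extract_native_contacts(coords, threshold = threshold)
  cset <- cluster_contacts(map, min_cluster_size = min_cluster_size,
                           regimes = c("medium", "long"))
  list(length = coords$length,
       n_medium_long_contacts = nrow(contact_pairs(map, c("medium", "long"))),
       n_clusters = cset$n_clusters,
       n_noise = cset$n_noise,
       clusters = cset,
       map = map,
       coords = coords)
}

#' Plot a contact map (optionally against a prediction)
#'
#' Native contacts in the lower triangle; predicted probabilities (when
#' given) in the upper triangle.
#'
#' @param x A [contact_map()].
#' @param pred Optional prediction map.
#' @param ... Passed to [image()].
#' @export
plot.contact_map <- function(x, pred = NULL, ...) {
  L <- x$length
  M <- matrix(0, L, L)
  M[x$states == .STATE_CONTACT] <- 1
  if (!is.null(pred)) {
    p <- as_prob_matrix(pred)
    M[upper.tri(M)] <- p[upper.tri(p)]
  }
  image(seq_len(L), seq_len(L), t(M[L:1, ]), col = hcl.colors(32, "Blues 3",
                                                              rev = TRUE),
        xlab = "residue j", ylab = "residue i", axes = FALSE, ...)
  axis(1L); axis(2L, at = c(1L, L), labels = c(L, 1L))
  invisible(x)
}
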