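# Conversion of confident contact predictions into modelling restraints
# and combination of predicted with template-derived contacts.

#' Convert positive predictions into distance restraints
#'
#' Each positive prediction (P > `cutoff`) yields one restraint: an upper
#' bound of `bound` Angstrom (default 8.0) on the distance between the two
#' residues' side-chain centers of mass, carrying the prediction
#' probability as its confidence. Restraints are sorted by descending
#' confidence.
#'
#' @param pred Symmetric probability matrix or `prediction_map`.
#' @param cutoff Positive cutoff in (0, 1), default 0.5 (strict).
#' @param bound Upper distance bound in Angstrom (default 8.0).
#' @return An object of class `restraint_set`: data frame with columns
#'   `i`, `j` (1-based, i < j), `bound`, `anchor`
#'   (`"sidechain_com"`), `p`, `source` (`"predicted"`).
#' @export
contacts_to_restraints <- function(pred, cutoff = 0.5, bound = 8.0) {
  pos <- positive_predictions(pred, cutoff = cutoff)
  out <- data.frame(i = pos$i, j = pos$j,
                    bound = rep(bound, nrow(pos)),
                    anchor = rep("sidechain_com", nrow(pos)),
                    p = pos$p, source = rep("predicted", nrow(pos)),
                    stringsAsFactors = FALSE)
  class(out) <- c("restraint_set", class(out))
  out
}

#' @export
print.restraint_set <- function(x, ...) {
  cat(sprintf("<restraint_set> %d restraints (bound %.1f A, %s anchor)\n",
              nrow(x), if (nrow(x)) x$bound[1L] else 8.0,
              if (nrow(x)) x$anchor[1L] else "sidechain_com"))
  if (nrow(x)) print(head(as.data.frame(x), 5L))
  invisible(x)
}

#' Combine template-derived and predicted contacts
#'
#' Union combination: the predicted probability map is kept unchanged, and
#' template-derived pairs are injected at (at least) a floor probability;
#' pairs supported by both sources are counted once and tagged `"both"`.
#' Template-origin pairs keep their tag so downstream restraint handling
#' can leave template restraints unchanged.
#'
#' @param template_contacts Data frame with columns `i`, `j` of
#'   template-derived contact pairs (1-based).
#' @param pred Predicted probability map (matrix or `prediction_map`) for
#'   the same target length.
#' @param floor_p Probability assigned to template-only pairs (default
#'   0.5, i.e. just at the positive cutoff boundary; combined value is
#'   `max(predicted, floor_p)` for template pairs).
#' @param cutoff Positive cutoff used for the source tags (default 0.5).
#' @return An object of class `combined_contacts`: list with `p` (the
#'   combined L x L matrix), `source` (L x L character matrix:
#'   `"none"`, `"predicted"`, `"template"`, `"both"`), and `length`.
#' @export
combine_contact_sources <- function(template_contacts, pred,
                                    floor_p = 0.5, cutoff = 0.5) {
  p <- as_prob_matrix(pred)
  L <- nrow(p)
  tpl <- as_pair_df(if (nrow(as.data.frame(template_contacts)) == 0L)
    data.frame(i = integer(0L), j = integer(0L)) else template_contacts)
  if (nrow(tpl) && (max(tpl$j) > L || min(tpl$i) < 1L))
    stop("template contact indices exceed the prediction map length (", L, ")")
  src <- matrix("none", L, L)
  pos <- positive_predictions(p, cutoff = cutoff)
  if (nrow(pos)) {
    src[cbind(pos$i, pos$j)] <- "predicted"
    src[cbind(pos$j, pos$i)] <- "predicted"
  }
  out <- p
  if (nrow(tpl)) {
    ij <- cbind(tpl$i, tpl$j)
    ji <- cbind(tpl$j, tpl$i)
    out[ij] <- pmax(out[ij], floor_p)
    out[ji] <- pmax(out[ji], floor_p)
    is_pred <- src[ij] == "predicted"
    src[ij] <- ifelse(is_pred, "both", "template")
    src[ji] <- src[ij]
  }
  structure(list(p = out, source = src, length = L, floor_p = floor_p),
            class = "combined_contacts")
}

#' @export
print.combined_contacts <- function(x, ...) {
  up <- upper.tri(x$source)
  tab <- table(factor(x$source[up],
                      levels = c("predicted", "template", "both")))
  cat(sprintf(
    "<combined_contacts> L = %d: %d predicted-only, %d template-only, %d shared pairs\n",
    x$length, tab[["predicted"]], tab[["template"]], tab[["both"]]))
  invisible(x)
}

#' Restraints from a combined contact source
#'
#' Template-origin pairs are emitted at the floor probability (their
#' restraints are kept unchanged); predicted pairs use their predicted
#' confidence; pairs supported by both use the larger value.
#'
#' @param combined A [combine_contact_sources()] result.
#' @param cutoff Positive cutoff (default 0.5). Template pairs are always
#'   included.
#' @param bound Upper distance bound in Angstrom (default 8.0).
#' @return A `restraint_set` data frame (as [contacts_to_restraints()])
#'   whose `source` column tags each restraint's origin.
#' @export
combined_to_restraints <- function(combined, cutoff = 0.5, bound = 8.0) {
  stopifnot(inherits(combined, "combined_contacts"))
  up <- which(upper.tri(combined$p), arr.ind = TRUE)
  keep <- combined$p[up] > cutoff | combined$source[up] %in% c("template", "both")
  up <- up[keep, , drop = FALSE]
  out <- data.frame(i = up[, 1L], j = up[, 2L],
                    bound = rep(bound, nrow(up)),
                    anchor = rep("sidechain_com", nrow(up)),
                    p = combined$p[up], source = combined$source[up],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$p, out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("restraint_set", class(out))
  out
}

#' Write a restraint table as TSV
#'
#' The header spells out the atom-selection semantics so generic
#' modelling engines can consume the file.
#'
#' @param restraints A `restraint_set`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(restraints, path) {
  stopifnot(inherits(restraints, "restraint_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# distance restraints: upper bound (Angstrom) between the side-chain",
    "# centers of mass of residues i and j (1-based); glycine falls back to",
    "# the C-alpha atom. p is the prediction confidence.",
    paste("i", "j", "bound_A", "anchor", "p", "source", sep = "\t")), con)
  df <- as.data.frame(restraints)
  writeLines(sprintf("%d\t%d\t%.1f\t%s\t%.6f\t%s", df$i, df$j, df$bound,
                     df$anchor, df$p, df$source), con)
  invisible(path)
}

#' Read a restraint table written by [write_restraints()]
#'
#' @param path Restraint TSV file.
#' @return A `restraint_set` data frame.
#' @export
read_restraints <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df) <- c("i", "j", "bound", "anchor", "p", "source")
  class(df) <- c("restraint_set", class(df))
  df
}
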