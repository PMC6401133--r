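# Shared fixtures and independent oracles used across test files.

# random symmetric probability matrix
random_pred <- function(L, seed) {
  set.seed(seed)
  m <- matrix(runif(L * L), L, L)
  p <- (m + t(m)) / 2
  diag(p) <- 0
  p
}

# random ternary contact-map states (symmetric), with optional ignored rows
random_native <- function(L, seed, contact_frac = 0.05, n_missing = 0L) {
  set.seed(seed)
  st <- matrix(0L, L, L)
  up <- which(upper.tri(st), arr.ind = TRUE)
  k <- max(1L, round(contact_frac * nrow(up)))
  sel <- up[sample.int(nrow(up), k), , drop = FALSE]
  st[sel] <- 1L
  st[sel[, c(2L, 1L), drop = FALSE]] <- 1L
  if (n_missing > 0L) {
    miss <- sample.int(L, n_missing)
    st[miss, ] <- 2L
    st[, miss] <- 2L
  }
  diag(st) <- 0L
  contact_map(st)
}

# brute-force top-L/k precision oracle: plain loops, independent of the
# package's ranking code
oracle_topk <- function(p, native, k, regimes) {
  L <- nrow(p)
  rows <- NULL
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    sep <- j - i
    reg <- if (sep <= 5) "local" else if (sep <= 11) "short"
           else if (sep <= 23) "medium" else "long"
    if (!(reg %in% regimes)) next
    if (native$states[i, j] == 2L) next
    rows <- rbind(rows, data.frame(i = i, j = j, p = p[i, j],
                                   ct = native$states[i, j] == 1L))
  }
  if (is.null(rows) || !any(rows$ct)) return(0)
  rows <- rows[order(-rows$p, rows$i, rows$j), ]
  n <- min(ceiling(L / k), nrow(rows))
  sum(rows$ct[seq_len(n)]) / n
}

# small helper: pairs data frame -> key strings
pkey <- function(df) paste(df$i, df$j)
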