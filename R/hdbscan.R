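# Hierarchical density-based clustering (HDBSCAN) of 2D point sets, used
# to group contact-map points into contact patterns. Dense O(n^2)
# implementation: core distances, mutual-reachability graph, Prim MST,
# single-linkage hierarchy, condensed tree (minimum cluster size), and
# excess-of-mass cluster selection with stability scores.

#' HDBSCAN clustering of a point set
#'
#' @param x n x 2 numeric matrix of points (Euclidean metric).
#' @param min_cluster_size Minimum points per cluster (default 3).
#' @param min_samples Neighborhood size for core distances (default:
#'   `min_cluster_size`). The core distance of a point is the distance to
#'   its `min_samples`-th nearest neighbor, counting the point itself.
#' @param allow_single_cluster `"auto"` (default) falls back to a single
#'   root cluster only when the cluster hierarchy contains no nested
#'   cluster at all; `TRUE`/`FALSE` force/forbid root selection.
#' @return Integer vector of cluster labels (1, 2, ... by decreasing
#'   cluster size; 0 = noise), with attribute `stability`.
#' @export
hdbscan_points <- function(x, min_cluster_size = 3L,
                           min_samples = min_cluster_size,
                           allow_single_cluster = "auto") {
  x <- as.matrix(x)
  n <- nrow(x)
  if (min_cluster_size < 2L) stop("min_cluster_size must be >= 2")
  if (n == 0L) return(integer(0L))
  if (n < min_cluster_size) return(structure(rep(0L, n), stability = numeric(0L)))

  D <- as.matrix(dist(x))
  core <- apply(D, 1L, function(r) sort(r)[min_samples])
  M <- pmax(D, outer(core, core, pmax))

  # Prim MST over the mutual-reachability graph
  in_tree <- logical(n)
  in_tree[1L] <- TRUE
  best_w <- M[1L, ]
  best_from <- rep(1L, n)
  mst_a <- mst_b <- integer(n - 1L)
  mst_w <- numeric(n - 1L)
  for (e in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_w[cand])]
    mst_a[e] <- best_from[v]; mst_b[e] <- v; mst_w[e] <- best_w[v]
    in_tree[v] <- TRUE
    upd <- !in_tree & M[v, ] < best_w
    best_w[upd] <- M[v, upd]
    best_from[upd] <- v
  }

  # single-linkage hierarchy: nodes 1..n are points, n+1..2n-1 merges
  ord <- order(mst_w, mst_a, mst_b)
  parent <- seq_len(2L * n - 1L)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  node_of <- seq_len(n)           # current hierarchy node of each component root
  child_l <- child_r <- integer(n - 1L)
  node_dist <- numeric(n - 1L)
  node_size <- integer(2L * n - 1L)
  node_size[seq_len(n)] <- 1L
  nxt <- n
  for (e in ord) {
    ra <- find(mst_a[e]); rb <- find(mst_b[e])
    na <- node_of[ra]; nb <- node_of[rb]
    nxt <- nxt + 1L
    child_l[nxt - n] <- na; child_r[nxt - n] <- nb
    node_dist[nxt - n] <- mst_w[e]
    node_size[nxt] <- node_size[na] + node_size[nb]
    parent[rb] <- ra
    node_of[ra] <- nxt
  }
  root <- nxt

  leaves_of <- function(node) {
    out <- integer(0L); stack <- node
    while (length(stack)) {
      nd <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      if (nd <= n) out <- c(out, nd)
      else stack <- c(stack, child_l[nd - n], child_r[nd - n])
    }
    out
  }
  lam <- function(d) if (d > 0) 1 / d else Inf

  # condensed tree: walk top-down, creating child clusters only at splits
  # where both sides have >= min_cluster_size points
  clusters <- list()   # each: parent, birth, death, pts, pt_lambda, children
  new_cluster <- function(parent_id, birth) {
    clusters[[length(clusters) + 1L]] <<- list(
      parent = parent_id, birth = birth, death = NA_real_,
      pts = integer(0L), pt_lambda = numeric(0L), children = integer(0L))
    length(clusters)
  }
  root_id <- new_cluster(0L, lam(node_dist[root - n]))
  queue <- list(list(node = root, cid = root_id))
  while (length(queue)) {
    task <- queue[[1L]]; queue <- queue[-1L]
    node <- task$node; cid <- task$cid
    repeat {
      if (node <= n) {  # single point left in the cluster
        clusters[[cid]]$pts <- c(clusters[[cid]]$pts, node)
        clusters[[cid]]$pt_lambda <- c(clusters[[cid]]$pt_lambda,
                                       clusters[[cid]]$death)
        break
      }
      l <- child_l[node - n]; r <- child_r[node - n]
      lambda_split <- lam(node_dist[node - n])
      big_l <- node_size[l] >= min_cluster_size
      big_r <- node_size[r] >= min_cluster_size
      if (big_l && big_r) {
        clusters[[cid]]$death <- lambda_split
        for (ch in c(l, r)) {
          ch_id <- new_cluster(cid, lambda_split)
          clusters[[cid]]$children <- c(clusters[[cid]]$children, ch_id)
          queue[[length(queue) + 1L]] <- list(node = ch, cid = ch_id)
        }
        break
      } else if (!big_l && !big_r) {
        pts <- leaves_of(node)
        clusters[[cid]]$pts <- c(clusters[[cid]]$pts, pts)
        clusters[[cid]]$pt_lambda <- c(clusters[[cid]]$pt_lambda,
                                       rep(lambda_split, length(pts)))
        clusters[[cid]]$death <- lambda_split
        break
      } else {
        small <- if (big_l) r else l
        pts <- leaves_of(small)
        clusters[[cid]]$pts <- c(clusters[[cid]]$pts, pts)
        clusters[[cid]]$pt_lambda <- c(clusters[[cid]]$pt_lambda,
                                       rep(lambda_split, length(pts)))
        node <- if (big_l) l else r
      }
    }
  }

  nc <- length(clusters)
  finite_cap <- max(c(1, unlist(lapply(clusters, function(cl)
    cl$pt_lambda[is.finite(cl$pt_lambda)])),
    unlist(lapply(clusters, function(cl) cl$birth[is.finite(cl$birth)]))))
  stab <- numeric(nc)
  subtree_size <- function(cid) {
    length(clusters[[cid]]$pts) +
      sum(vapply(clusters[[cid]]$children, subtree_size, numeric(1L)))
  }
  for (ci in seq_len(nc)) {
    cl <- clusters[[ci]]
    birth <- min(cl$birth, finite_cap)
    pl <- pmin(cl$pt_lambda, finite_cap)
    s <- sum(pl - birth)
    if (length(cl$children)) {
      death <- min(cl$death, finite_cap)
      s <- s + (death - birth) *
        sum(vapply(cl$children, subtree_size, numeric(1L)))
    }
    stab[ci] <- s
  }

  # excess-of-mass selection, bottom-up; the root is not a candidate
  depth <- integer(nc)
  for (ci in seq_len(nc))
    depth[ci] <- if (clusters[[ci]]$parent == 0L) 0L else depth[[clusters[[ci]]$parent]] + 1L
  selected <- logical(nc)
  subtree_stab <- numeric(nc)
  for (ci in order(depth, decreasing = TRUE)) {
    ch <- clusters[[ci]]$children
    child_sum <- sum(subtree_stab[ch])
    candidate <- !(ci == root_id && !isTRUE(allow_single_cluster))
    if (candidate && (length(ch) == 0L || stab[ci] >= child_sum)) {
      selected[ci] <- TRUE
      subtree_stab[ci] <- stab[ci]
      # deselect descendants
      stack <- ch
      while (length(stack)) {
        d <- stack[[length(stack)]]; stack <- stack[-length(stack)]
        selected[d] <- FALSE
        stack <- c(stack, clusters[[d]]$children)
      }
    } else {
      selected[ci] <- FALSE
      subtree_stab[ci] <- child_sum
    }
  }

  single_fallback <- FALSE
  if (!any(selected) && !isFALSE(allow_single_cluster)) {
    selected[root_id] <- TRUE
    single_fallback <- TRUE
  }

  labels <- rep(0L, n)
  assign_subtree <- function(cid, label) {
    labels[clusters[[cid]]$pts] <<- label
    for (ch in clusters[[cid]]$children) assign_subtree(ch, label)
  }
  sel_ids <- which(selected)
  for (k in seq_along(sel_ids)) {
    cid <- sel_ids[k]
    if (single_fallback && cid == root_id) {
      # keep only points that persist beyond the root's birth density
      birth <- clusters[[cid]]$birth
      keep <- clusters[[cid]]$pts[clusters[[cid]]$pt_lambda > birth]
      if (length(keep) >= min_cluster_size) {
        labels[keep] <- k
        for (ch in clusters[[cid]]$children) assign_subtree(ch, k)
      } else assign_subtree(cid, k)
    } else assign_subtree(cid, k)
  }
  # relabel by decreasing size for a stable, deterministic numbering
  if (any(labels > 0L)) {
    sizes <- table(labels[labels > 0L])
    new_order <- as.integer(names(sort(sizes, decreasing = TRUE)))
    remap <- integer(max(labels))
    remap[new_order] <- seq_along(new_order)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
    stability_out <- stab[sel_ids][new_order]
  } else stability_out <- numeric(0L)
  structure(labels, stability = stability_out)
}
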