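#' Weighted median of a numeric vector
#'
#' Minimizer of \eqn{\sum_k w_k |z - v_k|}. When the minimizer is an
#' interval (total weight splits exactly in half), the midpoint of the
#' optimal interval is returned, for determinism.
#'
#' @param values numeric vector.
#' @param weights nonnegative weights, same length.
#' @return scalar minimizer.
#' @export
weighted_median <- function(values, weights) {
  stopifnot(length(values) == length(weights), all(weights >= 0))
  keep <- weights > 0
  values <- values[keep]
  weights <- weights[keep]
  if (!length(values)) stop("weighted_median needs at least one positive weight")
  o <- order(values)
  v <- values[o]
  w <- weights[o]
  tot <- sum(w)
  cw <- cumsum(w)
  k <- which(cw >= tot / 2 - 1e-12 * tot)[1]
  # exact half split: every point of [v_k, v_{k+1}] is optimal
  if (k < length(v) && abs(cw[k] - tot / 2) <= 1e-12 * tot) {
    unname((v[k] + v[k + 1]) / 2)
  } else {
    unname(v[k])
  }
}

# Even-odd rule point-in-polygon test (boundary counts as inside).
point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]
    xj <- poly_x[j]; yj <- poly_y[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Indices reachable from `from` in the undirected graph with adjacency adj > 0.
reachable_from <- function(adj, from) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  seen[from] <- TRUE
  frontier <- from
  while (length(frontier)) {
    nb <- which(colSums(adj[frontier, , drop = FALSE] > 0) > 0)
    nb <- nb[!seen[nb]]
    seen[nb] <- TRUE
    frontier <- nb
  }
  which(seen)
}

# Connected components of the undirected graph adj > 0 restricted to `nodes`.
components_of <- function(adj, nodes) {
  remaining <- nodes
  comps <- list()
  sub <- adj[nodes, nodes, drop = FALSE]
  idx <- seq_along(nodes)
  seen <- rep(FALSE, length(nodes))
  for (s in idx) {
    if (seen[s]) next
    comp <- s
    seen[s] <- TRUE
    frontier <- s
    while (length(frontier)) {
      nb <- which(colSums(sub[frontier, , drop = FALSE] > 0) > 0)
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      comp <- c(comp, nb)
      frontier <- nb
    }
    comps[[length(comps) + 1]] <- nodes[sort(comp)]
  }
  comps
}
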