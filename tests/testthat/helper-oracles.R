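# Independent oracles used across the suite.

# scalar cost-distance, written out long-hand
dist_scalar <- function(a, b, spec) {
  spec <- wireopt::as_norm_spec(spec)
  if (spec$family == "l1") {
    abs(a[1] - b[1]) + abs(a[2] - b[2])
  } else {
    sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2)^spec$power
  }
}

# brute-force total wiring length: explicit double loop over ordered pairs
twl_brute <- function(layout, W, spec) {
  n <- nrow(layout)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (W[i, j] > 0) s <- s + W[i, j] * dist_scalar(layout[i, ], layout[j, ], spec)
  }
  s
}

# multi-resolution exhaustive grid search over the free coordinates.
# Full grid for <= 2 free nodes; block-cyclic per-node grids for more.
grid_search_optimum <- function(W, fixed, coords, spec, box,
                                n_grid = 11, stages = 9) {
  free <- which(!fixed)
  obj <- function(X) wireopt::total_wiring_length(X, W, spec)
  X <- coords
  search_node <- function(X, i, lo, hi, g) {
    gx <- seq(lo[1], hi[1], length.out = g)
    gy <- seq(lo[2], hi[2], length.out = g)
    best <- c(X[i, 1], X[i, 2])
    best_v <- obj(X)
    for (a in gx) for (b in gy) {
      X[i, ] <- c(a, b)
      v <- obj(X)
      if (v < best_v) { best_v <- v; best <- c(a, b) }
    }
    X[i, ] <- best
    X
  }
  if (length(free) <= 2) {
    dims <- length(free) * 2
    lo <- rep(box[1, ], each = length(free))
    hi <- rep(box[2, ], each = length(free))
    # flatten free coords as (x1, y1, x2, y2)
    lo <- as.vector(t(matrix(rep(box[1, ], length(free)), ncol = 2, byrow = TRUE)))
    hi <- as.vector(t(matrix(rep(box[2, ], length(free)), ncol = 2, byrow = TRUE)))
    for (s in seq_len(stages)) {
      grids <- lapply(seq_len(dims), function(d) seq(lo[d], hi[d], length.out = n_grid))
      combos <- as.matrix(expand.grid(grids))
      vals <- apply(combos, 1, function(par) {
        X[free, ] <- matrix(par, ncol = 2, byrow = TRUE)
        obj(X)
      })
      best <- combos[which.min(vals), ]
      span <- (hi - lo) / (n_grid - 1) * 2
      lo <- best - span
      hi <- best + span
    }
    X[free, ] <- matrix(best, ncol = 2, byrow = TRUE)
    return(list(layout = X, objective = obj(X)))
  }
  # cyclic per-node refinement
  for (sweep in 1:40) {
    v0 <- obj(X)
    for (i in free) {
      lo <- box[1, ]; hi <- box[2, ]
      for (s in 1:8) {
        X <- search_node(X, i, lo, hi, n_grid)
        span <- (hi - lo) / (n_grid - 1) * 2
        lo <- X[i, ] - span
        hi <- X[i, ] + span
      }
    }
    if (v0 - obj(X) < 1e-10 * max(v0, 1)) break
  }
  list(layout = X, objective = obj(X))
}

# small worm-like instance for fast tests
small_instance <- function(seed = 1, n_free = 20, lambda = 0.15) {
  cfg <- wireopt::synth_config(n_anchors_head = 25, n_anchors_tail = 18,
                               n_anchors_cord = 12, n_free = n_free,
                               decay_scale = lambda, seed = seed)
  wireopt::generate_instance(cfg)
}
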