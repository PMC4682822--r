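#' Monte-Carlo random-placement null for the wiring length
#'
#' Places the free neurons uniformly at random inside the body region
#' (keeping anchors at their real positions), recomputes the total
#' wiring length for each draw, and summarizes the null distribution.
#' The region is either the axis-aligned bounding box of all real
#' positions (default) or their convex hull (rejection sampling).
#'
#' @param problem a [placement_problem()].
#' @param real_layout n x 2 matrix of real positions defining the region.
#' @param n_iter number of random layouts (the study uses 1000).
#' @param seed RNG seed; results are reproducible bit-exactly given it.
#' @param region `"bbox"` or `"hull"`.
#' @return A `baseline_result`: `mean_twl`, `sd_twl`, `twl` (the draws),
#'   `n_iter`, `seed`, `region`.
#' @export
random_baseline <- function(problem, real_layout, n_iter = 1000, seed = 1,
                            region = c("bbox", "hull")) {
  stopifnot(inherits(problem, "placement_problem"), n_iter >= 1)
  region <- match.arg(region)
  real_layout <- as.matrix(real_layout)
  rx <- range(real_layout[, 1])
  ry <- range(real_layout[, 2])
  if (diff(rx) <= 0 || diff(ry) <= 0) {
    stop("degenerate sampling region: zero area bounding box")
  }
  F <- problem$free
  nf <- length(F)
  if (region == "hull") {
    h <- grDevices::chull(real_layout)
    hx <- real_layout[h, 1]
    hy <- real_layout[h, 2]
  }
  draw_free <- function(k) {
    if (region == "bbox") {
      cbind(stats::runif(k, rx[1], rx[2]), stats::runif(k, ry[1], ry[2]))
    } else {
      out <- matrix(NA_real_, k, 2)
      got <- 0L
      while (got < k) {
        m <- (k - got) * 2 + 8
        px <- stats::runif(m, rx[1], rx[2])
        py <- stats::runif(m, ry[1], ry[2])
        keep <- point_in_polygon(px, py, hx, hy)
        take <- min(sum(keep), k - got)
        if (take > 0) {
          idx <- which(keep)[seq_len(take)]
          out[got + seq_len(take), ] <- cbind(px[idx], py[idx])
          got <- got + take
        }
      }
      out
    }
  }
  twl <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      X <- problem$coords
      if (nf) X[F, ] <- draw_free(nf)
      total_wiring_length(X, problem$weights, problem$spec)
    }, numeric(1))
  })
  structure(list(mean_twl = mean(twl),
                 sd_twl = if (n_iter > 1) stats::sd(twl) else 0,
                 twl = twl, n_iter = n_iter, seed = seed, region = region),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("baseline_result: mean TWL %.6g (sd %.3g) over %d uniform draws in %s (seed %d)\n",
              x$mean_twl, x$sd_twl, x$n_iter, x$region, x$seed))
  invisible(x)
}
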