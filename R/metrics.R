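#' Specify a connection cost (distance) function
#'
#' The wiring cost of a link is a function of the straight-line
#' separation of its endpoints: the l1 (Manhattan) distance, or a power
#' of the Euclidean norm. Power 1 is the Euclidean distance, power 2 the
#' squared Euclidean "distance" (not a metric, but convex), powers 3 and
#' 4 probe steeper cost growth.
#'
#' @param family `"l1"` or `"euclidean"`.
#' @param power integer in 1..4, Euclidean family only.
#' @return A `norm_spec` object.
#' @seealso [as_norm_spec()] for the string shorthand `"l1"`, `"l2"`,
#'   `"sq"`, `"p3"`, `"p4"`.
#' @export
norm_spec <- function(family = c("euclidean", "l1"), power = 1L) {
  family <- match.arg(family)
  if (family == "l1") {
    power <- 1L
  } else {
    power <- as.integer(power)
    if (!power %in% 1:4) stop("supported Euclidean powers are 1, 2, 3, 4")
  }
  structure(list(family = family, power = power), class = "norm_spec")
}

#' Coerce a shorthand string to a norm_spec
#'
#' `"l1"` is the Manhattan norm; `"l2"`, `"sq"`, `"p3"`, `"p4"` are the
#' Euclidean norm raised to the power 1, 2, 3, 4.
#'
#' @param x a `norm_spec` or one of the shorthand strings.
#' @return A [norm_spec()].
#' @export
as_norm_spec <- function(x) {
  if (inherits(x, "norm_spec")) return(x)
  switch(as.character(x),
    l1 = norm_spec("l1"),
    l2 = norm_spec("euclidean", 1L),
    sq = norm_spec("euclidean", 2L),
    p3 = norm_spec("euclidean", 3L),
    p4 = norm_spec("euclidean", 4L),
    stop("unknown norm shorthand: ", x))
}

#' @export
format.norm_spec <- function(x, ...) {
  if (x$family == "l1") "l1"
  else c("l2", "sq", "p3", "p4")[x$power]
}

#' @export
print.norm_spec <- function(x, ...) {
  cat("norm_spec:", format(x),
      sprintf("(units mm%s)\n",
              if (x$family == "l1" || x$power == 1) "" else paste0("^", x$power)))
  invisible(x)
}

#' Pairwise connection-cost matrix of a layout
#'
#' @param layout n x 2 coordinate matrix (mm).
#' @param spec a [norm_spec()] or shorthand string.
#' @return symmetric n x n matrix with zero diagonal; entry ij is the
#'   cost-distance between rows i and j.
#' @export
pairwise_distance <- function(layout, spec = "l2") {
  spec <- as_norm_spec(spec)
  layout <- as.matrix(layout)
  stopifnot(ncol(layout) == 2, all(is.finite(layout)))
  if (spec$family == "l1") {
    d <- as.matrix(stats::dist(layout, method = "manhattan"))
  } else {
    d <- as.matrix(stats::dist(layout, method = "euclidean"))
    if (spec$power != 1L) d <- d^spec$power
  }
  unname(d)
}

#' Total wiring length of a layout
#'
#' The sum, over all ordered pairs (i, j), of the link weight times the
#' cost-distance between neurons i and j:
#' \deqn{TWL = \sum_{i,j} A_{ij}\, d(x_i, x_j).}
#' Since the distance matrix is symmetric the value only depends on the
#' symmetrized weights; the sum is accumulated in a fixed index order so
#' repeated runs are bit-identical.
#'
#' @param layout n x 2 coordinate matrix (mm).
#' @param weights n x n nonnegative weight matrix (see [build_weights()]).
#' @param spec a [norm_spec()] or shorthand string.
#' @return nonnegative scalar, in mm (or mm^p for powered costs).
#' @export
total_wiring_length <- function(layout, weights, spec = "l2") {
  layout <- as.matrix(layout)
  weights <- as.matrix(weights)
  if (nrow(layout) != nrow(weights) || nrow(weights) != ncol(weights)) {
    stop("layout and weight matrix dimensions disagree")
  }
  sum(weights * pairwise_distance(layout, spec))
}
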