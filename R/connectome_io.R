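#' Construct a neuron position table
#'
#' A neuron table holds the identity, functional class and reference 2D
#' position of every neuron. Axis 1 runs anterior to posterior, axis 2
#' ventral to dorsal; coordinates are in mm. Row order is the canonical
#' index used by all matrices in the package.
#'
#' @param id character vector of unique neuron labels (e.g. "PVCL").
#' @param class character vector, one of `"motor"`, `"sensory"`, `"inter"`.
#' @param x,y numeric coordinates in mm.
#' @return A `neuron_table` (a data frame with columns `id`, `class`,
#'   `x`, `y`).
#' @export
neuron_table <- function(id, class, x, y) {
  id <- as.character(id)
  class <- as.character(class)
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(id)
  stopifnot(length(class) == n, length(x) == n, length(y) == n)
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    stop("duplicate neuron id(s): ", paste(dup, collapse = ", "))
  }
  bad <- setdiff(unique(class), c("motor", "sensory", "inter"))
  if (length(bad)) {
    stop("unknown neuron class token(s): ", paste(bad, collapse = ", "))
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("all coordinates must be finite")
  }
  out <- data.frame(id = id, class = class, x = x, y = y,
                    stringsAsFactors = FALSE)
  class(out) <- c("neuron_table", "data.frame")
  out
}

#' @export
print.neuron_table <- function(x, ...) {
  cat(sprintf("neuron_table: %d neurons (%d motor, %d sensory, %d inter/free)\n",
              nrow(x), sum(x$class == "motor"), sum(x$class == "sensory"),
              sum(x$class == "inter")))
  NextMethod()
}

#' Extract the coordinate matrix of a neuron table
#'
#' @param table a [neuron_table()].
#' @return n x 2 numeric matrix (mm), rows in canonical order.
#' @export
layout_of <- function(table) {
  m <- cbind(x = table$x, y = table$y)
  rownames(m) <- table$id
  m
}

#' Logical mask of free (interneuron) rows
#'
#' @param table a [neuron_table()].
#' @param extra_fixed character vector of interneuron ids to anchor in
#'   addition to all motor and sensory neurons.
#' @return logical vector, `TRUE` for anchored rows.
#' @export
fixed_mask_of <- function(table, extra_fixed = character()) {
  unknown <- setdiff(extra_fixed, table$id)
  if (length(unknown)) {
    stop("extra_fixed ids not in table: ", paste(unknown, collapse = ", "))
  }
  cls <- table$class[match(extra_fixed, table$id)]
  if (any(cls != "inter")) {
    stop("extra_fixed ids must be interneurons: ",
         paste(extra_fixed[cls != "inter"], collapse = ", "))
  }
  table$class != "inter" | table$id %in% extra_fixed
}

#' Read a neuron position table from TSV
#'
#' Expects a tab-separated file with header columns `neuron_id`, `class`,
#' `x_mm`, `y_mm`. Row order is preserved and becomes the canonical index.
#'
#' @param path file path.
#' @return A [neuron_table()].
#' @export
read_positions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("neuron_id", "class", "x_mm", "y_mm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("positions file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  xs <- suppressWarnings(as.numeric(df$x_mm))
  ys <- suppressWarnings(as.numeric(df$y_mm))
  bad <- which(is.na(xs) | is.na(ys))
  if (length(bad)) {
    stop("non-numeric coordinate at row ", bad[1])
  }
  neuron_table(df$neuron_id, df$class, xs, ys)
}

#' Write a neuron position table to TSV
#'
#' Inverse of [read_positions()].
#'
#' @param table a [neuron_table()].
#' @param path file path.
#' @export
write_positions <- function(table, path) {
  df <- data.frame(neuron_id = table$id, class = table$class,
                   x_mm = table$x, y_mm = table$y)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct connectivity data
#'
#' Chemical connections are directed with synapse counts `nsyn(ij)`;
#' electrical (gap-junction) connections are symmetric with counts
#' `ngap(ij)`. Both matrices have zero diagonals and align with a
#' [neuron_table()] row order.
#'
#' @param chem n x n nonnegative integer matrix of synapse counts (directed).
#' @param elec n x n nonnegative integer matrix of gap-junction counts
#'   (must be symmetric).
#' @param ids optional character vector of neuron ids (dimnames).
#' @return A `connectivity` object (list with `n`, `ids`, `chem`, `elec`).
#' @export
connectivity <- function(chem, elec, ids = NULL) {
  chem <- as.matrix(chem)
  elec <- as.matrix(elec)
  n <- nrow(chem)
  stopifnot(ncol(chem) == n, nrow(elec) == n, ncol(elec) == n)
  if (is.null(ids)) ids <- rownames(chem)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (any(chem < 0) || any(elec < 0)) stop("connection counts must be nonnegative")
  if (any(chem != round(chem)) || any(elec != round(elec))) {
    stop("connection counts must be integers")
  }
  if (!isTRUE(all.equal(elec, t(elec)))) {
    stop("electrical connectivity matrix must be symmetric")
  }
  if (any(diag(chem) != 0) || any(diag(elec) != 0)) {
    stop("self-connections are not allowed (nonzero diagonal)")
  }
  dimnames(chem) <- dimnames(elec) <- list(ids, ids)
  structure(list(n = n, ids = ids, chem = chem, elec = elec),
            class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf(
    "connectivity: %d neurons, %d chemical links (%d synapses), %d electrical connections (%d gap junctions)\n",
    x$n, sum(x$chem > 0), sum(x$chem),
    sum(x$elec > 0) / 2, sum(x$elec) / 2))
  invisible(x)
}

#' Read an edge list into connectivity matrices
#'
#' Expects a CSV with header columns `pre`, `post`, `type` (one of
#' `chem`, `gap`) and optionally `count` (positive integer, default 1).
#' Chemical rows accumulate: repeated `pre,post,chem` rows sum their
#' counts. A gap row (i, j, c) sets both `elec[i,j]` and `elec[j,i]` to
#' c; listing the same unordered gap pair again with the same count is
#' tolerated (set semantics), with a conflicting count it is an error.
#'
#' @param path file path.
#' @param table the [neuron_table()] defining the canonical index; edge
#'   files reference ids, never indices.
#' @return A [connectivity()] object.
#' @export
read_edges <- function(path, table) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pre", "post", "type")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("edges file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(df$count)) df$count <- 1L
  n <- nrow(table)
  ids <- table$id
  chem <- matrix(0, n, n, dimnames = list(ids, ids))
  elec <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(df) == 0) return(connectivity(chem, elec, ids))

  i <- match(df$pre, ids)
  j <- match(df$post, ids)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(df$pre[is.na(i)], df$post[is.na(j)]))
    stop("edge references unknown neuron id(s): ", paste(bad, collapse = ", "))
  }
  cnt <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(cnt) | cnt <= 0 | cnt != round(cnt))
  if (length(bad)) stop("nonpositive or non-integer count at row ", bad[1])
  self <- which(i == j)
  if (length(self)) stop("self-edge at row ", self[1])
  bad_type <- which(!df$type %in% c("chem", "gap"))
  if (length(bad_type)) {
    stop("unknown edge type '", df$type[bad_type[1]], "' at row ", bad_type[1])
  }

  is_chem <- df$type == "chem"
  for (r in which(is_chem)) {
    chem[i[r], j[r]] <- chem[i[r], j[r]] + cnt[r]
  }
  gap_rows <- which(!is_chem)
  if (length(gap_rows)) {
    key <- paste(pmin(i[gap_rows], j[gap_rows]), pmax(i[gap_rows], j[gap_rows]))
    for (k in split(gap_rows, key)) {
      if (length(unique(cnt[k])) > 1) {
        stop("conflicting gap-junction counts for pair ",
             df$pre[k[1]], "--", df$post[k[1]], " (rows ",
             paste(k, collapse = ", "), ")")
      }
      elec[i[k[1]], j[k[1]]] <- cnt[k[1]]
      elec[j[k[1]], i[k[1]]] <- cnt[k[1]]
    }
  }
  connectivity(chem, elec, ids)
}

#' Write connectivity data as an edge list CSV
#'
#' Inverse of [read_edges()]: chemical entries become directed `chem`
#' rows; each electrical connection becomes one `gap` row (upper
#' triangle).
#'
#' @param conn a [connectivity()] object.
#' @param path file path.
#' @export
write_edges <- function(conn, path) {
  ch <- which(conn$chem > 0, arr.ind = TRUE)
  el <- which(conn$elec > 0 & upper.tri(conn$elec), arr.ind = TRUE)
  df <- rbind(
    if (nrow(ch)) data.frame(pre = conn$ids[ch[, 1]], post = conn$ids[ch[, 2]],
                             type = "chem", count = conn$chem[ch]),
    if (nrow(el)) data.frame(pre = conn$ids[el[, 1]], post = conn$ids[el[, 2]],
                             type = "gap", count = conn$elec[el]))
  if (is.null(df)) {
    df <- data.frame(pre = character(), post = character(),
                     type = character(), count = integer())
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Define a connection weighting scheme
#'
#' Four ways of turning chemical/electrical connectivity into the link
#' weights of the wiring-length objective:
#' \describe{
#'   \item{unit_joint}{every connection has unit weight regardless of
#'     type: \eqn{A = A^{ch} + 0.5 A^{el}} on indicator matrices, so an
#'     entry is one of 0, 0.5, 1, 1.5. The electrical half compensates
#'     for each electrical connection appearing twice in the symmetric
#'     indicator matrix, so it contributes once in total.}
#'   \item{synapse_counts}{weights are synapse / gap-junction counts:
#'     \eqn{A = nsyn + 0.5\, ngap}, retaining the same halving
#'     convention for the symmetric electrical counts.}
#'   \item{binary_union}{\eqn{A_{ij} = 1} if any connection (either
#'     type, any multiplicity) exists from i to j or electrically
#'     between them.}
#'   \item{scaled}{type-specific weights on indicators:
#'     \eqn{A = c_{ch} A^{ch} + 0.5\, c_{el} A^{el}}; e.g.
#'     `scaled(1, 0)` silences electrical links.}
#' }
#'
#' @param mode one of `"unit_joint"`, `"synapse_counts"`,
#'   `"binary_union"`, `"scaled"`.
#' @param chem_scale,elec_scale nonnegative scales (scaled mode).
#' @param elec_factor factor applied to the symmetric electrical matrix
#'   so each electrical connection is counted once in the ordered-pair
#'   sum; 0.5 by default, configurable for count-weighted variants.
#' @return A `weight_scheme` object.
#' @export
weight_scheme <- function(mode = c("unit_joint", "synapse_counts",
                                   "binary_union", "scaled"),
                          chem_scale = 1, elec_scale = 1,
                          elec_factor = 0.5) {
  mode <- match.arg(mode)
  stopifnot(chem_scale >= 0, elec_scale >= 0, elec_factor >= 0)
  structure(list(mode = mode, chem_scale = chem_scale,
                 elec_scale = elec_scale, elec_factor = elec_factor),
            class = "weight_scheme")
}

#' @export
format.weight_scheme <- function(x, ...) {
  if (x$mode == "scaled") {
    sprintf("scaled(%g,%g)", x$chem_scale, x$elec_scale)
  } else {
    x$mode
  }
}

#' @export
print.weight_scheme <- function(x, ...) {
  cat("weight_scheme:", format(x), "\n")
  invisible(x)
}

#' Build the weight matrix for a connectivity under a scheme
#'
#' @param conn a [connectivity()] object.
#' @param scheme a [weight_scheme()].
#' @return n x n nonnegative weight matrix with zero diagonal; entry ij
#'   is the weight of the directed link i -> j in the wiring-length sum.
#' @export
build_weights <- function(conn, scheme = weight_scheme("unit_joint")) {
  stopifnot(inherits(conn, "connectivity"), inherits(scheme, "weight_scheme"))
  ch_ind <- (conn$chem > 0) * 1
  el_ind <- (conn$elec > 0) * 1
  h <- scheme$elec_factor
  w <- switch(scheme$mode,
    unit_joint     = ch_ind + h * el_ind,
    synapse_counts = conn$chem + h * conn$elec,
    binary_union   = ((conn$chem > 0) | (conn$elec > 0)) * 1,
    scaled         = scheme$chem_scale * ch_ind + h * scheme$elec_scale * el_ind)
  dimnames(w) <- list(conn$ids, conn$ids)
  w
}
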