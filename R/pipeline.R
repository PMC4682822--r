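#' Per-neuron displacement between reference and optimized layouts
#'
#' Displacements are reported in plain Euclidean mm regardless of the
#' optimization cost, since averages of powered-norm displacements
#' carry different units and mislead when compared across costs.
#'
#' @param real,opt conformable n x 2 layouts (mm).
#' @param free_mask logical vector: rows whose displacement is of
#'   interest (fixed rows displace by exactly 0).
#' @param bin_width histogram bin width in mm (half-open bins
#'   `[k*w, (k+1)*w)`).
#' @param ids optional labels for the free rows.
#' @return A `displacement_summary`: `displacement` (named, free rows),
#'   `mean`, `bin_width`, `counts` (named by bin lower edge).
#' @export
displacement_distribution <- function(real, opt, free_mask,
                                      bin_width = 0.05, ids = NULL) {
  real <- as.matrix(real)
  opt <- as.matrix(opt)
  stopifnot(all(dim(real) == dim(opt)), length(free_mask) == nrow(real))
  if (is.null(ids)) ids <- rownames(real)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(real)))
  d <- sqrt(rowSums((real - opt)^2))[free_mask]
  names(d) <- ids[free_mask]
  bins <- floor(d / bin_width)
  counts <- table(factor(bins, levels = 0:max(bins, 0)))
  names(counts) <- sprintf("%g", as.numeric(names(counts)) * bin_width)
  structure(list(displacement = d, mean = if (length(d)) mean(d) else 0,
                 bin_width = bin_width, counts = counts),
            class = "displacement_summary")
}

#' @export
print.displacement_summary <- function(x, ...) {
  cat(sprintf("displacement_summary: %d free neurons, mean %.4g mm, bin width %g mm\n",
              length(x$displacement), x$mean, x$bin_width))
  invisible(x)
}

#' Detect displacement outliers by the largest gap in sorted displacements
#'
#' A bimodal displacement distribution (most neurons barely move, a
#' well-separated group travels far) shows up as a wide empty band in
#' the sorted displacements. This finds the largest gap between
#' consecutive sorted values; if it exceeds `gap_threshold`, every
#' neuron above the gap is flagged.
#'
#' @param summary a [displacement_distribution()] result.
#' @param gap_threshold minimum gap width in mm (default 0.2).
#' @return character vector of flagged ids (possibly empty).
#' @export
detect_outliers <- function(summary, gap_threshold = 0.2) {
  stopifnot(inherits(summary, "displacement_summary"),
            length(summary$displacement) > 0)
  d <- sort(summary$displacement)
  if (length(d) < 2) return(character(0))
  gaps <- diff(d)
  k <- which.max(gaps)
  if (gaps[k] <= gap_threshold) return(character(0))
  names(d)[(k + 1):length(d)]
}

#' Derived comparison statistics of a scenario
#'
#' The identities tying together the three wiring lengths a scenario
#' produces: \code{reduction_abs = twl_real - twl_opt},
#' \code{reduction_pct = 100 * reduction_abs / twl_real},
#' \code{pct_below_random = 100 * (twl_random_mean - twl_real) /
#' twl_random_mean} (how far the real TWL sits below the random mean)
#' and \code{pct_above_real = 100 * (twl_random_mean - twl_real) /
#' twl_real} (how much bigger the random mean is than the real TWL).
#'
#' @param twl_real,twl_opt real and optimal total wiring lengths.
#' @param twl_random_mean optional Monte-Carlo random-layout mean.
#' @return named list of the derived statistics (random-based entries
#'   are `NA` when no random mean is given).
#' @export
comparison_stats <- function(twl_real, twl_opt, twl_random_mean = NA_real_) {
  stopifnot(twl_real > 0)
  list(reduction_abs = twl_real - twl_opt,
       reduction_pct = 100 * (twl_real - twl_opt) / twl_real,
       pct_below_random = 100 * (twl_random_mean - twl_real) / twl_random_mean,
       pct_above_real = 100 * (twl_random_mean - twl_real) / twl_real)
}

#' Run one optimal-vs-real-vs-random comparison scenario
#'
#' Anchors all motor and sensory neurons (plus any `extra_fixed`
#' interneurons) at their real positions, minimizes the total wiring
#' length over the remaining interneurons, and derives the comparison
#' statistics: absolute and relative TWL reduction, optionally the
#' Monte-Carlo random-layout mean and how far the real TWL sits below
#' it, the displacement distribution and its gap outliers.
#'
#' @param table a [neuron_table()] with the real layout.
#' @param conn a [connectivity()] object.
#' @param spec cost function ([norm_spec()] or shorthand).
#' @param scheme a [weight_scheme()].
#' @param extra_fixed interneuron ids anchored in addition to
#'   motor/sensory neurons.
#' @param with_random also run the [random_baseline()]?
#' @param n_iter,seed,region Monte-Carlo settings.
#' @param gap_threshold outlier gap threshold, mm.
#' @param min_distance optional minimal inter-neuron distance, mm; if
#'   the string `"auto"`, the minimum pairwise distance of the real
#'   layout is used.
#' @return A `scenario_report` (see Details for fields).
#' @details Fields: `norm`, `scheme`, `fixed_set`, `twl_real`,
#'   `twl_opt`, `twl_random_mean`, `reduction_abs = twl_real - twl_opt`,
#'   `reduction_pct = 100 * reduction_abs / twl_real`,
#'   `pct_below_random = 100 * (twl_random_mean - twl_real) /
#'   twl_random_mean`, `mean_displacement` (Euclidean mm),
#'   `mean_displacement_pct_body` (percent of the anterior-posterior
#'   anchor span), `mean_displacement_spec` (in the cost's own units),
#'   `displacement` summary, `outlier_ids`, `solution`.
#' @export
run_scenario <- function(table, conn, spec = "l2",
                         scheme = weight_scheme("unit_joint"),
                         extra_fixed = character(), with_random = FALSE,
                         n_iter = 1000, seed = 1, region = "bbox",
                         gap_threshold = 0.2, min_distance = NULL) {
  spec <- as_norm_spec(spec)
  w <- build_weights(conn, scheme)
  fixed <- fixed_mask_of(table, extra_fixed)
  real <- layout_of(table)
  if (identical(min_distance, "auto")) {
    dr <- stats::dist(real)
    min_distance <- min(dr)
  }
  problem <- placement_problem(w, fixed, real, spec,
                               min_distance = min_distance, ids = table$id)
  sol <- solve_placement(problem)
  twl_real <- total_wiring_length(real, w, spec)
  twl_opt <- sol$objective
  disp <- displacement_distribution(real, sol$layout, !fixed, ids = table$id)
  spec_disp <- if (length(problem$free)) {
    dd <- disp$displacement
    if (spec$family == "l1") {
      mean(rowSums(abs(real - sol$layout))[!fixed])
    } else {
      mean(dd^spec$power)
    }
  } else 0
  body_len <- diff(range(real[fixed, 1]))
  rb <- NULL
  if (with_random) {
    rb <- random_baseline(problem, real, n_iter = n_iter, seed = seed,
                          region = region)
  }
  cs <- comparison_stats(twl_real, twl_opt,
                         if (is.null(rb)) NA_real_ else rb$mean_twl)
  structure(list(
    norm = spec, scheme = scheme,
    fixed_set = sprintf("motor+sensory%s",
                        if (length(extra_fixed))
                          paste0("+", length(extra_fixed), " extra") else ""),
    extra_fixed = extra_fixed,
    twl_real = twl_real, twl_opt = twl_opt,
    twl_random_mean = if (is.null(rb)) NA_real_ else rb$mean_twl,
    twl_random_sd = if (is.null(rb)) NA_real_ else rb$sd_twl,
    reduction_abs = cs$reduction_abs,
    reduction_pct = cs$reduction_pct,
    pct_below_random = cs$pct_below_random,
    pct_above_real = cs$pct_above_real,
    mean_displacement = disp$mean,
    mean_displacement_pct_body = if (body_len > 0) 100 * disp$mean / body_len
                                 else NA_real_,
    mean_displacement_spec = spec_disp,
    displacement = disp,
    outlier_ids = if (length(problem$free))
      detect_outliers(disp, gap_threshold) else character(0),
    baseline = rb, solution = sol, seed = seed),
    class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("scenario_report [%s, %s, %s]\n", format(x$norm),
              format(x$scheme), x$fixed_set))
  cat(sprintf("  TWL real %.6g, optimal %.6g  (reduction %.4g = %.2f%%)\n",
              x$twl_real, x$twl_opt, x$reduction_abs, x$reduction_pct))
  if (!is.na(x$twl_random_mean)) {
    cat(sprintf("  random mean %.6g; real is %.2f%% below random\n",
                x$twl_random_mean, x$pct_below_random))
  }
  cat(sprintf("  mean displacement %.4g mm", x$mean_displacement))
  if (!is.na(x$mean_displacement_pct_body)) {
    cat(sprintf(" (%.2f%% of body length)", x$mean_displacement_pct_body))
  }
  cat("\n")
  if (length(x$outlier_ids)) {
    cat("  displacement outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sweep connection weighting schemes over one instance
#'
#' Runs [run_scenario()] once per scheme with the same anchoring, and
#' computes the mean Euclidean displacement between the optimal layouts
#' of every pair of schemes (averaged over free neurons) — the natural
#' measure of how much a re-weighting moves the optimum.
#'
#' @param table,conn,spec as in [run_scenario()].
#' @param schemes list of [weight_scheme()] objects.
#' @param ... further arguments passed to [run_scenario()].
#' @return list with `reports` (one per scheme, named) and
#'   `pairwise_mean_displacement` (symmetric matrix, mm).
#' @export
weight_scheme_sweep <- function(table, conn, spec = "l2", schemes, ...) {
  stopifnot(length(schemes) >= 1)
  reports <- lapply(schemes, function(s)
    run_scenario(table, conn, spec = spec, scheme = s, ...))
  labs <- vapply(schemes, format, "")
  names(reports) <- make.unique(labs)
  k <- length(reports)
  free <- table$class == "inter"
  pmd <- matrix(0, k, k, dimnames = list(names(reports), names(reports)))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (a < b) {
      la <- reports[[a]]$solution$layout
      lb <- reports[[b]]$solution$layout
      pmd[a, b] <- pmd[b, a] <-
        mean(sqrt(rowSums((la - lb)^2))[free])
    }
  }
  list(reports = reports, pairwise_mean_displacement = pmd)
}
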