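#' Define an anchored placement problem
#'
#' The optimization state: a weight matrix over all neurons, a mask of
#' anchored (fixed) rows, reference coordinates, and the connection cost
#' function. Free rows are the optimization variables; their entries in
#' `coords` serve as the reference layout (and as the resting position
#' of free neurons with no connections). An optional minimal
#' inter-neuron distance turns the convex problem into a locally solved
#' constrained one (see [solve_with_min_distance()]).
#'
#' Every free neuron should be connected, through the weighted graph, to
#' some anchored neuron, otherwise its optimum is undefined; violations
#' are flagged with a warning here and are an error in the solvers.
#'
#' @param weights n x n nonnegative weight matrix ([build_weights()]).
#' @param fixed logical vector of length n, `TRUE` for anchored rows.
#' @param coords n x 2 coordinate matrix in mm (anchors at their fixed
#'   positions; free rows give the reference layout).
#' @param spec a [norm_spec()] or shorthand string.
#' @param min_distance optional nonnegative scalar, mm.
#' @param ids optional neuron labels for diagnostics.
#' @return A `placement_problem` object.
#' @export
placement_problem <- function(weights, fixed, coords, spec = "l2",
                              min_distance = NULL, ids = NULL) {
  weights <- as.matrix(weights)
  coords <- as.matrix(coords)
  n <- nrow(weights)
  stopifnot(ncol(weights) == n, length(fixed) == n, is.logical(fixed),
            nrow(coords) == n, ncol(coords) == 2, all(is.finite(coords)),
            all(weights >= 0))
  spec <- as_norm_spec(spec)
  if (!is.null(min_distance)) stopifnot(min_distance >= 0)
  if (is.null(ids)) ids <- rownames(weights)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  u <- weights + t(weights)          # the objective only sees symmetric structure
  free <- which(!fixed)
  iso <- free[rowSums(u)[free] == 0]
  solve_set <- setdiff(free, iso)
  unanchored <- integer(0)
  if (length(solve_set)) {
    if (!any(fixed)) {
      unanchored <- solve_set
    } else {
      reach <- reachable_from(u, which(fixed))
      unanchored <- setdiff(solve_set, reach)
    }
    if (length(unanchored)) {
      warning("free neuron(s) with no weighted path to an anchor: ",
              paste(ids[unanchored], collapse = ", "))
    }
  }
  anchor_span <- if (any(fixed)) {
    max(apply(coords[fixed, , drop = FALSE], 2,
              function(z) diff(range(z))))
  } else 0
  structure(list(weights = weights, u = u, fixed = fixed, coords = coords,
                 spec = spec, min_distance = min_distance, ids = ids,
                 n = n, free = free, iso = iso, solve_set = solve_set,
                 unanchored = unanchored,
                 scale = max(anchor_span, max(abs(coords)), 1e-8)),
            class = "placement_problem")
}

#' @export
print.placement_problem <- function(x, ...) {
  cat(sprintf("placement_problem: %d neurons (%d fixed, %d free), cost %s%s\n",
              x$n, sum(x$fixed), length(x$free), format(x$spec),
              if (is.null(x$min_distance)) ""
              else sprintf(", min distance %g mm", x$min_distance)))
  invisible(x)
}

new_solution <- function(problem, layout, converged, iterations, solver,
                         diagnostics = list()) {
  layout[problem$fixed, ] <- problem$coords[problem$fixed, ]  # bit-identical anchors
  obj <- total_wiring_length(layout, problem$weights, problem$spec)
  structure(list(layout = layout, objective = obj, converged = converged,
                 iterations = iterations, solver = solver,
                 diagnostics = diagnostics),
            class = "wiring_solution")
}

#' @export
print.wiring_solution <- function(x, ...) {
  cat(sprintf("wiring_solution (%s): objective %.6g, %d iterations, converged: %s\n",
              x$solver, x$objective, x$iterations, x$converged))
  invisible(x)
}

# error if some free component has no weighted path to an anchor
assert_anchored <- function(problem) {
  if (length(problem$unanchored)) {
    comps <- components_of(problem$u, problem$unanchored)
    stop("disconnected free component(s), placement undefined: ",
         paste(vapply(comps, function(cc)
           paste(problem$ids[cc], collapse = "+"), ""), collapse = "; "))
  }
}

# Solve the anchored quadratic: minimize sum_ij q_ij ||x_i - x_j||^2 / 2 over
# rows `solve_set`, everything else held at `coords`. q is symmetric with
# nonnegative entries; one sparse linear system, both coordinates as RHS.
anchored_quadratic_solve <- function(q, solve_set, coords) {
  if (!length(solve_set)) return(coords)
  rest <- setdiff(seq_len(nrow(q)), solve_set)
  Q <- Matrix::Matrix(q, sparse = TRUE)
  s <- Matrix::rowSums(Q)[solve_set]
  L <- Matrix::Diagonal(x = s) - Q[solve_set, solve_set, drop = FALSE]
  rhs <- Q[solve_set, rest, drop = FALSE] %*% coords[rest, , drop = FALSE]
  sol <- Matrix::solve(L, rhs)
  coords[solve_set, ] <- as.matrix(sol)
  coords
}

#' Exact minimizer under the squared Euclidean cost
#'
#' With squared-Euclidean link costs the objective is a positive
#' semidefinite quadratic in the free coordinates; the global minimum is
#' the solution of the anchored graph-Laplacian system
#' \eqn{x_i \sum_j u_{ij} = \sum_j u_{ij} x_j} (with
#' \eqn{u = W + W^T}) for each free neuron i, solved exactly as one
#' sparse linear system per coordinate. Free neurons with zero total
#' weight keep their input position and are reported in
#' `diagnostics$isolated`.
#'
#' @param problem a [placement_problem()] with spec `"sq"`.
#' @return A `wiring_solution`: `layout`, `objective`, `converged`,
#'   `iterations`, `solver`, `diagnostics` (with the max stationarity
#'   residual).
#' @export
solve_squared_l2 <- function(problem) {
  stopifnot(inherits(problem, "placement_problem"),
            problem$spec$family == "euclidean", problem$spec$power == 2L)
  assert_anchored(problem)
  X <- anchored_quadratic_solve(problem$u, problem$solve_set, problem$coords)
  res <- stationarity_residual(problem, X)
  new_solution(problem, X, converged = TRUE, iterations = 1L,
               solver = "anchored_laplacian",
               diagnostics = list(isolated = problem$ids[problem$iso],
                                  stationarity_residual = res))
}

# max_i ||x_i * sum_j u_ij - sum_j u_ij x_j|| over free solve-set rows
stationarity_residual <- function(problem, X) {
  F <- problem$solve_set
  if (!length(F)) return(0)
  u <- problem$u
  s <- rowSums(u)[F]
  R <- X[F, , drop = FALSE] * s - (u %*% X)[F, , drop = FALSE]
  max(sqrt(rowSums(R^2)))
}

# Smoothed objective and IRLS pair-coefficients for the Euclidean (power 1)
# cost: sum over unordered pairs of u_ij * sqrt(d_ij^2 + eps^2).
smoothed_l2_objective <- function(u, X, eps) {
  d <- as.matrix(stats::dist(X))
  sum(u * sqrt(d^2 + eps^2)) / 2
}

#' Weber (Euclidean-cost) placement via iteratively reweighted least squares
#'
#' Minimizes the sum of weighted Euclidean link lengths over the free
#' coordinates — a multifacility Weber problem with anchors. The solver
#' smooths each length to \eqn{\sqrt{d^2 + \varepsilon^2}} and solves
#' the resulting weighted quadratic repeatedly (IRLS, the multifacility
#' form of Weiszfeld's algorithm), driving the smoothing parameter down
#' to `1e-12` of the problem scale. Convergence: relative objective
#' change below `1e-10` across an iteration at the final smoothing.
#'
#' @param problem a [placement_problem()] with spec `"l2"`.
#' @param max_iter iteration cap; exceeded returns best layout with
#'   `converged = FALSE`.
#' @return A `wiring_solution`.
#' @export
solve_weber_l2 <- function(problem, max_iter = 1e4) {
  stopifnot(inherits(problem, "placement_problem"),
            problem$spec$family == "euclidean", problem$spec$power == 1L)
  assert_anchored(problem)
  u <- problem$u
  F <- problem$solve_set
  if (!length(F)) {
    return(new_solution(problem, problem$coords, TRUE, 0L, "weber_irls",
                        list(isolated = problem$ids[problem$iso])))
  }
  # warm start from the quadratic optimum
  X <- anchored_quadratic_solve(u, F, problem$coords)
  eps <- 1e-3 * problem$scale
  eps_min <- 1e-12 * problem$scale
  obj <- smoothed_l2_objective(u, X, eps)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    d <- as.matrix(stats::dist(X))
    q <- u / sqrt(d^2 + eps^2)
    diag(q) <- 0
    X <- anchored_quadratic_solve(q, F, problem$coords)
    obj_new <- smoothed_l2_objective(u, X, eps)
    if (abs(obj - obj_new) <= 1e-10 * max(obj_new, .Machine$double.eps)) {
      if (eps <= eps_min) { converged <- TRUE; break }
      eps <- max(eps / 100, eps_min)
      obj_new <- smoothed_l2_objective(u, X, eps)
    }
    obj <- obj_new
  }
  new_solution(problem, X, converged, iter, "weber_irls",
               list(isolated = problem$ids[problem$iso], eps_final = eps))
}

# exact 1D objective for one axis: sum over unordered pairs u_ij |z_i - z_j|
l1_axis_objective <- function(u, z) {
  sum(u * abs(outer(z, z, "-"))) / 2
}

#' L1 (Manhattan-cost) placement by separable weighted-median descent
#'
#' The l1 cost separates by coordinate: the x- and y-problems are
#' independent one-dimensional weighted absolute-deviation
#' minimizations. Each axis is solved by smoothed IRLS followed by
#' weighted-median coordinate-descent polish; a single free neuron is
#' solved exactly by the weighted median (degenerate median intervals
#' resolve to the interval midpoint, for determinism).
#'
#' @param problem a [placement_problem()] with spec `"l1"`.
#' @param max_iter IRLS iteration cap per axis.
#' @param polish_passes cap on coordinate-descent sweeps per axis.
#' @return A `wiring_solution`.
#' @export
solve_l1 <- function(problem, max_iter = 1e4, polish_passes = 200) {
  stopifnot(inherits(problem, "placement_problem"),
            problem$spec$family == "l1")
  assert_anchored(problem)
  u <- problem$u
  F <- problem$solve_set
  X <- problem$coords
  total_iter <- 0L
  converged <- TRUE
  for (axis in 1:2) {
    z <- X[, axis]
    if (!length(F)) break
    if (length(F) == 1L) {
      nb <- which(u[F, ] > 0)
      z[F] <- weighted_median(z[nb], u[F, nb])
    } else {
      # IRLS on the smoothed 1D absolute deviations; the median polish below
      # supplies the exact vertex solution, so a coarser smoothing floor is enough
      eps <- 1e-3 * problem$scale
      eps_min <- 1e-8 * problem$scale
      obj <- sum(u * sqrt(outer(z, z, "-")^2 + eps^2)) / 2
      iter <- 0L
      ok <- FALSE
      while (iter < max_iter) {
        iter <- iter + 1L
        q <- u / sqrt(outer(z, z, "-")^2 + eps^2)
        diag(q) <- 0
        z1 <- anchored_quadratic_solve(q, F, cbind(z, 0))[, 1]
        obj_new <- sum(u * sqrt(outer(z1, z1, "-")^2 + eps^2)) / 2
        z <- z1
        if (abs(obj - obj_new) <= 1e-12 * max(obj_new, .Machine$double.eps)) {
          if (eps <= eps_min) { ok <- TRUE; break }
          eps <- max(eps / 100, eps_min)
          obj_new <- sum(u * sqrt(outer(z, z, "-")^2 + eps^2)) / 2
        }
        obj <- obj_new
      }
      converged <- converged && ok
      total_iter <- total_iter + iter
      # polish to a vertex solution: weighted-median coordinate descent
      best <- l1_axis_objective(u, z)
      for (pass in seq_len(polish_passes)) {
        for (i in F) {
          nb <- which(u[i, ] > 0)
          z[i] <- weighted_median(z[nb], u[i, nb])
        }
        cur <- l1_axis_objective(u, z)
        if (best - cur <= 1e-13 * max(best, 1)) { best <- cur; break }
        best <- cur
      }
    }
    X[, axis] <- z
  }
  new_solution(problem, X, converged, max(total_iter, 1L), "l1_median",
               list(isolated = problem$ids[problem$iso]))
}

# objective and gradient of the powered-Euclidean cost over the free rows
power_obj_grad <- function(u, X, F, p) {
  d <- as.matrix(stats::dist(X))
  obj <- sum(u * d^p) / 2
  G <- p * u * d^(p - 2)         # 0^0 == 1 handles p == 2 at coincidence
  if (p < 2) diag(G) <- 0
  gx <- X[F, , drop = FALSE] * rowSums(G)[F] - (G %*% X)[F, , drop = FALSE]
  list(obj = obj, grad = gx)
}

#' Placement under higher powers of the Euclidean norm
#'
#' Minimizes the sum of weighted p-th powers of Euclidean link lengths
#' (p = 2, 3 or 4 — all smooth convex costs) by limited-memory BFGS with
#' analytic gradients, warm-started from the squared-Euclidean solution.
#' Stops when the largest free-neuron gradient norm falls below
#' `1e-10` of problem scale times total weight (restarting the line
#' search a few times if needed).
#'
#' @param problem a [placement_problem()] with spec `"sq"`, `"p3"` or `"p4"`.
#' @param max_restarts BFGS restarts before giving up.
#' @return A `wiring_solution`.
#' @export
solve_power_p <- function(problem, max_restarts = 6) {
  stopifnot(inherits(problem, "placement_problem"),
            problem$spec$family == "euclidean", problem$spec$power %in% 2:4)
  assert_anchored(problem)
  p <- as.numeric(problem$spec$power)
  u <- problem$u
  F <- problem$solve_set
  X <- anchored_quadratic_solve(u, F, problem$coords)  # warm start (exact for p = 2)
  if (!length(F)) {
    return(new_solution(problem, X, TRUE, 0L, "power_lbfgs",
                        list(isolated = problem$ids[problem$iso])))
  }
  gtol <- 1e-10 * problem$scale * max(sum(u) / 2, 1)
  fn <- function(par) {
    X[F, ] <- matrix(par, ncol = 2)
    power_obj_grad(u, X, F, p)$obj
  }
  gr <- function(par) {
    X[F, ] <- matrix(par, ncol = 2)
    as.vector(power_obj_grad(u, X, F, p)$grad)
  }
  par <- as.vector(X[F, , drop = FALSE])
  iters <- 0L
  converged <- FALSE
  for (r in seq_len(max_restarts)) {
    fit <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = 1000, factr = 1e1, pgtol = 0))
    par <- fit$par
    iters <- iters + fit$counts[["function"]]
    gnorm <- max(abs(gr(par)))
    if (gnorm <= gtol) { converged <- TRUE; break }
  }
  X[F, ] <- matrix(par, ncol = 2)
  new_solution(problem, X, converged, iters, "power_lbfgs",
               list(isolated = problem$ids[problem$iso],
                    grad_inf_norm = max(abs(gr(par)))))
}

# smoothed cost objective+gradient for any spec (used by the penalty solver)
smooth_cost_obj_grad <- function(problem, X, eps) {
  u <- problem$u
  F <- problem$solve_set
  if (problem$spec$family == "l1") {
    obj <- 0
    gx <- matrix(0, length(F), 2)
    for (axis in 1:2) {
      dz <- outer(X[, axis], X[, axis], "-")
      sm <- sqrt(dz^2 + eps^2)
      obj <- obj + sum(u * sm) / 2
      G <- u * dz / sm
      gx[, axis] <- rowSums(G)[F]
    }
    return(list(obj = obj, grad = gx))
  }
  p <- as.numeric(problem$spec$power)
  d <- as.matrix(stats::dist(X))
  if (p == 1) {
    sm <- sqrt(d^2 + eps^2)
    obj <- sum(u * sm) / 2
    G <- u / sm
    diag(G) <- 0
  } else {
    obj <- sum(u * d^p) / 2
    G <- p * u * d^(p - 2)
  }
  gx <- X[F, , drop = FALSE] * rowSums(G)[F] - (G %*% X)[F, , drop = FALSE]
  list(obj = obj, grad = gx)
}

#' Refine a solution under a minimal inter-neuron distance constraint
#'
#' Soma size imposes a floor on how close two cells can sit; enforcing
#' pairwise distance >= `min_distance` for every pair involving a free
#' neuron makes the problem non-convex, but a local optimum is found by
#' quadratic-penalty iterations started from the unconstrained solution.
#' The penalty weight escalates until all constraints hold to within
#' `1e-9 * min_distance`. If the warm start already satisfies every
#' constraint it is returned unchanged.
#'
#' @param problem a [placement_problem()] with `min_distance` set.
#' @param warm the unconstrained `wiring_solution` for the same problem.
#' @param bounds optional 2 x 2 matrix `rbind(lower, upper)` clamping
#'   free coordinates to a body bounding box during the refinement.
#' @param max_escalations penalty escalations before declaring the
#'   instance infeasible.
#' @return A `wiring_solution`; its objective is never below `warm`'s
#'   when the constraint binds.
#' @export
solve_with_min_distance <- function(problem, warm, bounds = NULL,
                                    max_escalations = 30) {
  stopifnot(inherits(problem, "placement_problem"),
            !is.null(problem$min_distance),
            inherits(warm, "wiring_solution"))
  delta <- problem$min_distance
  F <- problem$free
  n <- problem$n
  involves_free <- outer(seq_len(n) %in% F, seq_len(n) %in% F, "|")
  diag(involves_free) <- FALSE
  min_pair <- function(X) {
    d <- as.matrix(stats::dist(X))
    min(d[involves_free])
  }
  if (delta == 0 || min_pair(warm$layout) >= delta * (1 - 1e-12)) {
    return(warm)
  }
  X <- warm$layout
  # coincident violating pairs have a zero penalty gradient: nudge free nodes
  d0 <- as.matrix(stats::dist(X))
  coincident <- which(involves_free & d0 < 1e-12 * problem$scale, arr.ind = TRUE)
  if (nrow(coincident)) {
    for (k in seq_len(nrow(coincident))) {
      i <- coincident[k, 1]
      if (i %in% F) {
        ang <- 2 * pi * i / n
        X[i, ] <- X[i, ] + (delta / 4) * c(cos(ang), sin(ang))
      }
    }
  }
  eps <- 1e-9 * problem$scale
  Fs <- problem$solve_set
  pen_obj_grad <- function(Xc, mu) {
    base <- smooth_cost_obj_grad(problem, Xc, eps)
    d <- as.matrix(stats::dist(Xc))
    viol <- pmax(0, delta - d)
    viol[!involves_free] <- 0
    pobj <- mu * sum(viol^2) / 2
    dpos <- pmax(d, 1e-300)
    G <- -2 * mu * viol / dpos
    gx <- Xc[Fs, , drop = FALSE] * rowSums(G)[Fs] - (G %*% Xc)[Fs, , drop = FALSE]
    list(obj = base$obj + pobj, grad = base$grad + gx)
  }
  lower <- -Inf; upper <- Inf
  if (!is.null(bounds)) {
    lower <- rep(bounds[1, ], each = length(Fs))
    upper <- rep(bounds[2, ], each = length(Fs))
  }
  mu <- max(warm$objective, 1) / delta^2
  iters <- 0L
  ok <- FALSE
  for (esc in seq_len(max_escalations)) {
    fn <- function(par) {
      X[Fs, ] <- matrix(par, ncol = 2)
      pen_obj_grad(X, mu)$obj
    }
    gr <- function(par) {
      X[Fs, ] <- matrix(par, ncol = 2)
      as.vector(pen_obj_grad(X, mu)$grad)
    }
    fit <- stats::optim(as.vector(X[Fs, , drop = FALSE]), fn, gr,
                        method = "L-BFGS-B", lower = lower, upper = upper,
                        control = list(maxit = 500, factr = 1e1))
    X[Fs, ] <- matrix(fit$par, ncol = 2)
    iters <- iters + fit$counts[["function"]]
    if (min_pair(X) >= delta * (1 - 1e-9)) { ok <- TRUE; break }
    mu <- mu * 10
  }
  if (!ok) {
    stop("min-distance refinement infeasible after penalty escalation")
  }
  new_solution(problem, X, converged = TRUE, iterations = iters,
               solver = paste0(warm$solver, "+min_dist_penalty"),
               diagnostics = list(min_pairwise = min_pair(X),
                                  penalty_mu = mu,
                                  warm_objective = warm$objective))
}

#' Solve a placement problem with the solver matching its cost function
#'
#' Dispatches to [solve_l1()], [solve_weber_l2()], [solve_squared_l2()]
#' or [solve_power_p()]; when `min_distance` is set the unconstrained
#' solution is refined by [solve_with_min_distance()].
#'
#' @param problem a [placement_problem()].
#' @param ... passed to the specific solver.
#' @return A `wiring_solution`.
#' @export
solve_placement <- function(problem, ...) {
  base_problem <- problem
  if (!is.null(problem$min_distance)) {
    base_problem <- placement_problem(problem$weights, problem$fixed,
                                      problem$coords, problem$spec,
                                      min_distance = NULL, ids = problem$ids)
  }
  warm <- if (base_problem$spec$family == "l1") {
    solve_l1(base_problem, ...)
  } else if (base_problem$spec$power == 1L) {
    solve_weber_l2(base_problem, ...)
  } else if (base_problem$spec$power == 2L) {
    solve_squared_l2(base_problem)
  } else {
    solve_power_p(base_problem, ...)
  }
  if (is.null(problem$min_distance)) return(warm)
  solve_with_min_distance(problem, warm)
}

#' Write a solution layout as TSV
#'
#' Columns: `neuron_id`, `class`, `x_opt_mm`, `y_opt_mm`,
#' `displacement_mm` (Euclidean distance to the reference layout),
#' `is_fixed`.
#'
#' @param solution a `wiring_solution`.
#' @param table the [neuron_table()] with the reference layout.
#' @param path file path.
#' @export
write_solution <- function(solution, table, path) {
  ref <- layout_of(table)
  disp <- sqrt(rowSums((solution$layout - ref)^2))
  df <- data.frame(neuron_id = table$id, class = table$class,
                   x_opt_mm = solution$layout[, 1],
                   y_opt_mm = solution$layout[, 2],
                   displacement_mm = disp,
                   is_fixed = table$class != "inter")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
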