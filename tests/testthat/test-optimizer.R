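# convenience: single-free-node problem with given anchors and weights
one_free <- function(anchors, w, spec, start = c(0.5, 0.5), min_distance = NULL) {
  n <- nrow(anchors) + 1
  W <- matrix(0, n, n)
  W[n, seq_len(n - 1)] <- w
  placement_problem(W, c(rep(TRUE, n - 1), FALSE),
                    unname(rbind(anchors, start)),
                    spec, min_distance = min_distance)
}

test_that("squared-cost solver hits the closed-form weighted averages", {
  # equal weights: midpoint
  s <- solve_squared_l2(one_free(rbind(c(0, 0), c(2, 0)), c(1, 1), "sq"))
  expect_equal(s$layout[3, ], c(1, 0), tolerance = 1e-12)
  expect_equal(s$objective, 2)
  # weights 1 and 3: weighted average 2.25
  s2 <- solve_squared_l2(one_free(rbind(c(0, 0), c(3, 0)), c(1, 3), "sq"))
  expect_equal(s2$layout[3, ], c(2.25, 0), tolerance = 1e-12)
  # chain anchor--free--free--anchor: hand-solved 2x2 system gives thirds
  W <- matrix(0, 4, 4); W[1, 2] <- 1; W[2, 3] <- 1; W[3, 4] <- 1
  co <- rbind(c(0, 0), c(0.4, 0.7), c(2.9, -0.2), c(3, 0))
  p <- placement_problem(W, c(TRUE, FALSE, FALSE, TRUE), co, "sq")
  s3 <- solve_squared_l2(p)
  expect_equal(s3$layout[2, ], c(1, 0), tolerance = 1e-10)
  expect_equal(s3$layout[3, ], c(2, 0), tolerance = 1e-10)
})

test_that("squared-cost solutions satisfy the stationarity system", {
  for (seed in 1:5) {
    inst <- small_instance(seed = seed)
    w <- build_weights(inst$conn)
    p <- placement_problem(w, fixed_mask_of(inst$table), layout_of(inst$table),
                           "sq", ids = inst$table$id)
    s <- solve_squared_l2(p)
    u <- w + t(w)
    for (i in p$solve_set) {
      res <- s$layout[i, ] * sum(u[i, ]) - colSums(u[i, ] * s$layout)
      expect_lt(sqrt(sum(res^2)), 1e-9 * sum(u[i, ]) * p$scale)
    }
    # reported objective matches an independent recomputation
    expect_equal(s$objective, total_wiring_length(s$layout, w, "sq"),
                 tolerance = 1e-9)
    # anchors are bit-identical to their inputs
    expect_identical(s$layout[p$fixed, ], p$coords[p$fixed, ])
  }
})

test_that("isolated free neurons stay put; disconnected components error", {
  W <- matrix(0, 4, 4); W[3, 1] <- 1   # node 4 has no connections at all
  co <- rbind(c(0, 0), c(1, 0), c(0.5, 0.5), c(0.7, 0.7))
  p <- placement_problem(W, c(TRUE, TRUE, FALSE, FALSE), co, "sq",
                         ids = c("a1", "a2", "f1", "lonely"))
  s <- solve_squared_l2(p)
  expect_equal(s$layout[4, ], co[4, ])
  expect_equal(s$diagnostics$isolated, "lonely")
  # two free nodes wired only to each other: no path to an anchor
  W2 <- matrix(0, 4, 4); W2[3, 4] <- 1
  expect_warning(
    p2 <- placement_problem(W2, c(TRUE, TRUE, FALSE, FALSE), co, "sq",
                            ids = c("a1", "a2", "f1", "f2")),
    "no weighted path")
  expect_error(solve_squared_l2(p2), "f1\\+f2")
})

test_that("Weber solver finds Fermat points and degenerate-segment objectives", {
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  s <- solve_weber_l2(one_free(tri, c(1, 1, 1), "l2", start = c(0.8, 0.1)))
  expect_equal(s$layout[4, ], colMeans(tri), tolerance = 1e-7)
  expect_true(s$converged)
  # two equal anchors: any point on the segment is optimal; assert objective only
  s2 <- solve_weber_l2(one_free(rbind(c(0, 0), c(2, 1)), c(1, 1), "l2"))
  expect_equal(s2$objective, sqrt(5), tolerance = 1e-8)
})

test_that("Weber solutions match a fine-grid brute-force search", {
  set.seed(21)
  for (rep in 1:3) {
    anchors <- matrix(runif(10), 5, 2)
    nfree <- if (rep == 1) 1 else 2
    n <- 5 + nfree
    W <- matrix(0, n, n)
    for (i in 6:n) W[i, sample(5, 3)] <- runif(3, 0.5, 2)
    if (nfree == 2) W[6, 7] <- 1
    co <- rbind(anchors, matrix(0.5, nfree, 2))
    p <- placement_problem(W, c(rep(TRUE, 5), rep(FALSE, nfree)), co, "l2")
    s <- solve_weber_l2(p)
    g <- grid_search_optimum(W, p$fixed, co, "l2", rbind(c(-0.2, -0.2), c(1.2, 1.2)))
    expect_lt(s$objective, g$objective + 1e-3)
    expect_equal(s$objective, g$objective, tolerance = 1e-3)
  }
})

test_that("L1 solver applies the weighted-median rule per coordinate", {
  # median of three anchors at x in {0, 1, 10}
  s <- solve_l1(one_free(rbind(c(0, 5), c(1, 0), c(10, 2)), c(1, 1, 1), "l1"))
  expect_equal(s$layout[4, 1], 1)
  expect_equal(s$layout[4, 2], 2)
  # majority weight side: weights 3 vs 1 pins the optimum at x = 0
  s2 <- solve_l1(one_free(rbind(c(0, 0), c(10, 0)), c(3, 1), "l1"))
  expect_equal(s2$layout[3, 1], 0)
  # exact half-split: optimal interval [0, 10], deterministic midpoint
  s3 <- solve_l1(one_free(rbind(c(0, 0), c(10, 0)), c(1, 1), "l1"))
  expect_equal(s3$layout[3, 1], 5)
  expect_equal(s3$objective, 10)
})

test_that("the joint L1 solve equals solving each axis separately", {
  set.seed(22)
  inst <- small_instance(seed = 22, n_free = 8)
  w <- build_weights(inst$conn)
  fx <- fixed_mask_of(inst$table)
  co <- layout_of(inst$table)
  p <- placement_problem(w, fx, co, "l1", ids = inst$table$id)
  s <- solve_l1(p)
  # swap one axis's data out: the other axis's solution must not change
  co_y <- co; co_y[, 1] <- 0
  p_y <- placement_problem(w, fx, co_y, "l1", ids = inst$table$id)
  s_y <- solve_l1(p_y)
  expect_equal(s$layout[, 2], s_y$layout[, 2], tolerance = 1e-6)
})

test_that("L1 solutions match a fine-grid brute-force search", {
  set.seed(23)
  anchors <- matrix(runif(10), 5, 2)
  W <- matrix(0, 7, 7)
  W[6, c(1, 3, 5)] <- c(1, 2, 0.5)
  W[7, c(2, 4)] <- c(1.5, 1)
  W[6, 7] <- 1
  co <- rbind(anchors, matrix(0.5, 2, 2))
  p <- placement_problem(W, c(rep(TRUE, 5), FALSE, FALSE), co, "l1")
  s <- solve_l1(p)
  g <- grid_search_optimum(W, p$fixed, co, "l1", rbind(c(-0.2, -0.2), c(1.2, 1.2)))
  expect_equal(s$objective, g$objective, tolerance = 1e-3)
})

test_that("powered-cost solver agrees with the exact quadratic solve at p = 2", {
  inst <- small_instance(seed = 24, n_free = 6)
  w <- build_weights(inst$conn)
  p <- placement_problem(w, fixed_mask_of(inst$table), layout_of(inst$table),
                         "sq", ids = inst$table$id)
  s_exact <- solve_squared_l2(p)
  s_iter <- solve_power_p(p)
  expect_equal(s_iter$objective, s_exact$objective, tolerance = 1e-8)
})

test_that("powered costs put a symmetric free node at the midpoint", {
  for (pw in 2:4) {
    sp <- norm_spec("euclidean", pw)
    s <- solve_power_p(one_free(rbind(c(0, 0), c(2, 0)), c(1, 1), sp,
                                start = c(0.3, 0.8)))
    expect_equal(s$layout[3, ], c(1, 0), tolerance = 1e-6)
  }
})

test_that("fourth-power solutions match a fine-grid brute-force search", {
  set.seed(25)
  anchors <- matrix(runif(8), 4, 2)
  W <- matrix(0, 6, 6)
  W[5, c(1, 2)] <- c(1, 2)
  W[6, c(3, 4)] <- c(1, 1)
  W[5, 6] <- 0.5
  co <- rbind(anchors, matrix(0.5, 2, 2))
  sp <- norm_spec("euclidean", 4)
  p <- placement_problem(W, c(rep(TRUE, 4), FALSE, FALSE), co, sp)
  s <- solve_power_p(p)
  g <- grid_search_optimum(W, p$fixed, co, sp, rbind(c(-0.2, -0.2), c(1.2, 1.2)))
  expect_equal(s$objective, g$objective, tolerance = 1e-3)
})

test_that("optima transform with the anchors (translation, rotation, scale)", {
  inst <- small_instance(seed = 26, n_free = 6)
  w <- build_weights(inst$conn)
  fx <- fixed_mask_of(inst$table)
  co <- layout_of(inst$table)
  shift <- c(0.7, -0.3)
  th <- 0.6
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  cc <- 1.8
  for (nm in c("l2", "sq")) {
    solver <- if (nm == "sq") solve_squared_l2 else solve_weber_l2
    base <- solver(placement_problem(w, fx, co, nm))
    tr <- solver(placement_problem(w, fx, sweep(co, 2, shift, "+"), nm))
    expect_equal(tr$layout[fx, ], sweep(base$layout, 2, shift, "+")[fx, ])
    expect_equal(tr$layout, sweep(base$layout, 2, shift, "+"), tolerance = 1e-6)
    ro <- solver(placement_problem(w, fx, co %*% t(R), nm))
    expect_equal(ro$layout, base$layout %*% t(R), tolerance = 1e-6)
    sc <- solver(placement_problem(w, fx, cc * co, nm))
    expect_equal(sc$layout, cc * base$layout, tolerance = 1e-6)
  }
  # l1 is axis-dependent: translation and scale only
  b1 <- solve_l1(placement_problem(w, fx, co, "l1"))
  t1 <- solve_l1(placement_problem(w, fx, sweep(co, 2, shift, "+"), "l1"))
  expect_equal(t1$layout, sweep(b1$layout, 2, shift, "+"), tolerance = 1e-6)
  s1 <- solve_l1(placement_problem(w, fx, cc * co, "l1"))
  expect_equal(s1$layout, cc * b1$layout, tolerance = 1e-5)
})

test_that("anchoring more neurons never decreases the optimal objective", {
  inst <- small_instance(seed = 27)
  w <- build_weights(inst$conn)
  tb <- inst$table
  free_ids <- tb$id[tb$class == "inter"]
  for (nm in c("l1", "l2", "sq")) {
    p0 <- placement_problem(w, fixed_mask_of(tb), layout_of(tb), nm, ids = tb$id)
    o0 <- solve_placement(p0)$objective
    p1 <- placement_problem(w, fixed_mask_of(tb, free_ids[1:5]), layout_of(tb),
                            nm, ids = tb$id)
    o1 <- solve_placement(p1)$objective
    expect_gte(o1, o0 - 1e-9 * o0)
  }
})

test_that("minimal-distance refinement separates coincident optima", {
  # two free nodes pulled to the same point by a shared anchor pair
  W <- matrix(0, 4, 4)
  W[3, 1] <- 1; W[3, 2] <- 1; W[4, 1] <- 1; W[4, 2] <- 1
  co <- rbind(c(0, 0), c(2, 0), c(0.3, 0.4), c(1.7, -0.4))
  delta <- 0.1
  p <- placement_problem(W, c(TRUE, TRUE, FALSE, FALSE), co, "sq",
                         min_distance = delta)
  p0 <- placement_problem(W, c(TRUE, TRUE, FALSE, FALSE), co, "sq")
  warm <- solve_squared_l2(p0)
  # unconstrained optimum puts both free nodes at the midpoint
  expect_lt(sqrt(sum((warm$layout[3, ] - warm$layout[4, ])^2)), 1e-9)
  s <- solve_with_min_distance(p, warm)
  d <- as.matrix(dist(s$layout))
  expect_gte(min(d[3, c(1, 2, 4)]), delta * (1 - 1e-9))
  expect_gte(s$objective, warm$objective)
  expect_lt(s$objective - warm$objective, 0.1)   # O(delta) increase
})

test_that("an inactive minimal-distance constraint returns the warm start unchanged", {
  p0 <- one_free(rbind(c(0, 0), c(2, 0)), c(1, 3), "sq")
  warm <- solve_squared_l2(p0)
  p <- one_free(rbind(c(0, 0), c(2, 0)), c(1, 3), "sq", min_distance = 1e-4)
  s <- solve_with_min_distance(p, warm)
  expect_identical(s$layout, warm$layout)
  expect_identical(s$objective, warm$objective)
})

test_that("a tight constraint on near-coincident pairs barely moves the objective", {
  # worm-like instance solved under the Euclidean cost, then constrained at the
  # smallest real pairwise distance: only near-coincident optimal pairs move,
  # so the objective rises by well under 0.1%
  inst <- small_instance(seed = 28)
  w <- build_weights(inst$conn)
  fx <- fixed_mask_of(inst$table)
  co <- layout_of(inst$table)
  p0 <- placement_problem(w, fx, co, "l2", ids = inst$table$id)
  warm <- solve_weber_l2(p0)
  delta <- 2.33e-4
  p <- placement_problem(w, fx, co, "l2", min_distance = delta,
                         ids = inst$table$id)
  s <- solve_with_min_distance(p, warm)
  expect_gte(s$objective, warm$objective - 1e-12)
  expect_lt(100 * (s$objective - warm$objective) / warm$objective, 0.1)
})

test_that("solve_placement dispatches on the cost and honors min_distance", {
  inst <- small_instance(seed = 29, n_free = 5)
  w <- build_weights(inst$conn)
  fx <- fixed_mask_of(inst$table)
  co <- layout_of(inst$table)
  expect_identical(
    solve_placement(placement_problem(w, fx, co, "sq"))$solver,
    "anchored_laplacian")
  expect_identical(
    solve_placement(placement_problem(w, fx, co, "l2"))$solver, "weber_irls")
  expect_identical(
    solve_placement(placement_problem(w, fx, co, "l1"))$solver, "l1_median")
  expect_identical(
    solve_placement(placement_problem(w, fx, co, "p3"))$solver, "power_lbfgs")
  s <- solve_placement(placement_problem(w, fx, co, "sq", min_distance = 1e-3))
  expect_match(s$solver, "min_dist|anchored")
})
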