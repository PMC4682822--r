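#' Configuration for a synthetic worm-like connectome
#'
#' The generator emulates the geometry the analysis assumes: an
#' elongated body with a dense anterior (head) anchor cluster, a
#' posterior (tail) anchor cluster, a sparse mid-body ventral-cord line
#' of anchors, and free interneurons anywhere in the body. Connection
#' probability decays exponentially with distance; directed chemical
#' links and symmetric electrical links carry small integer
#' multiplicities (geometric, low variance — mirroring the fairly even
#' spread of synapses over connections in real data).
#'
#' Defaults mirror the real study's scale at desk cost: 200 anchors /
#' 80 free against the 193-anchored / 86-free split of the
#' 279-neuron dataset, on a 1.16 mm x 0.08 mm body.
#'
#' @param n_anchors_head,n_anchors_tail,n_anchors_cord anchor counts in
#'   the head cluster, tail cluster and mid-body cord line.
#' @param n_free number of free interneurons.
#' @param body_length,body_height body rectangle dimensions, mm.
#' @param decay_scale distance-decay scale lambda, mm: connection
#'   probability is proportional to `exp(-d / lambda)`.
#' @param chem_fraction fraction of the wiring budget that is chemical;
#'   each ordered pair gets a chemical link with probability
#'   `chem_fraction * exp(-d/lambda)`, each unordered pair an
#'   electrical one with probability `(1 - chem_fraction) * exp(-d/lambda)`.
#' @param count_mean mean link multiplicity (shifted-geometric, >= 1).
#' @param seed RNG seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_anchors_head = 80, n_anchors_tail = 60,
                         n_anchors_cord = 60, n_free = 80,
                         body_length = 1.16, body_height = 0.08,
                         decay_scale = 0.2, chem_fraction = 0.75,
                         count_mean = 2, seed = 1) {
  stopifnot(n_anchors_head >= 0, n_anchors_tail >= 0, n_anchors_cord >= 0,
            n_free >= 0, body_length > 0, body_height > 0, decay_scale > 0,
            chem_fraction >= 0, chem_fraction <= 1, count_mean >= 1)
  structure(list(n_anchors_head = n_anchors_head,
                 n_anchors_tail = n_anchors_tail,
                 n_anchors_cord = n_anchors_cord, n_free = n_free,
                 body_length = body_length, body_height = body_height,
                 decay_scale = decay_scale, chem_fraction = chem_fraction,
                 count_mean = count_mean, seed = seed),
            class = "synth_config")
}

#' Generate a synthetic worm-like instance
#'
#' Samples anchor and free positions (see [synth_config()]), wires
#' every ordered pair chemically with probability
#' `chem_fraction * exp(-d/lambda)` and every unordered pair
#' electrically with probability `(1-chem_fraction) * exp(-d/lambda)`,
#' drawing i.i.d. shifted-geometric multiplicities with mean
#' `count_mean`. Fully reproducible from `cfg$seed`; an empty graph is
#' resampled up to `retries` times, then it is an error.
#'
#' @param cfg a [synth_config()].
#' @param retries resampling cap for empty graphs.
#' @return list with `table` (a [neuron_table()]) and `conn`
#'   (a [connectivity()]).
#' @export
generate_instance <- function(cfg, retries = 10) {
  stopifnot(inherits(cfg, "synth_config"))
  withr::with_seed(cfg$seed, {
    for (attempt in seq_len(retries)) {
      inst <- generate_instance_once(cfg)
      if (sum(inst$conn$chem) + sum(inst$conn$elec) > 0) return(inst)
    }
    stop("empty graph after ", retries, " sampling attempts")
  })
}

generate_instance_once <- function(cfg) {
  L <- cfg$body_length
  H <- cfg$body_height
  nh <- cfg$n_anchors_head
  nt <- cfg$n_anchors_tail
  nc <- cfg$n_anchors_cord
  nf <- cfg$n_free
  pos <- rbind(
    cbind(stats::runif(nh, 0, 0.15 * L), stats::runif(nh, 0, H)),
    cbind(stats::runif(nt, 0.85 * L, L), stats::runif(nt, 0, H)),
    cbind(stats::runif(nc, 0.15 * L, 0.85 * L),
          stats::runif(nc, 0.05 * H, 0.25 * H)),   # ventral cord line
    cbind(stats::runif(nf, 0, L), stats::runif(nf, 0, H)))
  n_anchor <- nh + nt + nc
  n <- n_anchor + nf
  # alternate motor/sensory among anchors; free nodes are interneurons
  cls <- c(rep_len(c("motor", "sensory"), n_anchor), rep("inter", nf))
  ids <- sprintf("%s%03d", c(rep("A", n_anchor), rep("I", nf)),
                 c(seq_len(n_anchor), seq_len(nf)))
  table <- neuron_table(ids, cls, pos[, 1], pos[, 2])

  d <- as.matrix(stats::dist(pos))
  decay <- exp(-d / cfg$decay_scale)
  p_geom <- 1 / cfg$count_mean
  rcount <- function(k) stats::rgeom(k, p_geom) + 1L
  # directed chemical links
  p_ch <- cfg$chem_fraction * decay
  diag(p_ch) <- 0
  ch_hit <- matrix(stats::runif(n * n), n, n) < p_ch
  diag(ch_hit) <- FALSE
  chem <- matrix(0L, n, n)
  chem[ch_hit] <- rcount(sum(ch_hit))
  # symmetric electrical links (upper triangle decides)
  p_el <- (1 - cfg$chem_fraction) * decay
  el_hit <- matrix(stats::runif(n * n), n, n) < p_el & upper.tri(p_el)
  elec <- matrix(0L, n, n)
  elec[el_hit] <- rcount(sum(el_hit))
  elec <- elec + t(elec)
  list(table = table, conn = connectivity(chem, elec, ids))
}

#' Replace free positions with the exact squared-Euclidean optimum
#'
#' Builds a planted-optimum instance: the free neurons are moved to the
#' solution of the anchored squared-Euclidean stationarity system, so
#' the resulting "real" layout IS the squared-cost optimum. A
#' downstream [solve_squared_l2()] on the planted table must recover
#' the positions (to numerical precision) and report a zero reduction.
#'
#' @param table a [neuron_table()].
#' @param conn a [connectivity()].
#' @param scheme a [weight_scheme()].
#' @return The table with free-row positions replaced.
#' @export
plant_sq_l2_optimum <- function(table, conn,
                                scheme = weight_scheme("unit_joint")) {
  w <- build_weights(conn, scheme)
  fixed <- table$class != "inter"
  problem <- placement_problem(w, fixed, layout_of(table), "sq",
                               ids = table$id)
  sol <- solve_squared_l2(problem)
  neuron_table(table$id, table$class, sol$layout[, 1], sol$layout[, 2])
}
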