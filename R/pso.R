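## Particle swarm engine. Particles encode (z_1..z_N, R_1..R_N); the swarm
## is held as matrices (one particle per row) for vectorized updates.

.scheduleImpl <- function(t, config) {
  Tn <- config@iterations
  frac <- if (Tn > 1L) t / (Tn - 1) else 0
  list(w  = config@wStart  + frac * (config@wEnd  - config@wStart),
       c1 = config@c1Start + frac * (config@c1End - config@c1Start),
       c2 = config@c2Start + frac * (config@c2End - config@c2Start))
}

#' Coefficient schedules at an iteration
#'
#' The inertia decays linearly from `wStart` to `wEnd` over the run, while
#' the cognitive coefficient decreases and the social coefficient increases
#' linearly, shifting the swarm from individual exploration to collective
#' convergence.
#'
#' @param t 0-based iteration index, `0 <= t < iterations`
#' @param config a [SwarmConfig-class]
#' @return list with elements `w`, `c1`, `c2`
#' @examples
#' scheduleAt(0, swarmConfig())    # w 0.9, c1 2.5, c2 1.0
#' scheduleAt(119, swarmConfig())  # w 0.4, c1 1.0, c2 2.6
#' @export
scheduleAt <- function(t, config = swarmConfig()) {
  if (t < 0 || t >= config@iterations)
    stop("t must lie in [0, iterations - 1]", call. = FALSE)
  .scheduleImpl(t, config)
}

## evaluate every particle; rows PR, PZ, PO, L
.swarmLosses <- function(positions, prob, config) {
  t(apply(positions, 1L, .lossFromPosition, prob = prob, config = config))
}

#' Initialize the swarm
#'
#' Draws, for every particle, depths \eqn{z_i \sim U(z_{min}, z_{max})} and
#' radii \eqn{R_i \sim U(\alpha r^{nuc}_i, \beta r^{nuc}_i)} independently,
#' with zero initial velocities. Nucleus pairs whose 2D centroid distance is
#' below the sum of their nuclear radii would overlap if placed at equal
#' depth, so their z coordinates are re-drawn until the pair is separated in
#' 3D or the retry cap is reached (overlaps that survive the cap are left to
#' the penalty to repair, with a warning).
#'
#' @param obs nucleus table (id, x, y, r_nuc)
#' @param config a [SwarmConfig-class]; `config@seed` (when not NA) makes
#'   the draw reproducible
#' @return a [SwarmState-class] at iteration 0
#' @export
initializeSwarm <- function(obs, config = swarmConfig()) {
  .checkObservations(obs)
  if (nrow(obs) < 1L) stop("at least one observation required", call. = FALSE)
  if (!is.na(config@seed)) set.seed(config@seed)
  prob <- .makeProblem(obs, config)
  .initImpl(prob, config)
}

.initImpl <- function(prob, config) {
  n <- prob$n; m <- config@nSwarm
  width <- prob$upper - prob$lower
  positions <- matrix(stats::runif(m * 2L * n), nrow = m) *
    rep(width, each = m) + rep(prob$lower, each = m)

  ## pairs too close in 2D to coexist at equal depth
  close2d <- which(prob$dxy2 < prob$rsum^2 & upper.tri(prob$dxy2),
                   arr.ind = TRUE)
  exhausted <- 0L
  if (nrow(close2d)) {
    ii <- close2d[, 1L]; jj <- close2d[, 2L]
    need2 <- prob$rsum[close2d]^2 - prob$dxy2[close2d]  # required dz^2
    for (p in seq_len(m)) {
      z <- positions[p, seq_len(n)]
      ok <- FALSE
      for (a in seq_len(config@jitterRetryCap)) {
        bad <- (z[ii] - z[jj])^2 < need2
        if (!any(bad)) { ok <- TRUE; break }
        redraw <- unique(c(ii[bad], jj[bad]))
        z[redraw] <- stats::runif(length(redraw), config@zMin, config@zMax)
      }
      if (!ok) exhausted <- exhausted + 1L
      positions[p, seq_len(n)] <- z
    }
  }
  if (exhausted > 0L)
    warning(exhausted, " particle(s) still overlapping after ",
            config@jitterRetryCap, " z re-draws; penalty will repair",
            call. = FALSE)

  losses <- .swarmLosses(positions, prob, config)
  best <- which.min(losses[, "L"])
  new("SwarmState",
      positions = positions,
      velocities = matrix(0, nrow = m, ncol = 2L * n),
      pbestPositions = positions,
      pbestLoss = losses[, "L"],
      gbestPosition = positions[best, ],
      gbestLoss = losses[best, "L"],
      gbestPenalties = .penaltyBreakdown(losses[best, "PR"],
                                         losses[best, "PZ"],
                                         losses[best, "PO"], config),
      iteration = 0L,
      lossTrace = data.frame(iteration = integer(), L = numeric(),
                             P_R = numeric(), P_Z = numeric(),
                             P_O = numeric()))
}

.stepImpl <- function(state, prob, config) {
  m <- config@nSwarm
  d <- 2L * prob$n
  sch <- .scheduleImpl(min(state@iteration, config@iterations - 1L), config)
  r1 <- matrix(stats::runif(m * d), nrow = m)
  r2 <- matrix(stats::runif(m * d), nrow = m)
  gbestM <- matrix(state@gbestPosition, nrow = m, ncol = d, byrow = TRUE)
  v <- sch$w * state@velocities +
    sch$c1 * r1 * (state@pbestPositions - state@positions) +
    sch$c2 * r2 * (gbestM - state@positions)
  vmax <- rep(config@velocityClampFactor * (prob$upper - prob$lower), each = m)
  v <- pmin(pmax(v, -vmax), vmax)
  raw <- state@positions + v
  lowerM <- rep(prob$lower, each = m)
  upperM <- rep(prob$upper, each = m)
  pos <- pmin(pmax(raw, lowerM), upperM)
  v[pos != raw] <- 0  # zero velocity where the projection clipped

  losses <- .swarmLosses(pos, prob, config)
  if (any(!is.finite(losses)))
    stop("non-finite loss at iteration ", state@iteration + 1L,
         " (particle ", which(!is.finite(losses[, "L"]))[1L], ")",
         call. = FALSE)
  improved <- losses[, "L"] < state@pbestLoss
  pbestPositions <- state@pbestPositions
  pbestPositions[improved, ] <- pos[improved, , drop = FALSE]
  pbestLoss <- ifelse(improved, losses[, "L"], state@pbestLoss)

  gbestPosition <- state@gbestPosition
  gbestLoss <- state@gbestLoss
  gbestPenalties <- state@gbestPenalties
  b <- which.min(pbestLoss)
  if (pbestLoss[b] < gbestLoss) {
    gbestPosition <- pbestPositions[b, ]
    gbestLoss <- pbestLoss[b]
    lp <- .lossFromPosition(gbestPosition, prob, config)
    gbestPenalties <- .penaltyBreakdown(lp[["PR"]], lp[["PZ"]], lp[["PO"]],
                                        config)
  }
  it <- state@iteration + 1L
  new("SwarmState",
      positions = pos, velocities = v,
      pbestPositions = pbestPositions, pbestLoss = pbestLoss,
      gbestPosition = gbestPosition, gbestLoss = gbestLoss,
      gbestPenalties = gbestPenalties,
      iteration = it,
      lossTrace = rbind(state@lossTrace,
                        data.frame(iteration = it, L = gbestLoss,
                                   P_R = gbestPenalties@PR,
                                   P_Z = gbestPenalties@PZ,
                                   P_O = gbestPenalties@PO)))
}

#' One swarm iteration
#'
#' Updates every particle's velocity (inertia + cognitive + social terms
#' with fresh per-coordinate U(0,1) multipliers), clamps it, moves the
#' particle and projects the position back onto the feasible box by
#' per-coordinate clipping (the velocity component is zeroed where clipping
#' occurred). Losses are recomputed with neighbor pruning from each
#' particle's own geometry; personal and swarm bests are replaced only on
#' strict improvement, so the best-loss trace never increases.
#'
#' @param state a [SwarmState-class]
#' @param obs the nucleus table the swarm is fitting
#' @param config a [SwarmConfig-class]
#' @return the advanced [SwarmState-class]
#' @export
psoStep <- function(state, obs, config = swarmConfig()) {
  .checkObservations(obs)
  .stepImpl(state, .makeProblem(obs, config), config)
}

.perturbImpl <- function(state, prob, config) {
  m <- config@nSwarm
  if (m < 4L) {
    message("genetic perturbation skipped: swarm smaller than 4")
    return(state)
  }
  k <- m %/% 4L
  if (k < 1L) return(state)
  worst <- order(state@pbestLoss, decreasing = TRUE)[seq_len(k)]
  d <- 2L * prob$n
  width <- prob$upper - prob$lower
  pos <- state@positions
  vel <- state@velocities
  pbestPositions <- state@pbestPositions
  pbestLoss <- state@pbestLoss
  for (i in worst) {
    par <- sample.int(m, 2L)
    mask <- stats::runif(d) < 0.5
    child <- ifelse(mask, state@pbestPositions[par[1L], ],
                    state@pbestPositions[par[2L], ])
    child <- child + stats::rnorm(d, 0, 0.05 * width)
    child <- pmin(pmax(child, prob$lower), prob$upper)
    pos[i, ] <- child
    vel[i, ] <- 0
    lp <- .lossFromPosition(child, prob, config)
    pbestPositions[i, ] <- child
    pbestLoss[i] <- lp[["L"]]
  }
  gbestPosition <- state@gbestPosition
  gbestLoss <- state@gbestLoss
  gbestPenalties <- state@gbestPenalties
  b <- which.min(pbestLoss)
  if (pbestLoss[b] < gbestLoss) {
    gbestPosition <- pbestPositions[b, ]
    gbestLoss <- pbestLoss[b]
    lp <- .lossFromPosition(gbestPosition, prob, config)
    gbestPenalties <- .penaltyBreakdown(lp[["PR"]], lp[["PZ"]], lp[["PO"]],
                                        config)
  }
  new("SwarmState",
      positions = pos, velocities = vel,
      pbestPositions = pbestPositions, pbestLoss = pbestLoss,
      gbestPosition = gbestPosition, gbestLoss = gbestLoss,
      gbestPenalties = gbestPenalties,
      iteration = state@iteration, lossTrace = state@lossTrace)
}

#' Genetic perturbation of the swarm
#'
#' Optional diversification step: the worst quartile of particles (by
#' personal-best loss) is replaced by uniform crossover of two random
#' personal-best vectors plus Gaussian mutation (sd = 5% of each
#' coordinate's box width), projected back onto the box. The swarm best is
#' held separately and is never discarded; it changes only on improvement.
#' A no-op unless `config@gaEnabled`.
#'
#' @inheritParams psoStep
#' @return the (possibly) perturbed [SwarmState-class]
#' @export
geneticPerturbation <- function(state, obs, config = swarmConfig()) {
  if (!config@gaEnabled) return(state)
  .checkObservations(obs)
  .perturbImpl(state, .makeProblem(obs, config), config)
}

#' Reconstruct per-cell depth and whole-cell radius
#'
#' The main entry point: given the 2D nuclear centroids and radii of one
#' patch, infers each cell's depth z and whole-cell radius R by minimizing
#' the composite hinge loss (radius band, depth box, pairwise
#' non-interpenetration at nuclear-radius distance) with the scheduled,
#' projected particle swarm. Deterministic for a fixed `config@seed`. The
#' run stops early once a fully feasible solution (loss 0) is found; the
#' trace is padded to `iterations` rows with the final value.
#'
#' @param obs nucleus table (id, x, y, r_nuc)
#' @param config a [SwarmConfig-class]
#' @return a [CellDepthFit-class]
#' @examples
#' obs <- data.frame(id = 1:3, x = c(0, 6, 40), y = 0, r_nuc = 4)
#' fit <- optimizeCells(obs, swarmConfig(nSwarm = 20, iterations = 40,
#'                                       seed = 7))
#' cellEstimates(fit)
#' @export
optimizeCells <- function(obs, config = swarmConfig()) {
  .checkObservations(obs)
  if (nrow(obs) < 1L) stop("at least one observation required", call. = FALSE)
  if (!is.na(config@seed)) set.seed(config@seed)
  prob <- .makeProblem(obs, config)
  state <- .initImpl(prob, config)
  Tn <- config@iterations
  for (t in seq_len(Tn)) {
    state <- .stepImpl(state, prob, config)
    if (config@gaEnabled && state@iteration %% config@gaPeriod == 0L)
      state <- .perturbImpl(state, prob, config)
    if (state@gbestLoss == 0) break
  }
  trace <- state@lossTrace
  if (nrow(trace) < Tn) {  # pad after early feasibility
    last <- trace[nrow(trace), ]
    extra <- last[rep(1L, Tn - nrow(trace)), ]
    extra$iteration <- (nrow(trace) + 1L):Tn
    trace <- rbind(trace, extra)
    rownames(trace) <- NULL
  }
  n <- prob$n
  cells <- data.frame(id = obs$id, x = obs$x, y = obs$y,
                      z = state@gbestPosition[seq_len(n)],
                      R = state@gbestPosition[n + seq_len(n)])
  new("CellDepthFit", cells = cells, observations = as.data.frame(obs),
      penalties = state@gbestPenalties, lossTrace = trace, config = config)
}
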