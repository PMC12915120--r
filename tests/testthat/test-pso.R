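test_that("coefficient schedules interpolate linearly between endpoints", {
  cfg <- swarmConfig(iterations = 121L)
  expect_equal(scheduleAt(0, cfg), list(w = 0.9, c1 = 2.5, c2 = 1.0))
  expect_equal(scheduleAt(120, cfg), list(w = 0.4, c1 = 1.0, c2 = 2.6))
  expect_equal(scheduleAt(60, cfg), list(w = 0.65, c1 = 1.75, c2 = 1.8))
  expect_error(scheduleAt(121, cfg), "iterations")
  expect_error(scheduleAt(-1, cfg), "iterations")
  ## monotone over the whole run
  w <- vapply(0:120, function(t) scheduleAt(t, cfg)$w, numeric(1))
  c1 <- vapply(0:120, function(t) scheduleAt(t, cfg)$c1, numeric(1))
  c2 <- vapply(0:120, function(t) scheduleAt(t, cfg)$c2, numeric(1))
  expect_true(all(diff(w) < 0) && all(diff(c1) < 0) && all(diff(c2) > 0))
})

test_that("swarm initialization draws inside the box, reproducibly", {
  obs <- makeObs(12, seed = 3)
  cfg <- swarmConfig(nSwarm = 25L, seed = 99L)
  st <- initializeSwarm(obs, cfg)
  n <- nrow(obs)
  for (p in seq_len(25)) {
    z <- st@positions[p, 1:n]; R <- st@positions[p, n + 1:n]
    expect_true(all(z >= 0 & z <= 50))
    expect_true(all(R >= 1.5 * obs$r_nuc & R <= 2.5 * obs$r_nuc))
  }
  expect_true(all(st@velocities == 0))
  expect_identical(st@pbestPositions, st@positions)
  st2 <- initializeSwarm(obs, cfg)
  expect_identical(st@positions, st2@positions)  # bit-identical under seed
})

test_that("z-jitter separates 2D-coincident nuclei in nearly all particles", {
  obs <- data.frame(id = 1:2, x = 10, y = 10, r_nuc = 4)  # coincident (x,y)
  st <- initializeSwarm(obs, swarmConfig(nSwarm = 1000L, seed = 5L))
  dz <- abs(st@positions[, 1] - st@positions[, 2])
  expect_gte(mean(dz >= 8), 0.95)
})

test_that("a step is a fixed point at consensus and projects onto the box", {
  obs <- makeObs(6, seed = 2)
  cfg <- swarmConfig(nSwarm = 5L, iterations = 10L, seed = 1L)
  st <- initializeSwarm(obs, cfg)
  ## collapse the swarm onto gbest with zero velocity: nothing can move
  m <- nrow(st@positions)
  consensus <- matrix(st@gbestPosition, nrow = m,
                      ncol = length(st@gbestPosition), byrow = TRUE)
  stC <- new("SwarmState", positions = consensus,
             velocities = 0 * consensus, pbestPositions = consensus,
             pbestLoss = rep(st@gbestLoss, m),
             gbestPosition = st@gbestPosition, gbestLoss = st@gbestLoss,
             gbestPenalties = st@gbestPenalties, iteration = 0L,
             lossTrace = st@lossTrace)
  after <- psoStep(stC, obs, cfg)
  expect_equal(after@positions, consensus)
  expect_identical(after@gbestLoss, stC@gbestLoss)

  ## ordinary steps: strict box feasibility after every iteration
  prob <- celldepth:::.makeProblem(obs, cfg)
  for (k in 1:10) {
    st <- psoStep(st, obs, cfg)
    expect_true(all(st@positions >= rep(prob$lower, each = m) &
                    st@positions <= rep(prob$upper, each = m)))
    expect_lte(st@gbestLoss, Inf)
  }
})

test_that("the swarm-best trace never increases, across seeds", {
  for (s in 1:20) {
    obs <- makeObs(10, seed = s, field = 30)
    ## crowded draws may exhaust the init jitter cap; that path is expected
    fit <- suppressWarnings(
      optimizeCells(obs, swarmConfig(nSwarm = 12L, iterations = 25L,
                                     seed = s)))
    tr <- lossTrace(fit)$L
    expect_length(tr, 25L)
    expect_true(all(diff(tr) <= 0))
  }
})

test_that("optimization is deterministic under a fixed seed", {
  obs <- makeObs(15, seed = 8, field = 40)
  cfg <- swarmConfig(nSwarm = 15L, iterations = 30L, seed = 123L)
  f1 <- optimizeCells(obs, cfg)
  f2 <- optimizeCells(obs, cfg)
  expect_identical(cellEstimates(f1), cellEstimates(f2))
  expect_identical(lossTrace(f1), lossTrace(f2))
})

test_that("a single-cell problem is solved at initialization", {
  obs <- data.frame(id = 7L, x = 3, y = 4, r_nuc = 5)
  fit <- optimizeCells(obs, swarmConfig(nSwarm = 5L, iterations = 10L,
                                        seed = 2L))
  expect_identical(totalPenalty(penaltyBreakdown(fit)), 0)
  cells <- cellEstimates(fit)
  expect_identical(cells$x, obs$x)
  expect_identical(cells$y, obs$y)
  expect_true(cells$R >= 7.5 && cells$R <= 12.5)
})

test_that("widely separated nuclei are feasible from the first iteration", {
  ## all pairwise 2D distances exceed 2 * beta * max(r_nuc): no interaction
  obs <- data.frame(id = 1:5, x = (0:4) * 60, y = 0, r_nuc = 4)
  fit <- optimizeCells(obs, swarmConfig(nSwarm = 10L, iterations = 15L,
                                        seed = 4L))
  expect_identical(lossTrace(fit)$L[1], 0)
})

test_that("optimization repairs an infeasible crowded start", {
  ## dense 2D grid: many nuclei closer in-plane than their radius sums
  g <- expand.grid(x = seq(0, 9, by = 3), y = seq(0, 9, by = 3))
  obs <- data.frame(id = seq_len(nrow(g)), x = g$x, y = g$y, r_nuc = 4)
  cfg <- swarmConfig(nSwarm = 30L, iterations = 80L, seed = 11L,
                     jitterRetryCap = 1L)  # cripple the init repair
  fit <- suppressWarnings(optimizeCells(obs, cfg))
  tr <- lossTrace(fit)$L
  expect_true(tr[1] > 0)          # genuinely infeasible start
  expect_lt(tr[80], tr[1])        # the swarm improves it
})

test_that("genetic perturbation keeps the box and never loses the best", {
  obs <- makeObs(8, seed = 6, field = 25)
  cfgOff <- swarmConfig(nSwarm = 12L, iterations = 10L, seed = 3L)
  st <- initializeSwarm(obs, cfgOff)
  expect_identical(geneticPerturbation(st, obs, cfgOff), st)  # disabled

  cfgOn <- swarmConfig(nSwarm = 12L, iterations = 10L, seed = 3L,
                       gaEnabled = TRUE)
  prob <- celldepth:::.makeProblem(obs, cfgOn)
  m <- cfgOn@nSwarm
  for (s in 1:20) {
    set.seed(s)
    before <- psoStep(st, obs, cfgOn)
    after <- geneticPerturbation(before, obs, cfgOn)
    expect_lte(after@gbestLoss, before@gbestLoss)
    expect_true(all(after@positions >= rep(prob$lower, each = m) &
                    after@positions <= rep(prob$upper, each = m)))
  }

  tiny <- swarmConfig(nSwarm = 3L, gaEnabled = TRUE, seed = 1L)
  stTiny <- initializeSwarm(obs, tiny)
  expect_message(geneticPerturbation(stTiny, obs, tiny), "skipped")
})

test_that("a feasible synthetic packing is recovered to zero loss", {
  tis <- generateTissue(nCells = 50, seed = 21)
  fit <- optimizeCells(observations(tis),
                       swarmConfig(seed = 22L))  # standard settings
  expect_lt(totalPenalty(penaltyBreakdown(fit)), 1e-6 * 1e6)
  sc <- recoveryScore(truthCells(tis), cellEstimates(fit))
  expect_identical(sc$violations, 0L)
})
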