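test_that("radius penalty matches hand-evaluated hinge sums", {
  expect_identical(radiusPenalty(4, 6), 0)        # on the lower bound
  expect_identical(radiusPenalty(4, 5), 1)        # one unit below alpha band
  expect_identical(radiusPenalty(c(4, 4), c(11, 8)), 1)  # one above beta
  expect_identical(radiusPenalty(c(4, 4), c(6, 10)), 0)  # both bounds
  expect_error(radiusPenalty(c(4, 4), 5), "length")
  expect_error(radiusPenalty(0, 5), "rNuc")
  expect_error(radiusPenalty(-1, 5), "rNuc")
})

test_that("depth penalty matches hand-evaluated hinge sums", {
  expect_identical(zPenalty(c(0, 25, 50)), 0)
  expect_identical(zPenalty(-2), 2)
  expect_identical(zPenalty(55), 5)
  expect_identical(zPenalty(c(-2, 55)), 7)
  expect_error(zPenalty(1, zMin = 5, zMax = 5), "zMin")
})

test_that("overlap penalty follows the ordered-pair double-count convention", {
  cells <- data.frame(x = c(0, 10), y = 0, z = 0)
  nb <- list(2L, 1L)
  expect_identical(overlapPenalty(cells, c(3, 4), nb), 0)  # 10 > 7
  cells$x <- c(0, 5)
  expect_identical(overlapPenalty(cells, c(3, 4), nb), 4)  # (7 - 5) * 2
  cells$x <- c(0, 0)
  expect_identical(overlapPenalty(cells, c(3, 4), nb), 14) # 7 per ordered pair
  expect_error(overlapPenalty(cells, c(3, 4), list(1L, 1L)), "invalid")
})

test_that("overlap penalty is invariant to relabeling and rigid translation", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 12L
    cells <- data.frame(x = runif(n, 0, 30), y = runif(n, 0, 30),
                        z = runif(n, 0, 30))
    rn <- runif(n, 2, 6)
    full <- lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
    base <- overlapPenalty(cells, rn, full)
    perm <- sample(n)
    expect_equal(overlapPenalty(cells[perm, ], rn[perm], full), base)
    shifted <- cells
    shifted$x <- shifted$x + 100; shifted$y <- shifted$y - 7
    shifted$z <- shifted$z + 3
    expect_equal(overlapPenalty(shifted, rn, full), base)
  }
})

test_that("overlap penalty on the full graph equals the brute-force loop", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(2:200, 1)
    x <- runif(n, 0, 60); y <- runif(n, 0, 60); z <- runif(n, 0, 25)
    rn <- runif(n, 2, 6)
    full <- lapply(seq_len(n), function(i) setdiff(seq_len(n), i))
    expect_equal(overlapPenalty(data.frame(x = x, y = y, z = z), rn, full),
                 bruteOverlap(x, y, z, rn))
  }
})

test_that("total loss composes the weighted penalties and flags id mismatch", {
  obs <- data.frame(id = 1:2, x = c(0, 30), y = 0, r_nuc = 4)
  cells <- data.frame(id = 1:2, x = c(0, 30), y = 0, z = 10, R = 8)
  expect_identical(totalPenalty(totalLoss(cells, obs)), 0)

  cells1 <- data.frame(id = 1, x = 0, y = 0, z = 10, R = 5)
  obs1 <- data.frame(id = 1, x = 0, y = 0, r_nuc = 4)
  pb <- totalLoss(cells1, obs1)
  expect_identical(totalPenalty(pb), 5e4)          # lambda_R * 1
  expect_identical(unname(penaltyComponents(pb)[["P_R"]]), 1)

  zero <- swarmConfig(lambdaR = 0, lambdaZ = 0, lambdaO = 0)
  cellsBad <- data.frame(id = 1, x = 0, y = 0, z = -10, R = 1)
  expect_identical(totalPenalty(totalLoss(cellsBad, obs1, zero)), 0)

  obsBad <- data.frame(id = 3, x = 0, y = 0, r_nuc = 4)
  expect_error(totalLoss(cells1, obsBad), "ids")
})

test_that("loss is zero exactly on the feasible set (both directions)", {
  set.seed(11)
  cfg <- swarmConfig()
  for (rep in 1:40) {
    obs <- makeObs(8, seed = rep, field = 40)
    cells <- data.frame(id = obs$id, x = obs$x, y = obs$y,
                        z = runif(8, -5, 60),
                        R = runif(8, 1.2, 2.8) * obs$r_nuc)
    L <- totalPenalty(totalLoss(cells, obs, cfg))
    expect_gte(L, 0)
    expect_identical(L == 0, isFeasible(cells, obs))
  }
})
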