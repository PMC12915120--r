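test_that("N/C ratios and their feasibility bounds", {
  obs <- data.frame(id = 1:3, x = 0, y = 0, r_nuc = 4)
  cells <- data.frame(id = 1:3, x = 0, y = 0, z = 0, R = c(8, 6, 10))
  nc <- ncRatio(obs, cells)$nc
  expect_equal(nc, c(0.5, 2 / 3, 0.4))  # R = 2r, alpha*r, beta*r
  expect_error(ncRatio(obs, transform(cells, R = c(8, 0, 10))), "radii")
  ## misordered ids are realigned
  expect_equal(ncRatio(obs, cells[3:1, ])$nc, nc)
})

test_that("histogram entropy attains its exact bounds", {
  expect_identical(ncEntropy(rep(0.5, 17))$H, 0)
  expect_equal(ncEntropy(c(0.41, 0.48, 0.55, 0.62), nBins = 4)$H, log(4))
  e <- ncEntropy(c(0.45, 0.45, 0.45, 0.62), nBins = 2)
  expect_equal(e$H, -(0.75 * log(0.75) + 0.25 * log(0.25)))
  ## out-of-range values are clipped into the edge bins
  expect_identical(ncEntropy(c(-5, 0.2, 0.3), nBins = 10)$H, 0)
  set.seed(1)
  for (rep in 1:20) {
    v <- runif(sample(5:200, 1), 0.3, 0.8)
    H <- ncEntropy(v)$H
    expect_gte(H, 0); expect_lte(H, log(20))
    expect_identical(ncEntropy(sample(v))$H, H)  # permutation invariance
  }
  expect_error(ncEntropy(numeric()), "non-empty")
})

test_that("the random baseline draws inside the box, reproducibly", {
  obs <- makeObs(40, seed = 2)
  b1 <- randomBaseline(obs, seed = 7)
  b2 <- randomBaseline(obs, seed = 7)
  expect_identical(b1, b2)
  expect_true(all(b1$z >= 0 & b1$z <= 50))
  expect_true(all(b1$R >= 1.5 * obs$r_nuc & b1$R <= 2.5 * obs$r_nuc))
  nc <- ncRatio(obs, b1)$nc
  expect_true(all(nc >= 0.4 & nc <= 2 / 3))
  expect_identical(totalPenalty(totalLoss(b1, obs,
                                          swarmConfig(lambdaO = 0))), 0)
})

test_that("KS statistic and p-value match oracles", {
  ks <- ksTwoSample(1:3, 1:3)
  expect_identical(ks$D, 0)
  expect_identical(ks$p, 1)
  expect_identical(ksTwoSample(1:5, 11:15)$D, 1)       # disjoint supports
  expect_equal(ksTwoSample(c(1, 2, 3), c(1.5, 2.5, 3.5))$D, 1 / 3)

  set.seed(3)
  for (rep in 1:25) {
    a <- rnorm(sample(1:50, 1))
    b <- rnorm(sample(1:50, 1), mean = runif(1, -1, 1))
    got <- ksTwoSample(a, b)
    expect_identical(got$D, bruteKSD(a, b))
    ref <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
    expect_equal(got$D, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-3)
  }
  expect_error(ksTwoSample(numeric(), 1), "non-empty")
})

test_that("validation report separates narrow reconstructions from random", {
  ## narrow true ratios: per-patch N/C medians concentrate, entropies drop
  patches <- lapply(1:30, function(i)
    generateTissue(nCells = 40, ratioDist = "normal", ratioSd = 0.05,
                   seed = 100 + i))
  obsL <- lapply(patches, observations)
  cellsL <- lapply(patches, function(t)
    truthCells(t)[, c("id", "x", "y", "z", "R")])
  res <- validateAgainstRandom(obsL, cellsL, nReps = 5, seed = 17)
  expect_identical(nrow(res$report), 2L)
  expect_identical(res$report$summary, c("median_nc", "nc_entropy"))
  expect_true(all(res$report$p < 0.05))
  expect_true(all(is.finite(res$report$D)))
  ## CDF table covers both arms of both summaries
  expect_identical(sort(unique(res$cdf$arm)), c("random", "reconstructed"))
  expect_true(all(res$cdf$ecdf > 0 & res$cdf$ecdf <= 1))

  ## null case: the "reconstruction" is itself a baseline draw
  nullCells <- lapply(obsL, function(o) randomBaseline(o))
  resNull <- validateAgainstRandom(obsL, nullCells, nReps = 5, seed = 23)
  expect_true(all(resNull$report$p > 0.05))
})
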