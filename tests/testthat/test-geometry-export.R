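test_that("PLY export writes exact icosphere meshes per cell", {
  one <- data.frame(id = 1, x = 0, y = 0, z = 0, R = 1)
  f <- tempfile(fileext = ".ply")

  exportPLY(one, f, subdivisions = 0L)
  ico <- parsePly(f)
  expect_identical(c(ico$nVertex, ico$nFace), c(12L, 20L))

  exportPLY(one, f, subdivisions = 2L)
  ply <- parsePly(f)
  expect_identical(c(ply$nVertex, ply$nFace), c(162L, 320L))
  d <- sqrt(rowSums(ply$vertices^2))
  expect_true(all(abs(d - 1) < 1e-6))
  expect_true(all(ply$faces[, 1] == 3L))
  expect_true(all(ply$faces[, -1] >= 0L & ply$faces[, -1] < 162L))
})

test_that("re-parsed PLY reproduces every cell's center and radius", {
  set.seed(9)
  cells <- data.frame(id = 1:4, x = runif(4, 0, 100), y = runif(4, 0, 100),
                      z = runif(4, 0, 50), R = runif(4, 4, 12))
  f <- tempfile(fileext = ".ply")
  exportPLY(cells, f)
  ply <- parsePly(f)
  expect_identical(c(ply$nVertex, ply$nFace), c(4L * 162L, 4L * 320L))
  for (i in 1:4) {
    block <- ply$vertices[(i - 1) * 162 + 1:162, ]
    ctr <- colMeans(block)  # icosphere vertices are centro-symmetric
    expect_true(all(abs(ctr - unlist(cells[i, c("x", "y", "z")])) < 1e-5))
    expect_true(all(abs(sqrt(rowSums(sweep(block, 2, ctr)^2)) -
                        cells$R[i]) < 1e-5))
  }
  expect_error(exportPLY(cells[0, ], f), "non-empty")
})

test_that("projection modes give shadow and plane cross-section radii", {
  cells <- data.frame(id = 1:3, x = 1:3, y = 0, z = c(0, 4, 10),
                      R = c(8, 5, 5))
  sh <- projectCells(cells, "shadow")
  expect_identical(sh$radius, cells$R)
  cs <- projectCells(cells, "cross_section")
  expect_identical(cs$cell_id, c(1L, 2L))   # z = 10 > R = 5 is not cut
  expect_equal(cs$radius, c(8, 3))          # plane through center; 3-4-5
  expect_true(all(cs$radius <= sh$radius[match(cs$cell_id, sh$cell_id)]))
})

test_that("sliding tiling counts follow the closed form and pad edges", {
  img <- matrix(runif(120 * 120), 120, 120)
  ps <- extractPatchesSliding(img)
  expect_identical(length(patchImages(ps)), 4L)

  big <- matrix(0, 1000, 1000)
  expect_identical(length(patchImages(extractPatchesSliding(big))),
                   as.integer(ceiling(1000 / 60)^2))  # 289

  exact <- matrix(runif(3600), 60, 60)
  ps1 <- extractPatchesSliding(exact)
  expect_identical(length(patchImages(ps1)), 1L)
  expect_identical(patchImages(ps1)[[1]], exact)

  ## 100 x 100: edge tiles are zero-padded to 60 x 60
  ps2 <- extractPatchesSliding(matrix(1, 100, 100))
  p4 <- patchImages(ps2)[[4]]               # bottom-right tile
  expect_identical(dim(p4), c(60L, 60L))
  expect_identical(unique(as.numeric(p4[41:60, ])), 0)
})

test_that("nucleus-centered patches center the window and pad corners", {
  img <- matrix(runif(200 * 200), 200, 200)
  obs <- data.frame(id = 1:2, x = c(100, 0), y = c(100, 0), r_nuc = 4)
  ps <- extractPatchesNucleusCentered(img, obs)
  expect_identical(length(patchImages(ps)), 2L)
  expect_identical(patchImages(ps)[[1]], img[71:130, 71:130])
  corner <- patchImages(ps)[[2]]
  expect_identical(unique(as.numeric(corner[1:30, ])), 0)  # top pad
  expect_identical(unique(as.numeric(corner[, 1:30])), 0)  # left pad
  expect_identical(corner[31:60, 31:60], img[1:30, 1:30])
})

test_that("cell-region patches zero out pixels beyond the disk", {
  img <- matrix(1, 200, 200)
  reg <- data.frame(cell_id = 1:2, x = c(100, 150), y = c(100, 150),
                    radius = c(30, 0))
  ps <- extractPatchesCellRegion(img, reg)
  frac <- mean(patchImages(ps)[[1]] > 0)
  expect_equal(frac, pi * 30^2 / 60^2, tolerance = 0.02)
  expect_identical(unique(as.numeric(patchImages(ps)[[2]])), 0)
})

test_that("patches are labelled by where their defining point falls", {
  img <- matrix(0, 100, 100)
  obs <- data.frame(id = 1:4, x = c(10, 80, 20, 90), y = c(10, 15, 85, 90),
                    r_nuc = 3)
  ps <- extractPatchesNucleusCentered(img, obs)

  allT <- labelPatches(ps, matrix(1L, 100, 100))
  expect_identical(unique(patchManifest(allT)$label), "tumor")
  allN <- labelPatches(ps, matrix(0L, 100, 100))
  expect_identical(unique(patchManifest(allN)$label), "non_tumor")

  half <- matrix(0L, 100, 100); half[, 51:100] <- 1L  # x >= 50 is tumor
  lab <- patchManifest(labelPatches(ps, half))$label
  expect_identical(lab, ifelse(obs$x >= 50, "tumor", "non_tumor"))

  expect_error(labelPatches(ps, matrix(1L, 50, 100)), "frame")
})
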