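## Ground-truth generator: feasible 3D packings in a slab whose 2D
## observations drive every recovery and validation test.

#' Generate a feasible synthetic tissue
#'
#' Places cells sequentially at uniform random positions in a
#' `fieldSize` x `fieldSize` x `zMax` slab, rejecting any candidate whose 3D
#' center distance to an accepted cell is below the sum of their nuclear
#' radii — so the returned packing satisfies every reconstruction constraint
#' exactly (loss 0). Nuclear radii are drawn LogNormal (right-skewed, like
#' real nuclei) truncated to `radiusRange`; the whole-cell/nucleus ratio is
#' Normal truncated to \eqn{[\alpha, \beta]} (cells within a patch keep a
#' cohesive N/C ratio) or, for a null-matched tissue, uniform on the band.
#'
#' A density guard rejects parameter sets whose total nuclear cross-section
#' exceeds 40% of the field area, and placement aborts after 1e4 consecutive
#' rejections, both with an error advising fewer cells.
#'
#' @param nCells number of cells (>= 1)
#' @param fieldSize field edge length in pixels
#' @param zMax slab depth
#' @param alpha,beta admissible ratio band
#' @param radiusMeanLog,radiusSdLog LogNormal parameters of the nuclear
#'   radius (pixels)
#' @param radiusRange truncation interval for nuclear radii
#' @param ratioDist "normal" (default: cohesive within-patch ratios) or
#'   "uniform" (matches the random null band)
#' @param ratioMean,ratioSd Normal ratio parameters (used when
#'   `ratioDist = "normal"`)
#' @param seed integer seed
#' @return a [SyntheticTissue-class]
#' @examples
#' tis <- generateTissue(nCells = 10, seed = 3)
#' totalPenalty(totalLoss(truthCells(tis), observations(tis)))  # 0
#' @export
generateTissue <- function(nCells = 50L, fieldSize = 200, zMax = 50,
                           alpha = 1.5, beta = 2.5,
                           radiusMeanLog = log(4), radiusSdLog = 0.35,
                           radiusRange = c(2, 10),
                           ratioDist = c("normal", "uniform"),
                           ratioMean = 2.0, ratioSd = 0.25,
                           seed = NULL) {
  ratioDist <- match.arg(ratioDist)
  if (nCells < 1L) stop("nCells must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  rtrunc <- function(n, draw, lo, hi) {
    out <- numeric(0)
    while (length(out) < n) {
      v <- draw(n)
      out <- c(out, v[v >= lo & v <= hi])
    }
    out[seq_len(n)]
  }
  rNuc <- rtrunc(nCells,
                 function(n) stats::rlnorm(n, radiusMeanLog, radiusSdLog),
                 radiusRange[1L], radiusRange[2L])
  if (sum(pi * rNuc^2) > 0.4 * fieldSize^2)
    stop("tissue too dense: total nuclear cross-section exceeds 40% of ",
         "the field; reduce nCells or enlarge fieldSize", call. = FALSE)
  ratio <- switch(ratioDist,
    uniform = stats::runif(nCells, alpha, beta),
    normal = rtrunc(nCells,
                    function(n) stats::rnorm(n, ratioMean, ratioSd),
                    alpha, beta))

  x <- y <- z <- numeric(nCells)
  placed <- 0L
  rejects <- 0L
  while (placed < nCells) {
    cx <- stats::runif(1, 0, fieldSize)
    cy <- stats::runif(1, 0, fieldSize)
    cz <- stats::runif(1, 0, zMax)
    i <- placed + 1L
    ok <- TRUE
    if (placed > 0L) {
      d2 <- (x[seq_len(placed)] - cx)^2 + (y[seq_len(placed)] - cy)^2 +
            (z[seq_len(placed)] - cz)^2
      ok <- all(d2 >= (rNuc[seq_len(placed)] + rNuc[i])^2)
    }
    if (ok) {
      x[i] <- cx; y[i] <- cy; z[i] <- cz
      placed <- i
      rejects <- 0L
    } else {
      rejects <- rejects + 1L
      if (rejects >= 1e4L)
        stop("placement stalled after 1e4 consecutive rejections; ",
             "reduce nCells or enlarge the field", call. = FALSE)
    }
  }
  truth <- data.frame(id = seq_len(nCells), x = x, y = y, z = z,
                      R = ratio * rNuc, r_nuc = rNuc, ratio = ratio)
  obs <- truth[, c("id", "x", "y", "r_nuc")]
  new("SyntheticTissue", truth = truth, observations = obs,
      params = list(nCells = nCells, fieldSize = fieldSize, zMax = zMax,
                    alpha = alpha, beta = beta,
                    radiusMeanLog = radiusMeanLog,
                    radiusSdLog = radiusSdLog, radiusRange = radiusRange,
                    ratioDist = ratioDist, ratioMean = ratioMean,
                    ratioSd = ratioSd, seed = seed))
}

#' Rasterize a tissue's nuclei into a labelled mask
#'
#' Draws each nucleus as a filled disk of its nuclear radius at its (x, y)
#' centroid, labelled by cell id; on the rare pixels where two disks
#' overlap in 2D, later ids overwrite earlier ones.
#'
#' @param tissue a [SyntheticTissue-class]
#' @param fieldSize raster edge length in pixels; defaults to the
#'   generator's field size
#' @return integer matrix (`fieldSize` x `fieldSize`)
#' @export
renderMask <- function(tissue, fieldSize = NULL) {
  stopifnot(is(tissue, "SyntheticTissue"))
  if (is.null(fieldSize)) fieldSize <- tissue@params$fieldSize
  fieldSize <- as.integer(ceiling(fieldSize))
  mask <- matrix(0L, fieldSize, fieldSize)
  tr <- tissue@truth
  for (i in seq_len(nrow(tr))) {
    r <- tr$r_nuc[i]
    cs <- max(0L, floor(tr$x[i] - r)):min(fieldSize - 1L, ceiling(tr$x[i] + r))
    rs <- max(0L, floor(tr$y[i] - r)):min(fieldSize - 1L, ceiling(tr$y[i] + r))
    if (!length(cs) || !length(rs)) next
    d2 <- outer((rs - tr$y[i])^2, (cs - tr$x[i])^2, "+")
    hit <- d2 <= r * r
    sub <- mask[rs + 1L, cs + 1L, drop = FALSE]
    sub[hit] <- as.integer(tr$id[i])
    mask[rs + 1L, cs + 1L] <- sub
  }
  mask
}

#' Score a reconstruction against ground truth
#'
#' Reports the RMSE of the whole-cell radii, the RMSE of the depths up to
#' the global depth-reflection symmetry (the loss depends only on relative
#' depths, so z and zMax - z are indistinguishable; the smaller RMSE of the
#' two orientations is reported), the number of violated constraints
#' (radius band, depth box, overlapping pairs on the full graph) and the KS
#' distance between the true and recovered N/C distributions.
#'
#' @param truth truth table (id, x, y, z, R, r_nuc)
#' @param estimate estimated cell table (id, x, y, z, R)
#' @param zMax slab depth for the reflection; alpha/beta define the radius
#'   band
#' @param alpha,beta admissible ratio band
#' @return list with rmseR, rmseZ, violations, ksD
#' @export
recoveryScore <- function(truth, estimate, zMax = 50,
                          alpha = 1.5, beta = 2.5) {
  .checkCells(truth, "truth")
  if (!"r_nuc" %in% names(truth))
    stop("truth must carry r_nuc", call. = FALSE)
  est <- .alignCells(estimate, truth[, c("id", "x", "y", "r_nuc")])
  rmse <- function(e) sqrt(mean(e^2))
  rmseZ <- min(rmse(est$z - truth$z), rmse((zMax - est$z) - truth$z))
  nR <- sum(est$R < alpha * truth$r_nuc - 1e-9 |
            est$R > beta * truth$r_nuc + 1e-9)
  nZ <- sum(est$z < -1e-9 | est$z > zMax + 1e-9)
  n <- nrow(truth)
  nO <- 0L
  if (n > 1L) {
    D <- as.matrix(stats::dist(cbind(est$x, est$y, est$z)))
    rs <- outer(truth$r_nuc, truth$r_nuc, "+")
    nO <- sum(D < rs - 1e-9 & upper.tri(D))
  }
  ksD <- ksTwoSample(truth$r_nuc / truth$R, truth$r_nuc / est$R)$D
  list(rmseR = rmse(est$R - truth$R), rmseZ = rmseZ,
       violations = nR + nZ + nO, ksD = ksD)
}
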