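#' @import methods
NULL

## ---- input-table validators (shared across modules) -----------------------

## observations: one row per detected nucleus; lengths are in the same unit
## (pixels by default) for x, y and r_nuc.
.checkObservations <- function(obs, what = "observations") {
  if (!is.data.frame(obs))
    stop(what, " must be a data.frame", call. = FALSE)
  need <- c("id", "x", "y", "r_nuc")
  miss <- setdiff(need, names(obs))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(obs)) {
    if (anyDuplicated(obs$id))
      stop(what, ": nucleus ids must be unique within a patch", call. = FALSE)
    bad <- which(!is.finite(obs$r_nuc) | obs$r_nuc <= 0)
    if (length(bad))
      stop(what, ": r_nuc must be finite and > 0 (first bad row: ",
           bad[1L], ")", call. = FALSE)
    for (cl in c("x", "y")) {
      bad <- which(!is.finite(obs[[cl]]))
      if (length(bad))
        stop(what, ": non-finite ", cl, " (first bad row: ", bad[1L], ")",
             call. = FALSE)
    }
  }
  invisible(obs)
}

.checkCells <- function(cells, what = "cells") {
  if (!is.data.frame(cells))
    stop(what, " must be a data.frame", call. = FALSE)
  need <- c("id", "x", "y", "z", "R")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop(what, " is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(cells)
}

## cells and observations must describe the same nuclei, in the same order
.alignCells <- function(cells, obs) {
  .checkCells(cells)
  .checkObservations(obs)
  if (nrow(cells) != nrow(obs) || !all(cells$id == obs$id)) {
    m <- match(obs$id, cells$id)
    if (anyNA(m))
      stop("cells and observations do not share the same ids", call. = FALSE)
    cells <- cells[m, , drop = FALSE]
  }
  cells
}

## ---- SwarmConfig -----------------------------------------------------------

#' Algorithm parameters for the depth/radius reconstruction
#'
#' Holds every tunable of the penalized particle-swarm reconstruction: the
#' admissible cell-to-nucleus radius ratio band \eqn{[\alpha, \beta]}, the
#' depth box \eqn{[z_{min}, z_{max}]}, the penalty weights, the linear
#' schedules for the inertia and the cognitive/social coefficients, the swarm
#' size and iteration count, and run controls (seed, optional genetic
#' perturbation, neighbor threshold factor).
#'
#' All lengths share one unit (pixels by default). Defaults are the method's
#' standard settings: \eqn{\alpha = 1.5}, \eqn{\beta = 2.5},
#' \eqn{z \in [0, 50]}, \eqn{\lambda_R = 5\times10^4},
#' \eqn{\lambda_Z = 1\times10^4}, \eqn{\lambda_O = 1\times10^6}, inertia
#' 0.9 to 0.4, cognitive coefficient 2.5 to 1.0, social coefficient 1.0 to
#' 2.6, 50 particles, 120 iterations.
#'
#' @slot alpha,beta lower/upper bound of the whole-cell to nuclear radius
#'   ratio (dimensionless)
#' @slot zMin,zMax depth bounds (length units)
#' @slot lambdaR,lambdaZ,lambdaO penalty weights for radius-band, depth-box
#'   and overlap violations
#' @slot wStart,wEnd inertia weight at the first and last iteration
#' @slot c1Start,c1End cognitive coefficient schedule endpoints
#' @slot c2Start,c2End social coefficient schedule endpoints
#' @slot nSwarm number of particles
#' @slot iterations number of swarm iterations
#' @slot seed integer seed (NA for no seeding)
#' @slot gaEnabled logical; apply periodic genetic perturbation
#' @slot gaPeriod perturbation cadence in iterations
#' @slot neighborTauFactor neighbor threshold is this factor times the
#'   current maximum cell radius
#' @slot jitterRetryCap maximum z re-draws per particle at initialization
#' @slot velocityClampFactor velocity bound as a fraction of each
#'   coordinate's box width
#' @seealso [swarmConfig()]
#' @exportClass SwarmConfig
setClass("SwarmConfig",
  representation(
    alpha = "numeric", beta = "numeric",
    zMin = "numeric", zMax = "numeric",
    lambdaR = "numeric", lambdaZ = "numeric", lambdaO = "numeric",
    wStart = "numeric", wEnd = "numeric",
    c1Start = "numeric", c1End = "numeric",
    c2Start = "numeric", c2End = "numeric",
    nSwarm = "integer", iterations = "integer",
    seed = "integer",
    gaEnabled = "logical", gaPeriod = "integer",
    neighborTauFactor = "numeric",
    jitterRetryCap = "integer",
    velocityClampFactor = "numeric"))

setValidity("SwarmConfig", function(object) {
  msg <- character()
  if (!(object@alpha < object@beta))
    msg <- c(msg, "alpha must be < beta")
  if (object@alpha <= 0)
    msg <- c(msg, "alpha must be > 0")
  if (!(object@zMin < object@zMax))
    msg <- c(msg, "zMin must be < zMax")
  if (any(c(object@lambdaR, object@lambdaZ, object@lambdaO) < 0))
    msg <- c(msg, "penalty weights must be >= 0")
  if (object@nSwarm < 2L)
    msg <- c(msg, "nSwarm must be >= 2")
  if (object@iterations < 1L)
    msg <- c(msg, "iterations must be >= 1")
  if (object@neighborTauFactor <= 0)
    msg <- c(msg, "neighborTauFactor must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SwarmConfig
#'
#' @param alpha,beta admissible cell/nucleus radius ratio band
#' @param zMin,zMax depth bounds (same unit as the radii; defaults 0 and 50)
#' @param lambdaR,lambdaZ,lambdaO penalty weights
#' @param wStart,wEnd inertia schedule endpoints
#' @param c1Start,c1End cognitive coefficient schedule endpoints
#' @param c2Start,c2End social coefficient schedule endpoints
#' @param nSwarm swarm size
#' @param iterations number of iterations
#' @param seed integer seed, or NA to leave the RNG untouched
#' @param gaEnabled enable the periodic genetic perturbation (off by default)
#' @param gaPeriod perturbation cadence in iterations
#' @param neighborTauFactor neighbor threshold factor (threshold =
#'   factor * max current cell radius)
#' @param jitterRetryCap initialization z re-draw cap per particle
#' @param velocityClampFactor per-coordinate velocity bound as a fraction of
#'   the box width
#' @return a validated [SwarmConfig-class] object
#' @examples
#' cfg <- swarmConfig(iterations = 60, nSwarm = 30, seed = 1)
#' cfg
#' @export
swarmConfig <- function(alpha = 1.5, beta = 2.5,
                        zMin = 0, zMax = 50,
                        lambdaR = 5e4, lambdaZ = 1e4, lambdaO = 1e6,
                        wStart = 0.9, wEnd = 0.4,
                        c1Start = 2.5, c1End = 1.0,
                        c2Start = 1.0, c2End = 2.6,
                        nSwarm = 50L, iterations = 120L,
                        seed = NA_integer_,
                        gaEnabled = FALSE, gaPeriod = 20L,
                        neighborTauFactor = 2.0,
                        jitterRetryCap = 50L,
                        velocityClampFactor = 0.5) {
  new("SwarmConfig",
      alpha = alpha, beta = beta, zMin = zMin, zMax = zMax,
      lambdaR = lambdaR, lambdaZ = lambdaZ, lambdaO = lambdaO,
      wStart = wStart, wEnd = wEnd,
      c1Start = c1Start, c1End = c1End,
      c2Start = c2Start, c2End = c2End,
      nSwarm = as.integer(nSwarm), iterations = as.integer(iterations),
      seed = as.integer(seed),
      gaEnabled = gaEnabled, gaPeriod = as.integer(gaPeriod),
      neighborTauFactor = neighborTauFactor,
      jitterRetryCap = as.integer(jitterRetryCap),
      velocityClampFactor = velocityClampFactor)
}

## ---- PenaltyBreakdown ------------------------------------------------------

#' Decomposition of the reconstruction loss
#'
#' The loss of a candidate reconstruction is the weighted sum
#' \eqn{L = \lambda_R P_R + \lambda_Z P_Z + \lambda_O P_O} of three hinge
#' penalties: radius-band violation, depth-box violation and pairwise
#' overlap. \eqn{L = 0} exactly when the configuration is feasible.
#'
#' @slot PR,PZ,PO the unweighted penalty components (each \eqn{\ge 0})
#' @slot L the weighted total
#' @exportClass PenaltyBreakdown
setClass("PenaltyBreakdown",
  representation(PR = "numeric", PZ = "numeric", PO = "numeric",
                 L = "numeric"))

setValidity("PenaltyBreakdown", function(object) {
  v <- c(object@PR, object@PZ, object@PO, object@L)
  if (any(!is.finite(v))) return("penalty components must be finite")
  if (any(v < -1e-12)) return("penalty components must be non-negative")
  TRUE
})

.penaltyBreakdown <- function(PR, PZ, PO, config) {
  PR <- unname(PR); PZ <- unname(PZ); PO <- unname(PO)
  new("PenaltyBreakdown", PR = PR, PZ = PZ, PO = PO,
      L = config@lambdaR * PR + config@lambdaZ * PZ + config@lambdaO * PO)
}

## ---- SwarmState ------------------------------------------------------------

#' State of the particle swarm
#'
#' Particles are stored as rows of matrices of width \eqn{2N}: the first
#' \eqn{N} coordinates are depths \eqn{z_1..z_N}, the last \eqn{N} are
#' whole-cell radii \eqn{R_1..R_N}.
#'
#' @slot positions,velocities,pbestPositions numeric matrices, one particle
#'   per row
#' @slot pbestLoss per-particle best loss
#' @slot gbestPosition,gbestLoss swarm-wide best position and loss
#' @slot gbestPenalties [PenaltyBreakdown-class] of the swarm-wide best
#' @slot iteration number of completed iterations
#' @slot lossTrace data.frame (iteration, L, P_R, P_Z, P_O) of the swarm
#'   best after each iteration
#' @exportClass SwarmState
setClass("SwarmState",
  representation(
    positions = "matrix", velocities = "matrix",
    pbestPositions = "matrix", pbestLoss = "numeric",
    gbestPosition = "numeric", gbestLoss = "numeric",
    gbestPenalties = "PenaltyBreakdown",
    iteration = "integer", lossTrace = "data.frame"))

setValidity("SwarmState", function(object) {
  n <- nrow(object@positions)
  if (nrow(object@velocities) != n || nrow(object@pbestPositions) != n ||
      length(object@pbestLoss) != n)
    return("particle matrices/vectors disagree on swarm size")
  if (abs(object@gbestLoss - min(object@pbestLoss)) > 1e-9 * max(1, object@gbestLoss))
    return("gbestLoss must equal the minimum pbest loss")
  TRUE
})

## ---- CellDepthFit ----------------------------------------------------------

#' A fitted pseudo-3D reconstruction
#'
#' Result container returned by [optimizeCells()]: the per-cell estimates
#' (fixed 2D centroid, inferred depth z and whole-cell radius R), the penalty
#' breakdown of the returned solution, the per-iteration best-loss trace and
#' the configuration used.
#'
#' @slot cells data.frame with columns id, x, y, z, R
#' @slot observations the input nucleus table (id, x, y, r_nuc)
#' @slot penalties [PenaltyBreakdown-class] of `cells`
#' @slot lossTrace data.frame (iteration, L, P_R, P_Z, P_O)
#' @slot config the [SwarmConfig-class] used
#' @seealso [optimizeCells()], [cellEstimates()], [lossTrace()]
#' @exportClass CellDepthFit
setClass("CellDepthFit",
  representation(cells = "data.frame", observations = "data.frame",
                 penalties = "PenaltyBreakdown", lossTrace = "data.frame",
                 config = "SwarmConfig"))

## ---- SyntheticTissue -------------------------------------------------------

#' A synthetic ground-truth tissue
#'
#' A feasible 3D packing of cells in a slab together with the 2D observation
#' a section of it would yield. The truth table carries id, x, y, z, R,
#' r_nuc and the cell/nucleus ratio; the observation table is its projection
#' (id, x, y, r_nuc only). Truth satisfies every reconstruction constraint
#' exactly, so its loss is zero by construction.
#'
#' @slot truth data.frame (id, x, y, z, R, r_nuc, ratio)
#' @slot observations data.frame (id, x, y, r_nuc)
#' @slot params list of generator settings, including the seed
#' @seealso [generateTissue()]
#' @exportClass SyntheticTissue
setClass("SyntheticTissue",
  representation(truth = "data.frame", observations = "data.frame",
                 params = "list"))

setValidity("SyntheticTissue", function(object) {
  need <- c("id", "x", "y", "z", "R", "r_nuc")
  if (!all(need %in% names(object@truth)))
    return("truth must have columns id, x, y, z, R, r_nuc")
  if (!all(c("id", "x", "y", "r_nuc") %in% names(object@observations)))
    return("observations must have columns id, x, y, r_nuc")
  if (nrow(object@truth) != nrow(object@observations))
    return("truth and observations must have the same number of cells")
  TRUE
})

## ---- PatchSet --------------------------------------------------------------

#' A set of fixed-size image patches
#'
#' Produced by the three patch-construction schemes (sliding-window grid,
#' nucleus-centered, cell-region-masked). Every patch is exactly
#' `size` x `size` pixels after zero padding at image borders. The manifest
#' records one row per patch: its provenance, the defining point (cx, cy, in
#' 0-based pixel coordinates, x = column) and, for cell-region patches, the
#' disk radius.
#'
#' @slot patches list of numeric arrays (size x size, or size x size x C)
#' @slot manifest data.frame (patch_id, provenance, cx, cy, radius, label)
#' @slot size patch edge length in pixels
#' @slot imageDim dimensions of the source image (rows, cols)
#' @seealso [extractPatchesSliding()], [extractPatchesNucleusCentered()],
#'   [extractPatchesCellRegion()], [labelPatches()]
#' @exportClass PatchSet
setClass("PatchSet",
  representation(patches = "list", manifest = "data.frame",
                 size = "integer", imageDim = "integer"))

setValidity("PatchSet", function(object) {
  if (length(object@patches) != nrow(object@manifest))
    return("one manifest row per patch required")
  ok <- vapply(object@patches, function(p)
    all(dim(p)[1:2] == object@size), logical(1))
  if (!all(ok)) return("every patch must be size x size")
  TRUE
})
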