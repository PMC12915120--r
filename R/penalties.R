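## Hinge penalties defining feasibility of a reconstruction. All three are
## sums of max(0, .) terms, zero exactly on the feasible set.

#' Radius-band penalty
#'
#' Penalizes whole-cell radii outside the biologically plausible band
#' \eqn{[\alpha r^{nuc}_i, \beta r^{nuc}_i]} around each nuclear radius:
#' \deqn{P_R = \sum_i \max(0, \alpha r^{nuc}_i - R_i) +
#'       \sum_i \max(0, R_i - \beta r^{nuc}_i).}
#'
#' @param rNuc nuclear radii (> 0)
#' @param R whole-cell radii, same length
#' @param alpha,beta ratio band bounds
#' @return non-negative scalar; zero iff every \eqn{R_i} lies in its band
#' @examples
#' radiusPenalty(rNuc = 4, R = 5)        # 1: one unit below alpha * 4
#' radiusPenalty(rNuc = c(4, 4), R = c(11, 8))  # 1: one unit above beta * 4
#' @export
radiusPenalty <- function(rNuc, R, alpha = 1.5, beta = 2.5) {
  if (length(rNuc) != length(R))
    stop("rNuc and R must have the same length", call. = FALSE)
  if (any(!is.finite(rNuc)) || any(rNuc <= 0))
    stop("rNuc must be finite and > 0", call. = FALSE)
  sum(pmax(0, alpha * rNuc - R)) + sum(pmax(0, R - beta * rNuc))
}

#' Depth-box penalty
#'
#' Penalizes depths outside the section box:
#' \deqn{P_Z = \sum_i \max(0, z_{min} - z_i) + \max(0, z_i - z_{max}).}
#'
#' @param z depth coordinates
#' @param zMin,zMax box bounds, `zMin < zMax`
#' @return non-negative scalar; zero iff all depths lie in the box
#' @examples
#' zPenalty(c(0, 25, 50))   # 0
#' zPenalty(-2)             # 2
#' @export
zPenalty <- function(z, zMin = 0, zMax = 50) {
  if (!(zMin < zMax))
    stop("zMin must be < zMax", call. = FALSE)
  sum(pmax(0, zMin - z)) + sum(pmax(0, z - zMax))
}

#' Pairwise overlap penalty
#'
#' Enforces a minimal 3D center distance between adjacent cells. The minimal
#' distance is the sum of the two NUCLEAR radii (nuclei are treated as
#' incompressible; cytoplasm may deform):
#' \deqn{P_O = \sum_i \sum_{j \in N_i}
#'   \max(0, (r^{nuc}_i + r^{nuc}_j) - \lVert c_i - c_j \rVert).}
#' With symmetric neighbor sets each violating pair contributes twice (once
#' per ordered pair); this convention is kept as stated and only rescales
#' the overlap weight.
#'
#' @param cells data.frame with columns x, y, z (3D centers)
#' @param rNuc nuclear radii aligned with `cells`
#' @param neighbors list of integer vectors: `neighbors[[i]]` holds the
#'   indices of the cells adjacent to cell i (see [buildNeighborSets()])
#' @return non-negative scalar; zero iff every neighbor pair is separated by
#'   at least the sum of its nuclear radii
#' @examples
#' cells <- data.frame(x = c(0, 5), y = 0, z = 0)
#' overlapPenalty(cells, rNuc = c(3, 4), neighbors = list(2L, 1L))  # 4
#' @export
overlapPenalty <- function(cells, rNuc, neighbors) {
  n <- nrow(cells)
  if (length(rNuc) != n || length(neighbors) != n)
    stop("cells, rNuc and neighbors must agree in length", call. = FALSE)
  if (n == 0L) return(0)
  x <- cells$x; y <- cells$y
  z <- if ("z" %in% names(cells)) cells$z else numeric(n)
  total <- 0
  for (i in seq_len(n)) {
    js <- neighbors[[i]]
    if (!length(js)) next
    if (any(js < 1L | js > n | js == i))
      stop("neighbors[[", i, "]] contains invalid indices", call. = FALSE)
    d <- sqrt((x[i] - x[js])^2 + (y[i] - y[js])^2 + (z[i] - z[js])^2)
    total <- total + sum(pmax(0, (rNuc[i] + rNuc[js]) - d))
  }
  total
}

#' Composite reconstruction loss
#'
#' Weighted sum of the three feasibility penalties,
#' \eqn{L = \lambda_R P_R + \lambda_Z P_Z + \lambda_O P_O}. L is zero
#' exactly when all radius bands, the depth box and all neighbor-pair
#' separations hold.
#'
#' @param cells data.frame (id, x, y, z, R)
#' @param obs data.frame (id, x, y, r_nuc), same ids
#' @param config a [SwarmConfig-class]
#' @param neighbors optional precomputed neighbor sets; rebuilt from the
#'   cells' current geometry when NULL
#' @return a [PenaltyBreakdown-class]
#' @examples
#' obs <- data.frame(id = 1:2, x = c(0, 30), y = 0, r_nuc = 4)
#' cells <- data.frame(id = 1:2, x = c(0, 30), y = 0, z = 10, R = 8)
#' totalPenalty(totalLoss(cells, obs))  # 0: feasible
#' @export
totalLoss <- function(cells, obs, config = swarmConfig(), neighbors = NULL) {
  cells <- .alignCells(cells, obs)
  if (is.null(neighbors))
    neighbors <- buildNeighborSets(cells, tauFactor = config@neighborTauFactor)
  PR <- radiusPenalty(obs$r_nuc, cells$R, config@alpha, config@beta)
  PZ <- zPenalty(cells$z, config@zMin, config@zMax)
  PO <- overlapPenalty(cells, obs$r_nuc, neighbors)
  .penaltyBreakdown(PR, PZ, PO, config)
}

## ---- fast internal loss for the optimizer ---------------------------------

## Precomputes everything that is fixed across particles and iterations:
## squared 2D distances, nuclear-radius sums, and the per-coordinate box.
.makeProblem <- function(obs, config) {
  n <- nrow(obs)
  dx <- outer(obs$x, obs$x, "-")
  dy <- outer(obs$y, obs$y, "-")
  list(
    n = n,
    rNuc = obs$r_nuc,
    dxy2 = dx * dx + dy * dy,
    rsum = outer(obs$r_nuc, obs$r_nuc, "+"),
    lower = c(rep(config@zMin, n), config@alpha * obs$r_nuc),
    upper = c(rep(config@zMax, n), config@beta * obs$r_nuc))
}

## position layout: z_1..z_N then R_1..R_N. Neighbor sets are implicit:
## thresholding the dense 3D distance matrix at tau = factor * max(R) is
## exactly the fixed-radius neighbor query, and the symmetric matrix sum
## reproduces the ordered-pair double count.
.lossFromPosition <- function(pos, prob, config) {
  n <- prob$n
  z <- pos[seq_len(n)]
  R <- pos[n + seq_len(n)]
  PR <- sum(pmax(0, prob$lower[n + seq_len(n)] - R)) +
        sum(pmax(0, R - prob$upper[n + seq_len(n)]))
  PZ <- sum(pmax(0, config@zMin - z)) + sum(pmax(0, z - config@zMax))
  if (n > 1L) {
    dz <- outer(z, z, "-")
    D2 <- prob$dxy2 + dz * dz
    tau <- config@neighborTauFactor * max(R)
    hinge <- prob$rsum - sqrt(D2)
    keep <- D2 <= tau * tau & hinge > 0
    diag(keep) <- FALSE
    PO <- if (any(keep)) sum(hinge[keep]) else 0
  } else PO <- 0
  c(PR = PR, PZ = PZ, PO = PO,
    L = config@lambdaR * PR + config@lambdaZ * PZ + config@lambdaO * PO)
}
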