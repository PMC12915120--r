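#' Fixed-radius neighbor sets
#'
#' Builds the symmetric adjacency sets used by the overlap penalty:
#' \eqn{N_i = \{ j \ne i : \lVert c_i - c_j \rVert \le \tau \}} with
#' \eqn{\tau = } `tauFactor` times the current maximum cell radius. Cells
#' farther apart than \eqn{\tau} can never violate the nuclear-radius
#' separation (radii are bounded by \eqn{\beta r^{nuc} \le \tau/2} each), so
#' pruning them leaves the penalty unchanged.
#'
#' Small inputs use dense distance thresholding; larger inputs a uniform
#' grid (cell list) of side \eqn{\tau}, giving the sub-quadratic behavior of
#' a spatial index while returning exactly the brute-force sets.
#'
#' @param cells data.frame with columns x, y and optionally z (missing z is
#'   taken as 0, i.e. a flat configuration)
#' @param tauFactor threshold factor; threshold = `tauFactor * max(radii)`
#' @param radii current whole-cell radii; defaults to `cells$R`
#' @param method "auto" (default), "dense" or "grid"
#' @return list of sorted integer vectors, one per cell; symmetric
#' @examples
#' cells <- data.frame(x = c(0, 5, 100), y = 0, z = 0, R = 6)
#' buildNeighborSets(cells)
#' @export
buildNeighborSets <- function(cells, tauFactor = 2.0, radii = NULL,
                              method = c("auto", "dense", "grid")) {
  method <- match.arg(method)
  n <- nrow(cells)
  if (n == 0L) return(list())
  if (is.null(radii)) {
    if (!"R" %in% names(cells))
      stop("supply radii or a cells$R column", call. = FALSE)
    radii <- cells$R
  }
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("radii must be finite and > 0", call. = FALSE)
  tau <- tauFactor * max(radii)
  x <- cells$x; y <- cells$y
  z <- if ("z" %in% names(cells)) cells$z else numeric(n)
  if (method == "auto") method <- if (n <= 150L) "dense" else "grid"
  if (method == "dense") {
    D2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2 + outer(z, z, "-")^2
    adj <- D2 <= tau * tau
    diag(adj) <- FALSE
    return(lapply(seq_len(n), function(i) which(adj[i, ])))
  }
  ## grid: bin points into cubes of side tau; neighbors can only lie in the
  ## 27 surrounding cubes
  ix <- floor(x / tau); iy <- floor(y / tau); iz <- floor(z / tau)
  key <- paste(ix, iy, iz)
  buckets <- split(seq_len(n), key)
  out <- vector("list", n)
  tau2 <- tau * tau
  for (i in seq_len(n)) {
    cand <- integer()
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      b <- buckets[[paste(ix[i] + dx, iy[i] + dy, iz[i] + dz)]]
      if (!is.null(b)) cand <- c(cand, b)
    }
    cand <- cand[cand != i]
    d2 <- (x[i] - x[cand])^2 + (y[i] - y[cand])^2 + (z[i] - z[cand])^2
    out[[i]] <- sort(cand[d2 <= tau2])
  }
  out
}
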