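## Validation statistics: N/C ratio, its Shannon entropy, the random-radius
## null model, and the two-sample Kolmogorov-Smirnov comparison.

#' Nuclear-to-cytoplasmic ratio
#'
#' Operationalized as the ratio of nuclear radius to whole-cell radius,
#' \eqn{r^{nuc}_i / R_i}. Under the feasibility band the ratio lies in
#' \eqn{[1/\beta, 1/\alpha]} (defaults: [0.4, 2/3]).
#'
#' @param obs nucleus table (id, x, y, r_nuc)
#' @param cells cell table (id, x, y, z, R) with matching ids
#' @return data.frame (id, nc)
#' @examples
#' obs <- data.frame(id = 1, x = 0, y = 0, r_nuc = 4)
#' cells <- data.frame(id = 1, x = 0, y = 0, z = 0, R = 8)
#' ncRatio(obs, cells)$nc  # 0.5
#' @export
ncRatio <- function(obs, cells) {
  cells <- .alignCells(cells, obs)
  if (any(!is.finite(cells$R)) || any(cells$R <= 0))
    stop("cell radii must be finite and > 0", call. = FALSE)
  data.frame(id = obs$id, nc = obs$r_nuc / cells$R)
}

#' Shannon entropy of an N/C ratio distribution
#'
#' Histogram entropy in nats over a fixed range (default the feasibility
#' band \eqn{[1/\beta, 1/\alpha]} = [0.4, 2/3], 20 equal bins), so that
#' entropies are comparable across patches. Values outside the range are
#' clipped into the edge bins. \eqn{H = -\sum_b p_b \ln p_b} with
#' \eqn{0 \ln 0 = 0}; H is 0 for a constant sample and \eqn{\ln n_{bins}}
#' for exactly uniform bin occupancy.
#'
#' @param values N/C ratios (numeric, non-empty)
#' @param nBins number of histogram bins
#' @param range fixed histogram range (length 2)
#' @return list with H (nats), nCells, nBins, binEdges, counts
#' @examples
#' ncEntropy(rep(0.5, 10))$H                       # 0
#' ncEntropy(c(0.41, 0.48, 0.55, 0.62), nBins = 4)$H  # ln 4
#' @export
ncEntropy <- function(values, nBins = 20L, range = c(0.4, 1 / 1.5)) {
  if (!length(values) || any(!is.finite(values)))
    stop("values must be a non-empty finite vector", call. = FALSE)
  if (nBins < 1L) stop("nBins must be >= 1", call. = FALSE)
  lo <- range[1L]; hi <- range[2L]
  width <- (hi - lo) / nBins
  bin <- pmin(nBins, pmax(1L, floor((values - lo) / width) + 1L))
  counts <- tabulate(bin, nbins = nBins)
  p <- counts / length(values)
  p <- p[p > 0]
  list(H = -sum(p * log(p)), nCells = length(values),
       nBins = as.integer(nBins),
       binEdges = seq(lo, hi, length.out = nBins + 1L), counts = counts)
}

#' Random-radius null model
#'
#' The baseline the reconstruction is validated against: whole-cell radii
#' drawn uniformly from the admissible band
#' \eqn{R_i \sim U(\alpha r^{nuc}_i, \beta r^{nuc}_i)} and depths
#' \eqn{z_i \sim U(z_{min}, z_{max})}, independently and without any
#' optimization.
#'
#' @param obs nucleus table
#' @param config a [SwarmConfig-class] supplying alpha, beta and the depth
#'   box
#' @param seed integer seed for reproducibility (NULL leaves the RNG alone)
#' @return cell data.frame (id, x, y, z, R)
#' @export
randomBaseline <- function(obs, config = swarmConfig(), seed = NULL) {
  .checkObservations(obs)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(obs)
  data.frame(id = obs$id, x = obs$x, y = obs$y,
             z = stats::runif(n, config@zMin, config@zMax),
             R = stats::runif(n, config@alpha * obs$r_nuc,
                              config@beta * obs$r_nuc))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' \eqn{D = \sup_x |F_a(x) - F_b(x)|} over the pooled sample values, with a
#' two-sided p-value from the asymptotic Kolmogorov distribution at the
#' effective size \eqn{n = n_a n_b / (n_a + n_b)}.
#'
#' @param a,b numeric samples (each non-empty)
#' @return list with `D` and `p`
#' @examples
#' ksTwoSample(c(1, 2, 3), c(1.5, 2.5, 3.5))$D  # 1/3
#' @export
ksTwoSample <- function(a, b) {
  if (!length(a) || !length(b))
    stop("both samples must be non-empty", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("samples must be finite", call. = FALSE)
  na <- length(a); nb <- length(b)
  pooled <- sort(unique(c(a, b)))
  Fa <- vapply(pooled, function(v) sum(a <= v), numeric(1)) / na
  Fb <- vapply(pooled, function(v) sum(b <= v), numeric(1)) / nb
  D <- max(abs(Fa - Fb))
  neff <- na * nb / (na + nb)
  lambda <- sqrt(neff) * D
  ## survival function of the Kolmogorov distribution; the theta-function
  ## form is used at small lambda where the alternating series is unstable
  k <- seq_len(100L)
  p <- if (lambda < 1e-10) {
    1
  } else if (lambda < 1) {
    1 - sqrt(2 * pi) / lambda *
      sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * lambda^2)))
  } else {
    2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  }
  list(D = D, p = min(1, max(0, p)))
}

#' Validate a reconstruction against the random null model
#'
#' The desk analogue of comparing reconstructed and random N/C ratios over a
#' cohort of patches: for every patch the per-patch median N/C ratio and the
#' per-patch N/C entropy are computed for the reconstructed cells and for
#' `nReps` random-baseline draws (pooled into one null arm), and each
#' summary is compared across arms by the two-sample KS test. A CDF table of
#' both arms is returned for plotting.
#'
#' @param obsList list of nucleus tables (one per patch), or a single table
#' @param cellsList list of reconstructed cell tables aligned with `obsList`
#' @param config a [SwarmConfig-class]
#' @param nReps random baseline draws per patch
#' @param seed seed for the baseline draws
#' @param nBins,range histogram settings passed to [ncEntropy()]
#' @return list with `report` (data.frame: summary, D, p, n_recon, n_random)
#'   and `cdf` (data.frame: summary, arm, value) rows sorted within arm
#' @export
validateAgainstRandom <- function(obsList, cellsList,
                                  config = swarmConfig(), nReps = 10L,
                                  seed = NULL, nBins = 20L,
                                  range = c(1 / config@beta,
                                            1 / config@alpha)) {
  if (is.data.frame(obsList)) obsList <- list(obsList)
  if (is.data.frame(cellsList)) cellsList <- list(cellsList)
  if (length(obsList) != length(cellsList) || !length(obsList))
    stop("obsList and cellsList must be non-empty and aligned",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  summarize <- function(obs, cells) {
    nc <- ncRatio(obs, cells)$nc
    c(median = stats::median(nc),
      entropy = ncEntropy(nc, nBins = nBins, range = range)$H)
  }
  recon <- vapply(seq_along(obsList),
                  function(i) summarize(obsList[[i]], cellsList[[i]]),
                  numeric(2))
  rand <- vapply(seq_len(nReps), function(r)
    vapply(obsList, function(obs)
      summarize(obs, randomBaseline(obs, config)), numeric(2)),
    matrix(0, 2L, length(obsList)))
  randMedian <- as.numeric(rand[1L, , ])
  randEntropy <- as.numeric(rand[2L, , ])

  ksM <- ksTwoSample(recon["median", ], randMedian)
  ksE <- ksTwoSample(recon["entropy", ], randEntropy)
  report <- data.frame(
    summary = c("median_nc", "nc_entropy"),
    D = c(ksM$D, ksE$D), p = c(ksM$p, ksE$p),
    n_recon = length(obsList),
    n_random = length(randMedian))
  cdf <- rbind(
    data.frame(summary = "median_nc", arm = "reconstructed",
               value = sort(recon["median", ])),
    data.frame(summary = "median_nc", arm = "random",
               value = sort(randMedian)),
    data.frame(summary = "nc_entropy", arm = "reconstructed",
               value = sort(recon["entropy", ])),
    data.frame(summary = "nc_entropy", arm = "random",
               value = sort(randEntropy)))
  cdf$ecdf <- stats::ave(cdf$value, cdf$summary, cdf$arm,
                         FUN = function(v) seq_along(v) / length(v))
  rownames(cdf) <- NULL
  list(report = report, cdf = cdf)
}
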