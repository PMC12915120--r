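## Independent oracles and small fixture builders. Everything here is kept
## deliberately naive (double loops, exhaustive enumeration) so the oracles
## stay independent of the implementation paths they check.

## O(n^2) overlap penalty over the full ordered-pair graph
bruteOverlap <- function(x, y, z, rNuc) {
  n <- length(x)
  total <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2 + (z[i] - z[j])^2)
    total <- total + max(0, (rNuc[i] + rNuc[j]) - d)
  }
  total
}

## all-pairs fixed-radius thresholding
bruteNeighbors <- function(x, y, z, tau) {
  n <- length(x)
  lapply(seq_len(n), function(i) {
    d <- sqrt((x[i] - x)^2 + (y[i] - y)^2 + (z[i] - z)^2)
    setdiff(which(d <= tau), i)
  })
}

## exhaustive ECDF-breakpoint KS statistic
bruteKSD <- function(a, b) {
  breaks <- c(a, b)
  max(vapply(breaks, function(v)
    abs(mean(a <= v) - mean(b <= v)), numeric(1)))
}

## minimal independent ASCII PLY reader
parsePly <- function(path) {
  lines <- readLines(path)
  endHdr <- which(lines == "end_header")
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex ", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face ", lines, value = TRUE)))
  vl <- lines[endHdr + seq_len(nv)]
  fl <- lines[endHdr + nv + seq_len(nf)]
  verts <- do.call(rbind, lapply(strsplit(vl, " "), as.numeric))
  faces <- do.call(rbind, lapply(strsplit(fl, " "), as.integer))
  list(nVertex = nv, nFace = nf, vertices = verts, faces = faces)
}

## rasterized disk of radius r centered in a square matrix
drawDisk <- function(r, pad = 3L, label = 1L) {
  sz <- as.integer(2 * ceiling(r) + 1L + 2L * pad)
  ctr <- (sz - 1) / 2  # 0-based pixel-center coordinate of the middle pixel
  px <- 0:(sz - 1)
  d2 <- outer((px - ctr)^2, (px - ctr)^2, "+")
  m <- matrix(0L, sz, sz)
  m[d2 <= r^2] <- label
  m
}

## random but well-spread observation table
makeObs <- function(n, seed = 1L, field = 100) {
  set.seed(seed)
  data.frame(id = seq_len(n),
             x = stats::runif(n, 0, field),
             y = stats::runif(n, 0, field),
             r_nuc = stats::runif(n, 2, 6))
}

## constraint check independent of the penalty code
isFeasible <- function(cells, obs, alpha = 1.5, beta = 2.5,
                       zMin = 0, zMax = 50) {
  if (any(cells$R < alpha * obs$r_nuc | cells$R > beta * obs$r_nuc))
    return(FALSE)
  if (any(cells$z < zMin | cells$z > zMax)) return(FALSE)
  n <- nrow(cells)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    d <- sqrt((cells$x[i] - cells$x[j])^2 + (cells$y[i] - cells$y[j])^2 +
              (cells$z[i] - cells$z[j])^2)
    if (d < obs$r_nuc[i] + obs$r_nuc[j]) return(FALSE)
  }
  TRUE
}
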