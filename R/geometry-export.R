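## Mesh export, Z = 0 projections, and the three patch-construction schemes.

## unit icosphere: recursive subdivision of an icosahedron, midpoints pushed
## to the unit sphere. subdivisions = 0 gives the icosahedron (12 v / 20 f);
## each level quadruples the faces (2 -> 162 v / 320 f).
.icosphere <- function(subdivisions = 2L) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  t,  0), c( 1,  t,  0), c(-1, -t,  0), c( 1, -t,  0),
    c( 0, -1,  t), c( 0,  1,  t), c( 0, -1, -t), c( 0,  1, -t),
    c( t,  0, -1), c( t,  0,  1), c(-t,  0, -1), c(-t,  0,  1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    mid <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      i <- mid[[key]]
      if (!is.null(i)) return(i)
      p <- verts[a, ] + verts[b, ]
      p <- p / sqrt(sum(p^2))
      verts <<- rbind(verts, p)
      i <- nrow(verts)
      assign(key, i, envir = mid)
      i
    }
    nf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1L]; b <- f[k, 2L]; c0 <- f[k, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c0); ca <- midpoint(c0, a)
      nf[4L * k - 3L, ] <- c(a, ab, ca)
      nf[4L * k - 2L, ] <- c(b, bc, ab)
      nf[4L * k - 1L, ] <- c(c0, ca, bc)
      nf[4L * k, ]      <- c(ab, bc, ca)
    }
    v <- verts; f <- nf
  }
  list(vertices = v, faces = f)
}

#' Export a reconstruction as an ASCII PLY sphere mesh
#'
#' Each cell becomes one icosphere of radius R centered at (x, y, z). The
#' default 2 subdivision levels give 162 vertices and 320 faces per sphere.
#' Output is ASCII PLY (element vertex x/y/z float, element face vertex
#' index list), loadable by standard mesh viewers.
#'
#' @param cells data.frame (id, x, y, z, R), non-empty
#' @param path output file path
#' @param subdivisions icosphere subdivision level (0 = icosahedron)
#' @return the path, invisibly
#' @examples
#' cells <- data.frame(id = 1, x = 0, y = 0, z = 0, R = 1)
#' f <- tempfile(fileext = ".ply")
#' exportPLY(cells, f)
#' readLines(f, n = 4)
#' @export
exportPLY <- function(cells, path, subdivisions = 2L) {
  .checkCells(cells)
  if (nrow(cells) == 0L) stop("cells must be non-empty", call. = FALSE)
  ico <- .icosphere(subdivisions)
  nv <- nrow(ico$vertices); nf <- nrow(ico$faces)
  n <- nrow(cells)
  vlines <- character(n * nv)
  flines <- character(n * nf)
  for (i in seq_len(n)) {
    vv <- ico$vertices * cells$R[i]
    vv <- sweep(vv, 2L, c(cells$x[i], cells$y[i], cells$z[i]), "+")
    vlines[(i - 1L) * nv + seq_len(nv)] <-
      sprintf("%.6f %.6f %.6f", vv[, 1L], vv[, 2L], vv[, 3L])
    ff <- ico$faces - 1L + (i - 1L) * nv  # 0-based, offset per sphere
    flines[(i - 1L) * nf + seq_len(nf)] <-
      sprintf("3 %d %d %d", ff[, 1L], ff[, 2L], ff[, 3L])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               "comment one icosphere per reconstructed cell",
               sprintf("element vertex %d", n * nv),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", n * nf),
               "property list uchar int vertex_indices",
               "end_header", vlines, flines), con)
  invisible(path)
}

#' Project reconstructed cells onto the section plane
#'
#' `shadow` mode returns every cell's orthographic footprint (radius R);
#' `cross_section` intersects each sphere with the Z = 0 plane, keeping only
#' cells the plane cuts (|z| <= R) with radius \eqn{\sqrt{R^2 - z^2}}.
#'
#' @param cells data.frame (id, x, y, z, R)
#' @param mode "shadow" (default) or "cross_section"
#' @return data.frame (cell_id, x, y, radius, mode)
#' @examples
#' cells <- data.frame(id = 1:2, x = 0, y = 0, z = c(4, 10), R = 5)
#' projectCells(cells, "cross_section")  # only cell 1, radius 3
#' @export
projectCells <- function(cells, mode = c("shadow", "cross_section")) {
  mode <- match.arg(mode)
  .checkCells(cells)
  if (mode == "shadow") {
    out <- data.frame(cell_id = cells$id, x = cells$x, y = cells$y,
                      radius = cells$R, mode = mode)
  } else {
    keep <- abs(cells$z) <= cells$R
    out <- data.frame(cell_id = cells$id[keep], x = cells$x[keep],
                      y = cells$y[keep],
                      radius = sqrt(cells$R[keep]^2 - cells$z[keep]^2),
                      mode = mode)
  }
  rownames(out) <- NULL
  out
}

## ---- patch windows ---------------------------------------------------------

.asImage <- function(image) {
  if (is.matrix(image)) image <- array(image, dim = c(dim(image), 1L))
  if (length(dim(image)) != 3L)
    stop("image must be a matrix or H x W x C array", call. = FALSE)
  image
}

## zero-padded size x size window with 0-based top-left (r0, c0)
.window <- function(img, r0, c0, size) {
  H <- dim(img)[1L]; W <- dim(img)[2L]; C <- dim(img)[3L]
  out <- array(0, dim = c(size, size, C))
  rs <- max(0L, r0):min(H - 1L, r0 + size - 1L)
  cs <- max(0L, c0):min(W - 1L, c0 + size - 1L)
  if (length(rs) && length(cs) && rs[1L] <= rs[length(rs)] &&
      cs[1L] <= cs[length(cs)]) {
    out[rs - r0 + 1L, cs - c0 + 1L, ] <- img[rs + 1L, cs + 1L, , drop = FALSE]
  }
  out
}

.dropChannel <- function(p, wasMatrix) if (wasMatrix) p[, , 1L] else p

.newPatchSet <- function(patches, manifest, size, imageDim) {
  manifest$patch_id <- seq_len(nrow(manifest))
  manifest <- manifest[, c("patch_id",
                           setdiff(names(manifest), "patch_id"))]
  if (!"label" %in% names(manifest)) manifest$label <- NA_character_
  new("PatchSet", patches = patches, manifest = manifest,
      size = as.integer(size), imageDim = as.integer(imageDim))
}

#' Sliding-window patch grid
#'
#' Row-major tiling from the top-left corner; edge tiles are zero-padded to
#' the full patch size. The manifest's (cx, cy) is each window's center.
#'
#' @param image numeric matrix (H x W) or array (H x W x C)
#' @param size patch edge length in pixels
#' @param stride tiling stride in pixels
#' @return a [PatchSet-class] with `ceil(H/stride) * ceil(W/stride)` patches
#' @export
extractPatchesSliding <- function(image, size = 60L, stride = 60L) {
  img <- .asImage(image)
  wasMatrix <- is.matrix(image)
  H <- dim(img)[1L]; W <- dim(img)[2L]
  r0s <- seq(0L, H - 1L, by = stride)
  c0s <- seq(0L, W - 1L, by = stride)
  patches <- list(); cx <- cy <- numeric()
  for (r0 in r0s) for (c0 in c0s) {
    patches[[length(patches) + 1L]] <-
      .dropChannel(.window(img, r0, c0, size), wasMatrix)
    cx <- c(cx, c0 + (size - 1) / 2)
    cy <- c(cy, r0 + (size - 1) / 2)
  }
  .newPatchSet(patches,
               data.frame(provenance = "sliding", cx = cx, cy = cy,
                          radius = NA_real_),
               size, dim(img)[1:2])
}

#' Nucleus-centered patches
#'
#' One patch per detected nucleus, the window centered on the rounded
#' centroid and zero-padded at image borders.
#'
#' @inheritParams extractPatchesSliding
#' @param obs nucleus table (id, x, y, r_nuc)
#' @return a [PatchSet-class] with one patch per observation
#' @export
extractPatchesNucleusCentered <- function(image, obs, size = 60L) {
  img <- .asImage(image)
  wasMatrix <- is.matrix(image)
  .checkObservations(obs)
  half <- size %/% 2L
  patches <- lapply(seq_len(nrow(obs)), function(i) {
    r0 <- round(obs$y[i]) - half
    c0 <- round(obs$x[i]) - half
    .dropChannel(.window(img, r0, c0, size), wasMatrix)
  })
  .newPatchSet(patches,
               data.frame(provenance = "nucleus_centered",
                          cx = obs$x, cy = obs$y, radius = NA_real_),
               size, dim(img)[1:2])
}

#' Cell-region patches
#'
#' One patch per projected cell region: the window is centered on the
#' region's center and every pixel outside the region's disk is set to zero,
#' so the patch carries exactly the reconstruction-informed cell boundary.
#' Disks larger than the window are cropped by it.
#'
#' @inheritParams extractPatchesSliding
#' @param regions data.frame from [projectCells()] (cell_id, x, y, radius)
#' @return a [PatchSet-class] with one patch per region
#' @export
extractPatchesCellRegion <- function(image, regions, size = 60L) {
  img <- .asImage(image)
  wasMatrix <- is.matrix(image)
  if (!all(c("cell_id", "x", "y", "radius") %in% names(regions)))
    stop("regions must come from projectCells()", call. = FALSE)
  half <- size %/% 2L
  patches <- lapply(seq_len(nrow(regions)), function(i) {
    r0 <- round(regions$y[i]) - half
    c0 <- round(regions$x[i]) - half
    p <- .window(img, r0, c0, size)
    px <- c0 + 0:(size - 1L)            # absolute 0-based pixel coords
    py <- r0 + 0:(size - 1L)
    d2 <- outer((py - regions$y[i])^2, (px - regions$x[i])^2, "+")
    p[array(d2 >= regions$radius[i]^2, dim = dim(p))] <- 0
    .dropChannel(p, wasMatrix)
  })
  .newPatchSet(patches,
               data.frame(provenance = "cell_region",
                          cx = regions$x, cy = regions$y,
                          radius = regions$radius),
               size, dim(img)[1:2])
}

#' Label patches by a tumor annotation mask
#'
#' A patch is labelled `tumor` when its defining point (nucleus or region
#' center; the window center for sliding patches) falls inside the binary
#' annotation mask; points outside the mask frame count as non-tumor.
#'
#' @param patchset a [PatchSet-class]
#' @param tumorMask binary matrix in the same frame as the source image
#' @return the [PatchSet-class] with the manifest's `label` column filled
#' @export
labelPatches <- function(patchset, tumorMask) {
  stopifnot(is(patchset, "PatchSet"))
  if (!is.matrix(tumorMask) ||
      !all(dim(tumorMask) == patchset@imageDim))
    stop("tumorMask frame does not match the source image (",
         paste(patchset@imageDim, collapse = " x "), ")", call. = FALSE)
  man <- patchset@manifest
  px <- round(man$cx); py <- round(man$cy)
  inFrame <- px >= 0 & px < ncol(tumorMask) & py >= 0 & py < nrow(tumorMask)
  lab <- rep("non_tumor", nrow(man))
  idx <- which(inFrame)
  lab[idx] <- ifelse(tumorMask[cbind(py[idx] + 1L, px[idx] + 1L)] > 0,
                     "tumor", "non_tumor")
  man$label <- lab
  initialize(patchset, manifest = man)
}
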