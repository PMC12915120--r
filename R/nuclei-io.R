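## Readers/writers bridging segmentation output and the optimizer.
##
## Coordinate convention (documented also in the CSV header comment):
## 0-based pixel indices, x = column, y = row, centroids at pixel centers.
## All lengths are in pixels unless a pixel size is applied at I/O time.

#' Nucleus features from an instance-labelled mask
#'
#' Extracts, per label, the centroid (mean pixel position, pixel-center
#' convention, origin at the top-left, x = column, y = row, 0-based) and the
#' equivalent-circle radius \eqn{r = \sqrt{area/\pi}}. Labels need not be
#' contiguous; output rows are in ascending label order.
#'
#' A binary mask (single foreground label) can optionally be split into
#' instances first by distance-transform watershed (requires the EBImage
#' package); instance-labelled input is the primary path.
#'
#' All outputs are in pixels unless `pixelSize` (microns per pixel, e.g.
#' 0.25 at 40x magnification) is given, in which case centroids and radii
#' are converted to microns at read time so that they share the unit of the
#' depth box.
#'
#' @param mask integer matrix; 0 = background, k > 0 = nucleus instance k
#' @param watershed split a binary mask into instances before measuring
#' @param pixelSize optional microns-per-pixel scale applied to x, y, r_nuc
#' @return data.frame (id, x, y, r_nuc); zero rows (with a warning) when the
#'   mask has no foreground
#' @examples
#' m <- matrix(0L, 20, 20); m[3:7, 4:8] <- 1L  # 5 x 5 square
#' nucleiFromMask(m)  # r_nuc = sqrt(25/pi)
#' @export
nucleiFromMask <- function(mask, watershed = FALSE, pixelSize = NULL) {
  if (!is.matrix(mask))
    stop("mask must be a 2D integer matrix", call. = FALSE)
  storage.mode(mask) <- "integer"
  if (watershed)
    mask <- .watershedSplit(mask)
  fg <- which(mask > 0L)
  if (!length(fg)) {
    warning("no foreground labels in mask", call. = FALSE)
    return(data.frame(id = integer(), x = numeric(), y = numeric(),
                      r_nuc = numeric()))
  }
  lab <- mask[fg]
  row0 <- (fg - 1L) %% nrow(mask)        # 0-based row = y
  col0 <- (fg - 1L) %/% nrow(mask)       # 0-based col = x
  ids <- sort(unique(lab))
  idx <- match(lab, ids)
  area <- tabulate(idx, nbins = length(ids))
  sx <- vapply(split(col0, idx), sum, numeric(1))
  sy <- vapply(split(row0, idx), sum, numeric(1))
  scale <- if (is.null(pixelSize)) 1 else pixelSize
  data.frame(id = ids, x = scale * sx / area, y = scale * sy / area,
             r_nuc = scale * sqrt(area / pi))
}

.watershedSplit <- function(mask, minSep = 5) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("watershed splitting requires the EBImage package", call. = FALSE)
  bin <- mask > 0L
  dm <- EBImage::distmap(EBImage::Image(bin * 1))
  ws <- EBImage::watershed(dm, tolerance = 1, ext = as.integer(minSep))
  m <- EBImage::imageData(ws)
  storage.mode(m) <- "integer"
  m
}

#' Read and write labelled masks
#'
#' TIFF rasters are read with integer values preserved (16-bit, up to 65535
#' labels); PNG rasters are 8-bit scaled (label k stored as k/255, at most
#' 255 labels).
#'
#' @param path file path ending in .tif/.tiff or .png
#' @param mask integer matrix to write
#' @return `readLabeledMask()` an integer matrix; `writeLabeledMask()` the
#'   path, invisibly
#' @export
readLabeledMask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    tif = , tiff = tiff::readTIFF(path, as.is = TRUE),
    png = round(png::readPNG(path) * 255),
    stop("unsupported mask format: .", ext, call. = FALSE))
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  storage.mode(m) <- "integer"
  m
}

#' @rdname readLabeledMask
#' @export
writeLabeledMask <- function(mask, path) {
  storage.mode(mask) <- "integer"
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(mask / 65535, path,
                                   bits.per.sample = 16L),
    png = {
      if (max(mask) > 255L)
        stop("PNG masks support at most 255 labels; use TIFF",
             call. = FALSE)
      png::writePNG(mask / 255, path)
    },
    stop("unsupported mask format: .", ext, call. = FALSE))
  invisible(path)
}

## ---- CSV round trips -------------------------------------------------------

.readTable <- function(path, required, positive = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s) in ", basename(path), ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  ## data line numbers: header is line 1 (+ any leading comment lines)
  nSkip <- 0L
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, 1L)
    if (!length(ln) || !startsWith(ln, "#")) break
    nSkip <- nSkip + 1L
  }
  for (cl in required) {
    bad <- which(!is.finite(df[[cl]]))
    if (length(bad))
      stop("non-finite ", cl, " in ", basename(path), " at line ",
           bad[1L] + 1L + nSkip, call. = FALSE)
  }
  for (cl in positive) {
    bad <- which(df[[cl]] <= 0)
    if (length(bad))
      stop(cl, " must be > 0 in ", basename(path), " at line ",
           bad[1L] + 1L + nSkip, call. = FALSE)
  }
  df
}

#' CSV round trip for nucleus observations and cell estimates
#'
#' Plain comma-separated UTF-8 with '.' decimal. Observation files require
#' columns id, x, y, r_nuc; cell files additionally z and R. Unknown columns
#' are preserved on read and ignored by the model. A header comment records
#' the coordinate convention.
#'
#' @param path CSV file path
#' @param obs,cells data.frame to write
#' @return the read data.frame, or (for writers) the path invisibly
#' @export
readNucleiCsv <- function(path) {
  df <- .readTable(path, c("id", "x", "y", "r_nuc"), positive = "r_nuc")
  .checkObservations(df, what = basename(path))
  df
}

#' @rdname readNucleiCsv
#' @export
writeNucleiCsv <- function(obs, path) {
  .checkObservations(obs)
  .writeCommented(obs, path)
}

#' @rdname readNucleiCsv
#' @export
readCellsCsv <- function(path) {
  df <- .readTable(path, c("id", "x", "y", "z", "R"))
  .checkCells(df, what = basename(path))
  df
}

#' @rdname readNucleiCsv
#' @export
writeCellsCsv <- function(cells, path) {
  .checkCells(cells)
  .writeCommented(cells, path)
}

.writeCommented <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("# coordinates: 0-based pixel indices, x = column,",
                   "y = row, pixel-center convention; lengths in pixels"),
             con)
  ## full-precision numerics so that write -> read is lossless
  for (cl in names(df))
    if (is.double(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
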