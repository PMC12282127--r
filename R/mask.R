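#' Binarized vein mask
#'
#' Wraps a 2-D boolean raster in which foreground pixels are vein.  Raster
#' coordinates follow the (row, col) convention with the row index increasing
#' downward; exported tables use 0-based coordinates, while matrices in R are
#' indexed 1-based as usual.
#'
#' @param pixels logical or numeric matrix; nonzero/TRUE = vein.
#' @param pixel_scale physical length of one pixel side (any unit; default 1,
#'   i.e. features are reported in pixel units).
#' @return An object of class `vein_mask`: a logical matrix with a
#'   `pixel_scale` attribute.
#' @examples
#' m <- matrix(0, 5, 7); m[3, ] <- 1
#' vein_mask(m)
#' @export
vein_mask <- function(pixels, pixel_scale = 1) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  px <- if (is.logical(pixels)) pixels else pixels != 0
  if (!any(px)) stop("mask has no foreground (vein) pixels")
  if (!is.numeric(pixel_scale) || length(pixel_scale) != 1 || pixel_scale <= 0)
    stop("`pixel_scale` must be a single positive number")
  structure(px, pixel_scale = pixel_scale, class = c("vein_mask", "matrix"))
}

#' Read a binarized vein mask from a PNG or TIFF file
#'
#' Any nonzero pixel (first channel, if multi-channel) is treated as vein.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param pixel_scale physical length per pixel (default 1).
#' @return A [vein_mask()].
#' @export
read_vein_mask <- function(path, pixel_scale = 1) {
  img <- read_raster(path)
  vein_mask(img != 0, pixel_scale = pixel_scale)
}

read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext, " (use PNG or TIFF)")
  )
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' @export
print.vein_mask <- function(x, ...) {
  cat(sprintf("vein mask: %d x %d pixels, %d foreground (%.1f%%), pixel scale %g\n",
              nrow(x), ncol(x), sum(x), 100 * mean(x),
              attr(x, "pixel_scale")))
  invisible(x)
}

# --- raster helpers ---------------------------------------------------------

# 8-connected component labels of the TRUE pixels of a logical matrix.
# Returns an integer matrix (0 = background).
label_components8 <- function(px) {
  lab <- matrix(0L, nrow(px), ncol(px))
  idx <- which(px)
  if (!length(idx)) return(lab)
  nr <- nrow(px)
  pos <- seq_along(idx)
  lut <- integer(length(px)); lut[idx] <- pos
  # union-find over foreground pixels
  parent <- pos
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  offs <- cbind(c(-1L, -1L, -1L, 0L), c(-1L, 0L, 1L, -1L))  # causal half of 8-hood
  for (k in seq_len(nrow(offs))) {
    r2 <- rows + offs[k, 1]; c2 <- cols + offs[k, 2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= ncol(px)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- lut[nb] > 0L
    a <- pos[ok][hit]; b <- lut[nb][hit]
    for (j in seq_along(a)) unite(a[j], b[j])
  }
  roots <- vapply(pos, find, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

# number of 8-neighbours that are TRUE, per pixel (matrix of same shape)
neighbour_count8 <- function(px) {
  p <- matrix(0L, nrow(px) + 2L, ncol(px) + 2L)
  p[2:(nrow(px) + 1L), 2:(ncol(px) + 1L)] <- as.integer(px)
  nr <- nrow(px); nc <- ncol(px)
  out <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out + p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  out
}

# coordinates (row, col) of the TRUE pixels, as a 2-column integer matrix
which_coords <- function(px) {
  idx <- which(px)
  cbind(row = ((idx - 1L) %% nrow(px)) + 1L,
        col = ((idx - 1L) %/% nrow(px)) + 1L)
}
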