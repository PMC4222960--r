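#' Rasters, masks and circular footprints
#'
#' Images ("rasters") are plain numeric matrices of pixel intensities in the
#' 8-bit range; pixel masks are logical matrices of the same shape.  Circular
#' neighbourhoods are defined on the pixel lattice: an offset (dx, dy)
#' belongs to a disc of diameter d when dx^2 + dy^2 <= (d/2)^2, so a
#' diameter-21 disc is 21 pixels wide and holds 349 pixels.
#'
#' @param diameter disc diameter in pixels.
#' @return `disc_offsets()` returns a two-column integer matrix of (dx, dy)
#'   offsets; `disc_area()` the number of pixels in the footprint.
#' @examples
#' nrow(disc_offsets(21))   # 349
#' @export
disc_offsets <- function(diameter) {
  if (diameter < 1) stop_config("disc diameter must be >= 1")
  r <- diameter / 2
  if (diameter %% 2 == 1) {
    b <- floor(r)
    g <- expand.grid(dx = -b:b, dy = -b:b)
    keep <- g$dx^2 + g$dy^2 <= r^2
  } else {
    # even diameter: disc centred on a pixel corner (centre at +0.5, +0.5)
    b <- diameter / 2
    g <- expand.grid(dx = -b:(b - 1L), dy = -b:(b - 1L))
    keep <- (g$dx + 0.5)^2 + (g$dy + 0.5)^2 <= r^2
  }
  as.matrix(g[keep, , drop = FALSE])
}

#' @rdname disc_offsets
#' @export
disc_area <- function(diameter) nrow(disc_offsets(diameter))

# round-half-up, the quantization used for all 8-bit images
round_half_up <- function(x) floor(x + 0.5)

clip8 <- function(x) pmin(pmax(x, 0), 255)

quantize8 <- function(x) clip8(round_half_up(x))

# stamp TRUE into `mask` on the disc footprint centred at (ci, cj) (row, col),
# clipping at the borders; returns the linear indices touched
stamp_disc_idx <- function(dim_img, ci, cj, offsets) {
  ii <- ci + offsets[, 1L]
  jj <- cj + offsets[, 2L]
  ok <- ii >= 1L & ii <= dim_img[1L] & jj >= 1L & jj <= dim_img[2L]
  (jj[ok] - 1L) * dim_img[1L] + ii[ok]
}

as_mask <- function(x) {
  if (!is.logical(x)) storage.mode(x) <- "logical"
  x
}

check_same_shape <- function(a, b, what = "images") {
  if (!identical(dim(a), dim(b)))
    stop_config(sprintf("%s must have identical dimensions", what))
  invisible(TRUE)
}

# Poisson background field: drawn as Poisson(quanta) and rescaled so the
# mean equals `mean` (identical when mean == quanta); quanta = 0 disables
# noise and gives a flat field at `mean`.
poisson_background <- function(n, mean, quanta) {
  if (quanta <= 0) return(rep(mean, n))
  rpois(n, quanta) * (mean / quanta)
}
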