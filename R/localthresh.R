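#' Circular calculation window
#'
#' All local thresholds are computed from the pixels inside a circular
#' window centred on each pixel (default diameter 21 px, 349 pixels).
#' Windows are clipped at the image border: statistics use the in-bounds
#' pixels only.
#'
#' @param diameter window diameter in pixels (odd).
#' @return an object of class `window_spec` holding the diameter and the
#'   integer offsets of the footprint.
#' @export
window_spec <- function(diameter = 21) {
  if (diameter %% 2 != 1) stop_config("window diameter must be odd")
  off <- disc_offsets(diameter)
  structure(list(diameter = diameter, offsets = off, area = nrow(off)),
            class = "window_spec")
}

as_window <- function(w) {
  if (inherits(w, "window_spec")) w else window_spec(w)
}

new_threshold_field <- function(values, method, parameters = list()) {
  structure(values, method = method, parameters = parameters,
            class = c("threshold_field", class(values)))
}

#' @export
print.threshold_field <- function(x, ...) {
  cat(sprintf("<threshold_field> %s, %d x %d, range [%.2f, %.2f]\n",
              attr(x, "method"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Strip a threshold field to its plain numeric matrix
#'
#' @param f a `threshold_field`.
#' @return the field values as a bare numeric matrix.
#' @export
field_values <- function(f) {
  v <- unclass(f)
  attr(v, "method") <- NULL
  attr(v, "parameters") <- NULL
  v
}

#' Local window statistics as threshold fields
#'
#' Per-pixel threshold fields from circular-window statistics:
#' * `local_mean()` - the local mean threshold (LMT), the arithmetic mean of
#'   the window pixels;
#' * `local_sd()` - the population standard deviation over the same window;
#' * `local_median()` - the window median (mean of the central pair for an
#'   even pixel count);
#' * `lm_plus_ksd()` - local mean plus `k` local standard deviations
#'   (default k = 2);
#' * `lmb()` - the local mean background (LMB), the mean of the window
#'   pixels flagged as background by `background`; when a window holds no
#'   background pixel its diameter grows in 2 px steps until one is found;
#' * `lmb_plus_ksd()` - LMB plus `k` standard deviations of the local
#'   background pixels (default k = 2).
#'
#' Fields are real-valued; quantization happens only when a field is applied
#' (see [apply_threshold()]).
#'
#' @param img numeric matrix of pixel intensities.
#' @param w a [window_spec()] or a diameter.
#' @param k multiplier on the local standard deviation.
#' @param background logical matrix flagging background pixels (for the LMB
#'   variants); must contain at least one `TRUE`.
#' @return a `threshold_field` (numeric matrix with method metadata).
#' @examples
#' img <- matrix(rpois(900, 32), 30, 30)
#' f <- local_mean(img, window_spec(7))
#' @export
local_mean <- function(img, w = window_spec()) {
  w <- as_window(w)
  st <- cpp_window_mean_sd(img, w$offsets[, 1L], w$offsets[, 2L])
  new_threshold_field(st$mean, "local_mean", list(diameter = w$diameter))
}

#' @rdname local_mean
#' @export
local_sd <- function(img, w = window_spec()) {
  w <- as_window(w)
  st <- cpp_window_mean_sd(img, w$offsets[, 1L], w$offsets[, 2L])
  new_threshold_field(st$sd, "local_sd", list(diameter = w$diameter))
}

#' @rdname local_mean
#' @export
local_median <- function(img, w = window_spec()) {
  w <- as_window(w)
  v <- cpp_window_median(img, w$offsets[, 1L], w$offsets[, 2L])
  new_threshold_field(v, "local_median", list(diameter = w$diameter))
}

#' @rdname local_mean
#' @export
lm_plus_ksd <- function(img, w = window_spec(), k = 2) {
  w <- as_window(w)
  st <- cpp_window_mean_sd(img, w$offsets[, 1L], w$offsets[, 2L])
  new_threshold_field(st$mean + k * st$sd, "lm_plus_ksd",
                      list(diameter = w$diameter, k = k))
}

#' @rdname local_mean
#' @export
lmb <- function(img, background, w = window_spec()) {
  w <- as_window(w)
  background <- as_mask(background)
  check_same_shape(img, background, "image and background mask")
  if (!any(background)) stop_config("background mask is empty")
  st <- cpp_window_masked_mean_sd(img, background, w$offsets[, 1L],
                                  w$offsets[, 2L], w$diameter / 2)
  new_threshold_field(st$mean, "lmb", list(diameter = w$diameter))
}

#' @rdname local_mean
#' @export
lmb_plus_ksd <- function(img, background, w = window_spec(), k = 2) {
  w <- as_window(w)
  background <- as_mask(background)
  check_same_shape(img, background, "image and background mask")
  if (!any(background)) stop_config("background mask is empty")
  st <- cpp_window_masked_mean_sd(img, background, w$offsets[, 1L],
                                  w$offsets[, 2L], w$diameter / 2)
  new_threshold_field(st$mean + k * st$sd, "lmb_plus_ksd",
                      list(diameter = w$diameter, k = k))
}

#' Phansalkar local threshold
#'
#' The Phansalkar method, designed to reject low-intensity background:
#' on the normalized image the threshold is
#' `t = m * (1 + p * exp(-q * m) + k * (s / r - 1))`
#' with `m` and `s` the window mean and standard deviation.  The default
#' parameters (k = 0.25, r = 0.5, p = 2, q = 10) are the method's published
#' defaults.  `normalize = "stretch"` (the default, and what the common
#' ImageJ implementation does) min-max stretches the image to \[0, 1\]
#' before applying the formula; `"fixed"` divides by 255.  The returned
#' field is expressed back in intensity units.
#'
#' @inheritParams local_mean
#' @param k,r,p,q method parameters; `r` must be positive.
#' @param normalize `"stretch"` or `"fixed"`.
#' @return a `threshold_field` in intensity units.
#' @export
phansalkar <- function(img, w = window_spec(), k = 0.25, r = 0.5, p = 2,
                       q = 10, normalize = c("stretch", "fixed")) {
  if (r <= 0) stop_config("phansalkar: r must be positive")
  normalize <- match.arg(normalize)
  w <- as_window(w)
  if (normalize == "stretch") {
    lo <- min(img); hi <- max(img)
    scale <- if (hi > lo) hi - lo else 1
  } else {
    lo <- 0; scale <- 255
  }
  norm <- (img - lo) / scale
  st <- cpp_window_mean_sd(norm, w$offsets[, 1L], w$offsets[, 2L])
  m <- st$mean; s <- st$sd
  t_norm <- m * (1 + p * exp(-q * m) + k * (s / r - 1))
  new_threshold_field(lo + t_norm * scale, "phansalkar",
                      list(diameter = w$diameter, k = k, r = r, p = p, q = q,
                           normalize = normalize))
}

#' Apply a threshold field to an image
#'
#' A pixel is designated foreground when its intensity is strictly above its
#' local threshold.  By default the real-valued field is first quantized to
#' the integer intensity grid (round half up), reproducing the behaviour of
#' 8-bit threshold images; the discreteness of photon-counting intensities
#' makes the segmentation statistics sensitive to this convention, so it is
#' exposed via `quantize` and `ties`.
#'
#' @param img numeric matrix.
#' @param field a `threshold_field` or plain numeric matrix of the same shape.
#' @param mode `"binary"` returns the foreground mask; `"zero_below"`
#'   returns a copy of the image with non-foreground pixels set to zero.
#' @param quantize round the field to the integer grid before comparing.
#' @param ties `"background"` (default: a pixel exactly at the threshold is
#'   background) or `"foreground"`.
#' @return a logical mask (`"binary"`) or a numeric matrix (`"zero_below"`).
#' @examples
#' img <- matrix(rpois(400, 32), 20, 20)
#' mask <- apply_threshold(img, local_mean(img, window_spec(5)))
#' @export
apply_threshold <- function(img, field, mode = c("binary", "zero_below"),
                            quantize = TRUE, ties = c("background",
                                                      "foreground")) {
  mode <- match.arg(mode)
  ties <- match.arg(ties)
  f <- if (inherits(field, "threshold_field")) field_values(field) else field
  check_same_shape(img, f, "image and threshold field")
  if (quantize) f <- round_half_up(f)
  keep <- if (ties == "background") img > f else img >= f
  if (mode == "binary") return(keep)
  out <- img
  out[!keep] <- 0
  out
}

# shared dispatcher used by the evaluation experiments and the CLI
threshold_methods <- c("lm", "lm_sd2", "median", "lmb", "lmb_sd2",
                       "phansalkar")

# Compute several threshold fields sharing the window passes: one mean/SD
# pass serves lm, lm_sd2 and phansalkar (whose normalization is linear, so
# its window statistics follow from the raw ones), one masked pass serves
# both LMB variants.  Used by the benchmark sweeps where all methods run on
# the same image.
threshold_fields <- function(img, methods, w = window_spec(),
                             background = NULL, k = 2) {
  w <- as_window(w)
  out <- list()
  if (any(methods %in% c("lm", "lm_sd2", "phansalkar"))) {
    st <- cpp_window_mean_sd(img, w$offsets[, 1L], w$offsets[, 2L])
    if ("lm" %in% methods)
      out$lm <- new_threshold_field(st$mean, "local_mean",
                                    list(diameter = w$diameter))
    if ("lm_sd2" %in% methods)
      out$lm_sd2 <- new_threshold_field(st$mean + k * st$sd, "lm_plus_ksd",
                                        list(diameter = w$diameter, k = k))
    if ("phansalkar" %in% methods) {
      lo <- min(img); hi <- max(img)
      scale <- if (hi > lo) hi - lo else 1
      m <- (st$mean - lo) / scale
      s <- st$sd / scale
      t_norm <- m * (1 + 2 * exp(-10 * m) + 0.25 * (s / 0.5 - 1))
      out$phansalkar <- new_threshold_field(
        lo + t_norm * scale, "phansalkar",
        list(diameter = w$diameter, k = 0.25, r = 0.5, p = 2, q = 10,
             normalize = "stretch"))
    }
  }
  if ("median" %in% methods)
    out$median <- local_median(img, w)
  if (any(methods %in% c("lmb", "lmb_sd2"))) {
    if (is.null(background))
      stop_config("lmb methods require a background mask")
    background <- as_mask(background)
    stm <- cpp_window_masked_mean_sd(img, background, w$offsets[, 1L],
                                     w$offsets[, 2L], w$diameter / 2)
    if ("lmb" %in% methods)
      out$lmb <- new_threshold_field(stm$mean, "lmb",
                                     list(diameter = w$diameter))
    if ("lmb_sd2" %in% methods)
      out$lmb_sd2 <- new_threshold_field(stm$mean + k * stm$sd,
                                         "lmb_plus_ksd",
                                         list(diameter = w$diameter, k = k))
  }
  out[methods[methods %in% names(out)]]
}

compute_threshold <- function(img, method, w = window_spec(),
                              background = NULL, k = 2, ...) {
  switch(method,
    lm = local_mean(img, w),
    lm_sd2 = lm_plus_ksd(img, w, k = k),
    median = local_median(img, w),
    lmb = {
      if (is.null(background)) stop_config("lmb requires a background mask")
      lmb(img, background, w)
    },
    lmb_sd2 = {
      if (is.null(background)) stop_config("lmb_sd2 requires a background mask")
      lmb_plus_ksd(img, background, w, k = k)
    },
    phansalkar = phansalkar(img, w, ...),
    stop_config(sprintf("unknown threshold method '%s'", method)))
}
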