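#' Pixel populations for colocalization measurements
#'
#' Coefficients are only meaningful over a declared pixel population.  Given
#' per-channel foreground masks, `pixel_selection()` builds the standard
#' populations: `"all"` (every pixel), `"and"` (co-occurrence: foreground in
#' both channels), `"or"` (foreground in either), `"and+bg"` (AND plus the
#' pixels that are background in both), and `"background"` (background in
#' both).
#'
#' @param mode one of `"all"`, `"and"`, `"or"`, `"and+bg"`, `"background"`.
#' @param fg1,fg2 logical foreground masks for the two channels (required
#'   for every mode except `"all"`).
#' @return a logical matrix selecting the population.
#' @export
pixel_selection <- function(mode = c("all", "and", "or", "and+bg",
                                     "background"), fg1 = NULL, fg2 = NULL) {
  mode <- match.arg(mode)
  if (mode == "all") {
    if (is.null(fg1)) stop_config("mode 'all' needs fg1 (for the shape) or use a full mask directly")
    return(matrix(TRUE, nrow(fg1), ncol(fg1)))
  }
  if (is.null(fg1) || is.null(fg2))
    stop_config("fg1 and fg2 are required for this selection mode")
  check_same_shape(fg1, fg2, "foreground masks")
  fg1 <- as_mask(fg1); fg2 <- as_mask(fg2)
  switch(mode,
    "and" = fg1 & fg2,
    "or" = fg1 | fg2,
    "and+bg" = (fg1 & fg2) | (!fg1 & !fg2),
    "background" = !fg1 & !fg2)
}

select_pixels <- function(ch1, ch2, select) {
  check_same_shape(ch1, ch2, "channels")
  if (is.null(select)) {
    list(R = as.vector(ch1), G = as.vector(ch2))
  } else {
    check_same_shape(ch1, select, "channel and selection mask")
    select <- as_mask(select)
    list(R = ch1[select], G = ch2[select])
  }
}

#' Colocalization coefficients
#'
#' All coefficients are computed over the selected pixel population only
#' (`select = NULL` means all pixels):
#' * `pearson_r()` - sample Pearson correlation of the paired intensities;
#' * `h_coef()` - `H = N * sum(R * G) / (sum(R) * sum(G))` with `N` the
#'   number of selected pixels; 1 for independent channels with no empty
#'   pixels, inflated by empty pixels, not offset-invariant;
#' * `moc()` - the Manders overlap coefficient
#'   `sum(R * G) / sqrt(sum(R^2) * sum(G^2))`, unaffected by empty pixels;
#' * `manders()` - the co-occurrence pair `M1 = sum(R over pixels
#'   foreground in channel 2) / sum(R over foreground-1 pixels)` and the
#'   symmetric `M2` (or area fractions with `weighted = FALSE`);
#' * `cooccurrence_area()` - the fraction of all pixels foreground in both
#'   channels.
#'
#' Undefined results (empty or constant selections, zero-intensity channels)
#' signal a classed error of class `"colocbench_undefined"` rather than
#' returning a value, so that sweeps can record gaps.
#'
#' @param ch1,ch2 numeric matrices (the two channels), identical shape.
#' @param select logical matrix declaring the pixel population, or `NULL`
#'   for all pixels.
#' @return a single numeric value.
#' @examples
#' a <- matrix(c(10, 0, 3, 7), 2, 2)
#' h_coef(a, a)
#' moc(a, a)   # 1
#' @export
pearson_r <- function(ch1, ch2, select = NULL) {
  v <- select_pixels(ch1, ch2, select)
  if (length(v$R) < 2)
    stop_undefined("correlation needs at least two selected pixels")
  if (sd(v$R) == 0 || sd(v$G) == 0)
    stop_undefined("correlation is undefined for a constant channel")
  cor(v$R, v$G)
}

#' @rdname pearson_r
#' @export
h_coef <- function(ch1, ch2, select = NULL) {
  v <- select_pixels(ch1, ch2, select)
  sR <- sum(v$R); sG <- sum(v$G)
  if (length(v$R) == 0 || sR <= 0 || sG <= 0)
    stop_undefined("H coefficient is undefined when a channel has zero total intensity")
  length(v$R) * sum(v$R * v$G) / (sR * sG)
}

#' @rdname pearson_r
#' @export
moc <- function(ch1, ch2, select = NULL) {
  v <- select_pixels(ch1, ch2, select)
  e1 <- sum(v$R^2); e2 <- sum(v$G^2)
  if (length(v$R) == 0 || e1 <= 0 || e2 <= 0)
    stop_undefined("MOC is undefined when a channel has zero energy")
  sum(v$R * v$G) / sqrt(e1 * e2)
}

#' @rdname pearson_r
#' @param fg1,fg2 per-channel foreground masks.  When omitted, foreground is
#'   taken as intensity > 0 (the convention after [background_correct()],
#'   where zero is the reserved empty value).
#' @param weighted intensity-weighted Manders coefficients (the default) or
#'   plain area fractions.
#' @export
manders <- function(ch1, ch2, fg1 = NULL, fg2 = NULL, weighted = TRUE) {
  check_same_shape(ch1, ch2, "channels")
  if (is.null(fg1)) fg1 <- ch1 > 0
  if (is.null(fg2)) fg2 <- ch2 > 0
  fg1 <- as_mask(fg1); fg2 <- as_mask(fg2)
  if (!any(fg1) || !any(fg2))
    stop_undefined("Manders coefficients are undefined without foreground in both channels")
  both <- fg1 & fg2
  if (weighted) {
    M1 <- sum(ch1[both]) / sum(ch1[fg1])
    M2 <- sum(ch2[both]) / sum(ch2[fg2])
  } else {
    M1 <- sum(both) / sum(fg1)
    M2 <- sum(both) / sum(fg2)
  }
  c(M1 = M1, M2 = M2)
}

#' @rdname pearson_r
#' @export
cooccurrence_area <- function(fg1, fg2) {
  fg1 <- as_mask(fg1); fg2 <- as_mask(fg2)
  check_same_shape(fg1, fg2, "foreground masks")
  sum(fg1 & fg2) / length(fg1)
}

#' Background and offset correction
#'
#' `background_correct()` implements the two-step correction needed by the
#' co-occurrence measures: pixels below the threshold `th` are set to zero
#' (designated background), and the background mean `bkmn` is subtracted
#' from the remaining pixels (floored at zero) so that intensities are
#' proportional to fluorophore amounts.
#'
#' @param img numeric matrix.
#' @param th intensity threshold separating foreground from background.
#' @param bkmn background mean offset to subtract from foreground pixels.
#' @return corrected numeric matrix.
#' @export
background_correct <- function(img, th, bkmn) {
  if (bkmn > th)
    warning("background mean exceeds the threshold; inverted background model")
  out <- img
  out[img < th] <- 0
  keep <- img >= th
  out[keep] <- pmax(img[keep] - bkmn, 0)
  out
}

#' Estimate the background mean and threshold from the intensity histogram
#'
#' For an image whose intensity histogram is bimodal (a background peak and
#' a foreground peak), the background mean is the mode of the lower
#' intensity peak and the threshold is the histogram minimum between the two
#' peaks.  The 256-bin histogram is smoothed with a small moving average
#' before peak-finding because photon-counting backgrounds have noisy
#' histograms.  A histogram without two well-separated peaks signals a
#' classed error (`"colocbench_no_estimate"`); the caller must then supply
#' values.
#'
#' @param img numeric matrix with intensities in \[0, 255\].
#' @param smooth moving-average width in bins (odd, default 3).
#' @param min_prominence minimum height of the secondary peak, as a fraction
#'   of the main peak (default 0.05).
#' @return a list with `bkmn` (background mean) and `th` (threshold).
#' @export
estimate_background_mean <- function(img, smooth = 3, min_prominence = 0.05) {
  counts <- tabulate(pmin(pmax(round_half_up(img), 0), 255) + 1L,
                     nbins = 256L)
  k <- rep(1 / smooth, smooth)
  sm <- as.vector(stats::filter(counts, k, sides = 2))
  sm[is.na(sm)] <- counts[is.na(sm)]
  n <- length(sm)
  # interior local maxima (plateaus count once, at their first bin)
  left <- c(Inf, sm[-n]); right <- c(sm[-1L], Inf)
  peaks <- which(sm > left & sm >= right)
  peaks <- peaks[sm[peaks] >= min_prominence * max(sm)]
  if (length(peaks) < 2)
    stop_no_estimate("intensity histogram is not bimodal; supply th and bkmn")
  # the two tallest qualifying peaks, in intensity order
  top2 <- sort(peaks[order(sm[peaks], decreasing = TRUE)][1:2])
  between <- seq(top2[1L], top2[2L])
  valley <- between[which.min(sm[between])]
  if (sm[valley] >= min(sm[top2]))
    stop_no_estimate("no valley separates the two histogram peaks")
  # report the raw-histogram mode within the smoothed lower peak
  lo_window <- max(1L, top2[1L] - 2L):min(n, top2[1L] + 2L)
  bk_bin <- lo_window[which.max(counts[lo_window])]
  list(bkmn = bk_bin - 1L, th = valley - 1L)
}

#' Full coefficient report over a declared pixel population
#'
#' Computes every coefficient (r, H, MOC, M1, M2, co-occurrence area) over
#' one pixel selection; coefficients that are undefined on the selection are
#' reported as `NA`.
#'
#' @param ch1,ch2 numeric matrices.
#' @param fg1,fg2 per-channel foreground masks (default: intensity > 0).
#' @param selection a selection mode name (see [pixel_selection()]) or a
#'   logical matrix.
#' @return an object of class `coloc_report`: a list with the coefficient
#'   values, the selection label and `N`, the number of pixels used.
#' @export
coloc_report <- function(ch1, ch2, fg1 = ch1 > 0, fg2 = ch2 > 0,
                         selection = "all") {
  if (is.character(selection)) {
    label <- selection
    sel <- pixel_selection(selection, fg1, fg2)
  } else {
    label <- "custom"
    sel <- as_mask(selection)
  }
  out <- list(
    selection = label,
    N = sum(sel),
    r = na_if_undefined(pearson_r(ch1, ch2, sel)),
    H = na_if_undefined(h_coef(ch1, ch2, sel)),
    MOC = na_if_undefined(moc(ch1, ch2, sel)),
    M1 = na_if_undefined(manders(ch1, ch2, fg1, fg2)[["M1"]]),
    M2 = na_if_undefined(manders(ch1, ch2, fg1, fg2)[["M2"]]),
    cooccurrence_area = cooccurrence_area(fg1, fg2))
  class(out) <- "coloc_report"
  out
}

#' @export
print.coloc_report <- function(x, ...) {
  cat(sprintf("<coloc_report> selection=%s N=%d\n", x$selection, x$N))
  cat(sprintf("  r=%.4f  H=%.4f  MOC=%.4f  M1=%.4f  M2=%.4f  AND area=%.4f\n",
              x$r, x$H, x$MOC, x$M1, x$M2, x$cooccurrence_area))
  invisible(x)
}

#' @export
as.data.frame.coloc_report <- function(x, ...) {
  data.frame(selection = x$selection, N = x$N, r = x$r, H = x$H,
             MOC = x$MOC, M1 = x$M1, M2 = x$M2,
             cooccurrence_area = x$cooccurrence_area)
}
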