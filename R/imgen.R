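#' Disc test image specification
#'
#' Describes the segmentation test image: a row of circular objects of
#' increasing diameter at a uniform intensity above a Poisson background.
#' The default diameters (every integer from 1 to 55) extend the published
#' 3-39 px series; objects sit on a single row with margins wide enough that
#' the 10.5 px evaluation annuli never touch each other or the image border.
#'
#' @param diameters object diameters in pixels (all >= 1).
#' @param object_intensity intensity added on object pixels (default 128).
#' @param bg_mean background mean intensity (default 32).
#' @param bg_quanta expected Poisson count for the background noise
#'   (default 32, giving SD sqrt(32) = 5.66); 0 disables noise.
#' @param margin clearance, in pixels, between a disc edge and its nearest
#'   neighbour or the image border (default 30).
#' @param width,height optional canvas size; computed from the layout when
#'   `NULL`, and rejected if too small for non-touching discs.
#' @param centers optional n x 2 matrix of (row, col) disc centres
#'   overriding the automatic layout.
#' @param replicates number of noise replicates the spec is intended for.
#' @param seed base RNG seed; replicate k uses seed + k - 1.
#' @return an object of class `disc_image_spec`.
#' @seealso [make_disc_image()]
#' @export
disc_image_spec <- function(diameters = 1:55,
                            object_intensity = 128, bg_mean = 32,
                            bg_quanta = 32, margin = 30,
                            width = NULL, height = NULL, centers = NULL,
                            replicates = 8, seed = 1) {
  if (any(diameters < 1)) stop_config("all diameters must be >= 1")
  if (object_intensity + bg_mean > 255)
    stop_config("object_intensity + bg_mean must be <= 255 for 8-bit images")
  spec <- list(diameters = diameters, object_intensity = object_intensity,
               bg_mean = bg_mean, bg_quanta = bg_quanta, margin = margin,
               width = width, height = height, centers = centers,
               replicates = replicates, seed = seed)
  class(spec) <- "disc_image_spec"
  spec
}

# automatic one-row layout; returns centers (row, col) and canvas size
disc_layout <- function(diameters, margin, width = NULL, height = NULL) {
  r <- diameters / 2
  n <- length(diameters)
  # columns: margin, then discs separated by `margin`
  cx <- numeric(n)
  x <- margin
  for (k in seq_len(n)) {
    cx[k] <- x + r[k]
    x <- x + diameters[k] + margin
  }
  need_w <- ceiling(x)
  need_h <- ceiling(max(diameters) + 2 * margin)
  if (is.null(width)) width <- need_w
  if (is.null(height)) height <- need_h
  if (width < need_w || height < need_h)
    stop_config("canvas too small: discs would touch the image border")
  list(centers = cbind(row = rep(round(height / 2), n), col = round(cx)),
       width = width, height = height)
}

#' Generate a disc test image
#'
#' Renders the disc objects of a [disc_image_spec()] at a uniform intensity
#' on top of a Poisson background that covers the whole image (objects carry
#' `object_intensity` plus the same noise), then quantizes to 8 bits.
#'
#' @param spec a [disc_image_spec()].
#' @param replicate replicate index (seeds the noise as `seed + replicate - 1`).
#' @return a list with `image` (numeric matrix), `foreground` (logical
#'   ground-truth mask), `centers`, and `labels` (integer matrix, 0 =
#'   background, k = k-th disc).
#' @examples
#' d <- make_disc_image(disc_image_spec(diameters = c(5, 9), margin = 12))
#' mean(d$image[!d$foreground])  # close to 32
#' @export
make_disc_image <- function(spec, replicate = 1) {
  stopifnot(inherits(spec, "disc_image_spec"))
  if (is.null(spec$centers)) {
    lay <- disc_layout(spec$diameters, spec$margin, spec$width, spec$height)
  } else {
    if (is.null(spec$width) || is.null(spec$height))
      stop_config("width and height are required with explicit centers")
    lay <- list(centers = spec$centers, width = spec$width,
                height = spec$height)
  }
  nr <- lay$height; nc <- lay$width
  fg <- matrix(FALSE, nr, nc)
  labels <- matrix(0L, nr, nc)
  n <- length(spec$diameters)
  for (k in seq_len(n)) {
    off <- disc_offsets(spec$diameters[k])
    ci <- lay$centers[k, 1L]; cj <- lay$centers[k, 2L]
    if (ci + min(off[, 1L]) < 1 || ci + max(off[, 1L]) > nr ||
        cj + min(off[, 2L]) < 1 || cj + max(off[, 2L]) > nc)
      stop_config("disc exceeds the image bounds")
    idx <- stamp_disc_idx(c(nr, nc), ci, cj, off)
    if (any(fg[idx])) stop_config("discs overlap")
    fg[idx] <- TRUE
    labels[idx] <- k
  }
  set.seed(spec$seed + replicate - 1L)
  noise <- poisson_background(nr * nc, spec$bg_mean, spec$bg_quanta)
  img <- matrix(noise, nr, nc) + spec$object_intensity * fg
  list(image = quantize8(img), foreground = fg,
       centers = lay$centers, labels = labels)
}

#' Random-object pair specification
#'
#' Uncorrelated image pairs built by inserting radius-5 discs of random
#' uniform intensity at random positions until a target area fraction
#' (the Fill%) is occupied; image 1 is always filled to exactly half the
#' Fill% of image 2.  Non-object pixels carry a Poisson background.
#'
#' @param size image side in pixels (square, default 512).
#' @param object_radius disc radius in pixels (default 5).
#' @param fill2_percent target occupied-area percent of image 2
#'   (0 < fill <= 95; random insertion cannot fill an image completely).
#' @param intensity_low,intensity_high object intensity range (default 64, 254);
#'   each object takes one integer draw from this range.
#' @param bg_mean,bg_quanta background mean and Poisson quanta (default 16, 16).
#' @param seed RNG seed.
#' @return an object of class `random_object_spec`.
#' @export
random_object_spec <- function(size = 512, object_radius = 5,
                               fill2_percent = 50, intensity_low = 64,
                               intensity_high = 254, bg_mean = 16,
                               bg_quanta = 16, seed = 1) {
  if (fill2_percent <= 0 || fill2_percent > 95)
    stop_config("completely filling an image by inserting random objects is impractical: fill2_percent must be in (0, 95]")
  if (intensity_low >= intensity_high)
    stop_config("intensity_low must be < intensity_high")
  spec <- list(size = size, object_radius = object_radius,
               fill2_percent = fill2_percent, intensity_low = intensity_low,
               intensity_high = intensity_high, bg_mean = bg_mean,
               bg_quanta = bg_quanta, seed = seed)
  class(spec) <- "random_object_spec"
  spec
}

# grow one random-object channel, recording a snapshot as each target
# fill fraction (sorted, in [0, 1]) is first reached or exceeded
grow_random_objects <- function(size, radius, targets, int_low, int_high,
                                bg_mean, bg_quanta) {
  off <- disc_offsets(2 * radius + 1)
  npx <- size * size
  bg <- matrix(poisson_background(npx, bg_mean, bg_quanta), size, size)
  mask <- matrix(FALSE, size, size)
  vals <- matrix(0, size, size)
  targets <- sort(targets)
  snaps <- vector("list", length(targets))
  covered <- 0L
  t_i <- 1L
  # a target of 0 is an empty channel
  while (t_i <= length(targets) && targets[t_i] <= 0) {
    snaps[[t_i]] <- list(image = quantize8(bg), foreground = mask,
                         fill = 0, n_objects = 0L)
    t_i <- t_i + 1L
  }
  n_obj <- 0L
  while (t_i <= length(targets)) {
    ci <- sample.int(size, 1L); cj <- sample.int(size, 1L)
    idx <- stamp_disc_idx(c(size, size), ci, cj, off)
    covered <- covered + sum(!mask[idx])
    mask[idx] <- TRUE
    vals[idx] <- sample(int_low:int_high, 1L)   # one draw per object
    n_obj <- n_obj + 1L
    while (t_i <= length(targets) && covered / npx >= targets[t_i]) {
      img <- ifelse(mask, vals, bg)
      snaps[[t_i]] <- list(image = quantize8(img), foreground = mask,
                           fill = covered / npx, n_objects = n_obj)
      t_i <- t_i + 1L
    }
  }
  snaps
}

#' Generate a random-object image pair
#'
#' @param spec a [random_object_spec()].
#' @return a list with `image1`, `image2`, `fg1`, `fg2` (ground-truth object
#'   masks) and the realized fill fractions `fill1`, `fill2`.
#' @examples
#' p <- make_random_object_pair(random_object_spec(size = 128, fill2_percent = 20))
#' mean(p$fg1) # ~0.10
#' @export
make_random_object_pair <- function(spec) {
  stopifnot(inherits(spec, "random_object_spec"))
  set.seed(spec$seed)
  s2 <- grow_random_objects(spec$size, spec$object_radius,
                            spec$fill2_percent / 100,
                            spec$intensity_low, spec$intensity_high,
                            spec$bg_mean, spec$bg_quanta)[[1L]]
  s1 <- grow_random_objects(spec$size, spec$object_radius,
                            spec$fill2_percent / 200,
                            spec$intensity_low, spec$intensity_high,
                            spec$bg_mean, spec$bg_quanta)[[1L]]
  list(image1 = s1$image, image2 = s2$image,
       fg1 = s1$foreground, fg2 = s2$foreground,
       fill1 = s1$fill, fill2 = s2$fill)
}

#' Intensity distributions for the copy-fraction engine
#'
#' `dist_linear()` is a uniform ("linear") distribution described by its mean
#' and full width (default mean 128, width 200, i.e. uniform on \[28, 228\]);
#' `dist_gaussian()` is a normal distribution (default mean 128, SD 24)
#' truncated to \[23, 233\].
#'
#' @param mean distribution mean in intensity units.
#' @param width full width of the uniform distribution.
#' @param sd standard deviation of the Gaussian.
#' @param range clipping range for the Gaussian draw.
#' @return a distribution descriptor used by [copy_fraction_spec()].
#' @export
dist_linear <- function(mean = 128, width = 200) {
  structure(list(type = "linear", mean = mean, width = width),
            class = "cf_distribution")
}

#' @rdname dist_linear
#' @export
dist_gaussian <- function(mean = 128, sd = 24, range = c(23, 233)) {
  structure(list(type = "gaussian", mean = mean, sd = sd, range = range),
            class = "cf_distribution")
}

draw_cf_distribution <- function(dist, n) {
  switch(dist$type,
    linear = runif(n, dist$mean - dist$width / 2, dist$mean + dist$width / 2),
    gaussian = pmin(pmax(rnorm(n, dist$mean, dist$sd), dist$range[1L]),
                    dist$range[2L]),
    stop_config("unknown distribution type"))
}

#' Copy-fraction pair specification
#'
#' The copy-fraction engine turns two independent base images into a pair
#' with a chosen correlation: a fraction `cf` of each pixel's deviation from
#' its image mean is replaced by the (signed) deviation of the corresponding
#' pixel of the other image,
#' `I_n1 = m1 + (1 - |cf|) (I_o1 - m1) + sign(cf) |cf| (I_2 - m2)`.
#' `cf = +1` duplicates the second image (r = +1), `cf = -1` mirrors it
#' (r = -1), `cf = 0` leaves the images independent.  Optionally a fraction
#' of pixel positions is set to zero in both images ("void" pixels) and a
#' constant offset is added to the modified image.
#'
#' @param cf copy fraction in \[-1, 1\].
#' @param distribution a [dist_linear()] or [dist_gaussian()] descriptor for
#'   the base intensities.
#' @param void_fraction fraction of pixel positions zeroed in both images.
#' @param offset constant added to the modified image after voiding.
#' @param size image side in pixels (square, default 512).
#' @param seed RNG seed.
#' @return an object of class `copy_fraction_spec`.
#' @export
copy_fraction_spec <- function(cf, distribution = dist_linear(),
                               void_fraction = 0, offset = 0,
                               size = 512, seed = 1) {
  if (abs(cf) > 1) stop_config("|cf| must be <= 1")
  if (void_fraction < 0 || void_fraction >= 1)
    stop_config("void_fraction must be in [0, 1)")
  spec <- list(cf = cf, distribution = distribution,
               void_fraction = void_fraction, offset = offset,
               size = size, seed = seed)
  class(spec) <- "copy_fraction_spec"
  spec
}

# core mixing step on continuous base images (no quantization)
copy_fraction_mix <- function(base1, base2, cf) {
  m1 <- mean(base1); m2 <- mean(base2)
  m1 + (1 - abs(cf)) * (base1 - m1) + sign(cf) * abs(cf) * (base2 - m2)
}

finalize_cf_pair <- function(base2, mixed, void_idx, offset) {
  R <- quantize8(base2)
  G <- quantize8(mixed)
  if (length(void_idx)) {
    R[void_idx] <- 0
    G[void_idx] <- 0
  }
  if (offset != 0) G <- clip8(G + offset)
  list(R = R, G = G)
}

#' Generate a copy-fraction image pair
#'
#' @param spec a [copy_fraction_spec()].
#' @return a list with `R` (the fixed image, from the second base
#'   distribution) and `G` (the modified image), both 8-bit matrices.
#' @examples
#' p <- make_copy_fraction_pair(copy_fraction_spec(cf = 1, size = 64))
#' cor(as.vector(p$R), as.vector(p$G))  # ~ +1
#' @export
make_copy_fraction_pair <- function(spec) {
  stopifnot(inherits(spec, "copy_fraction_spec"))
  set.seed(spec$seed)
  n <- spec$size^2
  base1 <- matrix(draw_cf_distribution(spec$distribution, n),
                  spec$size, spec$size)
  base2 <- matrix(draw_cf_distribution(spec$distribution, n),
                  spec$size, spec$size)
  mixed <- copy_fraction_mix(base1, base2, spec$cf)
  void_idx <- if (spec$void_fraction > 0)
    sample.int(n, floor(spec$void_fraction * n)) else integer(0)
  finalize_cf_pair(base2, mixed, void_idx, spec$offset)
}

#' Cartoon-cell specification
#'
#' A two-compartment "cell": a circular cell containing a circular nucleus,
#' fluorophore 1 confined to the nucleus and fluorophore 2 to the cytoplasm
#' (cell minus nucleus), with no fluorophore outside the cell.  Intensities
#' per compartment are either uniform (a single value) or ranged (one
#' independent uniform draw per pixel).
#'
#' @param size image side in pixels.
#' @param cell_radius,nucleus_radius radii in pixels; the nucleus must lie
#'   inside the cell.
#' @param nucleus_offset (row, col) displacement of the nucleus centre from
#'   the cell centre.
#' @param ch1,ch2 compartment intensity models, [intensity_uniform()] or
#'   [intensity_ranged()]; channel 1 fills the nucleus, channel 2 the
#'   cytoplasm.
#' @param seed RNG seed (used by ranged intensities).
#' @return an object of class `cartoon_cell_spec`.
#' @export
cartoon_cell_spec <- function(size = 256, cell_radius = 100,
                              nucleus_radius = 45,
                              nucleus_offset = c(0, -25),
                              ch1 = intensity_uniform(180),
                              ch2 = intensity_uniform(140),
                              seed = 1) {
  if (sqrt(sum(nucleus_offset^2)) + nucleus_radius >= cell_radius)
    stop_config("nucleus must lie strictly inside the cell")
  if (cell_radius >= size / 2)
    stop_config("cell must fit inside the image")
  spec <- list(size = size, cell_radius = cell_radius,
               nucleus_radius = nucleus_radius,
               nucleus_offset = nucleus_offset, ch1 = ch1, ch2 = ch2,
               seed = seed)
  class(spec) <- "cartoon_cell_spec"
  spec
}

#' @rdname cartoon_cell_spec
#' @param value uniform compartment intensity.
#' @export
intensity_uniform <- function(value) {
  structure(list(type = "uniform", value = value), class = "intensity_model")
}

#' @rdname cartoon_cell_spec
#' @param low,high range of the per-pixel uniform draw.
#' @export
intensity_ranged <- function(low, high) {
  structure(list(type = "ranged", low = low, high = high),
            class = "intensity_model")
}

fill_compartment <- function(model, n) {
  switch(model$type,
    uniform = rep(model$value, n),
    ranged = runif(n, model$low, model$high),
    stop_config("unknown intensity model"))
}

#' Generate a cartoon cell
#'
#' @param spec a [cartoon_cell_spec()].
#' @return a list with `ch1`, `ch2` (8-bit matrices), and masks `nucleus`,
#'   `cytoplasm`, `cell` (nucleus OR cytoplasm).
#' @examples
#' cc <- make_cartoon_cell(cartoon_cell_spec(size = 128, cell_radius = 50,
#'                                           nucleus_radius = 20))
#' sel <- cc$cell
#' cor(cc$ch1[sel], cc$ch2[sel])  # exactly -1 for uniform intensities
#' @export
make_cartoon_cell <- function(spec) {
  stopifnot(inherits(spec, "cartoon_cell_spec"))
  n <- spec$size
  ctr <- (n + 1) / 2
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  cell <- (rows - ctr)^2 + (cols - ctr)^2 <= spec$cell_radius^2
  nuc_ci <- ctr + spec$nucleus_offset[1L]
  nuc_cj <- ctr + spec$nucleus_offset[2L]
  nucleus <- (rows - nuc_ci)^2 + (cols - nuc_cj)^2 <= spec$nucleus_radius^2
  if (any(nucleus & !cell)) stop_config("compartment masks overlap the exterior")
  cytoplasm <- cell & !nucleus
  set.seed(spec$seed)
  ch1 <- matrix(0, n, n)
  ch2 <- matrix(0, n, n)
  ch1[nucleus] <- fill_compartment(spec$ch1, sum(nucleus))
  ch2[cytoplasm] <- fill_compartment(spec$ch2, sum(cytoplasm))
  list(ch1 = quantize8(ch1), ch2 = quantize8(ch2),
       nucleus = nucleus, cytoplasm = cytoplasm, cell = cell)
}
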