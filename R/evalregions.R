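#' Decompose a ground-truth mask into evaluation regions
#'
#' Splits the image into the six regions used to localize where a
#' thresholding method succeeds or fails: the objects and the background,
#' each subdivided by proximity to the object edge.  The edge contour is
#' traced by the background pixels 8-adjacent to an object; the annuli
#' contain every pixel (inside or outside the objects) within
#' `annulus_width` pixels of an edge-pixel centre.  The six masks partition
#' the image exactly.
#'
#' @param fg logical ground-truth foreground mask (nonempty, not full).
#' @param annulus_width annulus half-width in pixels (default 10.5).
#' @return a list of class `region_set` with masks `objects_all`,
#'   `inner_annulus`, `objects_centre`, `background_all`, `outer_annulus`,
#'   `background_remainder`.
#' @export
decompose_regions <- function(fg, annulus_width = 10.5) {
  if (annulus_width <= 0) stop_config("annulus_width must be positive")
  fg <- as_mask(fg)
  if (!any(fg) || all(fg))
    stop_config("foreground mask must be nonempty and not cover everything")
  nr <- nrow(fg); nc <- ncol(fg)
  # edge = background pixels 8-adjacent to an object (the contour runs just
  # outside the foreground); padding keeps border objects counted
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- fg
  nb_fg <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb_fg <- nb_fg + pad[(2:(nr + 1L)) + di, (2:(nc + 1L)) + dj]
  }
  edge <- !fg & nb_fg > 0L
  # annulus = union of discs of radius annulus_width around edge pixels
  b <- floor(annulus_width)
  g <- expand.grid(dx = -b:b, dy = -b:b)
  off <- as.matrix(g[g$dx^2 + g$dy^2 <= annulus_width^2, , drop = FALSE])
  ed <- which(edge)
  ei <- ((ed - 1L) %% nr) + 1L
  ej <- ((ed - 1L) %/% nr) + 1L
  K <- nrow(off)
  ii <- rep(ei, each = K) + off[, 1L]
  jj <- rep(ej, each = K) + off[, 2L]
  ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
  annulus <- matrix(FALSE, nr, nc)
  annulus[cbind(ii[ok], jj[ok])] <- TRUE
  out <- list(objects_all = fg,
              inner_annulus = fg & annulus,
              objects_centre = fg & !annulus,
              background_all = !fg,
              outer_annulus = !fg & annulus,
              background_remainder = !fg & !annulus)
  class(out) <- "region_set"
  out
}

#' Score a predicted segmentation against ground-truth regions
#'
#' For each object region the score is the percentage of pixels predicted
#' foreground; for each background region, the percentage predicted
#' background.
#'
#' @param predicted_fg logical mask from a thresholding method.
#' @param regions a `region_set` from [decompose_regions()].
#' @return named numeric vector of percent-correct values for the six
#'   regions.
#' @export
score_classification <- function(predicted_fg, regions) {
  stopifnot(inherits(regions, "region_set"))
  predicted_fg <- as_mask(predicted_fg)
  check_same_shape(predicted_fg, regions$objects_all,
                   "prediction and region masks")
  pct <- function(mask, want_fg) {
    if (!any(mask)) return(NA_real_)
    100 * mean(if (want_fg) predicted_fg[mask] else !predicted_fg[mask])
  }
  c(objects_all = pct(regions$objects_all, TRUE),
    inner_annulus = pct(regions$inner_annulus, TRUE),
    objects_centre = pct(regions$objects_centre, TRUE),
    background_all = pct(regions$background_all, FALSE),
    outer_annulus = pct(regions$outer_annulus, FALSE),
    background_remainder = pct(regions$background_remainder, FALSE))
}

#' Per-region classification benchmark of the local thresholding methods
#'
#' Applies each thresholding method to noise replicates of the extended disc
#' test image and scores the six evaluation regions.  With the defaults
#' (diameters 1-55, window diameter 21, 8 replicates) this reproduces the
#' published per-method percent-correct table.
#'
#' @param spec a [disc_image_spec()]; the default extended image.
#' @param methods character vector of method names among `"lm"`,
#'   `"lm_sd2"`, `"median"`, `"lmb"`, `"lmb_sd2"`, `"phansalkar"`.
#' @param w calculation window, a [window_spec()].
#' @param replicates number of noise replicates.
#' @param annulus_width evaluation annulus half-width (default 10.5).
#' @return a data frame with one row per (method, replicate, region).  Use
#'   [table1_summary()] for the per-method means in table layout.
#' @export
run_table1 <- function(spec = disc_image_spec(), methods = threshold_methods,
                       w = window_spec(21), replicates = spec$replicates,
                       annulus_width = 10.5) {
  regions <- NULL
  rows <- list()
  for (rep_i in seq_len(replicates)) {
    d <- make_disc_image(spec, rep_i)
    if (is.null(regions))
      regions <- decompose_regions(d$foreground, annulus_width)
    bg_mask <- !d$foreground
    fields <- threshold_fields(d$image, methods, w, background = bg_mask)
    for (m in methods) {
      pred <- apply_threshold(d$image, fields[[m]], "binary")
      sc <- score_classification(pred, regions)
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, replicate = rep_i, region = names(sc),
        percent_correct = unname(sc))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname run_table1
#' @param result a data frame from [run_table1()].
#' @return `table1_summary()`: a data frame of per-method means, one column
#'   per region (objects: all / annulus / centre; background: all /
#'   annulus / remainder).
#' @export
table1_summary <- function(result) {
  regions <- c("objects_all", "inner_annulus", "objects_centre",
               "background_all", "outer_annulus", "background_remainder")
  methods <- unique(result$method)
  out <- data.frame(method = methods)
  for (rg in regions) {
    out[[rg]] <- vapply(methods, function(m) {
      mean(result$percent_correct[result$method == m & result$region == rg])
    }, numeric(1))
  }
  out
}

#' Thresholding effectiveness versus object size
#'
#' For each disc of the test image, the fraction of its pixels designated
#' foreground, against the object area expressed as a fraction of the
#' calculation-window area.
#'
#' @inheritParams run_table1
#' @return a data frame with one row per (method, replicate, object):
#'   `diameter`, `area_ratio` (object area / window area) and
#'   `fraction_correct`.
#' @export
run_size_sweep <- function(spec = disc_image_spec(),
                           methods = threshold_methods, w = window_spec(21),
                           replicates = spec$replicates) {
  w <- as_window(w)
  rows <- list()
  for (rep_i in seq_len(replicates)) {
    d <- make_disc_image(spec, rep_i)
    bg_mask <- !d$foreground
    fields <- threshold_fields(d$image, methods, w, background = bg_mask)
    for (m in methods) {
      pred <- apply_threshold(d$image, fields[[m]], "binary")
      for (k in seq_along(spec$diameters)) {
        obj <- d$labels == k
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, replicate = rep_i, object = k,
          diameter = spec$diameters[k],
          area_ratio = sum(obj) / w$area,
          fraction_correct = mean(pred[obj]))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation and co-occurrence versus Fill%
#'
#' Grows random-object image pairs (image 1 always at half the Fill% of
#' image 2) and records, at each Fill% step, the Pearson correlation over
#' the AND, OR and AND+background pixel populations, the Manders M1/M2, and
#' the co-occurrence area fraction.
#'
#' @param fills Fill% grid for image 2 (default 5 to 95 by 5).
#' @param replicates number of independently seeded image sets (default 4).
#' @param size image side in pixels.
#' @param seed base seed; replicate k uses seed + k - 1.
#' @param spec_template a [random_object_spec()] carrying the object and
#'   background parameters (its fill and seed are ignored).
#' @return a data frame with one row per (fill, replicate):
#'   realized fills, `r_and`, `r_or`, `r_and_bg`, `M1`, `M2`, `and_area`
#'   (fraction of image pixels in AND).
#' @export
run_fill_sweep <- function(fills = seq(5, 95, by = 5), replicates = 4,
                           size = 512, seed = 1,
                           spec_template = random_object_spec(size = size)) {
  rows <- list()
  for (rep_i in seq_len(replicates)) {
    set.seed(seed + rep_i - 1L)
    snaps2 <- grow_random_objects(size, spec_template$object_radius,
                                  fills / 100,
                                  spec_template$intensity_low,
                                  spec_template$intensity_high,
                                  spec_template$bg_mean,
                                  spec_template$bg_quanta)
    snaps1 <- grow_random_objects(size, spec_template$object_radius,
                                  fills / 200,
                                  spec_template$intensity_low,
                                  spec_template$intensity_high,
                                  spec_template$bg_mean,
                                  spec_template$bg_quanta)
    for (f_i in seq_along(fills)) {
      s1 <- snaps1[[f_i]]; s2 <- snaps2[[f_i]]
      fg1 <- s1$foreground; fg2 <- s2$foreground
      i1 <- s1$image; i2 <- s2$image
      mm <- na_if_undefined(manders(i1, i2, fg1, fg2))
      rows[[length(rows) + 1L]] <- data.frame(
        fill = fills[f_i], replicate = rep_i,
        fill1 = s1$fill, fill2 = s2$fill,
        r_and = na_if_undefined(
          pearson_r(i1, i2, pixel_selection("and", fg1, fg2))),
        r_or = na_if_undefined(
          pearson_r(i1, i2, pixel_selection("or", fg1, fg2))),
        r_and_bg = na_if_undefined(
          pearson_r(i1, i2, pixel_selection("and+bg", fg1, fg2))),
        M1 = if (length(mm) == 2) mm[["M1"]] else NA_real_,
        M2 = if (length(mm) == 2) mm[["M2"]] else NA_real_,
        and_area = cooccurrence_area(fg1, fg2))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Coefficient response to the copy fraction, void pixels and offsets
#'
#' Sweeps the copy fraction over a grid (default +1 down to -1 in steps of
#' 0.1, matching the published image stacks) for each combination of void
#' fraction and offset, holding the two base images fixed within a
#' replicate, and records r and the H coefficient over all pixels.
#'
#' @param cfs copy-fraction grid.
#' @param void_fractions fractions of pixel positions zeroed in both images.
#' @param offsets constants added to the modified image.
#' @param distribution a [dist_linear()] or [dist_gaussian()].
#' @param size image side in pixels.
#' @param seed base seed; replicate k uses seed + k - 1.
#' @param replicates independently seeded base-image pairs.
#' @return a data frame with one row per (cf, void_fraction, offset,
#'   replicate) holding `r` and `H`.
#' @export
run_copyfraction_sweep <- function(cfs = seq(1, -1, by = -0.1),
                                   void_fractions = 0, offsets = 0,
                                   distribution = dist_linear(),
                                   size = 512, seed = 1, replicates = 1) {
  rows <- list()
  n <- size * size
  for (rep_i in seq_len(replicates)) {
    set.seed(seed + rep_i - 1L)
    base1 <- matrix(draw_cf_distribution(distribution, n), size, size)
    base2 <- matrix(draw_cf_distribution(distribution, n), size, size)
    void_idx_all <- sample.int(n)   # one shuffle; prefixes give the voids
    for (vf in void_fractions) {
      void_idx <- if (vf > 0) void_idx_all[seq_len(floor(vf * n))] else integer(0)
      for (off in offsets) {
        for (cf in cfs) {
          pair <- finalize_cf_pair(base2, copy_fraction_mix(base1, base2, cf),
                                   void_idx, off)
          rows[[length(rows) + 1L]] <- data.frame(
            cf = cf, void_fraction = vf, offset = off, replicate = rep_i,
            r = na_if_undefined(pearson_r(pair$R, pair$G)),
            H = na_if_undefined(h_coef(pair$R, pair$G)))
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Effect of the local mean threshold on colocalization measurements
#'
#' Builds a pair of horizontal strips through the object row of the disc
#' test image, with the noise drawn independently for each strip, and
#' reports r and the H coefficient over the designated-foreground pixels and
#' over all pixels, before and after zeroing sub-threshold pixels with the
#' local mean threshold.  Before thresholding the foreground channels are
#' independent (r ~ 0); zeroing below the LMT creates new intensity
#' combinations that inflate both r and H.
#'
#' @param spec a [disc_image_spec()] (default: the original 3-39 px series).
#' @param strip_height strip height in pixels (default 62).
#' @param w calculation window.
#' @param seed RNG seed for the two independent noise draws.
#' @return a list with data frame `report` (population x stage rows of r, H
#'   and N) and the two strip pairs (`before1`, `before2`, `after1`,
#'   `after2`, `foreground`).
#' @export
run_lmt_strip_experiment <- function(spec = disc_image_spec(
                                       diameters = seq(3, 39, by = 2),
                                       margin = 22, seed = 101),
                                     strip_height = 62, w = window_spec(21),
                                     seed = spec$seed) {
  d1 <- make_disc_image(spec, 1)
  d2 <- make_disc_image(spec, 2)   # same objects, independent noise
  mid <- d1$centers[1L, 1L]
  half <- floor(strip_height / 2)
  rows_sel <- (mid - half + 1):(mid - half + strip_height)
  s1 <- d1$image[rows_sel, , drop = FALSE]
  s2 <- d2$image[rows_sel, , drop = FALSE]
  fg <- d1$foreground[rows_sel, , drop = FALSE]
  a1 <- apply_threshold(s1, local_mean(s1, w), "zero_below")
  a2 <- apply_threshold(s2, local_mean(s2, w), "zero_below")
  kept <- a1 > 0 & a2 > 0   # designated foreground in both channels
  report <- rbind(
    data.frame(stage = "before", population = "foreground",
               r = na_if_undefined(pearson_r(s1, s2, fg)),
               H = na_if_undefined(h_coef(s1, s2, fg)), N = sum(fg)),
    data.frame(stage = "before", population = "all",
               r = na_if_undefined(pearson_r(s1, s2)),
               H = na_if_undefined(h_coef(s1, s2)), N = length(s1)),
    data.frame(stage = "after", population = "foreground",
               r = na_if_undefined(pearson_r(a1, a2, kept)),
               H = na_if_undefined(h_coef(a1, a2, kept)), N = sum(kept)),
    data.frame(stage = "after", population = "all",
               r = na_if_undefined(pearson_r(a1, a2)),
               H = na_if_undefined(h_coef(a1, a2)), N = length(a1)))
  list(report = report, before1 = s1, before2 = s2, after1 = a1,
       after2 = a2, foreground = fg)
}
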