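test_that("window statistics match exhaustive oracles on random images", {
  set.seed(21)
  for (case in 1:25) {
    nr <- sample(5:20, 1); nc <- sample(5:20, 1)
    d <- sample(c(3, 5, 7), 1)
    img <- random_test_image(nr, nc)
    w <- window_spec(d)
    expect_equal(field_values(local_mean(img, w)),
                 oracle_window_stat(img, d, "mean"), tolerance = 1e-12)
    expect_equal(field_values(local_sd(img, w)),
                 oracle_window_stat(img, d, "sd"), tolerance = 1e-12)
    expect_equal(field_values(local_median(img, w)),
                 oracle_window_stat(img, d, "median"), tolerance = 1e-12)
    mask <- matrix(runif(nr * nc) < 0.7, nr, nc)
    mask[1, 1] <- TRUE   # keep the mask dense enough that no window is empty
    if (min(nr, nc) >= d) {
      expect_equal(field_values(lmb(img, mask, w)),
                   oracle_window_stat(img, d, "mean", mask), tolerance = 1e-12)
    }
  }
})

test_that("constant images give the trivial threshold fields", {
  img <- matrix(77, 12, 15)
  w <- window_spec(5)
  expect_true(all(field_values(local_mean(img, w)) == 77))
  expect_true(all(field_values(local_sd(img, w)) == 0))
  expect_true(all(field_values(local_median(img, w)) == 77))
  expect_true(all(field_values(lm_plus_ksd(img, w, k = 2)) == 77))
  mask <- matrix(TRUE, 12, 15)
  expect_true(all(field_values(lmb(img, mask, w)) == 77))
})

test_that("k = 0 reduces the SD variants to their base fields", {
  set.seed(4)
  img <- random_test_image(15, 15)
  mask <- matrix(runif(225) < 0.5, 15, 15)
  w <- window_spec(5)
  expect_equal(field_values(lm_plus_ksd(img, w, k = 0)),
               field_values(local_mean(img, w)))
  expect_equal(field_values(lmb_plus_ksd(img, mask, w, k = 0)),
               field_values(lmb(img, mask, w)))
  # a background mask covering everything degenerates to the local mean
  expect_equal(field_values(lmb(img, matrix(TRUE, 15, 15), w)),
               field_values(local_mean(img, w)))
})

test_that("shift equivariance: +c moves location fields by c, SD unchanged", {
  set.seed(8)
  img <- random_test_image(18, 14, max_val = 200)
  mask <- matrix(runif(18 * 14) < 0.6, 18, 14)
  w <- window_spec(7)
  c0 <- 17
  expect_equal(field_values(local_mean(img + c0, w)),
               field_values(local_mean(img, w)) + c0)
  expect_equal(field_values(local_median(img + c0, w)),
               field_values(local_median(img, w)) + c0)
  expect_equal(field_values(lmb(img + c0, mask, w)),
               field_values(lmb(img, mask, w)) + c0)
  expect_equal(field_values(local_sd(img + c0, w)),
               field_values(local_sd(img, w)))
})

test_that("raising k never increases the retained-pixel count", {
  set.seed(12)
  img <- random_test_image(20, 20)
  mask <- matrix(runif(400) < 0.5, 20, 20)
  w <- window_spec(5)
  for (fields in list(
    lapply(c(0, 1, 2, 3), function(k) lm_plus_ksd(img, w, k = k)),
    lapply(c(0, 1, 2, 3), function(k) lmb_plus_ksd(img, mask, w, k = k)))) {
    kept <- vapply(fields, function(f)
      sum(apply_threshold(img, f, "binary")), numeric(1))
    expect_true(all(diff(kept) <= 0))
  }
})

test_that("LMB grows its window until background is found", {
  img <- matrix(10, 25, 25)
  img[13, 1] <- 200            # the only background-flagged pixel
  bg <- matrix(FALSE, 25, 25)
  bg[13, 1] <- TRUE
  f <- field_values(lmb(img, bg, window_spec(21)))
  expect_true(all(is.finite(f)))
  # pixel (13, 13) is 12 px from the only background pixel: the base window
  # (radius 10.5) misses it and the field must equal that pixel's value
  expect_equal(f[13, 13], 200)
  expect_error(lmb(img, matrix(FALSE, 25, 25), window_spec(21)),
               class = "colocbench_config")
})

test_that("phansalkar closed form, reduction to local mean, errors", {
  img <- matrix(255, 10, 10)
  f <- field_values(phansalkar(img, window_spec(5), normalize = "fixed"))
  expect_equal(f[5, 5], (1 + 2 * exp(-10) - 0.25) * 255, tolerance = 1e-12)
  # p = 0, k = 0 reduces to the local mean (fixed normalization is linear)
  set.seed(2)
  rimg <- random_test_image(12, 12)
  f0 <- field_values(phansalkar(rimg, window_spec(5), k = 0, p = 0,
                                normalize = "fixed"))
  expect_equal(f0, field_values(local_mean(rimg, window_spec(5))),
               tolerance = 1e-12)
  expect_error(phansalkar(img, window_spec(5), r = 0),
               class = "colocbench_config")
})

test_that("apply_threshold modes agree and respect ties/quantization", {
  set.seed(30)
  img <- matrix(sample(1:255, 300, replace = TRUE), 15, 20)
  field <- local_mean(img, window_spec(5))
  mask <- apply_threshold(img, field, "binary")
  zeroed <- apply_threshold(img, field, "zero_below")
  expect_identical(zeroed > 0, mask)   # no retained pixel is 0 here
  expect_true(all(zeroed[mask] == img[mask]))
  # trivial fields (on a strictly positive image)
  expect_true(all(apply_threshold(img, matrix(0, 15, 20), "binary")))
  expect_false(any(apply_threshold(img, matrix(256, 15, 20), "binary")))
  # tie handling: pixel equal to the threshold
  tie <- matrix(5, 3, 3)
  expect_false(any(apply_threshold(tie, matrix(5, 3, 3), "binary")))
  expect_true(all(apply_threshold(tie, matrix(5, 3, 3), "binary",
                                  ties = "foreground")))
  # quantization: a field of 31.6 rounds to 32, so 32 is background
  expect_false(apply_threshold(matrix(32, 1, 1), matrix(31.6, 1, 1),
                               "binary")[1, 1])
  expect_true(apply_threshold(matrix(32, 1, 1), matrix(31.6, 1, 1),
                              "binary", quantize = FALSE)[1, 1])
})

test_that("threshold_fields agrees with the individual method functions", {
  set.seed(55)
  img <- random_test_image(30, 30)
  bg <- matrix(runif(900) < 0.5, 30, 30)
  w <- window_spec(7)
  fl <- colocbench:::threshold_fields(
    img, c("lm", "lm_sd2", "median", "lmb", "lmb_sd2", "phansalkar"), w,
    background = bg)
  expect_equal(field_values(fl$lm), field_values(local_mean(img, w)))
  expect_equal(field_values(fl$lm_sd2), field_values(lm_plus_ksd(img, w)))
  expect_equal(field_values(fl$median), field_values(local_median(img, w)))
  expect_equal(field_values(fl$lmb), field_values(lmb(img, bg, w)))
  expect_equal(field_values(fl$lmb_sd2),
               field_values(lmb_plus_ksd(img, bg, w)))
  expect_equal(field_values(fl$phansalkar),
               field_values(phansalkar(img, w)), tolerance = 1e-12)
})
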