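test_that("coefficients agree with direct-summation oracles on tiny images", {
  set.seed(99)
  for (case in 1:120) {
    nr <- sample(2:5, 1); nc <- sample(2:5, 1)
    R <- random_test_image(nr, nc, 40) + 1   # strictly positive
    G <- random_test_image(nr, nc, 40) + 1
    sel <- matrix(TRUE, nr, nc)
    if (sd(R) == 0 || sd(G) == 0) next
    expect_equal(pearson_r(R, G, sel), oracle_r(R, G, sel), tolerance = 1e-10)
    expect_equal(h_coef(R, G, sel), oracle_h(R, G, sel), tolerance = 1e-10)
    expect_equal(moc(R, G, sel), oracle_moc(R, G, sel), tolerance = 1e-10)
    fg1 <- matrix(runif(nr * nc) < 0.7, nr, nc)
    fg2 <- matrix(runif(nr * nc) < 0.7, nr, nc)
    if (any(fg1) && any(fg2)) {
      expect_equal(unname(manders(R, G, fg1, fg2)), oracle_m12(R, G, fg1, fg2),
                   tolerance = 1e-10)
    }
  }
})

test_that("trivial coefficient identities", {
  set.seed(14)
  R <- random_test_image(8, 8, 100) + 1
  expect_equal(pearson_r(R, R), 1)
  expect_equal(moc(R, R), 1)
  # all intensity in one pixel of N: H = N
  z <- matrix(0, 4, 4); z[2, 3] <- 50
  expect_equal(h_coef(z, z), 16)
  # disjoint supports: MOC = 0, M1 = M2 = 0
  a <- matrix(c(5, 5, 0, 0), 2, 2); b <- matrix(c(0, 0, 7, 7), 2, 2)
  expect_equal(moc(a, b), 0)
  expect_equal(unname(manders(a, b)), c(0, 0))
  # identical supports: M1 = M2 = 1
  expect_equal(unname(manders(a, a)), c(1, 1))
  # hand-built example: half of channel-1 intensity on channel-2 support
  R4 <- matrix(c(10, 10, 0, 0), 1, 4)
  G4 <- matrix(c(8, 0, 3, 0), 1, 4)
  expect_equal(manders(R4, G4)[["M1"]], 0.5)
  # co-occurrence area: full, disjoint, independent 10% fills ~ 1%
  m <- matrix(TRUE, 4, 4)
  expect_equal(cooccurrence_area(m, m), 1)
  expect_equal(cooccurrence_area(a > 0, b > 0), 0)
})

test_that("undefined coefficients signal instead of returning a value", {
  flat <- matrix(5, 3, 3)
  vary <- matrix(1:9, 3, 3)
  expect_error(pearson_r(flat, vary), class = "colocbench_undefined")
  expect_error(pearson_r(vary, vary, matrix(FALSE, 3, 3)),
               class = "colocbench_undefined")
  zero <- matrix(0, 3, 3)
  expect_error(h_coef(zero, vary), class = "colocbench_undefined")
  expect_error(moc(vary, zero), class = "colocbench_undefined")
  expect_error(manders(zero, vary), class = "colocbench_undefined")
  # selections of a single pixel are undefined for r
  one <- matrix(FALSE, 3, 3); one[1, 1] <- TRUE
  expect_error(pearson_r(vary, vary, one), class = "colocbench_undefined")
})

test_that("invariances: offsets and positive scaling", {
  set.seed(41)
  R <- random_test_image(32, 32, 150) + 1
  G <- random_test_image(32, 32, 150) + 1
  sel <- matrix(runif(1024) < 0.8, 32, 32)
  r0 <- pearson_r(R, G, sel)
  expect_equal(pearson_r(R + 31, G, sel), r0, tolerance = 1e-12)
  expect_equal(pearson_r(R, G + 12, sel), r0, tolerance = 1e-12)
  # H and MOC invariant under positive scaling of either channel
  expect_equal(h_coef(2.5 * R, G, sel), h_coef(R, G, sel), tolerance = 1e-12)
  expect_equal(moc(R, 0.3 * G, sel), moc(R, G, sel), tolerance = 1e-12)
  # H is NOT offset-invariant
  expect_false(isTRUE(all.equal(h_coef(R + 32, G, sel), h_coef(R, G, sel))))
})

test_that("coefficient bounds hold on random and structured inputs", {
  set.seed(77)
  for (case in 1:30) {
    R <- random_test_image(10, 10, 80)
    G <- random_test_image(10, 10, 80)
    sel <- matrix(TRUE, 10, 10)
    if (sd(R) > 0 && sd(G) > 0) {
      r <- pearson_r(R, G, sel)
      expect_true(r >= -1 && r <= 1)
    }
    if (sum(R) > 0 && sum(G) > 0) {
      H <- h_coef(R, G, sel)
      expect_true(H >= 0 && H <= length(R))
      expect_true(moc(R, G, sel) >= 0 && moc(R, G, sel) <= 1)
    }
    if (any(R > 0) && any(G > 0)) {
      m <- manders(R, G)
      expect_true(all(m >= 0 & m <= 1))
    }
  }
})

test_that("empty pixels inflate H, leave MOC unchanged, and lift r most when anti-correlated", {
  base <- make_copy_fraction_pair(copy_fraction_spec(
    cf = -0.8, size = 128, seed = 17))
  n <- length(base$R)
  set.seed(18)
  void <- sample.int(n, floor(0.5 * n))
  Rv <- base$R; Gv <- base$G
  Rv[void] <- 0; Gv[void] <- 0
  keep <- matrix(TRUE, 128, 128); keep[void] <- FALSE
  # adding the empty pixels to the population changes H but not MOC
  expect_equal(moc(Rv, Gv), moc(Rv, Gv, keep), tolerance = 1e-12)
  expect_gt(h_coef(Rv, Gv), h_coef(Rv, Gv, keep))
  # r over all pixels rises when the zeroed population is included
  expect_gt(pearson_r(Rv, Gv), pearson_r(Rv, Gv, keep))
})

test_that("background_correct zeroes below threshold and removes the offset", {
  img <- matrix(c(10, 40, 60, 100), 2, 2)
  out <- background_correct(img, th = 50, bkmn = 30)
  expect_equal(as.vector(out), c(0, 0, 30, 70))
  expect_equal(background_correct(img, 0, 0), img)
  # uniform background, threshold just above it: everything zero
  flat <- matrix(32, 4, 4)
  expect_true(all(background_correct(flat, 33, 32) == 0))
  expect_warning(background_correct(img, th = 20, bkmn = 30))
})

test_that("histogram background estimation recovers generator truth", {
  # noise-free two-level image: exact
  img <- matrix(c(rep(20, 600), rep(180, 400)), 25, 40)
  est <- estimate_background_mean(img)
  expect_equal(est$bkmn, 20)
  expect_true(est$th > 20 && est$th < 180)
  # disc test image: background mean 32 within 1 intensity unit
  d <- make_disc_image(disc_image_spec(seed = 6))
  est2 <- estimate_background_mean(d$image)
  expect_lte(abs(est2$bkmn - 32), 1)
  expect_true(est2$th > 32 && est2$th < 160)
  # pure noise: no estimate
  set.seed(10)
  noise <- matrix(rpois(1e4, 32), 100, 100)
  expect_error(estimate_background_mean(noise),
               class = "colocbench_no_estimate")
})

test_that("pixel selections satisfy their set identities", {
  set.seed(20)
  fg1 <- matrix(runif(100) < 0.4, 10, 10)
  fg2 <- matrix(runif(100) < 0.4, 10, 10)
  AND <- pixel_selection("and", fg1, fg2)
  OR <- pixel_selection("or", fg1, fg2)
  BG <- pixel_selection("background", fg1, fg2)
  ANDBG <- pixel_selection("and+bg", fg1, fg2)
  expect_true(all(OR[AND]))                       # AND subset of OR
  expect_identical(AND | BG, ANDBG)
  expect_identical(OR | BG, pixel_selection("all", fg1, fg2))
  expect_false(any(OR & BG))
})

test_that("coloc_report records NA for undefined coefficients", {
  cc <- make_cartoon_cell(cartoon_cell_spec(size = 64, cell_radius = 25,
                                            nucleus_radius = 10,
                                            nucleus_offset = c(0, -8)))
  rep_and <- coloc_report(cc$ch1, cc$ch2, cc$nucleus, cc$cytoplasm,
                          selection = "and")
  expect_equal(rep_and$N, 0)
  expect_true(is.na(rep_and$r))
  expect_equal(rep_and$cooccurrence_area, 0)
  rep_all <- coloc_report(cc$ch1, cc$ch2, cc$nucleus, cc$cytoplasm)
  expect_equal(rep_all$M1, 0)
  df <- as.data.frame(rep_all)
  expect_equal(nrow(df), 1)
})
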