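test_that("default kernel grid enumerates the 12-cell design with the calibrated noise levels", {
  grid <- defaultKernelGrid()
  expect_length(grid, 12L)
  keys <- vapply(grid, function(k) sprintf("%s%d", k@family, k@level),
                 character(1))
  expect_setequal(keys, as.vector(outer(c("Br", "Bv", "Qr"),
                                        c(36, 40, 44, 48), paste0)))
  br <- defaultKernelGrid("Br")
  expect_length(br, 4L)
  expect_equal(vapply(br, function(k) k@noiseSd, numeric(1)),
               c(37.9, 50.5, 72.4, 79.3))
  for (fam in c("Br", "Bv", "Qr")) {
    sub <- defaultKernelGrid(fam)
    psf <- vapply(sub, function(k) k@psfSigma, numeric(1))
    noi <- vapply(sub, function(k) k@noiseSd, numeric(1))
    expect_true(all(diff(psf) < 0))   # blur shrinks with sharpness level
    expect_true(all(diff(noi) > 0))   # noise grows with sharpness level
    expect_true(all(psf > 0))
    expect_true(all(vapply(sub, function(k) k@level, integer(1)) %in%
                      c(36L, 40L, 44L, 48L)))
  }
})

test_that("vessel images are reproducible and hit the expected values", {
  kern0 <- KernelSpec("Qr", 36, noiseSd = 0)
  spec <- PhantomSpec(kernel = kern0, seed = 7L)
  a <- generateVesselImage(spec)
  b <- generateVesselImage(spec)
  expect_identical(imageData(a), imageData(b))

  # noisy images: bit-identical for the same seed, different otherwise
  kernN <- KernelSpec("Qr", 36, noiseSd = 40)
  n1 <- generateVesselImage(PhantomSpec(kernel = kernN, seed = 3L))
  n2 <- generateVesselImage(PhantomSpec(kernel = kernN, seed = 3L))
  n3 <- generateVesselImage(PhantomSpec(kernel = kernN, seed = 4L))
  expect_identical(imageData(n1), imageData(n2))
  expect_false(identical(imageData(n1), imageData(n3)))

  # with a vanishing PSF the centre pixel reaches lumen HU plus kernel bias
  sharpKern <- KernelSpec("Br", 48, psfSigma = 1e-4, noiseSd = 0)
  img <- generateVesselImage(PhantomSpec(vesselHu = 800, fatHu = -80,
                                         kernel = sharpKern))
  d <- dim(imageData(img))
  centre <- imageData(img)[round(d[1] / 2), round(d[2] / 2)]
  expect_equal(centre, 800 + sharpKern@attenuationBias, tolerance = 1e-9)
})

test_that("phantom noise level and fat background are statistically faithful", {
  kern <- KernelSpec("Br", 36, noiseSd = 40)
  img <- generateVesselImage(PhantomSpec(kernel = kern, seed = 11L))
  fat <- CircularROI("fat", c(5, 5), 2)   # far from the 3.5 mm vessel at (10,10)
  m <- roiMeanSD(img, fat)
  expect_gte(m$n_pixels, 130)
  # sample SD of n iid N(0, 40) values has SE ~ 40 / sqrt(2 (n - 1))
  se_sd <- 40 / sqrt(2 * (m$n_pixels - 1))
  expect_lt(abs(m$sd_hu - 40), 4 * se_sd)
  # law of large numbers on the ROI mean
  se_mean <- 40 / sqrt(m$n_pixels)
  expect_lt(abs(m$mean_hu - (-80)), 4 * se_mean)
})

test_that("oversized vessels are rejected at spec construction", {
  expect_error(PhantomSpec(vesselDiameter = 18, fieldOfView = 20),
               "field of view")
  expect_error(PhantomSpec(vesselHu = -100, fatHu = -80), "fatHu")
})

test_that("synthetic profiles follow the double-sigmoid forward model", {
  g <- seq(-10, 13, by = 0.1)
  p <- generateProfile(-80, 880, 5, 0, 3, g, noiseSd = 0)
  v <- profileValues(p)
  expect_equal(v[1], -80, tolerance = 1e-9)           # left asymptote
  # sharp wide pulse reaches the plateau at the midpoint
  p2 <- generateProfile(-80, 880, 20, 0, 3, g, noiseSd = 0)
  expect_equal(profileValues(p2)[which.min(abs(g - 1.5))], 800,
               tolerance = 1e-6)
  # symmetry about the pulse midpoint
  mid <- 1.5
  xs <- c(0.3, 0.9, 1.2)
  left <- evalDoubleSigmoid(mid - xs, -80, 880, 5, 0, 3)
  right <- evalDoubleSigmoid(mid + xs, -80, 880, 5, 0, 3)
  expect_equal(left, right, tolerance = 1e-12)
  expect_error(generateProfile(-80, 880, 5, 0, 3, c(0, 1, 1, 2)),
               "ascending")
  # noise is reproducible under the seed
  pn1 <- generateProfile(-80, 880, 5, 0, 3, g, noiseSd = 30, seed = 5L)
  pn2 <- generateProfile(-80, 880, 5, 0, 3, g, noiseSd = 30, seed = 5L)
  expect_identical(profileValues(pn1), profileValues(pn2))
})

test_that("rating generator honours the latent ordinal model", {
  grid <- defaultKernelGrid()
  # no rater noise, no bias: raters agree on every score
  spec <- RatingModelSpec(nSubjects = 5, raterNoiseSd = 0, seed = 2L)
  r <- generateRatings(spec, grid)
  expect_true(all(r$score >= 1L & r$score <= 5L))
  expect_true(is.integer(r$score))
  wide <- reshape(r, idvar = c("subject", "family", "level", "criterion"),
                  timevar = "rater", direction = "wide")
  expect_equal(wide$score.1, wide$score.2)

  # flat latent quality: every score identical
  flat <- RatingModelSpec(nSubjects = 4, raterNoiseSd = 0,
    latentQuality = setNames(rep(0.6, 12), names(spec@latentQuality)))
  rf <- generateRatings(flat, grid)
  expect_length(unique(rf$score), 1L)

  # fixed seed reproducibility of the full table
  r2 <- generateRatings(RatingModelSpec(nSubjects = 5, raterNoiseSd = 0,
                                        seed = 2L), grid)
  expect_identical(r, r2)
})

test_that("noise-free two-rater tables give perfect inter-reader agreement", {
  r <- generateRatings(RatingModelSpec(nSubjects = 8, raterNoiseSd = 0,
                                       seed = 9L), defaultKernelGrid())
  sub <- r[r$criterion == "overall", ]
  wide <- reshape(sub[, c("subject", "family", "level", "rater", "score")],
                  idvar = c("subject", "family", "level"),
                  timevar = "rater", direction = "wide")
  res <- iccAbsoluteAgreement(as.matrix(wide[, c("score.1", "score.2")]))
  expect_equal(res@icc, 1.0)
  expect_identical(res@interpretation, "excellent")
})
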