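test_that("double-sigmoid evaluation is exact, symmetric and overflow-safe", {
  b <- -80; A <- 880; s <- 5; x1 <- 0; x2 <- 3
  expect_equal(evalDoubleSigmoid(-1e6, b, A, s, x1, x2), b)
  expect_equal(evalDoubleSigmoid(1e6, b, A, s, x1, x2), b)
  # wide sharp pulse plateaus at b + A
  expect_equal(evalDoubleSigmoid(1.5, b, A, 50, x1, x2), b + A,
               tolerance = 1e-10)
  # midpoint symmetry
  xs <- seq(-2, 5, by = 0.25)
  expect_equal(evalDoubleSigmoid(xs, b, A, s, x1, x2),
               evalDoubleSigmoid(x1 + x2 - xs, b, A, s, x1, x2),
               tolerance = 1e-12)
  # clamped exponents: no NaN at |s (x - xi)| >> 700
  v <- evalDoubleSigmoid(c(-1e5, 1e5), b, A, 100, x1, x2)
  expect_true(all(is.finite(v)))
  expect_equal(v, c(b, b))
})

test_that("profile extraction interpolates exactly on affine fields", {
  img <- ImageVolume(matrix(120, 50, 50), spacing = c(0.4, 0.4))
  site <- ProfileSite("c", c(10, 10), c(0.6, 0.8), 3, 0.1)
  p <- extractProfile(img, site)
  expect_true(all(abs(profileValues(p) - 120) < 1e-12))
  expect_equal(positions(p), seq(0, 6, by = 0.1))

  # bilinear interpolation reproduces an affine HU field exactly
  n <- 50
  cx <- (seq_len(n) - 0.5) * 0.4
  aff <- outer(2 * cx, 3 * cx, "+")  # HU = 2x + 3y
  imgA <- ImageVolume(aff, spacing = c(0.4, 0.4))
  pA <- extractProfile(imgA, site)
  t <- seq(-3, 3, by = 0.1)
  expected <- 2 * (10 + 0.6 * t) + 3 * (10 + 0.8 * t)
  expect_equal(profileValues(pA), expected, tolerance = 1e-9)

  expect_error(extractProfile(img, ProfileSite("far", c(1, 1), c(-1, 0), 4, 0.1)),
               "bounds")
})

test_that("half-rise of a mildly blurred disk sits at the vessel radius", {
  img <- phantomImage(psfSigma = 0.15, noiseSd = 0, diameter = 3.5)
  site <- radialSite(angle = 0.3, halfLength = 4, step = 0.05)
  p <- extractProfile(img, site)
  v <- profileValues(p)
  half <- (min(v) + max(v)) / 2
  pos <- positions(p)
  # falling crossing beyond the vessel centre (segment start is 4 mm before it)
  after <- pos > 4
  i <- which(after & v < half)[1]
  crossing <- approx(v[c(i - 1, i)], pos[c(i - 1, i)], xout = half)$y
  expect_lt(abs(crossing - (4 + 1.75)), 0.05 + 1e-9)  # within one step
})

test_that("fit initialization recovers edge locations and scales affinely", {
  g <- seq(-5, 8, by = 0.1)
  p <- generateProfile(-80, 880, 5, 0, 3, g, noiseSd = 0)
  init <- initializeFit(p)
  # half-maximum crossings of the analytic model, computed independently
  b0 <- init[["b"]]; A0 <- init[["A"]]
  half <- b0 + A0 / 2
  f <- function(x) evalDoubleSigmoid(x, -80, 880, 5, 0, 3) - half
  x1True <- uniroot(f, c(-3, 1.4))$root
  x2True <- uniroot(f, c(1.6, 6))$root
  expect_lt(abs(init[["x1"]] - 0), 0.2)
  expect_lt(abs(init[["x2"]] - 3), 0.2)
  expect_lt(abs(init[["x1"]] - x1True), 0.05)
  expect_lt(abs(init[["x2"]] - x2True), 0.05)
  expect_gt(init[["s"]], 0)

  # doubling the HU scale doubles A0 but leaves the edge guesses alone
  p2 <- new("LineProfile", positions = positions(p),
            values = 2 * profileValues(p), siteLabel = "scaled")
  init2 <- initializeFit(p2)
  expect_equal(init2[["A"]], 2 * init[["A"]], tolerance = 1e-9)
  expect_equal(init2[["x1"]], init[["x1"]], tolerance = 1e-9)
  expect_equal(init2[["x2"]], init[["x2"]], tolerance = 1e-9)

  ramp <- new("LineProfile", positions = g, values = seq_along(g) * 1.0,
              siteLabel = "ramp")
  expect_error(initializeFit(ramp), "pulse")
})

test_that("noiseless fits recover generating parameters over a parameter grid", {
  for (s in c(1, 3.5, 5, 9.7)) {
    for (width in c(1.5, 3)) {
      x1 <- 0.7; x2 <- x1 + width
      p <- generateProfile(-80, 880, s, x1, x2,
                           seq(x1 - 5, x2 + 5, by = 0.1), noiseSd = 0)
      fit <- fitDoubleSigmoid(p)
      expect_true(fit@converged)
      expect_equal(fit@s, s, tolerance = 1e-6)
      expect_equal(fit@b, -80, tolerance = 1e-6)
      expect_equal(fit@A, 880, tolerance = 1e-6)
      expect_equal(fit@x1, x1, tolerance = 1e-6)
      expect_equal(fit@x2, x2, tolerance = 1e-6)
      expect_lt(fit@rmse, 1e-6)
    }
  }
})

test_that("fits are shift invariant and HU-affine equivariant", {
  g <- seq(-5, 8, by = 0.1)
  p <- generateProfile(-80, 880, 4.2, 0.3, 2.8, g, noiseSd = 25, seed = 17L)
  f0 <- fitDoubleSigmoid(p)

  delta <- 2.37
  pShift <- new("LineProfile", positions = positions(p) + delta,
                values = profileValues(p), siteLabel = "shift")
  fS <- fitDoubleSigmoid(pShift)
  expect_equal(fS@s, f0@s, tolerance = 1e-6)
  expect_equal(fS@b, f0@b, tolerance = 1e-6)
  expect_equal(fS@A, f0@A, tolerance = 1e-6)
  expect_equal(fS@x1, f0@x1 + delta, tolerance = 1e-6)
  expect_equal(fS@x2, f0@x2 + delta, tolerance = 1e-6)

  alpha <- 2; beta <- 10
  pAff <- new("LineProfile", positions = positions(p),
              values = alpha * profileValues(p) + beta, siteLabel = "affine")
  fA <- fitDoubleSigmoid(pAff)
  expect_equal(fA@s, f0@s, tolerance = 1e-6)
  expect_equal(fA@x1, f0@x1, tolerance = 1e-6)
  expect_equal(fA@x2, f0@x2, tolerance = 1e-6)
  expect_equal(fA@b, alpha * f0@b + beta, tolerance = 1e-6)
  expect_equal(fA@A, alpha * f0@A, tolerance = 1e-6)
})

test_that("fitted sharpness decreases strictly with PSF width on noiseless phantoms", {
  sigmas <- c(0.2, 0.3, 0.45, 0.6)
  s <- vapply(sigmas, function(sg) {
    img <- phantomImage(psfSigma = sg, noiseSd = 0)
    sharpness(fitDoubleSigmoid(extractProfile(img, radialSite())))
  }, numeric(1))
  expect_true(all(diff(s) < 0))
  expect_true(all(s > 2 & s < 8))
})

test_that("sharpness summaries aggregate correctly and flag exclusions", {
  fits <- data.frame(
    subject = rep(1:2, each = 6),
    family = "Bv", level = 40L,
    site = rep(c("RCA_prox", "RCA_dist", "LAD_prox", "LAD_dist",
                 "LCX_prox", "LCX_dist"), 2),
    s = 4.0, converged = TRUE)
  tab <- sharpnessSummary(fits)
  expect_equal(tab$mean_s, 4.0)
  expect_equal(tab$sd_s, 0)
  expect_equal(tab$n, 12L)
  expect_equal(tab$n_excluded, 0)

  fits$s <- seq_len(nrow(fits)) / 2
  fits$converged[c(3, 9)] <- FALSE
  tab2 <- sharpnessSummary(fits)
  keep <- fits$converged
  expect_equal(tab2$mean_s, mean(fits$s[keep]), tolerance = 1e-12)
  expect_equal(tab2$sd_s, sd(fits$s[keep]), tolerance = 1e-12)
  expect_equal(tab2$n_excluded, 2)

  pd <- sharpnessSummary(fits, by = "prox_dist")
  for (grp in c("prox", "dist")) {
    sel <- keep & grepl(paste0("_", grp, "$"), fits$site)
    expect_equal(pd$mean_s[pd$prox_dist == grp], mean(fits$s[sel]),
                 tolerance = 1e-12)
  }

  fits$converged <- FALSE
  expect_error(sharpnessSummary(fits), "no converged")
})

test_that("grid-style summary has one row per reconstruction cell", {
  grid <- defaultKernelGrid()
  fits <- do.call(rbind, lapply(grid, function(k)
    data.frame(subject = 1L, family = k@family, level = k@level,
               site = c("RCA_prox", "RCA_dist"), s = 4 + k@level / 100,
               converged = TRUE)))
  tab <- sharpnessSummary(fits)
  expect_equal(nrow(tab), 12L)
  expect_identical(tab$family, rep(c("Br", "Bv", "Qr"), each = 4))
})
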