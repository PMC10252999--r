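#' @include kernels.R
NULL

# Run expr with a fixed RNG seed, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Create a vessel phantom specification
#'
#' @param vesselDiameter lumen diameter in mm (>= 2; the study measured
#'   vessels of at least 2 mm).
#' @param vesselHu lumen attenuation in HU (contrast-enhanced blood).
#' @param fatHu pericoronary fat attenuation in HU.
#' @param fieldOfView square field-of-view side in mm.
#' @param pixelSpacing in-plane pixel spacing in mm.
#' @param kernel a \linkS4class{KernelSpec}.
#' @param seed integer seed for the noise realization.
#' @return a \linkS4class{PhantomSpec}.
#' @examples
#' PhantomSpec(kernel = KernelSpec("Br", 36))
#' @export
PhantomSpec <- function(vesselDiameter = 3.5, vesselHu = 800, fatHu = -80,
                        fieldOfView = 20, pixelSpacing = 0.3,
                        kernel = KernelSpec("Bv", 40), seed = 1L) {
  new("PhantomSpec",
      vesselDiameter = as.numeric(vesselDiameter),
      vesselHu = as.numeric(vesselHu), fatHu = as.numeric(fatHu),
      fieldOfView = as.numeric(fieldOfView),
      pixelSpacing = as.numeric(pixelSpacing),
      kernel = kernel, seed = as.integer(seed))
}

# Exact Gaussian-blurred disk: fraction of the lumen indicator after
# convolution with an isotropic Gaussian of sd sigma, at distance r from the
# disk centre. P(||Z + c|| <= R) with Z ~ N(0, sigma^2 I2) is a noncentral
# chi-square probability. Far from the edge the indicator value is used
# directly to avoid extreme noncentrality parameters.
blurredDiskFraction <- function(r, radius, sigma) {
  if (sigma <= 1e-8) return(as.numeric(r <= radius))
  out <- numeric(length(r))
  inside <- r <= radius - 8 * sigma
  outside <- r >= radius + 8 * sigma
  edge <- !(inside | outside)
  out[inside] <- 1
  if (radius / sigma > 500) {
    # curvature is negligible at this scale: 1D Gaussian edge-spread function
    out[edge] <- stats::pnorm((radius - r[edge]) / sigma)
  } else if (sum(edge) > 1500L) {
    # the profile is radial: tabulate densely in r and spline-interpolate
    rg <- seq(max(0, radius - 8.5 * sigma), radius + 8.5 * sigma,
              by = sigma / 50)
    fg <- stats::pchisq((radius / sigma)^2, df = 2, ncp = (rg / sigma)^2)
    out[edge] <- stats::splinefun(rg, fg, method = "fmm")(r[edge])
  } else {
    out[edge] <- stats::pchisq((radius / sigma)^2, df = 2,
                               ncp = (r[edge] / sigma)^2)
  }
  out
}

#' Generate a synthetic vessel cross-section image
#'
#' Renders a circular contrast-enhanced lumen embedded in pericoronary fat,
#' convolved with the kernel's isotropic Gaussian point-spread function, and
#' adds white Gaussian noise of the kernel's noise level. The kernel's
#' attenuation bias is added inside the lumen before blurring. The
#' continuous disk-Gaussian convolution is evaluated in closed form and
#' area-averaged over an 8x8 supersample per pixel, so the noiseless image is
#' free of grid artifacts. The vessel is centred in the field of view.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @return an \linkS4class{ImageVolume} (2D).
#' @examples
#' img <- generateVesselImage(PhantomSpec(kernel = KernelSpec("Qr", 36)))
#' img
#' @export
generateVesselImage <- function(spec) {
  validObject(spec)
  h <- spec@pixelSpacing
  n <- as.integer(round(spec@fieldOfView / h))
  radius <- spec@vesselDiameter / 2
  ctr <- n * h / 2
  lumenHu <- spec@vesselHu + spec@kernel@attenuationBias

  ss <- 8L                               # supersampling factor per axis
  sub <- ((seq_len(ss) - 0.5) / ss - 0.5) * h
  base <- (seq_len(n) - 0.5) * h
  fine <- as.vector(outer(sub, base, "+"))  # ss*n ascending coordinates
  dx2 <- (fine - ctr)^2
  r <- sqrt(outer(dx2, dx2, "+"))
  frac <- blurredDiskFraction(as.vector(r), radius, spec@kernel@psfSigma)
  fineImg <- matrix(spec@fatHu + (lumenHu - spec@fatHu) * frac,
                    nrow = ss * n, ncol = ss * n)

  # area-average the 8x8 supersample blocks down to the pixel grid
  grp <- rep(seq_len(n), each = ss)
  img <- rowsum(fineImg, grp) / ss
  img <- t(rowsum(t(img), grp) / ss)
  dimnames(img) <- NULL

  if (spec@kernel@noiseSd > 0) {
    img <- img + withSeed(spec@seed,
      matrix(stats::rnorm(n * n, 0, spec@kernel@noiseSd), n, n))
  }
  new("ImageVolume", data = img, spacing = c(h, h), origin = c(0, 0))
}

#' Generate a synthetic edge profile from the double-sigmoid model
#'
#' Forward model for the sharpness fit: evaluates the double-sigmoid vessel
#' profile on a sampling grid and adds white Gaussian noise.
#'
#' @param b baseline attenuation in HU.
#' @param A pulse amplitude in HU.
#' @param s edge slope in 1/mm (> 0).
#' @param x1,x2 edge centres in mm, x2 > x1.
#' @param grid ascending sample positions in mm.
#' @param noiseSd noise standard deviation in HU.
#' @param seed integer seed (ignored when noiseSd is 0).
#' @param siteLabel label carried into the profile.
#' @return a \linkS4class{LineProfile}.
#' @examples
#' p <- generateProfile(-80, 880, 5, 0, 3, seq(-5, 8, by = 0.1))
#' range(profileValues(p))
#' @export
generateProfile <- function(b, A, s, x1, x2, grid, noiseSd = 0, seed = 1L,
                            siteLabel = "synthetic") {
  stopifnot(s > 0, x2 > x1)
  if (any(diff(grid) <= 0))
    stop("profile grid must be strictly ascending")
  vals <- evalDoubleSigmoid(grid, b, A, s, x1, x2)
  if (noiseSd > 0)
    vals <- vals + withSeed(seed, stats::rnorm(length(grid), 0, noiseSd))
  new("LineProfile", positions = as.numeric(grid), values = vals,
      siteLabel = siteLabel)
}
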