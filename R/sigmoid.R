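#' @include AllClasses.R
NULL

# logistic with exponent clamped at +/-700 so the asymptotes stay exact in
# double precision instead of overflowing
clampedLogistic <- function(z) {
  z <- pmin(pmax(z, -700), 700)
  1 / (1 + exp(-z))
}

#' Evaluate the double-sigmoid vessel model
#'
#' The vessel cross-profile model
#' \deqn{S(x) = b + A\left(\frac{1}{1+e^{-s(x-x_1)}} -
#'   \frac{1}{1+e^{-s(x-x_2)}}\right)}{S(x) = b + A (1/(1+exp(-s(x-x1))) -
#'   1/(1+exp(-s(x-x2))))}
#' a pulse rising from baseline \code{b} to about \code{b + A} between the two
#' edge centres \code{x1 < x2}, with a single shared edge slope \code{s}
#' (1/mm) that quantifies border sharpness. Exponents are clamped at +/-700
#' before exponentiation.
#'
#' @param x positions in mm (vectorized).
#' @param b baseline in HU.
#' @param A amplitude in HU.
#' @param s edge slope in 1/mm (> 0).
#' @param x1,x2 edge centres in mm.
#' @return model values in HU.
#' @examples
#' evalDoubleSigmoid(c(-100, 1.5, 100), -80, 880, 9.7, 0, 3)
#' @export
evalDoubleSigmoid <- function(x, b, A, s, x1, x2) {
  stopifnot(s > 0)
  b + A * (clampedLogistic(s * (x - x1)) - clampedLogistic(s * (x - x2)))
}

#' Starting values for the double-sigmoid fit
#'
#' Heuristic initialization: the baseline is the mean of the outer 10% of
#' samples on each side; the amplitude is the profile maximum minus the
#' baseline; the edge centres are the first and last crossings of the
#' half-maximum level (linearly interpolated); and the slope is
#' \code{4 * max |finite-difference slope| / A} — for a logistic edge the
#' maximal derivative is \code{A s / 4}.
#'
#' @param profile a \linkS4class{LineProfile} with a pulse shape (its maximum
#'   must strictly exceed both endpoint values).
#' @return named numeric with elements b, A, s, x1, x2.
#' @examples
#' p <- generateProfile(-80, 880, 5, 0, 3, seq(-5, 8, by = 0.1))
#' initializeFit(p)
#' @export
initializeFit <- function(profile) {
  validObject(profile)
  x <- profile@positions
  y <- profile@values
  n <- length(y)
  k <- max(1L, floor(0.1 * n))
  if (max(y) <= y[1] || max(y) <= y[n])
    stop("profile at site '", profile@siteLabel,
         "' has no pulse shape (maximum not above both endpoints); ",
         "cannot initialize the double-sigmoid fit")
  b0 <- mean(c(y[seq_len(k)], y[seq(n - k + 1L, n)]))
  A0 <- max(y) - b0
  half <- b0 + A0 / 2
  above <- y > half
  idx <- which(above)
  crossAt <- function(i) {
    # linear interpolation of the half-maximum crossing in [x_i, x_{i+1}]
    x[i] + (half - y[i]) / (y[i + 1L] - y[i]) * (x[i + 1L] - x[i])
  }
  x10 <- if (idx[1] == 1L) x[1] else crossAt(idx[1] - 1L)
  iLast <- idx[length(idx)]
  x20 <- if (iLast == n) x[n] else crossAt(iLast)
  slope <- max(abs(diff(y) / diff(x)))
  s0 <- 4 * slope / A0
  c(b = b0, A = A0, s = s0, x1 = x10, x2 = x20)
}

#' Fit the double-sigmoid model to a profile
#'
#' Bounded Levenberg-Marquardt least squares on the five model parameters,
#' started from \code{\link{initializeFit}}. The ordering constraint
#' \code{x2 > x1} is enforced by optimizing \code{w = log(x2 - x1)}, and the
#' slope is bounded to (0, 100] /mm. Non-convergence is reported through the
#' \code{converged} flag, never as an error, so callers can count and exclude
#' failed fits.
#'
#' @param profile a \linkS4class{LineProfile}.
#' @return a \linkS4class{DoubleSigmoidFit}; \code{sharpness()} extracts the
#'   slope in 1/mm.
#' @examples
#' p <- generateProfile(-80, 880, 9.7, 0, 2, seq(-5, 7, by = 0.1))
#' sharpness(fitDoubleSigmoid(p))
#' @export
fitDoubleSigmoid <- function(profile) {
  init <- initializeFit(profile)
  x <- profile@positions
  y <- profile@values
  start <- c(unname(init["b"]), unname(init["A"]),
             min(max(unname(init["s"]), 1e-3), 100),
             unname(init["x1"]),
             log(max(init["x2"] - init["x1"], 1e-3)))
  resFn <- function(p) {
    y - evalDoubleSigmoid(x, p[1], p[2], p[3], p[4], p[4] + exp(p[5]))
  }
  jacFn <- function(p) {
    # analytic Jacobian of the residuals (residual = y - model)
    L1 <- clampedLogistic(p[3] * (x - p[4]))
    L2 <- clampedLogistic(p[3] * (x - p[4] - exp(p[5])))
    d1 <- L1 * (1 - L1)
    d2 <- L2 * (1 - L2)
    -cbind(
      1,                                             # d model / d b
      L1 - L2,                                       # d model / d A
      p[2] * (d1 * (x - p[4]) - d2 * (x - p[4] - exp(p[5]))),
      -p[2] * p[3] * (d1 - d2),                      # d model / d x1
      p[2] * p[3] * d2 * exp(p[5]))                  # d model / d w
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = resFn, jac = jacFn,
      lower = c(-Inf, -Inf, 1e-6, -Inf, -Inf),
      upper = c(Inf, Inf, 100, Inf, Inf),
      control = minpack.lm::nls.lm.control(
        ftol = 1e-10, ptol = 1e-10, gtol = 1e-10,
        maxiter = 500, maxfev = 5000)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new("DoubleSigmoidFit",
      b = unname(init["b"]), A = unname(init["A"]), s = start[3],
      x1 = start[4], x2 = start[4] + exp(start[5]),
      rmse = sqrt(mean(resFn(start)^2)),
      converged = FALSE, nIter = 0L, siteLabel = profile@siteLabel))
  }
  p <- fit$par
  new("DoubleSigmoidFit",
    b = p[1], A = p[2], s = p[3], x1 = p[4], x2 = p[4] + exp(p[5]),
    rmse = sqrt(mean(fit$fvec^2)),
    converged = fit$info %in% 1:4,
    nIter = as.integer(fit$niter),
    siteLabel = profile@siteLabel)
}

#' Extract a line profile from an image
#'
#' Samples attenuation along the segment
#' \code{center +/- halfLength * direction} at steps of \code{site@step} by
#' bilinear interpolation in physical coordinates. Positions in the returned
#' profile are distances in mm from the segment start.
#'
#' @param volume a 2D \linkS4class{ImageVolume} (or a 3D volume with the
#'   site's slice selected beforehand).
#' @param site a \linkS4class{ProfileSite}.
#' @return a \linkS4class{LineProfile}.
#' @export
extractProfile <- function(volume, site) {
  validObject(volume)
  validObject(site)
  img <- volume@data
  if (length(dim(img)) != 2L)
    stop("extractProfile needs a 2D image; slice 3D volumes first")
  t <- seq(-site@halfLength, site@halfLength, by = site@step)
  px <- site@center[1] + t * site@direction[1]
  py <- site@center[2] + t * site@direction[2]
  # continuous pixel-centre index (1-based): centre of pixel i is (i-0.5)*h
  u <- (px - volume@origin[1]) / volume@spacing[1] + 0.5
  v <- (py - volume@origin[2]) / volume@spacing[2] + 0.5
  if (any(u < 1 | u > nrow(img) | v < 1 | v > ncol(img)))
    stop("profile segment at site '", site@label,
         "' exits the image bounds")
  i0 <- pmin(pmax(floor(u), 1L), nrow(img) - 1L)
  j0 <- pmin(pmax(floor(v), 1L), ncol(img) - 1L)
  fu <- u - i0
  fv <- v - j0
  vals <- img[cbind(i0, j0)] * (1 - fu) * (1 - fv) +
    img[cbind(i0 + 1L, j0)] * fu * (1 - fv) +
    img[cbind(i0, j0 + 1L)] * (1 - fu) * fv +
    img[cbind(i0 + 1L, j0 + 1L)] * fu * fv
  new("LineProfile", positions = t - t[1], values = unname(vals),
      siteLabel = site@label)
}

#' Summarize sharpness fits across sites and subjects
#'
#' Aggregates fitted slopes to the reconstruction grid: mean and SD of
#' \code{s} per (family, level), overall and split by proximal/distal site
#' (site labels ending in "_prox"/"_dist"). Non-converged fits are excluded
#' from the averages and counted.
#'
#' @param fits data.frame with columns subject, family, level, site, s,
#'   converged (as written by the pipeline), or a list of
#'   \linkS4class{DoubleSigmoidFit} plus matching family/level vectors.
#' @param by either "overall" or "prox_dist".
#' @return data.frame with columns family, level (and prox_dist when split),
#'   mean_s, sd_s, n, n_excluded.
#' @export
sharpnessSummary <- function(fits, by = c("overall", "prox_dist")) {
  by <- match.arg(by)
  stopifnot(is.data.frame(fits),
            all(c("family", "level", "s", "converged") %in% names(fits)))
  if (!any(fits$converged))
    stop("no converged fits to summarize")
  if (by == "prox_dist") {
    pd <- ifelse(grepl("_dist$", fits$site), "dist",
          ifelse(grepl("_prox$", fits$site), "prox", "other"))
    groups <- list(family = fits$family, level = fits$level, prox_dist = pd)
  } else {
    groups <- list(family = fits$family, level = fits$level)
  }
  ok <- fits$converged
  agg <- function(f, vals, keep) {
    g <- lapply(groups, function(gr) gr[keep])
    out <- stats::aggregate(vals[keep], by = g, FUN = f)
    out
  }
  m <- agg(mean, fits$s, ok)
  s <- agg(stats::sd, fits$s, ok)
  n <- agg(length, fits$s, ok)
  excl <- stats::aggregate(!fits$converged, by = groups, FUN = sum)
  keycols <- setdiff(names(m), "x")
  key <- function(d) do.call(paste, c(d[keycols], sep = "|"))
  out <- m
  names(out)[names(out) == "x"] <- "mean_s"
  out$sd_s <- s$x[match(key(out), key(s))]
  out$n <- n$x[match(key(out), key(n))]
  out$n_excluded <- excl$x[match(key(out), key(excl))]
  out$n_excluded[is.na(out$n_excluded)] <- 0L
  out[order(match(out$family, KERNEL_FAMILIES), out$level), , drop = FALSE]
}
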