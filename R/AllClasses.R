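#' @import methods
NULL

KERNEL_FAMILIES <- c("Br", "Bv", "Qr")
SHARPNESS_LEVELS <- c(36L, 40L, 44L, 48L)
RATING_CRITERIA <- c("overall", "noise", "sharp_coronaries")

#' Reconstruction-kernel specification
#'
#' Describes one cell of the reconstruction grid: a kernel family
#' (Br = body regular, Bv = body vascular, Qr = quantum regular) at a numeric
#' sharpness level, together with the image-formation parameters the phantom
#' generator uses to emulate it: the standard deviation of an isotropic
#' Gaussian point-spread function (mm), the standard deviation of additive
#' white Gaussian noise (HU), and a family-specific additive attenuation
#' offset applied inside the vessel lumen (HU).
#'
#' @slot family character, one of "Br", "Bv", "Qr".
#' @slot level integer sharpness level, one of 36, 40, 44, 48.
#' @slot psfSigma Gaussian PSF standard deviation in mm (> 0).
#' @slot noiseSd noise standard deviation in HU (>= 0).
#' @slot attenuationBias additive lumen attenuation offset in HU.
#' @exportClass KernelSpec
setClass("KernelSpec",
  representation(
    family = "character",
    level = "integer",
    psfSigma = "numeric",
    noiseSd = "numeric",
    attenuationBias = "numeric"
  )
)

setValidity("KernelSpec", function(object) {
  msg <- character()
  if (length(object@family) != 1L || !object@family %in% KERNEL_FAMILIES)
    msg <- c(msg, "family must be one of Br, Bv, Qr")
  if (length(object@level) != 1L || !object@level %in% SHARPNESS_LEVELS)
    msg <- c(msg, "level must be one of 36, 40, 44, 48")
  if (length(object@psfSigma) != 1L || !is.finite(object@psfSigma) ||
      object@psfSigma <= 0)
    msg <- c(msg, "psfSigma must be a single positive number (mm)")
  if (length(object@noiseSd) != 1L || !is.finite(object@noiseSd) ||
      object@noiseSd < 0)
    msg <- c(msg, "noiseSd must be a single non-negative number (HU)")
  if (length(object@attenuationBias) != 1L || !is.finite(object@attenuationBias))
    msg <- c(msg, "attenuationBias must be a single finite number (HU)")
  if (length(msg)) msg else TRUE
})

#' Vessel phantom specification
#'
#' Geometry and contrast of a synthetic coronary cross-section: a circular
#' lumen of diameter \code{vesselDiameter} (mm) at \code{vesselHu} embedded in
#' pericoronary fat at \code{fatHu}, rendered on a square field of view with
#' the given pixel spacing and degraded according to a \linkS4class{KernelSpec}.
#'
#' @slot vesselDiameter lumen diameter in mm (>= 2).
#' @slot vesselHu lumen attenuation in HU.
#' @slot fatHu fat background attenuation in HU.
#' @slot fieldOfView square field-of-view side length in mm.
#' @slot pixelSpacing in-plane pixel spacing in mm (> 0).
#' @slot kernel a \linkS4class{KernelSpec}.
#' @slot seed integer random seed for the noise realization.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    vesselDiameter = "numeric",
    vesselHu = "numeric",
    fatHu = "numeric",
    fieldOfView = "numeric",
    pixelSpacing = "numeric",
    kernel = "KernelSpec",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@vesselDiameter < 2)
    msg <- c(msg, "vesselDiameter must be >= 2 mm")
  if (object@pixelSpacing <= 0)
    msg <- c(msg, "pixelSpacing must be > 0")
  if (object@vesselDiameter + 4 > object@fieldOfView)
    msg <- c(msg, sprintf(
      "vessel (%.2f mm) does not fit in the %.2f mm field of view with a 2 mm margin",
      object@vesselDiameter, object@fieldOfView))
  if (object@vesselHu <= object@fatHu)
    msg <- c(msg, "vesselHu must exceed fatHu (contrast-enhanced lumen)")
  if (length(msg)) msg else TRUE
})

#' Latent-quality rating-model specification
#'
#' Generative model for two-rater 5-point Likert scores: each reconstruction
#' has a latent quality; a rater adds a systematic bias and Gaussian noise,
#' and the resulting latent value is cut into ordinal scores 1-5 by four
#' ascending thresholds.
#'
#' @slot nSubjects number of rated subjects.
#' @slot latentQuality named numeric, ground-truth quality per "family:level".
#' @slot raterBias numeric of length >= 1, one systematic offset per rater.
#' @slot raterNoiseSd standard deviation of rater noise (>= 0).
#' @slot thresholds four strictly ascending cutpoints on the latent scale.
#' @slot seed integer random seed.
#' @exportClass RatingModelSpec
setClass("RatingModelSpec",
  representation(
    nSubjects = "integer",
    latentQuality = "numeric",
    raterBias = "numeric",
    raterNoiseSd = "numeric",
    thresholds = "numeric",
    seed = "integer"
  )
)

setValidity("RatingModelSpec", function(object) {
  msg <- character()
  if (object@nSubjects < 1L)
    msg <- c(msg, "nSubjects must be >= 1")
  if (length(object@thresholds) != 4L || any(diff(object@thresholds) <= 0))
    msg <- c(msg, "thresholds must be 4 strictly ascending values")
  if (object@raterNoiseSd < 0)
    msg <- c(msg, "raterNoiseSd must be >= 0")
  if (is.null(names(object@latentQuality)))
    msg <- c(msg, "latentQuality must be named by 'family:level'")
  if (length(msg)) msg else TRUE
})

#' Image volume with physical spacing
#'
#' A 2D or 3D array of attenuation values in Hounsfield units together with
#' per-axis voxel spacing and origin in mm. The centre of voxel
#' \code{(i, j)} (1-based) sits at physical coordinate
#' \code{origin + (i - 0.5) * spacing}.
#'
#' @slot data 2D or 3D numeric array of HU values.
#' @slot spacing per-axis voxel spacing in mm, all > 0.
#' @slot origin per-axis origin in mm.
#' @exportClass ImageVolume
setClass("ImageVolume",
  representation(
    data = "array",
    spacing = "numeric",
    origin = "numeric"
  )
)

setValidity("ImageVolume", function(object) {
  msg <- character()
  nd <- length(dim(object@data))
  if (!nd %in% c(2L, 3L))
    msg <- c(msg, "data must be a 2D or 3D array")
  if (length(object@spacing) != nd || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be positive, one value per axis")
  if (length(object@origin) != nd || any(!is.finite(object@origin)))
    msg <- c(msg, "origin must be finite, one value per axis")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "data must be finite")
  if (length(msg)) msg else TRUE
})

#' Circular region of interest
#'
#' A circle defined in physical mm coordinates, applied unchanged to every
#' reconstruction of a subject. For 3D volumes \code{sliceIndex} selects the
#' axial slice the circle lives on.
#'
#' @slot label ROI label, e.g. "RCA_prox" or "fat".
#' @slot center numeric length-2, circle centre in mm.
#' @slot radius circle radius in mm (> 0).
#' @slot sliceIndex integer slice for 3D volumes (NA for 2D).
#' @exportClass CircularROI
setClass("CircularROI",
  representation(
    label = "character",
    center = "numeric",
    radius = "numeric",
    sliceIndex = "integer"
  )
)

setValidity("CircularROI", function(object) {
  msg <- character()
  if (length(object@center) != 2L || any(!is.finite(object@center)))
    msg <- c(msg, "center must be two finite mm coordinates")
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius <= 0)
    msg <- c(msg, "radius must be > 0")
  if (length(msg)) msg else TRUE
})

#' Profile sampling site
#'
#' A line segment perpendicular to the vessel border, defined by its centre
#' point on the border, a unit direction, a half length and a sampling step,
#' all in physical mm.
#'
#' @slot label site label, e.g. "RCA_dist".
#' @slot center numeric length-2, point on the vessel border in mm.
#' @slot direction unit 2-vector perpendicular to the border.
#' @slot halfLength half length of the sampled segment in mm.
#' @slot step sampling step in mm.
#' @exportClass ProfileSite
setClass("ProfileSite",
  representation(
    label = "character",
    center = "numeric",
    direction = "numeric",
    halfLength = "numeric",
    step = "numeric"
  )
)

setValidity("ProfileSite", function(object) {
  msg <- character()
  if (length(object@center) != 2L || any(!is.finite(object@center)))
    msg <- c(msg, "center must be two finite mm coordinates")
  if (length(object@direction) != 2L ||
      abs(sqrt(sum(object@direction^2)) - 1) > 1e-9)
    msg <- c(msg, "direction must be a unit 2-vector (norm within 1e-9 of 1)")
  if (object@step <= 0)
    msg <- c(msg, "step must be > 0")
  if (object@halfLength < object@step)
    msg <- c(msg, "halfLength must be >= step")
  if (length(msg)) msg else TRUE
})

#' Sampled attenuation profile
#'
#' Attenuation values sampled along a physical-coordinate segment; positions
#' are distances in mm from the segment start.
#'
#' @slot positions strictly ascending sample positions in mm.
#' @slot values attenuation values in HU, same length as positions.
#' @slot siteLabel label of the originating site.
#' @exportClass LineProfile
setClass("LineProfile",
  representation(
    positions = "numeric",
    values = "numeric",
    siteLabel = "character"
  )
)

setValidity("LineProfile", function(object) {
  msg <- character()
  if (length(object@positions) != length(object@values))
    msg <- c(msg, "positions and values must have equal length")
  if (length(object@positions) < 8L)
    msg <- c(msg, "a profile needs at least 8 samples")
  if (any(diff(object@positions) <= 0))
    msg <- c(msg, "positions must be strictly ascending")
  if (length(msg)) msg else TRUE
})

#' Double-sigmoid edge-model fit
#'
#' Result of fitting the double-sigmoid vessel model
#' \deqn{S(x) = b + A\left(\frac{1}{1+e^{-s(x-x_1)}} -
#'   \frac{1}{1+e^{-s(x-x_2)}}\right)}{S(x) = b + A (1/(1+exp(-s(x-x1))) -
#'   1/(1+exp(-s(x-x2))))}
#' to a \linkS4class{LineProfile}. The slope parameter \code{s} (1/mm) is the
#' vessel sharpness.
#'
#' @slot b baseline attenuation in HU.
#' @slot A pulse amplitude in HU.
#' @slot s shared edge slope in 1/mm; the sharpness readout.
#' @slot x1,x2 edge centre positions in mm, x2 > x1.
#' @slot rmse root-mean-square residual in HU.
#' @slot converged logical convergence flag.
#' @slot nIter number of solver iterations.
#' @slot siteLabel label of the fitted profile's site.
#' @exportClass DoubleSigmoidFit
setClass("DoubleSigmoidFit",
  representation(
    b = "numeric",
    A = "numeric",
    s = "numeric",
    x1 = "numeric",
    x2 = "numeric",
    rmse = "numeric",
    converged = "logical",
    nIter = "integer",
    siteLabel = "character"
  )
)

setValidity("DoubleSigmoidFit", function(object) {
  msg <- character()
  if (object@s <= 0) msg <- c(msg, "s must be > 0")
  if (object@x2 <= object@x1) msg <- c(msg, "x2 must exceed x1")
  if (object@rmse < 0) msg <- c(msg, "rmse must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Hypothesis-test result
#'
#' Uniform container for the comparison layer: test statistic, p-value,
#' degrees of freedom or group sizes, a method label and, for the ANOVA,
#' Tukey-adjusted pairwise post hoc comparisons. \code{degenerate} marks
#' inputs with zero variance everywhere, where the statistic is undefined.
#'
#' @slot statistic test statistic (NA when degenerate).
#' @slot pValue p-value in [0, 1] (NA when degenerate).
#' @slot df named numeric, degrees of freedom.
#' @slot groupSizes integer vector of per-group sizes.
#' @slot method method label.
#' @slot postHoc data.frame of pairwise comparisons (may be empty).
#' @slot degenerate logical, TRUE when the statistic is undefined (0/0).
#' @exportClass TestResult
setClass("TestResult",
  representation(
    statistic = "numeric",
    pValue = "numeric",
    df = "numeric",
    groupSizes = "integer",
    method = "character",
    postHoc = "data.frame",
    degenerate = "logical"
  )
)

setValidity("TestResult", function(object) {
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    "pValue must lie in [0, 1]" else TRUE
})

#' Intraclass correlation result
#'
#' ICC(2,1) (two-way random effects, absolute agreement, single measures)
#' with the qualitative agreement bin: poor (<= 0.2), fair (0.2, 0.4],
#' moderate (0.4, 0.6], substantial (0.6, 0.8], excellent (> 0.8). Values
#' exactly on a boundary fall in the lower bin.
#'
#' @slot icc the coefficient (<= 1).
#' @slot model model label.
#' @slot interpretation one of poor, fair, moderate, substantial, excellent.
#' @exportClass ICCResult
setClass("ICCResult",
  representation(
    icc = "numeric",
    model = "character",
    interpretation = "character"
  )
)

setValidity("ICCResult", function(object) {
  msg <- character()
  if (object@icc > 1 + 1e-12) msg <- c(msg, "icc cannot exceed 1")
  if (!object@interpretation %in%
      c("poor", "fair", "moderate", "substantial", "excellent"))
    msg <- c(msg, "unknown interpretation label")
  if (length(msg)) msg else TRUE
})
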