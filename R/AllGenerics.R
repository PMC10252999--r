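#' @include AllClasses.R
NULL

#' Accessors for package objects
#'
#' Small accessor generics: \code{imageData} and \code{spacing} expose the
#' array and voxel spacing of an \linkS4class{ImageVolume};
#' \code{sharpness} returns the fitted slope of a
#' \linkS4class{DoubleSigmoidFit} in 1/mm; \code{positions} and
#' \code{profileValues} expose the samples of a \linkS4class{LineProfile}.
#'
#' @param object the object to access.
#' @return the slot value.
#' @name accessors
#' @aliases imageData spacing origin sharpness positions profileValues
NULL

#' @rdname accessors
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("origin", function(object) standardGeneric("origin"))

#' @rdname accessors
#' @export
setGeneric("sharpness", function(object) standardGeneric("sharpness"))

#' @rdname accessors
#' @export
setGeneric("positions", function(object) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("profileValues", function(object) standardGeneric("profileValues"))

#' @rdname accessors
#' @export
setMethod("imageData", "ImageVolume", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("spacing", "ImageVolume", function(object) object@spacing)

#' @rdname accessors
#' @export
setMethod("origin", "ImageVolume", function(object) object@origin)

#' @rdname accessors
#' @export
setMethod("sharpness", "DoubleSigmoidFit", function(object) object@s)

#' @rdname accessors
#' @export
setMethod("positions", "LineProfile", function(object) object@positions)

#' @rdname accessors
#' @export
setMethod("profileValues", "LineProfile", function(object) object@values)

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageVolume: %s voxels, spacing (%s) mm, HU range [%.1f, %.1f]\n",
    paste(d, collapse = " x "),
    paste(format(object@spacing), collapse = ", "),
    min(object@data), max(object@data)))
})

setMethod("show", "KernelSpec", function(object) {
  cat(sprintf("KernelSpec %s%d: psf sigma %.3f mm, noise %.1f HU, bias %+.0f HU\n",
    object@family, object@level, object@psfSigma, object@noiseSd,
    object@attenuationBias))
})

setMethod("show", "LineProfile", function(object) {
  cat(sprintf("LineProfile '%s': %d samples over [%.2f, %.2f] mm\n",
    object@siteLabel, length(object@positions),
    min(object@positions), max(object@positions)))
})

setMethod("show", "DoubleSigmoidFit", function(object) {
  cat(sprintf(
    "DoubleSigmoidFit '%s': s = %.2f /mm, b = %.1f HU, A = %.1f HU, edges %.2f..%.2f mm\n  rmse %.2f HU, %sconverged (%d iterations)\n",
    object@siteLabel, object@s, object@b, object@A, object@x1, object@x2,
    object@rmse, if (object@converged) "" else "NOT ", object@nIter))
})

setMethod("show", "TestResult", function(object) {
  if (object@degenerate) {
    cat(sprintf("%s: degenerate (zero variance), statistic undefined\n",
      object@method))
  } else {
    cat(sprintf("%s: statistic = %.4f, p = %.4g\n",
      object@method, object@statistic, object@pValue))
    if (nrow(object@postHoc))
      cat(sprintf("  %d post hoc pairwise comparisons\n", nrow(object@postHoc)))
  }
})

setMethod("show", "ICCResult", function(object) {
  cat(sprintf("%s: ICC = %.4f (%s agreement)\n",
    object@model, object@icc, object@interpretation))
})
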