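#' @include AllClasses.R
NULL

#' Construct an image volume
#'
#' @param data 2D or 3D numeric array of HU values.
#' @param spacing per-axis voxel spacing in mm.
#' @param origin per-axis origin in mm (defaults to zeros).
#' @return an \linkS4class{ImageVolume}.
#' @examples
#' ImageVolume(matrix(0, 10, 10), spacing = c(0.3, 0.3))
#' @export
ImageVolume <- function(data, spacing, origin = rep(0, length(dim(data)))) {
  if (is.null(dim(data))) stop("data must be a matrix or array")
  new("ImageVolume", data = array(as.numeric(data), dim = dim(data)),
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

#' Select an axial slice of a 3D volume
#'
#' @param volume a 3D \linkS4class{ImageVolume}.
#' @param sliceIndex 1-based index along the third axis.
#' @return a 2D \linkS4class{ImageVolume} with the in-plane spacing/origin.
#' @export
axialSlice <- function(volume, sliceIndex) {
  d <- dim(volume@data)
  if (length(d) != 3L) stop("axialSlice needs a 3D volume")
  if (sliceIndex < 1L || sliceIndex > d[3])
    stop("sliceIndex out of range")
  ImageVolume(volume@data[, , sliceIndex, drop = TRUE],
              spacing = volume@spacing[1:2], origin = volume@origin[1:2])
}
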