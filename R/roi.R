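#' @include volume.R io.R
NULL

#' Mean attenuation and noise within a circular ROI
#'
#' Selects the pixels whose centres lie within the ROI radius (the usual
#' circular-ROI semantics of image-analysis tools) and returns their mean HU
#' and sample standard deviation (n - 1 denominator), the conventional ROI
#' noise estimate.
#'
#' @param volume a 2D \linkS4class{ImageVolume}, or 3D with the ROI's
#'   sliceIndex set.
#' @param roi a \linkS4class{CircularROI}.
#' @return data.frame with columns label, mean_hu, sd_hu, n_pixels.
#' @examples
#' img <- ImageVolume(matrix(250, 40, 40), spacing = c(0.3, 0.3))
#' roiMeanSD(img, CircularROI("fat", c(6, 6), 1.5))
#' @export
roiMeanSD <- function(volume, roi) {
  validObject(volume)
  validObject(roi)
  img <- volume@data
  if (length(dim(img)) == 3L) {
    if (is.na(roi@sliceIndex))
      stop("ROI '", roi@label, "' needs a sliceIndex for a 3D volume")
    volume <- axialSlice(volume, roi@sliceIndex)
    img <- volume@data
  }
  ext <- dim(img) * volume@spacing
  lo <- roi@center - roi@radius - volume@origin
  hi <- roi@center + roi@radius - volume@origin
  if (any(lo < 0) || any(hi > ext))
    stop("ROI '", roi@label, "' extends outside the image bounds")
  cx <- volume@origin[1] + (seq_len(nrow(img)) - 0.5) * volume@spacing[1]
  cy <- volume@origin[2] + (seq_len(ncol(img)) - 0.5) * volume@spacing[2]
  inside <- outer((cx - roi@center[1])^2, (cy - roi@center[2])^2, "+") <=
    roi@radius^2
  vals <- img[inside]
  if (!length(vals))
    stop("ROI '", roi@label, "' selects no pixel centres (radius too small ",
         "for the pixel spacing)")
  data.frame(label = roi@label, mean_hu = mean(vals),
             sd_hu = if (length(vals) > 1L) stats::sd(vals) else 0,
             n_pixels = length(vals), stringsAsFactors = FALSE)
}

#' Contrast-to-noise ratio of a coronary/fat ROI pair
#'
#' CNR = (mean coronary HU - mean fat HU) / SD of the coronary ROI. The
#' denominator is the coronary ROI's own standard deviation; a zero coronary
#' SD makes the ratio undefined and is an error rather than an infinity.
#'
#' @param coronary one-row data.frame from \code{\link{roiMeanSD}} for the
#'   coronary ROI.
#' @param fat one-row data.frame from \code{\link{roiMeanSD}} for the fat ROI.
#' @return data.frame with columns coronary_label, cnr.
#' @examples
#' cor <- data.frame(label = "LM", mean_hu = 800, sd_hu = 40, n_pixels = 50)
#' fat <- data.frame(label = "fat", mean_hu = -80, sd_hu = 38, n_pixels = 50)
#' cnr(cor, fat)$cnr  # 22
#' @export
cnr <- function(coronary, fat) {
  if (coronary$sd_hu <= 0)
    stop("CNR undefined: coronary ROI '", coronary$label,
         "' has zero standard deviation")
  data.frame(coronary_label = coronary$label,
             cnr = (coronary$mean_hu - fat$mean_hu) / coronary$sd_hu,
             stringsAsFactors = FALSE)
}

#' Aggregate per-subject ROI metrics over the reconstruction grid
#'
#' Reduces a tidy per-measurement table (one row per subject, family, level
#' and ROI) to the reporting shape: mean and SD per (family, level) cell —
#' optionally keeping proximal/distal as a grouping column — for each value
#' column present among mean_hu, sd_hu and cnr. Missing grid cells are
#' reported in the \code{missing_cells} attribute, never silently dropped.
#'
#' @param metrics data.frame with columns subject, family, level, label and
#'   one or more of mean_hu, sd_hu, cnr.
#' @param splitProxDist keep a prox/dist grouping column (from labels ending
#'   "_prox"/"_dist")?
#' @param expectedCells optional character vector of "family:level" keys that
#'   must be present (defaults to the 12-cell grid).
#' @return data.frame with one row per group and columns
#'   \code{<value>_mean}, \code{<value>_sd}, \code{n}.
#' @export
metricsTable <- function(metrics, splitProxDist = FALSE,
                         expectedCells = vapply(defaultKernelGrid(),
                                                kernelKey, character(1))) {
  stopifnot(all(c("family", "level") %in% names(metrics)))
  present <- unique(sprintf("%s:%d", metrics$family, metrics$level))
  miss <- setdiff(expectedCells, present)
  groups <- list(family = metrics$family, level = metrics$level)
  if (splitProxDist) {
    groups$prox_dist <- ifelse(grepl("_dist$", metrics$label), "dist",
                        ifelse(grepl("_prox$", metrics$label), "prox",
                               "other"))
  }
  valueCols <- intersect(c("mean_hu", "sd_hu", "cnr"), names(metrics))
  out <- NULL
  for (vc in valueCols) {
    m <- stats::aggregate(metrics[[vc]], by = groups, FUN = mean)
    s <- stats::aggregate(metrics[[vc]], by = groups, FUN = stats::sd)
    names(m)[names(m) == "x"] <- paste0(vc, "_mean")
    sdcol <- s$x
    sdcol[is.na(sdcol)] <- 0      # single observation per cell
    m[[paste0(vc, "_sd")]] <- sdcol
    out <- if (is.null(out)) m else merge(out, m, sort = FALSE)
  }
  nrows <- stats::aggregate(seq_len(nrow(metrics)), by = groups, FUN = length)
  names(nrows)[names(nrows) == "x"] <- "n"
  out <- merge(out, nrows, sort = FALSE)
  out <- out[order(match(out$family, KERNEL_FAMILIES), out$level), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing_cells") <- miss
  if (length(miss))
    warning("missing grid cells: ", paste(miss, collapse = ", "))
  out
}
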