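#' @include volume.R
NULL

# --- NPY v1.0 (little-endian float64) ---------------------------------------

npySidecarPath <- function(path) sub("\\.npy$", ".json", path)

writeNpy <- function(x, path) {
  d <- dim(x)
  shape <- paste0("(", paste(d, collapse = ", "),
                  if (length(d) == 1L) "," else "", ")")
  header <- sprintf("{'descr': '<f8', 'fortran_order': True, 'shape': %s, }",
                    shape)
  # total of magic(6) + version(2) + hlen(2) + header must be a multiple of 16
  pad <- (16 - (10 + nchar(header) + 1) %% 16) %% 16
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.vector(x, mode = "numeric"), con, size = 8, endian = "little")
}

readNpy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6)
  if (!identical(magic, as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an NPY file: ", path)
  ver <- readBin(con, "raw", 2)
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- readChar(con, hlen, useBytes = TRUE)
  if (!grepl("'descr':\\s*'<f8'", header))
    stop("only little-endian float64 NPY is supported; header: ", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shapeStr <- regmatches(header, regexpr("'shape':\\s*\\(([^)]*)\\)", header))
  shape <- as.integer(strsplit(gsub("[^0-9,]", "", shapeStr), ",")[[1]])
  n <- prod(shape)
  vals <- readBin(con, "numeric", n, size = 8, endian = "little")
  if (fortran) {
    array(vals, dim = shape)
  } else {
    aperm(array(vals, dim = rev(shape)), rev(seq_along(shape)))
  }
}

# --- volume I/O -------------------------------------------------------------

#' Read an image volume with spacing metadata
#'
#' Supports NIfTI (\code{.nii}/\code{.nii.gz}; spacing from the header pixdim)
#' and NPY (\code{.npy}) with a mandatory JSON sidecar (same basename,
#' \code{.json}) carrying \code{spacing_mm} and optionally \code{origin_mm}.
#' Missing spacing metadata is an error — spacing is never silently assumed
#' to be 1 mm.
#'
#' @param path file path.
#' @return an \linkS4class{ImageVolume}.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)
    arr <- array(as.numeric(img), dim = dim(img))
    nd <- length(dim(arr))
    if (length(sp) < nd || any(!is.finite(sp[seq_len(nd)])) ||
        any(sp[seq_len(nd)] <= 0))
      stop("NIfTI header of ", path, " lacks usable pixdim spacing")
    return(ImageVolume(arr, spacing = sp[seq_len(nd)]))
  }
  if (grepl("\\.npy$", path)) {
    side <- npySidecarPath(path)
    if (!file.exists(side))
      stop("NPY volume ", path, " has no JSON sidecar (", side,
           "); spacing metadata is required")
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (is.null(meta$spacing_mm))
      stop("sidecar ", side, " lacks spacing_mm")
    arr <- readNpy(path)
    org <- if (is.null(meta$origin_mm)) rep(0, length(dim(arr))) else
      as.numeric(meta$origin_mm)
    return(ImageVolume(arr, spacing = as.numeric(meta$spacing_mm),
                       origin = org))
  }
  stop("unsupported volume format: ", path,
       " (expected .nii, .nii.gz or .npy)")
}

#' Write an image volume
#'
#' The format follows the file extension: NIfTI (double datatype, spacing in
#' the header) or NPY + JSON sidecar with \code{spacing_mm}, \code{origin_mm}
#' and any extra metadata fields supplied via \code{meta}.
#'
#' @param volume an \linkS4class{ImageVolume}.
#' @param path output path (\code{.nii}, \code{.nii.gz} or \code{.npy}).
#' @param meta named list of extra sidecar fields (NPY only), e.g.
#'   kernel_family and sharpness_level.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(volume, path, meta = list()) {
  validObject(volume)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(volume@data)
    RNifti::pixdim(img) <- volume@spacing
    RNifti::writeNifti(img, path, datatype = "double")
  } else if (grepl("\\.npy$", path)) {
    writeNpy(volume@data, path)
    side <- c(list(spacing_mm = volume@spacing, origin_mm = volume@origin),
              meta)
    jsonlite::write_json(side, npySidecarPath(path), auto_unbox = TRUE,
                         digits = NA)
  } else {
    stop("unsupported volume format: ", path)
  }
  invisible(path)
}

# --- ROI / profile-site configuration ---------------------------------------

#' Create a circular ROI
#'
#' @param label ROI label (coronary location or "fat").
#' @param center circle centre, physical mm.
#' @param radius circle radius in mm.
#' @param sliceIndex axial slice for 3D volumes (NA for 2D).
#' @return a \linkS4class{CircularROI}.
#' @export
CircularROI <- function(label, center, radius, sliceIndex = NA_integer_) {
  new("CircularROI", label = as.character(label),
      center = as.numeric(center), radius = as.numeric(radius),
      sliceIndex = as.integer(sliceIndex))
}

#' Create a profile sampling site
#'
#' @param label site label.
#' @param center point on the vessel border, physical mm.
#' @param direction unit 2-vector perpendicular to the border.
#' @param halfLength half length of the segment in mm.
#' @param step sampling step in mm.
#' @return a \linkS4class{ProfileSite}.
#' @export
ProfileSite <- function(label, center, direction, halfLength = 4, step = 0.1) {
  new("ProfileSite", label = as.character(label),
      center = as.numeric(center), direction = as.numeric(direction),
      halfLength = as.numeric(halfLength), step = as.numeric(step))
}

#' Read ROI and profile-site definitions
#'
#' Reads a YAML or JSON configuration with top-level lists \code{rois}
#' (label, center, radius, optional slice_index) and \code{profiles} (label,
#' center, direction, half_length, step), all coordinates in physical mm so
#' one configuration applies unchanged to every reconstruction of a subject
#' regardless of pixel spacing.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return list with elements \code{rois} (list of
#'   \linkS4class{CircularROI}) and \code{sites} (list of
#'   \linkS4class{ProfileSite}).
#' @export
readROIConfig <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  asList <- function(x) {
    if (is.data.frame(x)) lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
    else x
  }
  rois <- lapply(asList(cfg$rois), function(r)
    CircularROI(r$label, unlist(r$center), r$radius,
                if (is.null(r$slice_index)) NA_integer_ else r$slice_index))
  sites <- lapply(asList(cfg$profiles), function(p)
    ProfileSite(p$label, unlist(p$center), unlist(p$direction),
                if (is.null(p$half_length)) 4 else p$half_length,
                if (is.null(p$step)) 0.1 else p$step))
  list(rois = rois, sites = sites)
}
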