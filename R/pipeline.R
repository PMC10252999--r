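#' @include phantom.R ratings.R roi.R sigmoid.R stats.R
NULL

CORONARY_LOCATIONS <- c("LM", "RCA_prox", "RCA_dist", "LAD_prox", "LAD_dist",
                        "LCX_prox", "LCX_dist")
PROFILE_LOCATIONS <- setdiff(CORONARY_LOCATIONS, "LM")

#' Default ROI and profile-site layout for the vessel phantom
#'
#' Builds the eight circular ROIs (seven coronary lumen ROIs plus one
#' pericoronary-fat ROI, attached to the LM image) and six profile sites
#' (proximal and distal RCA/LAD/LCX) matching the phantom geometry: each
#' location is imaged as its own vessel cross-section centred in the field
#' of view, proximal vessels at \code{proxDiameter} and distal at
#' \code{distDiameter}. Profile segments pass through the vessel centre at
#' staggered angles so each samples both vessel borders.
#'
#' @param fieldOfView field-of-view side in mm.
#' @param proxDiameter,distDiameter vessel diameters in mm.
#' @param halfLength,step profile geometry in mm.
#' @return list with elements \code{rois} and \code{sites}; each ROI/site
#'   carries an \code{image} attribute naming the location image it applies
#'   to.
#' @export
makeDefaultROIConfig <- function(fieldOfView = 20, proxDiameter = 3.5,
                                 distDiameter = 2, halfLength = 4,
                                 step = 0.1) {
  ctr <- c(fieldOfView / 2, fieldOfView / 2)
  lumenRadius <- function(label)
    0.55 * (if (grepl("_dist$", label)) distDiameter else proxDiameter) / 2
  rois <- lapply(CORONARY_LOCATIONS, function(lab) {
    r <- CircularROI(lab, ctr, lumenRadius(lab))
    attr(r, "image") <- lab
    r
  })
  fat <- CircularROI("fat", ctr + c(-fieldOfView / 4, -fieldOfView / 4), 2)
  attr(fat, "image") <- "LM"
  rois <- c(rois, list(fat))
  angles <- (seq_along(PROFILE_LOCATIONS) - 1) * pi / 6 + pi / 12
  sites <- mapply(function(lab, a) {
    s <- ProfileSite(lab, ctr, c(cos(a), sin(a)), halfLength, step)
    attr(s, "image") <- lab
    s
  }, PROFILE_LOCATIONS, angles, SIMPLIFY = FALSE)
  list(rois = rois, sites = unname(sites))
}

measureOneReconstruction <- function(volumes, rois, sites) {
  # volumes: named list of ImageVolume by location label
  roiRows <- lapply(rois, function(roi) {
    imgLab <- attr(roi, "image")
    if (is.null(imgLab)) imgLab <- roi@label
    if (!imgLab %in% names(volumes)) return(NULL)
    roiMeanSD(volumes[[imgLab]], roi)
  })
  roiTab <- do.call(rbind, roiRows)
  fatRow <- roiTab[roiTab$label == "fat", , drop = FALSE]
  cnrTab <- NULL
  if (nrow(fatRow) == 1L) {
    cor <- roiTab[roiTab$label != "fat", , drop = FALSE]
    cnrTab <- do.call(rbind, lapply(seq_len(nrow(cor)), function(i)
      cnr(cor[i, ], fatRow)))
  }
  fitRows <- lapply(sites, function(site) {
    imgLab <- attr(site, "image")
    if (is.null(imgLab)) imgLab <- site@label
    if (!imgLab %in% names(volumes)) return(NULL)
    prof <- extractProfile(volumes[[imgLab]], site)
    fit <- fitDoubleSigmoid(prof)
    data.frame(site = site@label, b = fit@b, A = fit@A, s_per_mm = fit@s,
               x1_mm = fit@x1, x2_mm = fit@x2, rmse = fit@rmse,
               converged = fit@converged, stringsAsFactors = FALSE)
  })
  list(rois = roiTab, cnr = cnrTab, fits = do.call(rbind, fitRows))
}

simulateSubjectCell <- function(subject, kernel, seeds, config) {
  diam <- function(lab)
    if (grepl("_dist$", lab)) config$distDiameter else config$proxDiameter
  vols <- lapply(seq_along(CORONARY_LOCATIONS), function(i) {
    lab <- CORONARY_LOCATIONS[i]
    generateVesselImage(PhantomSpec(
      vesselDiameter = diam(lab), vesselHu = config$vesselHu,
      fatHu = config$fatHu, fieldOfView = config$fieldOfView,
      pixelSpacing = config$pixelSpacing, kernel = kernel,
      seed = seeds[i]))
  })
  names(vols) <- CORONARY_LOCATIONS
  vols
}

defaultRunConfig <- function() {
  list(nSubjects = 1L, vesselHu = 800, fatHu = -80, fieldOfView = 20,
       pixelSpacing = 0.3, proxDiameter = 3.5, distDiameter = 2,
       format = "nifti", writeImages = TRUE)
}

#' Read a pipeline run configuration
#'
#' Reads a YAML or JSON run configuration and fills in package defaults for
#' unset fields (simulation geometry, output format).
#'
#' @param path YAML/JSON file; fields override \code{defaultRunConfig()}.
#' @return a named list.
#' @export
readRunConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  out <- defaultRunConfig()
  out[names(cfg)] <- cfg
  out
}

writeManifest <- function(outDir) {
  files <- setdiff(list.files(outDir, recursive = TRUE),
                   "manifest.json")
  md5 <- tools::md5sum(file.path(outDir, files))
  names(md5) <- files
  jsonlite::write_json(as.list(md5), file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE)
}

statsReport <- function(metrics, fits, ratings, con) {
  wl <- function(...) writeLines(sprintf(...), con)
  wl("== Objective image quality: per-cell summaries ==")
  tab <- metricsTable(metrics[metrics$label != "fat", ])
  noiseTab <- metricsTable(metrics[metrics$label == "fat", ])
  sTab <- sharpnessSummary(transform(fits, s = s_per_mm))
  for (i in seq_len(nrow(tab))) {
    key <- paste(tab$family[i], tab$level[i])
    j <- which(noiseTab$family == tab$family[i] &
                 noiseTab$level == tab$level[i])
    k <- which(sTab$family == tab$family[i] & sTab$level == tab$level[i])
    wl("%-6s attenuation %7.1f +/- %5.1f  noise %5.1f  sharpness %4.2f +/- %4.2f  CNR %5.2f +/- %4.2f",
       key, tab$mean_hu_mean[i], tab$mean_hu_sd[i],
       if (length(j)) noiseTab$sd_hu_mean[j] else NA_real_,
       if (length(k)) sTab$mean_s[k] else NA_real_,
       if (length(k) && is.finite(sTab$sd_s[k])) sTab$sd_s[k] else 0,
       tab$cnr_mean[i], tab$cnr_sd[i])
  }
  wl("")
  wl("== Sharpness comparison across kernel families (one-way ANOVA) ==")
  ok <- fits$converged
  if (sum(ok) >= 6 && length(unique(fits$family[ok])) >= 2) {
    res <- anovaOnewayPosthoc(fits$s_per_mm[ok], fits$family[ok])
    if (res@degenerate) {
      wl("degenerate: zero variance")
    } else {
      wl("F = %.3f, p = %.3g", res@statistic, res@pValue)
      for (i in seq_len(nrow(res@postHoc)))
        wl("  %-8s diff %+6.3f  p_adj %.3g", res@postHoc$pair[i],
           res@postHoc$diff[i], res@postHoc$p_adj[i])
    }
  }
  if (!is.null(ratings) && nrow(ratings)) {
    wl("")
    wl("== Subjective image quality: median (IQR) and Kruskal-Wallis ==")
    for (crit in unique(ratings$criterion)) {
      sub <- ratings[ratings$criterion == crit, ]
      byFam <- likertSummary(sub$score, sub$family)
      kwF <- kruskalWallis(sub$score, sub$family)
      wl("%s by family:  %s   KW p = %.3g", crit,
         paste(sprintf("%s %s", byFam$group, byFam$formatted),
               collapse = "  "), kwF@pValue)
      byLev <- likertSummary(sub$score, sub$level)
      kwL <- kruskalWallis(sub$score, sub$level)
      wl("%s by level:   %s   KW p = %.3g", crit,
         paste(sprintf("%s %s", byLev$group, byLev$formatted),
               collapse = "  "), kwL@pValue)
    }
    wl("")
    wl("== Inter-reader agreement (ICC(2,1), absolute agreement) ==")
    for (crit in unique(ratings$criterion)) {
      sub <- ratings[ratings$criterion == crit, ]
      wide <- stats::reshape(
        sub[, c("subject", "family", "level", "rater", "score")],
        idvar = c("subject", "family", "level"), timevar = "rater",
        direction = "wide")
      m <- as.matrix(wide[, grep("^score", names(wide)), drop = FALSE])
      res <- iccAbsoluteAgreement(m)
      wl("%-18s ICC = %.3f (%s agreement)", crit, res@icc,
         res@interpretation)
    }
  }
}

#' Simulate the full reconstruction grid and analyze it
#'
#' Generates phantom images for every subject, grid cell and coronary
#' location, measures ROI metrics and CNR, extracts and fits the six edge
#' profiles, simulates the two-rater Likert ratings, runs the statistical
#' comparison layer, and writes metrics.csv, fits.csv, ratings.csv,
#' volumes.csv (image index), report.txt and manifest.json (md5 of every
#' output) to the output directory. Fully deterministic for a fixed seed.
#'
#' @param outDir output directory (created if needed).
#' @param seed integer master seed.
#' @param config named list overriding \code{defaultRunConfig()} entries.
#' @return invisibly, a list with the metrics, fits and ratings tables.
#' @export
runSimulate <- function(outDir, seed, config = list()) {
  cfg <- defaultRunConfig()
  cfg[names(config)] <- config
  badField <- setdiff(names(config), names(defaultRunConfig()))
  if (length(badField))
    stop("unknown config field(s): ", paste(badField, collapse = ", "))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  grid <- defaultKernelGrid()
  layout <- makeDefaultROIConfig(cfg$fieldOfView, cfg$proxDiameter,
                                 cfg$distDiameter)
  nImg <- cfg$nSubjects * length(grid) * length(CORONARY_LOCATIONS)
  seeds <- withSeed(seed, sample.int(.Machine$integer.max - 1L, nImg))
  ext <- if (identical(cfg$format, "npy")) ".npy" else ".nii.gz"

  metrics <- list(); fits <- list(); volindex <- list()
  si <- 0L
  for (subj in seq_len(cfg$nSubjects)) {
    for (kern in grid) {
      cellSeeds <- seeds[si + seq_along(CORONARY_LOCATIONS)]
      si <- si + length(CORONARY_LOCATIONS)
      vols <- simulateSubjectCell(subj, kern, cellSeeds, cfg)
      meas <- measureOneReconstruction(vols, layout$rois, layout$sites)
      roiTab <- meas$rois
      roiTab$cnr <- meas$cnr$cnr[match(roiTab$label,
                                       meas$cnr$coronary_label)]
      roiTab <- cbind(subject = subj, family = kern@family,
                      level = kern@level, roiTab)
      fitTab <- cbind(subject = subj, family = kern@family,
                      level = kern@level, meas$fits)
      metrics[[length(metrics) + 1L]] <- roiTab
      fits[[length(fits) + 1L]] <- fitTab
      if (isTRUE(cfg$writeImages)) {
        imgDir <- file.path(outDir, "images")
        dir.create(imgDir, showWarnings = FALSE)
        for (lab in names(vols)) {
          f <- file.path(imgDir, sprintf("s%02d_%s%d_%s%s", subj,
                                         kern@family, kern@level, lab, ext))
          writeVolume(vols[[lab]], f,
                      meta = list(kernel_family = kern@family,
                                  sharpness_level = kern@level))
          volindex[[length(volindex) + 1L]] <- data.frame(
            subject = subj, family = kern@family, level = kern@level,
            label = lab, path = file.path("images", basename(f)),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  fits <- do.call(rbind, fits)
  ratings <- generateRatings(
    RatingModelSpec(nSubjects = cfg$nSubjects,
                    seed = withSeed(seed + 1L,
                                    sample.int(.Machine$integer.max - 1L, 1))),
    grid)

  utils::write.csv(metrics, file.path(outDir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(fits, file.path(outDir, "fits.csv"), row.names = FALSE)
  utils::write.csv(ratings, file.path(outDir, "ratings.csv"),
                   row.names = FALSE)
  if (length(volindex))
    utils::write.csv(do.call(rbind, volindex),
                     file.path(outDir, "volumes.csv"), row.names = FALSE)
  con <- file(file.path(outDir, "report.txt"), "w")
  statsReport(metrics, fits, ratings, con)
  close(con)
  writeManifest(outDir)
  invisible(list(metrics = metrics, fits = fits, ratings = ratings))
}

#' Measure existing reconstructions with a fixed ROI/site layout
#'
#' Applies one ROI and profile-site configuration, unchanged, to every
#' reconstruction of every subject listed in the volume index — mirroring
#' the study's reuse of a stored ROI set across all 12 reconstructions —
#' and writes metrics.csv, fits.csv, report.txt and manifest.json. Subjects
#' with missing reconstructions are reported in the output and skipped, not
#' fatal.
#'
#' @param volumeIndex data.frame (or CSV path) with columns subject, family,
#'   level, label, path; paths are resolved relative to \code{baseDir}.
#' @param roiConfig a list with \code{rois}/\code{sites} (as from
#'   \code{\link{readROIConfig}} or \code{\link{makeDefaultROIConfig}}), or a
#'   YAML/JSON path.
#' @param outDir output directory.
#' @param baseDir directory volume paths are relative to.
#' @return invisibly, a list with the metrics and fits tables.
#' @export
runMeasure <- function(volumeIndex, roiConfig, outDir, baseDir = ".") {
  if (is.character(volumeIndex))
    volumeIndex <- utils::read.csv(volumeIndex, stringsAsFactors = FALSE)
  if (is.character(roiConfig)) roiConfig <- readROIConfig(roiConfig)
  need <- c("subject", "family", "level", "label", "path")
  if (!all(need %in% names(volumeIndex)))
    stop("volume index needs columns: ", paste(need, collapse = ", "))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  metrics <- list(); fits <- list(); problems <- character()
  cells <- unique(volumeIndex[, c("subject", "family", "level")])
  for (i in seq_len(nrow(cells))) {
    sel <- volumeIndex$subject == cells$subject[i] &
      volumeIndex$family == cells$family[i] &
      volumeIndex$level == cells$level[i]
    rows <- volumeIndex[sel, ]
    vols <- list()
    for (j in seq_len(nrow(rows))) {
      p <- file.path(baseDir, rows$path[j])
      if (!file.exists(p)) {
        problems <- c(problems, sprintf("missing volume: %s", rows$path[j]))
        next
      }
      vols[[rows$label[j]]] <- readVolume(p)
    }
    if (!length(vols)) next
    meas <- measureOneReconstruction(vols, roiConfig$rois, roiConfig$sites)
    roiTab <- meas$rois
    roiTab$cnr <- if (!is.null(meas$cnr))
      meas$cnr$cnr[match(roiTab$label, meas$cnr$coronary_label)] else NA_real_
    metrics[[i]] <- cbind(subject = cells$subject[i],
                          family = cells$family[i], level = cells$level[i],
                          roiTab)
    fits[[i]] <- cbind(subject = cells$subject[i],
                       family = cells$family[i], level = cells$level[i],
                       meas$fits)
  }
  metrics <- do.call(rbind, metrics)
  fits <- do.call(rbind, fits)
  utils::write.csv(metrics, file.path(outDir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(fits, file.path(outDir, "fits.csv"), row.names = FALSE)
  con <- file(file.path(outDir, "report.txt"), "w")
  if (length(problems)) {
    writeLines("== Problems ==", con)
    writeLines(problems, con)
    writeLines("", con)
  }
  statsReport(metrics, fits, NULL, con)
  close(con)
  writeManifest(outDir)
  invisible(list(metrics = metrics, fits = fits, problems = problems))
}
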