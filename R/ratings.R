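#' @include kernels.R
NULL

# Default latent quality per grid cell: an additive family + level structure
# chosen to emulate the observed reader preferences (Bv rated above Br and
# Qr; levels 36/40 above 44/48).
.DEFAULT_LATENT <- local({
  fam <- c(Br = 0, Bv = 0.9, Qr = -0.05)
  lev <- c("36" = 0.8, "40" = 0.7, "44" = -0.1, "48" = -0.7)
  q <- as.vector(outer(fam, lev, "+"))
  names(q) <- as.vector(outer(names(fam), names(lev), paste, sep = ":"))
  q
})

#' Create a rating-model specification
#'
#' Defaults emulate the study's reading setup: 30 subjects, two raters with
#' no systematic bias, moderate rater noise, and latent qualities that favour
#' the Bv family and the softer sharpness levels.
#'
#' @param nSubjects number of subjects.
#' @param latentQuality named numeric ("family:level") of latent qualities.
#' @param raterBias per-rater systematic offsets.
#' @param raterNoiseSd rater noise standard deviation.
#' @param thresholds four ascending cutpoints mapping latent values to 1-5.
#' @param seed integer seed.
#' @return a \linkS4class{RatingModelSpec}.
#' @examples
#' RatingModelSpec(nSubjects = 10)
#' @export
RatingModelSpec <- function(nSubjects = 30, latentQuality = .DEFAULT_LATENT,
                            raterBias = c(0, 0), raterNoiseSd = 0.5,
                            thresholds = c(-1.5, -0.75, 0, 0.75),
                            seed = 1L) {
  new("RatingModelSpec", nSubjects = as.integer(nSubjects),
      latentQuality = latentQuality, raterBias = as.numeric(raterBias),
      raterNoiseSd = as.numeric(raterNoiseSd),
      thresholds = as.numeric(thresholds), seed = as.integer(seed))
}

#' Generate a two-rater Likert rating table
#'
#' Draws one ordinal score per (subject, reconstruction, rater, criterion)
#' from the latent-quality model: latent quality of the reconstruction plus
#' the rater's bias plus Gaussian rater noise, cut into scores 1-5 by the
#' model's thresholds (score = 1 + number of thresholds strictly exceeded, so
#' scores are automatically in [1, 5]).
#'
#' @param spec a \linkS4class{RatingModelSpec}.
#' @param grid list of \linkS4class{KernelSpec} (the reconstructions rated).
#' @param criteria character vector of rated criteria.
#' @return a tidy data.frame with columns subject, family, level, rater,
#'   criterion, score.
#' @examples
#' r <- generateRatings(RatingModelSpec(nSubjects = 3), defaultKernelGrid())
#' table(r$score)
#' @export
generateRatings <- function(spec, grid = defaultKernelGrid(),
                            criteria = RATING_CRITERIA) {
  validObject(spec)
  keys <- vapply(grid, kernelKey, character(1))
  missing <- setdiff(keys, names(spec@latentQuality))
  if (length(missing))
    stop("latentQuality has no entry for: ", paste(missing, collapse = ", "))
  nR <- length(spec@raterBias)
  df <- expand.grid(
    subject = seq_len(spec@nSubjects),
    cell = seq_along(grid),
    rater = seq_len(nR),
    criterion = criteria,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  latent <- spec@latentQuality[keys[df$cell]] + spec@raterBias[df$rater]
  latent <- latent + withSeed(spec@seed,
    stats::rnorm(nrow(df), 0, spec@raterNoiseSd))
  score <- 1L + rowSums(outer(latent, spec@thresholds, ">"))
  data.frame(
    subject = df$subject,
    family = vapply(grid, function(k) k@family, character(1))[df$cell],
    level = vapply(grid, function(k) k@level, integer(1))[df$cell],
    rater = df$rater,
    criterion = df$criterion,
    score = as.integer(score),
    stringsAsFactors = FALSE)
}
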