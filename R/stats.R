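#' @include AllClasses.R
NULL

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' Univariate analysis of variance of \code{values} across the levels of
#' \code{group}, followed by Tukey honest-significant-difference pairwise
#' comparisons. When every observation is identical the F statistic is 0/0;
#' this is reported as a degenerate result instead of propagating NaN.
#'
#' @param values numeric observations.
#' @param group grouping factor (>= 2 levels, each with >= 2 observations).
#' @return a \linkS4class{TestResult}; the \code{postHoc} slot holds one row
#'   per group pair with the difference, confidence bounds and adjusted p.
#' @examples
#' anovaOnewayPosthoc(c(1, 2, 3, 5, 6, 7), rep(c("a", "b"), each = 3))
#' @export
anovaOnewayPosthoc <- function(values, group) {
  group <- factor(group)
  sizes <- table(group)
  if (nlevels(group) < 2L)
    stop("ANOVA needs at least 2 groups")
  if (any(sizes < 2L))
    stop("every group needs at least 2 observations; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  if (stats::var(values) == 0) {
    return(new("TestResult", statistic = NA_real_, pValue = NA_real_,
               df = c(df1 = nlevels(group) - 1,
                      df2 = length(values) - nlevels(group)),
               groupSizes = as.integer(sizes),
               method = "One-way ANOVA (Tukey HSD post hoc)",
               postHoc = data.frame(), degenerate = TRUE))
  }
  fit <- stats::aov(values ~ group)
  tab <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  postHoc <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        p_adj = tk[, "p adj"], row.names = NULL,
                        stringsAsFactors = FALSE)
  new("TestResult",
      statistic = tab[1, "F value"], pValue = tab[1, "Pr(>F)"],
      df = c(df1 = tab[1, "Df"], df2 = tab[2, "Df"]),
      groupSizes = as.integer(sizes),
      method = "One-way ANOVA (Tukey HSD post hoc)",
      postHoc = postHoc, degenerate = FALSE)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with the chi-square asymptotic p-value,
#' suited to heavily tied ordinal data such as Likert scores. When all
#' observations are identical there is no rank separation: H = 0, p = 1.
#'
#' @param values numeric or ordinal observations.
#' @param group grouping factor (>= 2 groups, each non-empty).
#' @return a \linkS4class{TestResult}.
#' @examples
#' kruskalWallis(c(1, 2, 2, 4, 5, 5), rep(c("a", "b"), each = 3))
#' @export
kruskalWallis <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L)
    stop("Kruskal-Wallis needs at least 2 groups")
  sizes <- table(group)
  if (any(sizes < 1L)) stop("empty group")
  if (length(unique(values)) == 1L) {
    return(new("TestResult", statistic = 0, pValue = 1,
               df = c(df = nlevels(group) - 1),
               groupSizes = as.integer(sizes),
               method = "Kruskal-Wallis rank sum test",
               postHoc = data.frame(), degenerate = FALSE))
  }
  kw <- stats::kruskal.test(values, group)
  new("TestResult", statistic = unname(kw$statistic),
      pValue = unname(kw$p.value),
      df = c(df = unname(kw$parameter)),
      groupSizes = as.integer(sizes),
      method = "Kruskal-Wallis rank sum test",
      postHoc = data.frame(), degenerate = FALSE)
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' ICC(2,1): single-measure absolute agreement between raters treated as a
#' random sample, computed from the two-way mean squares
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the row (target), column
#' (rater) and residual mean squares, \eqn{n} targets and \eqn{k} raters.
#' The qualitative bin is assigned per \code{\link{interpretICC}}.
#'
#' @param ratings numeric matrix, one row per rated target and one column per
#'   rater (two columns for the two-reader design).
#' @return an \linkS4class{ICCResult}.
#' @examples
#' m <- cbind(r1 = c(4, 5, 3, 4, 5, 2), r2 = c(4, 5, 3, 4, 5, 2))
#' iccAbsoluteAgreement(m)
#' @export
iccAbsoluteAgreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2L) stop("ICC needs at least 2 rated targets")
  if (k < 2L) stop("ICC needs at least 2 raters")
  if (any(!is.finite(ratings))) stop("ratings must be complete")
  grand <- mean(ratings)
  rowM <- rowMeans(ratings)
  colM <- colMeans(ratings)
  ssr <- k * sum((rowM - grand)^2)
  ssc <- n * sum((colM - grand)^2)
  sse <- sum((ratings - outer(rowM, rep(1, k)) -
                outer(rep(1, n), colM) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- if (denom == 0) 1 else (msr - mse) / denom
  new("ICCResult", icc = icc,
      model = "ICC(2,1) two-way random, absolute agreement, single measures",
      interpretation = interpretICC(icc))
}

#' Qualitative agreement bin for an ICC value
#'
#' Bins: poor (<0.2), fair (0.2-0.4), moderate (0.4-0.6), substantial
#' (0.6-0.8), excellent (>0.8). A value exactly on a boundary falls into the
#' lower bin, so the bins partition (-Inf, 1] without gaps.
#'
#' @param icc numeric ICC value(s).
#' @return character vector of bin labels.
#' @examples
#' interpretICC(c(0.1, 0.2, 0.5, 0.95))
#' @export
interpretICC <- function(icc) {
  as.character(cut(icc, breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
      labels = c("poor", "fair", "moderate", "substantial", "excellent"),
      right = TRUE))
}

#' Median (IQR) summaries of Likert scores
#'
#' Per-group median and interquartile range of ordinal scores, formatted
#' "median (q1-q3)" as in reader-study report tables. Quantiles use linear
#' interpolation (type 7). Empty groups are reported with NA entries.
#'
#' @param scores integer scores in [1, 5].
#' @param group grouping vector (kernel family or sharpness level).
#' @return data.frame with columns group, median, q1, q3, formatted, n.
#' @examples
#' likertSummary(c(4, 4, 5, 5, 5), rep("Bv", 5))$formatted  # "5 (4–5)"
#' @export
likertSummary <- function(scores, group) {
  if (!is.factor(group)) group <- factor(group)
  fmtNum <- function(x) {
    ifelse(is.na(x), "NA",
           ifelse(x == round(x), format(round(x)), format(x)))
  }
  out <- do.call(rbind, lapply(levels(group), function(g) {
    v <- scores[group == g]
    if (!length(v)) {
      return(data.frame(group = g, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_, formatted = NA_character_, n = 0L,
                        stringsAsFactors = FALSE))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(group = g, median = q[2], q1 = q[1], q3 = q[3],
               formatted = sprintf("%s (%s–%s)", fmtNum(q[2]),
                                   fmtNum(q[1]), fmtNum(q[3])),
               n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
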