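# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Tie-corrected Kruskal-Wallis H from first principles
oracleH <- function(values, group) {
  r <- rank(values)
  n <- length(values)
  num <- sum(tapply(r, group, function(x) length(x) * (mean(x) - (n + 1) / 2)^2))
  H <- 12 / (n * (n + 1)) * num
  ties <- table(r)
  H / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exact permutation p-value for Kruskal-Wallis on tiny samples (full
# enumeration of label permutations)
oracleKWExactP <- function(values, group) {
  n <- length(values)
  stopifnot(n <= 8)
  H0 <- oracleH(values, group)
  allperm <- function(x) {
    if (length(x) == 1L) return(list(x))
    do.call(c, lapply(seq_along(x), function(i)
      lapply(allperm(x[-i]), function(p) c(x[i], p))))
  }
  Hs <- vapply(allperm(seq_len(n)), function(ord) oracleH(values[ord], group),
               numeric(1))
  mean(Hs >= H0 - 1e-9)
}

# One-way ANOVA F from an explicit sum-of-squares decomposition
oracleAnovaF <- function(values, group) {
  group <- factor(group)
  grand <- mean(values)
  ssb <- sum(tapply(values, group, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(unlist(tapply(values, group, function(v) (v - mean(v))^2)))
  df1 <- nlevels(group) - 1
  df2 <- length(values) - nlevels(group)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# ICC(2,1) with mean squares taken from a two-way aov fit (independent of the
# package's sums-based decomposition)
oracleICC21 <- function(ratings) {
  n <- nrow(ratings)
  k <- ncol(ratings)
  long <- data.frame(
    score = as.vector(ratings),
    target = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n)))
  tab <- summary(stats::aov(score ~ target + rater, data = long))[[1]]
  msr <- tab["target", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
}

# Type-7 quantile written out by hand
oracleQuantile7 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Hierarchical grid search for the double-sigmoid fit: exhaustive over
# (s, x1, width), refined in two stages down to 0.01 resolution around the
# running optimum; b and A are solved in closed form at every node (the model
# is linear in them). Independent of the package's optimizer.
oracleGridSearchS <- function(x, y, sRange, x1Range, widthRange) {
  logis <- function(z) 1 / (1 + exp(pmin(pmax(z, -700), 700)))
  n <- length(y)
  sy <- sum(y)
  ssrAt <- function(s, x1, w) {
    g <- logis(s * (x - x1)) - logis(s * (x - x1 - w))
    sg <- sum(g)
    sgg <- sum(g * g)
    sgy <- sum(g * y)
    det <- n * sgg - sg * sg
    if (det < 1e-12) return(sum((y - mean(y))^2))
    A <- (n * sgy - sg * sy) / det
    b <- (sy - A * sg) / n
    sum((y - b - A * g)^2)
  }
  scan <- function(sv, x1v, wv) {
    best <- NULL
    for (s in sv) for (x1 in x1v) for (w in wv) {
      ssr <- ssrAt(s, x1, w)
      if (is.null(best) || ssr < best$ssr)
        best <- list(s = s, x1 = x1, w = w, ssr = ssr)
    }
    best
  }
  b1 <- scan(seq(sRange[1], sRange[2], by = 0.1),
             seq(x1Range[1], x1Range[2], by = 0.1),
             seq(widthRange[1], widthRange[2], by = 0.1))
  b2 <- scan(seq(b1$s - 0.12, b1$s + 0.12, by = 0.05),
             seq(b1$x1 - 0.12, b1$x1 + 0.12, by = 0.05),
             seq(b1$w - 0.12, b1$w + 0.12, by = 0.05))
  b3 <- scan(seq(b2$s - 0.06, b2$s + 0.06, by = 0.01),
             seq(b2$x1 - 0.06, b2$x1 + 0.06, by = 0.01),
             seq(b2$w - 0.06, b2$w + 0.06, by = 0.01))
  b3$s
}

# Build a quick noiseless or noisy phantom image for one kernel
phantomImage <- function(family = "Br", level = 36L, psfSigma = NULL,
                         noiseSd = NULL, diameter = 3.5, seed = 1L) {
  kern <- KernelSpec(family, level, psfSigma = psfSigma, noiseSd = noiseSd)
  generateVesselImage(PhantomSpec(vesselDiameter = diameter, kernel = kern,
                                  seed = seed))
}

# Radial profile site through the phantom centre (field of view 20 mm)
radialSite <- function(angle = 0.3, label = "site", halfLength = 4,
                       step = 0.1) {
  ProfileSite(label, c(10, 10), c(cos(angle), sin(angle)), halfLength, step)
}
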