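# Spatiotemporal feature panel computed from the kinematic series of one
# spiral tracing. Feature names follow the field's established nomenclature
# (Sp.*, Dt.mean, Rv.*, Ds.*, Ads.*, Av.*, R.*, Angle.incDev, TOTSYMM,
# Err/Err0/errBF/err0BF).

#' Names of the full spiral feature panel
#'
#' @return Character vector of the 29 feature names, in canonical order.
#' @export
spiral_feature_names <- function() {
  c("Sp.mean", "Sp.cv", "Sp.skew", "Dt.mean",
    "Rv.hf.cv", "Ds.hf.min", "Ds.hf.max",
    "Rv.apen", "Ds.apen",
    "R.avgP", "R.stdP", "R.nPeaks", "R.incDev",
    "Ads.avgP", "Ads.stdP", "Ads.nPeaks",
    "Rv.avgP", "Rv.stdP", "Rv.nPeaks", "Rv.pn005",
    "Av.avgP", "Av.stdP", "Av.nPeaks",
    "Angle.incDev", "TOTSYMM",
    "Err", "Err0", "errBF", "err0BF")
}

#' Moment features of the speed series
#'
#' First three statistical moments of drawing speed plus mean delta time:
#' `Sp.mean` is the arithmetic mean of the per-interval speeds, `Sp.cv` the
#' ratio of standard deviation to mean, `Sp.skew` the skewness
#' \eqn{(\sum (v_i - \bar v)^3 / n) / s^3} with `s` the sample standard
#' deviation, and `Dt.mean` the mean inter-sample time (the hesitation proxy:
#' arrests stretch sample spacing when the device thins idle samples, and in
#' any case bound total progress).
#'
#' @param speed Per-interval speed series (px/s), length >= 3.
#' @param dt Per-interval time differences (s).
#' @return Named list `Sp.mean`, `Sp.cv`, `Sp.skew`, `Dt.mean`. A zero mean
#'   speed yields `Sp.cv = NA`; a zero spread yields `Sp.skew = 0`.
#' @export
moment_features <- function(speed, dt) {
  if (length(speed) < 3L) {
    return(list(Sp.mean = NA_real_, Sp.cv = NA_real_, Sp.skew = NA_real_,
                Dt.mean = mean(dt)))
  }
  m <- mean(speed)
  s <- stats::sd(speed)
  cv <- if (m == 0) NA_real_ else s / abs(m)
  skew <- if (s == 0) 0 else mean((speed - m)^3) / s^3
  list(Sp.mean = m, Sp.cv = cv, Sp.skew = skew, Dt.mean = mean(dt))
}

#' Approximate Entropy
#'
#' Pincus' regularity statistic ApEn(m, r): with tolerance
#' \code{r = r_frac * sd(x)}, \eqn{\Phi^m} is the mean natural log of the fraction
#' of windows of length `m` within Chebyshev distance `r` of each window
#' (self-matches included), and \eqn{ApEn = \Phi^m - \Phi^{m+1}}. Regular
#' signals score near 0; complex multi-frequency signals score high.
#'
#' @param x Numeric series, length >= `m + 2`.
#' @param m Window length (default 2).
#' @param r_frac Tolerance as a fraction of the series standard deviation
#'   (default 0.2).
#' @return ApEn in nats. A constant series returns 0.
#' @examples
#' approximate_entropy(rep(1, 50))  # 0
#' @export
approximate_entropy <- function(x, m = 2L, r_frac = 0.2) {
  n <- length(x)
  if (n < m + 2L) stop("series too short for ApEn", call. = FALSE)
  sdx <- stats::sd(x)
  if (sdx == 0) return(0)
  r <- r_frac * sdx
  phi <- function(mm) {
    nw <- n - mm + 1L
    within <- matrix(TRUE, nw, nw)
    for (k in seq_len(mm)) {
      col <- x[k:(k + nw - 1L)]
      within <- within & (abs(outer(col, col, "-")) <= r)
    }
    mean(log(rowSums(within) / nw))
  }
  phi(m) - phi(m + 1L)
}

#' Local extremes of a series
#'
#' Runs of equal consecutive values are collapsed to their first element;
#' an interior point of the collapsed series is an extreme when the signs of
#' the differences on either side oppose. The first and last points of the
#' original series are always included. `delta_peaks` holds the absolute
#' differences between values at consecutive extremes.
#'
#' @param v Numeric series, length >= 2.
#' @return List with `indices` (1-based positions in `v`; first is 1, last is
#'   `length(v)`), `values`, `delta_peaks` and `n` (series length).
#' @examples
#' find_extremes(c(1, 3, 2, 4, 1))$delta_peaks  # 2 1 2 3
#' @export
find_extremes <- function(v) {
  n <- length(v)
  if (n < 2L) stop("series too short for extreme detection", call. = FALSE)
  keep <- c(TRUE, diff(v) != 0)
  idx <- which(keep)
  cv <- v[idx]
  m <- length(cv)
  if (m == 1L) {  # constant series: the two endpoints are the only extremes
    return(list(indices = c(1L, n), values = c(v[1L], v[1L]),
                delta_peaks = 0, n = n))
  }
  is_ext <- rep(FALSE, m)
  is_ext[c(1L, m)] <- TRUE
  if (m >= 3L) {
    d <- diff(cv)
    is_ext[2:(m - 1L)] <- d[-(m - 1L)] * d[-1L] < 0
  }
  indices <- idx[is_ext]
  values <- cv[is_ext]
  indices[length(indices)] <- n  # trailing plateau maps to the last point
  list(indices = indices, values = values,
       delta_peaks = abs(diff(values)), n = n)
}

#' Delta-peak summary features
#'
#' `avgP` and `stdP` are the mean and sample standard deviation of the
#' absolute differences between consecutive local extremes (`delta_peaks` of
#' [find_extremes()]); `nPeaks` is the number of extremes divided by the
#' series length.
#'
#' @param v Numeric series, length >= 2.
#' @return Named list `avgP`, `stdP`, `nPeaks`. A single delta-peak gives
#'   `stdP = 0`.
#' @export
peak_features <- function(v) {
  ex <- find_extremes(v)
  dp <- ex$delta_peaks
  list(avgP = mean(dp),
       stdP = if (length(dp) < 2L) 0 else stats::sd(dp),
       nPeaks = length(ex$values) / ex$n)
}

#' Drift of delta-peak variability along the trial
#'
#' Measures whether irregularity grows or shrinks over the tracing: the
#' delta-peak series is scanned with overlapping windows of length
#' `max(2, floor(len / 3))` whose starts are spread as evenly as possible over
#' the admissible range (`n_windows` of them, fewer when the series is short),
#' and `incDev` is the Spearman rank correlation between window order and
#' window standard deviation.
#'
#' @param v Numeric series (the extremes are extracted internally).
#' @param n_windows Number of overlapping windows (default 30).
#' @return Correlation in \[-1, 1\]; 0 when fewer than 4 delta-peaks or
#'   fewer than 2 distinct window standard deviations exist (a monotone
#'   series — e.g. the angle of a clean tracing — carries no variability
#'   trend, which is reported as 0, not as missing).
#' @export
inc_dev <- function(v, n_windows = 30L) {
  dp <- find_extremes(v)$delta_peaks
  len <- length(dp)
  if (len < 4L) return(0)
  w <- max(2L, len %/% 3L)
  starts <- unique(round(seq(1L, len - w + 1L, length.out = n_windows)))
  sds <- vapply(starts, function(s) stats::sd(dp[s:(s + w - 1L)]), numeric(1L))
  if (length(unique(sds)) < 2L) return(0)
  stats::cor(seq_along(sds), sds, method = "spearman")
}

#' Fraction of path drawn toward the centre
#'
#' `Rv.pn005`: the percentage of the drawn path length over which the radial
#' velocity falls below a slightly negative threshold (default -0.05 px/s,
#' allowing for measurement noise). An ideal outward spiral scores 0.
#'
#' @param rv Per-interval radial velocity (px/s).
#' @param seg_len Per-interval path lengths (px), same length as `rv`.
#' @param threshold Radial-velocity threshold (px/s, default -0.05).
#' @return Percentage in \[0, 100\]; 0 when the total path length is 0.
#' @export
inward_fraction <- function(rv, seg_len, threshold = -0.05) {
  total <- sum(seg_len)
  if (total == 0) return(0)
  100 * sum(seg_len[rv < threshold]) / total
}

#' Total drawing asymmetry about the origin
#'
#' Horizontal asymmetry is the absolute difference between the distances of
#' the leftmost and rightmost points from the vertical axis through the
#' origin, divided by their sum; vertical asymmetry is defined analogously
#' with the topmost and bottommost points. `TOTSYMM` is their sum. A drawing
#' entirely on one side of an axis contributes that axis's full asymmetry
#' of 1. The measure is invariant to uniform scaling about the origin.
#'
#' @param x,y Sample coordinates (px).
#' @param origin Numeric length-2 reference point.
#' @return `TOTSYMM` in \[0, 2\]; 0 when all points coincide with the origin.
#' @export
total_asymmetry <- function(x, y, origin) {
  axis_asym <- function(lo, hi) {
    d1 <- max(0, -lo)
    d2 <- max(0, hi)
    if (d1 + d2 == 0) return(0)
    abs(d1 - d2) / (d1 + d2)
  }
  dx <- x - origin[1L]
  dy <- y - origin[2L]
  axis_asym(min(dx), max(dx)) + axis_asym(min(dy), max(dy))
}

#' Configuration of the feature extractor
#'
#' Collects every tunable of the feature panel in one place so that a trial
#' plus a configuration fully determines the feature vector.
#'
#' @param origin Origin convention for the kinematic series:
#'   `"first_sample"` or a numeric point.
#' @param apen_m,apen_r_frac Approximate-entropy window length and tolerance
#'   fraction.
#' @param rv_threshold Radial-velocity threshold for [inward_fraction()].
#' @param incdev_windows Window count for [inc_dev()].
#' @param de_seed Seed of the differential-evolution origin search.
#' @param de_control Hyperparameters of the search, see [de_control()].
#' @return List of class `feature_config`.
#' @export
feature_config <- function(origin = "first_sample",
                           apen_m = 2L, apen_r_frac = 0.2,
                           rv_threshold = -0.05,
                           incdev_windows = 30L,
                           de_seed = 17L,
                           de_control = NULL) {
  de_control <- de_control %||% spiralkin_de_defaults()
  structure(list(origin = origin, apen_m = apen_m, apen_r_frac = apen_r_frac,
                 rv_threshold = rv_threshold, incdev_windows = incdev_windows,
                 de_seed = de_seed, de_control = de_control),
            class = "feature_config")
}

#' Extract the full feature vector of one trial
#'
#' Orchestrates the whole panel: moment features of speed, wavelet detail-band
#' features, Approximate Entropy of radial velocity and speed, delta-peak
#' summaries of radius, speed, radial velocity and angular velocity, the
#' variability-drift features of radius and angle, the inward-drawing
#' fraction, total asymmetry, and the four Archimedean-fit error features.
#' Deterministic given the trial and configuration (the origin search is
#' seeded from the configuration).
#'
#' Features whose length preconditions fail (e.g. wavelet features on trials
#' shorter than 21 samples) are returned as `NA`.
#'
#' @param trial A [spiral_trial()] object.
#' @param config A [feature_config()].
#' @return Named numeric vector with the 29 entries of
#'   [spiral_feature_names()].
#' @export
extract_feature_vector <- function(trial, config = feature_config()) {
  k <- compute_kinematics(trial, origin = config$origin)
  out <- stats::setNames(rep(NA_real_, length(spiral_feature_names())),
                         spiral_feature_names())

  mom <- moment_features(k$speed, k$dt)
  out[c("Sp.mean", "Sp.cv", "Sp.skew", "Dt.mean")] <-
    unlist(mom[c("Sp.mean", "Sp.cv", "Sp.skew", "Dt.mean")])

  wav <- wavelet_band_features(k$rv, k$speed)
  out[c("Rv.hf.cv", "Ds.hf.min", "Ds.hf.max")] <-
    unlist(wav[c("Rv.hf.cv", "Ds.hf.min", "Ds.hf.max")])

  if (length(k$rv) >= config$apen_m + 2L) {
    out["Rv.apen"] <- approximate_entropy(k$rv, config$apen_m, config$apen_r_frac)
    out["Ds.apen"] <- approximate_entropy(k$speed, config$apen_m, config$apen_r_frac)
  }

  pk <- peak_features(k$r)
  out[c("R.avgP", "R.stdP", "R.nPeaks")] <- unlist(pk)
  out["R.incDev"] <- inc_dev(k$r, config$incdev_windows)

  pk <- peak_features(k$speed)
  out[c("Ads.avgP", "Ads.stdP", "Ads.nPeaks")] <- unlist(pk)

  pk <- peak_features(k$rv)
  out[c("Rv.avgP", "Rv.stdP", "Rv.nPeaks")] <- unlist(pk)
  out["Rv.pn005"] <- inward_fraction(k$rv, k$seg_len, config$rv_threshold)

  pk <- peak_features(k$av)
  out[c("Av.avgP", "Av.stdP", "Av.nPeaks")] <- unlist(pk)
  out["Angle.incDev"] <- inc_dev(k$phi, config$incdev_windows)

  out["TOTSYMM"] <- total_asymmetry(trial$samples$x, trial$samples$y, k$origin)

  err <- spiral_error_features(trial, seed = config$de_seed,
                               control = config$de_control,
                               origin = config$origin)
  out[c("Err", "Err0", "errBF", "err0BF")] <-
    unlist(err[c("Err", "Err0", "errBF", "err0BF")])

  out
}

#' Extract a feature table from a collection of trials
#'
#' Applies [extract_feature_vector()] to every trial and binds the results
#' into a data frame with identifier columns, suitable for writing to CSV and
#' feeding to [fit_pca()].
#'
#' @param trials List of [spiral_trial()] objects.
#' @param config A [feature_config()].
#' @return Data frame: `subject_id`, `occasion_id`, `trial_index`, `group`,
#'   `label`, `mean_impairment`, then one column per feature.
#' @export
extract_feature_table <- function(trials, config = feature_config()) {
  stopifnot(length(trials) > 0L)
  rows <- lapply(trials, function(tr) {
    fv <- extract_feature_vector(tr, config)
    cbind(
      data.frame(subject_id = tr$subject_id, occasion_id = tr$occasion_id,
                 trial_index = tr$trial_index, group = tr$group,
                 label = tr$label, mean_impairment = tr$mean_impairment,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(fv))
    )
  })
  out <- do.call(rbind, rows)
  # as.list/as.data.frame mangles nothing here, but restore canonical names
  names(out)[-(1:6)] <- spiral_feature_names()
  rownames(out) <- NULL
  out
}
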