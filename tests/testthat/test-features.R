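# Moment, extreme, delta-peak, drift, inward-fraction and asymmetry features.

test_that("moment features match closed forms and an independent skewness sum", {
  m <- moment_features(rep(100, 10), rep(0.1, 10))
  expect_equal(m$Sp.mean, 100)
  expect_equal(m$Sp.cv, 0)
  expect_equal(m$Sp.skew, 0)

  m <- moment_features(c(1, 2, 3), rep(0.1, 3))
  expect_equal(m$Sp.mean, 2)
  expect_equal(m$Dt.mean, 0.1)
  expect_equal(m$Sp.skew, 0)  # symmetric sample

  # brute-force evaluation of the skewness formula on a lognormal sample
  set.seed(31)
  v <- exp(rnorm(99, 0, 0.8))
  m <- moment_features(v, rep(0.1, 99))
  s <- sd(v)
  skew_direct <- sum((v - mean(v))^3) / length(v) / s^3
  expect_equal(m$Sp.skew, skew_direct, tolerance = 1e-12)
  expect_equal(m$Sp.cv, s / mean(v), tolerance = 1e-12)
})

test_that("extreme detection matches hand enumeration and handles plateaus", {
  ex <- find_extremes(c(1, 3, 2, 4, 1))
  expect_equal(ex$values, c(1, 3, 2, 4, 1))
  expect_equal(ex$delta_peaks, c(2, 1, 2, 3))
  expect_equal(ex$indices[1], 1)
  expect_equal(ex$indices[length(ex$indices)], 5)

  mono <- find_extremes(0:9)
  expect_equal(mono$values, c(0, 9))
  expect_equal(mono$delta_peaks, 9)

  flat <- find_extremes(rep(2, 6))
  expect_equal(flat$values, c(2, 2))
  expect_equal(flat$delta_peaks, 0)
  expect_equal(flat$indices, c(1, 6))

  # plateau inside a peak still counts once
  pl <- find_extremes(c(0, 5, 5, 5, 1))
  expect_equal(pl$values, c(0, 5, 1))
})

test_that("delta-peak summaries scale correctly", {
  pf <- peak_features(c(1, 3, 2, 4, 1))
  expect_equal(pf$avgP, 2)
  expect_equal(pf$stdP, sd(c(2, 1, 2, 3)))  # 0.8165 with n-1 denominator
  expect_equal(pf$nPeaks, 1)

  ramp <- peak_features(0:9)
  expect_equal(ramp$avgP, 9)
  expect_equal(ramp$stdP, 0)
  expect_equal(ramp$nPeaks, 0.2)

  # |c|-homogeneity of avgP/stdP; nPeaks scale-free
  set.seed(7)
  for (i in 1:5) {
    v <- rnorm(60)
    c0 <- runif(1, 0.5, 5) * sample(c(-1, 1), 1)
    a <- peak_features(v); b <- peak_features(c0 * v)
    expect_equal(b$avgP, abs(c0) * a$avgP, tolerance = 1e-10)
    expect_equal(b$stdP, abs(c0) * a$stdP, tolerance = 1e-10)
    expect_equal(b$nPeaks, a$nPeaks)
  }
})

test_that("incDev detects growing variability and flips under time reversal", {
  set.seed(11)
  n <- 200
  grow <- (1:n) * rnorm(n)       # variance grows along the series
  expect_gt(inc_dev(grow), 0)
  expect_lt(inc_dev(rev(grow)), 0)

  # sign agrees with a brute-force Spearman on the window sds
  dp <- find_extremes(grow)$delta_peaks
  w <- max(2, length(dp) %/% 3)
  starts <- unique(round(seq(1, length(dp) - w + 1, length.out = 30)))
  sds <- sapply(starts, function(s) sd(dp[s:(s + w - 1)]))
  expect_equal(inc_dev(grow), cor(seq_along(sds), sds, method = "spearman"),
               tolerance = 1e-12)

  # stationary (exchangeable) noise: mean incDev compatible with 0
  set.seed(12)
  reps <- replicate(300, inc_dev(rnorm(120)))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps)), 3 * se + 0.02)

  # monotone series has no delta-peak trend
  expect_identical(inc_dev(1:50), 0)
})

test_that("inward fraction is 0 outward, 100 reversed, ~50 for a half retrace", {
  tr <- ideal_spiral_trial(pitch = 10, omega = 1.9, n = 100)
  k <- compute_kinematics(tr)
  expect_equal(inward_fraction(k$rv, k$seg_len), 0)

  kb <- compute_kinematics(reverse_trial(tr), origin = c(0, 0))
  expect_equal(inward_fraction(kb$rv, kb$seg_len), 100)

  # out along +x then back at the same speed: half the path length is inward
  n <- 101
  xs <- c(seq(0, 50, length.out = (n + 1) / 2),
          seq(50, 0, length.out = (n + 1) / 2)[-1])
  tr2 <- spiral_trial(xs, rep(0, n), (0:(n - 1)) / 10)
  k2 <- suppressWarnings(compute_kinematics(tr2))
  expect_equal(inward_fraction(k2$rv, k2$seg_len), 50, tolerance = 2)
})

test_that("total asymmetry matches hand computation and its invariances", {
  # symmetric about both axes
  expect_equal(total_asymmetry(c(-1, 1, 0, 0), c(0, 0, -2, 2), c(0, 0)), 0)
  # d_left 2, d_right 1, vertical symmetric
  expect_equal(total_asymmetry(c(-2, 1, 0, 0), c(0, 0, -1, 1), c(0, 0)), 1 / 3)
  # scale invariance about the origin
  set.seed(5)
  x <- rnorm(40); y <- rnorm(40)
  a1 <- total_asymmetry(x, y, c(0, 0))
  a2 <- total_asymmetry(3.7 * x, 3.7 * y, c(0, 0))
  expect_equal(a1, a2, tolerance = 1e-12)
  # all mass on one side of an axis contributes 1
  expect_equal(total_asymmetry(c(1, 2), c(-1, 1), c(0, 0)), 1 + 0)
  # degenerate: all points on the origin
  expect_equal(total_asymmetry(c(0, 0), c(0, 0), c(0, 0)), 0)
})

test_that("feature vector is complete, named and deterministic", {
  tr <- simulate_trial(sim_profile("dyskinetic"), seed = 9)
  f1 <- extract_feature_vector(tr)
  f2 <- extract_feature_vector(tr)
  expect_identical(f1, f2)
  expect_named(f1, spiral_feature_names())
  expect_true(all(is.finite(f1)))
  expect_gte(f1[["Rv.pn005"]], 0)
  expect_lte(f1[["Rv.pn005"]], 100)
  expect_gt(f1[["R.nPeaks"]], 0)
  expect_lte(f1[["R.nPeaks"]], 1)
})

test_that("a noiseless template trace is a fixed point of the error features", {
  tr <- constant_speed_spiral_trial(pitch = 10, turns = 3, n = 100)
  f <- extract_feature_vector(tr)
  expect_lt(f[["Err0"]], 1e-6)
  expect_equal(f[["Rv.pn005"]], 0)
  expect_lt(f[["Sp.cv"]], 0.03)   # chord-vs-arc discretisation only
  expect_lt(f[["err0BF"]], 1e-3)
  # a 3-turn spiral has an inherent extent asymmetry of ~2/11 about its
  # centre; anything near that floor indicates no added asymmetry
  expect_lt(f[["TOTSYMM"]], 0.25)
})

test_that("features are invariant under rigid translation of trial and origin", {
  tr <- simulate_trial(sim_profile("bradykinetic"), seed = 21)
  f0 <- extract_feature_vector(tr)
  s <- tr$samples
  tr2 <- spiral_trial(s$x + 777, s$y - 333, s$t,
                      group = tr$group, label = tr$label)
  f1 <- extract_feature_vector(tr2)
  expect_equal(f0, f1, tolerance = 1e-6)
})
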