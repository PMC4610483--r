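# PCA, learning-set assembly, cross-validation, confusion metrics and
# agreement statistics.

test_that("correlation-matrix PCA has the expected spectral structure", {
  set.seed(1)
  # isotropic: six independent features share the variance evenly
  xi <- matrix(rnorm(500 * 6), 500, 6)
  p <- fit_pca(xi, n_components = 6)
  expect_true(all(abs(p$explained - 1 / 6) < 0.05))
  expect_equal(sum(p$explained), 1, tolerance = 1e-12)
  expect_true(all(diff(p$explained) <= 1e-12))

  # rank-2: two signals duplicated four times each
  s1 <- rnorm(300); s2 <- rnorm(300)
  x2 <- cbind(s1, s1 + rnorm(300, sd = 0.01), s1 + rnorm(300, sd = 0.01),
              s1 + rnorm(300, sd = 0.01),
              s2, s2 + rnorm(300, sd = 0.01), s2 + rnorm(300, sd = 0.01),
              s2 + rnorm(300, sd = 0.01))
  p2 <- fit_pca(x2, n_components = 2)
  expect_gt(sum(p2$explained[1:2]), 0.99)

  # loadings orthonormal
  g <- crossprod(p2$loadings_full)
  expect_equal(g, diag(ncol(x2)), tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(fit_pca(xi, n_components = 10), "more components")
})

test_that("PCA reconstruction with all components recovers the z-scores", {
  set.seed(2)
  x <- matrix(rnorm(80 * 5), 80, 5) %*% matrix(runif(25), 5, 5)
  colnames(x) <- paste0("f", 1:5)
  p <- fit_pca(x, n_components = 5)
  z <- scale(x, center = p$means, scale = p$sds)
  recon <- (z %*% p$loadings_full) %*% t(p$loadings_full)
  expect_equal(recon, z, tolerance = 1e-8, ignore_attr = TRUE)
  # deterministic sign convention: dominant loading entry positive
  for (k in 1:5) {
    v <- p$loadings_full[, k]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("learning-set assembly filters, samples raters uniformly, and is seed-stable", {
  cases <- data.frame(case_id = sprintf("C%03d", 1:200),
                      mean_impairment = rep(c(2, 7), 100),
                      PC1 = rnorm(200), PC2 = rnorm(200),
                      PC3 = rnorm(200), PC4 = rnorm(200))
  raters <- paste0("R", 1:4)
  ratings <- do.call(rbind, lapply(raters, function(r) {
    data.frame(case_id = cases$case_id, rater_id = r,
               symptom = rep(c("bradykinesia", "dyskinesia"), 100))
  }))

  ls <- assemble_learning_set(ratings, cases, impairment_threshold = 5,
                              seed = 3)
  expect_equal(nrow(ls), 100)  # half the cases pass the threshold
  expect_true(all(cases$mean_impairment[match(ls$case_id, cases$case_id)] >= 5))

  # all raters agree -> labels independent of the seed
  ls2 <- assemble_learning_set(ratings, cases, impairment_threshold = 5,
                               seed = 99)
  expect_identical(ls$label, ls2$label)

  # threshold 0 retains everything
  ls0 <- assemble_learning_set(ratings, cases, impairment_threshold = 0,
                               seed = 3)
  expect_equal(nrow(ls0), 200)

  # rater selection is uniform across seeds
  counts <- table(unlist(lapply(1:60, function(s) {
    assemble_learning_set(ratings, cases, impairment_threshold = 5,
                          seed = s)$rater_id
  })))
  props <- counts / sum(counts)
  expect_true(all(abs(props - 0.25) < 0.04))

  # tremor/unidentified ratings are ineligible
  ratings_t <- ratings
  ratings_t$symptom[ratings_t$case_id == "C002"] <- "tremor"
  expect_message(
    ls_t <- assemble_learning_set(ratings_t, cases, impairment_threshold = 5,
                                  seed = 3),
    "no eligible")
  expect_false("C002" %in% ls_t$case_id)
})

test_that("confusion metrics reproduce the published worked example", {
  cm <- confusion_matrix_2x2(tp = 28, fn = 8, fp = 9, tn = 64)
  m <- confusion_metrics(cm)
  expect_equal(round(m$accuracy_pct), 84)
  expect_equal(m$sensitivity_pct, 100 * 28 / 37, tolerance = 1e-12)
  expect_equal(round(m$sensitivity_pct, 1), 75.7)
  expect_equal(round(m$specificity_pct, 1), 88.9)
  expect_equal(round(m$weighted_kappa, 2), 0.65)

  perfect <- confusion_metrics(confusion_matrix_2x2(50, 0, 0, 50))
  expect_equal(perfect$accuracy_pct, 100)
  expect_equal(perfect$weighted_kappa, 1)

  # independent formula-by-formula recomputation on random matrices
  set.seed(4)
  for (i in 1:20) {
    v <- rmultinom(1, 200, runif(4, 0.05, 1))
    m2 <- confusion_metrics(confusion_matrix_2x2(v[1], v[2], v[3], v[4]))
    tot <- sum(v)
    po <- (v[1] + v[4]) / tot
    pe <- ((v[1] + v[2]) * (v[1] + v[3]) + (v[3] + v[4]) * (v[2] + v[4])) / tot^2
    expect_equal(m2$accuracy_pct, 100 * po, tolerance = 1e-12)
    expect_equal(m2$weighted_kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
    expect_gte(m2$weighted_kappa, -1)
    expect_lte(m2$weighted_kappa, 1)
  }
})

test_that("well-separated classes are classified near-perfectly by every method", {
  set.seed(10)
  n <- 100
  x <- rbind(matrix(rnorm(n * 4), n, 4),
             matrix(rnorm(n * 4, mean = 6), n, 4))
  ex <- data.frame(PC1 = x[, 1], PC2 = x[, 2], PC3 = x[, 3], PC4 = x[, 4],
                   label = factor(rep(c("bradykinesia", "dyskinesia"),
                                      each = n),
                                  levels = c("bradykinesia", "dyskinesia")))
  for (m in c("MLP", "RF", "SVM_linear", "SVM_rbf", "LR")) {
    ev <- suppressWarnings(
      cross_validated_evaluation(ex, method = m, folds = 10, seed = 5))
    expect_gte(ev$metrics$accuracy_pct, 95)
    expect_gte(ev$auc, 0.99)
  }
})

test_that("permuted labels give chance-level accuracy and near-zero kappa", {
  set.seed(11)
  n <- 250
  ex <- data.frame(PC1 = rnorm(2 * n), PC2 = rnorm(2 * n),
                   PC3 = rnorm(2 * n), PC4 = rnorm(2 * n),
                   label = factor(sample(rep(c("bradykinesia", "dyskinesia"),
                                             n)),
                                  levels = c("bradykinesia", "dyskinesia")))
  ev <- suppressWarnings(
    cross_validated_evaluation(ex, method = "LR", folds = 10, seed = 12))
  expect_lt(abs(ev$metrics$accuracy_pct / 100 - 0.5), 0.1)
  expect_lt(abs(ev$metrics$weighted_kappa), 0.15)
})

test_that("cross-validation is deterministic given the seed", {
  set.seed(14)
  ex <- data.frame(PC1 = rnorm(60), PC2 = rnorm(60),
                   label = factor(rep(c("bradykinesia", "dyskinesia"), 30),
                                  levels = c("bradykinesia", "dyskinesia")))
  ex$PC1 <- ex$PC1 + ifelse(ex$label == "bradykinesia", 1.5, -1.5)
  e1 <- cross_validated_evaluation(ex, method = "RF", folds = 5, seed = 77)
  e2 <- cross_validated_evaluation(ex, method = "RF", folds = 5, seed = 77)
  expect_identical(e1$prob_brady, e2$prob_brady)
  expect_identical(e1$confusion, e2$confusion)

  expect_error(
    cross_validated_evaluation(ex[1:12, ], method = "RF", folds = 10),
    "fewer")
})

test_that("pairwise rater agreement behaves at its anchors", {
  set.seed(15)
  v <- sample(c("bradykinesia", "dyskinesia"), 500, replace = TRUE)
  id <- pairwise_rater_agreement(v, v)
  expect_equal(id$weighted_kappa, 1)
  expect_equal(id$percent_agreement, 100)
  expect_equal(id$fp_rate_pct, 0)
  expect_equal(id$fn_rate_pct, 0)

  w <- sample(c("bradykinesia", "dyskinesia"), 500, replace = TRUE)
  ind <- pairwise_rater_agreement(v, w)
  expect_lt(abs(ind$weighted_kappa), 0.1)

  flipped <- ifelse(v == "bradykinesia", "dyskinesia", "bradykinesia")
  expect_lt(pairwise_rater_agreement(v, flipped)$weighted_kappa, 0)
})

test_that("the agreement table covers every rater pair", {
  set.seed(16)
  ratings <- expand.grid(case_id = sprintf("C%02d", 1:40),
                         rater_id = paste0("R", 1:4),
                         stringsAsFactors = FALSE)
  ratings$symptom <- sample(c("bradykinesia", "dyskinesia"),
                            nrow(ratings), replace = TRUE)
  tab <- rater_agreement_table(ratings)
  expect_equal(nrow(tab), 6)  # choose(4, 2)
  expect_true(all(tab$n == 40))

  one <- ratings[ratings$rater_id == "R1", ]
  expect_error(rater_agreement_table(one), "2 raters")
})

test_that("mean pairwise correlation matches the attenuation closed form", {
  # identical vectors
  v <- rnorm(50)
  expect_equal(mean_pairwise_icc(cbind(v, v, v, v)), 1)

  # two vectors: plain Pearson correlation
  set.seed(17)
  a <- rnorm(100); b <- a + rnorm(100)
  expect_equal(mean_pairwise_icc(cbind(a, b)), cor(a, b))

  # v, v+noise, v+noise with noise sd = signal sd: corr(v+e1, v+e2) ~ 0.5
  set.seed(18)
  reps <- replicate(40, {
    s <- rnorm(200)
    m <- cbind(s, s + rnorm(200), s + rnorm(200))
    mean_pairwise_icc(m)
  })
  expect_lt(abs(mean(reps) - (2 / 3 * sqrt(0.5) + 1 / 3 * 0.5)), 0.05)

  expect_warning(mean_pairwise_icc(cbind(a, b, rep(1, 100))), "zero-variance")
})

test_that("component-rating correlations hit their anchors", {
  set.seed(19)
  pcs <- matrix(rnorm(300 * 4), 300, 4,
                dimnames = list(NULL, paste0("PC", 1:4)))
  # a monotone transform of PC1 correlates perfectly in rank
  ratings <- cbind(impairment = exp(pcs[, 1]),
                   speed = rnorm(300), irregularity = rnorm(300),
                   hesitation = rnorm(300))
  m <- pc_rating_correlations(pcs, ratings)
  expect_equal(dim(m), c(4, 4))
  expect_equal(m["impairment", "PC1"], 1, tolerance = 1e-12)
  expect_true(all(m >= 0 & m <= 1))
  # independent columns stay near zero
  expect_true(all(m[2:4, ] < 0.15))
})
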