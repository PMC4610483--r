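# Dimension reduction, classification and agreement statistics.
# PCA uses the correlation-matrix method (features are z-scored before the
# eigendecomposition) so that px-scaled and unitless features contribute
# comparably; classifiers consume the first few component scores.

#' Correlation-matrix principal component analysis
#'
#' Standardises each feature to zero mean and unit variance and performs PCA,
#' i.e. an eigendecomposition of the feature correlation matrix. Features
#' with zero variance are dropped with a warning. Component signs follow a
#' deterministic convention: within each loading vector, the entry of
#' largest magnitude is made positive.
#'
#' @param x Numeric matrix or data frame (rows = trials, columns = features).
#'   Rows with missing values are dropped with a warning.
#' @param n_components Number of components to retain (default 4).
#' @return Object of class `spiral_pca`: `means`, `sds`, `loadings`
#'   (features x `n_components`), `loadings_full`, `explained` (variance
#'   fractions of all components), `n_components`, `feature_names`, `n_used`.
#' @export
fit_pca <- function(x, n_components = 4L) {
  x <- as.matrix(x)
  complete <- stats::complete.cases(x)
  if (!all(complete)) {
    warning(sprintf("dropping %d row(s) with missing features from PCA",
                    sum(!complete)))
    x <- x[complete, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("PCA needs at least 2 complete rows", call. = FALSE)
  sds <- apply(x, 2L, stats::sd)
  zero <- sds == 0
  if (any(zero)) {
    warning(sprintf("dropping zero-variance feature(s): %s",
                    paste(colnames(x)[zero], collapse = ", ")))
    x <- x[, !zero, drop = FALSE]
  }
  if (n_components > ncol(x)) {
    stop("more components requested than (non-degenerate) features",
         call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  flip <- apply(rot, 2L, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2L, flip, "*")
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(means = pc$center, sds = pc$scale,
         loadings = rot[, seq_len(n_components), drop = FALSE],
         loadings_full = rot,
         explained = explained,
         n_components = n_components,
         feature_names = colnames(x),
         n_used = nrow(x)),
    class = "spiral_pca"
  )
}

#' Project feature rows onto fitted principal components
#'
#' @param object A `spiral_pca` from [fit_pca()].
#' @param newdata Matrix or data frame containing at least the features the
#'   model was fitted on.
#' @param ... Unused.
#' @return Matrix of component scores (rows x `n_components`), columns
#'   `PC1..PCk`. Rows with missing features yield `NA` scores.
#' @export
predict.spiral_pca <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$feature_names, drop = FALSE])
  z <- sweep(sweep(x, 2L, object$means, "-"), 2L, object$sds, "/")
  scores <- z %*% object$loadings
  colnames(scores) <- paste0("PC", seq_len(object$n_components))
  scores
}

#' @export
print.spiral_pca <- function(x, ...) {
  cat(sprintf("<spiral_pca> %d features, %d rows; first %d components explain %.1f%% of variance\n",
              length(x$feature_names), x$n_used, x$n_components,
              100 * sum(x$explained[seq_len(x$n_components)])))
  invisible(x)
}

#' Assemble classifier examples from ratings and component scores
#'
#' Builds one learning example per rated case: the case's component scores
#' paired with one rater's symptom label. Cases with a mean impairment below
#' `impairment_threshold` are excluded (mild tracings carry too little
#' symptom-specific signal); ratings whose symptom is not bradykinesia or
#' dyskinesia are ineligible; among the eligible ratings of a case one is
#' drawn uniformly at random, so each rater is represented equally in
#' expectation.
#'
#' @param ratings Data frame with columns `case_id`, `rater_id`, `symptom`
#'   (values `bradykinesia`, `dyskinesia`, `tremor`, `unidentified`) and
#'   optionally the ordinal columns `impairment`, `speed`, `irregularity`,
#'   `hesitation`.
#' @param case_scores Data frame with `case_id`, `mean_impairment` and the
#'   component-score columns `PC1..PCk` (typically per-case means of
#'   per-trial scores, see [case_score_table()]).
#' @param impairment_threshold Minimum mean impairment for inclusion
#'   (default 5 on the 0-10 scale).
#' @param seed Seed of the rating draw.
#' @return Data frame with `case_id`, `rater_id`, the PC columns and a
#'   factor `label` with levels `bradykinesia`, `dyskinesia`. Cases with no
#'   eligible rating are dropped (count reported via message).
#' @export
assemble_learning_set <- function(ratings, case_scores,
                                  impairment_threshold = 5, seed = 1L) {
  stopifnot(all(c("case_id", "rater_id", "symptom") %in% names(ratings)))
  pc_cols <- grep("^PC[0-9]+$", names(case_scores), value = TRUE)
  stopifnot(length(pc_cols) > 0L)
  keep <- case_scores[
    !is.na(case_scores$mean_impairment) &
      case_scores$mean_impairment >= impairment_threshold, , drop = FALSE]
  eligible <- ratings[ratings$symptom %in% c("bradykinesia", "dyskinesia"), ,
                      drop = FALSE]
  dropped <- 0L
  rows <- with_seed(seed, {
    lapply(seq_len(nrow(keep)), function(i) {
      cid <- keep$case_id[i]
      cand <- eligible[eligible$case_id == cid, , drop = FALSE]
      if (nrow(cand) == 0L) { dropped <<- dropped + 1L; return(NULL) }
      pick <- cand[sample.int(nrow(cand), 1L), ]
      cbind(data.frame(case_id = cid, rater_id = pick$rater_id,
                       stringsAsFactors = FALSE),
            keep[i, pc_cols, drop = FALSE],
            data.frame(label = pick$symptom, stringsAsFactors = FALSE))
    })
  })
  if (dropped > 0L) {
    message(sprintf("%d case(s) had no eligible (bradykinesia/dyskinesia) rating and were dropped",
                    dropped))
  }
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    stop("no cases left after impairment/eligibility filtering", call. = FALSE)
  }
  out$label <- factor(out$label, levels = c("bradykinesia", "dyskinesia"))
  rownames(out) <- NULL
  out
}

#' Per-case component scores from a per-trial feature table
#'
#' The protocol records three tracings per test occasion (case); features are
#' extracted per trial but symptoms are rated per case. The case score is the
#' mean of the case's per-trial component scores.
#'
#' @param feature_table Output of [extract_feature_table()].
#' @param pca A fitted `spiral_pca`.
#' @param case_col Column identifying the case (default `"occasion_id"`).
#' @return Data frame with `case_id`, `mean_impairment`, `label` (truth label
#'   when present, else `NA`) and `PC1..PCk` columns.
#' @export
case_score_table <- function(feature_table, pca, case_col = "occasion_id") {
  scores <- stats::predict(pca, feature_table)
  agg <- stats::aggregate(scores, by = list(case_id = feature_table[[case_col]]),
                          FUN = mean)
  meta <- unique(feature_table[, c(case_col, "mean_impairment", "label")])
  names(meta)[1L] <- "case_id"
  merge(meta, agg, by = "case_id")
}

# ---- classification -------------------------------------------------------

fit_symptom_classifier <- function(method, data) {
  p <- ncol(data) - 1L
  switch(method,
    MLP = nnet::nnet(label ~ ., data = data,
                     size = ceiling((p + 2L) / 2L), maxit = 500L,
                     decay = 0, trace = FALSE),
    RF = randomForest::randomForest(label ~ ., data = data, ntree = 100L),
    SVM_linear = e1071::svm(label ~ ., data = data, kernel = "linear",
                            cost = 1, probability = TRUE),
    SVM_rbf = e1071::svm(label ~ ., data = data, kernel = "radial",
                         cost = 1, gamma = 1 / p, probability = TRUE),
    LR = stats::glm(label ~ ., data = data, family = stats::binomial()),
    stop(sprintf("unknown method '%s'", method), call. = FALSE)
  )
}

# Probability of the positive class (bradykinesia, the first factor level).
predict_prob_brady <- function(method, fit, newdata) {
  switch(method,
    MLP = 1 - as.numeric(stats::predict(fit, newdata, type = "raw")),
    RF = as.numeric(stats::predict(fit, newdata, type = "prob")[, "bradykinesia"]),
    SVM_linear = ,
    SVM_rbf = {
      pr <- stats::predict(fit, newdata, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "bradykinesia"])
    },
    LR = 1 - as.numeric(stats::predict(fit, newdata, type = "response"))
  )
}

#' Stratified cross-validated classifier evaluation
#'
#' Assigns examples to `folds` stratified folds (each class spread as evenly
#' as possible), trains the chosen classifier on each training split with
#' fixed documented hyperparameters, pools the out-of-fold predictions, and
#' summarises them as a 2x2 confusion matrix (bradykinesia positive),
#' accuracy, sensitivity, specificity, weighted kappa and AUC (from the
#' pooled out-of-fold probability rankings, midrank ties).
#'
#' Hyperparameters: MLP = single hidden layer of `ceiling((p + 2) / 2)`
#' units, 500 epochs; RF = 100 trees; SVMs cost 1 (RBF gamma `1/p`);
#' LR = unpenalised logistic regression.
#'
#' @param examples Data frame from [assemble_learning_set()] (or any frame
#'   with numeric `PC*` columns and a binary factor `label` with levels
#'   `bradykinesia`, `dyskinesia`).
#' @param method One of `"MLP"`, `"RF"`, `"SVM_linear"`, `"SVM_rbf"`, `"LR"`.
#' @param folds Number of folds (default 10).
#' @param seed Seed for fold assignment and classifier initialisation.
#' @return Object of class `spiral_eval`: `method`, `folds`, `confusion`
#'   (see [confusion_matrix_2x2()]), `metrics` (see [confusion_metrics()]),
#'   `auc`, `prob_brady`, `predicted`, `truth`, `n`.
#' @export
cross_validated_evaluation <- function(examples,
                                       method = c("MLP", "RF", "SVM_linear",
                                                  "SVM_rbf", "LR"),
                                       folds = 10L, seed = 1L) {
  method <- match.arg(method)
  stopifnot(is.factor(examples$label))
  examples$label <- droplevels(examples$label)
  stopifnot(identical(levels(examples$label),
                      c("bradykinesia", "dyskinesia")))
  if (min(table(examples$label)) < folds) {
    stop(sprintf("smallest class has fewer members than folds = %d; use fewer folds",
                 folds), call. = FALSE)
  }
  pc_cols <- grep("^PC[0-9]+$", names(examples), value = TRUE)
  dat <- examples[, c(pc_cols, "label")]
  n <- nrow(dat)

  with_seed(seed, {
    fold_id <- integer(n)
    for (cl in levels(dat$label)) {
      idx <- sample(which(dat$label == cl))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
    prob <- rep(NA_real_, n)
    for (k in seq_len(folds)) {
      test <- fold_id == k
      fit <- fit_symptom_classifier(method, dat[!test, , drop = FALSE])
      prob[test] <- predict_prob_brady(method, fit, dat[test, , drop = FALSE])
    }
    predicted <- factor(ifelse(prob >= 0.5, "bradykinesia", "dyskinesia"),
                        levels = levels(dat$label))
    cm <- confusion_matrix_2x2(truth = dat$label, predicted = predicted)
    auc <- as.numeric(pROC::auc(
      response = dat$label, predictor = prob,
      levels = c("dyskinesia", "bradykinesia"), direction = "<",
      quiet = TRUE))
    structure(
      list(method = method, folds = folds, confusion = cm,
           metrics = confusion_metrics(cm), auc = auc,
           prob_brady = prob, predicted = predicted, truth = dat$label,
           n = n),
      class = "spiral_eval"
    )
  })
}

#' @export
print.spiral_eval <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<spiral_eval> %s, %d-fold CV, n = %d\n", x$method, x$folds, x$n))
  cat(sprintf("  accuracy %.1f%%  sensitivity %.1f%%  specificity %.1f%%  kappa %.2f  AUC %.2f\n",
              m$accuracy_pct, m$sensitivity_pct, m$specificity_pct,
              m$weighted_kappa, x$auc))
  invisible(x)
}

# ---- confusion-matrix statistics ------------------------------------------

#' 2x2 confusion matrix with bradykinesia as the positive class
#'
#' Either pass the four counts directly, or factor vectors `truth` and
#' `predicted` (levels `bradykinesia`, `dyskinesia`). `tp` counts cases
#' called bradykinesia by both, `tn` cases called dyskinesia by both, `fn`
#' truth-bradykinesia called dyskinesia, `fp` truth-dyskinesia called
#' bradykinesia.
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @param truth,predicted Optional factor vectors from which to tabulate.
#' @return Object of class `confusion_2x2` (named list of the four counts).
#' @export
confusion_matrix_2x2 <- function(tp = NULL, fn = NULL, fp = NULL, tn = NULL,
                                 truth = NULL, predicted = NULL) {
  if (!is.null(truth)) {
    pos <- "bradykinesia"
    tp <- sum(truth == pos & predicted == pos)
    fn <- sum(truth == pos & predicted != pos)
    fp <- sum(truth != pos & predicted == pos)
    tn <- sum(truth != pos & predicted != pos)
  }
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(counts), class = "confusion_2x2")
}

#' Summary metrics of a 2x2 confusion matrix
#'
#' Accuracy is the fraction of agreeing cases. Sensitivity and specificity
#' follow the predicted-margin convention used in the reference evaluation
#' tables: sensitivity = `tp` over all cases the classifier called
#' bradykinesia (`tp + fp`), specificity = `tn` over all cases called
#' dyskinesia (`tn + fn`). The conventional truth-margin variants are also
#' returned, explicitly labelled. The weighted kappa is the chance-corrected
#' agreement computed from the margins; with two categories linear weighting
#' coincides with unweighted Cohen's kappa.
#'
#' @param cm A [confusion_matrix_2x2()].
#' @return Named list: `accuracy_pct`, `sensitivity_pct`, `specificity_pct`,
#'   `sensitivity_truth_pct`, `specificity_truth_pct`, `weighted_kappa`
#'   (`NA` when a margin is degenerate), and the four counts.
#' @examples
#' cm <- confusion_matrix_2x2(tp = 28, fn = 8, fp = 9, tn = 64)
#' confusion_metrics(cm)$accuracy_pct  # 84.4
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_2x2"))
  tp <- cm$tp; fn <- cm$fn; fp <- cm$fp; tn <- cm$tn
  tot <- tp + fn + fp + tn
  if (tot == 0) stop("empty confusion matrix", call. = FALSE)
  po <- (tp + tn) / tot
  row_b <- tp + fn; row_d <- fp + tn   # truth margins
  col_b <- tp + fp; col_d <- fn + tn   # predicted margins
  pe <- (row_b * col_b + row_d * col_d) / tot^2
  kappa <- if (pe == 1) NA_real_ else (po - pe) / (1 - pe)
  list(
    accuracy_pct = 100 * po,
    sensitivity_pct = if (col_b == 0) NA_real_ else 100 * tp / col_b,
    specificity_pct = if (col_d == 0) NA_real_ else 100 * tn / col_d,
    sensitivity_truth_pct = if (row_b == 0) NA_real_ else 100 * tp / row_b,
    specificity_truth_pct = if (row_d == 0) NA_real_ else 100 * tn / row_d,
    weighted_kappa = kappa,
    tp = tp, fn = fn, fp = fp, tn = tn
  )
}

# ---- rater agreement ------------------------------------------------------

#' Agreement between two raters on binary symptom labels
#'
#' Over the cases both raters labelled, computes the weighted kappa, percent
#' agreement, and — treating the first rater as reference with bradykinesia
#' positive — the false positive rate (fraction of reference-dyskinesia cases
#' the second rater called bradykinesia) and false negative rate (fraction of
#' reference-bradykinesia cases the second rater called dyskinesia).
#'
#' @param labels1,labels2 Character or factor vectors of labels
#'   (`bradykinesia` / `dyskinesia`) over the same cases.
#' @return Named list `weighted_kappa`, `percent_agreement`, `fp_rate_pct`,
#'   `fn_rate_pct`, `n`.
#' @export
pairwise_rater_agreement <- function(labels1, labels2) {
  ok <- !is.na(labels1) & !is.na(labels2)
  l1 <- as.character(labels1)[ok]
  l2 <- as.character(labels2)[ok]
  if (length(l1) < 2L) stop("need at least 2 shared cases", call. = FALSE)
  pos <- "bradykinesia"
  cm <- confusion_matrix_2x2(
    tp = sum(l1 == pos & l2 == pos),
    fn = sum(l1 == pos & l2 != pos),
    fp = sum(l1 != pos & l2 == pos),
    tn = sum(l1 != pos & l2 != pos)
  )
  m <- confusion_metrics(cm)
  list(
    weighted_kappa = m$weighted_kappa,
    percent_agreement = m$accuracy_pct,
    fp_rate_pct = if (cm$fp + cm$tn == 0) NA_real_
                  else 100 * cm$fp / (cm$fp + cm$tn),
    fn_rate_pct = if (cm$tp + cm$fn == 0) NA_real_
                  else 100 * cm$fn / (cm$tp + cm$fn),
    n = length(l1)
  )
}

#' Pairwise agreement table over all raters
#'
#' @param ratings Data frame with `case_id`, `rater_id`, `symptom`; only
#'   bradykinesia/dyskinesia ratings enter.
#' @return Data frame with one row per rater pair and the metrics of
#'   [pairwise_rater_agreement()].
#' @export
rater_agreement_table <- function(ratings) {
  ratings <- ratings[ratings$symptom %in% c("bradykinesia", "dyskinesia"), ]
  raters <- sort(unique(ratings$rater_id))
  if (length(raters) < 2L) {
    stop("agreement requires at least 2 raters", call. = FALSE)
  }
  wide <- stats::reshape(ratings[, c("case_id", "rater_id", "symptom")],
                         idvar = "case_id", timevar = "rater_id",
                         direction = "wide")
  pairs <- utils::combn(raters, 2L, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    a <- wide[[paste0("symptom.", p[1L])]]
    b <- wide[[paste0("symptom.", p[2L])]]
    m <- pairwise_rater_agreement(a, b)
    data.frame(rater_a = p[1L], rater_b = p[2L],
               weighted_kappa = m$weighted_kappa,
               percent_agreement = m$percent_agreement,
               fp_rate_pct = m$fp_rate_pct, fn_rate_pct = m$fn_rate_pct,
               n = m$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean pairwise correlation (ICC surrogate)
#'
#' The agreement of k parallel score vectors (k raters, or k repeated trials)
#' summarised as the mean of all `k * (k - 1) / 2` pairwise Pearson
#' correlations. Pairs involving a zero-variance vector are excluded with a
#' warning.
#'
#' @param scores Numeric matrix or data frame, one column per rater/trial,
#'   `ncol >= 2`, `nrow >= 3`.
#' @return Mean pairwise correlation.
#' @export
mean_pairwise_icc <- function(scores) {
  m <- as.matrix(scores)
  if (ncol(m) < 2L || nrow(m) < 3L) {
    stop("need at least 2 vectors of length >= 3", call. = FALSE)
  }
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding zero-variance vector(s) from pairwise correlations")
    m <- m[, sds > 0, drop = FALSE]
    if (ncol(m) < 2L) stop("fewer than 2 non-degenerate vectors", call. = FALSE)
  }
  cm <- stats::cor(m)
  mean(cm[upper.tri(cm)])
}

#' Absolute Spearman correlations between components and mean ratings
#'
#' @param pc_scores Numeric matrix/data frame of per-case component scores.
#' @param mean_ratings Numeric matrix/data frame of per-case mean visual
#'   ratings (same row order), e.g. columns impairment, speed, irregularity,
#'   hesitation.
#' @return Matrix `ncol(mean_ratings)` x `ncol(pc_scores)` of absolute
#'   Spearman rank correlations; entries for constant columns are `NA`.
#' @export
pc_rating_correlations <- function(pc_scores, mean_ratings) {
  p <- as.matrix(pc_scores)
  r <- as.matrix(mean_ratings)
  if (nrow(p) < 5L || nrow(p) != nrow(r)) {
    stop("need >= 5 cases with both scores and ratings", call. = FALSE)
  }
  out <- matrix(NA_real_, ncol(r), ncol(p),
                dimnames = list(colnames(r), colnames(p)))
  for (i in seq_len(ncol(r))) {
    if (stats::sd(r[, i]) == 0) next
    for (j in seq_len(ncol(p))) {
      out[i, j] <- abs(stats::cor(r[, i], p[, j], method = "spearman"))
    }
  }
  out
}
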