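# Spectral feature extraction, gradient-boosted 4-class classification and
# patient-grouped k-fold evaluation.

# Class coding follows the ROC-curve convention: 0 normal, 1 MF, 2 PsO, 3 AD.
CLASS_LEVELS <- c("normal", "MF", "PsO", "AD")

FEATURE_STATS <- c("mean", "sd", "p10", "p50", "p90")

#' Extract spectral features from a lesion region
#'
#' Projects each masked pixel's spectrum (minus the basis mean) onto the
#' PCA components, then aggregates the per-pixel scores over the region
#' with the mean, standard deviation and the 10th/50th/90th percentiles,
#' giving `n_components * 5` features (60 with the default 12-component
#' basis). Deterministic.
#'
#' @param cube H x W x 401 array from [image_to_cube()].
#' @param mask `lesion_mask` selecting the region (must be non-empty).
#' @param basis The `spectral_basis` whose components define the scores.
#' @return Named numeric feature vector (`pc01_mean`, `pc01_sd`, ...).
#' @export
extract_features <- function(cube, mask, basis) {
  stopifnot(inherits(mask, "lesion_mask"), inherits(basis, "spectral_basis"))
  if (!all(dim(cube)[1:2] == dim(mask$grid))) {
    stop("cube and mask dimensions differ", call. = FALSE)
  }
  sel <- which(mask$grid == 1)
  if (length(sel) == 0) stop("empty region: mask selects no pixels", call. = FALSE)
  spec <- matrix(cube, nrow = prod(dim(cube)[1:2]))[sel, , drop = FALSE]  # m x 401
  if (anyNA(spec)) stop("masked region contains excluded (NA) pixels", call. = FALSE)
  scores <- sweep(spec, 2, basis$mean_spectrum) %*% basis$EV              # m x k
  k <- ncol(scores)
  out <- numeric(k * length(FEATURE_STATS))
  nms <- character(length(out))
  for (j in seq_len(k)) {
    s <- scores[, j]
    sdev <- stats::sd(s)
    if (is.na(sdev)) sdev <- 0      # single-pixel region
    q <- stats::quantile(s, c(0.1, 0.5, 0.9), names = FALSE)
    idx <- (j - 1) * 5 + 1:5
    out[idx] <- c(mean(s), sdev, q)
    nms[idx] <- sprintf("pc%02d_%s", j, FEATURE_STATS)
  }
  names(out) <- nms
  out
}

#' Partition patients into k folds
#'
#' Fold assignment is at the patient level so that no subject contributes
#' images to both the training and the test side of any fold (the data
#' leakage guard that motivates grouped cross-validation on small clinical
#' cohorts). Patient counts per fold differ by at most one; the shuffle is
#' deterministic for a fixed seed.
#'
#' @param patient_ids Character/factor vector of per-sample patient ids
#'   (duplicates expected; folds are built on the distinct ids).
#' @param k Number of folds (>= 2, <= number of distinct patients).
#' @param seed Integer seed for the patient shuffle.
#' @return List with `patient_fold` (named integer vector over distinct
#'   patients) and `sample_fold` (integer vector aligned with
#'   `patient_ids`).
#' @export
make_group_folds <- function(patient_ids, k, seed = 0) {
  patients <- unique(as.character(patient_ids))
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > length(patients)) {
    stop("k = ", k, " exceeds the number of distinct patients (", length(patients), ")",
         call. = FALSE)
  }
  shuffled <- with_seed(seed, sample(patients))
  patient_fold <- stats::setNames(rep_len(seq_len(k), length(patients)), shuffled)
  patient_fold <- patient_fold[patients]   # stable name order
  list(patient_fold = patient_fold,
       sample_fold = unname(patient_fold[as.character(patient_ids)]))
}

#' Gradient-boosting hyperparameters
#'
#' The classifier is a gradient-boosted decision-tree ensemble. Defaults
#' are moderate-capacity choices for a few hundred 60-dimensional samples:
#' shallow trees, shrinkage 0.1, a few hundred rounds, mild row/column
#' subsampling.
#'
#' @param nrounds Boosting rounds.
#' @param max_depth Tree depth.
#' @param eta Learning rate.
#' @param subsample,colsample_bytree Stochastic-boosting fractions.
#' @param ... Further parameters passed through to the booster (e.g.
#'   `lambda`, `min_child_weight`).
#' @return Parameter list for [train_classifier()].
#' @export
boost_params <- function(nrounds = 200, max_depth = 4, eta = 0.1,
                         subsample = 0.9, colsample_bytree = 0.9, ...) {
  c(list(nrounds = nrounds, max_depth = max_depth, eta = eta,
         subsample = subsample, colsample_bytree = colsample_bytree),
    list(...))
}

#' Train the 4-class lesion classifier
#'
#' @param features n x p numeric feature matrix.
#' @param labels Vector of class labels among `normal, MF, PsO, AD` (at
#'   least two classes must be present).
#' @param params Hyperparameters from [boost_params()].
#' @param seed Integer seed (fixed seed gives a reproducible model).
#' @return A `lesion_classifier` emitting class probabilities over the four
#'   classes.
#' @export
train_classifier <- function(features, labels, params = boost_params(), seed = 0) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (!all(labels %in% CLASS_LEVELS)) {
    stop("labels must be among: ", paste(CLASS_LEVELS, collapse = ", "), call. = FALSE)
  }
  if (length(unique(labels)) < 2) {
    stop("training set contains a single class", call. = FALSE)
  }
  y <- match(labels, CLASS_LEVELS) - 1L
  xgb_params <- c(list(objective = "multi:softprob",
                       num_class = length(CLASS_LEVELS),
                       nthread = 1, seed = seed),
                  params[setdiff(names(params), "nrounds")])
  booster <- with_seed(seed, xgboost::xgb.train(
    params = xgb_params,
    data = xgboost::xgb.DMatrix(features, label = y),
    nrounds = params$nrounds, verbose = 0))
  structure(list(booster = booster, classes = CLASS_LEVELS, n_features = ncol(features)),
            class = "lesion_classifier")
}

#' Predict class probabilities
#' @param object A `lesion_classifier`.
#' @param newdata n x p feature matrix.
#' @param ... Unused.
#' @return n x 4 probability matrix, columns `normal, MF, PsO, AD`.
#' @export
predict.lesion_classifier <- function(object, newdata, ...) {
  p <- predict(object$booster, xgboost::xgb.DMatrix(as.matrix(newdata)))
  if (!is.matrix(p)) p <- matrix(p, ncol = length(object$classes), byrow = TRUE)
  colnames(p) <- object$classes
  p
}

#' Per-class and macro metrics from a confusion matrix
#'
#' Rows index the true class, columns the predicted class. Sensitivity is
#' TP / (TP + FN), specificity TN / (TN + FP), F1 the harmonic mean of
#' precision and sensitivity; macro values average the per-class one-vs-rest
#' metrics. Classes absent from the data (empty row and column) are
#' excluded from the macro averages.
#'
#' @param confusion Square integer matrix of counts.
#' @return List with `per_class` (data.frame) and macro `sensitivity`,
#'   `specificity`, `f1`.
#' @export
metrics_from_confusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion))
  n <- sum(confusion)
  cls <- rownames(confusion)
  if (is.null(cls)) cls <- as.character(seq_len(nrow(confusion)))
  per <- data.frame(class = cls, sensitivity = NA_real_, specificity = NA_real_,
                    precision = NA_real_, f1 = NA_real_)
  present <- logical(nrow(confusion))
  for (i in seq_len(nrow(confusion))) {
    tp <- confusion[i, i]
    fn <- sum(confusion[i, ]) - tp
    fp <- sum(confusion[, i]) - tp
    tn <- n - tp - fn - fp
    present[i] <- (tp + fn) > 0 || fp > 0
    per$sensitivity[i] <- if (tp + fn > 0) tp / (tp + fn) else NA
    per$specificity[i] <- if (tn + fp > 0) tn / (tn + fp) else NA
    per$precision[i]   <- if (tp + fp > 0) tp / (tp + fp) else NA
    per$f1[i] <- if (!is.na(per$precision[i]) && !is.na(per$sensitivity[i]) &&
                     per$precision[i] + per$sensitivity[i] > 0) {
      2 * per$precision[i] * per$sensitivity[i] / (per$precision[i] + per$sensitivity[i])
    } else if ((tp + fn) > 0) 0 else NA
    }
  keep <- present & !is.na(per$sensitivity)
  list(per_class = per,
       sensitivity = mean(per$sensitivity[keep]),
       specificity = mean(per$specificity[keep]),
       f1 = mean(per$f1[keep]))
}

# One-vs-rest ROC-AUC for one class (trapezoid convention via pROC).
ovr_auc <- function(truth_binary, scores) {
  if (length(unique(truth_binary)) < 2) return(NA_real_)
  as.numeric(pROC::auc(pROC::roc(response = truth_binary, predictor = scores,
                                 levels = c(0, 1), direction = "<", quiet = TRUE)))
}

# Macro one-vs-rest AUC over the fixed class set; absent classes excluded.
macro_auc <- function(labels, prob) {
  aucs <- vapply(CLASS_LEVELS, function(cl) {
    ovr_auc(as.integer(labels == cl), prob[, cl])
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Patient-grouped k-fold cross-validation
#'
#' Trains on k-1 patient folds and predicts the held-out fold, for each
#' fold in turn. Metrics are reported two ways: pooled (all out-of-fold
#' predictions collected, then one confusion matrix / macro metric set) and
#' mean-of-folds (per-fold metrics averaged). The patient-disjointness of
#' every train/test split is asserted on every run.
#'
#' @param samples Data frame with columns `patient_id`, `label`, and the
#'   feature columns (everything except `image_id`, `patient_id`, `label`
#'   is treated as a feature).
#' @param k Number of folds.
#' @param seed Integer seed driving the fold shuffle and the boosters.
#' @param params Hyperparameters from [boost_params()].
#' @return A `cv_report`: `k`, `fold_assignment`, `confusion` (pooled 4 x 4,
#'   rows = truth), `aggregate` (pooled macro sensitivity/specificity/f1/
#'   roc_auc), `mean_of_folds`, `per_fold`, and the pooled out-of-fold
#'   `predictions` data frame.
#' @export
run_cross_validation <- function(samples, k, seed = 0, params = boost_params()) {
  stopifnot(is.data.frame(samples), all(c("patient_id", "label") %in% names(samples)))
  feat_cols <- setdiff(names(samples), c("image_id", "patient_id", "label"))
  if (length(feat_cols) == 0) stop("no feature columns found", call. = FALSE)
  X <- as.matrix(samples[feat_cols])
  labels <- as.character(samples$label)
  folds <- make_group_folds(samples$patient_id, k, seed = seed)

  pred_prob <- matrix(NA_real_, nrow(samples), length(CLASS_LEVELS),
                      dimnames = list(NULL, CLASS_LEVELS))
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test <- folds$sample_fold == f
    train_pat <- unique(samples$patient_id[!test])
    test_pat <- unique(samples$patient_id[test])
    stopifnot(length(intersect(train_pat, test_pat)) == 0)  # leakage guard
    missing <- setdiff(CLASS_LEVELS, unique(labels[test]))
    if (length(missing) > 0) {
      warning("fold ", f, " has no samples of: ", paste(missing, collapse = ", "),
              "; their fold-level AUC is undefined and excluded", call. = FALSE)
    }
    clf <- train_classifier(X[!test, , drop = FALSE], labels[!test],
                            params = params, seed = seed + f)
    p <- predict(clf, X[test, , drop = FALSE])
    pred_prob[test, ] <- p
    pred_lab <- CLASS_LEVELS[max.col(p, ties.method = "first")]
    conf_f <- table(factor(labels[test], CLASS_LEVELS),
                    factor(pred_lab, CLASS_LEVELS))
    m <- metrics_from_confusion(conf_f)
    per_fold[[f]] <- list(fold = f, confusion = unclass(conf_f),
                          sensitivity = m$sensitivity, specificity = m$specificity,
                          f1 = m$f1, roc_auc = macro_auc(labels[test], p))
  }

  pred_lab <- CLASS_LEVELS[max.col(pred_prob, ties.method = "first")]
  confusion <- table(truth = factor(labels, CLASS_LEVELS),
                     predicted = factor(pred_lab, CLASS_LEVELS))
  pooled <- metrics_from_confusion(confusion)
  pooled$roc_auc <- macro_auc(labels, pred_prob)
  fold_stat <- function(name) mean(vapply(per_fold, `[[`, numeric(1), name), na.rm = TRUE)

  structure(list(
    k = k,
    fold_assignment = folds$patient_fold,
    confusion = unclass(confusion),
    aggregate = list(sensitivity = pooled$sensitivity,
                     specificity = pooled$specificity,
                     f1 = pooled$f1, roc_auc = pooled$roc_auc),
    per_class = pooled$per_class,
    mean_of_folds = list(sensitivity = fold_stat("sensitivity"),
                         specificity = fold_stat("specificity"),
                         f1 = fold_stat("f1"), roc_auc = fold_stat("roc_auc")),
    per_fold = per_fold,
    predictions = data.frame(samples[intersect(c("image_id", "patient_id"), names(samples))],
                             label = labels, predicted = pred_lab, pred_prob,
                             fold = folds$sample_fold)),
    class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<cv_report: k = %d, pooled sensitivity %.4f, specificity %.4f, F1 %.4f, ROC-AUC %.4f>\n",
              x$k, a$sensitivity, a$specificity, a$f1, a$roc_auc))
  invisible(x)
}

#' Serialize a cross-validation report to JSON
#' @param report A `cv_report`.
#' @param path Output JSON path.
#' @export
write_cv_report_json <- function(report, path) {
  stopifnot(inherits(report, "cv_report"))
  obj <- list(k = report$k,
              aggregate = report$aggregate,
              mean_of_folds = report$mean_of_folds,
              confusion = as.data.frame.matrix(report$confusion),
              per_class = report$per_class,
              fold_assignment = as.list(report$fold_assignment))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
}
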