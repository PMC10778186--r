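test_that("feature extraction matches a brute-force per-pixel oracle", {
  pipe <- calibrated_pipeline(0, default_test_camera())
  basis <- pipe$basis
  set.seed(51)
  img <- array(runif(10 * 10 * 3, 40, 220), dim = c(10, 10, 3))
  g <- matrix(rbinom(100, 1, 0.5), 10, 10)
  if (sum(g) < 2) g[1:2, 1] <- 1
  cube <- image_to_cube(img, pipe$calib, basis)
  feats <- extract_features(cube, lesion_mask(g), basis)
  expect_length(feats, 60)

  # oracle: loop pixels, project, aggregate
  sel <- which(g == 1, arr.ind = TRUE)
  scores <- matrix(NA_real_, nrow(sel), 12)
  for (r in seq_len(nrow(sel))) {
    spec <- cube[sel[r, 1], sel[r, 2], ]
    scores[r, ] <- as.numeric(t(basis$EV) %*% (spec - basis$mean_spectrum))
  }
  for (j in 1:12) {
    expect_equal(feats[[sprintf("pc%02d_mean", j)]], mean(scores[, j]), tolerance = 1e-10)
    expect_equal(feats[[sprintf("pc%02d_sd", j)]], sd(scores[, j]), tolerance = 1e-10)
    expect_equal(feats[[sprintf("pc%02d_p50", j)]],
                 quantile(scores[, j], 0.5, names = FALSE), tolerance = 1e-10)
  }
})

test_that("feature extraction handles uniform and tiny regions", {
  pipe <- calibrated_pipeline(0, default_test_camera())
  img <- array(0, dim = c(6, 6, 3))
  img[, , 1] <- 150; img[, , 2] <- 100; img[, , 3] <- 90
  cube <- image_to_cube(img, pipe$calib, pipe$basis)
  g <- matrix(0, 6, 6); g[2:4, 2:4] <- 1
  f <- extract_features(cube, lesion_mask(g), pipe$basis)
  sds <- f[grepl("_sd$", names(f))]
  expect_equal(unname(unlist(sds)), rep(0, 12), tolerance = 1e-10)
  expect_equal(f[["pc01_mean"]], f[["pc01_p50"]], tolerance = 1e-10)

  # two-pixel region: mean is the midpoint of the two pixel scores
  set.seed(52)
  img2 <- array(runif(6 * 6 * 3, 0, 255), dim = c(6, 6, 3))
  cube2 <- image_to_cube(img2, pipe$calib, pipe$basis)
  g2 <- matrix(0, 6, 6); g2[1, 1] <- 1; g2[3, 4] <- 1
  f2 <- extract_features(cube2, lesion_mask(g2), pipe$basis)
  s1 <- as.numeric(t(pipe$basis$EV) %*% (cube2[1, 1, ] - pipe$basis$mean_spectrum))
  s2 <- as.numeric(t(pipe$basis$EV) %*% (cube2[3, 4, ] - pipe$basis$mean_spectrum))
  expect_equal(f2[["pc01_mean"]], (s1[1] + s2[1]) / 2, tolerance = 1e-10)

  expect_error(extract_features(cube, lesion_mask(matrix(0, 6, 6)), pipe$basis),
               "empty region")
})

test_that("grouped folds partition patients evenly, disjointly and reproducibly", {
  ids <- rep(sprintf("pt%02d", 1:34), times = sample(3:8, 34, replace = TRUE))
  f <- make_group_folds(ids, k = 7, seed = 0)
  counts <- table(f$patient_fold)
  expect_true(all(counts %in% c(4, 5)))
  expect_equal(sum(counts), 34)
  expect_length(f$sample_fold, length(ids))
  # per-sample folds agree with their patient's fold
  expect_true(all(f$sample_fold == f$patient_fold[ids]))

  expect_error(make_group_folds(ids, k = 1), "at least 2")
  expect_error(make_group_folds(ids, k = 35), "exceeds")

  f2 <- make_group_folds(ids, k = 7, seed = 0)
  expect_identical(f$patient_fold, f2$patient_fold)
  f3 <- make_group_folds(ids, k = 7, seed = 1)
  expect_false(identical(f$patient_fold, f3$patient_fold))
})

test_that("classifier separates constructed clusters and emits proper probabilities", {
  set.seed(53)
  n <- 60
  X <- rbind(matrix(rnorm(n * 5, 0), n, 5), matrix(rnorm(n * 5, 6), n, 5))
  y <- rep(c("normal", "MF"), each = n)
  clf <- train_classifier(X, y, seed = 0)
  p <- predict(clf, X)
  expect_equal(dim(p), c(2 * n, 4))
  expect_equal(unname(rowSums(p)), rep(1, 2 * n), tolerance = 1e-6)
  acc <- mean(c("normal", "MF", "PsO", "AD")[max.col(p)] == y)
  expect_gte(acc, 0.99)

  expect_error(train_classifier(X, rep("MF", 2 * n)), "single class")
  expect_error(train_classifier(X, rep(c("MF", "bad"), n)), "labels")
})

test_that("duplicating every training sample leaves predictions unchanged", {
  set.seed(54)
  X <- matrix(rnorm(200), 40, 5)
  y <- rep(c("normal", "MF", "PsO", "AD"), 10)
  probe <- matrix(rnorm(50), 10, 5)
  # exact greedy boosting without row/column subsampling or regularization:
  # duplicating every sample scales all gradient statistics uniformly, so
  # splits and leaf values G/H are unchanged
  # moderate capacity: with many rounds, floating-point summation order over
  # the duplicated rows drifts split choices, so equivalence is tested where
  # it is numerically stable
  det <- boost_params(subsample = 1, colsample_bytree = 1,
                      lambda = 0, min_child_weight = 0,
                      nrounds = 50, max_depth = 3)
  p1 <- predict(train_classifier(X, y, params = det, seed = 7), probe)
  p2 <- predict(train_classifier(rbind(X, X), c(y, y), params = det, seed = 7), probe)
  expect_equal(p1, p2, tolerance = 1e-3)
})

test_that("confusion-matrix metrics match hand-computed values", {
  conf <- matrix(c(10, 2, 0,
                   1, 15, 4,
                   3, 0, 12), 3, 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  m <- metrics_from_confusion(conf)
  # class a: TP 10, FN 2, FP 4, TN 31
  expect_equal(m$per_class$sensitivity[1], 10 / 12)
  expect_equal(m$per_class$specificity[1], 31 / 35)
  expect_equal(m$per_class$precision[1], 10 / 14)
  expect_equal(m$per_class$f1[1], 2 * (10 / 14) * (10 / 12) / (10 / 14 + 10 / 12))
  # class b: TP 15, FN 5, FP 2, TN 25
  expect_equal(m$per_class$sensitivity[2], 15 / 20)
  expect_equal(m$per_class$specificity[2], 25 / 27)
  expect_equal(m$sensitivity, mean(c(10 / 12, 15 / 20, 12 / 15)))
})

test_that("one-vs-rest AUC hits the perfect and chance endpoints", {
  truth <- rep(c(0, 1), each = 50)
  expect_equal(dermspectra:::ovr_auc(truth, truth * 2 + 1), 1.0)
  expect_equal(dermspectra:::ovr_auc(truth, rep(0.5, 100)), 0.5)
})

test_that("grouped cross-validation produces coherent, leakage-free reports", {
  fx <- lesion_sample_table()
  rep <- suppressWarnings(run_cross_validation(fx$table, k = 5, seed = 0))
  # accounting identity: confusion rows sum to class counts
  expect_equal(unname(rowSums(rep$confusion)),
               unname(as.vector(table(factor(fx$table$label,
                                             c("normal", "MF", "PsO", "AD"))))))
  # every sample predicted exactly once
  expect_equal(nrow(rep$predictions), nrow(fx$table))
  # patient-disjoint folds
  ass <- rep$fold_assignment
  for (f in 1:5) {
    test_pat <- names(ass)[ass == f]
    train_pat <- names(ass)[ass != f]
    expect_length(intersect(test_pat, train_pat), 0)
  }
  # strong signal at default separation
  expect_gte(rep$aggregate$roc_auc, 0.95)
  expect_gte(rep$aggregate$sensitivity, 0.9)
  # mean-of-folds view is reported alongside pooled
  expect_true(is.finite(rep$mean_of_folds$roc_auc))
})

test_that("cross-validation on permuted labels collapses to chance", {
  fx <- lesion_sample_table()
  tab <- fx$table
  tab$label <- withr::with_seed(101, sample(tab$label))
  rep <- suppressWarnings(run_cross_validation(tab, k = 5, seed = 0))
  expect_gte(rep$aggregate$roc_auc, 0.40)
  expect_lte(rep$aggregate$roc_auc, 0.60)
})

test_that("cv report serializes to JSON", {
  fx <- lesion_sample_table()
  rep <- suppressWarnings(run_cross_validation(fx$table, k = 5, seed = 0))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_cv_report_json(rep, tmp)
  back <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(back$aggregate$roc_auc, rep$aggregate$roc_auc, tolerance = 1e-12)
  expect_equal(back$k, 5)
})
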