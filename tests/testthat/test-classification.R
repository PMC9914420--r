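# Classifier training, prediction, k-fold CV and confusion metrics.

# small, well-separated two-class feature table
make_gaussian_data <- function(n = 200, sep = 4, seed = 7, p = 5) {
  set.seed(seed)
  half <- n / 2
  x <- rbind(matrix(rnorm(half * p), half, p),
             matrix(rnorm(half * p, mean = sep / sqrt(p)), half, p))
  colnames(x) <- paste0("f", seq_len(p))
  d <- tibble::as_tibble(as.data.frame(x))
  d$id <- sprintf("s%03d", seq_len(n))
  d$label <- factor(rep(c("normal", "abnormal"), each = half),
                    levels = c("normal", "abnormal"))
  d[sample(n), ]
}

test_that("the network separates well-separated Gaussian classes", {
  d <- make_gaussian_data(n = 200, seed = 7)
  m <- fit_classifier(d, classifier_config(seed = 7))
  p <- predict(m, d)
  expect_gte(mean(p$.pred == d$label), 0.95)
  expect_true(all(p$.score >= 0 & p$.score <= 1))
  expect_false(m$degenerate)
})

test_that("duplicating every row leaves the decision function unchanged", {
  d <- make_gaussian_data(n = 80, seed = 3)
  dd <- dplyr::bind_rows(d, d)
  dd$id <- sprintf("s%03d", seq_len(nrow(dd)))
  m1 <- fit_classifier(d, classifier_config(seed = 5))
  m2 <- fit_classifier(dd, classifier_config(seed = 5))
  p1 <- predict(m1, d)$.score
  p2 <- predict(m2, d)$.score
  expect_equal(cor(p1, p2), 1, tolerance = 0.05)
  expect_equal(predict(m1, d)$.pred, predict(m2, d)$.pred)
})

test_that("degenerate and invalid training sets are handled", {
  d <- make_gaussian_data(n = 40, seed = 1)
  d[paste0("f", 1:5)] <- 1  # constant features
  m <- fit_classifier(d, classifier_config(seed = 1))
  expect_true(m$degenerate)
  one_class <- make_gaussian_data(n = 40, seed = 1)
  one_class$label <- factor("normal", levels = c("normal", "abnormal"))
  expect_error(fit_classifier(one_class), "each class")
  bad <- make_gaussian_data(n = 40, seed = 1)
  bad$f1[3] <- NaN
  expect_error(fit_classifier(bad), "non-finite")
})

test_that("prediction validates dimensions and is row independent", {
  d <- make_gaussian_data(n = 60, seed = 9)
  m <- fit_classifier(d, classifier_config(seed = 9))
  expect_error(predict(m, d[, 1:3]), "lacks feature columns")
  perm <- sample(nrow(d))
  expect_equal(predict(m, d[perm, ])$.score, predict(m, d)$.score[perm])
})

test_that("score ties at 0.5 are called abnormal", {
  scores <- c(0.4999, 0.5, 0.5001)
  labels <- ifelse(scores >= 0.5, "abnormal", "normal")
  expect_identical(labels, c("normal", "abnormal", "abnormal"))
  # the exported rule: predict() labels via .score >= 0.5
  d <- make_gaussian_data(n = 40, seed = 2)
  m <- fit_classifier(d, classifier_config(seed = 2))
  p <- predict(m, d)
  expect_identical(as.character(p$.pred),
                   ifelse(p$.score >= 0.5, "abnormal", "normal"))
})

test_that("confusion metrics match the worked example and conventions", {
  m <- metrics_from_counts(90, 95, 5, 10)
  expect_equal(m$sensitivity, 0.90)
  expect_equal(m$specificity, 0.95)
  expect_equal(m$accuracy, 0.925)
  expect_equal(m$ppv, 90 / 95, tolerance = 1e-12)
  expect_equal(m$precision, m$ppv)
  # FP = 0: specificity 1, LR+ undefined
  m0 <- metrics_from_counts(10, 20, 0, 5)
  expect_equal(m0$specificity, 1)
  expect_true(is.na(m0$lr_pos))
  # symmetry: TP == TN, FP == FN implies PPV == NPV
  ms <- metrics_from_counts(12, 12, 4, 4)
  expect_equal(ms$ppv, ms$npv)
  expect_error(metrics_from_counts(-1, 0, 0, 2), "non-negative")
  expect_error(metrics_from_counts(0, 0, 0, 0), "positive")
})

test_that("metrics agree with brute-force formulas over a dense count grid", {
  grid <- expand.grid(tp = 0:20, tn = 0:20, fp = 0:20, fn = 0:20)
  grid <- grid[rowSums(grid) > 0, ]
  want <- oracle_metrics(grid$tp, grid$tn, grid$fp, grid$fn)
  got <- cervitex:::metrics_vec(grid$tp, grid$tn, grid$fp, grid$fn)
  for (nm in names(want)) {
    expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12, info = nm)
  }
  # the tibble wrapper reproduces the vectorized core on a subsample
  set.seed(6)
  for (i in sample(nrow(grid), 50)) {
    row <- metrics_from_counts(grid$tp[i], grid$tn[i], grid$fp[i],
                               grid$fn[i])
    expect_equal(row$sensitivity, want$sensitivity[i])
    expect_equal(row$lr_pos, want$lr_pos[i])
    expect_equal(row$npv, want$npv[i])
  }
})

test_that("stratified k-fold CV pools counts and averages fold errors", {
  d <- make_gaussian_data(n = 200, seed = 7)
  cv <- kfold_cv(d, k = 2, seed = 7, config = classifier_config(seed = 7))
  expect_equal(cv$cv_error, mean(cv$fold_errors))
  expect_lte(cv$cv_error, 0.1)  # separable data
  expect_gte(cv$cv_error, 0)
  expect_equal(sum(cv$counts), 200)
  expect_equal(nrow(cv$predictions), 200)
  # stratification: each fold carries half of each class
  tab <- table(cv$predictions$fold, cv$predictions$truth)
  expect_true(all(tab == 50))
  expect_error(kfold_cv(d, k = 1), ">= 2")
  expect_error(kfold_cv(d[1:3, ], k = 5), "exceed")
})

test_that("CV is reproducible bit-for-bit under a fixed seed", {
  d <- make_gaussian_data(n = 60, seed = 4)
  cv1 <- kfold_cv(d, k = 3, seed = 4, config = classifier_config(seed = 4))
  cv2 <- kfold_cv(d, k = 3, seed = 4, config = classifier_config(seed = 4))
  expect_identical(cv1$fold_errors, cv2$fold_errors)
  expect_identical(cv1$predictions$.score, cv2$predictions$.score)
})

test_that("cv error stays within [0, 1] across random small runs", {
  for (s in 1:5) {
    d <- make_gaussian_data(n = 24, sep = runif(1, 0, 3), seed = s)
    cv <- kfold_cv(d, k = sample(2:4, 1), seed = s,
                   config = classifier_config(seed = s, epochs = 50))
    expect_gte(cv$cv_error, 0)
    expect_lte(cv$cv_error, 1)
  }
})

test_that("tidiers summarise models and CV runs", {
  d <- make_gaussian_data(n = 60, seed = 8)
  m <- fit_classifier(d, classifier_config(seed = 8))
  cv <- kfold_cv(d, k = 2, seed = 8, config = classifier_config(seed = 8))
  td <- tidy(cv)
  expect_equal(nrow(td), 2)
  expect_named(td, c("fold", "error", "n_test"))
  gl <- glance(cv)
  expect_equal(gl$cv_error, cv$cv_error)
  expect_equal(glance(m)$n_weights, length(m$net$wts))
  expect_equal(nrow(tidy(m)), length(m$net$wts))
})
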