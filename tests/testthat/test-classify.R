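test_that("median split: documented tie rule and guards", {
  expect_equal(as.character(median_split(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  # median 2, ties go low
  expect_equal(as.character(median_split(c(1, 2, 2, 5))),
               c("low", "low", "low", "high"))
  expect_error(median_split(c(3, 3, 3)), "identical")
  expect_error(median_split(2), "at least 2")
  # group size difference bounded by the number of scores at the median
  set.seed(1)
  x <- sample(1:7, 101, replace = TRUE)
  lab <- median_split(x)
  expect_lte(abs(sum(lab == "high") - sum(lab == "low")),
             sum(x == stats::median(x)))
})

test_that("splits have the right sizes, determinism, dyad integrity", {
  set.seed(2)
  labels <- factor(rep(c("low", "high"), 50), levels = c("low", "high"))
  dyads <- rep(sprintf("d%02d", 1:50), each = 2)
  sp <- make_split(labels, dyads, 0.7, 5, seed = 9)
  expect_equal(length(sp$train), 70)
  expect_equal(length(sp$test), 30)
  expect_identical(sp, make_split(labels, dyads, 0.7, 5, seed = 9))
  # dyad-grouped: no dyad straddles the partition or folds
  side <- split(seq_along(labels) %in% sp$train, dyads)
  expect_true(all(vapply(side, function(v) length(unique(v)) == 1,
                         logical(1))))
  fold_by_dyad <- split(sp$fold, dyads[sp$train])
  expect_true(all(vapply(fold_by_dyad, function(v) length(unique(v)) == 1,
                         logical(1))))
  # fold sizes differ by at most one unit (dyad = 2 rows)
  expect_lte(diff(range(table(sp$fold))), 2)
  # participant-level mode
  sp2 <- make_split(labels, dyads, 0.7, 5, seed = 9, group_by_dyad = FALSE)
  expect_equal(length(sp2$train), 70)
})

test_that("CFS picks the single perfect feature (exhaustive merit oracle)", {
  set.seed(3)
  n <- 60
  y <- factor(rep(c("low", "high"), each = n / 2), levels = c("low", "high"))
  A <- as.numeric(y == "high")
  X <- cbind(A = A, B = A, C = rnorm(n))
  # independent oracle: evaluate the merit of every nonempty subset
  yn <- as.numeric(y == "high")
  rcf <- abs(cor(X, yn))[, 1]
  subsets <- unlist(lapply(1:3, function(k)
    combn(colnames(X), k, simplify = FALSE)), recursive = FALSE)
  merit_of <- vapply(subsets, function(s) {
    k <- length(s)
    rff <- if (k > 1) mean(abs(cor(X[, s]))[upper.tri(diag(k))]) else 0
    k * mean(rcf[s]) / sqrt(k + k * (k - 1) * rff)
  }, numeric(1))
  best <- subsets[[which.max(merit_of)]]
  sel <- cfs_select(X, y)
  expect_equal(length(sel), length(best))
  expect_true(all(sel %in% c("A", "B")))   # A and B are interchangeable
  expect_equal(attr(sel, "merit"), max(merit_of), tolerance = 1e-9)
  expect_equal(attr(sel, "merit"), 1, tolerance = 1e-9)  # k = 1, r_cf = 1
})

test_that("CFS on pure noise keeps the merit near zero", {
  # with equally weak uncorrelated features the merit heuristic grows like
  # sqrt(k), so the subset size is not tightly bounded on pure noise; the
  # meaningful property is that the achieved merit stays near zero and the
  # first pick is the feature most correlated with the label
  set.seed(4)
  n <- 400
  y <- factor(rep(c("low", "high"), n / 2), levels = c("low", "high"))
  X <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, paste0("f", 1:12)))
  sel <- cfs_select(X, y)
  expect_lt(attr(sel, "merit"), 0.3)
  rcf <- abs(cor(X, as.numeric(y == "high")))[, 1]
  expect_equal(sel[1], names(which.max(rcf)))
})

test_that("SVM-RFE keeps informative features and honors target_k", {
  set.seed(5)
  n <- 80
  x1 <- rnorm(n)
  y <- factor(ifelse(x1 > 0, "high", "low"), levels = c("low", "high"))
  X <- cbind(x1 = x1, matrix(rnorm(n * 9), n, 9,
                             dimnames = list(NULL, paste0("z", 1:9))))
  keep <- svm_rfe(X, y, target_k = 3)
  expect_true("x1" %in% keep)
  expect_equal(length(keep), 3)
  expect_equal(length(attr(keep, "eliminated")), 7)
  # target_k equal to the feature count is the identity
  expect_equal(sort(as.character(svm_rfe(X, y, target_k = 10))),
               sort(colnames(X)))
  expect_error(svm_rfe(X, y, target_k = 11), "below target_k")
  # duplicated informative features: one copy may go, but both never fall
  # before all noise features have been eliminated
  X2 <- cbind(a = x1, b = x1, n1 = rnorm(n), n2 = rnorm(n))
  k2 <- svm_rfe(X2, y, target_k = 1)
  expect_true(as.character(k2) %in% c("a", "b"))
})

test_that("random forest and MLP fit, predict, and stay deterministic", {
  set.seed(6)
  n <- 120
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("u", "v", "w")))
  y <- factor(ifelse(X[, 1] - X[, 2] > 0, "high", "low"),
              levels = c("low", "high"))
  rf <- fit_random_forest(X, y)
  expect_gt(mean(predict(rf, X) == y), 0.95)
  expect_identical(predict(fit_random_forest(X, y), X), predict(rf, X))
  mlp <- suppressWarnings(fit_mlp(X, y))
  expect_gt(mean(predict(mlp, X) == y), 0.9)
  expect_identical(predict(suppressWarnings(fit_mlp(X, y)), X),
                   predict(mlp, X))
  one <- factor(rep("low", n), levels = c("low", "high"))
  expect_error(fit_random_forest(X, one), "one class")
  expect_error(fit_mlp(X, one), "one class")
  expect_error(fit_random_forest(X, y, hp = list(ntree = 500, mtry = 0,
                                                 nodesize = 7,
                                                 max_depth = 10, seed = 30)),
               "outside documented domain")
})

test_that("MLP learns a nonlinear (XOR-style) pattern", {
  set.seed(7)
  n <- 200
  X <- matrix(rnorm(n * 2, sd = 0.3), n, 2,
              dimnames = list(NULL, c("a", "b"))) +
    cbind(sample(c(-1, 1), n, TRUE), sample(c(-1, 1), n, TRUE))
  y <- factor(ifelse(X[, 1] * X[, 2] > 0, "high", "low"),
              levels = c("low", "high"))
  mlp <- suppressWarnings(fit_mlp(X, y))
  expect_gt(mean(predict(mlp, X) == y), 0.9)
})

test_that("cross-validation composes fold accuracies correctly", {
  set.seed(8)
  n <- 100
  X <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("p", "q")))
  y <- factor(ifelse(X[, 1] > 0, "high", "low"), levels = c("low", "high"))
  fold <- rep(1:5, 20)
  # perfectly learnable: mean 1, sd 0 (wide margin, no boundary points)
  Xs <- X; Xs[, 1] <- Xs[, 1] + ifelse(y == "high", 2, -2)
  cv <- cross_validate(function(X, y) fit_random_forest(X, y), Xs, y, fold)
  expect_equal(cv$mean, 1)
  expect_equal(cv$sd, 0)
  expect_equal(length(cv$per_fold), 5)
  # label-shuffled data stays near the majority rate
  ysh <- sample(y)
  cv2 <- cross_validate(function(X, y) fit_random_forest(X, y), X, ysh, fold)
  base <- max(table(ysh)) / n
  expect_lt(abs(cv2$mean - base), 3 * sqrt(base * (1 - base) / n) + 0.05)
})

test_that("evaluation reports the documented quantities", {
  # 72 test labels with 37 in the majority class -> baseline 51.39%
  y <- factor(c(rep("high", 37), rep("low", 35)), levels = c("low", "high"))
  perfect <- structure(list(), class = "oracle_model")
  assign("predict.oracle_model",
         function(object, newdata, ...) y, envir = globalenv())
  on.exit(rm("predict.oracle_model", envir = globalenv()))
  rep <- evaluate_classifier(perfect, matrix(0, 72, 1), y)
  expect_equal(rep$majority_baseline, 37 / 72)
  expect_equal(round(100 * rep$majority_baseline, 2), 51.39)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$sensitivity, 1)
  expect_equal(rep$specificity, 1)
  # predict-all-high on balanced labels: sensitivity 1, specificity 0
  yb <- factor(rep(c("low", "high"), 10), levels = c("low", "high"))
  allhigh <- structure(list(), class = "oracle_model")
  assign("predict.oracle_model",
         function(object, newdata, ...)
           factor(rep("high", 20), levels = c("low", "high")),
         envir = globalenv())
  rep2 <- evaluate_classifier(allhigh, matrix(0, 20, 1), yb)
  expect_equal(rep2$accuracy, 0.5)
  expect_equal(rep2$sensitivity, 1)
  expect_equal(rep2$specificity, 0)
  expect_equal(sum(rep2$confusion), 20)
  expect_error(evaluate_classifier(perfect, matrix(0, 0, 1), y[0]), "empty")
})

test_that("selection and standardization never see test rows", {
  set.seed(9)
  n <- 80
  feats <- matrix(rnorm(n * 30), n, 30,
                  dimnames = list(NULL, sprintf("f%02d", 1:30)))
  attraction <- rnorm(n) + feats[, 1]
  tab <- data.frame(participant_id = sprintf("p%03d", 1:n),
                    dyad_id = rep(sprintf("d%02d", 1:(n / 2)), each = 2),
                    attraction = attraction)
  tab <- cbind(tab, as.data.frame(feats))
  attr(tab, "feature_names") <- colnames(feats)
  class(tab) <- c("feature_table", "data.frame")
  cfg <- pipeline_config(rfe_target_k = 5)
  res <- suppressWarnings(classify_attraction(tab, cfg, seed = 4))
  # corrupt every test row's features: selection must not change
  tab2 <- tab
  tab2[res$split$test, colnames(feats)] <- 1e6 *
    matrix(rnorm(length(res$split$test) * 30), ncol = 30)
  attr(tab2, "feature_names") <- colnames(feats)
  res2 <- suppressWarnings(classify_attraction(tab2, cfg, seed = 4))
  expect_identical(res$selected, res2$selected)
  expect_identical(res$split$train, res2$split$train)
  expect_equal(res$rf$cv$per_fold, res2$rf$cv$per_fold)
})
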