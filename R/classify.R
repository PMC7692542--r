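#' Median-split class labels
#'
#' Dichotomizes a continuous score at the sample median: scores strictly
#' above the median are "high", scores at or below it are "low" (ties go
#' low).  The median is taken over the full labeled cohort.
#'
#' @param scores numeric vector (length >= 2).
#' @return factor with levels `c("low", "high")`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 scores")
  if (length(unique(scores)) == 1) {
    stop("all scores identical; median split is degenerate")
  }
  med <- stats::median(scores)
  factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
}

#' Train/test partition with cross-validation folds
#'
#' Randomly partitions participants into a training fraction and a test
#' set, stratified by class label where possible, and assigns the training
#' rows to `cv_folds` folds.  In the default dyad-grouped mode both
#' members of a dyad always land on the same side of every split (dyad
#' members share their synchrony features, so splitting a dyad would leak
#' test information into training); participant-level mode is available
#' for a strict reading of a per-participant random partition.
#'
#' @param labels factor of class labels, one per participant.
#' @param dyad_ids character vector parallel to `labels`.
#' @param train_fraction fraction of participants in the training set.
#' @param cv_folds number of folds over the training set.
#' @param seed integer seed.
#' @param group_by_dyad logical (default TRUE).
#' @return a `split_plan`: list with integer vectors `train`, `test`, and
#'   `fold` (fold id per training row, parallel to `train`).
#' @export
make_split <- function(labels, dyad_ids, train_fraction = 0.7, cv_folds = 5,
                       seed = 1L, group_by_dyad = TRUE) {
  n <- length(labels)
  stopifnot(length(dyad_ids) == n)
  with_seed(seed, {
    if (group_by_dyad) {
      units <- split(seq_len(n), dyad_ids)
      # stratify dyads by their majority label
      ulab <- vapply(units, function(ix) {
        names(sort(table(labels[ix]), decreasing = TRUE))[1]
      }, character(1))
    } else {
      units <- as.list(seq_len(n))
      ulab <- as.character(labels)
    }
    n_units <- length(units)
    train_units <- integer(0)
    for (lv in unique(ulab)) {
      pool <- which(ulab == lv)
      k <- round(train_fraction * length(pool))
      train_units <- c(train_units, sample(pool, k))
    }
    train <- sort(unlist(units[train_units]))
    test <- setdiff(seq_len(n), train)
    if (length(test) == 0 || length(train) == 0) {
      stop("degenerate partition; adjust train_fraction or cohort size")
    }
    # folds over training units, stratified the same way
    fold_of_unit <- integer(n_units)
    for (lv in unique(ulab)) {
      pool <- intersect(train_units, which(ulab == lv))
      fold_of_unit[sample(pool)] <- rep_len(seq_len(cv_folds), length(pool))
    }
    fold <- integer(length(train))
    for (u in train_units) {
      fold[train %in% units[[u]]] <- fold_of_unit[u]
    }
    structure(list(train = train, test = test, fold = fold,
                   group_by_dyad = group_by_dyad, seed = seed),
              class = "split_plan")
  })
}

#' Correlation-based feature selection (CFS)
#'
#' Greedy forward search over feature subsets scored by the merit
#' heuristic `k * r_cf / sqrt(k + k (k - 1) * r_ff)`, where `r_cf` is the
#' mean absolute feature--label (point-biserial) correlation of the subset
#' and `r_ff` the mean absolute pairwise feature correlation: features
#' that correlate with the outcome but not with each other score high.
#' The search stops when no addition improves the merit.  Constant
#' features are skipped.
#'
#' @param X numeric matrix (training rows x features, named columns).
#' @param y factor with two levels.
#' @return character vector of selected feature names (merit order), with
#'   attribute `merit`.
#' @export
cfs_select <- function(X, y) {
  stopifnot(is.matrix(X), ncol(X) >= 1)
  yn <- as.numeric(y == levels(y)[2])
  sds <- col_sds(X)
  usable <- which(sds > 0 & !is.na(sds))
  if (length(usable) == 0) stop("no non-constant features")
  r_cf <- abs(suppressWarnings(stats::cor(X[, usable, drop = FALSE], yn)))[, 1]
  r_cf[is.na(r_cf)] <- 0
  merit <- function(sel, r_ff_sum) {
    k <- length(sel)
    rcf <- mean(r_cf[sel])
    rff <- if (k > 1) r_ff_sum / (k * (k - 1) / 2) else 0
    k * rcf / sqrt(k + k * (k - 1) * rff)
  }
  sel <- integer(0)
  sel_r_ff_sum <- 0
  best_merit <- -Inf
  # cache of |cor| between each selected feature and all usable features
  cor_rows <- list()
  repeat {
    cand <- setdiff(seq_along(usable), sel)
    if (!length(cand)) break
    # sum of |cor| of each candidate with the current subset
    cross <- if (length(sel)) {
      Reduce(`+`, lapply(cor_rows, function(rw) rw[cand]))
    } else numeric(length(cand))
    merits <- vapply(seq_along(cand), function(i) {
      merit(c(sel, cand[i]), sel_r_ff_sum + cross[i])
    }, numeric(1))
    i_best <- which.max(merits)
    if (merits[i_best] <= best_merit + 1e-12) break
    best_merit <- merits[i_best]
    new <- cand[i_best]
    rw <- abs(suppressWarnings(
      stats::cor(X[, usable, drop = FALSE], X[, usable[new]])))[, 1]
    rw[is.na(rw)] <- 0
    sel_r_ff_sum <- sel_r_ff_sum + cross[i_best]
    cor_rows[[length(cor_rows) + 1]] <- rw
    sel <- c(sel, new)
  }
  structure(colnames(X)[usable[sel]], merit = best_merit)
}

#' SVM recursive feature elimination
#'
#' Repeatedly fits a linear soft-margin SVM on standardized training
#' features and removes the feature with the smallest squared weight,
#' until `target_k` features remain.  The elimination order is recorded.
#'
#' @param X numeric matrix (training rows x features, named columns).
#' @param y factor with two levels.
#' @param target_k number of features to retain.
#' @param cost soft-margin cost (default 1).
#' @return character vector of surviving feature names, with attribute
#'   `eliminated` (names in elimination order).
#' @export
svm_rfe <- function(X, y, target_k = 23, cost = 1) {
  stopifnot(is.matrix(X))
  if (ncol(X) < target_k) {
    stop("feature count (", ncol(X), ") below target_k (", target_k, ")")
  }
  mu <- colMeans(X)
  sd <- col_sds(X)
  sd[sd == 0 | is.na(sd)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd, "/")
  keep <- colnames(X)
  eliminated <- character(0)
  while (length(keep) > target_k) {
    fit <- e1071::svm(Z[, keep, drop = FALSE], y, kernel = "linear",
                      cost = cost, scale = FALSE)
    w <- drop(crossprod(fit$coefs, fit$SV))
    worst <- keep[which.min(w^2)]
    eliminated <- c(eliminated, worst)
    keep <- setdiff(keep, worst)
  }
  structure(keep, eliminated = eliminated)
}

#' Fit the random-forest classifier
#'
#' Bagged classification forest on the selected (raw, unstandardized)
#' features: 500 trees, 20 candidate features per split, at least 7
#' samples per leaf, tree depth capped at 10, bootstrap resampling, fixed
#' seed.
#'
#' @param X numeric matrix (training rows x selected features).
#' @param y factor with two levels.
#' @param hp hyperparameter list (see [pipeline_config()]).
#' @return fitted model of class `dyad_rf`.
#' @export
fit_random_forest <- function(X, y, hp = pipeline_config()$rf) {
  if (nlevels(droplevels(y)) < 2) stop("training labels contain one class")
  check_hp(hp, list(ntree = c(1, Inf), mtry = c(1, Inf),
                    nodesize = c(1, Inf), max_depth = c(1, 31)))
  fit <- with_seed(hp$seed, {
    randomForest::randomForest(
      x = X, y = y, ntree = hp$ntree, mtry = min(hp$mtry, ncol(X)),
      nodesize = hp$nodesize, maxnodes = min(2^hp$max_depth, nrow(X)),
      replace = isTRUE(hp$bootstrap))
  })
  structure(list(fit = fit, features = colnames(X)), class = "dyad_rf")
}

#' @export
predict.dyad_rf <- function(object, newdata, ...) {
  stats::predict(object$fit, newdata[, object$features, drop = FALSE])
}

#' Fit the multilayer-perceptron classifier
#'
#' Single-hidden-layer perceptron (50 logistic units, L2 penalty 0.03,
#' at most 200 optimizer iterations, fixed seed) on features standardized
#' with training-set statistics only.  Non-convergence within the
#' iteration budget is reported as a warning; the model is still
#' returned.
#'
#' @inheritParams fit_random_forest
#' @return fitted model of class `dyad_mlp`.
#' @export
fit_mlp <- function(X, y, hp = pipeline_config()$mlp) {
  if (nlevels(droplevels(y)) < 2) stop("training labels contain one class")
  check_hp(hp, list(hidden = c(1, Inf), decay = c(0, Inf),
                    maxit = c(1, Inf)))
  mu <- colMeans(X)
  sd <- col_sds(X)
  sd[sd == 0 | is.na(sd)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sd, "/")
  fit <- with_seed(hp$seed, {
    nnet::nnet(Z, class_indicator(y), size = hp$hidden, decay = hp$decay,
               maxit = hp$maxit, entropy = TRUE, trace = FALSE,
               MaxNWts = 100000)
  })
  if (fit$convergence != 0) {
    warning("MLP did not converge within ", hp$maxit, " iterations")
  }
  structure(list(fit = fit, mu = mu, sd = sd, levels = levels(y),
                 features = colnames(X)),
            class = "dyad_mlp")
}

# 0/1 target column for the positive (second) class
class_indicator <- function(y) matrix(as.numeric(y == levels(y)[2]), ncol = 1)

#' @export
predict.dyad_mlp <- function(object, newdata, ...) {
  Z <- sweep(sweep(newdata[, object$features, drop = FALSE], 2, object$mu),
             2, object$sd, "/")
  p <- stats::predict(object$fit, Z)
  factor(ifelse(p[, 1] > 0.5, object$levels[2], object$levels[1]),
         levels = object$levels)
}

check_hp <- function(hp, domain) {
  for (nm in names(domain)) {
    v <- hp[[nm]]
    if (is.null(v) || !is.numeric(v) || v < domain[[nm]][1] ||
        v > domain[[nm]][2]) {
      stop("hyperparameter '", nm, "' outside documented domain [",
           domain[[nm]][1], ", ", domain[[nm]][2], "]")
    }
  }
}

#' Cross-validate a classifier over preassigned folds
#'
#' Per fold: fit on the other folds, score accuracy on the held-out fold;
#' the composite validation accuracy is the mean over folds, with its SD.
#' Folds whose held-out part contains a single class are still scored
#' (accuracy remains defined); folds whose training part collapses to one
#' class are skipped with a warning.
#'
#' @param fit_fun function(X, y) returning a model with a `predict` method.
#' @param X training feature matrix.
#' @param y training labels.
#' @param fold integer fold assignment per training row.
#' @return list with `mean`, `sd`, `per_fold` accuracies.
#' @export
cross_validate <- function(fit_fun, X, y, fold) {
  accs <- c()
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (nlevels(droplevels(y[tr])) < 2) {
      warning("fold ", f, " skipped: single-class training labels")
      next
    }
    m <- fit_fun(X[tr, , drop = FALSE], y[tr])
    pred <- predict(m, X[!tr, , drop = FALSE])
    accs <- c(accs, mean(pred == y[!tr]))
  }
  list(mean = mean(accs), sd = stats::sd(accs), per_fold = accs)
}

#' Evaluate a fitted classifier on the held-out test set
#'
#' @param model fitted model with a `predict` method.
#' @param X test feature matrix.
#' @param y test labels (factor, "low"/"high").
#' @return a `classifier_report`: confusion counts, accuracy, sensitivity
#'   (high recalled as high), specificity, and the majority-class
#'   baseline of the test labels.
#' @export
evaluate_classifier <- function(model, X, y) {
  if (length(y) == 0) stop("empty test set")
  pred <- predict(model, X)
  tp <- sum(pred == "high" & y == "high")
  tn <- sum(pred == "low" & y == "low")
  fp <- sum(pred == "high" & y == "low")
  fn <- sum(pred == "low" & y == "high")
  structure(
    list(confusion = matrix(c(tn, fp, fn, tp), 2, 2,
                            dimnames = list(predicted = c("low", "high"),
                                            actual = c("low", "high"))),
         accuracy = (tp + tn) / length(y),
         sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
         majority_baseline = max(table(y)) / length(y),
         n_test = length(y)),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(paste0("<classifier_report> accuracy %.2f%% (baseline ",
                     "%.2f%%), sensitivity %.2f, specificity %.2f, ",
                     "n = %d\n"),
              100 * x$accuracy, 100 * x$majority_baseline, x$sensitivity,
              x$specificity, x$n_test))
  invisible(x)
}

#' Full attraction-classification protocol on a feature table
#'
#' Implements the complete protocol: median split of the attraction
#' composite into high/low classes; random 70/30 train/test partition;
#' correlation-based feature selection followed by SVM recursive feature
#' elimination down to `rfe_target_k` features, both on training rows
#' only; five-fold cross-validation of the random forest and the MLP on
#' the training set; final fit and evaluation on the untouched test set.
#'
#' @param table a `feature_table` from [build_feature_table()].
#' @param cfg a [pipeline_config()].
#' @param seed seed for the partition (defaults to `cfg$seed`).
#' @return list with `selected` (feature names), `split` (the
#'   `split_plan`), `labels`, and per-model lists (`rf`, `mlp`) holding
#'   `cv` and `report`.
#' @export
classify_attraction <- function(table, cfg = pipeline_config(),
                                seed = cfg$seed) {
  feats <- attr(table, "feature_names")
  stopifnot(!is.null(feats))
  labels <- median_split(table$attraction)
  split <- make_split(labels, table$dyad_id, cfg$train_fraction,
                      cfg$cv_folds, seed, cfg$group_by_dyad)
  X <- as.matrix(table[, feats, drop = FALSE])
  Xtr <- X[split$train, , drop = FALSE]
  ytr <- labels[split$train]
  sel <- cfs_select(Xtr, ytr)
  if (length(sel) > cfg$rfe_target_k) {
    sel <- svm_rfe(Xtr[, sel, drop = FALSE], ytr, cfg$rfe_target_k)
  }
  Xtr_s <- Xtr[, sel, drop = FALSE]
  Xte_s <- X[split$test, sel, drop = FALSE]
  yte <- labels[split$test]
  out <- list(selected = as.character(sel), split = split, labels = labels)
  fitters <- list(
    rf = function(X, y) fit_random_forest(X, y, cfg$rf),
    mlp = function(X, y) fit_mlp(X, y, cfg$mlp))
  for (nm in names(fitters)) {
    cv <- cross_validate(fitters[[nm]], Xtr_s, ytr, split$fold)
    model <- fitters[[nm]](Xtr_s, ytr)
    out[[nm]] <- list(cv = cv, model = model,
                      report = evaluate_classifier(model, Xte_s, yte))
  }
  out
}
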