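#' Majority vote over six annotators
#'
#' Returns the modal class of the six labels; ties between modal classes
#' break toward the more severe class (Pathological 3 > Suspicious 2 >
#' Normal 1), the conservative clinical choice.
#'
#' @param rater_labels Integer vector of exactly six labels in `{1, 2, 3}`.
#' @return The aggregated class (integer).
#' @export
aggregate_annotations <- function(rater_labels) {
  if (length(rater_labels) != 6)
    stop("exactly six rater labels are required, got ",
         length(rater_labels), call. = FALSE)
  if (!all(rater_labels %in% 1:3))
    stop("rater labels must lie in {1, 2, 3}", call. = FALSE)
  counts <- tabulate(rater_labels, nbins = 3)
  winners <- which(counts == max(counts))
  as.integer(max(winners))
}

#' Numeric encoding of the 11-feature table
#'
#' Encodes the feature rows for the classifiers: numeric columns pass
#' through (`baseline`, `variability`, the event counts), the logical
#' acceleration flag becomes 0/1, the ordered variability class is encoded
#' ordinally (Absent 0 < Minimal 1 < Moderate 2 < Marked 3), and the
#' unordered categoricals (`baseline_type`, `shr`, `stage`) are one-hot
#' encoded, keeping `"Undetermined"` as its own indicator rather than
#' imputing it.
#'
#' @param features Data frame as from [extract_cohort_features()] (extra
#'   columns such as `id`/`label` are ignored).
#' @return A numeric matrix with one row per record.
#' @export
encode_ctg_features <- function(features) {
  stopifnot(is.data.frame(features))
  f <- features
  ord_var <- c(Absent = 0, Minimal = 1, Moderate = 2, Marked = 3)
  onehot <- function(x, levels, prefix) {
    m <- sapply(levels, function(l) as.numeric(x == l))
    m <- matrix(m, nrow = length(x))
    colnames(m) <- paste0(prefix, "_", tolower(levels))
    m
  }
  out <- cbind(
    baseline = ifelse(is.na(f$baseline), 0, f$baseline),
    baseline_known = as.numeric(!is.na(f$baseline)),
    variability = f$variability,
    variability_ord = unname(ord_var[f$variability_type]),
    acceleration_present = as.numeric(f$acceleration_present),
    n_accelerations = f$n_accelerations,
    n_early = f$n_early,
    n_late = f$n_late,
    n_variable = f$n_variable,
    onehot(f$baseline_type,
           c("Normal", "Bradycardia", "Tachycardia", "Undetermined"), "bt"),
    onehot(f$shr, c("Present", "Absent", "Undetermined"), "shr"),
    onehot(f$stage, c("normal", "stage1", "stage2"), "stage"))
  rownames(out) <- NULL
  out
}

#' SMOTE oversampling to class parity
#'
#' Oversamples every minority class by interpolation: a synthetic row lies
#' on the segment between a randomly chosen minority sample and one of its
#' `k_neighbors` nearest neighbours within the same class, at a uniform
#' random position. Classes are filled up to the majority-class count.
#' Intended for training folds only; synthetic rows are flagged so a
#' leakage guard can assert they never reach a test fold.
#'
#' @param x Numeric feature matrix.
#' @param y Class labels (coercible to factor).
#' @param k_neighbors Number of nearest same-class neighbours (default 5).
#'   If a minority class has fewer than `k_neighbors + 1` members, `k` is
#'   reduced for that class with a warning.
#' @param seed Optional integer seed.
#' @return A list with `x` (augmented matrix), `y` (augmented labels) and
#'   `provenance` (`"real"` or `"smote"` per row).
#' @export
smote_balance <- function(x, y, k_neighbors = 5, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  y <- factor(y)
  counts <- table(y)
  target <- max(counts)
  new_x <- list()
  new_y <- character()
  for (cl in names(counts)) {
    need <- target - counts[[cl]]
    if (need == 0) next
    rows <- which(y == cl)
    if (length(rows) < 2)
      stop("SMOTE needs at least 2 samples in class ", cl, call. = FALSE)
    k <- k_neighbors
    if (length(rows) < k + 1) {
      k <- length(rows) - 1
      warning("class ", cl, " has only ", length(rows),
              " samples; reducing k_neighbors to ", k, call. = FALSE)
    }
    xc <- x[rows, , drop = FALSE]
    d <- as.matrix(stats::dist(xc))
    diag(d) <- Inf
    nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
    picks <- sample.int(nrow(xc), need, replace = TRUE)
    for (p in picks) {
      nb <- nn[p, sample.int(k, 1)]
      lam <- stats::runif(1)
      new_x[[length(new_x) + 1L]] <- xc[p, ] + lam * (xc[nb, ] - xc[p, ])
      new_y <- c(new_y, cl)
    }
  }
  if (length(new_x)) {
    add <- do.call(rbind, new_x)
    list(x = rbind(x, add), y = factor(c(as.character(y), new_y),
                                       levels = levels(y)),
         provenance = c(rep("real", nrow(x)), rep("smote", nrow(add))))
  } else {
    list(x = x, y = y, provenance = rep("real", nrow(x)))
  }
}

# stratified fold assignment: per class, shuffled round-robin => per-fold
# class counts within 1 of n_c / k
stratified_folds <- function(y, k, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  y <- factor(y)
  if (any(table(y) < k))
    stop("stratification failure: every class needs at least k = ", k,
         " samples", call. = FALSE)
  folds <- integer(length(y))
  offset <- 0L
  for (cl in levels(y)) {
    rows <- which(y == cl)
    rows <- rows[sample.int(length(rows))]
    # rotate the fold sequence per class so fold sizes stay balanced overall
    folds[rows] <- ((seq_along(rows) - 1L + offset) %% k) + 1L
    offset <- offset + length(rows) %% k
  }
  folds
}

# --- model fitting -----------------------------------------------------

fit_model <- function(model, x, y, hyper) {
  y <- factor(y, levels = levels(y))
  switch(model,
    rf = randomForest::randomForest(
      x, y, ntree = hyper$ntree %||% 500),
    svm = {
      keep <- apply(x, 2, stats::sd) > 0
      fit <- e1071::svm(x[, keep, drop = FALSE], y, kernel = "radial",
                        probability = TRUE, cost = hyper$cost %||% 1)
      attr(fit, "keep_cols") <- keep
      fit
    },
    mlp = {
      sc <- scale(x)
      sc[, attr(sc, "scaled:scale") == 0] <- 0
      fit <- nnet::nnet(sc, stats::model.matrix(~ y - 1),
                        size = hyper$size %||% 8,
                        decay = hyper$decay %||% 0.01,
                        maxit = hyper$maxit %||% 300, softmax = TRUE,
                        trace = FALSE)
      attr(fit, "center") <- attr(sc, "scaled:center")
      attr(fit, "scale") <- attr(sc, "scaled:scale")
      fit
    },
    bagging = {
      n_bag <- hyper$n_bag %||% 25
      dat <- data.frame(x, y = y, check.names = FALSE)
      trees <- lapply(seq_len(n_bag), function(b) {
        idx <- sample.int(nrow(dat), replace = TRUE)
        rpart::rpart(y ~ ., data = dat[idx, , drop = FALSE],
                     method = "class",
                     control = rpart::rpart.control(cp = 0.01, minsplit = 5))
      })
      structure(list(trees = trees, levels = levels(y)),
                class = "ctg_bag")
    },
    stop("unknown model: ", model, call. = FALSE))
}

predict_scores <- function(model, fit, x, levels) {
  switch(model,
    rf = {
      p <- stats::predict(fit, x, type = "prob")
      p[, levels, drop = FALSE]
    },
    svm = {
      keep <- attr(fit, "keep_cols")
      pr <- stats::predict(fit, x[, keep, drop = FALSE], probability = TRUE)
      p <- attr(pr, "probabilities")
      p[, levels, drop = FALSE]
    },
    mlp = {
      sc <- sweep(x, 2, attr(fit, "center"))
      sdv <- attr(fit, "scale")
      sdv[sdv == 0] <- 1
      sc <- sweep(sc, 2, sdv, "/")
      p <- stats::predict(fit, sc)
      colnames(p) <- sub("^y", "", colnames(p))
      p[, levels, drop = FALSE]
    },
    bagging = {
      votes <- sapply(fit$trees, function(tr) {
        as.character(stats::predict(tr, data.frame(x, check.names = FALSE),
                                    type = "class"))
      })
      votes <- matrix(votes, nrow = nrow(x))
      p <- t(apply(votes, 1, function(v)
        tabulate(factor(v, levels = levels), nbins = length(levels))))
      p <- p / length(fit$trees)
      colnames(p) <- levels
      p
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cross-validated CTG classification
#'
#' The central fitting function: stratified k-fold cross-validation of one
#' of four standard classifiers on an encoded feature matrix. Per fold the
#' training portion is (optionally) SMOTE-balanced -- never the test
#' portion -- the model is fitted, and the held-out fold is predicted, so
#' every record receives exactly one out-of-fold prediction. A final model
#' is also fitted on the full data for [predict.ctg_cv()].
#'
#' Models: `"rf"` (random forest, 500 trees), `"svm"` (RBF-kernel SVM with
#' probability estimates), `"mlp"` (single-hidden-layer perceptron with
#' logistic hidden units and softmax output, size 8), `"bagging"`
#' (bootstrap-aggregated classification trees, 25 bags). Hyperparameters
#' live in the `hyper` list (`ntree`, `cost`, `size`, `decay`, `maxit`,
#' `n_bag`).
#'
#' @param x Numeric feature matrix (e.g. from [encode_ctg_features()]), or
#'   a feature data frame which is encoded automatically.
#' @param y Class labels in `{1, 2, 3}` (coercible to factor).
#' @param model One of `"rf"`, `"svm"`, `"mlp"`, `"bagging"`.
#' @param k Number of folds (default 5).
#' @param seed Integer seed fixing folds, SMOTE and model initialization.
#' @param smote Apply SMOTE to each training fold (default `FALSE`).
#' @param hyper Named list of hyperparameter overrides.
#' @return An object of class `ctg_cv`: list with `model`, `k`, `folds`
#'   (fold id per record), `actual`, `predicted` (pooled out-of-fold),
#'   `scores` (per-class probability matrix), `fold_metrics` (k x 9 matrix:
#'   Accuracy, TPR, FPR, Precision, Recall, F-Measure, ROC, kappa, RMSE),
#'   `pooled_accuracy`, `smote`, and `final_fit`.
#' @seealso [fold_metric_correlation()], [confusion()], [evaluate_agreement()]
#' @export
ctg_cv <- function(x, y, model = c("rf", "svm", "mlp", "bagging"), k = 5,
                   seed = 1L, smote = FALSE, hyper = list()) {
  model <- match.arg(model)
  if (is.data.frame(x)) x <- encode_ctg_features(x)
  y <- factor(as.integer(y), levels = sort(unique(as.integer(y))))
  n <- nrow(x)
  stopifnot(length(y) == n)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- stratified_folds(y, k)

  predicted <- factor(rep(NA_character_, n), levels = levels(y))
  scores <- matrix(NA_real_, n, nlevels(y),
                   dimnames = list(NULL, levels(y)))
  fold_metrics <- matrix(NA_real_, k, 9,
                         dimnames = list(paste0("fold", seq_len(k)),
                                         c("Accuracy", "TPR", "FPR",
                                           "Precision", "Recall",
                                           "F-Measure", "ROC", "kappa",
                                           "RMSE")))
  for (i in seq_len(k)) {
    test <- folds == i
    if (length(unique(y[test])) < 2 || length(unique(y[!test])) < 2)
      stop("stratification failure: single-class fold", call. = FALSE)
    xtr <- x[!test, , drop = FALSE]
    ytr <- y[!test]
    if (smote) {
      bal <- smote_balance(xtr, ytr)
      xtr <- bal$x
      ytr <- bal$y
    }
    fit <- fit_model(model, xtr, ytr, hyper)
    sc <- predict_scores(model, fit, x[test, , drop = FALSE], levels(y))
    pred <- factor(levels(y)[max.col(sc, ties.method = "first")],
                   levels = levels(y))
    predicted[test] <- pred
    scores[test, ] <- sc
    fold_metrics[i, ] <- fold_metric_set(y[test], pred, sc)
  }

  final_fit <- fit_model(model, x, y, hyper)
  out <- list(model = model, k = k, folds = folds, actual = y,
              predicted = predicted, scores = scores,
              fold_metrics = fold_metrics,
              pooled_accuracy = mean(predicted == y),
              smote = smote, seed = seed,
              feature_names = colnames(x), final_fit = final_fit,
              hyper = hyper)
  class(out) <- "ctg_cv"
  out
}

# the nine-element per-fold metric set (support-weighted one-vs-rest)
fold_metric_set <- function(actual, predicted, scores) {
  lv <- levels(actual)
  n <- length(actual)
  acc <- mean(predicted == actual)
  tpr <- fpr <- prec <- f1 <- 0
  for (cl in lv) {
    w <- mean(actual == cl)
    tp <- sum(actual == cl & predicted == cl)
    fn <- sum(actual == cl & predicted != cl)
    fp <- sum(actual != cl & predicted == cl)
    tn <- n - tp - fn - fp
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    tpr <- tpr + w * r
    fpr <- fpr + w * (if (fp + tn > 0) fp / (fp + tn) else 0)
    prec <- prec + w * p
    f1 <- f1 + w * (if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
  auc <- multiclass_auc(scores, actual)$macro_auc
  po <- acc
  pe <- sum(table(actual) / n * table(factor(predicted, levels = lv)) / n)
  kap <- if (pe < 1) (po - pe) / (1 - pe) else 1
  rmse <- sqrt(mean((as.numeric(as.character(actual)) -
                       as.numeric(as.character(predicted)))^2))
  c(acc, tpr, fpr, prec, tpr, f1, auc, kap, rmse)
}

#' @export
print.ctg_cv <- function(x, ...) {
  cat(sprintf("<ctg_cv> %s, %d-fold stratified CV%s, n = %d\n",
              toupper(x$model), x$k,
              if (x$smote) " with SMOTE-balanced training folds" else "",
              length(x$actual)))
  cat(sprintf("  pooled out-of-fold accuracy: %.3f\n", x$pooled_accuracy))
  invisible(x)
}

#' @export
summary.ctg_cv <- function(object, ...) {
  cat(sprintf("%s, %d-fold stratified cross-validation (n = %d)\n",
              toupper(object$model), object$k, length(object$actual)))
  cat("\nPer-fold metrics:\n")
  print(round(object$fold_metrics, 3))
  cat("\nPooled out-of-fold confusion matrix:\n")
  print(confusion(object$actual, object$predicted))
  invisible(object)
}

#' Predict from a cross-validated classifier
#'
#' Applies the final model (fitted on the full data) to new feature rows;
#' with `newdata = NULL` the pooled out-of-fold predictions are returned.
#'
#' @param object A `ctg_cv` fit.
#' @param newdata Feature matrix or data frame, or `NULL`.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @return Factor of classes, or a probability matrix.
#' @export
predict.ctg_cv <- function(object, newdata = NULL,
                           type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    if (type == "class") return(object$predicted)
    return(object$scores)
  }
  if (is.data.frame(newdata)) newdata <- encode_ctg_features(newdata)
  lv <- levels(object$actual)
  sc <- predict_scores(object$model, object$final_fit, newdata, lv)
  if (type == "prob") return(sc)
  factor(lv[max.col(sc, ties.method = "first")], levels = lv)
}

#' Plot pooled one-vs-rest ROC curves
#'
#' One ROC curve per class from the pooled out-of-fold scores.
#'
#' @param x A `ctg_cv` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ctg_cv <- function(x, ...) {
  lv <- levels(x$actual)
  cols <- c("#1b6ca8", "#d1495b", "#66a182")
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("%s: pooled one-vs-rest ROC", toupper(x$model)),
                 ...)
  for (j in seq_along(lv)) {
    pos <- x$actual == lv[j]
    sc <- x$scores[, lv[j]]
    th <- sort(unique(sc), decreasing = TRUE)
    tprv <- vapply(th, function(t) mean(sc[pos] >= t), numeric(1))
    fprv <- vapply(th, function(t) mean(sc[!pos] >= t), numeric(1))
    graphics::lines(c(0, fprv, 1), c(0, tprv, 1), col = cols[j], lwd = 2)
  }
  graphics::legend("bottomright", legend = paste("class", lv), col = cols,
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Per-fold correlation of classifier metric vectors
#'
#' For each fold, the Pearson correlation between the 9-metric vectors of
#' every pair of fitted classifiers: a high off-diagonal correlation means
#' the classifiers behave alike under the chosen fold configuration. A
#' zero-variance metric vector makes the correlation undefined; the entry
#' is reported `NA`.
#'
#' @param results Named list of `ctg_cv` fits sharing the same folds.
#' @return A list (one per fold) of symmetric correlation matrices with
#'   unit diagonal.
#' @export
fold_metric_correlation <- function(results) {
  stopifnot(length(results) >= 2)
  k <- results[[1]]$k
  for (r in results) {
    if (r$k != k || !identical(r$folds, results[[1]]$folds))
      stop("all results must share the same folds", call. = FALSE)
  }
  nm <- names(results)
  if (is.null(nm)) nm <- paste0("model", seq_along(results))
  lapply(seq_len(k), function(i) {
    m <- sapply(results, function(r) r$fold_metrics[i, ])
    cc <- suppressWarnings(stats::cor(m))
    diag(cc) <- 1
    dimnames(cc) <- list(nm, nm)
    cc
  })
}
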