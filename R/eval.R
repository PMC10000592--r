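#' 3-class confusion matrix
#'
#' Tabulates actual vs predicted labels over the three fetal-state classes
#' (1 Normal, 2 Suspicious, 3 Pathological). Rows are the actual class,
#' columns the predicted class.
#'
#' @param actual,predicted Vectors of labels in `{1, 2, 3}` (or factors on
#'   those levels), equal length, non-empty.
#' @return A 3x3 integer matrix of class `ctg_confusion`.
#' @export
confusion <- function(actual, predicted) {
  actual <- as.integer(as.character(actual))
  predicted <- as.integer(as.character(predicted))
  if (!length(actual)) stop("empty input", call. = FALSE)
  if (length(actual) != length(predicted))
    stop("actual and predicted must have equal length", call. = FALSE)
  if (!all(actual %in% 1:3) || !all(predicted %in% 1:3))
    stop("labels must lie in {1, 2, 3}", call. = FALSE)
  m <- table(factor(actual, levels = 1:3),
             factor(predicted, levels = 1:3))
  m <- matrix(as.integer(m), 3, 3,
              dimnames = list(actual = 1:3, predicted = 1:3))
  class(m) <- c("ctg_confusion", class(m))
  m
}

#' @export
print.ctg_confusion <- function(x, ...) {
  m <- unclass(x)
  print(m)
  invisible(x)
}

#' Coerce a plain 3x3 count matrix to `ctg_confusion`
#'
#' @param m 3x3 non-negative integer matrix (rows = actual).
#' @return A `ctg_confusion` matrix.
#' @export
as_confusion <- function(m) {
  m <- as.matrix(m)
  stopifnot(all(dim(m) == c(3, 3)), all(m >= 0))
  m <- matrix(as.integer(round(m)), 3, 3,
              dimnames = list(actual = 1:3, predicted = 1:3))
  class(m) <- c("ctg_confusion", class(m))
  m
}

#' Expand a confusion matrix into label pairs
#'
#' Produces one `(actual, predicted)` pair per counted record -- the
#' canonical sequence realizing the matrix. Any ordering of these pairs
#' yields the same agreement statistics, so the canonical order suffices.
#'
#' @param cm A `ctg_confusion` (or 3x3 count matrix).
#' @return A list with integer vectors `actual` and `predicted`.
#' @export
realize_pairs <- function(cm) {
  cm <- as_confusion(cm)
  actual <- predicted <- integer(0)
  for (a in 1:3) for (p in 1:3) {
    actual <- c(actual, rep.int(a, cm[a, p]))
    predicted <- c(predicted, rep.int(p, cm[a, p]))
  }
  list(actual = actual, predicted = predicted)
}

#' Model performance metrics from a confusion matrix
#'
#' Accuracy is the trace over the total; sensitivity (= recall),
#' specificity and precision are one-vs-rest per class, averaged either
#' weighted by class support (default; under this convention sensitivity
#' equals accuracy) or unweighted (`"macro"`). An empty actual class is
#' excluded from the average with a warning.
#'
#' @param cm A `ctg_confusion` or 3x3 count matrix.
#' @param average `"weighted"` or `"macro"`.
#' @return A list of class `ctg_metrics`: `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, plus `per_class` (matrix of the
#'   one-vs-rest components).
#' @export
model_metrics <- function(cm, average = c("weighted", "macro")) {
  average <- match.arg(average)
  cm <- as_confusion(cm)
  n <- sum(cm)
  stopifnot(n > 0)
  per <- matrix(NA_real_, 3, 4,
                dimnames = list(1:3, c("sensitivity", "specificity",
                                       "precision", "support")))
  for (k in 1:3) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- n - tp - fn - fp
    per[k, ] <- c(if (tp + fn > 0) tp / (tp + fn) else NA,
                  if (tn + fp > 0) tn / (tn + fp) else NA,
                  if (tp + fp > 0) tp / (tp + fp) else NA,
                  tp + fn)
  }
  empty <- per[, "support"] == 0
  if (any(empty))
    warning("class(es) ", paste(which(empty), collapse = ", "),
            " have no actual records; excluded from averaging",
            call. = FALSE)
  w <- if (average == "weighted") per[, "support"] / n
       else as.numeric(!empty) / sum(!empty)
  w[empty] <- 0
  avg <- function(col) sum(w * per[, col], na.rm = TRUE)
  out <- list(accuracy = sum(diag(cm)) / n,
              sensitivity = avg("sensitivity"),
              specificity = avg("specificity"),
              precision = avg("precision"),
              average = average, per_class = per)
  class(out) <- "ctg_metrics"
  out
}

#' Combined performance measures from a confusion matrix
#'
#' The measures built from sensitivity and specificity plus the chance-
#' corrected agreement statistics: geometric mean `sqrt(sens * spec)`;
#' discriminant power `(sqrt(3)/pi) * (ln(sens/(1-spec)) + ln(spec/(1-sens)))`
#' (reported `Inf` when sensitivity or specificity touches 0 or 1);
#' balanced accuracy `(macro sensitivity + macro specificity)/2`;
#' multiclass Matthews correlation; Cohen's kappa; and Youden's index
#' `sens + spec - 1`.
#'
#' @param cm A `ctg_confusion` or 3x3 count matrix.
#' @param sens,spec Sensitivity/specificity to build the combined measures
#'   from; default to the support-weighted values of [model_metrics()].
#' @return A list of class `ctg_metrics` with `g_mean`,
#'   `discriminant_power`, `balanced_accuracy`, `mcc`, `kappa`, `youden`.
#' @export
combined_metrics <- function(cm, sens = NULL, spec = NULL) {
  cm <- as_confusion(cm)
  mm <- model_metrics(cm)
  if (is.null(sens)) sens <- mm$sensitivity
  if (is.null(spec)) spec <- mm$specificity
  dp <- if (sens <= 0 || sens >= 1 || spec <= 0 || spec >= 1) Inf else
    (sqrt(3) / pi) * (log(sens / (1 - spec)) + log(spec / (1 - sens)))
  macro <- model_metrics(cm, average = "macro")
  out <- list(g_mean = sqrt(sens * spec),
              discriminant_power = dp,
              balanced_accuracy = (macro$sensitivity + macro$specificity) / 2,
              mcc = mcc_multiclass(cm),
              kappa = cohen_kappa(cm),
              youden = sens + spec - 1,
              sensitivity = sens, specificity = spec)
  class(out) <- "ctg_metrics"
  out
}

#' Cohen's kappa from a confusion matrix
#'
#' `(po - pe) / (1 - pe)` with observed agreement `po = trace/n` and chance
#' agreement `pe` from the row/column margin products.
#'
#' @param cm 3x3 count matrix.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}

#' Multiclass Matthews correlation coefficient
#'
#' The covariance form:
#' `(c*s - sum(p_k t_k)) / sqrt((s^2 - sum(p_k^2)) (s^2 - sum(t_k^2)))`
#' with `c` the trace, `s` the total, `p_k`/`t_k` the predicted/actual
#' margins.
#'
#' @param cm Square count matrix.
#' @return MCC in `[-1, 1]` (`NA` if a denominator term vanishes).
#' @export
mcc_multiclass <- function(cm) {
  cm <- as.matrix(cm)
  s <- sum(cm)
  c_ <- sum(diag(cm))
  pk <- colSums(cm)
  tk <- rowSums(cm)
  den <- sqrt((s^2 - sum(pk^2)) * (s^2 - sum(tk^2)))
  if (den == 0) return(NA_real_)
  (c_ * s - sum(pk * tk)) / den
}

#' Pearson chi-squared test of independence on a confusion matrix
#'
#' Tests whether the actual and predicted classifications are independent:
#' `X2 = sum (O - E)^2 / E` with expected counts from the margin products,
#' df = 4 for a 3x3 table, compared against the chi-squared critical value
#' at level `alpha`.
#'
#' @param cm A `ctg_confusion` or 3x3 count matrix with positive margins.
#' @param alpha Significance level (default 0.05).
#' @return A list of class `ctg_chi2`: `chi2`, `df`, `p_value`,
#'   `critical_value`, `reject` (logical), `expected`.
#' @export
chi2_independence <- function(cm, alpha = 0.05) {
  cm <- as_confusion(cm)
  if (any(rowSums(cm) == 0) || any(colSums(cm) == 0))
    stop("expected counts undefined: zero row or column margin",
         call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(unclass(cm), correct = FALSE))
  crit <- stats::qchisq(1 - alpha, ht$parameter)
  out <- list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
              p_value = unname(ht$p.value), critical_value = crit,
              reject = unname(ht$statistic) > crit, alpha = alpha,
              expected = ht$expected)
  class(out) <- "ctg_chi2"
  out
}

#' @export
print.ctg_chi2 <- function(x, ...) {
  cat(sprintf("Chi-squared independence test: X2 = %.3f, df = %d, %s\n",
              x$chi2, x$df,
              if (x$p_value < 1e-4) "p < 0.0001"
              else sprintf("p = %.4f", x$p_value)))
  cat(sprintf("  critical value at alpha = %.2f: %.3f -> %s H0\n",
              x$alpha, x$critical_value,
              if (x$reject) "reject" else "retain"))
  invisible(x)
}

#' Bland-Altman agreement between actual and predicted classes
#'
#' Treats the class labels as a 1--3 scale and summarizes the per-record
#' differences `d = actual - predicted`: the bias (mean difference), the
#' 95% limits of agreement `mean(d) +/- 1.96 sd(d)`, normal-theory 95%
#' confidence intervals for the bias (`se = sd/sqrt(n)`) and for each limit
#' (`se = sd * sqrt(3/n)`), and the least-squares slope/intercept of the
#' difference on the pair mean `(actual + predicted)/2` (a proportional-
#' bias check). The SD uses the population (n) denominator by default;
#' `"n-1"` is available.
#'
#' @param actual,predicted Label vectors in `{1, 2, 3}`, length >= 2.
#' @param sd_denominator `"n"` (default) or `"n-1"`.
#' @param conf Confidence level for the intervals (default 0.95).
#' @return A list of class `ctg_bland_altman`: `mean_diff`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, each with a `*_ci` two-vector, plus
#'   `slope`, `intercept` with CIs, and `n`.
#' @export
bland_altman <- function(actual, predicted, sd_denominator = c("n", "n-1"),
                         conf = 0.95) {
  sd_denominator <- match.arg(sd_denominator)
  actual <- as.numeric(as.character(actual))
  predicted <- as.numeric(as.character(predicted))
  n <- length(actual)
  if (n < 2 || length(predicted) != n)
    stop("need equal-length vectors with n >= 2", call. = FALSE)
  d <- actual - predicted
  m <- (actual + predicted) / 2
  md <- mean(d)
  sdd <- if (sd_denominator == "n") sqrt(mean((d - md)^2)) else stats::sd(d)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  loa_l <- md - 1.96 * sdd
  loa_u <- md + 1.96 * sdd
  se_md <- sdd / sqrt(n)
  se_loa <- sdd * sqrt(3 / n)
  if (stats::var(m) > 0) {
    fit <- stats::lm(d ~ m)
    cf <- stats::coef(fit)
    ci <- stats::confint(fit, level = conf)
    slope <- unname(cf[2]); intercept <- unname(cf[1])
    slope_ci <- unname(ci[2, ]); intercept_ci <- unname(ci[1, ])
  } else {
    slope <- intercept <- NA_real_
    slope_ci <- intercept_ci <- c(NA_real_, NA_real_)
  }
  out <- list(n = n, mean_diff = md, sd_diff = sdd,
              mean_diff_ci = c(md - z * se_md, md + z * se_md),
              loa_lower = loa_l,
              loa_lower_ci = c(loa_l - z * se_loa, loa_l + z * se_loa),
              loa_upper = loa_u,
              loa_upper_ci = c(loa_u - z * se_loa, loa_u + z * se_loa),
              slope = slope, slope_ci = slope_ci,
              intercept = intercept, intercept_ci = intercept_ci,
              sd_denominator = sd_denominator, conf = conf)
  class(out) <- "ctg_bland_altman"
  out
}

#' @export
print.ctg_bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  bias (mean diff): %6.3f  [%.3f, %.3f]\n", x$mean_diff,
              x$mean_diff_ci[1], x$mean_diff_ci[2]))
  cat(sprintf("  upper LoA:        %6.3f  [%.3f, %.3f]\n", x$loa_upper,
              x$loa_upper_ci[1], x$loa_upper_ci[2]))
  cat(sprintf("  lower LoA:        %6.3f  [%.3f, %.3f]\n", x$loa_lower,
              x$loa_lower_ci[1], x$loa_lower_ci[2]))
  if (!is.na(x$slope))
    cat(sprintf("  diff ~ mean: intercept %.3f, slope %.3f\n",
                x$intercept, x$slope))
  invisible(x)
}

#' Full agreement report for one classifier
#'
#' Bundles the confusion matrix, model metrics, combined measures,
#' chi-squared independence test and Bland-Altman analysis for one
#' actual/predicted pair of label vectors.
#'
#' @param actual,predicted Label vectors in `{1, 2, 3}`.
#' @param alpha Chi-squared significance level.
#' @return A list of class `ctg_agreement` with elements `cm`, `metrics`,
#'   `combined`, `chi2`, `bland_altman`.
#' @export
evaluate_agreement <- function(actual, predicted, alpha = 0.05) {
  cm <- confusion(actual, predicted)
  out <- list(cm = cm,
              metrics = model_metrics(cm),
              combined = combined_metrics(cm),
              chi2 = chi2_independence(cm, alpha),
              bland_altman = bland_altman(actual, predicted))
  class(out) <- "ctg_agreement"
  out
}

#' @export
print.ctg_agreement <- function(x, ...) {
  cat("Confusion matrix (rows = actual):\n")
  print(unclass(x$cm))
  m <- x$metrics
  cat(sprintf("accuracy %.3f | sensitivity %.3f | specificity %.3f | precision %.3f\n",
              m$accuracy, m$sensitivity, m$specificity, m$precision))
  cmb <- x$combined
  cat(sprintf("G-mean %.3f | DP %.3f | bal.acc %.3f | MCC %.3f | kappa %.3f | Youden %.3f\n",
              cmb$g_mean, cmb$discriminant_power, cmb$balanced_accuracy,
              cmb$mcc, cmb$kappa, cmb$youden))
  print(x$chi2)
  print(x$bland_altman)
  invisible(x)
}

#' Kaiser-Meyer-Olkin adequacy and Bartlett's sphericity test
#'
#' KMO compares the observed correlations with the anti-image partial
#' correlations: `sum r^2 / (sum r^2 + sum a^2)` over the off-diagonal
#' entries, where `a_ij = -inv(R)_ij / sqrt(inv(R)_ii inv(R)_jj)`. A value
#' near 1 means the variables share enough common variance for factor
#' analysis. Bartlett's statistic `-(n - 1 - (2p + 5)/6) ln det(R)` tests
#' sphericity (all correlations zero) against chi-squared with
#' `p (p - 1)/2` df.
#'
#' @param x Numeric matrix/data frame (rows = observations > columns).
#' @return A list of class `ctg_kmo`: `kmo`, `bartlett_chi2`, `df`,
#'   `p_value`, `n`, `p`.
#' @export
kmo_bartlett <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n <= p) stop("need more observations than variables", call. = FALSE)
  R <- stats::cor(x)
  if (anyNA(R)) stop("correlation matrix undefined (constant column?)",
                     call. = FALSE)
  detR <- det(R)
  if (detR < .Machine$double.eps)
    stop("singular correlation matrix: a variable is (nearly) a linear ",
         "combination of the others", call. = FALSE)
  Rinv <- solve(R)
  A <- -Rinv / sqrt(outer(diag(Rinv), diag(Rinv)))
  off <- upper.tri(R)
  kmo <- sum(R[off]^2) / (sum(R[off]^2) + sum(A[off]^2))
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * log(detR)
  df <- p * (p - 1) / 2
  out <- list(kmo = kmo, bartlett_chi2 = chi2, df = df,
              p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
              n = n, p = p)
  class(out) <- "ctg_kmo"
  out
}

#' @export
print.ctg_kmo <- function(x, ...) {
  cat(sprintf("KMO sampling adequacy: %.3f\n", x$kmo))
  cat(sprintf("Bartlett sphericity: chi2 = %.3f, df = %d, %s\n",
              x$bartlett_chi2, x$df,
              if (x$p_value < 1e-4) "p < 0.0001"
              else sprintf("p = %.4f", x$p_value)))
  invisible(x)
}

#' Eigenvalues of the feature correlation matrix (scree)
#'
#' Descending eigenvalues of the correlation matrix; their sum equals the
#' number of columns. The scree inflexion point suggests how many features
#' carry distinct information.
#'
#' @inheritParams kmo_bartlett
#' @return Numeric vector of eigenvalues, descending.
#' @export
scree_eigenvalues <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) <= ncol(x)) stop("need more observations than variables",
                               call. = FALSE)
  R <- stats::cor(x)
  if (anyNA(R)) stop("correlation matrix undefined (constant column?)",
                     call. = FALSE)
  sort(eigen(R, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}

#' One-vs-rest multiclass AUC
#'
#' For every class, the area under the ROC curve of that class's score
#' against all other classes, computed by the rank (Mann-Whitney) formula
#' with midpoint handling of ties; the macro AUC is their unweighted mean.
#' A class absent from `actual` has undefined AUC, reported `NA` and
#' excluded from the macro mean.
#'
#' @param scores Numeric matrix, one column of scores per class (columns
#'   named with the class labels, or in class order).
#' @param actual Vector/factor of actual classes.
#' @return A list with `per_class` (named numeric) and `macro_auc`.
#' @export
multiclass_auc <- function(scores, actual) {
  actual <- factor(actual)
  lv <- levels(actual)
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) colnames(scores) <- lv
  per <- stats::setNames(rep(NA_real_, length(lv)), lv)
  for (cl in lv) {
    pos <- actual == cl
    n1 <- sum(pos)
    n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) next
    r <- rank(scores[, cl], ties.method = "average")
    per[cl] <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(per_class = per,
       macro_auc = if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE))
}

#' Round half away from zero
#'
#' Display rounding used in the report tables (2.5 -> 3, -2.5 -> -3),
#' unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 3) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
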