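tables <- stage1_contingency_tables()

test_that("confusion tabulates labels and rejects bad input", {
  cm <- confusion(c(1, 2, 3, 3), c(1, 2, 3, 3))
  expect_equal(sum(diag(cm)), 4)
  expect_equal(sum(cm) - sum(diag(cm)), 0)
  expect_error(confusion(integer(0), integer(0)), "empty")
  expect_error(confusion(c(1, 4), c(1, 1)), "labels")
  expect_error(confusion(c(1, 2), c(1)), "equal length")
})

test_that("the reference contingency tables carry the published margins", {
  m <- tables$mlp
  expect_equal(unname(rowSums(m)), c(137, 154, 108))
  expect_equal(sum(m), 399)
  for (t in tables) expect_equal(sum(t), 399)
})

test_that("model metrics reproduce the published accuracy values", {
  expect_equal(model_metrics(tables$mlp)$accuracy, 0.927, tolerance = 1e-3)
  expect_equal(model_metrics(tables$rf)$accuracy, 0.967, tolerance = 1e-3)
  mm <- model_metrics(diag(c(5, 7, 9)))
  expect_equal(mm$accuracy, 1)
  expect_equal(mm$sensitivity, 1)
  expect_equal(mm$specificity, 1)
  expect_equal(mm$precision, 1)
  # support-weighted sensitivity coincides with accuracy
  expect_equal(model_metrics(tables$svm)$sensitivity,
               model_metrics(tables$svm)$accuracy)
})

test_that("combined measures reproduce the published kappa values", {
  expect_equal(combined_metrics(tables$mlp)$kappa, 0.889, tolerance = 1e-3)
  expect_equal(combined_metrics(tables$rf)$kappa, 0.950, tolerance = 1e-3)
  perfect <- combined_metrics(diag(c(10, 10, 10)))
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$youden, 1)
  expect_true(is.infinite(perfect$discriminant_power))
})

test_that("kappa and MCC agree with independent formula implementations", {
  set.seed(3)
  for (i in 1:25) {
    m <- matrix(rpois(9, 30) + 1, 3, 3)
    expect_equal(cohen_kappa(m), kappa_oracle(m), tolerance = 1e-9)
    expect_equal(mcc_multiclass(m), mcc_oracle(m), tolerance = 1e-9)
    # kappa cannot exceed accuracy when chance agreement is positive
    expect_lte(cohen_kappa(m), sum(diag(m)) / sum(m) + 1e-12)
  }
  # kappa is 1 iff the off-diagonal vanishes
  expect_equal(cohen_kappa(diag(c(3, 4, 5))), 1)
  expect_lt(cohen_kappa(matrix(c(10, 1, 0, 0, 10, 0, 0, 0, 10), 3, 3)), 1)
})

test_that("chi-squared equals the brute-force double loop and the published values", {
  expect_equal(chi2_independence(tables$mlp)$chi2, 624.194, tolerance = 5e-4)
  expect_equal(chi2_independence(tables$svm)$chi2, 723.633, tolerance = 5e-4)
  set.seed(8)
  for (i in 1:25) {
    m <- matrix(rpois(9, 25) + 1, 3, 3)
    ht <- chi2_independence(m)
    expect_equal(ht$chi2, chi2_brute(m), tolerance = 1e-9)
    expect_equal(ht$df, 4)
    # invariance under row/column permutation
    pr <- sample(3); pc <- sample(3)
    expect_equal(chi2_independence(m[pr, pc])$chi2, ht$chi2,
                 tolerance = 1e-9)
  }
  # observed equal to expected -> statistic 0
  rs <- c(40, 60, 100); cs <- c(50, 70, 80)
  e <- outer(rs, cs) / 200
  expect_equal(chi2_independence(round(e * 5))$chi2, 0, tolerance = 1e-9)
  expect_error(chi2_independence(matrix(c(1, 1, 0, 1, 1, 0, 1, 1, 0),
                                        3, 3, byrow = TRUE)), "margin")
})

test_that("Bland-Altman reproduces published limits and is order independent", {
  pr <- realize_pairs(tables$rf)
  ba <- bland_altman(pr$actual, pr$predicted)
  expect_equal(round_half_away(ba$mean_diff, 2), -0.02)
  expect_equal(round_half_away(ba$loa_lower, 2), -0.64)
  expect_equal(round_half_away(ba$loa_upper, 2), 0.60)

  prs <- realize_pairs(tables$svm)
  bas <- bland_altman(prs$actual, prs$predicted)
  expect_equal(round_half_away(bas$loa_lower, 2), -0.59)
  expect_equal(round_half_away(bas$loa_upper, 2), 0.58)

  # any sequence realizing the same matrix gives identical agreement
  set.seed(12)
  o <- sample(length(pr$actual))
  ba2 <- bland_altman(pr$actual[o], pr$predicted[o])
  expect_equal(ba2$mean_diff, ba$mean_diff)
  expect_equal(ba2$loa_lower, ba$loa_lower)
  expect_equal(ba2$loa_upper, ba$loa_upper)

  ident <- bland_altman(c(1, 2, 3, 2), c(1, 2, 3, 2))
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$loa_lower, 0)
  expect_equal(ident$loa_upper, 0)
  expect_error(bland_altman(1, 1), "n >= 2")
})

test_that("KMO and Bartlett match an independent reference computation", {
  # two-factor structure, frozen via the default RNG; reference values
  # computed once with an independent NumPy implementation of the
  # anti-image formula
  set.seed(42)
  n <- 120
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- cbind(f1 + 0.5 * rnorm(n), f1 + 0.5 * rnorm(n), f1 + 0.5 * rnorm(n),
             f2 + 0.5 * rnorm(n), f2 + 0.5 * rnorm(n), f2 + 0.5 * rnorm(n))
  k <- kmo_bartlett(x)
  expect_equal(k$kmo, 0.761278, tolerance = 1e-5)
  expect_equal(k$bartlett_chi2, 500.7462, tolerance = 1e-5)
  expect_equal(k$df, 15)
  expect_lt(k$p_value, 1e-10)

  # a clear factor structure at n = 400 is comfortably adequate
  set.seed(7)
  n <- 400
  g1 <- rnorm(n); g2 <- rnorm(n)
  x2 <- cbind(g1 + 0.5 * rnorm(n), g1 + 0.5 * rnorm(n),
              g1 + 0.5 * rnorm(n), g2 + 0.5 * rnorm(n),
              g2 + 0.5 * rnorm(n), g2 + 0.5 * rnorm(n))
  expect_gte(kmo_bartlett(x2)$kmo, 0.7)

  # independent columns: Bartlett statistic near zero
  set.seed(9)
  xi <- matrix(rnorm(5000 * 5), ncol = 5)
  expect_lt(kmo_bartlett(xi)$bartlett_chi2, 30)

  # a duplicated column makes the correlation matrix singular
  expect_error(kmo_bartlett(cbind(x, x[, 1])), "singular")
})

test_that("scree eigenvalues sum to the column count and expose rank-1 structure", {
  set.seed(14)
  xi <- matrix(rnorm(600 * 6), ncol = 6)
  ev <- scree_eigenvalues(xi)
  expect_equal(sum(ev), 6, tolerance = 1e-9)
  expect_true(all(abs(ev - 1) < 0.3))
  f <- rnorm(600)
  xr <- sapply(1:6, function(i) f + 0.3 * rnorm(600))
  evr <- scree_eigenvalues(xr)
  expect_gt(evr[1], 3)
  expect_gt(evr[1], 5 * evr[2])
})

test_that("one-vs-rest AUC behaves at the extremes and matches pROC", {
  actual <- c(1, 1, 2, 2, 3, 3)
  perfect <- rbind(c(.9, .05, .05), c(.8, .1, .1), c(.1, .8, .1),
                   c(.2, .7, .1), c(.1, .1, .8), c(.05, .05, .9))
  colnames(perfect) <- 1:3
  expect_equal(multiclass_auc(perfect, actual)$macro_auc, 1)
  # anti-ranking: negate the scores (strictly decreasing transform)
  expect_equal(multiclass_auc(-perfect, actual)$macro_auc, 0)

  set.seed(15)
  n <- 4000
  act <- sample(1:3, n, replace = TRUE)
  sc <- matrix(runif(3 * n), ncol = 3, dimnames = list(NULL, 1:3))
  expect_equal(multiclass_auc(sc, act)$macro_auc, 0.5, tolerance = 0.03)

  # invariance under a strictly monotone transform of the scores
  a1 <- multiclass_auc(sc, act)$per_class
  a2 <- multiclass_auc(exp(3 * sc), act)$per_class
  expect_equal(a1, a2)

  for (cl in 1:3) {
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(act == cl, sc[, cl], quiet = TRUE,
                          direction = "<"))))
    expect_equal(unname(a1[as.character(cl)]), ref, tolerance = 1e-12)
  }
})

test_that("the agreement report bundles consistent components", {
  pr <- realize_pairs(tables$bagging)
  rep_ <- evaluate_agreement(pr$actual, pr$predicted)
  expect_s3_class(rep_, "ctg_agreement")
  expect_equal(sum(rep_$cm), 399)
  expect_equal(rep_$chi2$chi2, 650.510, tolerance = 5e-4)
  expect_equal(rep_$chi2$critical_value, 9.488, tolerance = 5e-4)
  expect_true(rep_$chi2$reject)
  expect_output(print(rep_), "Confusion matrix")
})
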