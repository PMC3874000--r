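test_that("probit transform maps percentages to normal quantiles monotonely", {
  expect_equal(probit_transform(50), 0)
  expect_equal(probit_transform(97.5), qnorm(0.975))
  expect_lt(abs(probit_transform(97.5) - 1.96), 0.001)
  expect_error(probit_transform(c(5, 101)), "\\[0, 100\\]")
  expect_error(probit_transform(-2), "\\[0, 100\\]")
  # endpoints stay finite through the clamp
  expect_true(all(is.finite(probit_transform(c(0, 100)))))
  set.seed(2)
  x <- runif(50, 0, 100)
  expect_true(all(diff(probit_transform(sort(x))) >= 0))
  r <- probit_transform(x, mode = "rank_INT")
  expect_equal(order(r), order(x))
})

test_that("empirical ROC reproduces pair counting and the textbook anchors", {
  # malignant {3,5} vs benign {1,4}: 3 of 4 pairs concordant
  roc <- empirical_roc(c(3, 5, 1, 4), c(1, 1, 0, 0))
  expect_equal(roc$auc_empirical, 0.75)
  expect_equal(roc$operating_points$sensitivity[1], 0)
  op <- roc$operating_points
  expect_equal(op$sensitivity[nrow(op)], 1)
  expect_equal(op$one_minus_specificity[nrow(op)], 1)

  # perfectly separated classes
  sep <- empirical_roc(c(1, 2, 3, 10, 11, 12), rep(c(0, 1), each = 3))
  expect_equal(sep$auc_empirical, 1.0)

  # random samples: AUC equals the pair-counting oracle, with ties present
  set.seed(6)
  for (k in 1:8) {
    sc <- sample(1:12, 30, TRUE)
    lb <- rbinom(30, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(suppressWarnings(empirical_roc(sc, lb)$auc_empirical),
                 auc_pair_count(sc, lb))
  }
  expect_error(empirical_roc(1:5, rep(1, 5)), "both classes")
})

test_that("ROC operating points are monotone and agree with pROC", {
  set.seed(44)
  sc <- c(rnorm(40), rnorm(40, 1))
  lb <- rep(c(0, 1), each = 40)
  roc <- empirical_roc(sc, lb)
  op <- roc$operating_points
  expect_true(all(diff(op$sensitivity) >= 0))
  expect_true(all(diff(op$one_minus_specificity) >= 0))
  skip_if_not_installed("pROC")
  ref <- pROC::roc(lb, sc, quiet = TRUE, direction = "<")
  expect_equal(roc$auc_empirical, as.numeric(pROC::auc(ref)))
})

test_that("empirical AUC is rank-identical to U and antisymmetric", {
  set.seed(10)
  sc <- rgamma(60, 2); lb <- rbinom(60, 1, 0.4)
  roc <- suppressWarnings(empirical_roc(sc, lb))  # chance-level orientation
  u <- mann_whitney_u(sc[lb == 1], sc[lb == 0])$U
  expect_equal(roc$auc_empirical, u / (sum(lb == 1) * sum(lb == 0)))
  flipped <- suppressWarnings(empirical_roc(-sc, lb))
  expect_equal(flipped$auc_empirical, 1 - roc$auc_empirical)
  # invariance under the (monotone) probit transform of percent scores
  af <- runif(60, 0.1, 99.9)
  lb2 <- rbinom(60, 1, 0.5)
  expect_equal(empirical_roc(probit_transform(af), lb2)$auc_empirical,
               empirical_roc(af, lb2)$auc_empirical)
})

test_that("binormal ROC follows the closed form and matches simulation", {
  expect_error(binormal_roc(c(1, 1, 2, 2), c(0, 0, 1, 1)), "zero within-class")
  set.seed(15)
  eq <- binormal_roc(c(rnorm(200, 5, 1), rnorm(200, 5, 1)),
                     rep(c(0, 1), each = 200))
  expect_lt(abs(eq$auc_binormal - 0.5), 0.05)

  x0 <- rnorm(2e4, 0, 1); x1 <- rnorm(2e4, 1, 1)
  fit <- binormal_roc(c(x0, x1), rep(c(0, 1), each = 2e4))
  expect_lt(abs(fit$a - 1), 0.05)
  expect_lt(abs(fit$b - 1), 0.05)
  expect_lt(abs(fit$auc_binormal - pnorm(1 / sqrt(2))), 0.01)
  # empirical AUC of the same normal data agrees with the binormal closed form
  emp <- empirical_roc(c(x0, x1), rep(c(0, 1), each = 2e4))$auc_empirical
  expect_lt(abs(emp - fit$auc_binormal), 0.01)
})

test_that("operating points report sensitivity, specificity and LRs by counting", {
  set.seed(19)
  sc <- sample(1:20, 50, TRUE)
  lb <- rbinom(50, 1, 0.5)
  roc <- empirical_roc(sc, lb)
  for (crit in c(5, 10, 15)) {
    op <- operating_point(roc, crit)
    sens_direct <- sum(sc > crit & lb == 1) / sum(lb == 1)
    spec_direct <- sum(sc <= crit & lb == 0) / sum(lb == 0)
    expect_equal(op$sensitivity, sens_direct)
    expect_equal(op$specificity, spec_direct)
    if (spec_direct < 1)
      expect_equal(op$lr_plus, sens_direct / (1 - spec_direct))
  }
  # the direct-formula anchor: sens 0.7, spec 0.6 gives LR+ = 1.75
  expect_equal(0.7 / (1 - 0.6), 1.75)
  perfect <- empirical_roc(c(1, 2, 3, 4), c(0, 0, 1, 1))
  op <- operating_point(perfect, 2)
  expect_equal(op$specificity, 1)
  expect_true(is.infinite(op$lr_plus))
  expect_error(operating_point(roc, 1e6), "range")
})

test_that("two-marker logistic regression matches a direct-likelihood oracle", {
  set.seed(26)
  x1 <- rnorm(80); x2 <- rnorm(80)
  y <- rbinom(80, 1, plogis(0.3 + 0.8 * x1 - 0.5 * x2))
  fit <- fit_logistic_pair(x1, x2, y)
  oracle <- logistic_mle_direct(x1, x2, y)
  expect_lt(max(abs(c(fit$beta0, fit$beta1, fit$beta2) - oracle)), 1e-4)
  expect_true(fit$converged)
  expect_false(fit$separation)
  # classification rate at cutoff 0.5 recomputed by hand
  p <- plogis(fit$beta0 + fit$beta1 * x1 + fit$beta2 * x2)
  expect_equal(fit$pct_correct, 100 * mean((p > 0.5) == (y == 1)))
})

test_that("null labels give ~50% correct; separable clusters give 100% flagged", {
  set.seed(27)
  x1 <- rnorm(400); x2 <- rnorm(400)
  y <- rep(c(0, 1), each = 200)  # independent of the markers
  fit <- fit_logistic_pair(x1, x2, y)
  expect_gt(fit$pct_correct, 40)
  expect_lt(fit$pct_correct, 62)

  xs <- c(rnorm(30, -3, 0.3), rnorm(30, 3, 0.3))
  ys <- rep(c(0, 1), each = 30)
  sep_fit <- fit_logistic_pair(xs, rnorm(60, 0, 0.1), ys)
  expect_true(sep_fit$separation)
  expect_equal(sep_fit$pct_correct, 100)
  expect_true(all(is.finite(c(sep_fit$beta0, sep_fit$beta1, sep_fit$beta2))))
})

test_that("adding an informative second marker does not hurt the panel", {
  set.seed(28)
  tab <- generate_cohort(cohort_spec(n_benign = 120, n_malignant = 120, seed = 4))
  y <- as.integer(tab$diagnosis == "malignant")
  x1 <- tab$area_fraction
  # single-marker baseline: the second slot carries pure noise
  base <- fit_logistic_pair(x1, rnorm(length(y)), y)
  # an independent second marker with its own signal
  x2 <- rnorm(length(y), mean = ifelse(y == 1, 1, 0))
  panel <- fit_logistic_pair(x1, x2, y)
  expect_gt(panel$pct_correct, base$pct_correct - 3)
})
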