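#' Probit transform of area-fraction percentages
#'
#' The default mode reads each area fraction as a proportion `p = af / 100`,
#' clamps it to `[eps, 1 - eps]` (eps = 1e-6, the resolution of a megapixel
#' image) and applies the standard normal quantile `qnorm(p)`. The
#' `rank_INT` mode is the rank-based inverse-normal transform
#' `qnorm((rank - 0.5) / n)`, useful when the raw fractions are heavily
#' skewed. Both modes are strictly monotone, so rank-based statistics (the
#' empirical ROC in particular) are unchanged by the transform.
#'
#' @param af_percent numeric values in \[0, 100\].
#' @param mode `"proportion"` (default) or `"rank_INT"`.
#' @param eps clamp bound for the proportion mode.
#' @return transformed values on the standard normal scale.
#' @examples
#' probit_transform(50)    # 0
#' probit_transform(97.5)  # ~1.96
#' @export
probit_transform <- function(af_percent, mode = c("proportion", "rank_INT"),
                             eps = 1e-6) {
  mode <- match.arg(mode)
  if (any(!is.finite(af_percent)) || any(af_percent < 0 | af_percent > 100))
    stop("area fractions must lie in [0, 100]", call. = FALSE)
  if (mode == "proportion") {
    qnorm(pmin(pmax(af_percent / 100, eps), 1 - eps))
  } else {
    qnorm((rank(af_percent) - 0.5) / length(af_percent))
  }
}

#' Empirical ROC curve with likelihood ratios
#'
#' Builds the empirical ROC of a score against binary labels using the
#' "criterion >" orientation: a case is called positive when its score
#' strictly exceeds the criterion, and malignant is the high-score class. One
#' operating point is emitted per distinct score (plus the extremes, so the
#' curve runs from (0,0) to (1,1)), each with sensitivity, 1-specificity,
#' LR+ = sens/(1-spec) (infinite when specificity is 1) and
#' LR- = (1-sens)/spec. The AUC is computed through the Mann-Whitney
#' identity, (concordant pairs + half ties) / (n0 n1). A warning flags
#' AUC < 0.5, i.e. a marker oriented the wrong way for this convention.
#'
#' @param scores numeric marker values.
#' @param labels 0/1 (or logical) vector; 1 = malignant/positive class.
#' @return an object of class `roc_result`: `operating_points` (data frame of
#'   criterion, sensitivity, one_minus_specificity, lr_plus, lr_minus),
#'   `auc_empirical`, `n0`, `n1`, and the input `scores`/`labels` for
#'   downstream operating-point queries. Binormal fields are NA until
#'   [binormal_roc()] results are merged by the caller.
#' @examples
#' empirical_roc(c(3, 5, 1, 4), c(1, 1, 0, 0))$auc_empirical  # 0.75
#' @export
empirical_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n1 <- as.numeric(sum(labels == 1L)); n0 <- as.numeric(sum(labels == 0L))
  if (n0 == 0 || n1 == 0)
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  vals <- sort(unique(scores))
  # counts per distinct value, cumulated: P(score > v) per class in O(n log n)
  idx <- match(scores, vals)
  pos_le <- cumsum(tabulate(idx[labels == 1L], nbins = length(vals)))
  neg_le <- cumsum(tabulate(idx[labels == 0L], nbins = length(vals)))
  crits <- c(rev(vals), -Inf)
  op <- data.frame(criterion = crits,
                   sensitivity = c(rev((n1 - pos_le) / n1), 1),
                   one_minus_specificity = c(rev((n0 - neg_le) / n0), 1))
  rownames(op) <- NULL
  spec <- 1 - op$one_minus_specificity
  op$lr_plus <- ifelse(op$one_minus_specificity == 0,
                       ifelse(op$sensitivity == 0, NA_real_, Inf),
                       op$sensitivity / op$one_minus_specificity)
  op$lr_minus <- ifelse(spec == 0, NA_real_, (1 - op$sensitivity) / spec)
  r <- rank(scores)
  U1 <- sum(r[labels == 1L]) - n1 * (n1 + 1) / 2
  auc <- U1 / (n0 * n1)
  if (auc < 0.5)
    warning(sprintf("AUC = %.3f < 0.5: scores may be oriented low = positive",
                    auc))
  structure(list(operating_points = op, auc_empirical = auc,
                 auc_binormal = NA_real_, binormal_a = NA_real_,
                 binormal_b = NA_real_, n0 = n0, n1 = n1,
                 scores = scores, labels = labels),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d operating points, n0 = %d, n1 = %d\n",
              nrow(x$operating_points), x$n0, x$n1))
  cat(sprintf("  empirical AUC = %.4f", x$auc_empirical))
  if (!is.na(x$auc_binormal))
    cat(sprintf(", binormal AUC = %.4f (a = %.3f, b = %.3f)",
                x$auc_binormal, x$binormal_a, x$binormal_b))
  cat("\n")
  invisible(x)
}

#' Binormal ROC fit from per-class moments
#'
#' Fits the two-parameter binormal ROC model from the class-conditional
#' moments of the scores: `a = (m1 - m0) / s1`, `b = s0 / s1`, and
#' `AUC = pnorm(a / sqrt(1 + b^2))`. Moments are deterministic and exactly
#' testable; callers who want the Gaussian fit on probit-normalized area
#' fractions apply [probit_transform()] first.
#'
#' @param scores numeric marker values.
#' @param labels 0/1 vector, 1 = malignant.
#' @return a list with `a`, `b`, `auc_binormal`.
#' @examples
#' # m0 = 0, s0 = 1, m1 = 1, s1 = 1 gives AUC = pnorm(1 / sqrt(2)) ~ 0.760
#' @export
binormal_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  x0 <- scores[labels == 0L]; x1 <- scores[labels == 1L]
  if (length(x0) < 2 || length(x1) < 2)
    stop("need at least 2 observations per class", call. = FALSE)
  s0 <- sd(x0); s1 <- sd(x1)
  if (s0 == 0 || s1 == 0)
    stop("zero within-class variance: binormal fit undefined", call. = FALSE)
  a <- (mean(x1) - mean(x0)) / s1
  b <- s0 / s1
  list(a = a, b = b, auc_binormal = pnorm(a / sqrt(1 + b^2)))
}

#' Sensitivity, specificity and likelihood ratios at a criterion
#'
#' Evaluates one operating point of a fitted [empirical_roc()] by direct
#' counting on the stored scores: sensitivity = P(score > criterion |
#' malignant), specificity = P(score <= criterion | benign), LR+ =
#' sens/(1-spec) (flagged infinite when specificity is 1) and LR- =
#' (1-sens)/spec.
#'
#' @param roc a `roc_result`.
#' @param criterion decision threshold, within the observed score range.
#' @return a list with `criterion`, `sensitivity`, `specificity`, `lr_plus`,
#'   `lr_minus`.
#' @export
operating_point <- function(roc, criterion) {
  stopifnot(inherits(roc, "roc_result"))
  if (criterion < min(roc$scores) - 1e-12 || criterion > max(roc$scores) + 1e-12)
    stop("criterion outside the observed score range", call. = FALSE)
  pos <- roc$scores[roc$labels == 1L]
  neg <- roc$scores[roc$labels == 0L]
  sens <- mean(pos > criterion)
  spec <- mean(neg <= criterion)
  list(criterion = criterion, sensitivity = sens, specificity = spec,
       lr_plus = if (spec == 1) Inf else sens / (1 - spec),
       lr_minus = if (spec == 0) NA_real_ else (1 - sens) / spec)
}

ridge_irls <- function(X, y, lambda = 1e-4, maxit = 100L, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)))  # intercept unpenalized
  converged <- FALSE
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    H <- crossprod(X, X * W) + pen
    g <- crossprod(X, y - p) - pen %*% beta
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  list(beta = beta, converged = converged)
}

#' Two-marker logistic regression with in-sample classification rate
#'
#' Fits `logit P(malignant) = b0 + b1 x1 + b2 x2` by maximum likelihood
#' (iteratively reweighted least squares). When complete or quasi-complete
#' separation is detected (fitted probabilities numerically 0/1 or runaway
#' coefficients), the model is refit with a small ridge penalty
#' (lambda = 1e-4 on the slopes) to keep estimates finite, and the result is
#' flagged. The percentage of cases correctly identified is computed
#' in-sample at the probability cutoff 0.5, matching how marker-panel tables
#' report combined diagnostic power within the fitted cohort.
#'
#' @param x1,x2 numeric marker values (finite).
#' @param labels 0/1 vector, 1 = malignant.
#' @param maxit IRLS iteration cap; non-convergence is flagged and the last
#'   iterate returned.
#' @return an object of class `logistic_pair`: `beta0`, `beta1`, `beta2`,
#'   `pct_correct` (percent in \[0, 100\]), `converged`, `separation`,
#'   `n_used`, `fitted`.
#' @export
fit_logistic_pair <- function(x1, x2, labels, maxit = 100L) {
  labels <- as.integer(labels)
  stopifnot(length(x1) == length(labels), length(x2) == length(labels),
            all(is.finite(x1)), all(is.finite(x2)),
            all(labels %in% c(0L, 1L)))
  if (!any(labels == 0L) || !any(labels == 1L))
    stop("both classes must be present", call. = FALSE)
  X <- cbind(1, x1, x2)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(labels ~ x1 + x2, family = binomial(), control = list(maxit = maxit)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(coef(fit))
  beta[is.na(beta)] <- 0  # aliased (collinear) predictor drops to zero
  converged <- fit$converged
  if (sep || any(abs(beta[-1]) > 1e3)) {
    sep <- TRUE
    rr <- ridge_irls(X, labels)
    beta <- rr$beta
    converged <- rr$converged
  }
  p <- 1 / (1 + exp(-drop(X %*% beta)))
  structure(list(beta0 = beta[1], beta1 = beta[2], beta2 = beta[3],
                 pct_correct = 100 * mean((p > 0.5) == (labels == 1L)),
                 converged = converged, separation = sep,
                 n_used = length(labels), fitted = p),
            class = "logistic_pair")
}

#' @export
print.logistic_pair <- function(x, ...) {
  cat(sprintf("<logistic_pair> logit(p) = %.4g + %.4g x1 + %.4g x2\n",
              x$beta0, x$beta1, x$beta2))
  cat(sprintf("  %.1f%% correctly identified (n = %d, cutoff 0.5)%s%s\n",
              x$pct_correct, x$n_used,
              if (x$separation) ", separation: ridge-stabilized" else "",
              if (!x$converged) ", NOT converged" else ""))
  invisible(x)
}
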