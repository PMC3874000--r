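#' Mann-Whitney U test with exact enumeration or tie-corrected approximation
#'
#' Computes the Mann-Whitney U statistic of `x` against `y` from midrank sums
#' (`U = R_x - n_x (n_x + 1) / 2`). The exact method enumerates the full
#' permutation distribution of U over all group relabelings (feasible for
#' `n_x + n_y <= 16`) and returns the two-sided tail probability of deviating
#' from the null mean `n_x n_y / 2` at least as far as observed; the
#' permutation distribution is symmetric about that mean even under ties. The
#' normal approximation uses the tie-corrected variance and a 0.5 continuity
#' correction.
#'
#' @param x,y non-empty numeric samples.
#' @param method `"normal_approx"` (default) or `"exact"`.
#' @return a list with `U` (for sample `x`), `p_two_sided` and `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6), method = "exact")  # U = 0, p = 0.1
#' @export
mann_whitney_u <- function(x, y, method = c("normal_approx", "exact")) {
  method <- match.arg(method)
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- as.numeric(length(x)); n2 <- as.numeric(length(y)); N <- n1 + n2
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across both samples: p = 1")
    return(list(U = n1 * n2 / 2, p_two_sided = 1, method = method))
  }
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (method == "exact") {
    if (N > 16)
      stop("exact enumeration is limited to n_x + n_y <= 16", call. = FALSE)
    sets <- combn(N, n1)
    crit <- abs(U - mu)
    hits <- apply(sets, 2, function(idx) {
      u <- sum(r[idx]) - n1 * (n1 + 1) / 2
      abs(u - mu) >= crit - 1e-9
    })
    p <- mean(hits)
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * (N + 1 - tie_term)
    if (sigma2 <= 0) {
      warning("degenerate variance: p = 1")
      return(list(U = U, p_two_sided = 1, method = method))
    }
    dev <- U - mu
    z <- (dev - sign(dev) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
  }
  list(U = U, p_two_sided = p, method = method)
}

#' One-sample Kolmogorov-Smirnov test against a fitted normal
#'
#' Tests normality the way cohort spreadsheets are screened before choosing a
#' rank-based comparison: the KS statistic `D = sup |F_hat - Phi((x - m)/s)|`
#' against a normal with the sample mean and SD, with the asymptotic p-value.
#' Because the reference uses estimated moments the p-value is approximate
#' (anti-conservative), which is adequate for its screening role here.
#'
#' @param x numeric sample, `n >= 5`, non-degenerate.
#' @return a list with `D` and `p`.
#' @export
ks_normality <- function(x) {
  stopifnot(length(x) >= 5)
  s <- sd(x)
  if (s == 0) stop("zero variance: KS normality test undefined", call. = FALSE)
  res <- suppressWarnings(ks.test(x, "pnorm", mean(x), s))
  list(D = unname(res$statistic), p = res$p.value)
}

#' Fold change between malignant and benign measurements
#'
#' `mean_ratio` is the ratio of group means, the quantity printed in cohort
#' tables; `mountain_auc_ratio` integrates each group's mountain-plot
#' distribution on a shared binning (Freedman-Diaconis width on the pooled
#' sample) and takes the ratio of the areas, confirming the mean-based fold
#' when group sizes are equal. `fold_1dp` rounds to one decimal, the printed
#' precision.
#'
#' @param benign,malignant non-empty numeric vectors; the benign mean must be
#'   positive.
#' @param method `"mean_ratio"` (default) or `"mountain_auc_ratio"`.
#' @return a list with `fold`, `fold_1dp` and `method`.
#' @examples
#' fold_change(c(1.66), c(4.09))$fold_1dp  # 2.5
#' @export
fold_change <- function(benign, malignant,
                        method = c("mean_ratio", "mountain_auc_ratio")) {
  method <- match.arg(method)
  stopifnot(length(benign) >= 1, length(malignant) >= 1)
  if (mean(benign) <= 0)
    stop("benign mean must be positive for a fold change", call. = FALSE)
  fold <- if (method == "mean_ratio") {
    mean(malignant) / mean(benign)
  } else {
    pooled <- c(benign, malignant)
    bw <- fd_bin_width(pooled)
    breaks <- seq(min(pooled) - bw, max(pooled) + bw, by = bw)
    mountain_auc(malignant, bw, breaks = breaks) /
      mountain_auc(benign, bw, breaks = breaks)
  }
  list(fold = fold, fold_1dp = round(fold, 1), method = method)
}

# Freedman-Diaconis bin width with a sane fallback for degenerate IQR.
fd_bin_width <- function(x) {
  bw <- 2 * IQR(x) / length(x)^(1 / 3)
  if (bw <= 0) bw <- diff(range(x)) / max(1, ceiling(sqrt(length(x))))
  if (bw <= 0) bw <- 1
  bw
}

#' Area under a mountain-plot distribution
#'
#' Bins the per-core values on a fixed grid (shared between groups when
#' comparing them) and accumulates the value mass per bin; the area is the
#' trapezoidal integral over the value axis of the bin-total polyline,
#' zero-padded one bin beyond each end. With a single occupied bin of total
#' mass T the area is exactly `T * bin_width`, and the area is linear in the
#' data under a fixed binning.
#'
#' @param values non-empty numeric vector (`n >= 2` for a meaningful plot).
#' @param bin_width positive bin width on the value axis.
#' @param breaks optional explicit break points covering the data; computed
#'   from `bin_width` when omitted.
#' @return the area (value units squared).
#' @export
mountain_auc <- function(values, bin_width, breaks = NULL) {
  stopifnot(length(values) >= 2)
  if (is.null(breaks)) {
    if (!is.numeric(bin_width) || bin_width <= 0)
      stop("bin_width must be positive", call. = FALSE)
    breaks <- seq(min(values) - bin_width, max(values) + bin_width,
                  by = bin_width)
    if (max(breaks) < max(values)) breaks <- c(breaks, max(breaks) + bin_width)
  } else {
    bin_width <- diff(breaks)[1]
    if (min(values) < min(breaks) || max(values) > max(breaks))
      stop("breaks do not cover the data", call. = FALSE)
  }
  bins <- cut(values, breaks, include.lowest = TRUE, labels = FALSE)
  totals <- vapply(seq_len(length(breaks) - 1L),
                   function(b) sum(values[bins == b]), numeric(1))
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  xs <- c(centers[1] - bin_width, centers, centers[length(centers)] + bin_width)
  ys <- c(0, totals, 0)
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2)
}

#' Per-marker group summary of a cohort table
#'
#' For each marker, summarizes the benign and malignant groups of a cohort
#' table (n, mean, standard error of the chosen value column), the fold
#' change by both methods, and the Mann-Whitney comparison.
#'
#' @param cohort a cohort table as produced by [generate_cohort()] or
#'   [run_dab_pipeline()]: columns `marker_name`, `diagnosis` and the value
#'   column.
#' @param value name of the value column (default `"area_fraction"`).
#' @return a `data.frame` with one row per marker: group n/mean/se, `fold`
#'   (mean ratio, 1 dp), `fold_auc` (mountain-AUC ratio, 1 dp), `U`, `p`.
#' @export
cohort_group_stats <- function(cohort, value = "area_fraction") {
  stopifnot(all(c("marker_name", "diagnosis", value) %in% names(cohort)))
  do.call(rbind, lapply(split(cohort, cohort$marker_name), function(d) {
    b <- d[[value]][d$diagnosis == "benign"]
    m <- d[[value]][d$diagnosis == "malignant"]
    mw <- mann_whitney_u(b, m)
    data.frame(marker = d$marker_name[1],
               n_benign = length(b), mean_benign = mean(b),
               se_benign = sd(b) / sqrt(length(b)),
               n_malignant = length(m), mean_malignant = mean(m),
               se_malignant = sd(m) / sqrt(length(m)),
               fold = fold_change(b, m)$fold_1dp,
               fold_auc = fold_change(b, m, "mountain_auc_ratio")$fold_1dp,
               U = mw$U, p = mw$p_two_sided,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
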