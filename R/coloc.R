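#' Maximum-intensity z-projection of a fluorescence stack
#'
#' Collapses each channel of a stack to a single slice by the per-pixel
#' maximum across slices. Idempotent on single-slice input.
#'
#' @param stack a [fluor_stack].
#' @return a `fluor_stack` whose channels each have one slice.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "fluor_stack"))
  out <- stack
  out$channels <- lapply(stack$channels, function(ch) {
    proj <- apply(ch, c(1, 2), max)
    array(proj, dim = c(dim(proj), 1L))
  })
  out
}

# Single-slice matrix view of a channel.
channel_matrix <- function(ch) {
  if (is.matrix(ch)) return(ch)
  if (dim(ch)[3] == 1L) return(ch[, , 1]) else
    stop("channel has multiple slices: max-project first", call. = FALSE)
}

#' Pixel-selection mask for colocalization
#'
#' Colocalization over a whole frame is inflated by the empty (dark, jointly
#' low) background, so the Pearson coefficient is usually computed on pixels
#' carrying signal. `either_above` keeps pixels above threshold in at least
#' one channel (default thresholds: per-channel Otsu cuts), `both_above`
#' requires both, and `all_pixels` keeps the full frame for sensitivity
#' analysis.
#'
#' @param ch_a,ch_b single-slice channel matrices (or h x w x 1 arrays) of
#'   identical shape.
#' @param mode `"either_above"` (default), `"both_above"` or `"all_pixels"`.
#' @param t_a,t_b per-channel thresholds; per-channel Otsu cuts when `NULL`.
#' @param bit_depth intensity bit depth used for the Otsu histogram.
#' @return a logical matrix mask with attribute `mask_mode`.
#' @export
coloc_mask <- function(ch_a, ch_b,
                       mode = c("either_above", "both_above", "all_pixels"),
                       t_a = NULL, t_b = NULL, bit_depth = 16L) {
  mode <- match.arg(mode)
  a <- channel_matrix(ch_a); b <- channel_matrix(ch_b)
  if (!identical(dim(a), dim(b)))
    stop("channels must share identical dimensions", call. = FALSE)
  if (mode == "all_pixels") {
    m <- matrix(TRUE, nrow(a), ncol(a))
  } else {
    if (is.null(t_a)) t_a <- otsu_cut(a, 2^bit_depth - 1)
    if (is.null(t_b)) t_b <- otsu_cut(b, 2^bit_depth - 1)
    if (is.na(t_a) || is.na(t_b))
      stop("constant channel: supply explicit thresholds", call. = FALSE)
    m <- if (mode == "either_above") (a > t_a) | (b > t_b)
         else (a > t_a) & (b > t_b)
  }
  if (!any(m))
    stop("empty colocalization mask: relax thresholds or use mode = ",
         "'all_pixels' / 'either_above'", call. = FALSE)
  attr(m, "mask_mode") <- if (mode == "all_pixels") mode
    else sprintf("%s(%s, %s)", mode, format(t_a), format(t_b))
  m
}

#' Pearson colocalization coefficient of two channels
#'
#' Computes the pixel-wise Pearson correlation of two channels over a mask:
#' `r = sum((a - mean a)(b - mean b)) / sqrt(sum(a - mean a)^2 sum(b - mean
#' b)^2)`. The coefficient is symmetric in its arguments and invariant under
#' positive affine rescaling (gain/offset) of either channel.
#'
#' @param ch_a,ch_b single-slice channel matrices of identical shape.
#' @param mask logical matrix of pixels to use; the full frame when `NULL`.
#' @param channel_pair optional label (e.g. `"BTF3_FITC~HINT1_Cy3"`).
#' @return an object of class `coloc_result`: `channel_pair`, `pearson_r`,
#'   `n_pixels_used`, `mask_mode`.
#' @examples
#' a <- matrix(runif(100), 10)
#' pearson_coloc(a, 2 * a + 1)$pearson_r  # 1
#' @export
pearson_coloc <- function(ch_a, ch_b, mask = NULL, channel_pair = NA_character_) {
  a <- channel_matrix(ch_a); b <- channel_matrix(ch_b)
  if (!identical(dim(a), dim(b)))
    stop("channels must share identical dimensions", call. = FALSE)
  mask_mode <- "all_pixels"
  if (is.null(mask)) {
    av <- as.vector(a); bv <- as.vector(b)
  } else {
    if (!is.null(attr(mask, "mask_mode"))) mask_mode <- attr(mask, "mask_mode")
    av <- a[mask]; bv <- b[mask]
  }
  if (length(av) < 2L)
    stop("need at least 2 masked pixels", call. = FALSE)
  if (sd(av) == 0 || sd(bv) == 0)
    stop("constant channel on mask: Pearson coefficient undefined",
         call. = FALSE)
  structure(list(channel_pair = channel_pair,
                 pearson_r = cor(av, bv),
                 n_pixels_used = length(av),
                 mask_mode = mask_mode),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> %sr = %.4f over %d px [%s]\n",
              if (is.na(x$channel_pair)) "" else paste0(x$channel_pair, ": "),
              x$pearson_r, x$n_pixels_used, x$mask_mode))
  invisible(x)
}

#' Compare colocalization between matched relapse and non-relapse cores
#'
#' Given per-pair Pearson coefficients from matched non-relapse / relapse
#' cores (pairs matched for Gleason score and PSA), reports each group's mean
#' and SD of r and a two-sided paired t-test on the per-pair differences.
#' Because r is bounded, an optional Fisher-z mode applies `atanh` before
#' testing. When every difference is zero the comparison is degenerate and p
#' is reported as 1 with a warning.
#'
#' @param r_nonrelapse,r_relapse numeric vectors of equal length (>= 2
#'   matched pairs), in pair order.
#' @param method `"t"` (default, paired t on r) or `"fisher_z"` (paired t on
#'   atanh r).
#' @return a list with `mean_nonrelapse`, `sd_nonrelapse`, `mean_relapse`,
#'   `sd_relapse`, `n_pairs`, `t`, `df`, `p_two_sided`, `method`.
#' @examples
#' compare_coloc_groups(c(0.74, 0.72, 0.73, 0.71), c(0.62, 0.55, 0.66, 0.58))
#' @export
compare_coloc_groups <- function(r_nonrelapse, r_relapse,
                                 method = c("t", "fisher_z")) {
  method <- match.arg(method)
  stopifnot(length(r_nonrelapse) == length(r_relapse),
            length(r_nonrelapse) >= 2)
  a <- r_nonrelapse; b <- r_relapse
  ta <- if (method == "fisher_z") atanh(a) else a
  tb <- if (method == "fisher_z") atanh(b) else b
  d <- ta - tb
  if (all(d == 0) || sd(d) == 0) {
    warning("degenerate variance of paired differences: p = 1")
    tt <- list(statistic = NA_real_, parameter = length(d) - 1, p.value = 1)
  } else {
    tt <- t.test(ta, tb, paired = TRUE)
  }
  list(mean_nonrelapse = mean(a), sd_nonrelapse = sd(a),
       mean_relapse = mean(b), sd_relapse = sd(b),
       n_pairs = length(a),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value, method = method)
}
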