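#' Specification for one synthetic DAB-stained tissue core
#'
#' Describes a brightfield core image to generate: a roughly circular tissue
#' region of unstained (pink-gray) tissue on a near-white slide background,
#' with dark-brown DAB-stained blobs confined to the tissue. The true stained
#' fraction and tissue fraction are controlled so the quantification pipeline
#' can be checked against known ground truth.
#'
#' @param image_width_px,image_height_px positive integer image size.
#' @param tissue_fraction proportion in (0, 1] of the image covered by tissue.
#' @param stained_fraction proportion in \[0, 1\] of the image area carrying DAB
#'   stain; must not exceed `tissue_fraction` (stain lies on tissue). This is
#'   the ground-truth area fraction divided by 100.
#' @param blob_count positive integer number of stained blobs (ellipses;
#'   overlaps are unioned before the ground-truth fraction is computed).
#' @param noise_sd per-channel Gaussian noise SD, in 8-bit gray levels.
#' @param jpeg_quality integer 1-100 or `"lossless"` (default). Generation is
#'   unaffected; see [write_core_image()].
#' @param seed integer; the generator is a pure function of the spec including
#'   this seed.
#' @return an object of class `core_spec`.
#' @seealso [generate_core_image()]
#' @export
core_spec <- function(image_width_px = 1024L, image_height_px = 1024L,
                      tissue_fraction = 0.6, stained_fraction = 0.02,
                      blob_count = 150L, noise_sd = 0,
                      jpeg_quality = "lossless", seed = 1L) {
  stopifnot(image_width_px >= 1, image_height_px >= 1, blob_count >= 1,
            noise_sd >= 0)
  if (!(tissue_fraction > 0 && tissue_fraction <= 1))
    stop("tissue_fraction must lie in (0, 1]", call. = FALSE)
  if (!(stained_fraction >= 0 && stained_fraction <= 1))
    stop("stained_fraction must lie in [0, 1]", call. = FALSE)
  if (stained_fraction > tissue_fraction)
    stop("invalid spec: stained_fraction exceeds tissue_fraction ",
         "(stain must lie on tissue)", call. = FALSE)
  if (!(identical(jpeg_quality, "lossless") ||
        (is.numeric(jpeg_quality) && jpeg_quality >= 1 && jpeg_quality <= 100)))
    stop("jpeg_quality must be 'lossless' or an integer in 1..100",
         call. = FALSE)
  structure(list(image_width_px = as.integer(image_width_px),
                 image_height_px = as.integer(image_height_px),
                 tissue_fraction = tissue_fraction,
                 stained_fraction = stained_fraction,
                 blob_count = as.integer(blob_count),
                 noise_sd = noise_sd, jpeg_quality = jpeg_quality,
                 seed = as.integer(seed)),
            class = "core_spec")
}

# Rasterize a centered disc clipped to the image so that its pixel count hits
# `target` (monotone in the radius; bisection on the continuous radius).
disc_mask_with_area <- function(h, w, target) {
  cx <- (w + 1) / 2
  cy <- (h + 1) / 2
  dx2 <- (matrix(rep(seq_len(w), each = h), h) - cx)^2
  dy2 <- (matrix(rep(seq_len(h), w), h) - cy)^2
  d2 <- dx2 + dy2
  if (target >= h * w) return(matrix(TRUE, h, w))
  lo <- 0; hi <- sqrt(max(d2)) + 1
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    if (sum(d2 <= mid^2) < target) lo <- mid else hi <- mid
  }
  d2 <= hi^2
}

rasterize_ellipses <- function(h, w, blobs, scale) {
  m <- matrix(FALSE, h, w)
  for (b in blobs) {
    a <- b$a * scale; bb <- b$b * scale
    r <- max(a, bb)
    x0 <- max(1L, floor(b$cx - r)); x1 <- min(w, ceiling(b$cx + r))
    y0 <- max(1L, floor(b$cy - r)); y1 <- min(h, ceiling(b$cy + r))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    dx <- matrix(rep(xs - b$cx, each = length(ys)), length(ys))
    dy <- matrix(rep(ys - b$cy, length(xs)), length(ys))
    u <- (dx * cos(b$theta) + dy * sin(b$theta)) / a
    v <- (-dx * sin(b$theta) + dy * cos(b$theta)) / bb
    m[ys, xs] <- m[ys, xs] | (u^2 + v^2 <= 1)
  }
  m
}

#' Generate a synthetic DAB-stained core image with ground-truth masks
#'
#' Builds an RGB core image from a [core_spec()]: near-white background
#' (gray level 250), unstained tissue around RGB (200, 170, 180) and
#' DAB-stained blobs around RGB (90, 60, 30), so that unweighted grayscale
#' means separate the three classes by well over 40 gray levels. Stained
#' blobs are random ellipses centered on tissue, unioned and intersected with
#' the tissue mask; a global size factor is bisected so the realized stained
#' pixel count matches `stained_fraction` to well under 0.5 percentage
#' points. Identical specs (including the seed) give bit-identical images.
#'
#' @param spec a [core_spec()].
#' @return a `core_image` (subclass `synthetic_core`) with extra elements
#'   `tissue_mask`, `stained_mask` (logical matrices, stained is a subset of
#'   tissue), `true_tissue_fraction`, `true_stained_fraction`, and `spec`.
#' @examples
#' core <- generate_core_image(core_spec(128, 128, stained_fraction = 0.05,
#'                                       blob_count = 20, seed = 7))
#' core$true_stained_fraction
#' @export
generate_core_image <- function(spec) {
  stopifnot(inherits(spec, "core_spec"))
  h <- spec$image_height_px; w <- spec$image_width_px
  n <- h * w
  with_seed(spec$seed, {
    tissue <- disc_mask_with_area(h, w, round(spec$tissue_fraction * n))
    target <- round(spec$stained_fraction * n)
    if (target == 0) {
      stained <- matrix(FALSE, h, w)
    } else {
      idx <- which(tissue)
      centers <- idx[sample.int(length(idx), spec$blob_count, replace = TRUE)]
      base <- sqrt(target / (pi * spec$blob_count))
      blobs <- lapply(centers, function(ci) {
        list(cy = (ci - 1L) %% h + 1L, cx = (ci - 1L) %/% h + 1L,
             a = base * runif(1, 0.5, 1.6),
             b = base * runif(1, 0.5, 1.6),
             theta = runif(1, 0, pi))
      })
      # bisect a global blob-size factor so |union & tissue| hits the target
      lo <- 0; hi <- 1
      while (sum(rasterize_ellipses(h, w, blobs, hi) & tissue) < target &&
             hi < 64 * max(h, w) / base) hi <- hi * 2
      for (i in 1:40) {
        mid <- (lo + hi) / 2
        if (sum(rasterize_ellipses(h, w, blobs, mid) & tissue) < target)
          lo <- mid else hi <- mid
      }
      stained <- rasterize_ellipses(h, w, blobs, hi) & tissue
    }
    px <- array(0, dim = c(h, w, 3))
    cols <- list(background = c(250, 250, 250),
                 tissue = c(200, 170, 180),
                 stain = c(90, 60, 30))
    for (k in 1:3) {
      plane <- matrix(cols$background[k], h, w)
      plane[tissue] <- cols$tissue[k]
      plane[stained] <- cols$stain[k]
      px[, , k] <- plane
    }
    if (spec$noise_sd > 0)
      px <- px + array(rnorm(3 * n, 0, spec$noise_sd), dim = dim(px))
    px <- round(pmin(pmax(px, 0), 255))
    out <- core_image(px, bit_depth = 8L,
                      core_id = sprintf("synthetic_seed%d", spec$seed))
    out$tissue_mask <- tissue
    out$stained_mask <- stained
    out$true_tissue_fraction <- sum(tissue) / n
    out$true_stained_fraction <- sum(stained) / n
    out$spec <- spec
    class(out) <- c("synthetic_core", class(out))
    out
  })
}

#' Specification for a synthetic fluorescence stack
#'
#' Describes a multi-channel stack whose channels are built by linear mixing
#' of shared latent Gaussian fields, so each channel pair realizes a
#' prescribed Pearson correlation.
#'
#' @param channels character vector of channel names (e.g.
#'   `c("BTF3_FITC", "HINT1_Cy3", "NDRG1_Cy5")`).
#' @param pairwise_rho either a single correlation (two channels) or a full
#'   symmetric correlation matrix with unit diagonal, one entry per channel
#'   pair, each in \[-1, 1\]. Must be positive semi-definite.
#' @param n_slices positive integer number of z-slices.
#' @param n_pixels_per_slice requested pixels per slice; the realized slice is
#'   the smallest near-square grid with at least this many pixels.
#' @param seed integer seed.
#' @return an object of class `fluor_spec`.
#' @export
fluor_spec <- function(channels = c("BTF3_FITC", "HINT1_Cy3"),
                       pairwise_rho = 0.73, n_slices = 1L,
                       n_pixels_per_slice = 1e4, seed = 1L) {
  k <- length(channels)
  stopifnot(k >= 2, n_slices >= 1, n_pixels_per_slice >= 4)
  if (is.matrix(pairwise_rho)) {
    R <- pairwise_rho
  } else {
    if (k != 2L || length(pairwise_rho) != 1L)
      stop("scalar pairwise_rho is only valid for exactly two channels",
           call. = FALSE)
    R <- matrix(c(1, pairwise_rho, pairwise_rho, 1), 2)
  }
  if (nrow(R) != k || ncol(R) != k || any(abs(R - t(R)) > 1e-12) ||
      any(abs(diag(R) - 1) > 1e-12) || any(abs(R) > 1 + 1e-12))
    stop("pairwise_rho must be a symmetric correlation matrix with unit ",
         "diagonal and entries in [-1, 1]", call. = FALSE)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("invalid spec: target correlation matrix is not positive ",
         "semi-definite", call. = FALSE)
  dimnames(R) <- list(channels, channels)
  structure(list(channels = channels, pairwise_rho = R,
                 n_slices = as.integer(n_slices),
                 n_pixels_per_slice = as.integer(n_pixels_per_slice),
                 seed = as.integer(seed)),
            class = "fluor_spec")
}

#' Generate a fluorescence stack with prescribed channel correlations
#'
#' Latent standard-normal fields are mixed through the symmetric square root
#' of the target correlation matrix (so exactly singular targets such as
#' rho = 1 are honored), then each channel is affinely mapped to the 16-bit
#' range (mean 32768, SD 6553) and rounded. The target correlation holds in
#' expectation; at 10^4 or more pixels the realized sample Pearson
#' correlation is within about +/-0.05 of target, and the realized values are
#' returned as ground truth.
#'
#' @param spec a [fluor_spec()].
#' @return a `fluor_stack` with extra elements `realized_rho` (matrix of
#'   sample Pearson correlations over all pixels and slices) and `spec`.
#' @examples
#' st <- generate_fluorescence_stack(fluor_spec(pairwise_rho = 0.73, seed = 3))
#' st$realized_rho
#' @export
generate_fluorescence_stack <- function(spec) {
  stopifnot(inherits(spec, "fluor_spec"))
  k <- length(spec$channels)
  h <- floor(sqrt(spec$n_pixels_per_slice))
  w <- ceiling(spec$n_pixels_per_slice / h)
  npx <- h * w * spec$n_slices
  R <- spec$pairwise_rho
  e <- eigen(R, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), k) %*% t(e$vectors)
  with_seed(spec$seed, {
    X <- matrix(rnorm(npx * k), npx, k) %*% A
    X <- round(pmin(pmax(32768 + 6553 * X, 0), 65535))
    chans <- lapply(seq_len(k), function(j)
      array(X[, j], dim = c(h, w, spec$n_slices)))
    names(chans) <- spec$channels
    out <- fluor_stack(chans, bit_depth = 16L)
    out$realized_rho <- stats::cor(X)
    dimnames(out$realized_rho) <- list(spec$channels, spec$channels)
    out$spec <- spec
    out
  })
}

#' Specification for a synthetic per-core area-fraction cohort
#'
#' Describes two diagnosis groups of per-core area fractions (percent) with
#' prescribed group means and standard errors, from which the per-core
#' standard deviation is `se * sqrt(n)`. Values are drawn from a gamma or
#' lognormal family (both strictly positive and right-skewed, as stain area
#' fractions are).
#'
#' @param n_benign,n_malignant positive integer group sizes (usable cores).
#' @param benign_mean_af,malignant_mean_af group mean area fractions in
#'   percent, both > 0.
#' @param benign_se,malignant_se standard errors of the group means, >= 0.
#' @param distribution_family `"gamma"` (default) or `"lognormal"`.
#' @param seed integer seed.
#' @return an object of class `cohort_spec`. The implied fold change
#'   `malignant_mean_af / benign_mean_af` is stored as `implied_fold`.
#' @export
cohort_spec <- function(n_benign = 236L, n_malignant = 228L,
                        benign_mean_af = 1.66, malignant_mean_af = 4.09,
                        benign_se = 0.12, malignant_se = 0.27,
                        distribution_family = c("gamma", "lognormal"),
                        seed = 1L) {
  distribution_family <- match.arg(distribution_family)
  stopifnot(n_benign >= 1, n_malignant >= 1, benign_se >= 0, malignant_se >= 0)
  if (benign_mean_af <= 0 || malignant_mean_af <= 0)
    stop("invalid spec: group mean area fractions must be positive",
         call. = FALSE)
  structure(list(n_benign = as.integer(n_benign),
                 n_malignant = as.integer(n_malignant),
                 benign_mean_af = benign_mean_af,
                 malignant_mean_af = malignant_mean_af,
                 benign_se = benign_se, malignant_se = malignant_se,
                 distribution_family = distribution_family,
                 implied_fold = malignant_mean_af / benign_mean_af,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

draw_positive <- function(n, mean, sd, family) {
  if (sd == 0) return(rep(mean, n))
  if (family == "gamma") {
    shape <- (mean / sd)^2
    rgamma(n, shape = shape, rate = shape / mean)
  } else {
    sdlog2 <- log(1 + (sd / mean)^2)
    rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
  }
}

#' Generate a synthetic cohort table of per-core area fractions
#'
#' Draws per-core area fractions for a benign and a malignant group at the
#' moments prescribed by a [cohort_spec()] and labels them the way a
#' tissue-microarray spreadsheet would: core and patient identifiers (six
#' cores per patient), diagnosis, Gleason pattern for malignant cores, and an
#' optional relapse flag (NA by default).
#'
#' @param spec a [cohort_spec()].
#' @param marker_name marker label written into every row.
#' @return a `data.frame` with columns `core_id`, `patient_id`, `marker_name`,
#'   `area_fraction`, `normalized_signal` (area fraction / 100), `diagnosis`
#'   (`"benign"`/`"malignant"`), `gleason`, `relapse`.
#' @examples
#' tab <- generate_cohort(cohort_spec(n_benign = 20, n_malignant = 20, seed = 2))
#' aggregate(area_fraction ~ diagnosis, tab, mean)
#' @export
generate_cohort <- function(spec, marker_name = "marker1") {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    nb <- spec$n_benign; nm <- spec$n_malignant
    af <- c(draw_positive(nb, spec$benign_mean_af,
                          spec$benign_se * sqrt(nb), spec$distribution_family),
            draw_positive(nm, spec$malignant_mean_af,
                          spec$malignant_se * sqrt(nm),
                          spec$distribution_family))
    diagnosis <- c(rep("benign", nb), rep("malignant", nm))
    gleason <- c(rep(NA_character_, nb),
                 sample(c("3+4", "4+3"), nm, replace = TRUE))
    data.frame(core_id = sprintf("core_%04d", seq_len(nb + nm)),
               patient_id = sprintf("P%03d", (seq_len(nb + nm) - 1L) %/% 6L + 1L),
               marker_name = marker_name,
               area_fraction = af,
               normalized_signal = af / 100,
               diagnosis = diagnosis,
               gleason = gleason,
               relapse = NA_character_,
               stringsAsFactors = FALSE)
  })
}
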