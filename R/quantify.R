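#' Configuration for per-core DAB quantification
#'
#' Collects every tunable of [quantify_core()] in one validated object.
#' Fixed thresholds (and the tissue background margin) are specified in 8-bit
#' gray levels and rescaled internally to the working bit depth, so the same
#' configuration applies to 8- and 16-bit images.
#'
#' @param gray_mode grayscale conversion mode, see [rgb_to_gray()].
#' @param dab_threshold list describing the stain threshold: either
#'   `list(method = "otsu_dark")` (default) or
#'   `list(method = "fixed", lo =, hi =)` with bounds in 8-bit gray levels.
#'   The default follows Otsu because the manually chosen cuts of the
#'   original protocol are not published; a fixed cut reproduces any manual
#'   choice exactly.
#' @param tissue_margin gray levels (8-bit scale) added to the Otsu cut when
#'   segmenting tissue on the inverted image, to keep faint background
#'   vignette out of the tissue mask.
#' @param connectivity particle connectivity, 8 (default) or 4.
#' @param size_min,size_max,circ_min,circ_max particle filters, see
#'   [filter_particles()]; defaults are the macro settings (pass-all).
#' @return an object of class `quant_config`.
#' @export
quant_config <- function(gray_mode = c("unweighted", "luma"),
                         dab_threshold = list(method = "otsu_dark"),
                         tissue_margin = 10,
                         connectivity = 8L,
                         size_min = 0.5, size_max = Inf,
                         circ_min = 0, circ_max = 1) {
  gray_mode <- match.arg(gray_mode)
  stopifnot(is.list(dab_threshold),
            dab_threshold$method %in% c("otsu_dark", "fixed"),
            connectivity %in% c(4L, 8L), tissue_margin >= 0)
  if (identical(dab_threshold$method, "fixed") &&
      (is.null(dab_threshold$lo) || is.null(dab_threshold$hi)))
    stop("fixed dab_threshold needs `lo` and `hi`", call. = FALSE)
  if (size_min > size_max) stop("size_min must not exceed size_max", call. = FALSE)
  structure(list(gray_mode = gray_mode, dab_threshold = dab_threshold,
                 tissue_margin = tissue_margin,
                 connectivity = as.integer(connectivity),
                 size_min = size_min, size_max = size_max,
                 circ_min = circ_min, circ_max = circ_max),
            class = "quant_config")
}

#' Quantify DAB signal and tissue amount in one core image
#'
#' Runs the full quantification chain on a core image: grayscale conversion,
#' stain threshold, particle labeling and filtering, then the particle
#' statistics count, total area (TA, pixels), average size and area fraction
#' (AF = 100 TA / total image pixels). The amount of tissue is measured on
#' the inverted grayscale image, where tissue is bright: an Otsu cut plus a
#' background margin segments tissue, and the same particle pipeline yields
#' the tissue area. The tissue-standardized signal is
#' `normalized_signal = TA / tissue_area` (0 with a warning when no tissue is
#' detected). The function never sees diagnosis or outcome labels;
#' quantification is blind by construction.
#'
#' @param image a [core_image], RGB or grayscale.
#' @param config a [quant_config()].
#' @return a one-row `data.frame` (class `quant_result`) with columns
#'   `core_id`, `count`, `total_area`, `average_size`, `area_fraction`,
#'   `tissue_area`, `normalized_signal`.
#' @examples
#' core <- generate_core_image(core_spec(96, 96, stained_fraction = 0.05,
#'                                       blob_count = 8, seed = 1))
#' quantify_core(core, quant_config(dab_threshold = list(method = "fixed",
#'                                                       lo = 0, hi = 120)))
#' @export
quantify_core <- function(image, config = quant_config()) {
  stopifnot(inherits(image, "core_image"), inherits(config, "quant_config"))
  gray <- if (is_rgb(image)) rgb_to_gray(image, config$gray_mode) else image
  scale <- (2^gray$bit_depth - 1) / 255
  total_px <- prod(dim(gray$pixels)[1:2])

  dab_mask <- if (identical(config$dab_threshold$method, "fixed")) {
    threshold_mask(gray, "fixed",
                   lo = config$dab_threshold$lo * scale,
                   hi = min(config$dab_threshold$hi * scale, 2^gray$bit_depth - 1))
  } else {
    threshold_mask(gray, "otsu_dark")
  }
  dab <- filter_particles(label_particles(dab_mask, config$connectivity),
                          config$size_min, config$size_max,
                          config$circ_min, config$circ_max)
  total_area <- sum(dab$particles$area_px)
  count <- nrow(dab$particles)

  # Tissue on the inverted image, where tissue is bright. The Otsu cut is
  # computed with the already-detected stain pixels excluded, so the
  # background/tissue boundary is found even when heavy stain makes the
  # histogram trimodal; stained pixels are tissue and rejoin the mask.
  inv <- invert_image(gray)
  t_cut <- otsu_cut(inv$pixels[!dab_mask], 2^gray$bit_depth - 1)
  tissue_mask <- if (is.na(t_cut)) {
    if (any(!dab_mask)) warning("constant non-stain intensities: ",
                                "tissue limited to the stain mask")
    dab_mask
  } else {
    (inv$pixels >= t_cut + config$tissue_margin * scale) | dab_mask
  }
  tissue <- filter_particles(label_particles(tissue_mask, config$connectivity),
                             config$size_min, config$size_max,
                             config$circ_min, config$circ_max)
  tissue_area <- sum(tissue$particles$area_px)

  normalized <- if (tissue_area == 0) {
    if (total_area > 0)
      warning("no tissue detected: normalized_signal set to 0")
    0
  } else total_area / tissue_area

  out <- data.frame(core_id = if (is.null(image$core_id)) NA_character_
                    else image$core_id,
                    count = count,
                    total_area = total_area,
                    average_size = if (count > 0) total_area / count else 0,
                    area_fraction = 100 * total_area / total_px,
                    tissue_area = tissue_area,
                    normalized_signal = normalized,
                    stringsAsFactors = FALSE)
  class(out) <- c("quant_result", "data.frame")
  out
}
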