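#' Tissue-core image container
#'
#' A light container for one tissue-core image: an integer pixel grid
#' (grayscale matrix or height x width x 3 RGB array), its bit depth, and an
#' opaque core identifier. All pixel values must lie in `[0, 2^bit_depth - 1]`.
#'
#' @param pixels numeric matrix (grayscale) or 3-d array with third dimension 3
#'   (RGB). Values are stored as given but must be within the bit-depth range.
#' @param bit_depth 8 or 16.
#' @param core_id optional identifier carried through quantification.
#' @return an object of class `core_image` with elements `pixels`,
#'   `bit_depth`, `core_id`.
#' @examples
#' img <- core_image(matrix(0:255, 16, 16), bit_depth = 8, core_id = "demo")
#' img
#' @export
core_image <- function(pixels, bit_depth = 8L, core_id = NULL) {
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  d <- dim(pixels)
  if (is.null(d) || !(length(d) == 2L || (length(d) == 3L && d[3] == 3L)))
    stop("pixels must be a matrix or an h x w x 3 array", call. = FALSE)
  maxv <- 2^bit_depth - 1
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > maxv)
    stop(sprintf("pixel values outside [0, %d]", maxv), call. = FALSE)
  structure(list(pixels = pixels, bit_depth = as.integer(bit_depth),
                 core_id = core_id),
            class = "core_image")
}

#' @export
print.core_image <- function(x, ...) {
  d <- dim(x$pixels)
  kind <- if (length(d) == 3L) "RGB" else "grayscale"
  cat(sprintf("<core_image> %s, %d x %d px, %d-bit%s\n",
              kind, d[1], d[2], x$bit_depth,
              if (is.null(x$core_id)) "" else paste0(", core ", x$core_id)))
  invisible(x)
}

is_rgb <- function(image) length(dim(image$pixels)) == 3L

#' Read a tissue-core image from PNG or TIFF
#'
#' PNG files are read as 8-bit; TIFF files keep their stored depth (8 or 16
#' bit). Grayscale files yield a matrix, color files an RGB array (any alpha
#' channel is dropped). Unreadable files raise an error that carries the
#' core identifier, so pipeline callers can log and skip them.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param core_id identifier attached to the result (defaults to the file
#'   name without extension).
#' @return a [core_image].
#' @export
read_core_image <- function(path, core_id = NULL) {
  if (is.null(core_id)) core_id <- sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  arr <- tryCatch({
    if (ext == "png") {
      list(px = png::readPNG(path), depth = 8L)
    } else if (ext %in% c("tif", "tiff")) {
      a <- tiff::readTIFF(path, as.is = TRUE)
      depth <- if (max(a) > 255) 16L else attr(a, "bits.per.sample")
      if (is.null(depth)) depth <- 8L
      list(px = a / (2^depth - 1), depth = as.integer(depth))
    } else stop("unsupported image format: ", ext)
  }, error = function(e) {
    stop(sprintf("cannot read image for core '%s' (%s): %s",
                 core_id, path, conditionMessage(e)), call. = FALSE)
  })
  px <- arr$px
  if (length(dim(px)) == 3L && dim(px)[3] >= 3L) px <- px[, , 1:3, drop = FALSE]
  if (length(dim(px)) == 3L && dim(px)[3] == 1L) px <- px[, , 1]
  core_image(round(px * (2^arr$depth - 1)), bit_depth = arr$depth,
             core_id = core_id)
}

#' Write a tissue-core image as PNG
#'
#' Output is always lossless PNG (8- or 16-bit to match the image); lossy
#' JPEG encoding is not performed, whatever a core spec's `jpeg_quality`
#' requested.
#'
#' @param image a [core_image].
#' @param path output path (.png).
#' @return `path`, invisibly.
#' @export
write_core_image <- function(image, path) {
  stopifnot(inherits(image, "core_image"))
  maxv <- 2^image$bit_depth - 1
  png::writePNG(image$pixels / maxv, target = path,
                dpi = NULL)
  invisible(path)
}

#' Fluorescence stack container
#'
#' Named multi-channel stack of 16-bit intensity arrays. Every channel must
#' share identical dimensions; slices are the third array dimension (a matrix
#' is a single slice).
#'
#' @param channels named list of matrices or h x w x n_slices arrays.
#' @param bit_depth bit depth of the intensities (default 16).
#' @param core_id,pair_id,relapse optional metadata carried to results.
#' @return an object of class `fluor_stack`.
#' @export
fluor_stack <- function(channels, bit_depth = 16L, core_id = NULL,
                        pair_id = NULL, relapse = NA) {
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("channels must be a named list", call. = FALSE)
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, dim = c(dim(ch), 1L))
    ch
  })
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, identity))) != 1L)
    stop("all channels must share identical dimensions", call. = FALSE)
  structure(list(channels = channels, bit_depth = as.integer(bit_depth),
                 core_id = core_id, pair_id = pair_id, relapse = relapse),
            class = "fluor_stack")
}

#' @export
print.fluor_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<fluor_stack> %d channel(s) [%s], %d x %d px, %d slice(s), %d-bit\n",
              length(x$channels), paste(names(x$channels), collapse = ", "),
              d[1], d[2], d[3], x$bit_depth))
  invisible(x)
}

#' Read one fluorescence channel from a (multi-page) TIFF
#'
#' @param path TIFF path; pages become slices.
#' @param bit_depth stored bit depth (default 16).
#' @return an h x w x n_slices array of integer intensities.
#' @export
read_fluor_channel <- function(path, bit_depth = 16L) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  maxv <- 2^bit_depth - 1
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- round(pages[[i]] * maxv)
  arr
}

#' Write one fluorescence channel as a multi-page 16-bit TIFF
#'
#' @param channel matrix or h x w x n_slices array of intensities.
#' @param path output path.
#' @param bit_depth bit depth used for scaling (default 16).
#' @return `path`, invisibly.
#' @export
write_fluor_channel <- function(channel, path, bit_depth = 16L) {
  if (is.matrix(channel)) channel <- array(channel, dim = c(dim(channel), 1L))
  maxv <- 2^bit_depth - 1
  pages <- lapply(seq_len(dim(channel)[3]),
                  function(i) channel[, , i] / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
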