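#' Convert an RGB core image to grayscale
#'
#' The default mode is the unweighted channel mean `round((R + G + B) / 3)`,
#' matching the convention of common particle-analysis tools; `luma` applies
#' the Rec. 601 weights `0.299 R + 0.587 G + 0.114 B` for sensitivity
#' analysis. 8-bit input is promoted to a 16-bit result by scaling the
#' rounded 8-bit gray value by 257, mirroring the "convert to 16-bit" step of
#' the quantification macro.
#'
#' @param image an RGB [core_image]. A grayscale image is returned unchanged
#'   with a notice.
#' @param mode `"unweighted"` (default) or `"luma"`.
#' @return a grayscale `core_image` (16-bit when the input was 8-bit RGB).
#' @export
rgb_to_gray <- function(image, mode = c("unweighted", "luma")) {
  stopifnot(inherits(image, "core_image"))
  mode <- match.arg(mode)
  if (!is_rgb(image)) {
    message("rgb_to_gray: image is already grayscale; returned unchanged")
    return(image)
  }
  px <- image$pixels
  r <- px[, , 1, drop = FALSE]; gg <- px[, , 2, drop = FALSE]
  b <- px[, , 3, drop = FALSE]
  g <- if (mode == "unweighted") {
    round((r + gg + b) / 3)
  } else {
    round(0.299 * r + 0.587 * gg + 0.114 * b)
  }
  dim(g) <- dim(px)[1:2]
  if (image$bit_depth == 8L) {
    core_image(g * 257, bit_depth = 16L, core_id = image$core_id)
  } else {
    core_image(g, bit_depth = image$bit_depth, core_id = image$core_id)
  }
}

#' Invert a grayscale image
#'
#' Maps every pixel `v` to `2^bit_depth - 1 - v`. Applying the function twice
#' restores the original image exactly. Inversion turns dark tissue bright so
#' the same threshold-and-particle machinery that measures stain can measure
#' the amount of tissue per core.
#'
#' @param image a grayscale [core_image].
#' @return the inverted `core_image`.
#' @export
invert_image <- function(image) {
  stopifnot(inherits(image, "core_image"))
  if (is_rgb(image)) stop("invert_image expects a grayscale image", call. = FALSE)
  out <- image
  out$pixels <- (2^image$bit_depth - 1) - image$pixels
  out[c("tissue_mask", "stained_mask")] <- NULL
  class(out) <- "core_image"
  out
}

# Otsu's threshold on an integer-valued image: the cut t maximizing the
# between-class variance of {v <= t} vs {v > t}; first argmax on ties.
# Returns NA when the image is constant.
otsu_cut <- function(v, max_level) {
  counts <- tabulate(as.integer(v) + 1L, nbins = max_level + 1L)
  if (sum(counts > 0) < 2L) return(NA_integer_)
  p <- counts / sum(counts)
  levels <- 0:max_level
  w0 <- cumsum(p)
  mu0 <- cumsum(p * levels)
  mu_t <- mu0[length(mu0)]
  sb2 <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- -Inf
  t_candidates <- which(sb2 == max(sb2))
  levels[t_candidates[1]]
}

#' Threshold a grayscale image into a binary mask
#'
#' Three methods are offered. `fixed` keeps pixels with `lo <= v <= hi`,
#' reproducing any manually chosen cut. `otsu_dark` computes Otsu's
#' between-class-variance-maximizing cut `t` on the image histogram and keeps
#' the dark side `v <= t` (DAB stain is dark). `otsu_bright` keeps the bright
#' side `v >= t + offset`, used on inverted images where tissue is bright;
#' `offset` adds a background margin above the cut.
#'
#' All methods are deterministic. A constant image under the Otsu methods
#' yields an empty mask with a warning (no separable classes).
#'
#' @param image a grayscale [core_image].
#' @param method `"otsu_dark"` (default), `"fixed"` or `"otsu_bright"`.
#' @param lo,hi inclusive bounds for `method = "fixed"`, in the image's own
#'   intensity scale.
#' @param offset gray levels added to the Otsu cut for `"otsu_bright"`.
#' @return a logical matrix mask, `TRUE` = foreground.
#' @examples
#' img <- core_image(matrix(c(rep(50, 40), rep(200, 60)), 10, 10))
#' sum(threshold_mask(img, "otsu_dark"))  # the 40 dark pixels
#' @export
threshold_mask <- function(image, method = c("otsu_dark", "fixed", "otsu_bright"),
                           lo = 0, hi = Inf, offset = 0) {
  stopifnot(inherits(image, "core_image"))
  if (is_rgb(image)) stop("threshold_mask expects a grayscale image", call. = FALSE)
  method <- match.arg(method)
  v <- image$pixels
  if (method == "fixed") {
    if (lo > hi) stop("fixed threshold: lo must not exceed hi", call. = FALSE)
    return(v >= lo & v <= hi)
  }
  t <- otsu_cut(v, 2^image$bit_depth - 1)
  if (is.na(t)) {
    warning("constant image: no separable classes, returning an empty mask")
    return(matrix(FALSE, nrow(v), ncol(v)))
  }
  if (method == "otsu_dark") v <= t else v >= t + offset
}

# Flood-fill-equivalent labeling. EBImage::bwlabel provides 4-connectivity
# components; 8-connectivity merges any 4-components that touch diagonally,
# via union-find over the diagonal contact pairs, then re-densifies labels.
label_matrix <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  if (!any(mask)) return(matrix(0L, h, w))
  lab <- matrix(as.integer(EBImage::bwlabel(mask * 1L)), h, w)
  if (connectivity == 4L || h == 1L || w == 1L) return(lab)
  edges <- rbind(
    cbind(as.vector(lab[-h, -w]), as.vector(lab[-1, -1])),   # \ diagonals
    cbind(as.vector(lab[-1, -w]), as.vector(lab[-h, -1])))   # / diagonals
  edges <- edges[edges[, 1] > 0L & edges[, 2] > 0L &
                   edges[, 1] != edges[, 2], , drop = FALSE]
  if (nrow(edges) == 0L) return(lab)
  edges <- unique(edges)
  k <- max(lab)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(k), find, integer(1))
  dense <- match(root, sort(unique(root)))
  lab[lab > 0L] <- dense[lab[lab > 0L]]
  lab
}

# Per-component crack-length perimeter: each foreground pixel contributes one
# unit for every 4-edge not shared with another foreground pixel. 4-adjacent
# pixels always belong to the same component under either connectivity.
component_metrics <- function(lab) {
  fg <- lab > 0L
  if (!any(fg)) {
    return(data.frame(label = integer(), area_px = numeric(),
                      perimeter_px = numeric(), circularity = numeric()))
  }
  h <- nrow(fg); w <- ncol(fg)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1), 2:(w + 1)] <- fg
  nb <- pad[1:h, 2:(w + 1)] + pad[3:(h + 2), 2:(w + 1)] +
        pad[2:(h + 1), 1:w] + pad[2:(h + 1), 3:(w + 2)]
  exposed <- 4L - nb
  k <- max(lab)
  area <- tabulate(lab[fg], nbins = k)
  perim <- as.vector(rowsum(as.numeric(exposed[fg]), lab[fg],
                            reorder = TRUE))
  circ <- pmin(1, 4 * pi * area / perim^2)
  data.frame(label = seq_len(k), area_px = as.numeric(area),
             perimeter_px = perim, circularity = circ)
}

#' Label connected stain particles in a binary mask
#'
#' Finds maximal connected components of the foreground under 8-connectivity
#' (the convention of the Analyze Particles tool; diagonal neighbors touch)
#' or 4-connectivity. Labels are dense from 1, and each particle carries its
#' pixel area, crack-length perimeter and clipped circularity
#' `min(1, 4 pi area / perimeter^2)`.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 8 (default) or 4.
#' @return an object of class `particle_set`: `labels` (integer matrix, 0 =
#'   background), `particles` (data frame of label, area_px, perimeter_px,
#'   circularity) and `connectivity`.
#' @examples
#' m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
#' nrow(label_particles(m, 8)$particles)  # 1: diagonal pixels touch
#' nrow(label_particles(m, 4)$particles)  # 2
#' @export
label_particles <- function(mask, connectivity = 8L) {
  if (is.numeric(mask)) mask <- mask > 0
  stopifnot(is.matrix(mask), is.logical(mask),
            connectivity %in% c(4L, 8L))
  lab <- label_matrix(mask, as.integer(connectivity))
  structure(list(labels = lab, particles = component_metrics(lab),
                 connectivity = as.integer(connectivity)),
            class = "particle_set")
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particle(s), %s-connectivity, total area %s px\n",
              nrow(x$particles), x$connectivity,
              format(sum(x$particles$area_px))))
  invisible(x)
}

#' Area, perimeter and circularity of one connected region
#'
#' Computes the metrics of a single particle given as a logical mask: pixel
#' area, crack-length perimeter (number of exposed pixel edges) and
#' circularity `min(1, 4 pi area / perimeter^2)`. A single pixel has area 1,
#' perimeter 4 and circularity `4 pi / 16 ~ 0.785`.
#'
#' @param mask logical matrix containing exactly one connected region.
#' @return a list with `area_px`, `perimeter_px`, `circularity`.
#' @export
particle_metrics <- function(mask) {
  if (is.numeric(mask)) mask <- mask > 0
  stopifnot(is.matrix(mask), any(mask))
  m <- component_metrics(matrix(as.integer(mask), nrow(mask)))
  list(area_px = m$area_px[1], perimeter_px = m$perimeter_px[1],
       circularity = m$circularity[1])
}

#' Filter particles by size and circularity
#'
#' Keeps particles with `size_min <= area <= size_max` and
#' `circ_min <= circularity <= circ_max` (all bounds inclusive). The defaults
#' reproduce the macro settings "Size 0.5-Infinity, Circularity 0.00-1.00",
#' under which every particle survives (any pixel area is at least 1 > 0.5);
#' they are retained for fidelity and configurability. Removed particles are
#' zeroed out of the label map; surviving labels keep their ids.
#'
#' @param ps a `particle_set`.
#' @param size_min,size_max area bounds in pixels.
#' @param circ_min,circ_max circularity bounds in \[0, 1\].
#' @return the filtered `particle_set`.
#' @export
filter_particles <- function(ps, size_min = 0.5, size_max = Inf,
                             circ_min = 0, circ_max = 1) {
  stopifnot(inherits(ps, "particle_set"))
  if (size_min > size_max)
    stop("size_min must not exceed size_max", call. = FALSE)
  if (circ_min > circ_max)
    stop("circ_min must not exceed circ_max", call. = FALSE)
  keep <- with(ps$particles,
               area_px >= size_min & area_px <= size_max &
               circularity >= circ_min & circularity <= circ_max)
  out <- ps
  out$particles <- ps$particles[keep, , drop = FALSE]
  if (!all(keep)) {
    drop_ids <- ps$particles$label[!keep]
    out$labels[out$labels %in% drop_ids] <- 0L
  }
  out
}
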