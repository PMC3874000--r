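test_that("grayscale conversion matches the per-pixel formulas", {
  img <- rgb_image(matrix(255, 1, 1), matrix(255, 1, 1), matrix(255, 1, 1))
  g <- rgb_to_gray(img)
  expect_equal(g$pixels[1, 1] / 257, 255)  # white fixed point, 8-bit scale
  expect_equal(g$bit_depth, 16L)

  img2 <- rgb_image(matrix(100, 1, 1), matrix(150, 1, 1), matrix(200, 1, 1))
  expect_equal(rgb_to_gray(img2, "unweighted")$pixels[1, 1] / 257, 150)

  set.seed(3)
  r <- matrix(sample(0:255, 96, TRUE), 12)
  g2 <- matrix(sample(0:255, 96, TRUE), 12)
  b <- matrix(sample(0:255, 96, TRUE), 12)
  out <- rgb_to_gray(rgb_image(r, g2, b), "unweighted")$pixels
  # per-pixel loop oracle
  for (i in 1:12) for (j in 1:8)
    expect_equal(out[i, j], round((r[i, j] + g2[i, j] + b[i, j]) / 3) * 257)
  luma <- rgb_to_gray(rgb_image(r, g2, b), "luma")$pixels
  expect_equal(luma, round(0.299 * r + 0.587 * g2 + 0.114 * b) * 257)

  gray_in <- core_image(matrix(5, 2, 2))
  expect_message(same <- rgb_to_gray(gray_in), "already grayscale")
  expect_identical(same, gray_in)
})

test_that("inversion is an involution with the expected linear structure", {
  img <- core_image(matrix(c(0, 255, 17, 200), 2, 2), bit_depth = 8L)
  inv <- invert_image(img)
  expect_equal(inv$pixels[1, 1], 255)
  expect_identical(invert_image(inv)$pixels, img$pixels)
  set.seed(4)
  r16 <- core_image(matrix(sample(0:65535, 64, TRUE), 8), bit_depth = 16L)
  expect_equal(mean(r16$pixels) + mean(invert_image(r16)$pixels), 65535)
  expect_equal(invert_image(invert_image(r16))$pixels, r16$pixels,
               ignore_attr = TRUE)
  expect_error(invert_image(rgb_image(matrix(1, 1, 1), matrix(1, 1, 1),
                                      matrix(1, 1, 1))), "grayscale")
})

test_that("thresholding: fixed bounds and Otsu agree with brute force", {
  img <- core_image(matrix(c(rep(50, 40), rep(200, 60)), 10, 10))
  expect_true(all(threshold_mask(img, "fixed", lo = 0, hi = 255)))
  m <- threshold_mask(img, "otsu_dark")
  expect_identical(m, img$pixels == 50)  # exactly the dark class

  # random images: package Otsu equals exhaustive maximization
  set.seed(9)
  for (k in 1:5) {
    v <- matrix(sample(0:255, 400, TRUE, prob = runif(256)^2), 20)
    img_k <- core_image(v)
    t_pkg <- max(img_k$pixels[threshold_mask(img_k, "otsu_dark")])
    expect_equal(t_pkg, otsu_brute(as.vector(v), 255L))
  }

  blank <- core_image(matrix(255, 6, 6))
  expect_warning(mb <- threshold_mask(blank, "otsu_dark"), "constant image")
  expect_equal(sum(mb), 0)
  expect_error(threshold_mask(img, "fixed", lo = 10, hi = 5), "lo must not")
})

test_that("Otsu cut agrees with EBImage's implementation on random images", {
  set.seed(31)
  for (k in 1:3) {
    v <- matrix(sample(0:255, 1024, TRUE, prob = runif(256)), 32)
    img <- core_image(v)
    t_pkg <- max(img$pixels[threshold_mask(img, "otsu_dark")])
    t_eb <- EBImage::otsu(EBImage::Image(v / 255), range = c(0, 1),
                          levels = 256) * 255
    expect_lte(abs(t_pkg - round(t_eb)), 2)  # binning conventions differ
  }
})

test_that("particle labeling matches a flood-fill oracle at both connectivities", {
  # the diagonal pair from the connectivity definition
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE; m[2, 2] <- TRUE
  expect_equal(nrow(label_particles(m, 8)$particles), 1)
  expect_equal(nrow(label_particles(m, 4)$particles), 2)
  expect_equal(nrow(label_particles(matrix(FALSE, 3, 3))$particles), 0)

  set.seed(17)
  for (k in 1:50) {
    mk <- matrix(runif(400) < runif(1, 0.2, 0.6), 20)
    for (conn in c(4L, 8L)) {
      ps <- label_particles(mk, conn)
      oracle <- flood_fill_label(mk, conn)
      expect_equal(max(ps$labels), max(oracle))
      expect_equal(sort(ps$particles$area_px), component_areas(oracle))
      # identical partitions: label maps agree up to renaming
      if (any(mk))
        expect_equal(length(unique(paste(ps$labels[mk], oracle[mk]))),
                     max(oracle))
    }
  }
})

test_that("area bookkeeping: particle areas sum to the mask foreground", {
  set.seed(23)
  mk <- matrix(runif(64 * 64) < 0.4, 64)
  ps <- label_particles(mk, 8)
  expect_equal(sum(ps$particles$area_px), sum(mk))
  expect_equal(sum(ps$labels > 0), sum(mk))
})

test_that("particle metrics follow the crack-length perimeter convention", {
  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  m1 <- particle_metrics(one)
  expect_equal(m1$area_px, 1)
  expect_equal(m1$perimeter_px, 4)
  expect_equal(m1$circularity, 4 * pi / 16)

  sq <- matrix(TRUE, 3, 3)
  m3 <- particle_metrics(sq)
  expect_equal(m3$area_px, 9)
  expect_equal(m3$perimeter_px, 12)
  expect_equal(m3$circularity, 4 * pi * 9 / 144)

  # large rasterized disc: crack-length perimeter converges to the taxicab
  # circumference 8r, so circularity tends to 4*pi*(pi r^2)/(8r)^2 = pi^2/16
  r <- 100
  xy <- expand.grid(x = -110:110, y = -110:110)
  disc <- matrix(xy$x^2 + xy$y^2 <= r^2, 221)
  md <- particle_metrics(disc)
  expect_equal(md$area_px, sum(disc))
  expect_equal(md$perimeter_px / (8 * r), 1, tolerance = 0.01)
  expect_equal(md$circularity, pi^2 / 16, tolerance = 0.02)
  expect_lte(md$circularity, 1)
})

test_that("size/circularity filters keep inclusive bounds and pass-all defaults", {
  set.seed(5)
  mk <- matrix(runif(900) < 0.35, 30)
  ps <- label_particles(mk, 8)
  expect_identical(filter_particles(ps)$particles, ps$particles)

  # areas {5, 10, 20}: size_min = 10 keeps 10 and 20 (inclusive)
  m <- matrix(FALSE, 9, 40)
  m[2, 2:6] <- TRUE              # area 5
  m[4:5, 10:14] <- TRUE          # area 10
  m[7:8, 20:29] <- TRUE          # area 20
  ps2 <- label_particles(m, 8)
  kept <- filter_particles(ps2, size_min = 10)
  expect_equal(sort(kept$particles$area_px), c(10, 20))
  expect_equal(sum(kept$labels > 0), 30)

  # single pixel (circularity 0.785) removed by circ_max = 0.5
  one <- matrix(FALSE, 3, 3); one[2, 2] <- TRUE
  expect_equal(nrow(filter_particles(label_particles(one), circ_max = 0.5)$particles), 0)
  expect_error(filter_particles(ps2, size_min = 5, size_max = 1), "size_min")
})

test_that("blank white cores quantify to zero signal and zero tissue", {
  blank <- rgb_image(matrix(255, 16, 16), matrix(255, 16, 16),
                     matrix(255, 16, 16), core_id = "blank")
  q <- suppressWarnings(quantify_core(blank))
  expect_equal(q$total_area, 0)
  expect_equal(q$area_fraction, 0)
  expect_equal(q$normalized_signal, 0)
})

test_that("tissue standardization recovers the stained/tissue ratio", {
  spec <- core_spec(256, 256, tissue_fraction = 0.5, stained_fraction = 0.125,
                    blob_count = 25, seed = 31)
  core <- generate_core_image(spec)
  q <- quantify_core(core, synthetic_dab_config())
  expect_lt(abs(q$normalized_signal - 0.25), 0.02)
  expect_lt(abs(q$tissue_area - sum(core$tissue_mask)), 0.01 * 256^2)
})

test_that("area fraction is scale-free and monotone in the stained region", {
  base <- core_spec(128, 128, stained_fraction = 0.05, blob_count = 12, seed = 3)
  dbl <- core_spec(256, 256, stained_fraction = 0.05, blob_count = 12, seed = 3)
  af1 <- quantify_core(generate_core_image(base), synthetic_dab_config())$area_fraction
  af2 <- quantify_core(generate_core_image(dbl), synthetic_dab_config())$area_fraction
  expect_lt(abs(af1 - af2), 0.5)

  # enlarging the stained ground truth never decreases total area
  afs <- vapply(c(0.02, 0.05, 0.10, 0.20), function(sf) {
    core <- generate_core_image(core_spec(128, 128, stained_fraction = sf,
                                          blob_count = 12, seed = 3))
    quantify_core(core, synthetic_dab_config())$total_area
  }, numeric(1))
  expect_true(all(diff(afs) >= 0))
})

test_that("image round-trip through PNG preserves pixels and core ids", {
  core <- generate_core_image(core_spec(48, 48, stained_fraction = 0.05,
                                        blob_count = 6, seed = 2))
  path <- file.path(tempdir(), "core_roundtrip.png")
  write_core_image(core, path)
  back <- read_core_image(path)
  expect_equal(back$pixels, core$pixels, ignore_attr = TRUE)
  expect_equal(back$core_id, "core_roundtrip")
  expect_error(read_core_image(file.path(tempdir(), "absent_core.png"),
                               core_id = "c77"), "c77")
})
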