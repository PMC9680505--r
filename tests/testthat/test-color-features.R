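# Closed-form corner colours used as the oracle below: the 8 RGB cube
# corners plus three grays.
cube_corners <- rbind(
  c(0, 0, 0), c(255, 0, 0), c(0, 255, 0), c(0, 0, 255),
  c(255, 255, 0), c(255, 0, 255), c(0, 255, 255), c(255, 255, 255),
  c(128, 128, 128), c(64, 64, 64), c(192, 192, 192))

test_that("the feature space has exactly 23 channels and the default subset 14", {
  expect_length(feature_channels(), 23L)
  expect_false(anyDuplicated(feature_channels()) > 0)
  expect_length(default_feature_subset(), 14L)
  expect_true(all(default_feature_subset() %in% feature_channels()))
  expect_equal(dim(extract_features(c(0L, 128L, 0L))), c(1L, 23L))
  expect_equal(dim(extract_features(c(0L, 128L, 0L), default_feature_subset())),
               c(1L, 14L))
})

test_that("the packaged subset config round-trips and equals the default", {
  shipped <- read_feature_subset(system.file("extdata", "default_subset.json",
                                             package = "canopyseg"))
  expect_equal(unclass(shipped), unclass(default_feature_subset()))
  tmp <- tempfile(fileext = ".json")
  write_feature_subset(default_feature_subset(), tmp)
  expect_equal(unclass(read_feature_subset(tmp)), unclass(default_feature_subset()))
})

test_that("HSV matches the hexcone model on primaries and grays", {
  expect_equal(unname(rgb_to_hsv(c(255, 0, 0))), matrix(c(0, 1, 1), 1))
  expect_equal(unname(rgb_to_hsv(c(0, 255, 0))), matrix(c(120, 1, 1), 1))
  expect_equal(unname(rgb_to_hsv(c(128, 128, 128))),
               matrix(c(0, 0, 128 / 255), 1))
  # independent oracle: grDevices::rgb2hsv on the corner set
  got <- rgb_to_hsv(cube_corners)
  ref <- t(grDevices::rgb2hsv(t(cube_corners), maxColorValue = 255))
  expect_equal(got[, "H"], ref[, "h"] * 360, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(got[, "S"], ref[, "s"], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(got[, "V"], ref[, "v"], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("CIELab matches an independent sRGB->Lab conversion", {
  expect_equal(unname(rgb_to_lab(c(255, 255, 255))), matrix(c(100, 0, 0), 1),
               tolerance = 0.1)
  expect_equal(unname(rgb_to_lab(c(0, 0, 0))), matrix(c(0, 0, 0), 1),
               tolerance = 1e-8)
  # oracle: grDevices::convertColor (independent implementation)
  pts <- rbind(cube_corners, c(0, 255, 0), c(37, 201, 94))
  ref <- grDevices::convertColor(pts / 255, from = "sRGB", to = "Lab")
  expect_equal(unname(rgb_to_lab(pts)), unname(ref), tolerance = 1e-2)
})

test_that("CMYK handles the black division guard and primaries", {
  expect_equal(unname(rgb_to_cmyk(c(255, 255, 255))), matrix(c(0, 0, 0, 0), 1))
  expect_equal(unname(rgb_to_cmyk(c(0, 0, 0))), matrix(c(0, 0, 0, 1), 1))
  expect_equal(unname(rgb_to_cmyk(c(255, 0, 0))), matrix(c(0, 1, 1, 0), 1))
  # closed form on all corners
  rgbp <- cube_corners / 255
  k <- 1 - pmax(rgbp[, 1], rgbp[, 2], rgbp[, 3])
  expect_equal(rgb_to_cmyk(cube_corners)[, "K"], k, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("YCbCr follows the full-range BT.601 matrix", {
  expect_equal(unname(rgb_to_ycbcr(c(128, 128, 128))),
               matrix(c(128, 128, 128), 1), tolerance = 1e-6)
  expect_equal(unname(rgb_to_ycbcr(c(0, 0, 0))), matrix(c(0, 128, 128), 1))
  # hand-multiplied matrix for primary red
  expect_equal(unname(rgb_to_ycbcr(c(255, 0, 0))),
               matrix(c(0.299 * 255, 128 - 0.168736 * 255, 128 + 0.5 * 255), 1),
               tolerance = 1e-9)
})

test_that("YIQ follows the NTSC matrix and is zero-chroma on grays", {
  expect_equal(unname(rgb_to_yiq(c(128, 128, 128))),
               matrix(c(128 / 255, 0, 0), 1), tolerance = 1e-9)
  expect_equal(unname(rgb_to_yiq(c(255, 255, 255))), matrix(c(1, 0, 0), 1),
               tolerance = 1e-9)
  # hand-multiplied matrix for primary green
  expect_equal(unname(rgb_to_yiq(c(0, 255, 0))),
               matrix(c(0.587, -0.274453, -0.522591), 1), tolerance = 1e-9)
})

test_that("the four luminance variants agree with their closed forms", {
  expect_equal(unname(rgb_to_gray_luminances(c(255, 255, 255))),
               matrix(1, 1, 4))
  expect_equal(unname(rgb_to_gray_luminances(c(0, 0, 0))), matrix(0, 1, 4))
  expect_equal(unname(rgb_to_gray_luminances(c(255, 0, 0))),
               matrix(c(0.2126, 1 / 3, 0.5, 0.299), 1), tolerance = 1e-12)
})

test_that("achromatic pixels are chroma-neutral in every space", {
  grays <- cbind(c(0, 64, 128, 200, 255), c(0, 64, 128, 200, 255),
                 c(0, 64, 128, 200, 255))
  expect_equal(rgb_to_hsv(grays)[, "S"], rep(0, 5), ignore_attr = TRUE)
  expect_equal(rgb_to_hsv(grays)[, "H"], rep(0, 5), ignore_attr = TRUE)
  lab <- rgb_to_lab(grays)
  expect_equal(lab[, "a"], rep(0, 5), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(lab[, "b"], rep(0, 5), tolerance = 1e-6, ignore_attr = TRUE)
  yiq <- rgb_to_yiq(grays)
  expect_equal(yiq[, "I"], rep(0, 5), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(yiq[, "Q"], rep(0, 5), tolerance = 1e-12, ignore_attr = TRUE)
  ycc <- rgb_to_ycbcr(grays)
  expect_equal(ycc[, "Cb"], rep(128, 5), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(ycc[, "Cr"], rep(128, 5), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("extract_features is column-equivariant and row-consistent", {
  set.seed(1)
  px <- matrix(sample(0:255, 60, replace = TRUE), ncol = 3)
  sub <- feature_subset(c("H", "a", "Y", "Cr", "GE"))
  perm <- feature_subset(c("Cr", "GE", "H", "Y", "a"))
  f1 <- extract_features(px, sub)
  f2 <- extract_features(px, perm)
  expect_equal(f1[, unclass(perm)], f2)
  # identity channels pass through raw intensities
  expect_equal(unname(extract_features(c(10L, 20L, 30L),
                                       feature_subset(c("R", "G", "B")))),
               matrix(c(10, 20, 30), 1))
  # batch extraction equals pixel-by-pixel application
  full <- extract_features(px)
  rowwise <- do.call(rbind, lapply(seq_len(nrow(px)),
                                   function(i) extract_features(px[i, ])))
  expect_equal(full, rowwise)
})

test_that("declared channel ranges hold on random pixels", {
  set.seed(2)
  px <- matrix(sample(0:255, 900, replace = TRUE), ncol = 3)
  f <- extract_features(px)
  expect_true(all(f[, "H"] >= 0 & f[, "H"] < 360))
  for (ch in c("S", "V", "GE", "LA", "LB", "LC", "C", "M", "Y", "K", "Yj")) {
    expect_true(all(f[, ch] >= 0 & f[, ch] <= 1), label = ch)
  }
  expect_true(all(f[, "L"] >= 0 & f[, "L"] <= 100))
  expect_true(all(f[, "Yi"] >= 0 & f[, "Yi"] <= 255))
})

test_that("invalid subsets and pixels are rejected", {
  expect_error(feature_subset(c("R", "R")), "duplicate")
  expect_error(feature_subset(c("R", "XX")), "unknown")
  expect_error(extract_features(c(300L, 0L, 0L)), "0, 255")
  expect_error(extract_features(c(1.5, 0, 0)), "integers")
})
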