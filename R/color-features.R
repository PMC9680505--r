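#' The 23 colour-feature channel names, in canonical order
#'
#' Every pixel is described by 23 channels derived from its 8-bit RGB value:
#' the raw channels (R, G, B, on 0--255), hexcone HSV (H in degrees
#' \[0, 360), S and V in \[0, 1\]), CIELab under D65 (L in \[0, 100\], a and b
#' unbounded), four grayscale/luminance variants (GE, LA, LB, LC, each in
#' \[0, 1\]), naive CMYK (C, M, Y, K in \[0, 1\]), full-range BT.601 YCbCr
#' (Yi, Cb, Cr on 0--255, neutral chroma at 128) and NTSC YIQ (Yj in
#' \[0, 1\], I and Q signed, zero for grays).
#'
#' The luminance variants are: GE, the Rec.709 luminosity grayscale
#' 0.2126R' + 0.7152G' + 0.0722B'; LA, the channel mean; LB, the HSL
#' lightness (max + min)/2; LC, the BT.601 luma 0.299R' + 0.587G' + 0.114B'
#' (primed channels are unit-scaled).
#'
#' @return Character vector of length 23.
#' @seealso [default_feature_subset()], [extract_features()]
#' @export
#' @examples
#' feature_channels()
feature_channels <- function() {
  c("R", "G", "B", "H", "S", "V", "L", "a", "b",
    "GE", "LA", "LB", "LC", "C", "M", "Y", "K",
    "Yi", "Cb", "Cr", "Yj", "I", "Q")
}

#' The default 14-channel subset used by the green/senescent classifier
#'
#' The shipped pixel classifier uses 14 of the 23 channels: R, G, B, H, S,
#' a, b, GE, M, Y, Cb, Cr, I, Q. The CMYK yellow channel Y covers the
#' yellow axis along which senescent tissue departs from green. The same
#' list ships as a JSON config file under `extdata/default_subset.json`.
#'
#' @return Character vector of length 14, a valid [feature_subset()].
#' @export
default_feature_subset <- function() {
  feature_subset(c("R", "G", "B", "H", "S", "a", "b",
                   "GE", "M", "Y", "Cb", "Cr", "I", "Q"))
}

#' Validate an ordered feature subset
#'
#' @param names Character vector of channel names drawn from
#'   [feature_channels()]; order is significant (it fixes column order in
#'   [extract_features()]).
#' @return `names`, invisibly classed as `"feature_subset"`.
#' @export
feature_subset <- function(names) {
  names <- as.character(names)
  if (length(names) == 0L) stop("a feature subset must contain at least one channel")
  bad <- setdiff(names, feature_channels())
  if (length(bad) > 0L) {
    stop("unknown feature channel(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(names)) stop("duplicate channel names in feature subset")
  structure(names, class = "feature_subset")
}

#' Read or write a feature subset as a JSON list of channel names
#'
#' @param path File path.
#' @param subset A [feature_subset()] (or plain character vector of channel
#'   names) for writing.
#' @return `read_feature_subset` returns a validated [feature_subset()];
#'   `write_feature_subset` returns `path` invisibly.
#' @export
read_feature_subset <- function(path) {
  feature_subset(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_feature_subset
#' @export
write_feature_subset <- function(subset, path) {
  subset <- feature_subset(subset)
  jsonlite::write_json(unclass(subset), path)
  invisible(path)
}

# Coerce pixel input to an n x 3 numeric matrix of 0-255 intensities.
# Accepts an n x 3 matrix/data.frame, a length-3 vector, or an H x W x 3
# image array on [0, 1] (rounded to 8-bit levels).
as_rgb255 <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[3] < 3L) stop("image array must have 3 colour channels")
    x <- round(cbind(as.vector(x[, , 1]), as.vector(x[, , 2]), as.vector(x[, , 3])) * 255)
  }
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("a single pixel must have exactly 3 channels")
    x <- matrix(x, nrow = 1L)
  }
  if (ncol(x) != 3L) stop("RGB input must have 3 columns")
  if (nrow(x) == 0L) stop("RGB input is empty")
  x <- unname(x * 1.0)
  if (any(x < 0 | x > 255) || any(x != round(x))) {
    stop("RGB intensities must be integers in [0, 255]")
  }
  x
}

#' Colour-space conversions for 8-bit RGB pixels
#'
#' Vectorised conversions from 8-bit RGB to the colour spaces used by the
#' pixel classifier. All take an `n x 3` matrix of integer intensities in
#' \[0, 255\] (a single length-3 pixel, or an image array on \[0, 1\], is
#' also accepted) and return an `n x k` matrix with named columns.
#'
#' Conventions (fixed so that downstream classifiers are reproducible):
#' \describe{
#'   \item{HSV}{hexcone model; H in degrees \[0, 360), S and V in \[0, 1\].
#'     Achromatic pixels take H = 0 and S = 0.}
#'   \item{CIELab}{sRGB gamma decoding, XYZ under the D65/2 degree white
#'     point; L in \[0, 100\].}
#'   \item{CMYK}{naive conversion K = 1 - max(R', G', B'),
#'     C = (1 - R' - K)/(1 - K) etc.; black maps to C = M = Y = 0, K = 1.}
#'   \item{YCbCr}{ITU-R BT.601 full-range (JFIF) matrix on 0--255 with
#'     chroma offset 128; grays map to Cb = Cr = 128.}
#'   \item{YIQ}{NTSC matrix on unit-scaled channels; grays map to
#'     I = Q = 0.}
#'   \item{Grayscale/luminance}{see [feature_channels()] for the GE, LA,
#'     LB, LC definitions; all on \[0, 1\].}
#' }
#'
#' @param rgb Pixel input as described above.
#' @return Numeric matrix, one row per pixel.
#' @name color_conversions
NULL

#' @rdname color_conversions
#' @export
rgb_to_hsv <- function(rgb) {
  rgb <- as_rgb255(rgb) / 255
  mx <- pmax(rgb[, 1], rgb[, 2], rgb[, 3])
  mn <- pmin(rgb[, 1], rgb[, 2], rgb[, 3])
  d <- mx - mn
  h <- numeric(nrow(rgb))
  idx <- d > 0 & mx == rgb[, 1]
  h[idx] <- ((rgb[idx, 2] - rgb[idx, 3]) / d[idx]) %% 6
  idx <- d > 0 & mx == rgb[, 2] & mx != rgb[, 1]
  h[idx] <- (rgb[idx, 3] - rgb[idx, 1]) / d[idx] + 2
  idx <- d > 0 & mx == rgb[, 3] & mx != rgb[, 1] & mx != rgb[, 2]
  h[idx] <- (rgb[idx, 1] - rgb[idx, 2]) / d[idx] + 4
  h <- (h * 60) %% 360
  s <- ifelse(mx > 0, d / mx, 0)
  cbind(H = h, S = s, V = mx)
}

#' @rdname color_conversions
#' @export
rgb_to_lab <- function(rgb) {
  rgb <- as_rgb255(rgb) / 255
  # sRGB electro-optical transfer (IEC 61966-2-1)
  lin <- ifelse(rgb <= 0.04045, rgb / 12.92, ((rgb + 0.055) / 1.055)^2.4)
  m <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041),
              nrow = 3, byrow = TRUE)
  xyz <- lin %*% t(m)
  # D65 white as the image of sRGB white under the matrix above, so that
  # achromatic pixels map to a = b = 0 exactly
  white <- rowSums(m)
  t3 <- sweep(xyz, 2, white, "/")
  delta <- 6 / 29
  f <- ifelse(t3 > delta^3, t3^(1 / 3), t3 / (3 * delta^2) + 4 / 29)
  cbind(L = 116 * f[, 2] - 16,
        a = 500 * (f[, 1] - f[, 2]),
        b = 200 * (f[, 2] - f[, 3]))
}

#' @rdname color_conversions
#' @export
rgb_to_cmyk <- function(rgb) {
  rgb <- as_rgb255(rgb) / 255
  k <- 1 - pmax(rgb[, 1], rgb[, 2], rgb[, 3])
  denom <- ifelse(k < 1, 1 - k, 1)  # black pixel guard
  cbind(C = ifelse(k < 1, (1 - rgb[, 1] - k) / denom, 0),
        M = ifelse(k < 1, (1 - rgb[, 2] - k) / denom, 0),
        Y = ifelse(k < 1, (1 - rgb[, 3] - k) / denom, 0),
        K = k)
}

#' @rdname color_conversions
#' @export
rgb_to_ycbcr <- function(rgb) {
  rgb <- as_rgb255(rgb)
  cbind(Yi = 0.299 * rgb[, 1] + 0.587 * rgb[, 2] + 0.114 * rgb[, 3],
        Cb = 128 - 0.168736 * rgb[, 1] - 0.331264 * rgb[, 2] + 0.5 * rgb[, 3],
        Cr = 128 + 0.5 * rgb[, 1] - 0.418688 * rgb[, 2] - 0.081312 * rgb[, 3])
}

#' @rdname color_conversions
#' @export
rgb_to_yiq <- function(rgb) {
  rgb <- as_rgb255(rgb) / 255
  cbind(Yj = 0.299 * rgb[, 1] + 0.587 * rgb[, 2] + 0.114 * rgb[, 3],
        I = 0.595716 * rgb[, 1] - 0.274453 * rgb[, 2] - 0.321263 * rgb[, 3],
        Q = 0.211456 * rgb[, 1] - 0.522591 * rgb[, 2] + 0.311135 * rgb[, 3])
}

#' @rdname color_conversions
#' @export
rgb_to_gray_luminances <- function(rgb) {
  rgb <- as_rgb255(rgb) / 255
  cbind(GE = 0.2126 * rgb[, 1] + 0.7152 * rgb[, 2] + 0.0722 * rgb[, 3],
        LA = rowMeans(rgb),
        LB = (pmax(rgb[, 1], rgb[, 2], rgb[, 3]) +
                pmin(rgb[, 1], rgb[, 2], rgb[, 3])) / 2,
        LC = 0.299 * rgb[, 1] + 0.587 * rgb[, 2] + 0.114 * rgb[, 3])
}

#' Extract colour features from pixels
#'
#' Computes the requested colour-feature channels for a batch of 8-bit RGB
#' pixels. With the full channel list the result has 23 columns; with the
#' shipped [default_feature_subset()] it has 14. Column order follows the
#' subset order, so permuting the subset permutes the columns identically.
#'
#' @param rgb Pixels as an `n x 3` integer matrix (0--255), a single
#'   length-3 pixel, or an RGB image array on \[0, 1\].
#' @param subset A [feature_subset()]; defaults to all 23 channels.
#' @return Numeric matrix of dimension `n x length(subset)` with the
#'   subset names as column names.
#' @export
#' @examples
#' extract_features(c(10L, 20L, 30L), feature_subset(c("R", "G", "B")))
#' dim(extract_features(matrix(c(0, 128, 0), 1), default_feature_subset()))
extract_features <- function(rgb, subset = feature_subset(feature_channels())) {
  subset <- feature_subset(subset)
  rgb <- as_rgb255(rgb)
  full <- cbind(R = rgb[, 1], G = rgb[, 2], B = rgb[, 3],
                rgb_to_hsv(rgb), rgb_to_lab(rgb),
                rgb_to_gray_luminances(rgb), rgb_to_cmyk(rgb),
                rgb_to_ycbcr(rgb), rgb_to_yiq(rgb))
  full[, unclass(subset), drop = FALSE]
}
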