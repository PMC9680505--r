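#' Parameters for synthetic canopy scenes
#'
#' Describes a procedurally generated nadir canopy scene: blob-structured
#' green and senescent vegetation over a soil-like background, with exact
#' per-pixel ground truth. Vegetation patches are carved from thresholded
#' smoothed Gaussian random fields, which produces irregular, organ-like
#' shapes and mixed-colour borders; thin 1--2 px elongated structures
#' emulate awns. Two illumination regimes are supported: `"natural"`
#' (mid-range brightness) and `"flash"` (non-collimated flash lighting:
#' a heavier dark-shadow tail plus saturated highlights).
#'
#' @param size Image side in pixels (square scenes).
#' @param fractions Target class fractions, in order background, green
#'   vegetation, senescent vegetation; must be non-negative and sum to 1.
#' @param blob_scale Correlation length of the random fields in pixels;
#'   larger values give fewer, larger organs.
#' @param green_hue,senescent_hue Hue ranges in degrees for the two
#'   vegetation classes. Defaults straddle the green-to-yellow senescence
#'   continuum: green 70--160, senescent 20--60.
#' @param background_saturation Saturation range of the soil palette; soil
#'   shares brownish hues with senescent tissue but at low saturation,
#'   which is the classically hard case for colour-only classification.
#' @param regime Illumination regime, `"natural"` or `"flash"`.
#' @param awn_density Expected number of awn-like thin segments per
#'   kilopixel of vegetation.
#' @param noise Standard deviation of additive Gaussian RGB noise on
#'   \[0, 1\] (clipped).
#' @return A list of class `"scene_params"`.
#' @export
scene_params <- function(size = 64,
                         fractions = c(background = 0.35, green = 0.45,
                                       senescent = 0.20),
                         blob_scale = 8,
                         green_hue = c(70, 160),
                         senescent_hue = c(20, 60),
                         background_saturation = c(0.03, 0.30),
                         regime = c("natural", "flash"),
                         awn_density = 0.5,
                         noise = 0.02) {
  regime <- match.arg(regime)
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be 3 non-negative numbers summing to 1")
  }
  if (any(c(green_hue, senescent_hue) < 0) ||
      any(c(green_hue, senescent_hue) >= 360)) {
    stop("hue ranges must lie within [0, 360)")
  }
  structure(list(size = as.integer(size), fractions = fractions,
                 blob_scale = blob_scale, green_hue = green_hue,
                 senescent_hue = senescent_hue,
                 background_saturation = background_saturation,
                 regime = regime, awn_density = awn_density, noise = noise),
            class = "scene_params")
}

# Smoothed standard-normal random field: iid noise blurred with a
# separable Gaussian kernel, then re-standardised.
smooth_field <- function(h, w, scale) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (scale > 0) {
    half <- max(1L, as.integer(round(2 * scale)))
    k <- stats::dnorm(seq(-half, half), sd = scale)
    k <- k / sum(k)
    pad <- function(m, n) rbind(m[rep(1L, n), , drop = FALSE], m,
                                m[rep(nrow(m), n), , drop = FALSE])
    blur1 <- function(m) {
      mp <- pad(m, half)
      out <- matrix(0, nrow(m), ncol(m))
      for (i in seq_along(k)) out <- out + k[i] * mp[i:(i + nrow(m) - 1L), , drop = FALSE]
      out
    }
    z <- t(blur1(t(blur1(z))))
  }
  (z - mean(z)) / stats::sd(z)
}

# Vectorised HSV (H degrees, S, V in [0,1]) -> RGB in [0,1].
hsv_to_rgb <- function(h, s, v) {
  h <- (h %% 360) / 60
  i <- floor(h)
  f <- h - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  cbind(r, g, b)
}

# Brightness (V) sampler per illumination regime. Flash scenes mix a dark
# shadow component with a saturated-highlight component.
sample_brightness <- function(n, regime) {
  if (regime == "flash") {
    comp <- stats::runif(n)
    v <- ifelse(comp < 0.35, stats::rbeta(n, 1.2, 6),          # deep shadows
         ifelse(comp < 0.85, stats::rbeta(n, 4, 3),            # lit canopy
                1 - stats::rbeta(n, 1.5, 12)))                 # near-saturated
  } else {
    v <- stats::rbeta(n, 5, 3)
  }
  pmin(pmax(v, 0), 1)
}

sample_class_colors <- function(n, class, params) {
  v <- sample_brightness(n, params$regime)
  if (class == "green") {
    h <- stats::runif(n, params$green_hue[1], params$green_hue[2])
    s <- stats::rbeta(n, 5, 2)
  } else if (class == "senescent") {
    h <- stats::runif(n, params$senescent_hue[1], params$senescent_hue[2])
    s <- stats::rbeta(n, 5, 2)
  } else {  # soil background: brownish-gray hues at low saturation
    h <- stats::runif(n, 15, 55)
    s <- stats::runif(n, params$background_saturation[1],
                      params$background_saturation[2])
    v <- v * 0.85
  }
  hsv_to_rgb(h, s, v)
}

#' Generate a synthetic canopy scene with exact ground truth
#'
#' Builds an RGB image and its per-pixel 3-class mask (0 = background,
#' 1 = green vegetation, 2 = senescent vegetation). Class regions are
#' carved from two independent smoothed random fields by quantile
#' thresholding, so realised fractions track the targets closely (the
#' generator contract is within 0.1 per class); awns are drawn as thin
#' random segments of vegetation. Fully reproducible given `seed`.
#'
#' @param params A [scene_params()] object.
#' @param seed Integer seed; the scene is a pure function of
#'   `(params, seed)`.
#' @return A list of class `"canopy_scene"` with elements `image`
#'   (`size x size x 3` array on \[0, 1\]), `mask` (integer matrix valued
#'   in \{0, 1, 2\}), `fractions` (realised fractions, named), and
#'   `params`.
#' @export
#' @examples
#' sc <- generate_scene(scene_params(size = 32), seed = 1)
#' table(sc$mask) / length(sc$mask)
generate_scene <- function(params = scene_params(), seed = 1) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(as.integer(seed))
  n <- params$size
  veg_target <- params$fractions[2] + params$fractions[3]

  mask <- matrix(0L, n, n)
  if (veg_target > 0) {
    f_veg <- smooth_field(n, n, params$blob_scale)
    mask[f_veg >= stats::quantile(f_veg, 1 - veg_target)] <- 1L
    # awns: thin 1-2 px segments sprouting from vegetation
    n_awns <- stats::rpois(1, params$awn_density * sum(mask) / 1000)
    if (n_awns > 0 && any(mask == 1L)) {
      origins <- which(mask == 1L)
      for (a in seq_len(n_awns)) {
        o <- origins[sample.int(length(origins), 1)]
        r <- (o - 1L) %% n + 1L
        c0 <- (o - 1L) %/% n + 1L
        ang <- stats::runif(1, 0, 2 * pi)
        len <- sample(6:14, 1)
        rr <- round(r + sin(ang) * seq_len(len))
        cc <- round(c0 + cos(ang) * seq_len(len))
        ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
        mask[cbind(rr[ok], cc[ok])] <- 1L
      }
    }
    # split vegetation into green / senescent by a second field
    veg_idx <- which(mask == 1L)
    if (params$fractions[3] > 0 && length(veg_idx) > 0) {
      f_sen <- smooth_field(n, n, params$blob_scale)
      sen_share <- params$fractions[3] / veg_target
      thr <- stats::quantile(f_sen[veg_idx], 1 - sen_share)
      mask[veg_idx[f_sen[veg_idx] >= thr]] <- 2L
    }
  }

  img <- array(0, dim = c(n, n, 3))
  flat <- matrix(0, n * n, 3)
  for (cl in 0:2) {
    idx <- which(mask == cl)
    if (length(idx) > 0) {
      flat[idx, ] <- sample_class_colors(length(idx),
                                         c("background", "green", "senescent")[cl + 1],
                                         params)
    }
  }
  if (params$noise > 0) {
    flat <- flat + matrix(stats::rnorm(length(flat), sd = params$noise),
                          nrow(flat), 3)
    flat <- pmin(pmax(flat, 0), 1)
  }
  # quantise to 8-bit so that written PNGs round-trip exactly
  flat <- round(flat * 255) / 255
  img[, , 1] <- flat[, 1]; img[, , 2] <- flat[, 2]; img[, , 3] <- flat[, 3]

  realized <- as.numeric(table(factor(mask, levels = 0:2))) / (n * n)
  if (any(abs(realized - params$fractions) > 0.1)) {
    warning("realised class fractions deviate from targets by more than 0.1")
  }
  structure(list(image = img, mask = mask,
                 fractions = c(background = realized[1], green = realized[2],
                               senescent = realized[3]),
                 params = params),
            class = "canopy_scene")
}

#' @export
print.canopy_scene <- function(x, ...) {
  cat(sprintf("synthetic canopy scene %dx%d (%s illumination)\n",
              nrow(x$mask), ncol(x$mask), x$params$regime))
  cat(sprintf("  fractions: background %.3f, green %.3f, senescent %.3f\n",
              x$fractions[1], x$fractions[2], x$fractions[3]))
  invisible(x)
}

#' Display a scene and its ground-truth mask side by side
#'
#' @param x A `"canopy_scene"`.
#' @param ... Unused.
#' @export
plot.canopy_scene <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(0.5, 0.5, 1.5, 0.5))
  on.exit(graphics::par(op))
  graphics::plot(grDevices::as.raster(x$image), main = "image")
  graphics::plot(grDevices::as.raster(mask_to_rgb(x$mask)), main = "mask")
  invisible(x)
}

#' Generate a dataset of scenes with grid annotations
#'
#' Produces `n` scenes and, for each, sparse grid-pixel annotations read
#' off the true mask at the intersections of a regular grid (see
#' [make_grid()]). An optional label-noise rate reassigns a fraction of
#' points to the unsure/unknown/other categories, emulating annotator
#' uncertainty on mixed or extreme pixels.
#'
#' @param n Number of scenes (>= 1).
#' @param params A [scene_params()] shared by all scenes.
#' @param seed Integer seed.
#' @param grid_n Grid points per side (one value, recycled, or one per
#'   scene); the annotation canon is 8--11.
#' @param label_noise Probability that a grid point is relabelled into one
#'   of the non-retained categories.
#' @param subdataset Tag recorded in the annotation table.
#' @return List with `scenes` (list of `"canopy_scene"`) and
#'   `annotations` (a [grid_annotations()] data frame).
#' @export
generate_dataset <- function(n, params = scene_params(), seed = 1,
                             grid_n = 8, label_noise = 0,
                             subdataset = "synthetic") {
  if (n < 1) stop("n must be >= 1")
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, n)
  grid_n <- rep_len(grid_n, n)
  scenes <- vector("list", n)
  ann <- vector("list", n)
  retained <- retained_labels()
  unsure <- setdiff(label_schema(), retained)
  for (i in seq_len(n)) {
    sc <- generate_scene(params, seed = seeds[i])
    scenes[[i]] <- sc
    pts <- make_grid(dim(sc$mask), grid_n[i])
    lab <- retained[sc$mask[cbind(pts$row + 1L, pts$col + 1L)] + 1L]
    if (label_noise > 0) {
      set.seed(seeds[i] %% 1000003L + i)
      flip <- stats::runif(nrow(pts)) < label_noise
      lab[flip] <- sample(unsure, sum(flip), replace = TRUE)
    }
    ann[[i]] <- grid_annotations(image_id = sprintf("scene_%03d", i),
                                 row = pts$row, col = pts$col,
                                 label = lab, subdataset = subdataset)
  }
  list(scenes = scenes, annotations = do.call(rbind, ann))
}

#' Generate a labelled green/senescent pixel dataset
#'
#' Samples raw vegetation pixel colours from the per-class hue and
#' brightness distributions of [scene_params()] and passes them through
#' [extract_features()]. This is the training fodder for the stage-2
#' classifier: with the default disjoint hue ranges the two classes are
#' cleanly separable; passing identical ranges for both classes yields a
#' chance-level control set (flagged with a warning).
#'
#' @param n_per_class Pixels per class (>= 1).
#' @param params A [scene_params()] providing the colour distributions.
#' @param seed Integer seed.
#' @param subset Feature subset to extract; default all 23 channels.
#' @return List of class `"pixel_dataset"`: `features` (matrix), `labels`
#'   (factor with levels green, senescent), `rgb` (n x 3 integer matrix).
#' @export
generate_pixel_dataset <- function(n_per_class, params = scene_params(),
                                   seed = 1,
                                   subset = feature_subset(feature_channels())) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  if (isTRUE(all.equal(params$green_hue, params$senescent_hue))) {
    warning("green and senescent colour distributions are identical; ",
            "classes are indistinguishable by construction")
  }
  set.seed(as.integer(seed))
  g <- sample_class_colors(n_per_class, "green", params)
  s <- sample_class_colors(n_per_class, "senescent", params)
  rgb <- round(rbind(g, s) * 255)
  labels <- factor(rep(c("green", "senescent"), each = n_per_class),
                   levels = c("green", "senescent"))
  structure(list(features = extract_features(rgb, subset),
                 labels = labels, rgb = rgb),
            class = "pixel_dataset")
}

# colour-coded preview of a class mask: black/green/yellow
mask_to_rgb <- function(mask) {
  pal <- rbind(c(0, 0, 0), c(0, 0.8, 0), c(0.95, 0.85, 0.1))
  out <- array(0, dim = c(nrow(mask), ncol(mask), 3))
  for (ch in 1:3) out[, , ch] <- matrix(pal[mask + 1L, ch], nrow(mask))
  out
}
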