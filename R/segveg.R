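#' Assemble the two-stage canopy segmentation model
#'
#' Bundles a fitted stage-1 vegetation/background network with a fitted
#' green/senescent pixel SVM into a single 3-class predictor. At
#' inference, stage 1 assigns every pixel to background or vegetation;
#' the SVM then classifies only the vegetation pixels, and the two binary
#' outputs are merged into a 3-class mask (0 = background, 1 = green
#' vegetation, 2 = senescent vegetation). The merge is conservative: the
#' output's background set equals the stage-1 background set exactly.
#'
#' @param stage1 A 2-class `"seg_net"` from [train_stage1()].
#' @param classifier A `"pixel_svm"` from [train_svm()] whose feature
#'   subset names valid colour channels.
#' @return An object of class `"segveg"`.
#' @export
segveg <- function(stage1, classifier) {
  if (!inherits(stage1, "seg_net") || stage1$classes != 2L) {
    stop("stage1 must be a 2-class seg_net")
  }
  if (!inherits(classifier, "pixel_svm")) stop("classifier must be a pixel_svm")
  bad <- setdiff(classifier$subset, feature_channels())
  if (length(bad) > 0L) {
    stop("classifier uses unknown colour channels: ", paste(bad, collapse = ", "))
  }
  if (!all(c("green", "senescent") %in% classifier$levels)) {
    stop("classifier must predict the classes 'green' and 'senescent'")
  }
  structure(list(stage1 = stage1, classifier = classifier,
                 subset = feature_subset(classifier$subset)),
            class = "segveg")
}

#' @export
print.segveg <- function(x, ...) {
  cat("two-stage canopy segmentation model\n")
  cat("  stage 1: "); print(x$stage1)
  cat("  stage 2: "); print(x$classifier)
  invisible(x)
}

#' Predict a 3-class mask with the two-stage model
#'
#' @param model A [segveg()] bundle.
#' @param image `H x W x 3` RGB array on \[0, 1\].
#' @param svm_all_pixels If `TRUE`, bypass stage 1 and apply the SVM to
#'   every pixel (background included), mapping its green/senescent
#'   decision to classes 1/2. This reproduces the colour-only baseline
#'   that confuses senescent vegetation with soil; the default `FALSE`
#'   is the two-stage architecture.
#' @return Integer matrix valued in \{0, 1, 2\}, same shape as the image.
#' @export
segveg_predict <- function(model, image, svm_all_pixels = FALSE) {
  stopifnot(inherits(model, "segveg"))
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("input must be an RGB array")
  out <- matrix(0L, d[1], d[2])
  if (svm_all_pixels) {
    veg_idx <- seq_len(d[1] * d[2])
  } else {
    veg <- predict_vegetation(model$stage1, image)
    veg_idx <- which(veg == 1L)
    if (length(veg_idx) == 0L) return(out)
  }
  rgb <- round(cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
                     as.vector(image[, , 3]))[veg_idx, , drop = FALSE] * 255)
  feats <- extract_features(rgb, model$subset)
  lab <- classify_pixels(model$classifier, feats)
  out[veg_idx] <- ifelse(lab == "green", 1L, 2L)
  out
}

#' @export
predict.segveg <- function(object, image, svm_all_pixels = FALSE, ...) {
  segveg_predict(object, image, svm_all_pixels = svm_all_pixels)
}

#' Generate pseudo-masks for weak supervision
#'
#' Applies a fitted two-stage model to a set of RGB images and returns
#' the predicted 3-class masks, the training fodder for
#' [train_unet3c()]: no hand-made 3-class masks are needed, the
#' two-stage model is the annotator. Failures on individual images are
#' reported (with the image index) and skipped with a warning rather
#' than silently dropped.
#'
#' @param model A [segveg()] bundle.
#' @param images List of RGB arrays, or a character vector of PNG paths.
#' @param out_dir Optional directory; when given, each mask is written as
#'   `mask_<i>.png` in the stage-1 training layout via [write_mask_png()].
#' @return List with `images` (the successfully processed inputs) and
#'   `masks` (their \{0, 1, 2\} masks).
#' @export
generate_pseudo_masks <- function(model, images, out_dir = NULL) {
  stopifnot(inherits(model, "segveg"))
  if (is.character(images)) images <- lapply(images, read_image_png)
  masks <- vector("list", length(images))
  ok <- logical(length(images))
  for (i in seq_along(images)) {
    res <- tryCatch(segveg_predict(model, images[[i]]), error = function(e) e)
    if (inherits(res, "error")) {
      warning("pseudo-mask generation failed for image ", i, ": ",
              conditionMessage(res))
    } else {
      masks[[i]] <- res
      ok[i] <- TRUE
    }
  }
  masks <- masks[ok]
  images <- images[ok]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(masks)) {
      write_mask_png(masks[[i]], file.path(out_dir, sprintf("mask_%03d.png", i)))
    }
  }
  list(images = images, masks = masks)
}

#' Map a pixel classifier over an RGB colour cube
#'
#' Samples `levels` evenly spaced intensities per channel across
#' \[0, 255\] (inclusive endpoints), classifies all `levels^3` colours
#' with the green/senescent SVM, and returns a point-cloud table. At the
#' default resolution of 35 levels this probes 42,875 colours — a dense
#' enough sweep to visualise where the decision surface places senescent
#' tissue within colour space.
#'
#' @param classifier A `"pixel_svm"`.
#' @param levels Samples per channel, >= 2.
#' @return Data frame of class `"rgb_cube"` with columns `r`, `g`, `b`
#'   (0--255 integers) and `label` (factor).
#' @export
rgb_cube_map <- function(classifier, levels = 35) {
  stopifnot(inherits(classifier, "pixel_svm"))
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2")
  vals <- as.integer(round(seq(0, 255, length.out = levels)))
  grid <- expand.grid(r = vals, g = vals, b = vals)
  feats <- extract_features(as.matrix(grid), feature_subset(classifier$subset))
  grid$label <- classify_pixels(classifier, feats)
  class(grid) <- c("rgb_cube", "data.frame")
  grid
}

#' @export
print.rgb_cube <- function(x, ...) {
  cat(sprintf("RGB colour cube: %d classified colours\n", nrow(x)))
  print(table(x$label))
  invisible(x)
}
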