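#' Configuration for the miniature segmentation network
#'
#' The vegetation/background stage (and the direct 3-class variant) is a
#' small fully convolutional encoder-decoder: one 2x-downsampling encoder
#' level, one decoder level with a skip connection, and a 1x1
#' classification head with softmax. The encoder is pluggable in
#' principle; the shipped miniature tier (`width = 8`, about 3,000
#' parameters, well under 0.5 M) trains in minutes on one CPU, which is
#' the tested default. Optimisation uses the soft Dice loss with Adam and
#' a step-based geometric learning-rate decay from `lr_init` to
#' `lr_final` across the epoch budget, with early stopping on validation
#' Dice loss.
#'
#' @param classes Number of output classes, 2 or 3.
#' @param width Channel width of the first encoder level.
#' @param patch Training patch side in pixels (patches are square; the
#'   full-scale canon is 512, the miniature default 64).
#' @param lr_init,lr_final Initial and final learning rates
#'   (`lr_init > lr_final > 0`); defaults 0.01 and 1e-6.
#' @param schedule Learning-rate schedule; `"step"` decays geometrically
#'   in equal per-epoch steps, `"constant"` holds `lr_init`.
#' @param batch Minibatch size (>= 1).
#' @param epochs Maximum number of epochs.
#' @param patience Early-stopping patience in epochs on validation loss.
#' @param val_fraction Fraction of the training set held out for
#'   validation (at least one patch when the set has >= 4 patches).
#' @param augment Logical: apply random flips/rotations and photometric
#'   jitter during training.
#' @param loss Loss name; only `"dice"` is implemented.
#' @param dice_eps Smoothing constant of the soft Dice loss used during
#'   training.
#' @param tile,overlap Inference tiling: images larger than `tile` pixels
#'   per side are processed in `tile x tile` windows overlapping by
#'   `overlap` pixels and stitched from the window centres.
#' @param seed Integer seed controlling initialisation, shuffling and
#'   augmentation; two runs with identical config and data produce
#'   bitwise-identical loss sequences.
#' @return A list of class `"seg_config"`.
#' @export
seg_config <- function(classes = 2, width = 8, patch = 64,
                       lr_init = 0.01, lr_final = 1e-6,
                       schedule = c("step", "constant"),
                       batch = 8, epochs = 40, patience = 5,
                       val_fraction = 0.15, augment = TRUE,
                       loss = "dice", dice_eps = 1,
                       tile = 512, overlap = 64, seed = 1) {
  schedule <- match.arg(schedule)
  if (!classes %in% c(2, 3)) stop("classes must be 2 or 3")
  if (!(lr_init > lr_final && lr_final > 0)) {
    stop("need lr_init > lr_final > 0")
  }
  if (batch < 1) stop("batch must be >= 1")
  if (loss != "dice") stop("only the dice loss is implemented")
  structure(list(classes = as.integer(classes), width = as.integer(width),
                 patch = as.integer(patch), lr_init = lr_init,
                 lr_final = lr_final, schedule = schedule,
                 batch = as.integer(batch), epochs = as.integer(epochs),
                 patience = as.integer(patience),
                 val_fraction = val_fraction, augment = isTRUE(augment),
                 loss = loss, dice_eps = dice_eps,
                 tile = as.integer(tile), overlap = as.integer(overlap),
                 seed = as.integer(seed)),
            class = "seg_config")
}

#' Soft Dice loss between a probability raster and a binary mask
#'
#' `1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)`. Zero for a
#' perfect binary prediction, one for a disjoint one (up to `eps`).
#'
#' @param p Predicted probabilities in \[0, 1\], any array shape.
#' @param t Target mask of the same shape, values in \{0, 1\}.
#' @param eps Smoothing constant.
#' @return Scalar in \[0, 1\].
#' @export
#' @examples
#' m <- matrix(c(1, 1, 0, 0), 2)
#' dice_loss(m, m)
dice_loss <- function(p, t, eps = 1e-6) {
  if (!identical(dim(p), dim(t)) || length(p) != length(t)) {
    stop("shape mismatch between prediction and target")
  }
  1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
}

init_weights <- function(width, classes) {
  he <- function(fan_in, n) stats::rnorm(n, sd = sqrt(2 / fan_in))
  w <- width
  list(W1 = array(he(27, 9 * 3 * w), dim = c(3, 3, 3, w)),
       b1 = numeric(w),
       W2 = array(he(9 * w, 9 * w * 2 * w), dim = c(3, 3, w, 2 * w)),
       b2 = numeric(2 * w),
       W3 = array(he(27 * w, 9 * 3 * w * w), dim = c(3, 3, 3 * w, w)),
       b3 = numeric(w),
       W4 = matrix(he(w, w * classes), w, classes),
       b4 = numeric(classes))
}

# pad an image (H x W x C array) or mask to even spatial dims by edge
# replication; returns list(x, h, w) with the original size
pad_even <- function(x) {
  d <- dim(x)
  h <- d[1]; w <- d[2]
  ph <- h %% 2L; pw <- w %% 2L
  if (ph == 0L && pw == 0L) return(list(x = x, h = h, w = w))
  if (length(d) == 3L) {
    out <- array(0, dim = c(h + ph, w + pw, d[3]))
    out[seq_len(h), seq_len(w), ] <- x
    if (ph) out[h + 1L, seq_len(w), ] <- x[h, , ]
    if (pw) out[, w + 1L, ] <- out[, w, ]
  } else {
    out <- rbind(x, if (ph) x[h, , drop = FALSE])
    out <- cbind(out, if (pw) out[, ncol(out), drop = FALSE])
  }
  list(x = out, h = h, w = w)
}

check_images_masks <- function(images, masks, classes) {
  if (length(images) == 0L) stop("empty training dataset")
  if (length(images) != length(masks)) stop("images and masks differ in length")
  for (i in seq_along(images)) {
    d <- dim(images[[i]])
    if (length(d) != 3L || d[3] != 3L) stop("image ", i, " is not an RGB array")
    if (!identical(d[1:2], dim(masks[[i]]))) {
      stop("image and mask ", i, " differ in shape")
    }
    if (!all(masks[[i]] %in% 0:(classes - 1L))) {
      stop("mask ", i, " contains values outside {0..", classes - 1L, "}")
    }
  }
  invisible(TRUE)
}

train_segnet <- function(images, masks, config) {
  stopifnot(inherits(config, "seg_config"))
  check_images_masks(images, masks, config$classes)
  set.seed(config$seed)
  n <- length(images)

  prep <- function(i) {
    im <- pad_even(images[[i]])$x
    mk <- pad_even(masks[[i]])$x
    storage.mode(mk) <- "integer"
    list(image = im, mask = mk)
  }
  data <- lapply(seq_len(n), prep)

  n_val <- if (n >= 4) max(1L, floor(config$val_fraction * n)) else 0L
  val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(train_idx) == 0L) train_idx <- seq_len(n)
  monitor_idx <- if (n_val > 0) val_idx else train_idx

  weights <- init_weights(config$width, config$classes)
  m1 <- rapply(weights, function(x) x * 0, how = "replace")
  m2 <- m1
  adam_t <- 0
  lr_for <- function(epoch) {
    if (config$schedule == "constant" || config$epochs == 1L) return(config$lr_init)
    config$lr_init * (config$lr_final / config$lr_init)^((epoch - 1) / (config$epochs - 1))
  }

  log <- data.frame(epoch = integer(0), lr = numeric(0),
                    train_loss = numeric(0), val_loss = numeric(0))
  best <- list(loss = Inf, weights = weights, epoch = 0L)
  stall <- 0L
  for (epoch in seq_len(config$epochs)) {
    lr <- lr_for(epoch)
    order <- sample(train_idx)
    epoch_loss <- 0
    nb <- 0
    for (start in seq(1, length(order), by = config$batch)) {
      batch <- order[start:min(start + config$batch - 1L, length(order))]
      gsum <- NULL
      bloss <- 0
      for (i in batch) {
        d <- data[[i]]
        if (config$augment) {
          a <- augment(d$image, d$mask, seed = sample.int(.Machine$integer.max, 1))
          d <- list(image = a$image, mask = a$mask)
          storage.mode(d$mask) <- "integer"
        }
        g <- segnet_grad(d$image, d$mask, weights, config$classes, config$dice_eps)
        bloss <- bloss + g$loss
        gsum <- if (is.null(gsum)) g$grads else {
          Map(function(a, b) a + b, gsum, g$grads)
        }
      }
      k <- length(batch)
      gsum <- lapply(gsum, function(g) g / k)
      adam_t <- adam_t + 1
      for (nm in names(weights)) {
        m1[[nm]] <- 0.9 * m1[[nm]] + 0.1 * gsum[[nm]]
        m2[[nm]] <- 0.999 * m2[[nm]] + 0.001 * gsum[[nm]]^2
        mhat <- m1[[nm]] / (1 - 0.9^adam_t)
        vhat <- m2[[nm]] / (1 - 0.999^adam_t)
        weights[[nm]] <- weights[[nm]] - lr * mhat / (sqrt(vhat) + 1e-8)
      }
      epoch_loss <- epoch_loss + bloss / k
      nb <- nb + 1
    }
    val_loss <- mean(vapply(monitor_idx, function(i) {
      segnet_loss(data[[i]]$image, data[[i]]$mask, weights,
                  config$classes, config$dice_eps)
    }, numeric(1)))
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 train_loss = epoch_loss / nb,
                                 val_loss = val_loss))
    if (val_loss < best$loss - 1e-6) {
      best <- list(loss = val_loss, weights = weights, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  structure(list(weights = best$weights, config = config, log = log,
                 best_epoch = best$epoch, classes = config$classes),
            class = "seg_net")
}

#' Train the stage-1 vegetation/background network
#'
#' Fits the miniature encoder-decoder to binary masks (0 = background,
#' 1 = vegetation, green or senescent alike). Training minimises the soft
#' Dice loss with Adam under the step-decay schedule of [seg_config()],
#' holds out a validation fraction for early stopping, and is fully
#' reproducible given the config seed.
#'
#' @param images List of `H x W x 3` arrays on \[0, 1\].
#' @param masks List of integer matrices valued in \{0, 1\}, same shapes.
#' @param config A [seg_config()] with `classes = 2`.
#' @return An object of class `"seg_net"` with elements `weights`,
#'   `config`, `log` (per-epoch learning rate and train/validation loss)
#'   and `best_epoch`.
#' @seealso [predict.seg_net()], [predict_vegetation()], [train_unet3c()]
#' @export
train_stage1 <- function(images, masks, config = seg_config(classes = 2)) {
  if (config$classes != 2L) stop("stage 1 is a 2-class model")
  train_segnet(images, masks, config)
}

#' Train the direct 3-class network on (pseudo-)masks
#'
#' Same architecture, loss and training contract as [train_stage1()] but
#' with a 3-class head and multi-class soft Dice. Intended for weak
#' supervision: the masks are typically pseudo-masks produced by
#' [generate_pseudo_masks()] from a fitted two-stage model, so the
#' student network distils the teacher into a single forward pass.
#'
#' @param images List of `H x W x 3` arrays on \[0, 1\].
#' @param masks List of integer matrices valued in \{0, 1, 2\}.
#' @param config A [seg_config()] with `classes = 3`.
#' @return A `"seg_net"` object.
#' @export
train_unet3c <- function(images, masks, config = seg_config(classes = 3)) {
  if (config$classes != 3L) stop("the direct model needs a 3-class config")
  train_segnet(images, masks, config)
}

#' @export
print.seg_net <- function(x, ...) {
  npar <- sum(vapply(x$weights, length, integer(1)))
  cat(sprintf("miniature encoder-decoder: %d classes, width %d, %d parameters\n",
              x$classes, x$config$width, npar))
  cat(sprintf("  trained %d epoch(s), best validation dice loss %.4f at epoch %d\n",
              nrow(x$log), min(x$log$val_loss), x$best_epoch))
  invisible(x)
}

#' Predict class probabilities or labels for an image
#'
#' Runs the fully convolutional network over an RGB image of any size.
#' Images larger than the configured tile size are processed in
#' overlapping tiles and stitched from the tile centres; odd dimensions
#' are edge-padded to even and cropped back. Per-pixel classes are the
#' probability argmax (equivalently a 0.5 threshold in the binary case).
#'
#' @param object A `"seg_net"` model.
#' @param image `H x W x 3` array on \[0, 1\].
#' @param type `"class"` for an integer label matrix (0-based codes) or
#'   `"prob"` for an `H x W x classes` probability array.
#' @param ... Unused.
#' @return Matrix of class codes, or probability array.
#' @export
predict.seg_net <- function(object, image, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L) stop("input must be an RGB array")
  probs <- predict_probs(object, image)
  if (type == "prob") return(probs)
  cls <- apply(probs, c(1, 2), which.max) - 1L
  storage.mode(cls) <- "integer"
  cls
}

predict_probs <- function(object, image) {
  h <- dim(image)[1]; w <- dim(image)[2]
  tile <- object$config$tile
  ov <- object$config$overlap
  run <- function(im) {
    p <- pad_even(im)
    pr <- segnet_forward(p$x, object$weights)
    pr[seq_len(p$h), seq_len(p$w), , drop = FALSE]
  }
  if (h <= tile && w <= tile) return(run(image))

  probs <- array(0, dim = c(h, w, object$classes))
  starts <- function(total) {
    if (total <= tile) return(0L)
    s <- seq(0L, total - tile, by = max(1L, tile - 2L * ov))
    unique(c(s, total - tile))
  }
  for (r0 in starts(h)) {
    for (c0 in starts(w)) {
      tp <- run(image[r0 + seq_len(min(tile, h)), c0 + seq_len(min(tile, w)), ,
                      drop = FALSE])
      th <- dim(tp)[1]; tw <- dim(tp)[2]
      # keep the tile centre, except where the tile touches the image edge
      rlo <- if (r0 == 0L) 1L else ov + 1L
      rhi <- if (r0 + th == h) th else th - ov
      clo <- if (c0 == 0L) 1L else ov + 1L
      chi <- if (c0 + tw == w) tw else tw - ov
      probs[r0 + rlo:rhi, c0 + clo:chi, ] <- tp[rlo:rhi, clo:chi, , drop = FALSE]
    }
  }
  probs
}

#' Predict a binary vegetation mask
#'
#' Convenience wrapper around [predict.seg_net()] for the 2-class stage-1
#' model: returns a \{0, 1\} mask (1 = vegetation) with the same spatial
#' shape as the input.
#'
#' @param model A 2-class `"seg_net"`.
#' @param image `H x W x 3` array on \[0, 1\].
#' @return Integer matrix valued in \{0, 1\}.
#' @export
predict_vegetation <- function(model, image) {
  if (model$classes != 2L) stop("predict_vegetation needs a 2-class model")
  predict(model, image, type = "class")
}

#' Random augmentation of a patch/mask pair
#'
#' Applies horizontal/vertical flips and 90-degree rotations (identically
#' to the image and its mask) plus brightness and contrast jitter (image
#' only; photometric transforms never touch labels). Reproducible given
#' `seed`.
#'
#' @param patch `H x W x 3` array on \[0, 1\].
#' @param mask Matrix of class codes, same spatial shape.
#' @param seed Integer seed.
#' @param geometric,photometric Toggle the two transform families.
#' @param rotations Include quarter-turn rotations among the geometric
#'   transforms; with `rotations = FALSE` the geometric family reduces to
#'   flips, which are involutions (applying the same augmentation twice
#'   recovers the original).
#' @return List with `image` and `mask`.
#' @export
augment <- function(patch, mask, seed = 1, geometric = TRUE,
                    photometric = TRUE, rotations = TRUE) {
  if (!identical(dim(patch)[1:2], dim(mask))) stop("patch/mask shape mismatch")
  set.seed(as.integer(seed))
  img <- patch
  if (geometric) {
    if (stats::runif(1) < 0.5) {  # horizontal flip
      img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
      mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
    }
    if (stats::runif(1) < 0.5) {  # vertical flip
      img <- img[rev(seq_len(dim(img)[1])), , , drop = FALSE]
      mask <- mask[rev(seq_len(nrow(mask))), , drop = FALSE]
    }
    if (rotations) {
      k <- sample(0:3, 1)         # quarter-turn rotations
      rot90a <- function(a) {
        out <- array(0, dim = c(dim(a)[2], dim(a)[1], dim(a)[3]))
        for (ch in seq_len(dim(a)[3])) out[, , ch] <- t(a[, , ch])[rev(seq_len(dim(a)[2])), ]
        out
      }
      rot90m <- function(m) t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
      if (k > 0) for (i in seq_len(k)) { img <- rot90a(img); mask <- rot90m(mask) }
    }
  }
  if (photometric) {
    gain <- stats::runif(1, 0.85, 1.15)     # brightness
    contrast <- stats::runif(1, 0.9, 1.1)
    img <- (img - 0.5) * contrast + 0.5
    img <- pmin(pmax(img * gain, 0), 1)
  }
  list(image = img, mask = mask)
}
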