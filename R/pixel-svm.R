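#' Configuration for the green/senescent pixel classifier
#'
#' Defaults follow the calibrated operating point of the two-stage
#' approach: an RBF-kernel support vector machine with `cost = 1` and
#' `gamma = 1e-3`, the optimum of a leave-one-out grid search, with the
#' RBF kernel chosen because green and senescent pixel clouds are not
#' linearly separable in colour space. Features are z-scored with
#' training-set statistics by default; the RBF kernel at a fixed gamma is
#' scale-sensitive and the channels live on heterogeneous scales (0--255,
#' \[0, 1\], degrees), so standardisation makes the decision surface
#' independent of those unit choices. The flag exposes the
#' unstandardised variant.
#'
#' @param kernel Kernel name, `"radial"` or `"linear"`.
#' @param cost Positive soft-margin cost C.
#' @param gamma Positive RBF width parameter.
#' @param standardize Logical; z-score features with training statistics.
#' @return A list of class `"svm_config"`.
#' @export
svm_config <- function(kernel = c("radial", "linear"), cost = 1,
                       gamma = 1e-3, standardize = TRUE) {
  kernel <- match.arg(kernel)
  if (cost <= 0 || gamma <= 0) stop("cost and gamma must be positive")
  structure(list(kernel = kernel, cost = cost, gamma = gamma,
                 standardize = isTRUE(standardize)),
            class = "svm_config")
}

standardize_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1  # constant columns pass through
  list(center = center, scale = scale)
}

standardize_apply <- function(x, stats) {
  scale(x, center = stats$center, scale = stats$scale)[, , drop = FALSE]
}

standardize_invert <- function(z, stats) {
  sweep(sweep(z, 2, stats$scale, "*"), 2, stats$center, "+")
}

#' Train the green/senescent support vector machine
#'
#' Fits an SVM on labelled vegetation pixels described by colour
#' features. The fitted object stores the feature subset (the training
#' column names) and the standardisation statistics, and refuses to
#' predict on feature matrices whose columns do not match.
#'
#' @param features Numeric matrix, one row per pixel; column names define
#'   the classifier's feature subset.
#' @param labels Factor or character vector with two classes (canonically
#'   `green` and `senescent`), one per row.
#' @param config An [svm_config()].
#' @return An object of class `"pixel_svm"`.
#' @export
#' @examples
#' px <- generate_pixel_dataset(60, seed = 1, subset = default_feature_subset())
#' clf <- train_svm(px$features, px$labels)
#' mean(classify_pixels(clf, px$features) == px$labels)
train_svm <- function(features, labels, config = svm_config()) {
  stopifnot(inherits(config, "svm_config"))
  features <- as.matrix(features)
  labels <- factor(labels)
  if (nrow(features) != length(labels)) {
    stop("feature rows and labels differ in length")
  }
  if (nlevels(droplevels(labels)) < 2L) {
    stop("training data must contain both classes")
  }
  labels <- droplevels(labels)
  std <- if (config$standardize) standardize_fit(features) else NULL
  x <- if (is.null(std)) features else standardize_apply(features, std)
  fit <- e1071::svm(x = x, y = labels, kernel = config$kernel,
                    cost = config$cost, gamma = config$gamma,
                    scale = FALSE)
  structure(list(fit = fit, subset = colnames(features), std = std,
                 config = config, levels = levels(labels),
                 n_train = nrow(features)),
            class = "pixel_svm")
}

#' @export
print.pixel_svm <- function(x, ...) {
  cat(sprintf("pixel SVM (%s kernel, C = %g, gamma = %g)%s\n",
              x$config$kernel, x$config$cost, x$config$gamma,
              if (x$config$standardize) ", standardized features" else ""))
  cat(sprintf("  %d support vectors over %d training pixels; features: %s\n",
              x$fit$tot.nSV, x$n_train, paste(x$subset, collapse = ", ")))
  invisible(x)
}

#' Classify pixels with a trained SVM
#'
#' @param clf A `"pixel_svm"` from [train_svm()].
#' @param features Numeric matrix whose column names match the
#'   classifier's feature subset (order included). An empty matrix yields
#'   an empty factor.
#' @return Factor of predicted labels, one per row.
#' @export
classify_pixels <- function(clf, features) {
  stopifnot(inherits(clf, "pixel_svm"))
  features <- as.matrix(features)
  if (!is.null(clf$subset) &&
      !identical(colnames(features), clf$subset)) {
    stop("feature columns do not match the classifier's subset")
  }
  if (nrow(features) == 0L) return(factor(character(0), levels = clf$levels))
  x <- if (is.null(clf$std)) features else standardize_apply(features, clf$std)
  unname(stats::predict(clf$fit, x))
}

#' @export
predict.pixel_svm <- function(object, newdata, ...) {
  classify_pixels(object, newdata)
}

#' Cross-validated accuracy scorer for wrapper feature selection
#'
#' Returns a scorer function `f(features, labels)` computing mean k-fold
#' cross-validated accuracy of an SVM with the given config. Folds are a
#' deterministic function of `seed` and the sample size, so selection
#' runs are reproducible.
#'
#' @param folds Number of folds.
#' @param config [svm_config()] used for every candidate evaluation.
#' @param seed Integer seed fixing the fold assignment.
#' @return A function `(features, labels) -> accuracy in [0, 1]`.
#' @export
cv_accuracy_scorer <- function(folds = 5, config = svm_config(), seed = 1) {
  force(folds); force(config); force(seed)
  function(features, labels) {
    features <- as.matrix(features)
    labels <- factor(labels)
    n <- nrow(features)
    k <- min(folds, n)
    set.seed(as.integer(seed))
    fold <- sample(rep_len(seq_len(k), n))
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      if (nlevels(droplevels(labels[tr])) < 2L) next
      clf <- train_svm(features[tr, , drop = FALSE], labels[tr], config)
      pred <- classify_pixels(clf, features[!tr, , drop = FALSE])
      correct <- correct + sum(pred == labels[!tr])
    }
    correct / n
  }
}

#' Sequential (step) forward feature selection
#'
#' Greedy wrapper selection: starting from the empty set, each step adds
#' the candidate channel that maximises the cross-validated score of the
#' classifier refitted on the enlarged subset, until the stop rule fires.
#' The shipped configuration mirrors the calibrated pipeline, which
#' retains 14 of the 23 channels, so the default stop rule is a fixed
#' subset size `k`; alternatively selection stops when the best
#' improvement falls below `tol`. Ties are broken lexicographically by
#' channel name, making the procedure deterministic given the data and
#' scorer.
#'
#' @param features Numeric matrix with named columns.
#' @param labels Class labels, one per row.
#' @param candidates Candidate channel names; default all columns.
#' @param k Target subset size (`NULL` to rely on `tol` alone).
#' @param tol Minimum score improvement to continue when `k` is `NULL`.
#' @param scorer Function `(features, labels) -> score`; default
#'   [cv_accuracy_scorer()].
#' @return A [feature_subset()] in selection order, with attributes
#'   `"scores"` (score after each addition).
#' @export
step_forward_select <- function(features, labels, candidates = colnames(features),
                                k = 14, tol = 1e-6,
                                scorer = cv_accuracy_scorer()) {
  features <- as.matrix(features)
  if (is.null(candidates) || length(candidates) == 0L) {
    stop("at least one candidate feature is required")
  }
  if (!all(candidates %in% colnames(features))) {
    stop("candidates must name columns of the feature matrix")
  }
  threshold_mode <- is.null(k)
  k <- if (threshold_mode) length(candidates) else min(k, length(candidates))
  selected <- character(0)
  scores <- numeric(0)
  best_so_far <- -Inf
  remaining <- sort(candidates)  # lexicographic tie-break order
  while (length(selected) < k && length(remaining) > 0L) {
    step_scores <- vapply(remaining, function(cand) {
      scorer(features[, c(selected, cand), drop = FALSE], labels)
    }, numeric(1))
    best <- which.max(step_scores)  # first max = lexicographically smallest
    if (threshold_mode && length(selected) >= 1L &&
        step_scores[best] - best_so_far < tol) {
      break
    }
    selected <- c(selected, remaining[best])
    scores <- c(scores, step_scores[best])
    best_so_far <- step_scores[best]
    remaining <- remaining[-best]
  }
  out <- selected
  attr(out, "scores") <- scores
  class(out) <- "feature_subset"
  out
}

#' Leave-one-out grid search over SVM hyperparameters
#'
#' Scores every `(cost, gamma)` cell of a grid by leave-one-out
#' cross-validated accuracy and returns the argmax, with ties broken by
#' smallest cost then smallest gamma. Leave-one-out refits the model `n`
#' times per cell, so `n` is capped (use k-fold scoring beyond the cap).
#' The degenerate case `n = 2` (one pixel per class) leaves every fold
#' single-class and is rejected.
#'
#' @param features Numeric matrix.
#' @param labels Class labels.
#' @param cost_grid,gamma_grid Positive values to try.
#' @param config Base [svm_config()] supplying kernel/standardisation.
#' @param cap Maximum n for which leave-one-out is attempted.
#' @return List with `best` (named vector cost, gamma) and `scores`
#'   (data frame cost, gamma, accuracy).
#' @export
tune_hyperparameters <- function(features, labels, cost_grid = c(0.1, 1, 10),
                                 gamma_grid = c(1e-3, 1e-2, 1e-1),
                                 config = svm_config(), cap = 200) {
  features <- as.matrix(features)
  labels <- factor(labels)
  n <- nrow(features)
  if (length(cost_grid) == 0L || length(gamma_grid) == 0L) stop("empty grid")
  if (n > cap) {
    stop("n = ", n, " exceeds the leave-one-out cap (", cap,
         "); use k-fold scoring (cv_accuracy_scorer) instead")
  }
  if (any(table(labels) < 2L)) {
    stop("leave-one-out needs at least 2 pixels per class")
  }
  grid <- expand.grid(cost = sort(cost_grid), gamma = sort(gamma_grid))
  grid <- grid[order(grid$cost, grid$gamma), ]
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    cfg <- svm_config(kernel = config$kernel, cost = grid$cost[g],
                      gamma = grid$gamma[g],
                      standardize = config$standardize)
    correct <- vapply(seq_len(n), function(i) {
      clf <- train_svm(features[-i, , drop = FALSE], labels[-i], cfg)
      as.character(classify_pixels(clf, features[i, , drop = FALSE])) ==
        as.character(labels[i])
    }, logical(1))
    mean(correct)
  }, numeric(1))
  best <- which.max(acc)  # grid sorted by (cost, gamma): first max = tie-break
  list(best = c(cost = grid$cost[best], gamma = grid$gamma[best]),
       scores = data.frame(grid, accuracy = acc))
}
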