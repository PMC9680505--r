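#' Confusion matrix between reference and predicted labels
#'
#' Cell (i, j) counts pixels whose reference class is i and predicted
#' class is j (rows = reference, columns = predicted).
#'
#' @param reference,predicted Vectors of equal length with values drawn
#'   from `classes`.
#' @param classes Ordered class list; defaults to the sorted union of the
#'   observed labels.
#' @return Integer matrix of class `"confusion_matrix"` with dimnames
#'   `reference` x `predicted`.
#' @export
confusion <- function(reference, predicted,
                      classes = sort(unique(c(as.character(reference),
                                              as.character(predicted))))) {
  reference <- as.character(reference)
  predicted <- as.character(predicted)
  if (length(reference) != length(predicted)) {
    stop("reference and predicted labels differ in length")
  }
  bad <- setdiff(unique(c(reference, predicted)), as.character(classes))
  if (length(bad) > 0L) stop("labels outside the class list: ",
                             paste(bad, collapse = ", "))
  m <- table(factor(reference, levels = classes),
             factor(predicted, levels = classes))
  m <- matrix(as.integer(m), nrow = length(classes),
              dimnames = list(reference = as.character(classes),
                              predicted = as.character(classes)))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("confusion matrix (rows = reference, columns = predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class and overall classification metrics
#'
#' Derives the standard one-vs-rest counts (Tp, Tn, Fp, Fn) per class and
#' reports, in percent: precision `Tp/(Tp+Fp)`, recall `Tp/(Tp+Fn)`,
#' one-vs-rest accuracy `(Tp+Tn)/n`, F1 `2Tp/(2Tp+Fp+Fn)`, and the
#' half-width of the 95% confidence interval on F1
#' ([f1_confidence_interval()]). The overall F1 is the unweighted mean of
#' the per-class F1 scores; the overall accuracy is the plain multi-class
#' accuracy `trace/n` (the mean one-vs-rest accuracy is also reported as
#' `accuracy_ovr`, the two coincide for two classes).
#'
#' A class absent from both reference and prediction has undefined F1;
#' it is reported as 0 with a warning, and `na_absent = TRUE` instead
#' excludes such classes from the macro means.
#'
#' @param m A [confusion()] matrix.
#' @param na_absent Treat classes absent from both margins as missing
#'   rather than 0.
#' @return A list of class `"metrics_report"`: `per_class` data frame
#'   (tp, fp, fn, tn, precision, recall, accuracy, f1, ci), `accuracy`,
#'   `accuracy_ovr`, `f1_all`, `n`.
#' @export
class_metrics <- function(m, na_absent = FALSE) {
  stopifnot(inherits(m, "confusion_matrix"))
  n <- sum(m)
  k <- nrow(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- n - tp - fp - fn
  absent <- (tp + fp + fn) == 0
  if (any(absent)) {
    warning("class(es) absent from both reference and prediction: ",
            paste(rownames(m)[absent], collapse = ", "),
            "; their F1 is reported as ", if (na_absent) "NA" else "0")
  }
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, 0)
  f1 <- pct(2 * tp, 2 * tp + fp + fn)
  prec <- pct(tp, tp + fp)
  rec <- pct(tp, tp + fn)
  acc_c <- pct(tp + tn, rep(n, k))
  ci <- vapply(seq_len(k), function(i) {
    if (n > 0) f1_confidence_interval(f1[i] / 100, n) else NA_real_
  }, numeric(1))
  if (na_absent) f1[absent] <- NA_real_
  per_class <- data.frame(class = rownames(m), tp = tp, fp = fp, fn = fn,
                          tn = tn, precision = prec, recall = rec,
                          accuracy = acc_c, f1 = f1, ci = ci,
                          row.names = NULL)
  structure(list(per_class = per_class,
                 accuracy = if (n > 0) 100 * sum(tp) / n else NA_real_,
                 accuracy_ovr = mean(acc_c, na.rm = na_absent),
                 f1_all = mean(f1, na.rm = na_absent),
                 n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 1, ...) {
  cat(sprintf("classification metrics over %d pixels\n", x$n))
  df <- x$per_class
  num <- c("precision", "recall", "accuracy", "f1", "ci")
  df[num] <- lapply(df[num], round, digits = digits)
  print(df[c("class", "precision", "recall", "f1", "ci")], row.names = FALSE)
  cat(sprintf("overall accuracy %.*f%%, overall F1 %.*f%%\n",
              digits, x$accuracy, digits, x$f1_all))
  invisible(x)
}

#' 95% confidence-interval half-width on an F1 score
#'
#' `100 * 1.96 * sqrt(f1 * (1 - f1) / n)`, the normal-approximation
#' binomial half-width in percent. Maximal at F1 = 0.5 for fixed n and
#' shrinking as 1/sqrt(n).
#'
#' @param f1 F1 score as a fraction in \[0, 1\].
#' @param n Number of evaluated pixels, >= 1.
#' @return Half-width in percent.
#' @export
#' @examples
#' f1_confidence_interval(0.5, 100)  # 9.8
f1_confidence_interval <- function(f1, n) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(f1 < 0 | f1 > 1)) stop("f1 must be a fraction in [0, 1]")
  100 * 1.96 * sqrt(f1 * (1 - f1) / n)
}

#' Per-class pixel fractions of a mask
#'
#' The canopy fraction of a class is its pixel count divided by the total
#' pixel count. Fractions over all classes of a mask sum to 1 exactly.
#'
#' @param mask Integer matrix of class codes.
#' @param class Optional single class code; when omitted, a named vector
#'   over `classes` is returned.
#' @param classes Class codes to report (default \{0, 1, 2\} or \{0, 1\}
#'   depending on the mask's range).
#' @return Fraction in \[0, 1\], or a named vector of fractions.
#' @export
canopy_fraction <- function(mask, class = NULL,
                            classes = if (max(mask) > 1) 0:2 else 0:1) {
  if (length(mask) == 0L) stop("empty mask")
  counts <- table(factor(as.vector(mask), levels = classes))
  fr <- as.numeric(counts) / length(mask)
  names(fr) <- as.character(classes)
  if (!is.null(class)) return(unname(fr[as.character(class)]))
  fr
}

#' Class fraction over retained grid points
#'
#' Same count ratio as [canopy_fraction()] but over a set of sparse grid
#' labels or predictions rather than a dense mask. As the grid densifies
#' the grid fraction converges to the whole-mask fraction.
#'
#' @param labels Vector of class labels at the retained grid points.
#' @param class The class whose fraction is wanted.
#' @return Fraction in \[0, 1\].
#' @export
grid_fraction <- function(labels, class) {
  if (length(labels) == 0L) stop("no retained grid points")
  mean(as.character(labels) == as.character(class))
}

#' Agreement regression between predicted and reference fractions
#'
#' Regresses predicted per-image fractions on reference ones and reports
#' `R2 = 1 - sum((pred - ref)^2) / sum((ref - mean(ref))^2)`,
#' `RMSE = sqrt(mean((ref - pred)^2))`, and the ordinary least-squares
#' slope and offset of `pred ~ ref`. With a constant reference the R2 is
#' undefined and reported as `NaN` with a warning.
#'
#' @param predicted,reference Numeric vectors of per-image fractions,
#'   length >= 2.
#' @return List with `r2`, `rmse`, `slope`, `offset`, `n`.
#' @export
fraction_regression <- function(predicted, reference) {
  if (length(predicted) != length(reference)) stop("length mismatch")
  if (length(predicted) < 2L) stop("need at least 2 images")
  ss_tot <- sum((reference - mean(reference))^2)
  if (ss_tot == 0) {
    warning("constant reference fractions: R2 is undefined")
    r2 <- NaN
  } else {
    r2 <- 1 - sum((predicted - reference)^2) / ss_tot
  }
  fit <- stats::lm(predicted ~ reference)
  list(r2 = r2,
       rmse = sqrt(mean((reference - predicted)^2)),
       slope = unname(stats::coef(fit)[2]),
       offset = unname(stats::coef(fit)[1]),
       n = length(predicted))
}

#' Model-vs-model agreement ("similitude")
#'
#' Builds the standard confusion matrix and metrics with one model's
#' predictions as the reference and another's as the prediction. This
#' quantifies agreement between models over the same pixels, not
#' correctness against ground truth; `similitude(A, A)` is exact
#' agreement (off-diagonal zero, accuracy 100).
#'
#' @param reference Labels (or a list of masks) from the reference model.
#' @param predicted Labels (or a list of masks) from the compared model;
#'   must cover exactly the same pixels.
#' @param classes Ordered class list; defaults as in [confusion()].
#' @return List with `confusion` and `metrics`.
#' @export
similitude <- function(reference, predicted, classes = NULL) {
  flatten <- function(x) {
    if (is.list(x)) unlist(lapply(x, as.vector), use.names = FALSE)
    else as.vector(x)
  }
  ref <- flatten(reference)
  pred <- flatten(predicted)
  if (length(ref) != length(pred)) {
    stop("the two models must be evaluated over the same pixels")
  }
  cm <- if (is.null(classes)) confusion(ref, pred) else confusion(ref, pred, classes)
  list(confusion = cm, metrics = class_metrics(cm))
}

#' Brightness/saturation profile of misclassified pixels
#'
#' For each evaluated pixel, computes HSV brightness V and saturation S
#' and flags whether the prediction matched the reference. Returns the
#' per-pixel table plus empirical cumulative distribution functions of
#' brightness for the misclassified and well-classified groups —
#' misclassifications concentrating at the dark and saturated ends of
#' the brightness range show up as a separation between the two curves.
#'
#' @param rgb Pixel colours (`n x 3`, 0--255).
#' @param reference,predicted Labels, one per pixel.
#' @return List of class `"color_profile"`: `table` (data frame V, S,
#'   correct), `ecdf_misclassified`, `ecdf_correct` (each `NULL` if its
#'   group is empty).
#' @export
misclassification_color_profile <- function(rgb, reference, predicted) {
  if (length(reference) != length(predicted)) stop("length mismatch")
  hsv <- rgb_to_hsv(rgb)
  if (nrow(hsv) != length(reference)) stop("one RGB row per label is required")
  correct <- as.character(reference) == as.character(predicted)
  tab <- data.frame(V = hsv[, "V"], S = hsv[, "S"], correct = correct)
  structure(list(
    table = tab,
    ecdf_misclassified = if (any(!correct)) stats::ecdf(tab$V[!correct]),
    ecdf_correct = if (any(correct)) stats::ecdf(tab$V[correct])),
    class = "color_profile")
}

#' @export
print.color_profile <- function(x, ...) {
  cat(sprintf("colour profile over %d pixels (%d misclassified)\n",
              nrow(x$table), sum(!x$table$correct)))
  invisible(x)
}

#' Plot cumulative brightness distributions of a colour profile
#'
#' @param x A `"color_profile"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.color_profile <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "brightness V", ylab = "cumulative fraction", ...)
  v <- seq(0, 1, length.out = 201)
  if (!is.null(x$ecdf_correct)) {
    graphics::lines(v, x$ecdf_correct(v), col = "blue")
  }
  if (!is.null(x$ecdf_misclassified)) {
    graphics::lines(v, x$ecdf_misclassified(v), col = "red")
  }
  graphics::legend("bottomright", c("well-classified", "misclassified"),
                   col = c("blue", "red"), lty = 1, bty = "n")
  invisible(x)
}
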