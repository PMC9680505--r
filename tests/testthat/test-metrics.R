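# independent brute-force one-vs-rest metrics used as the oracle
brute_metrics <- function(ref, pred, classes) {
  per <- lapply(classes, function(cl) {
    tp <- sum(ref == cl & pred == cl)
    fp <- sum(ref != cl & pred == cl)
    fn <- sum(ref == cl & pred != cl)
    tn <- sum(ref != cl & pred != cl)
    c(precision = if (tp + fp > 0) 100 * tp / (tp + fp) else 0,
      recall = if (tp + fn > 0) 100 * tp / (tp + fn) else 0,
      f1 = if (2 * tp + fp + fn > 0) 100 * 2 * tp / (2 * tp + fp + fn) else 0)
  })
  list(per = do.call(rbind, per),
       accuracy = 100 * mean(ref == pred))
}

test_that("confusion matrices count exactly", {
  ref <- c("g", "g", "s", "b")
  pred <- c("g", "s", "s", "b")
  cm <- confusion(ref, pred, classes = c("b", "g", "s"))
  expect_equal(unclass(cm),
               matrix(as.integer(c(1, 0, 0, 0, 1, 0, 0, 1, 1)), 3,
                      dimnames = list(reference = c("b", "g", "s"),
                                      predicted = c("b", "g", "s"))),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 4L)
  perfect <- confusion(rep(c("g", "s"), 25), rep(c("g", "s"), 25))
  expect_equal(sum(diag(perfect)), 50L)
  empty <- confusion(character(0), character(0), classes = c("g", "s"))
  expect_true(all(empty == 0L))
  expect_error(confusion(c("g"), c("g", "s")), "length")
  expect_error(confusion("x", "g", classes = "g"), "outside")
})

test_that("class metrics match a brute-force oracle on random instances", {
  set.seed(3)
  for (rep in 1:100) {
    k <- sample(2:4, 1)
    classes <- letters[1:k]
    n <- sample(5:40, 1)
    ref <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    cm <- confusion(ref, pred, classes = classes)
    got <- suppressWarnings(class_metrics(cm))
    want <- brute_metrics(ref, pred, classes)
    expect_equal(got$per_class$precision, unname(want$per[, "precision"]))
    expect_equal(got$per_class$recall, unname(want$per[, "recall"]))
    expect_equal(got$per_class$f1, unname(want$per[, "f1"]))
    expect_equal(got$accuracy, want$accuracy)
    expect_equal(got$f1_all, mean(want$per[, "f1"]))
  }
})

test_that("metric edge cases follow the documented conventions", {
  perfect <- class_metrics(confusion(rep(c("g", "s"), 10), rep(c("g", "s"), 10)))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$f1_all, 100)
  expect_true(all(perfect$per_class$precision == 100))
  # macro mean of per-class F1
  ref <- c(rep("g", 5), rep("s", 5))
  pred <- c("g", "g", "g", "g", "s", rep("s", 5))
  m <- class_metrics(confusion(ref, pred, classes = c("g", "s")))
  expect_equal(m$f1_all, mean(m$per_class$f1))
  # class absent from both margins: F1 0 with warning, NA under the flag
  cm <- confusion(c("g", "g"), c("g", "g"), classes = c("g", "s"))
  expect_warning(z <- class_metrics(cm), "absent")
  expect_equal(z$per_class$f1[2], 0)
  expect_warning(na <- class_metrics(cm, na_absent = TRUE))
  expect_true(is.na(na$per_class$f1[2]))
  expect_equal(na$f1_all, 100)
})

test_that("the F1 confidence interval follows its closed form", {
  expect_equal(f1_confidence_interval(0.5, 100), 9.8)
  expect_equal(f1_confidence_interval(1, 57), 0)
  expect_equal(f1_confidence_interval(0.9, 13606), 0.504, tolerance = 1e-3)
  # decreasing in n, maximal at 0.5
  ns <- c(10, 100, 1000, 10000)
  expect_true(all(diff(f1_confidence_interval(0.5, ns)) < 0))
  f1s <- seq(0.05, 0.95, by = 0.05)
  ci <- f1_confidence_interval(f1s, 100)
  expect_equal(f1s[which.max(ci)], 0.5)
  expect_error(f1_confidence_interval(0.5, 0), "n must")
})

test_that("canopy and grid fractions are exact count ratios", {
  mask <- matrix(0L, 10, 10)
  mask[1:25] <- 1L
  expect_equal(canopy_fraction(mask, class = 1), 0.25)
  expect_equal(canopy_fraction(matrix(0L, 5, 5), class = 1, classes = 0:2), 0)
  expect_equal(sum(canopy_fraction(mask, classes = 0:2)), 1)
  set.seed(8)
  rnd <- matrix(sample(0:2, 400, replace = TRUE), 20)
  expect_equal(unname(canopy_fraction(rnd, class = 2)),
               sum(rnd == 2) / 400)
  expect_error(canopy_fraction(integer(0)), "empty")
  labs <- c(rep("green_veg", 16), rep("background", 48))
  expect_equal(grid_fraction(labs, "green_veg"), 0.25)
  expect_equal(grid_fraction(rep("sen_veg", 9), "sen_veg"), 1)
  expect_error(grid_fraction(character(0), "sen_veg"), "no retained")
})

test_that("grid fractions converge to mask fractions as the grid densifies", {
  diffs <- vapply(1:20, function(i) {
    sc <- generate_scene(scene_params(size = 64), seed = 400 + i)
    pts <- suppressWarnings(make_grid(dim(sc$mask), 32))
    labs <- sc$mask[cbind(pts$row + 1L, pts$col + 1L)]
    abs(grid_fraction(labs, 1) - canopy_fraction(sc$mask, class = 1))
  }, numeric(1))
  expect_lte(mean(diffs), 0.05)
})

test_that("fraction regression matches least squares and handles offsets", {
  ref <- c(0.2, 0.4, 0.6, 0.8)
  same <- fraction_regression(ref, ref)
  expect_equal(same$r2, 1)
  expect_equal(same$rmse, 0)
  expect_equal(same$slope, 1)
  expect_equal(same$offset, 0)
  shifted <- fraction_regression(ref + 0.1, ref)
  expect_equal(shifted$rmse, 0.1)
  expect_equal(shifted$slope, 1)
  expect_equal(shifted$offset, 0.1)
  set.seed(12)
  x <- runif(30); y <- 0.8 * x + 0.05 + rnorm(30, 0, 0.03)
  got <- fraction_regression(y, x)
  # hand-coded least-squares oracle
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  expect_equal(got$slope, slope, tolerance = 1e-9)
  expect_equal(got$offset, mean(y) - slope * mean(x), tolerance = 1e-9)
  expect_equal(got$r2, 1 - sum((y - x)^2) / sxx, tolerance = 1e-9)
  expect_equal(got$rmse, sqrt(mean((x - y)^2)), tolerance = 1e-12)
  expect_warning(const <- fraction_regression(c(0.1, 0.2), c(0.5, 0.5)),
                 "undefined")
  expect_true(is.nan(const$r2))
  expect_error(fraction_regression(1, 1), "at least 2")
})

test_that("similitude treats one model's output as the reference", {
  a <- matrix(sample(0:2, 100, replace = TRUE), 10)
  self <- similitude(a, a, classes = 0:2)
  expect_equal(self$metrics$accuracy, 100)
  expect_true(all(self$confusion[upper.tri(self$confusion)] == 0L))
  expect_true(all(self$confusion[lower.tri(self$confusion)] == 0L))
  b <- a; b[1] <- (a[1] + 1) %% 3
  one_off <- similitude(a, b, classes = 0:2)
  expect_equal(one_off$metrics$accuracy, 99)
  expect_error(similitude(a, b[1:50]), "same pixels")
})

test_that("the misclassification colour profile isolates wrong pixels", {
  set.seed(13)
  rgb <- matrix(sample(0:255, 300, replace = TRUE), ncol = 3)
  ref <- sample(c("g", "s"), 100, replace = TRUE)
  # all correct -> empty misclassified table
  all_ok <- misclassification_color_profile(rgb, ref, ref)
  expect_equal(sum(!all_ok$table$correct), 0L)
  expect_null(all_ok$ecdf_misclassified)
  # single wrong pixel -> its V and S are reported
  one <- misclassification_color_profile(rgb[1, , drop = FALSE], "g", "s")
  expect_equal(nrow(one$table), 1L)
  expect_false(one$table$correct)
  expect_equal(one$table$V, rgb_to_hsv(rgb[1, ])[, "V"], ignore_attr = TRUE)
  expect_error(misclassification_color_profile(rgb, ref, ref[-1]), "mismatch")
})

test_that("errors constructed among dark pixels dominate the brightness ecdf", {
  set.seed(14)
  v <- runif(400)
  rgb <- round(cbind(v, v, v) * 255)
  ref <- rep("g", 400)
  pred <- ifelse(v < 0.1, "s", "g")  # only dark pixels are wrong
  prof <- misclassification_color_profile(rgb, ref, pred)
  grid <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(prof$ecdf_misclassified(grid) >= prof$ecdf_correct(grid)))
})
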