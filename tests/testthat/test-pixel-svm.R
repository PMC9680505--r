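make_clusters <- function(n = 200, sep = 3, sd = 1, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("green", "senescent"), each = n / 2))
  x <- cbind(f1 = rnorm(n, ifelse(y == "green", -sep, sep), sd),
             f2 = rnorm(n, 0, sd))
  list(x = x, y = y)
}

test_that("well-separated clusters are classified almost perfectly", {
  d <- make_clusters(n = 200, sep = 3, sd = 1, seed = 1)
  clf <- train_svm(d$x, d$y, svm_config(cost = 1, gamma = 0.5))
  expect_gte(mean(classify_pixels(clf, d$x) == d$y), 0.99)
})

test_that("the rbf kernel solves XOR where a linear kernel cannot", {
  set.seed(9)
  n <- 400
  x1 <- runif(n, -1, 1); x2 <- runif(n, -1, 1)
  y <- factor(ifelse(xor(x1 > 0, x2 > 0), "green", "senescent"))
  X <- cbind(a = x1 + rnorm(n, 0, 0.05), b = x2 + rnorm(n, 0, 0.05))
  rbf <- train_svm(X, y, svm_config(cost = 10, gamma = 1))
  lin <- train_svm(X, y, svm_config(kernel = "linear", cost = 10, gamma = 1))
  expect_gte(mean(classify_pixels(rbf, X) == y), 0.95)
  expect_lte(mean(classify_pixels(lin, X) == y), 0.6)
})

test_that("the decision surface survives dataset duplication and row shuffling", {
  px <- generate_pixel_dataset(50, seed = 2, subset = default_feature_subset())
  cfg <- svm_config(cost = 100, gamma = 0.1)
  probe <- generate_pixel_dataset(100, seed = 3,
                                  subset = default_feature_subset())$features
  c1 <- train_svm(px$features, px$labels, cfg)
  c2 <- train_svm(rbind(px$features, px$features),
                  c(px$labels, px$labels), cfg)
  expect_equal(classify_pixels(c1, probe), classify_pixels(c2, probe))
  set.seed(4)
  perm <- sample(nrow(px$features))
  c3 <- train_svm(px$features[perm, ], px$labels[perm], cfg)
  expect_equal(classify_pixels(c1, probe), classify_pixels(c3, probe))
})

test_that("classification memorises separable training points and guards inputs", {
  px <- generate_pixel_dataset(60, seed = 6, subset = default_feature_subset())
  clf <- train_svm(px$features, px$labels, svm_config(cost = 100, gamma = 0.1))
  expect_equal(classify_pixels(clf, px$features), px$labels, ignore_attr = TRUE)
  # empty feature matrix -> empty labels
  empty <- px$features[0, , drop = FALSE]
  expect_length(classify_pixels(clf, empty), 0L)
  # column mismatch is refused
  wrong <- px$features[, rev(colnames(px$features))]
  expect_error(classify_pixels(clf, wrong), "subset")
  expect_error(train_svm(px$features, rep("green", nrow(px$features))),
               "both classes")
  expect_error(train_svm(px$features, px$labels[-1]), "length")
})

test_that("standardisation round-trips and is stored with the model", {
  set.seed(5)
  x <- matrix(rnorm(60, mean = 100, sd = 25), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  st <- canopyseg:::standardize_fit(x)
  z <- canopyseg:::standardize_apply(x, st)
  expect_equal(canopyseg:::standardize_invert(z, st), x, tolerance = 1e-12)
  d <- make_clusters(seed = 2)
  clf <- train_svm(d$x, d$y)
  expect_named(clf$std, c("center", "scale"))
  off <- train_svm(d$x, d$y, svm_config(standardize = FALSE))
  expect_null(off$std)
})

test_that("step-forward selection recovers the informative features", {
  set.seed(11)
  n <- 120
  y <- factor(rep(c("green", "senescent"), each = n / 2))
  X <- cbind(f1 = rnorm(n, ifelse(y == "green", -1.5, 1.5)),
             f2 = rnorm(n, ifelse(y == "green", 1.5, -1.5)),
             f3 = rnorm(n), f4 = rnorm(n), f5 = rnorm(n))
  sc <- cv_accuracy_scorer(folds = 5, config = svm_config(cost = 1, gamma = 0.1),
                           seed = 3)
  sel <- step_forward_select(X, y, k = 2, scorer = sc)
  expect_setequal(unclass(sel)[1:2], c("f1", "f2"))
  # exhaustive oracle over all subsets of size <= 2 agrees
  subs <- c(as.list(colnames(X)), utils::combn(colnames(X), 2, simplify = FALSE))
  scores <- vapply(subs, function(s) sc(X[, s, drop = FALSE], y), numeric(1))
  expect_setequal(subs[[which.max(scores)]], unclass(sel)[1:2])
})

test_that("step-forward selection honours trivial stop rules", {
  d <- make_clusters(seed = 7)
  sc <- cv_accuracy_scorer(folds = 3, config = svm_config(cost = 1, gamma = 0.1),
                           seed = 1)
  all5 <- step_forward_select(d$x, d$y, k = ncol(d$x), scorer = sc)
  expect_setequal(unclass(all5), colnames(d$x))
  one <- step_forward_select(d$x[, "f1", drop = FALSE], d$y, k = 1, scorer = sc)
  expect_equal(unclass(one), "f1", ignore_attr = TRUE)
  expect_error(step_forward_select(d$x, d$y, candidates = character(0)),
               "at least one")
})

test_that("leave-one-out grid search matches a brute-force oracle", {
  set.seed(10)
  y <- factor(rep(c("green", "senescent"), each = 20))
  x <- cbind(f = rnorm(40, ifelse(y == "green", 80, 180), 15),
             g = rnorm(40, 128, 20))
  cfg <- svm_config(standardize = FALSE)
  tu <- tune_hyperparameters(x, y, cost_grid = 1, gamma_grid = c(1e-3, 10),
                             config = cfg)
  # independent brute-force LOO for each cell
  loo <- function(cost, gamma) {
    mean(vapply(seq_len(nrow(x)), function(i) {
      f <- e1071::svm(x = x[-i, ], y = y[-i], kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
      as.character(predict(f, x[i, , drop = FALSE])) == as.character(y[i])
    }, logical(1)))
  }
  expect_equal(tu$scores$accuracy[tu$scores$gamma == 1e-3], loo(1, 1e-3))
  expect_equal(tu$scores$accuracy[tu$scores$gamma == 10], loo(1, 10))
  # on raw colour-scale clusters the wide kernel beats the narrow one
  expect_gte(tu$scores$accuracy[tu$scores$gamma == 1e-3],
             tu$scores$accuracy[tu$scores$gamma == 10])
  expect_equal(unname(tu$best), c(1, 1e-3))
})

test_that("grid-search guards: single cell, tie-break, cap and degenerate n", {
  d <- make_clusters(n = 40, seed = 3)
  one <- tune_hyperparameters(d$x, d$y, cost_grid = 2, gamma_grid = 0.5)
  expect_equal(unname(one$best), c(2, 0.5))
  # a duplicated-score grid resolves ties to smallest cost then gamma
  two <- tune_hyperparameters(d$x, d$y, cost_grid = c(5, 1), gamma_grid = 0.5)
  if (two$scores$accuracy[1] == two$scores$accuracy[2]) {
    expect_equal(unname(two$best["cost"]), 1)
  }
  expect_error(tune_hyperparameters(d$x, d$y, cap = 10), "cap")
  tiny <- make_clusters(n = 2, seed = 1)
  expect_error(tune_hyperparameters(tiny$x, tiny$y), "2 pixels per class")
})
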