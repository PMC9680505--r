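#' The six-label annotation schema
#'
#' Sparse grid-pixel annotation uses six categories: the three retained
#' classes (`green_veg`, `sen_veg`, `background`) plus three uncertainty
#' categories (`green_sen_unsure`, `unknown`, `other`) that are dropped
#' before training and evaluation.
#'
#' @return `label_schema()` returns all six labels; `retained_labels()`
#'   the three retained ones, ordered background, green, senescent to
#'   match mask class codes 0, 1, 2.
#' @export
label_schema <- function() {
  c("background", "green_veg", "sen_veg",
    "green_sen_unsure", "unknown", "other")
}

#' @rdname label_schema
#' @export
retained_labels <- function() {
  c("background", "green_veg", "sen_veg")
}

#' Regular annotation grid over an image
#'
#' Places an `n x n` grid of points at the cell centres of a uniform
#' `n x n` partition of the image — a symmetric, boundary-safe layout.
#' Coordinates are 0-based `(row, col)` with row increasing downward. On a
#' 512 x 512 image with `n = 8` the first point falls at (32, 32) with
#' spacing 64. The annotation canon uses 8 to 11 points per side; other
#' values are allowed with a warning.
#'
#' @param shape Image shape `c(height, width)`.
#' @param n Points per side (n x n points in total).
#' @return Data frame with integer columns `row`, `col`, in row-major
#'   order.
#' @export
#' @examples
#' head(make_grid(c(512, 512), 8))
make_grid <- function(shape, n) {
  h <- as.integer(shape[1]); w <- as.integer(shape[2])
  n <- as.integer(n)
  if (n < 1) stop("n must be >= 1")
  if (n > min(h, w)) stop("image smaller than grid")
  if (n < 8 || n > 11) {
    warning("grid sides of 8-11 points are the annotation canon; got n = ", n)
  }
  rows <- as.integer(floor((seq_len(n) - 0.5) * h / n))
  cols <- as.integer(floor((seq_len(n) - 0.5) * w / n))
  data.frame(row = rep(rows, each = n), col = rep(cols, times = n))
}

#' Construct a grid annotation set
#'
#' @param image_id Image identifier (recycled).
#' @param row,col 0-based pixel coordinates.
#' @param label Labels from [label_schema()].
#' @param subdataset Source sub-dataset tag (recycled).
#' @return Data frame of class `"grid_annotations"` with columns
#'   `image_id`, `row`, `col`, `label`, `subdataset`.
#' @export
grid_annotations <- function(image_id, row, col, label,
                             subdataset = "default") {
  bad <- setdiff(unique(label), label_schema())
  if (length(bad) > 0L) stop("invalid label(s): ", paste(bad, collapse = ", "))
  out <- data.frame(image_id = as.character(image_id),
                    row = as.integer(row), col = as.integer(col),
                    label = as.character(label),
                    subdataset = as.character(subdataset))
  if (anyDuplicated(out[c("image_id", "row", "col")])) {
    stop("duplicate grid points within an image")
  }
  if (any(out$row < 0) || any(out$col < 0)) stop("coordinates must be >= 0")
  class(out) <- c("grid_annotations", "data.frame")
  out
}

#' Drop uncertain annotations
#'
#' Keeps only the three retained classes; points labelled
#' `green_sen_unsure`, `unknown` or `other` are removed (never relabelled)
#' and their counts reported via a message. An all-uncertain input yields
#' an empty set with a warning.
#'
#' @param ann A [grid_annotations()] set.
#' @return The filtered set, with a `"dropped"` attribute holding the
#'   per-category counts of removed points.
#' @export
filter_retained <- function(ann) {
  stopifnot(inherits(ann, "grid_annotations"))
  bad <- setdiff(unique(ann$label), label_schema())
  if (length(bad) > 0L) stop("invalid label(s): ", paste(bad, collapse = ", "))
  keep <- ann$label %in% retained_labels()
  dropped <- table(factor(ann$label[!keep],
                          levels = setdiff(label_schema(), retained_labels())))
  if (any(dropped > 0)) {
    message("dropped ", sum(dropped), " uncertain point(s): ",
            paste(sprintf("%s=%d", names(dropped), dropped), collapse = ", "))
  }
  out <- ann[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("no retained annotations remain")
  attr(out, "dropped") <- dropped
  out
}

#' Random train/test split of annotated pixels per sub-dataset
#'
#' Splits annotation points into training and testing pools at the pixel
#' level, with a separate train fraction per sub-dataset. The reference
#' scheme holds one sub-dataset out entirely (fraction 0) and assigns 30%
#' and ~40% of the other two to training; fractions are targets, with the
#' train count rounded down. Reproducible by `seed`; per sub-dataset the
#' two pools are disjoint and their union is the input.
#'
#' @param ann A [grid_annotations()] set.
#' @param fractions Named numeric vector mapping subdataset tag to train
#'   fraction in \[0, 1\]; unnamed scalar applies to all.
#' @param seed Integer seed.
#' @return List with `train` and `test`, both `"grid_annotations"`.
#' @export
split_train_test <- function(ann, fractions, seed = 1) {
  stopifnot(inherits(ann, "grid_annotations"))
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  set.seed(as.integer(seed))
  subs <- unique(ann$subdataset)
  train_idx <- integer(0)
  for (s in subs) {
    f <- if (is.null(names(fractions))) fractions[1] else {
      if (!s %in% names(fractions)) stop("no train fraction given for subdataset ", s)
      fractions[[s]]
    }
    idx <- which(ann$subdataset == s)
    n_train <- floor(f * length(idx))
    if (n_train > 0) train_idx <- c(train_idx, sample(idx, n_train))
  }
  train <- ann[sort(train_idx), , drop = FALSE]
  test <- ann[setdiff(seq_len(nrow(ann)), train_idx), , drop = FALSE]
  class(train) <- class(test) <- c("grid_annotations", "data.frame")
  list(train = train, test = test)
}

#' Read and write annotation CSV files
#'
#' The on-disk format is a plain CSV with header
#' `image_id,row,col,label,subdataset`; coordinates 0-based. Reading
#' validates every label and reports offending data lines by number;
#' write-then-read round-trips losslessly.
#'
#' @param path CSV file path.
#' @param ann A [grid_annotations()] set for writing.
#' @return `read_annotations` returns a `"grid_annotations"` data frame;
#'   `write_annotations` returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, colClasses = c(image_id = "character",
                                             row = "integer", col = "integer",
                                             label = "character",
                                             subdataset = "character"))
  need <- c("image_id", "row", "col", "label", "subdataset")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns ", paste(need, collapse = ", "))
  }
  bad <- which(!df$label %in% label_schema())
  if (length(bad) > 0L) {
    stop("invalid label(s) at line(s) ",
         paste(bad + 1L, collapse = ", "),  # +1 for the header line
         ": ", paste(unique(df$label[bad]), collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(grid_annotations(character(0), integer(0), integer(0),
                            character(0), character(0)))
  }
  grid_annotations(df$image_id, df$row, df$col, df$label, df$subdataset)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "grid_annotations"))
  utils::write.csv(as.data.frame(ann), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
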