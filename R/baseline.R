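# Pixel-interval color baseline: a pixel belongs to a class when all three
# RGB channels fall inside that class's mean +/- half-width interval; the
# cell label is the majority membership over non-background pixels.

#' Baseline RGB color profile
#'
#' The defaults are the published interval parameters: pink pixels at
#' (133.83, 75.84, 182.24) and blue pixels at (70.99, 75.87, 163.05), each
#' channel with a shared +/- 27 half-width. With these values the red-channel
#' intervals of the two classes are disjoint, so no pixel can match both.
#'
#' @param pink_mean RGB triple of the pink interval centers.
#' @param blue_mean RGB triple of the blue interval centers.
#' @param half_width positive half-width applied to every channel.
#' @return A `color_profile` object.
#' @export
color_profile <- function(pink_mean = c(133.83, 75.84, 182.24),
                          blue_mean = c(70.99, 75.87, 163.05),
                          half_width = 27) {
  if (half_width <= 0) stop("half_width must be positive")
  if (any(pink_mean < 0 | pink_mean > 255) ||
      any(blue_mean < 0 | blue_mean > 255)) {
    stop("interval centers must lie in [0, 255]")
  }
  structure(list(pink_mean = pink_mean, blue_mean = blue_mean,
                 half_width = half_width),
            class = "color_profile")
}

#' Calibrate a color profile from sample images
#'
#' Samples `n_sample_images` images per class, computes per-class channel
#' means over their cell (non-background) pixels as interval centers, and the
#' pooled per-channel standard deviation as the shared half-width. Pass
#' `half_width` to keep a fixed width (the published value is 27) instead of
#' the pooled estimate.
#'
#' @param ds a [labeled_dataset()] containing both classes.
#' @param n_sample_images images sampled per class.
#' @param seed integer seed for the sampling.
#' @param background_threshold channel value for background masking.
#' @param half_width optional fixed half-width overriding the pooled SD.
#' @return A [color_profile()].
#' @export
calibrate_profile <- function(ds, n_sample_images = 5L, seed = 1L,
                              background_threshold = 250, half_width = NULL) {
  labels <- dataset_labels(ds)
  means <- list()
  pooled_ss <- 0
  pooled_n <- 0
  sampled <- with_seed(seed, {
    lapply(c("blue", "pink"), function(cl) {
      pool <- which(labels == cl)
      if (length(pool) == 0) stop("class '", cl, "' absent from the dataset")
      sample(pool, min(n_sample_images, length(pool)))
    })
  })
  names(sampled) <- c("blue", "pink")
  for (cl in c("blue", "pink")) {
    px <- do.call(rbind, lapply(ds$images[sampled[[cl]]], cell_pixel_matrix,
                                background_threshold = background_threshold))
    if (nrow(px) == 0) stop("sampled '", cl, "' images have no cell pixels")
    means[[cl]] <- colMeans(px)
    ctr <- sweep(px, 2, means[[cl]])
    pooled_ss <- pooled_ss + sum(ctr^2)
    pooled_n <- pooled_n + length(ctr)
  }
  hw <- half_width %||% max(sqrt(pooled_ss / max(pooled_n - 1, 1)), 1e-6)
  color_profile(pink_mean = means$pink, blue_mean = means$blue,
                half_width = hw)
}

#' Classify pixels by interval membership
#'
#' A pixel is `"pink"` when every channel lies within the pink interval,
#' `"blue"` analogously; `"both"` and `"neither"` cover the remaining cases
#' (with the default profile `"both"` cannot occur, as the red intervals are
#' disjoint).
#'
#' @param pixels an RGB triple or an (n x 3) matrix of channel values.
#' @param profile a [color_profile()].
#' @return Character vector of memberships, one per pixel.
#' @export
classify_pixel <- function(pixels, profile = color_profile()) {
  m <- if (is.null(dim(pixels))) matrix(pixels, 1, 3) else pixels
  in_interval <- function(center) {
    abs(m[, 1] - center[1]) <= profile$half_width &
      abs(m[, 2] - center[2]) <= profile$half_width &
      abs(m[, 3] - center[3]) <= profile$half_width
  }
  is_pink <- in_interval(profile$pink_mean)
  is_blue <- in_interval(profile$blue_mean)
  out <- rep("neither", nrow(m))
  out[is_pink] <- "pink"
  out[is_blue] <- "blue"
  out[is_pink & is_blue] <- "both"
  out
}

#' Classify a cell by majority pixel color
#'
#' Counts pink- and blue-interval pixels among the non-background pixels; the
#' larger count labels the cell. Ties (including 0--0) default to blue, the
#' unstressed wild-type state; set `tie` to change that.
#'
#' @param img a [cell_image()].
#' @param profile a [color_profile()].
#' @param background_threshold channel value for background masking.
#' @param tie label returned when the counts are equal.
#' @return A list with `label`, `pink_count` and `blue_count`.
#' @export
classify_cell <- function(img, profile = color_profile(),
                          background_threshold = 250, tie = "blue") {
  m <- cell_pixel_matrix(img, background_threshold)
  if (nrow(m) == 0) {
    stop("image '", img$source_id, "' has no non-background pixels")
  }
  member <- classify_pixel(m, profile)
  pink <- sum(member == "pink" | member == "both")
  blue <- sum(member == "blue" | member == "both")
  label <- if (pink > blue) "pink" else if (blue > pink) "blue" else tie
  list(label = label, pink_count = pink, blue_count = blue)
}

#' Evaluate the baseline classifier on a split
#'
#' Classifies every image in the train and test partitions and reports
#' accuracy (correct fraction, equivalently (TP+TN)/(P+N)) on each.
#'
#' @param split a [split_dataset()] result.
#' @param profile a [color_profile()].
#' @param background_threshold channel value for background masking.
#' @return A list with `train_accuracy`, `test_accuracy` and the per-partition
#'   confusion matrices.
#' @export
evaluate_baseline <- function(split, profile = color_profile(),
                              background_threshold = 250) {
  eval_part <- function(ds) {
    if (length(ds$images) == 0) stop("empty partition")
    pred <- vapply(ds$images, function(img) {
      classify_cell(img, profile, background_threshold)$label
    }, character(1))
    cm <- confusion_matrix(pred, dataset_labels(ds))
    list(accuracy = accuracy_from_confusion(cm), confusion = cm)
  }
  tr <- eval_part(split$train)
  te <- eval_part(split$test)
  list(train_accuracy = tr$accuracy, test_accuracy = te$accuracy,
       train_confusion = tr$confusion, test_confusion = te$confusion)
}
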