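# Class-labeled image folders, train/test splits, descriptive statistics with
# background masking, and per-architecture preprocessing.

#' A single-cell color image
#'
#' @param pixels H x W x 3 integer array of 8-bit channel values (R, G, B).
#' @param label cell class, `"blue"` or `"pink"`.
#' @param source_id identifier of the image origin (file stem or generator id).
#' @return A `cell_image` object.
#' @export
cell_image <- function(pixels, label, source_id = "") {
  img <- structure(list(pixels = pixels, label = label,
                        source_id = source_id),
                   class = "cell_image")
  validate_cell_image(img)
  img
}

#' Validate a cell image against the dataset invariants
#'
#' Checks the 13--256 px bounds on both sides, the three-channel layout and
#' the 8-bit value range.
#'
#' @param img a [cell_image()].
#' @return `img`, invisibly; errors with the offending property otherwise.
#' @export
validate_cell_image <- function(img) {
  d <- dim(img$pixels)
  id <- if (nzchar(img$source_id)) paste0(" [", img$source_id, "]") else ""
  if (length(d) != 3 || d[3] != 3) {
    stop("cell image", id, " must be an H x W x 3 array")
  }
  if (any(d[1:2] < 13) || any(d[1:2] > 256)) {
    stop("cell image", id, " sides must lie in [13, 256], got ",
         d[1], "x", d[2])
  }
  rng <- range(img$pixels)
  if (rng[1] < 0 || rng[2] > 255) {
    stop("cell image", id, " channel values must lie in [0, 255]")
  }
  if (!img$label %in% CELL_CLASSES) {
    stop("cell image", id, " has unknown label '", img$label, "'")
  }
  invisible(img)
}

#' A labeled collection of cell images
#'
#' @param images list of [cell_image()] objects.
#' @param class_names ordered class pair.
#' @return A `labeled_dataset` object.
#' @export
labeled_dataset <- function(images, class_names = CELL_CLASSES) {
  labels <- vapply(images, function(i) i$label, character(1))
  if (!all(labels %in% class_names)) {
    stop("dataset contains labels outside class_names: ",
         paste(setdiff(labels, class_names), collapse = ", "))
  }
  structure(list(images = images, class_names = class_names),
            class = "labeled_dataset")
}

#' @export
length.labeled_dataset <- function(x) length(x$images)

#' @export
print.labeled_dataset <- function(x, ...) {
  labels <- dataset_labels(x)
  cat("<labeled_dataset> ", length(x$images), " images (",
      paste(sprintf("%s: %d", x$class_names,
                    vapply(x$class_names, function(cl) sum(labels == cl),
                           integer(1))),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Labels of all images in a dataset
#' @param ds a [labeled_dataset()].
#' @return Character vector of class labels.
#' @export
dataset_labels <- function(ds) {
  vapply(ds$images, function(i) i$label, character(1))
}

#' Write a dataset as one PNG folder per class
#'
#' Images land in `<root>/<class>/<source_id>.png`.
#'
#' @param ds a [labeled_dataset()].
#' @param root output directory, created if missing.
#' @return `root`, invisibly.
#' @export
save_dataset <- function(ds, root) {
  for (cl in ds$class_names) {
    dir.create(file.path(root, cl), recursive = TRUE, showWarnings = FALSE)
  }
  for (i in seq_along(ds$images)) {
    img <- ds$images[[i]]
    id <- if (nzchar(img$source_id)) img$source_id else sprintf("img_%04d", i)
    png::writePNG(img$pixels / 255,
                  file.path(root, img$label, paste0(id, ".png")))
  }
  invisible(root)
}

#' Load a dataset from one image folder per class
#'
#' Subdirectory names become class labels. Every image is validated against
#' the [cell_image()] invariants; all offending files are listed in a single
#' error.
#'
#' @param root directory containing one subdirectory per class.
#' @param class_names ordered classes to read.
#' @return A [labeled_dataset()].
#' @export
load_dataset <- function(root, class_names = CELL_CLASSES) {
  images <- list()
  problems <- character(0)
  for (cl in class_names) {
    dir <- file.path(root, cl)
    files <- list.files(dir, pattern = "\\.(png|PNG)$", full.names = TRUE)
    if (length(files) == 0) {
      stop("class directory '", dir, "' is empty or missing")
    }
    for (f in files) {
      px <- tryCatch(png::readPNG(f), error = function(e) NULL)
      if (is.null(px)) {
        problems <- c(problems, paste0(f, ": cannot decode"))
        next
      }
      if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
      px <- px[, , 1:3, drop = FALSE]  # drop alpha if present
      px <- round(px * 255)
      storage.mode(px) <- "integer"
      img <- tryCatch(
        cell_image(px, cl, source_id = sub("\\.[^.]+$", "", basename(f))),
        error = function(e) conditionMessage(e))
      if (is.character(img)) problems <- c(problems, img) else {
        images[[length(images) + 1L]] <- img
      }
    }
  }
  if (length(problems) > 0) {
    stop("invalid images in '", root, "':\n  ",
         paste(problems, collapse = "\n  "))
  }
  labeled_dataset(images, class_names)
}

#' Split a dataset into train and test partitions
#'
#' The partitions are disjoint and exhaustive. In stratified mode (the
#' default) the test set balances classes to within one image, mirroring the
#' balanced composition of the source dataset.
#'
#' @param ds a [labeled_dataset()].
#' @param test_count number of test images, strictly between 0 and the
#'   dataset size.
#' @param seed integer seed.
#' @param stratified balance classes in the test partition?
#' @return A `dataset_split` list with `train`, `test` (both
#'   [labeled_dataset()]) and the seed.
#' @export
split_dataset <- function(ds, test_count, seed = 1L, stratified = TRUE) {
  n <- length(ds$images)
  test_count <- as.integer(test_count)
  if (test_count <= 0L || test_count >= n) {
    stop("test_count must satisfy 0 < test_count < ", n, ", got ", test_count)
  }
  labels <- dataset_labels(ds)
  test_idx <- with_seed(seed, {
    if (stratified) {
      per_class <- diff(c(0, round(seq_len(length(ds$class_names)) *
                                     test_count / length(ds$class_names))))
      idx <- integer(0)
      for (k in seq_along(ds$class_names)) {
        pool <- which(labels == ds$class_names[k])
        if (per_class[k] > length(pool)) {
          stop("class '", ds$class_names[k], "' has only ", length(pool),
               " images; cannot place ", per_class[k], " in the test set")
        }
        idx <- c(idx, sample(pool, per_class[k]))
      }
      idx
    } else {
      sample.int(n, test_count)
    }
  })
  structure(list(
    train = labeled_dataset(ds$images[-test_idx], ds$class_names),
    test = labeled_dataset(ds$images[test_idx], ds$class_names),
    seed = as.integer(seed)
  ), class = "dataset_split")
}

#' Background mask of an image
#'
#' A pixel is background iff all three channels are at or above
#' `background_threshold`; near-white rather than exactly white, so that
#' anti-aliased crop borders are excluded too.
#'
#' @param img a [cell_image()].
#' @param background_threshold channel value, default 250.
#' @return Logical H x W matrix, `TRUE` for background.
#' @export
background_mask <- function(img, background_threshold = 250) {
  px <- img$pixels
  px[, , 1] >= background_threshold & px[, , 2] >= background_threshold &
    px[, , 3] >= background_threshold
}

# (n_cell_pixels x 3) matrix of non-background pixel values.
cell_pixel_matrix <- function(img, background_threshold = 250) {
  keep <- !background_mask(img, background_threshold)
  cbind(img$pixels[, , 1][keep], img$pixels[, , 2][keep],
        img$pixels[, , 3][keep])
}

#' Per-class descriptive statistics of cell pixels
#'
#' Statistics are computed over non-background pixels only. Per-image
#' channelwise maxima and minima are averaged across images
#' (`avg_max_pixel`, `avg_min_pixel`); `avg_pixel` and `sd_pixel` pool all
#' cell pixels of the class.
#'
#' @param ds a [labeled_dataset()].
#' @param background_threshold channel value above which a pixel counts as
#'   background on all three channels.
#' @return A list, one `channel_stats` entry per class, each with fields
#'   `n_images`, `max_pixels_per_image`, `min_pixels_per_image`,
#'   `avg_pixels_per_image`, `avg_max_pixel`, `avg_min_pixel`, `avg_pixel`
#'   and `sd_pixel`.
#' @export
compute_descriptive_stats <- function(ds, background_threshold = 250) {
  labels <- dataset_labels(ds)
  out <- list()
  for (cl in ds$class_names) {
    imgs <- ds$images[labels == cl]
    if (length(imgs) == 0) stop("class '", cl, "' has no images")
    counts <- integer(length(imgs))
    maxs <- mins <- matrix(NA_real_, length(imgs), 3)
    sums <- sq_sums <- numeric(3)
    for (i in seq_along(imgs)) {
      m <- cell_pixel_matrix(imgs[[i]], background_threshold)
      if (nrow(m) == 0) {
        stop("image '", imgs[[i]]$source_id, "' has no cell pixels below ",
             "the background threshold")
      }
      counts[i] <- nrow(m)
      maxs[i, ] <- apply(m, 2, max)
      mins[i, ] <- apply(m, 2, min)
      sums <- sums + colSums(m)
      sq_sums <- sq_sums + colSums(m^2)
    }
    n_px <- sum(counts)
    avg <- sums / n_px
    out[[cl]] <- structure(list(
      n_images = length(imgs),
      max_pixels_per_image = max(counts),
      min_pixels_per_image = min(counts),
      avg_pixels_per_image = mean(counts),
      avg_max_pixel = colMeans(maxs),
      avg_min_pixel = colMeans(mins),
      avg_pixel = avg,
      sd_pixel = sqrt(pmax(sq_sums / n_px - avg^2, 0) * n_px / (n_px - 1))
    ), class = "channel_stats")
  }
  out
}

#' Format per-class descriptive statistics as a table
#'
#' One row per statistic, one column per class, mirroring the published
#' descriptive-statistics table layout.
#'
#' @param stats result of [compute_descriptive_stats()].
#' @return A data.frame with a `statistic` column and one column per class.
#' @export
stats_table <- function(stats) {
  fmt <- function(s) c(
    sprintf("%d", s$n_images),
    sprintf("%d", s$max_pixels_per_image),
    sprintf("%d", s$min_pixels_per_image),
    sprintf("%.1f", s$avg_pixels_per_image),
    sprintf("(%.1f, %.1f, %.1f)", s$avg_max_pixel[1], s$avg_max_pixel[2],
            s$avg_max_pixel[3]),
    sprintf("(%.1f, %.1f, %.1f)", s$avg_min_pixel[1], s$avg_min_pixel[2],
            s$avg_min_pixel[3]),
    sprintf("(%.1f, %.1f, %.1f)", s$avg_pixel[1], s$avg_pixel[2],
            s$avg_pixel[3]),
    sprintf("(%.1f, %.1f, %.1f)", s$sd_pixel[1], s$sd_pixel[2], s$sd_pixel[3])
  )
  df <- data.frame(statistic = c(
    "Number of images", "Max number of pixels per image",
    "Min number of pixels per image", "Average number of pixels per image",
    "Average maximum pixel value", "Average minimum pixel value",
    "Average pixel value", "Standard deviation"
  ), stringsAsFactors = FALSE)
  for (cl in names(stats)) df[[cl]] <- fmt(stats[[cl]])
  df
}

# Input sizes and normalization constants per architecture. The ResNet34
# branch standardizes with the conventional CIFAR-10 RGB statistics used by
# the source analysis.
ARCH_INPUT_SIZE <- c(tinyvgg = 64L, vgg16 = 227L, resnet34 = 224L)
RESNET_NORM_MEAN <- c(0.4914, 0.4822, 0.4465)
RESNET_NORM_SD <- c(0.2023, 0.1994, 0.201)

#' Preprocess an image for a network architecture
#'
#' Resizes bilinearly to the architecture's input size (64 for TinyVGG, 227
#' for VGG16, 224 for ResNet34), scales channels to `[0, 1]`, and for
#' ResNet34 additionally standardizes each channel with the fixed RGB
#' mean/SD constants.
#'
#' @param img a [cell_image()].
#' @param arch `"tinyvgg"`, `"vgg16"` or `"resnet34"`.
#' @return A size x size x 3 numeric array.
#' @export
preprocess_for_model <- function(img, arch) {
  if (!arch %in% names(ARCH_INPUT_SIZE)) {
    stop("unknown architecture '", arch, "'; expected one of: ",
         paste(names(ARCH_INPUT_SIZE), collapse = ", "))
  }
  size <- ARCH_INPUT_SIZE[[arch]]
  # EBImage uses (x, y, channel) order, i.e. transposed spatial axes
  eb <- EBImage::Image(aperm(img$pixels / 255, c(2, 1, 3)),
                       colormode = "Color")
  resized <- EBImage::resize(eb, w = size, h = size)
  x <- aperm(EBImage::imageData(resized), c(2, 1, 3))
  x <- pmin(pmax(x, 0), 1)
  if (arch == "resnet34") {
    for (ch in 1:3) {
      x[, , ch] <- (x[, , ch] - RESNET_NORM_MEAN[ch]) / RESNET_NORM_SD[ch]
    }
  }
  x
}

# Preprocess a list of images into one (size, size, 3, n) batch array.
preprocess_batch <- function(images, arch) {
  size <- ARCH_INPUT_SIZE[[arch]]
  out <- array(0, dim = c(size, size, 3, length(images)))
  for (i in seq_along(images)) {
    out[, , , i] <- preprocess_for_model(images[[i]], arch)
  }
  out
}
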