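test_that("cell image validation names the offending property", {
  good <- array(100L, dim = c(20, 20, 3))
  expect_silent(cell_image(good, "blue"))
  expect_error(cell_image(array(100L, dim = c(10, 20, 3)), "blue",
                          source_id = "tiny"),
               "\\[13, 256\\].*10x20|tiny")
  expect_error(cell_image(array(100L, dim = c(20, 20, 2)), "blue"),
               "H x W x 3")
  bad_range <- good
  bad_range[1] <- 300L
  expect_error(cell_image(bad_range, "blue"), "\\[0, 255\\]")
  expect_error(cell_image(good, "purple"), "unknown label")
})

test_that("save/load round-trips pixels and labels through PNG folders", {
  ds <- generate_dataset(small_config(n_per_class = 3))
  root <- withr::local_tempdir()
  save_dataset(ds, root)
  back <- load_dataset(root)
  expect_length(back$images, 6)
  # match by source id (file order may differ from generation order)
  by_id <- function(d) {
    ids <- vapply(d$images, `[[`, "", "source_id")
    d$images[order(ids)]
  }
  orig <- by_id(ds)
  reread <- by_id(back)
  for (i in seq_along(orig)) {
    expect_identical(reread[[i]]$pixels, orig[[i]]$pixels)
    expect_identical(reread[[i]]$label, orig[[i]]$label)
  }
})

test_that("loading rejects undersized images, listing the file", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "blue"), recursive = TRUE)
  dir.create(file.path(root, "pink"), recursive = TRUE)
  png::writePNG(array(0.5, dim = c(20, 20, 3)),
                file.path(root, "blue", "ok.png"))
  png::writePNG(array(0.5, dim = c(10, 10, 3)),
                file.path(root, "blue", "small.png"))
  png::writePNG(array(0.5, dim = c(20, 20, 3)),
                file.path(root, "pink", "ok.png"))
  expect_error(load_dataset(root), "small")
  expect_error(load_dataset(withr::local_tempdir()), "empty or missing")
})

test_that("splits are disjoint, exhaustive and reproducible for any seed", {
  ds <- generate_dataset(small_config(n_per_class = 7))
  for (seed in c(1, 99, 2024)) {
    sp <- split_dataset(ds, 4, seed = seed)
    ids <- function(d) vapply(d$images, `[[`, "", "source_id")
    expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
    expect_setequal(c(ids(sp$train), ids(sp$test)), ids(ds))
    # stratified test set balances classes within one image
    counts <- table(dataset_labels(sp$test))
    expect_lte(max(counts) - min(counts), 1)
    sp2 <- split_dataset(ds, 4, seed = seed)
    expect_identical(ids(sp2$train), ids(sp$train))
  }
  expect_error(split_dataset(ds, 0), "test_count")
  expect_error(split_dataset(ds, 14), "test_count")
})

test_that("split sizes mirror the published train/test compositions", {
  # same arithmetic as the published 204 -> 164/40 and 106 -> 84/22 splits,
  # checked at reduced scale by ratio and exactly by construction
  ds <- generate_dataset(small_config(n_per_class = 10))
  sp <- split_dataset(ds, 4, seed = 3)
  expect_length(sp$train$images, 16)
  expect_length(sp$test$images, 4)
})

test_that("descriptive statistics exclude background and ignore image order", {
  # 2x2-ish constructed image: three gray pixels, one white
  px <- array(255L, dim = c(13, 13, 3))
  px[1, 1, ] <- 100L
  px[1, 2, ] <- 100L
  px[2, 1, ] <- 100L
  img <- cell_image(px, "blue", "constructed")
  other <- flat_image(c(50, 60, 70), "pink", id = "p1")
  ds <- labeled_dataset(list(img, other))
  st <- compute_descriptive_stats(ds)
  expect_equal(st$blue$avg_pixels_per_image, 3)
  expect_equal(unname(st$blue$avg_pixel), c(100, 100, 100))
  expect_equal(unname(st$blue$sd_pixel), c(0, 0, 0))
  # order invariance
  st2 <- compute_descriptive_stats(labeled_dataset(list(other, img)))
  expect_equal(st$blue, st2$blue)
  expect_equal(st$pink, st2$pink)
  # adding pure-white border leaves the contribution unchanged
  padded <- array(255L, dim = c(15, 15, 3))
  padded[2:14, 2:14, ] <- px
  ds3 <- labeled_dataset(list(cell_image(padded, "blue"), other))
  expect_equal(compute_descriptive_stats(ds3)$blue$avg_pixel, st$blue$avg_pixel)
  # an all-white image is an error naming the image
  expect_error(
    compute_descriptive_stats(labeled_dataset(list(
      flat_image(c(255, 255, 255), "blue", id = "white"), other))),
    "white")
})

test_that("stats table mirrors the published row layout", {
  ds <- generate_dataset(small_config(n_per_class = 3))
  tab <- stats_table(compute_descriptive_stats(ds))
  expect_identical(tab$statistic[1], "Number of images")
  expect_identical(tab$blue[1], "3")
  expect_identical(names(tab), c("statistic", "blue", "pink"))
  expect_equal(nrow(tab), 8)
})

test_that("preprocessing resizes per architecture and standardizes for resnet", {
  img <- generate_cell_image(cell_spec("pink", "oval", 40, rng_seed = 4),
                             small_config())
  expect_equal(dim(preprocess_for_model(img, "tinyvgg")), c(64, 64, 3))
  expect_equal(dim(preprocess_for_model(img, "vgg16")), c(227, 227, 3))
  expect_equal(dim(preprocess_for_model(img, "resnet34")), c(224, 224, 3))
  expect_error(preprocess_for_model(img, "lenet"), "unknown architecture")
  # values scaled to [0, 1] for the unstandardized archs
  x <- preprocess_for_model(img, "tinyvgg")
  expect_true(all(x >= 0 & x <= 1))
  # standardization identity: a uniform image at round(0.4914 * 255) maps the
  # red channel to ~0 under the fixed constants
  uni <- flat_image(rep(round(0.4914 * 255), 3), "blue")
  z <- preprocess_for_model(uni, "resnet34")
  expect_lt(max(abs(z[, , 1])), 0.01)
  # idempotent in shape: re-running preserves dimensions
  expect_equal(dim(preprocess_for_model(img, "vgg16")),
               dim(preprocess_for_model(img, "vgg16")))
})
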