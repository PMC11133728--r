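test_that("pixel membership at the published interval centers is correct", {
  p <- color_profile()
  expect_identical(classify_pixel(c(133.83, 75.84, 182.24), p), "pink")
  expect_identical(classify_pixel(c(70.99, 75.87, 163.05), p), "blue")
  expect_identical(classify_pixel(c(255, 255, 255), p), "neither")
  # matrix form classifies rowwise
  m <- rbind(c(134, 76, 182), c(71, 76, 163), c(0, 0, 0))
  expect_identical(classify_pixel(m, p), c("pink", "blue", "neither"))
})

test_that("default red intervals are disjoint so 'both' cannot occur", {
  p <- color_profile()
  # interval arithmetic: pink R in [106.83, 160.83], blue R in [43.99, 97.99]
  expect_gt(p$pink_mean[1] - p$half_width, p$blue_mean[1] + p$half_width)
  withr::with_seed(5, {
    pixels <- matrix(runif(3000, 0, 255), ncol = 3)
    expect_false(any(classify_pixel(pixels, p) == "both"))
  })
})

test_that("profile calibration recovers means of constant-color samples", {
  imgs <- list(
    flat_image(c(134, 76, 182), "pink", id = "p1"),
    flat_image(c(134, 76, 182), "pink", id = "p2"),
    flat_image(c(71, 76, 163), "blue", id = "b1"),
    flat_image(c(71, 76, 163), "blue", id = "b2")
  )
  ds <- labeled_dataset(imgs)
  prof <- calibrate_profile(ds, n_sample_images = 2, seed = 1)
  expect_equal(unname(prof$pink_mean), c(134, 76, 182))
  expect_equal(unname(prof$blue_mean), c(71, 76, 163))
  # pooled SD of constant images is 0; floored to stay a valid half-width
  expect_gt(prof$half_width, 0)
  # two pink images of different constant colors -> arithmetic mean
  ds2 <- labeled_dataset(list(
    flat_image(c(100, 70, 180), "pink", id = "pa"),
    flat_image(c(140, 90, 190), "pink", id = "pb"),
    flat_image(c(71, 76, 163), "blue", id = "ba")
  ))
  prof2 <- calibrate_profile(ds2, n_sample_images = 2, seed = 1)
  expect_equal(unname(prof2$pink_mean), c(120, 80, 185))
  # deterministic given the seed
  ds3 <- generate_dataset(small_config(n_per_class = 4))
  expect_equal(calibrate_profile(ds3, 2, seed = 9),
               calibrate_profile(ds3, 2, seed = 9))
  # fixed half-width override
  expect_equal(calibrate_profile(ds3, 2, seed = 9, half_width = 27)$half_width,
               27)
})

test_that("cell classification is a majority vote with a blue tie rule", {
  p <- color_profile()
  # constructed cell: 60 pink-interval + 40 blue-interval pixels on white
  px <- array(255L, dim = c(13, 13, 3))
  fill <- function(px, idx, rgb) {
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[idx] <- as.integer(rgb[ch])
      px[, , ch] <- plane
    }
    px
  }
  px <- fill(px, 1:60, c(134, 76, 182))
  px <- fill(px, 61:100, c(71, 76, 163))
  img <- cell_image(px, "pink")
  res <- classify_cell(img, p)
  expect_identical(res$label, "pink")
  expect_equal(res$pink_count, 60)
  expect_equal(res$blue_count, 40)
  # constant image at the blue mean
  blue_img <- flat_image(c(70.99, 75.87, 163.05), "blue")
  res_b <- classify_cell(blue_img, p)
  expect_identical(res_b$label, "blue")
  expect_equal(res_b$pink_count, 0)
  # equal counts (including 0-0) fall to blue, configurably
  px_tie <- fill(fill(array(255L, c(13, 13, 3)), 1:10, c(134, 76, 182)),
                 11:20, c(71, 76, 163))
  tie_img <- cell_image(px_tie, "blue")
  expect_identical(classify_cell(tie_img, p)$label, "blue")
  expect_identical(classify_cell(tie_img, p, tie = "pink")$label, "pink")
  # pixel-order invariance: shuffling pixels leaves counts unchanged
  shuffled <- withr::with_seed(3, {
    perm <- sample(13 * 13)
    arr <- array(255L, c(13, 13, 3))
    for (ch in 1:3) arr[, , ch] <- px[, , ch][perm]
    arr
  })
  res_s <- classify_cell(cell_image(shuffled, "pink"), p)
  expect_equal(res_s$pink_count, res$pink_count)
  expect_equal(res_s$blue_count, res$blue_count)
  # counts never exceed the non-background pixel count
  img_r <- generate_cell_image(cell_spec("pink", "round", 40, 0.2,
                                         rng_seed = 8), small_config())
  rr <- classify_cell(img_r, p)
  expect_lte(rr$pink_count + rr$blue_count,
             sum(!background_mask(img_r)))
})

test_that("baseline evaluation matches an independent per-image recount", {
  ds <- separable_dataset()
  split <- split_dataset(ds, 6, seed = 4)
  prof <- color_profile()  # matched by construction of the fixture
  res <- evaluate_baseline(split, prof)
  expect_equal(res$train_accuracy, 1.0)
  expect_equal(res$test_accuracy, 1.0)
  # inverted labels give the complement
  flip <- function(d) {
    d$images <- lapply(d$images, function(i) {
      i$label <- setdiff(c("blue", "pink"), i$label)
      i
    })
    d
  }
  inv <- split
  inv$train <- flip(split$train)
  inv$test <- flip(split$test)
  res_inv <- evaluate_baseline(inv, prof)
  expect_equal(res_inv$train_accuracy, 0.0)
  expect_equal(res_inv$test_accuracy, 0.0)
  # oracle: recount correctness per image directly from pixel memberships
  recount_acc <- function(d) {
    correct <- vapply(d$images, function(img) {
      m <- tradshm:::cell_pixel_matrix(img)
      member <- classify_pixel(m, prof)
      pink <- sum(member == "pink")
      blue <- sum(member == "blue")
      lab <- if (pink > blue) "pink" else "blue"
      lab == img$label
    }, logical(1))
    mean(correct)
  }
  mixed <- generate_dataset(small_config(
    n_per_class = 6, seed = 404, class_colors = profile_matched_colors(20),
    minority_fraction_range = c(0.1, 0.4)))
  sp_m <- split_dataset(mixed, 4, seed = 1)
  res_m <- evaluate_baseline(sp_m, prof)
  expect_equal(res_m$train_accuracy, recount_acc(sp_m$train))
  expect_equal(res_m$test_accuracy, recount_acc(sp_m$test))
})
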