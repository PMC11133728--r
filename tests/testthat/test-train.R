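test_that("confusion-matrix accuracy equals the direct correct fraction", {
  # property: Accuracy = (TP+TN)/(P+N) is the fraction of correct predictions
  withr::with_seed(17, {
    for (i in 1:200) {
      n <- sample(1:60, 1)
      pred <- sample(c("blue", "pink"), n, replace = TRUE)
      truth <- sample(c("blue", "pink"), n, replace = TRUE)
      cm <- confusion_matrix(pred, truth)
      expect_equal(cm$TP + cm$FP + cm$FN + cm$TN, n)
      expect_equal(accuracy_from_confusion(cm), mean(pred == truth))
    }
  })
  # worked example: TP=3, TN=4, FP=2, FN=1 -> 0.7
  cm <- list(TP = 3, FP = 2, FN = 1, TN = 4)
  expect_equal(accuracy_from_confusion(cm), 0.7)
  # inversion complements the accuracy
  pred <- c("pink", "pink", "blue", "blue", "pink")
  truth <- c("pink", "blue", "blue", "pink", "pink")
  inv <- ifelse(pred == "pink", "blue", "pink")
  expect_equal(accuracy_from_confusion(confusion_matrix(inv, truth)),
               1 - accuracy_from_confusion(confusion_matrix(pred, truth)))
})

test_that("training histories have one row per epoch and seeds reproduce", {
  ds <- separable_dataset()
  split <- split_dataset(ds, 4, seed = 31)
  cfg <- train_config("tinyvgg", epochs = 20, batch_size = 4, seed = 5)
  fit <- train_model(build_tinyvgg(seed = 5), split, cfg)
  expect_equal(nrow(fit$history), 20)
  expect_equal(fit$history$epoch, 1:20)
  expect_true(all(fit$history$train_acc >= 0 & fit$history$train_acc <= 1))
  fit2 <- train_model(build_tinyvgg(seed = 5), split, cfg)
  expect_identical(fit$history, fit2$history)
  # separable data trains to high accuracy within the default epochs
  expect_gte(tail(fit$history$train_acc, 1), 0.9)
})

test_that("zero learning rate leaves parameters unchanged and history flat", {
  ds <- separable_dataset()
  split <- split_dataset(ds, 4, seed = 31)
  model <- build_tinyvgg(seed = 6)
  before <- lapply(tradshm:::nn_param_layers(model$net),
                   function(l) l$params)
  cfg <- train_config("tinyvgg", epochs = 3, batch_size = 4,
                      learning_rate = 0, seed = 1)
  fit <- train_model(model, split, cfg)
  after <- lapply(tradshm:::nn_param_layers(fit$model$net),
                  function(l) l$params)
  expect_equal(before, after)
  expect_equal(length(unique(fit$history$train_acc)), 1)
  expect_equal(length(unique(fit$history$train_loss)), 1)
})

test_that("training requires both classes in the train partition", {
  ds <- separable_dataset()
  blue_only <- labeled_dataset(
    ds$images[dataset_labels(ds) == "blue"])
  split <- list(train = blue_only,
                test = labeled_dataset(ds$images[1:2]), seed = 1L)
  class(split) <- "dataset_split"
  expect_error(train_model(build_tinyvgg(), split, train_config("tinyvgg")),
               "class missing")
})

test_that("model evaluation matches per-image argmax predictions", {
  ds <- separable_dataset()
  split <- split_dataset(ds, 4, seed = 31)
  cfg <- train_config("tinyvgg", epochs = 20, batch_size = 4, seed = 5)
  fit <- train_model(build_tinyvgg(seed = 5), split, cfg,
                     stop_at_train_acc = 1.0)
  ev <- evaluate_model(fit$model, split$train)
  expect_equal(ev$accuracy,
               mean(ev$predicted == dataset_labels(split$train)))
  n <- length(split$train$images)
  expect_equal(ev$confusion$TP + ev$confusion$FP + ev$confusion$FN +
                 ev$confusion$TN, n)
})

test_that("architecture comparison reuses one split and is reproducible", {
  ds <- separable_dataset()
  cfgs <- list(train_config("tinyvgg", epochs = 4, batch_size = 4, seed = 2))
  cmp <- compare_architectures(ds, cfgs, test_count = 4, seed = 12)
  expect_equal(cmp$table$model, c("baseline", "tinyvgg"))
  expect_equal(nrow(cmp$histories$tinyvgg), 4)
  cmp2 <- compare_architectures(ds, cfgs, test_count = 4, seed = 12)
  # identical up to wall-clock timing, which is informational only
  expect_identical(cmp$table[setdiff(names(cmp$table), "seconds")],
                   cmp2$table[setdiff(names(cmp2$table), "seconds")])
  expect_identical(cmp$histories, cmp2$histories)
})

test_that("train_config applies the per-architecture published defaults", {
  expect_identical(train_config("tinyvgg")$optimizer, "adam")
  expect_equal(train_config("tinyvgg")$learning_rate, 0.001)
  expect_identical(train_config("vgg16")$optimizer, "sgd")
  expect_equal(train_config("vgg16")$learning_rate, 0.005)
  expect_identical(train_config("resnet34")$optimizer, "sgd")
  expect_equal(train_config("resnet34")$learning_rate, 0.01)
  expect_equal(train_config("tinyvgg")$epochs, 20L)
  expect_equal(train_config("tinyvgg")$batch_size, 32L)
  expect_error(train_config("alexnet"), "unknown architecture")
  expect_error(train_config("tinyvgg", epochs = 0), "epochs")
})
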