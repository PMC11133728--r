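# Training loops with per-architecture optimizer defaults, confusion-matrix
# accuracy, and the multi-architecture comparison harness.

#' Training configuration
#'
#' Defaults follow the published settings per architecture: 20 epochs, batch
#' size 32, Adam with learning rate 0.001 for TinyVGG, plain SGD with 0.005
#' for VGG16 and 0.01 for ResNet34 (momentum 0 unless configured; the source
#' does not print one). Cross-entropy is the loss throughout.
#'
#' @param arch `"tinyvgg"`, `"vgg16"` or `"resnet34"`.
#' @param epochs training epochs, at least 1.
#' @param batch_size mini-batch size.
#' @param optimizer `"adam"` or `"sgd"`; default depends on `arch`.
#' @param learning_rate positive step size; default depends on `arch`.
#' @param momentum SGD momentum.
#' @param seed seed for initialization, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(arch, epochs = 20L, batch_size = 32L,
                         optimizer = NULL, learning_rate = NULL,
                         momentum = 0, seed = 1L) {
  if (!arch %in% names(ARCH_INPUT_SIZE)) {
    stop("unknown architecture '", arch, "'")
  }
  defaults <- list(tinyvgg = list(optimizer = "adam", lr = 0.001),
                   vgg16 = list(optimizer = "sgd", lr = 0.005),
                   resnet34 = list(optimizer = "sgd", lr = 0.01))[[arch]]
  optimizer <- optimizer %||% defaults$optimizer
  learning_rate <- learning_rate %||% defaults$lr
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1")
  if (learning_rate < 0) stop("learning_rate must be non-negative")
  if (!optimizer %in% c("adam", "sgd")) {
    stop("optimizer must be 'adam' or 'sgd'")
  }
  structure(list(arch = arch, epochs = epochs,
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 learning_rate = learning_rate, momentum = momentum,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Two-class confusion matrix
#'
#' Pink is the positive class: TP are pink cells predicted pink, TN blue
#' cells predicted blue, FP blue cells predicted pink, FN pink cells
#' predicted blue.
#'
#' @param predicted character vector of predicted labels.
#' @param actual character vector of true labels, same length.
#' @return A `confusion_matrix` list with integer fields `TP`, `FP`, `FN`,
#'   `TN`.
#' @export
confusion_matrix <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  structure(list(
    TP = sum(predicted == "pink" & actual == "pink"),
    FP = sum(predicted == "pink" & actual == "blue"),
    FN = sum(predicted == "blue" & actual == "pink"),
    TN = sum(predicted == "blue" & actual == "blue")
  ), class = "confusion_matrix")
}

#' Accuracy from a confusion matrix
#'
#' Accuracy = (TP + TN) / (P + N) with P = TP + FN and N = TN + FP.
#'
#' @param cm a [confusion_matrix()].
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy_from_confusion <- function(cm) {
  p <- cm$TP + cm$FN
  n <- cm$TN + cm$FP
  if (p + n == 0) stop("empty confusion matrix")
  (cm$TP + cm$TN) / (p + n)
}

# Forward a preprocessed batch in evaluation mode, in chunks to bound memory.
predict_logits <- function(model, batch, chunk = 16L) {
  n <- dim(batch)[4]
  out <- matrix(0, n, model$n_classes)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    out[idx, ] <- model_forward(model, batch[, , , idx, drop = FALSE])
  }
  out
}

eval_on_batch <- function(model, batch, targets, class_names) {
  logits <- predict_logits(model, batch)
  ce <- cross_entropy(t(logits), targets)
  pred <- class_names[max.col(logits, ties.method = "first")]
  cm <- confusion_matrix(pred, class_names[targets])
  list(loss = ce$loss, accuracy = accuracy_from_confusion(cm), confusion = cm)
}

#' Train a model on a dataset split
#'
#' Minimizes cross-entropy over shuffled mini-batches for `cfg$epochs`
#' epochs, recording train/test loss and accuracy after every epoch.
#' Deterministic given `cfg$seed`. If `stop_at_train_acc` is set, training
#' halts after the first epoch whose training accuracy reaches it (the
#' history then ends at that epoch).
#'
#' Before each evaluation the batch-normalization running statistics are
#' re-estimated over the training images with the current weights (a precise
#' re-estimation pass); otherwise the few large updates of a short run leave
#' the running averages far behind the weights they are scored with.
#'
#' @param model a `tradshm_model` matching `cfg$arch`.
#' @param split a [split_dataset()] result.
#' @param cfg a [train_config()].
#' @param stop_at_train_acc optional early-stop threshold in `[0, 1]`.
#' @param bn_recalibrate re-estimate batch-norm statistics before each
#'   evaluation?
#' @return A list with the trained `model` and `history`, a data.frame with
#'   columns `epoch`, `train_loss`, `test_loss`, `train_acc`, `test_acc`.
#' @export
train_model <- function(model, split, cfg, stop_at_train_acc = NULL,
                        bn_recalibrate = TRUE) {
  stopifnot(inherits(model, "tradshm_model"), inherits(cfg, "train_config"),
            model$arch == cfg$arch)
  class_names <- split$train$class_names
  train_labels <- dataset_labels(split$train)
  if (!all(class_names %in% train_labels)) {
    stop("class missing from the training partition: ",
         paste(setdiff(class_names, train_labels), collapse = ", "))
  }
  train_x <- preprocess_batch(split$train$images, model$arch)
  test_x <- preprocess_batch(split$test$images, model$arch)
  train_y <- match(train_labels, class_names)
  test_y <- match(dataset_labels(split$test), class_names)
  n <- length(train_y)

  opt <- make_optimizer(model$net, cfg$optimizer, lr = cfg$learning_rate,
                        momentum = cfg$momentum)
  history <- vector("list", cfg$epochs)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      order <- sample.int(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- order[start:min(start + cfg$batch_size - 1L, n)]
        logits <- nn_forward(model$net, train_x[, , , idx, drop = FALSE],
                             training = TRUE)
        ce <- cross_entropy(logits, train_y[idx])
        nn_backward(model$net, ce$grad)
        optimizer_step(opt)
      }
      if (bn_recalibrate) {
        nn_recalibrate_bn(model$net, train_x, chunk = cfg$batch_size)
      }
      tr <- eval_on_batch(model, train_x, train_y, class_names)
      te <- eval_on_batch(model, test_x, test_y, class_names)
      history[[epoch]] <- data.frame(epoch = epoch, train_loss = tr$loss,
                                     test_loss = te$loss,
                                     train_acc = tr$accuracy,
                                     test_acc = te$accuracy)
      if (!is.null(stop_at_train_acc) && tr$accuracy >= stop_at_train_acc) {
        break
      }
    }
  })
  list(model = model, history = do.call(rbind, history))
}

#' Evaluate a model on a list of images
#'
#' Predicts by argmax over the logits and reports the confusion matrix and
#' accuracy (pink positive).
#'
#' @param model a trained `tradshm_model`.
#' @param images list of [cell_image()] objects (or a [labeled_dataset()]).
#' @param class_names ordered class pair.
#' @return A list with `confusion`, `accuracy` and the `predicted` labels.
#' @export
evaluate_model <- function(model, images, class_names = CELL_CLASSES) {
  if (inherits(images, "labeled_dataset")) images <- images$images
  if (length(images) == 0) stop("no images to evaluate")
  batch <- preprocess_batch(images, model$arch)
  logits <- predict_logits(model, batch)
  pred <- class_names[max.col(logits, ties.method = "first")]
  actual <- vapply(images, function(i) i$label, character(1))
  cm <- confusion_matrix(pred, actual)
  list(confusion = cm, accuracy = accuracy_from_confusion(cm),
       predicted = pred)
}

#' Train and compare several architectures on one dataset
#'
#' Splits the dataset once, evaluates the interval baseline (profile
#' calibrated from the training partition), trains each configured network on
#' the identical split, and tabulates final train/test accuracies alongside
#' the full per-epoch curves.
#'
#' @param ds a [labeled_dataset()].
#' @param cfgs list of [train_config()] objects.
#' @param test_count test images held out.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param stop_at_train_acc optional early-stop threshold passed to
#'   [train_model()].
#' @return A list with `table` (one row per model, baseline first),
#'   `histories` (named per-architecture), and the `split` used.
#' @export
compare_architectures <- function(ds, cfgs, test_count, seed = 1L,
                                  stop_at_train_acc = NULL) {
  if (length(cfgs) < 1) stop("at least one training configuration required")
  split <- split_dataset(ds, test_count, seed = derive_seed(seed, "split"))
  profile <- calibrate_profile(split$train,
                               seed = derive_seed(seed, "baseline"))
  base <- evaluate_baseline(split, profile)
  rows <- list(data.frame(model = "baseline",
                          train_accuracy = base$train_accuracy,
                          test_accuracy = base$test_accuracy,
                          seconds = NA_real_))
  histories <- list()
  for (cfg in cfgs) {
    model <- build_model(cfg$arch, seed = derive_seed(seed,
                                                      paste0("init_", cfg$arch)))
    t0 <- proc.time()[["elapsed"]]
    fit <- train_model(model, split, cfg,
                       stop_at_train_acc = stop_at_train_acc)
    elapsed <- proc.time()[["elapsed"]] - t0
    last <- fit$history[nrow(fit$history), ]
    rows[[length(rows) + 1L]] <- data.frame(model = cfg$arch,
                                            train_accuracy = last$train_acc,
                                            test_accuracy = last$test_acc,
                                            seconds = elapsed)
    histories[[cfg$arch]] <- fit$history
  }
  list(table = do.call(rbind, rows), histories = histories, split = split)
}
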