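# The three network architectures, built from scratch on the engine in
# engine.R: TinyVGG (two conv/ReLU blocks with max-pooling), VGG16 with batch
# normalization (13 conv layers in five blocks), and ResNet34 (basic residual
# blocks [3,4,6,3]). Each maps a preprocessed image batch to two-class logits.

#' Build a TinyVGG classifier
#'
#' Two blocks of (conv 3x3 s1 p1, ReLU, conv 3x3 s1 p1, ReLU, 2x2 max-pool
#' stride 2) with `hidden_units` channels, then flatten and a linear layer to
#' `n_classes` logits. Accepts 64 x 64 inputs; after the two pools the
#' feature maps are 16 x 16, so the flattened width is
#' `hidden_units * 16 * 16`.
#'
#' @param hidden_units channels in the convolutional blocks (10, matching the
#'   hidden-layer width of the source architecture).
#' @param n_classes output classes.
#' @param seed seed for weight initialization.
#' @return A `tradshm_model`.
#' @export
build_tinyvgg <- function(hidden_units = 10L, n_classes = 2L, seed = 1L) {
  size <- ARCH_INPUT_SIZE[["tinyvgg"]]
  net <- with_seed(seed, nn_sequential(
    nn_conv2d(3L, hidden_units), nn_relu(),
    nn_conv2d(hidden_units, hidden_units), nn_relu(),
    nn_maxpool2d(2L, 2L),
    nn_conv2d(hidden_units, hidden_units), nn_relu(),
    nn_conv2d(hidden_units, hidden_units), nn_relu(),
    nn_maxpool2d(2L, 2L),
    nn_flatten(),
    nn_linear(hidden_units * (size %/% 4L)^2, n_classes)
  ))
  new_model("tinyvgg", net, n_classes, seed)
}

#' Build a VGG16 (batch-norm variant) classifier
#'
#' The standard VGG-16 feature extractor: 13 convolutional layers (3x3, s1,
#' p1) in five blocks of 2, 2, 3, 3, 3 at widths 64, 128, 256, 512, 512, each
#' conv followed by batch normalization and ReLU, with 2x2 max-pooling after
#' every block. The classifier head is dropout, a hidden linear layer, ReLU,
#' and a final linear layer to the logits. Accepts 227 x 227 inputs (feature
#' maps reach 7 x 7 after the five pools).
#'
#' @param hidden_units width of the hidden linear layer. The conventional
#'   4096 would dwarf a ~100-image task; the default 256 keeps the head
#'   proportionate and is a configuration knob, not an architectural claim.
#' @param dropout dropout probability before the hidden layer.
#' @param n_classes output classes.
#' @param seed seed for weight initialization.
#' @return A `tradshm_model`.
#' @export
build_vgg16 <- function(hidden_units = 256L, dropout = 0.5, n_classes = 2L,
                        seed = 1L) {
  size <- ARCH_INPUT_SIZE[["vgg16"]]
  widths <- list(c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L),
                 c(512L, 512L, 512L), c(512L, 512L, 512L))
  net <- with_seed(seed, {
    layers <- list()
    in_ch <- 3L
    for (block in widths) {
      for (out_ch in block) {
        layers <- c(layers, list(nn_conv2d(in_ch, out_ch),
                                 nn_batchnorm2d(out_ch), nn_relu()))
        in_ch <- out_ch
      }
      layers <- c(layers, list(nn_maxpool2d(2L, 2L)))
    }
    spatial <- size
    for (i in 1:5) spatial <- spatial %/% 2L
    layers <- c(layers, list(
      nn_flatten(),
      nn_dropout(dropout),
      nn_linear(512L * spatial^2, hidden_units), nn_relu(),
      nn_linear(hidden_units, n_classes)
    ))
    do.call(nn_sequential, layers)
  })
  new_model("vgg16", net, n_classes, seed)
}

#' Build a ResNet34 classifier
#'
#' Stem of 7x7 conv stride 2, batch norm, ReLU and 3x3 max-pool stride 2,
#' followed by four stages of basic residual blocks (3, 4, 6, 3 blocks at
#' widths 64, 128, 256, 512; each block two 3x3 convs with batch norm and an
#' identity shortcut, 1x1 projection shortcuts where the resolution or width
#' changes), global average pooling and a linear layer to the logits: 33
#' convolutions plus the final linear layer give the 34 weighted layers of
#' the name. Accepts 224 x 224 inputs.
#'
#' @param n_classes output classes.
#' @param seed seed for weight initialization.
#' @return A `tradshm_model`.
#' @export
build_resnet34 <- function(n_classes = 2L, seed = 1L) {
  blocks_per_stage <- c(3L, 4L, 6L, 3L)
  stage_width <- c(64L, 128L, 256L, 512L)
  net <- with_seed(seed, {
    layers <- list(
      nn_conv2d(3L, 64L, kernel = 7L, stride = 2L, pad = 3L),
      nn_batchnorm2d(64L), nn_relu(),
      nn_maxpool2d(3L, 2L, pad = 1L)
    )
    in_ch <- 64L
    for (s in seq_along(blocks_per_stage)) {
      for (bidx in seq_len(blocks_per_stage[s])) {
        stride <- if (s > 1L && bidx == 1L) 2L else 1L
        layers <- c(layers, list(nn_residual_block(in_ch, stage_width[s],
                                                   stride)))
        in_ch <- stage_width[s]
      }
    }
    layers <- c(layers, list(nn_global_avgpool(),
                             nn_linear(512L, n_classes)))
    do.call(nn_sequential, layers)
  })
  new_model("resnet34", net, n_classes, seed)
}

new_model <- function(arch, net, n_classes, seed) {
  structure(list(arch = arch, net = net,
                 input_size = ARCH_INPUT_SIZE[[arch]],
                 n_classes = as.integer(n_classes), init_seed = as.integer(seed)),
            class = "tradshm_model")
}

#' Build a model by architecture id
#'
#' @param arch `"tinyvgg"`, `"vgg16"` or `"resnet34"`.
#' @param seed seed for weight initialization.
#' @param ... passed to the architecture's builder.
#' @return A `tradshm_model`.
#' @export
build_model <- function(arch, seed = 1L, ...) {
  switch(arch,
         tinyvgg = build_tinyvgg(seed = seed, ...),
         vgg16 = build_vgg16(seed = seed, ...),
         resnet34 = build_resnet34(seed = seed, ...),
         stop("unknown architecture '", arch, "'"))
}

#' @export
print.tradshm_model <- function(x, ...) {
  cat("<tradshm_model> ", x$arch, ": input ", x$input_size, "x", x$input_size,
      "x3, ", format(nn_count_params(x$net), big.mark = ","),
      " parameters, ", x$n_classes, " classes\n", sep = "")
  invisible(x)
}

#' Forward pass of a model
#'
#' Maps a preprocessed batch to logits. In evaluation mode (the default)
#' dropout is disabled and batch normalization uses running statistics, so
#' the output is deterministic.
#'
#' @param model a `tradshm_model`.
#' @param batch a (size, size, 3, n) array from [preprocess_batch()], or a
#'   single (size, size, 3) image.
#' @param training use training-mode stochastic layers and record caches for
#'   backpropagation?
#' @return An (n x n_classes) matrix of logits.
#' @export
model_forward <- function(model, batch, training = FALSE) {
  if (length(dim(batch)) == 3) dim(batch) <- c(dim(batch), 1L)
  d <- dim(batch)
  if (d[1] != model$input_size || d[2] != model$input_size || d[3] != 3) {
    stop(model$arch, " expects ", model$input_size, "x", model$input_size,
         "x3 inputs, got ", paste(d[1:3], collapse = "x"))
  }
  t(nn_forward(model$net, batch, training = training))
}

# Number of convolutional layers in a network (including projections).
count_conv_layers <- function(layer) {
  if (inherits(layer, "nn_sequential")) {
    return(sum(vapply(layer$layers, count_conv_layers, numeric(1))))
  }
  if (inherits(layer, "nn_residual_block")) {
    return(2 + if (is.null(layer$proj)) 0 else 1)
  }
  as.numeric(inherits(layer, "nn_conv2d"))
}
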