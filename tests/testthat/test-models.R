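# Engine correctness (finite-difference oracles) and architecture contracts.

test_that("layer backward passes agree with finite differences", {
  # conv kernels run in single precision, so the comparison uses a larger
  # step and tolerance than the double-precision layers
  cases <- list(
    list(name = "conv s1p1", xdim = c(5, 4, 2, 2), eps = 1e-3, tol = 5e-3,
         make = function() withr::with_seed(7, tradshm:::nn_conv2d(2L, 3L))),
    list(name = "conv s2p1", xdim = c(7, 7, 2, 2), eps = 1e-3, tol = 5e-3,
         make = function() withr::with_seed(8, tradshm:::nn_conv2d(2L, 3L, 3L, 2L, 1L))),
    list(name = "conv 1x1 s2 p0", xdim = c(6, 6, 2, 2), eps = 1e-3, tol = 5e-3,
         make = function() withr::with_seed(12, tradshm:::nn_conv2d(2L, 3L, 1L, 2L, 0L))),
    list(name = "batchnorm", xdim = c(4, 4, 3, 3), eps = 1e-5, tol = 1e-6,
         make = function() withr::with_seed(9, {
           l <- tradshm:::nn_batchnorm2d(3L)
           l$params$gamma <- runif(3, 0.5, 1.5)
           l$params$beta <- rnorm(3)
           l
         })),
    list(name = "linear", xdim = c(6, 5), eps = 1e-5, tol = 1e-6,
         make = function() withr::with_seed(10, tradshm:::nn_linear(6L, 4L))),
    list(name = "maxpool 2x2", xdim = c(6, 6, 2, 2), eps = 1e-5, tol = 1e-6,
         make = function() tradshm:::nn_maxpool2d(2L, 2L)),
    list(name = "maxpool 3x3 s2 p1", xdim = c(7, 7, 2, 2), eps = 1e-5, tol = 1e-6,
         make = function() tradshm:::nn_maxpool2d(3L, 2L, 1L)),
    list(name = "global avgpool", xdim = c(3, 3, 4, 2), eps = 1e-5, tol = 1e-6,
         make = function() tradshm:::nn_global_avgpool()),
    list(name = "residual block s2", xdim = c(6, 6, 2, 2), eps = 1e-3, tol = 5e-3,
         make = function() withr::with_seed(11, tradshm:::nn_residual_block(2L, 3L, 2L)))
  )
  for (cs in cases) {
    l <- cs$make()
    x <- withr::with_seed(20, array(rnorm(prod(cs$xdim)), cs$xdim))
    y <- tradshm:::nn_forward(l, x, training = TRUE)
    gy <- withr::with_seed(21, {
      g <- array(rnorm(length(y)), dim = dim(y))
      g
    })
    gx <- tradshm:::nn_backward(l, gy)
    f <- function(xx) {
      sum(tradshm:::nn_forward(cs$make(), xx, training = TRUE) * gy)
    }
    gnum <- numeric_gradient(f, x, eps = cs$eps)
    scale <- max(abs(gnum), 1)
    expect_lt(max(abs(gx - gnum)) / scale, cs$tol, label = cs$name)
    if (!is.null(l$params)) {
      for (nm in names(l$params)) {
        fp <- function(p) {
          l2 <- cs$make()
          l2$params[[nm]] <- p
          sum(tradshm:::nn_forward(l2, x, training = TRUE) * gy)
        }
        gn <- numeric_gradient(fp, l$params[[nm]], eps = cs$eps)
        expect_lt(max(abs(l$grads[[nm]] - gn)) / max(abs(gn), 1), cs$tol,
                  label = paste(cs$name, nm))
      }
    }
  }
})

test_that("tinyvgg follows the printed block layout and shape arithmetic", {
  m <- build_tinyvgg()
  # conv k3 s1 p1 preserves spatial size; two 2x2 pools leave 16x16 maps,
  # so the flattened width is 10 * 16 * 16
  lin <- m$net$layers[[length(m$net$layers)]]
  expect_equal(dim(lin$params$w), c(2L, 10L * 16L * 16L))
  expect_equal(tradshm:::count_conv_layers(m$net), 4)
  x <- withr::with_seed(1, array(runif(64 * 64 * 3 * 4), c(64, 64, 3, 4)))
  logits <- model_forward(m, x)
  expect_equal(dim(logits), c(4L, 2L))
  expect_true(all(is.finite(logits)))
  # conv with k3 s1 p1 preserves the spatial size
  y1 <- tradshm:::nn_forward(m$net$layers[[1]], x)
  expect_equal(dim(y1)[1:2], c(64L, 64L))
})

test_that("vgg16 has 13 convs in five blocks and deterministic eval logits", {
  m <- build_vgg16()
  expect_equal(tradshm:::count_conv_layers(m$net), 13)
  pools <- sum(vapply(m$net$layers, inherits, logical(1), "nn_maxpool2d"))
  expect_equal(pools, 5)
  x <- withr::with_seed(2, array(runif(227 * 227 * 3), c(227, 227, 3, 1)))
  l1 <- model_forward(m, x)
  l2 <- model_forward(m, x)
  expect_equal(dim(l1), c(1L, 2L))
  expect_identical(l1, l2)  # dropout disabled in evaluation mode
  expect_error(model_forward(m, array(0, c(64, 64, 3, 1))), "227")
})

test_that("resnet34 counts 34 weighted layers and zero blocks are identities", {
  m <- build_resnet34()
  # 33 convolutions outside the projections plus the final linear layer
  n_proj <- sum(vapply(m$net$layers, function(l) {
    inherits(l, "nn_residual_block") && !is.null(l$proj)
  }, logical(1)))
  expect_equal(tradshm:::count_conv_layers(m$net) - n_proj + 1, 34)
  n_blocks <- sum(vapply(m$net$layers, inherits, logical(1),
                         "nn_residual_block"))
  expect_equal(n_blocks, 16)  # 3 + 4 + 6 + 3
  x <- withr::with_seed(3, array(runif(224 * 224 * 3 * 2), c(224, 224, 3, 2)))
  logits <- model_forward(m, x)
  expect_equal(dim(logits), c(2L, 2L))
  # a basic block with zero conv weights reduces to relu(x) = x for x >= 0
  blk <- withr::with_seed(4, tradshm:::nn_residual_block(4L, 4L, 1L))
  blk$conv1$params$w[] <- 0
  blk$conv2$params$w[] <- 0
  xin <- withr::with_seed(5, array(runif(6 * 6 * 4 * 2), c(6, 6, 4, 2)))
  expect_equal(tradshm:::nn_forward(blk, xin), xin)
})

test_that("forward passes are pure with softmax-consistent logits", {
  m <- build_tinyvgg(seed = 6)
  x1 <- withr::with_seed(7, array(runif(64 * 64 * 3), c(64, 64, 3)))
  batch <- array(0, c(64, 64, 3, 2))
  batch[, , , 1] <- x1
  batch[, , , 2] <- x1  # duplicate row
  logits <- model_forward(m, batch)
  expect_equal(logits[1, ], logits[2, ])
  p <- exp(logits[1, ]) / sum(exp(logits[1, ]))
  expect_equal(sum(p), 1)
  # zero final layer -> all logits zero -> uniform softmax
  lin <- m$net$layers[[length(m$net$layers)]]
  lin$params$w[] <- 0
  lin$params$b[] <- 0
  l0 <- model_forward(m, batch)
  expect_true(all(l0 == 0))
})

test_that("one optimizer step changes every trainable layer", {
  # vanishing-gradient smoke test at a trainable depth
  m <- build_tinyvgg(seed = 8)
  x <- withr::with_seed(9, array(runif(64 * 64 * 3 * 4), c(64, 64, 3, 4)))
  before <- lapply(tradshm:::nn_param_layers(m$net),
                   function(l) l$params)
  logits <- tradshm:::nn_forward(m$net, x, training = TRUE)
  ce <- tradshm:::cross_entropy(logits, c(1L, 2L, 1L, 2L))
  tradshm:::nn_backward(m$net, ce$grad)
  opt <- tradshm:::make_optimizer(m$net, "adam", lr = 1e-3)
  tradshm:::optimizer_step(opt)
  after <- lapply(tradshm:::nn_param_layers(m$net), function(l) l$params)
  for (i in seq_along(before)) {
    expect_false(identical(before[[i]]$w %||% before[[i]]$gamma,
                           after[[i]]$w %||% after[[i]]$gamma),
                 label = sprintf("layer %d updated", i))
  }
})
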