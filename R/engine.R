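# Minimal CNN engine: layers are mutable environments holding parameters,
# gradients and forward caches; models are (possibly nested) compositions.
# Activations are (H, W, C, N) arrays between spatial layers and
# (features, N) matrices after flattening. All heavy lifting (convolution,
# pooling) is in src/conv_ops.cpp via im2col + BLAS gemm.

new_layer <- function(class, ...) {
  e <- new.env(parent = emptyenv())
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(class, "nn_layer")
  e
}

# He-uniform initialization, fan-in convention.
init_weight <- function(dims, fan_in) {
  bound <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -bound, bound), dim = dims)
}

nn_conv2d <- function(in_ch, out_ch, kernel = 3L, stride = 1L, pad = 1L) {
  w <- init_weight(c(kernel, kernel, in_ch, out_ch), kernel * kernel * in_ch)
  new_layer("nn_conv2d",
            params = list(w = w, b = numeric(out_ch)),
            grads = NULL, cache = NULL,
            stride = as.integer(stride), pad = as.integer(pad))
}

# momentum = NULL keeps a cumulative moving average of the batch statistics
# (the torch `momentum = None` convention); with the few optimizer steps of a
# desk-scale run this makes evaluation-mode statistics track the data from
# the first batch on, instead of decaying slowly away from the (0, 1) init.
nn_batchnorm2d <- function(ch, eps = 1e-5, momentum = NULL) {
  new_layer("nn_batchnorm2d",
            params = list(gamma = rep(1, ch), beta = numeric(ch)),
            grads = NULL, cache = NULL, eps = eps, momentum = momentum,
            n_batches = 0L,
            running_mean = numeric(ch), running_var = rep(1, ch))
}

nn_relu <- function() new_layer("nn_relu", params = NULL, cache = NULL)

nn_maxpool2d <- function(kernel = 2L, stride = 2L, pad = 0L) {
  new_layer("nn_maxpool2d", params = NULL, cache = NULL,
            kernel = as.integer(kernel), stride = as.integer(stride),
            pad = as.integer(pad))
}

nn_flatten <- function() new_layer("nn_flatten", params = NULL, cache = NULL)

nn_global_avgpool <- function() {
  new_layer("nn_global_avgpool", params = NULL, cache = NULL)
}

nn_dropout <- function(p = 0.5) {
  new_layer("nn_dropout", params = NULL, cache = NULL, p = p)
}

nn_linear <- function(in_features, out_features) {
  new_layer("nn_linear",
            params = list(w = matrix(stats::runif(out_features * in_features,
                                                  -sqrt(6 / in_features),
                                                  sqrt(6 / in_features)),
                                     out_features, in_features),
                          b = numeric(out_features)),
            grads = NULL, cache = NULL)
}

nn_sequential <- function(...) {
  new_layer("nn_sequential", layers = list(...), params = NULL)
}

# Basic residual block: two 3x3 conv+BN with an identity (or 1x1 projection)
# shortcut added before the final ReLU.
nn_residual_block <- function(in_ch, out_ch, stride = 1L) {
  proj <- NULL
  proj_bn <- NULL
  if (stride != 1L || in_ch != out_ch) {
    proj <- nn_conv2d(in_ch, out_ch, kernel = 1L, stride = stride, pad = 0L)
    proj_bn <- nn_batchnorm2d(out_ch)
  }
  new_layer("nn_residual_block",
            conv1 = nn_conv2d(in_ch, out_ch, stride = stride),
            bn1 = nn_batchnorm2d(out_ch),
            relu1 = nn_relu(),
            conv2 = nn_conv2d(out_ch, out_ch),
            bn2 = nn_batchnorm2d(out_ch),
            proj = proj, proj_bn = proj_bn,
            params = NULL, cache = NULL)
}

## ---- forward ----

nn_forward <- function(layer, x, training = FALSE) UseMethod("nn_forward")

#' @exportS3Method
nn_forward.nn_sequential <- function(layer, x, training = FALSE) {
  for (l in layer$layers) x <- nn_forward(l, x, training)
  x
}

#' @exportS3Method
nn_forward.nn_conv2d <- function(layer, x, training = FALSE) {
  y <- .conv2d_fwd(x, layer$params$w, layer$params$b, layer$stride, layer$pad)
  if (isTRUE(training)) layer$cache <- x
  y
}

#' @exportS3Method
nn_forward.nn_batchnorm2d <- function(layer, x, training = FALSE) {
  d <- dim(x)
  hw <- d[1] * d[2]
  ch <- d[3]
  n_eff <- hw * d[4]
  # training = "stats" re-estimates running statistics with the current
  # weights (used by the per-epoch recalibration pass) without caching
  # anything for backpropagation.
  update_stats <- isTRUE(training) || identical(training, "stats")
  if (update_stats) {
    st <- .channel_stats(x, hw, ch)
    mu <- st$sum / n_eff
    v <- pmax(st$sumsq / n_eff - mu^2, 0)
    mom <- if (identical(training, "stats")) {
      1 / (layer$n_batches + 1)
    } else {
      layer$momentum %||% (1 / (layer$n_batches + 1))
    }
    layer$n_batches <- layer$n_batches + 1L
    layer$running_mean <- (1 - mom) * layer$running_mean + mom * mu
    layer$running_var <- (1 - mom) * layer$running_var +
      mom * v * n_eff / max(n_eff - 1, 1)
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  inv_std <- 1 / sqrt(v + layer$eps)
  if (isTRUE(training)) {
    xhat <- .scale_shift(x, inv_std, -mu * inv_std, hw)
    y <- .scale_shift(xhat, layer$params$gamma, layer$params$beta, hw)
    layer$cache <- list(xhat = xhat, inv_std = inv_std, dims = d)
  } else {
    scale <- layer$params$gamma * inv_std
    y <- .scale_shift(x, scale, layer$params$beta - mu * scale, hw)
  }
  y
}

#' @exportS3Method
nn_forward.nn_relu <- function(layer, x, training = FALSE) {
  y <- .relu_fwd(x)
  if (isTRUE(training)) layer$cache <- y
  y
}

#' @exportS3Method
nn_forward.nn_maxpool2d <- function(layer, x, training = FALSE) {
  out <- .maxpool_fwd(x, layer$kernel, layer$stride, layer$pad)
  if (isTRUE(training)) layer$cache <- list(idx = out$idx, xdim = dim(x))
  out$y
}

#' @exportS3Method
nn_forward.nn_flatten <- function(layer, x, training = FALSE) {
  d <- dim(x)
  if (isTRUE(training)) layer$cache <- d
  dim(x) <- c(prod(d[-length(d)]), d[length(d)])
  x
}

#' @exportS3Method
nn_forward.nn_global_avgpool <- function(layer, x, training = FALSE) {
  d <- dim(x)
  hw <- d[1] * d[2]
  y <- matrix(.colSums(x, hw, d[3] * d[4]) / hw, d[3], d[4])
  if (isTRUE(training)) layer$cache <- d
  y
}

#' @exportS3Method
nn_forward.nn_dropout <- function(layer, x, training = FALSE) {
  if (!isTRUE(training) || layer$p <= 0) return(x)
  mask <- (stats::runif(length(x)) >= layer$p) / (1 - layer$p)
  layer$cache <- mask
  y <- x * mask
  dim(y) <- dim(x)
  y
}

#' @exportS3Method
nn_forward.nn_linear <- function(layer, x, training = FALSE) {
  if (isTRUE(training)) layer$cache <- x
  layer$params$w %*% x + layer$params$b
}

#' @exportS3Method
nn_forward.nn_residual_block <- function(layer, x, training = FALSE) {
  main <- nn_forward(layer$conv1, x, training)
  main <- nn_forward(layer$bn1, main, training)
  main <- nn_forward(layer$relu1, main, training)
  main <- nn_forward(layer$conv2, main, training)
  main <- nn_forward(layer$bn2, main, training)
  if (is.null(layer$proj)) {
    sc <- x
  } else {
    sc <- nn_forward(layer$proj, x, training)
    sc <- nn_forward(layer$proj_bn, sc, training)
  }
  y <- .add_relu(main, sc)
  if (isTRUE(training)) layer$cache <- y
  y
}

## ---- backward ----

nn_backward <- function(layer, grad) UseMethod("nn_backward")

#' @exportS3Method
nn_backward.nn_sequential <- function(layer, grad) {
  for (l in rev(layer$layers)) grad <- nn_backward(l, grad)
  grad
}

#' @exportS3Method
nn_backward.nn_conv2d <- function(layer, grad) {
  g <- .conv2d_bwd(layer$cache, layer$params$w, grad, layer$stride, layer$pad)
  layer$grads <- list(w = g$gw, b = g$gb)
  layer$cache <- NULL
  g$gx
}

#' @exportS3Method
nn_backward.nn_batchnorm2d <- function(layer, grad) {
  cc <- layer$cache
  d <- cc$dims
  hw <- d[1] * d[2]
  n_eff <- hw * d[4]
  gamma <- layer$params$gamma
  red <- .channel_dot(grad, cc$xhat, hw, d[3])
  gbeta <- red$sum
  ggamma <- red$dot
  # gx = (g*gamma - mean(g*gamma) - xhat * mean(g*gamma*xhat)) * inv_std
  gx <- .bn_bwd_fused(grad, cc$xhat, gamma, gbeta * gamma / n_eff,
                      ggamma * gamma / n_eff, cc$inv_std, hw)
  layer$grads <- list(gamma = ggamma, beta = gbeta)
  layer$cache <- NULL
  gx
}

#' @exportS3Method
nn_backward.nn_relu <- function(layer, grad) {
  gx <- .relu_bwd(grad, layer$cache)
  layer$cache <- NULL
  gx
}

#' @exportS3Method
nn_backward.nn_maxpool2d <- function(layer, grad) {
  gx <- .maxpool_bwd(grad, layer$cache$idx, layer$cache$xdim)
  layer$cache <- NULL
  gx
}

#' @exportS3Method
nn_backward.nn_flatten <- function(layer, grad) {
  dim(grad) <- layer$cache
  layer$cache <- NULL
  grad
}

#' @exportS3Method
nn_backward.nn_global_avgpool <- function(layer, grad) {
  d <- layer$cache
  hw <- d[1] * d[2]
  gx <- array(rep(as.vector(grad) / hw, each = hw), dim = d)
  layer$cache <- NULL
  gx
}

#' @exportS3Method
nn_backward.nn_dropout <- function(layer, grad) {
  if (is.null(layer$cache)) return(grad)
  gx <- grad * layer$cache
  dim(gx) <- dim(grad)
  layer$cache <- NULL
  gx
}

#' @exportS3Method
nn_backward.nn_linear <- function(layer, grad) {
  x <- layer$cache
  layer$grads <- list(w = grad %*% t(x), b = .rowSums(grad, nrow(grad), ncol(grad)))
  layer$cache <- NULL
  t(layer$params$w) %*% grad
}

#' @exportS3Method
nn_backward.nn_residual_block <- function(layer, grad) {
  gs <- .relu_bwd(grad, layer$cache)
  layer$cache <- NULL
  g <- nn_backward(layer$bn2, gs)
  g <- nn_backward(layer$conv2, g)
  g <- nn_backward(layer$relu1, g)
  g <- nn_backward(layer$bn1, g)
  gx_main <- nn_backward(layer$conv1, g)
  if (is.null(layer$proj)) {
    gx_sc <- gs
  } else {
    gx_sc <- nn_backward(layer$proj_bn, gs)
    gx_sc <- nn_backward(layer$proj, gx_sc)
  }
  gx_main + gx_sc
}

## ---- parameter traversal and optimizers ----

# Flat list of parameter-bearing primitive layers, in definition order.
nn_param_layers <- function(layer) {
  if (inherits(layer, "nn_sequential")) {
    return(do.call(c, lapply(layer$layers, nn_param_layers)))
  }
  if (inherits(layer, "nn_residual_block")) {
    inner <- list(layer$conv1, layer$bn1, layer$conv2, layer$bn2)
    if (!is.null(layer$proj)) inner <- c(inner, list(layer$proj, layer$proj_bn))
    return(do.call(c, lapply(inner, nn_param_layers)))
  }
  if (is.null(layer$params)) list() else list(layer)
}

# All batch-normalization layers in a (possibly nested) network.
nn_bn_layers <- function(layer) {
  Filter(function(l) inherits(l, "nn_batchnorm2d"), nn_param_layers(layer))
}

# Re-estimate batch-norm running statistics with the current weights by a
# stats-only forward sweep over `x` (chunked). With stale running averages a
# network that fits its training batches can still evaluate poorly; this
# precise re-estimation makes evaluation-mode metrics reflect the weights
# actually being scored.
nn_recalibrate_bn <- function(net, x, chunk = 8L) {
  bns <- nn_bn_layers(net)
  if (length(bns) == 0) return(invisible(net))
  for (bn in bns) bn$n_batches <- 0L
  n <- dim(x)[4]
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    nn_forward(net, x[, , , idx, drop = FALSE], training = "stats")
  }
  invisible(net)
}

nn_count_params <- function(layer) {
  sum(vapply(nn_param_layers(layer),
             function(l) sum(vapply(l$params, length, numeric(1))), numeric(1)))
}

make_optimizer <- function(net, kind = c("sgd", "adam"), lr,
                           momentum = 0, beta1 = 0.9, beta2 = 0.999,
                           eps = 1e-8) {
  kind <- match.arg(kind)
  opt <- new.env(parent = emptyenv())
  opt$kind <- kind
  opt$lr <- lr
  opt$momentum <- momentum
  opt$beta1 <- beta1
  opt$beta2 <- beta2
  opt$eps <- eps
  opt$t <- 0L
  opt$layers <- nn_param_layers(net)
  opt$state <- lapply(opt$layers, function(l) {
    lapply(l$params, function(p) list(m = p * 0, v = p * 0))
  })
  class(opt) <- "nn_optimizer"
  opt
}

optimizer_step <- function(opt) {
  opt$t <- opt$t + 1L
  for (i in seq_along(opt$layers)) {
    l <- opt$layers[[i]]
    if (is.null(l$grads)) next
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      if (opt$kind == "sgd") {
        if (opt$momentum > 0) {
          buf <- opt$state[[i]][[nm]]$m * opt$momentum + g
          opt$state[[i]][[nm]]$m <- buf
          g <- buf
        }
        l$params[[nm]] <- l$params[[nm]] - opt$lr * g
      } else {
        st <- opt$state[[i]][[nm]]
        st$m <- opt$beta1 * st$m + (1 - opt$beta1) * g
        st$v <- opt$beta2 * st$v + (1 - opt$beta2) * g * g
        opt$state[[i]][[nm]] <- st
        mhat <- st$m / (1 - opt$beta1^opt$t)
        vhat <- st$v / (1 - opt$beta2^opt$t)
        l$params[[nm]] <- l$params[[nm]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
      }
    }
    l$grads <- NULL
  }
  invisible(opt)
}

## ---- loss ----

# Softmax cross-entropy on a (n_classes x N) logit matrix; targets are
# integer class indices in 1..n_classes. Returns loss and logit gradient.
cross_entropy <- function(logits, targets) {
  n <- ncol(logits)
  zmax <- apply(logits, 2, max)
  z <- logits - rep(zmax, each = nrow(logits))
  ez <- exp(z)
  p <- ez / rep(.colSums(ez, nrow(ez), n), each = nrow(ez))
  picked <- p[cbind(targets, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  grad <- p
  grad[cbind(targets, seq_len(n))] <- grad[cbind(targets, seq_len(n))] - 1
  list(loss = loss, grad = grad / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
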