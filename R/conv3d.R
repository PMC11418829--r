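#' Training configuration for the 3D convolutional network
#'
#' Defaults follow the reference training recipe: Adam with learning rate
#' 0.001, batch size 1, 20 epochs, dropout 0.4 before each wide dense layer,
#' batch normalization after every convolution. `filters`, `dense_units` and
#' the spatial input size are overridable to run reduced-width variants of
#' the same architecture on small problems.
#'
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param dropout Dropout rate before each wide dense layer.
#' @param filters Channel widths of the five convolution layers.
#' @param dense_units Widths of the two dense layers before the classifier.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer.
#' @param bn_eps,bn_momentum Batch-norm stabilizer and running-stat momentum.
#' @return A list of class `conv3d_config`.
#' @export
conv3d_config <- function(epochs = 20L, lr = 1e-3, dropout = 0.4,
                          filters = c(64L, 128L, 256L, 256L, 256L),
                          dense_units = c(1024L, 1024L),
                          beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                          bn_eps = 1e-5, bn_momentum = 0.1) {
  stopifnot(length(filters) == 5L, length(dense_units) == 2L)
  structure(list(epochs = as.integer(epochs), lr = lr, dropout = dropout,
                 filters = as.integer(filters),
                 dense_units = as.integer(dense_units),
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 bn_eps = bn_eps, bn_momentum = bn_momentum, batch = 1L),
            class = "conv3d_config")
}

conv_same_geom <- function(in_dim, stride, k = 3L) {
  out <- ceiling(in_dim / stride)
  pad_total <- pmax((out - 1L) * stride + k - in_dim, 0L)
  list(out = as.integer(out), pad_before = as.integer(pad_total %/% 2L))
}

#' Build the 3D convolutional architecture specification
#'
#' Declares the layer stack: five same-padded (ceil-mode) strided 3x3x3
#' convolutions with batch normalization and ReLU (channel widths
#' 64/128/256/256/256, stride schedule 1, 2, 2, 2, (2,4,4)), a flatten, two
#' 1024-unit ReLU dense layers each preceded by dropout, and a softmax
#' classifier. For the canonical input `(12, 128, 128, C)` the output-shape
#' chain is `(12,128,128,64)`, `(6,64,64,128)`, `(3,32,32,256)`,
#' `(2,16,16,256)`, `(1,4,4,256)`, 1024, 1024, `n_classes`.
#'
#' @param in_channels Number of kinematic input channels (>= 1).
#' @param n_classes Number of output classes (>= 2; pairwise tasks use 2).
#' @param input_shape Temporal and spatial input dims `(T, H, W)`.
#' @param config A [conv3d_config] (supplies widths and dropout).
#' @return An object of class `conv3d_spec`; element `layers` is the ordered
#'   layer list with per-layer output shapes and trainable parameter counts.
#' @export
build_architecture <- function(in_channels, n_classes = 2L,
                               input_shape = c(12L, 128L, 128L),
                               config = conv3d_config()) {
  if (in_channels < 1L) stopf("in_channels must be >= 1")
  if (n_classes < 2L) stopf("n_classes must be >= 2")
  in_channels <- as.integer(in_channels)
  n_classes <- as.integer(n_classes)
  input_shape <- as.integer(input_shape)
  strides <- list(c(1L, 1L, 1L), c(2L, 2L, 2L), c(2L, 2L, 2L),
                  c(2L, 2L, 2L), c(2L, 4L, 4L))
  names_conv <- c("conv3d", paste0("conv3d_", 1:4))
  layers <- list()
  shape <- c(input_shape, in_channels)   # (T, H, W, C)
  for (i in seq_len(5L)) {
    g <- conv_same_geom(shape[1:3], strides[[i]])
    cout <- config$filters[i]
    layers[[names_conv[i]]] <- list(
      name = names_conv[i], kind = "conv3d", filters = cout,
      kernel = c(3L, 3L, 3L), stride = strides[[i]], padding = "same",
      pad_before = g$pad_before, batch_norm = TRUE, activation = "relu",
      in_shape = shape, out_shape = c(g$out, cout),
      params = 27L * shape[4] * cout + cout)
    shape <- c(g$out, cout)
  }
  flat <- as.integer(prod(shape))
  layers[["flatten"]] <- list(name = "flatten", kind = "flatten",
                              in_shape = shape, out_shape = flat, params = 0L)
  n_in <- flat
  dn <- c("dense", "dense_1")
  for (i in 1:2) {
    u <- config$dense_units[i]
    layers[[dn[i]]] <- list(name = dn[i], kind = "dense", units = u,
                            dropout_rate = config$dropout, activation = "relu",
                            in_shape = n_in, out_shape = u,
                            params = as.integer(n_in * u + u))
    n_in <- u
  }
  layers[["dense_2"]] <- list(name = "dense_2", kind = "dense",
                              units = n_classes, dropout_rate = 0,
                              activation = "softmax", in_shape = n_in,
                              out_shape = n_classes,
                              params = as.integer(n_in * n_classes + n_classes))
  structure(list(layers = layers, in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape), config = config),
            class = "conv3d_spec")
}

#' Trainable parameter count of a layer
#'
#' Kernel parameters plus bias: `kt*ky*kx*C_in*C_out + C_out` for a
#' convolution (batch-norm scale/shift counted separately),
#' `units_in*units_out + units_out` for a dense layer.
#'
#' @param spec A `conv3d_spec` from [build_architecture].
#' @param layer_name Layer name, e.g. `"conv3d_1"`, `"dense_1"`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec, layer_name) {
  stopifnot(inherits(spec, "conv3d_spec"))
  ly <- spec$layers[[layer_name]]
  if (is.null(ly)) stopf("unknown layer '%s' (have: %s)", layer_name,
                         paste(names(spec$layers), collapse = ", "))
  ly$params
}

#' @export
print.conv3d_spec <- function(x, ...) {
  cat(sprintf("<conv3d_spec> input (%s, %d), %d classes\n",
              paste(x$input_shape, collapse = ", "), x$in_channels,
              x$n_classes))
  cat(sprintf("  %-10s %-18s %12s  %s\n", "layer", "output shape", "params",
              "activation"))
  for (ly in x$layers) {
    shp <- paste(ly$out_shape, collapse = ", ")
    cat(sprintf("  %-10s (%-16s %12s  %s\n", ly$name, paste0(shp, ")"),
                format(ly$params, big.mark = ","), ly$activation %||% "-"))
  }
  invisible(x)
}

# ---- parameter initialization --------------------------------------------

init_net_params <- function(spec) {
  params <- list()
  for (ly in spec$layers) {
    if (ly$kind == "conv3d") {
      ci <- ly$in_shape[4]; co <- ly$filters
      params[[ly$name]] <- list(
        w = array(rnorm(27 * ci * co) * sqrt(2 / (27 * ci)),
                  dim = c(3, 3, 3, ci, co)),
        b = numeric(co),
        gamma = rep(1, co), beta = numeric(co),
        run_mean = numeric(co), run_var = rep(1, co))
    } else if (ly$kind == "dense") {
      ni <- ly$in_shape; no <- ly$out_shape
      params[[ly$name]] <- list(
        w = matrix(rnorm(ni * no) * sqrt(2 / ni), ni, no),
        b = numeric(no))
    }
  }
  params
}

# ---- forward / backward ---------------------------------------------------

bn_forward <- function(z, dims, p, cfg, training) {
  C <- dims[4]; N <- prod(dims[1:3])
  M <- matrix(z, ncol = C)
  if (N == 1L) {
    # single voxel per channel: per-sample statistics are degenerate, so the
    # normalization reduces to the learned affine transform alone
    y <- M * rep(p$gamma, each = N) + rep(p$beta, each = N)
    return(list(y = as.vector(y), xhat = M, inv = rep(1, C),
                mu = numeric(C), va = rep(1, C), identity = TRUE))
  }
  if (training) {
    mu <- colMeans(M)
    va <- pmax(colMeans(M^2) - mu^2, 0)
  } else {
    mu <- p$run_mean; va <- p$run_var
  }
  inv <- 1 / sqrt(va + cfg$bn_eps)
  xhat <- (M - rep(mu, each = N)) * rep(inv, each = N)
  y <- xhat * rep(p$gamma, each = N) + rep(p$beta, each = N)
  list(y = as.vector(y), xhat = xhat, inv = inv, mu = mu, va = va,
       identity = FALSE)
}

net_forward <- function(net, x, training = FALSE, capture = NULL) {
  spec <- net$spec; cfg <- spec$config
  cache <- list(); cur <- x; cur_dim <- dim(x)
  captured <- NULL
  for (ly in spec$layers) {
    nm <- ly$name
    if (ly$kind == "conv3d") {
      p <- net$params[[nm]]
      out_dim <- ly$out_shape
      z <- cpp_conv3d_forward(as.vector(cur), as.integer(cur_dim),
                              as.vector(p$w), dim(p$w), p$b,
                              ly$stride, ly$pad_before, out_dim[1:3])
      bn <- bn_forward(z, out_dim, p, cfg, training)
      act <- pmax(bn$y, 0)
      cache[[nm]] <- list(x = cur, x_dim = cur_dim, z = z, bn = bn, act = act,
                          out_dim = out_dim)
      cur <- act; cur_dim <- out_dim
    } else if (ly$kind == "flatten") {
      cur <- as.vector(cur); cur_dim <- length(cur)
      cache[[nm]] <- list()
    } else {                                   # dense
      p <- net$params[[nm]]
      drop_mask <- NULL
      if (training && (ly$dropout_rate %||% 0) > 0) {
        drop_mask <- (runif(length(cur)) >= ly$dropout_rate) /
          (1 - ly$dropout_rate)
        cur <- cur * drop_mask
      }
      z <- drop(cur %*% p$w) + p$b
      act <- if (identical(ly$activation, "relu")) pmax(z, 0) else z
      cache[[nm]] <- list(x = cur, z = z, act = act, drop_mask = drop_mask)
      cur <- act; cur_dim <- length(cur)
    }
    if (!is.null(capture) && nm == capture) captured <- cur
  }
  logits <- cache[["dense_2"]]$z
  pm <- exp(logits - max(logits))
  probs <- pm / sum(pm)
  list(probs = probs, cache = cache, captured = captured)
}

net_backward <- function(net, fwd, y_index) {
  spec <- net$spec; cfg <- spec$config
  grads <- list()
  g <- fwd$probs
  g[y_index] <- g[y_index] - 1          # d loss / d logits
  lnames <- rev(names(spec$layers))
  for (nm in lnames) {
    ly <- spec$layers[[nm]]
    ch <- fwd$cache[[nm]]
    if (ly$kind == "dense") {
      p <- net$params[[nm]]
      if (identical(ly$activation, "relu")) g <- g * (ch$z > 0)
      grads[[nm]] <- list(w = outer(ch$x, g), b = g)
      g <- drop(p$w %*% g)
      if (!is.null(ch$drop_mask)) g <- g * ch$drop_mask
    } else if (ly$kind == "flatten") {
      # g stays a flat vector; conv layer below reshapes via dims
    } else {                               # conv3d
      p <- net$params[[nm]]
      od <- ch$out_dim
      g <- g * (ch$bn$y > 0)               # through ReLU (post-BN activation)
      # batch-norm backward (per-channel stats over T*H*W)
      C <- od[4]; N <- prod(od[1:3])
      Gm <- matrix(g, ncol = C)
      dgamma <- colSums(Gm * ch$bn$xhat)
      dbeta <- colSums(Gm)
      dxhat <- Gm * rep(p$gamma, each = N)
      if (isTRUE(ch$bn$identity)) {
        dz <- dxhat
      } else {
        sum_dxhat <- colSums(dxhat)
        sum_dxx <- colSums(dxhat * ch$bn$xhat)
        dz <- (dxhat - rep(sum_dxhat / N, each = N) -
                 ch$bn$xhat * rep(sum_dxx / N, each = N)) *
          rep(ch$bn$inv, each = N)
      }
      bk <- cpp_conv3d_backward(as.vector(ch$x), as.integer(ch$x_dim),
                                as.vector(p$w), dim(p$w),
                                as.vector(dz), od[1:3],
                                ly$stride, ly$pad_before,
                                need_gx = !identical(nm, "conv3d"))
      grads[[nm]] <- list(w = bk$gw, b = bk$gb, gamma = dgamma, beta = dbeta)
      g <- bk$gx
    }
  }
  grads
}

adam_step <- function(net, grads, state, t, cfg) {
  for (nm in names(grads)) {
    for (pn in names(grads[[nm]])) {
      g <- as.numeric(grads[[nm]][[pn]])
      key <- paste0(nm, ".", pn)
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- numeric(length(g))
        state$v[[key]] <- numeric(length(g))
      }
      state$m[[key]] <- cfg$beta1 * state$m[[key]] + (1 - cfg$beta1) * g
      state$v[[key]] <- cfg$beta2 * state$v[[key]] + (1 - cfg$beta2) * g^2
      mhat <- state$m[[key]] / (1 - cfg$beta1^t)
      vhat <- state$v[[key]] / (1 - cfg$beta2^t)
      upd <- cfg$lr * mhat / (sqrt(vhat) + cfg$adam_eps)
      cur <- net$params[[nm]][[pn]]
      net$params[[nm]][[pn]] <- cur - array(upd, dim = dim(cur) %||% length(cur))
    }
  }
  list(net = net, state = state)
}

stack_array <- function(s) {
  if (inherits(s, "kinematic_stack")) s$data
  else if (is.array(s) && length(dim(s)) == 4L) s
  else stopf("expected a kinematic_stack or a 4D array")
}

#' Train the 3D convolutional classifier
#'
#' Trains the architecture of [build_architecture] end-to-end with
#' cross-entropy, Adam (lr 0.001), batch size 1 and 20 epochs by default,
#' with batch normalization (per-sample statistics during training, running
#' statistics at inference) and dropout 0.4 before each wide dense layer.
#' Fully deterministic given `seed` (one RNG stream drives initialization,
#' sample shuffling and dropout masks).
#'
#' @param stacks List of `kinematic_stack`s (or 4D arrays) of identical
#'   shape.
#' @param labels Class label per stack; at least two classes, at least two
#'   samples per class recommended.
#' @param config A [conv3d_config].
#' @param seed Integer RNG seed.
#' @return A `conv3d_net` with elements `spec`, `params`, `classes`,
#'   `loss_history` (mean cross-entropy per epoch) and `seed`.
#' @export
train_binary <- function(stacks, labels, config = conv3d_config(), seed = 0L) {
  arrs <- lapply(stacks, stack_array)
  d0 <- dim(arrs[[1]])
  for (a in arrs) if (!identical(dim(a), d0))
    stopf("all stacks must share one shape")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    stopf("need at least 2 classes, got %d", length(classes))
  if (length(labels) != length(arrs)) stopf("labels/stacks length mismatch")
  y <- match(labels, classes)

  set.seed(seed)
  spec <- build_architecture(in_channels = d0[4], n_classes = length(classes),
                             input_shape = d0[1:3], config = config)
  net <- list(spec = spec, params = init_net_params(spec),
              classes = classes, seed = seed)
  state <- list(m = list(), v = list())
  step <- 0L
  loss_hist <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(length(arrs))
    ep_loss <- 0
    for (i in ord) {
      fwd <- net_forward(net, arrs[[i]], training = TRUE)
      ep_loss <- ep_loss - log(max(fwd$probs[y[i]], 1e-12))
      # update batch-norm running stats
      for (nm in names(spec$layers)) {
        if (spec$layers[[nm]]$kind != "conv3d") next
        bn <- fwd$cache[[nm]]$bn
        mom <- config$bn_momentum
        net$params[[nm]]$run_mean <-
          (1 - mom) * net$params[[nm]]$run_mean + mom * bn$mu
        net$params[[nm]]$run_var <-
          (1 - mom) * net$params[[nm]]$run_var + mom * bn$va
      }
      grads <- net_backward(net, fwd, y[i])
      step <- step + 1L
      res <- adam_step(net, grads, state, step, config)
      net <- res$net; state <- res$state
    }
    loss_hist[ep] <- ep_loss / length(arrs)
  }
  net$loss_history <- loss_hist
  net$config <- config
  class(net) <- "conv3d_net"
  net
}

#' @export
print.conv3d_net <- function(x, ...) {
  cat(sprintf("<conv3d_net> classes [%s]; input (%s, %d); %d epochs, final loss %.4f\n",
              paste(x$classes, collapse = ", "),
              paste(x$spec$input_shape, collapse = ", "),
              x$spec$in_channels, length(x$loss_history),
              tail(x$loss_history, 1)))
  invisible(x)
}

#' @export
summary.conv3d_net <- function(object, ...) {
  print(object)
  print(object$spec)
  invisible(object)
}

#' Class probabilities from a trained network
#'
#' @param object A `conv3d_net`.
#' @param newdata A `kinematic_stack`, 4D array, or list of them, matching
#'   the training shape.
#' @param ... Unused.
#' @return A numeric matrix (samples x classes) of softmax probabilities;
#'   rows sum to 1.
#' @export
predict.conv3d_net <- function(object, newdata, ...) {
  items <- if (inherits(newdata, "kinematic_stack") ||
               (is.array(newdata) && length(dim(newdata)) == 4L))
    list(newdata) else newdata
  out <- matrix(0, length(items), length(object$classes),
                dimnames = list(NULL, object$classes))
  exp_dim <- c(object$spec$input_shape, object$spec$in_channels)
  for (i in seq_along(items)) {
    a <- stack_array(items[[i]])
    if (!identical(dim(a), as.integer(exp_dim)))
      stopf("stack shape (%s) does not match model input (%s)",
            paste(dim(a), collapse = ","), paste(exp_dim, collapse = ","))
    out[i, ] <- net_forward(object, a, training = FALSE)$probs
  }
  out
}

#' Extract a penultimate-layer embedding
#'
#' Runs a forward pass in inference mode (dropout disabled, batch-norm on
#' running statistics) and returns the post-ReLU activations of a chosen
#' dense layer as a learned cardiac descriptor. The default `"dense_1"` is
#' the last wide dense layer before the classifier.
#'
#' @param model A `conv3d_net`.
#' @param stack A `kinematic_stack` (or 4D array) matching the model input.
#' @param layer `"dense_1"` (default) or `"dense"`.
#' @return An `embedding_vector`: list with `values` (length = layer width),
#'   `source_layer`, `kinematic_channels`, `patient_id`, `slice_index`,
#'   `label`.
#' @export
extract_embedding <- function(model, stack, layer = "dense_1") {
  stopifnot(inherits(model, "conv3d_net"))
  if (!layer %in% c("dense", "dense_1"))
    stopf("unknown embedding layer '%s' (use 'dense' or 'dense_1')", layer)
  a <- stack_array(stack)
  fwd <- net_forward(model, a, training = FALSE, capture = layer)
  meta <- if (inherits(stack, "kinematic_stack")) stack else list()
  structure(list(values = as.numeric(fwd$captured), source_layer = layer,
                 kinematic_channels = meta$channel_names %||% NA_character_,
                 patient_id = meta$patient_id %||% NA_character_,
                 slice_index = meta$slice_index %||% NA_integer_,
                 label = meta$label %||% NA_character_),
            class = "embedding_vector")
}
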