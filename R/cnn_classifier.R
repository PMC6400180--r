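# A deliberately tiny supervised CNN for 64 x 64 diffraction snapshots:
# three [conv 3x3 -> batch norm -> ReLU -> 2x2 max-pool -> dropout]
# stages, one hidden dense unit and a sigmoid output, 316 trainable
# parameters in the default configuration.  Forward pass, backpropagation
# and the Adam optimizer are implemented directly on base-R arrays
# (im2col convolutions), so training is exactly reproducible from a seed
# on a single CPU.

#' CNN architecture specification
#'
#' @param input_size length-2 input image size; must survive three 2x2
#'   poolings (divisible by 8).
#' @param conv_channels output channels of the three conv layers.
#' @param kernel_size odd kernel edge (same padding).
#' @param conv_bias add a bias per conv channel.
#' @param hidden_units width of the hidden dense layer.
#' @param hidden_bias,output_bias bias flags of the dense layers.
#' @param dropout_rate dropout probability on the pooled conv feature
#'   maps (training only).
#' @param batch_norm batch-normalize after every conv layer (2 trainable
#'   parameters per channel).
#' @return An object of class `cnn_spec`.  The default specification has
#'   exactly 316 trainable parameters (see [count_parameters()]).
#' @export
cnn_spec <- function(input_size = c(64L, 64L), conv_channels = c(2L, 2L, 3L),
                     kernel_size = 3L, conv_bias = FALSE,
                     hidden_units = 1L, hidden_bias = TRUE,
                     output_bias = FALSE, dropout_rate = 0.2,
                     batch_norm = TRUE) {
  stopifnot(length(input_size) == 2, length(conv_channels) == 3,
            kernel_size %% 2 == 1, hidden_units >= 1,
            dropout_rate >= 0, dropout_rate < 1)
  if (any(input_size %% 8 != 0))
    stop("input_size must map through three 2x2 poolings ",
         "(divisible by 8)")
  structure(list(input_size = as.integer(input_size),
                 conv_channels = as.integer(conv_channels),
                 kernel_size = as.integer(kernel_size),
                 conv_bias = conv_bias,
                 hidden_units = as.integer(hidden_units),
                 hidden_bias = hidden_bias, output_bias = output_bias,
                 dropout_rate = dropout_rate, batch_norm = batch_norm),
            class = "cnn_spec")
}

#' Closed-form trainable-parameter count of a specification
#'
#' Convolution kernels (`k^2 * C_in * C_out`, + `C_out` per bias), two
#' batch-norm parameters per normalized channel, dense weights and
#' biases; pooling and dropout contribute nothing.
#'
#' @param spec a [cnn_spec()].
#' @return integer parameter count.
#' @export
count_parameters_spec <- function(spec) {
  stopifnot(inherits(spec, "cnn_spec"))
  cin <- c(1L, spec$conv_channels[1:2])
  cout <- spec$conv_channels
  conv <- sum(spec$kernel_size^2 * cin * cout) +
    if (spec$conv_bias) sum(cout) else 0L
  bn <- if (spec$batch_norm) 2L * sum(cout) else 0L
  flat <- prod(spec$input_size %/% 8L) * cout[3]
  hidden <- flat * spec$hidden_units +
    if (spec$hidden_bias) spec$hidden_units else 0L
  out <- spec$hidden_units + if (spec$output_bias) 1L else 0L
  as.integer(conv + bn + hidden + out)
}

#' Build an untrained CNN model
#'
#' Weights are He-initialized from the supplied seed; batch-norm running
#' statistics start at mean 0, variance 1.
#'
#' @param spec a [cnn_spec()].
#' @param init_seed seed for the weight initialization.
#' @return An object of class `cnn_model`.
#' @export
build_cnn <- function(spec = cnn_spec(), init_seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(init_seed)
  k2 <- spec$kernel_size^2
  cin <- c(1L, spec$conv_channels[1:2])
  cout <- spec$conv_channels
  conv <- lapply(1:3, function(l) {
    w <- matrix(rnorm(k2 * cin[l] * cout[l], 0,
                      sqrt(2 / (k2 * cin[l]))), k2 * cin[l], cout[l])
    list(w = w,
         b = if (spec$conv_bias) numeric(cout[l]) else NULL,
         gamma = if (spec$batch_norm) rep(1, cout[l]) else NULL,
         beta = if (spec$batch_norm) numeric(cout[l]) else NULL,
         run_mean = numeric(cout[l]), run_var = rep(1, cout[l]))
  })
  flat <- prod(spec$input_size %/% 8L) * cout[3]
  dense <- list(
    wh = matrix(rnorm(flat * spec$hidden_units, 0, sqrt(2 / flat)),
                flat, spec$hidden_units),
    bh = if (spec$hidden_bias) rep(0.1, spec$hidden_units) else NULL,
    wo = matrix(rnorm(spec$hidden_units, 0, sqrt(1 / spec$hidden_units)),
                spec$hidden_units, 1),
    bo = if (spec$output_bias) 0 else NULL)
  structure(list(spec = spec, conv = conv, dense = dense,
                 bn_momentum = 0.1, trained = FALSE),
            class = "cnn_model")
}

#' Count the trainable parameters of a built model
#'
#' Sums the actual parameter tensors; agrees with
#' [count_parameters_spec()] by construction and returns 0 for a model
#' with no layers.
#'
#' @param model a `cnn_model` (or any list of parameter tensors in the
#'   same layout).
#' @return integer parameter count.
#' @export
count_parameters <- function(model) {
  if (is.null(model$conv) && is.null(model$dense)) return(0L)
  n <- 0L
  for (l in model$conv)
    n <- n + length(l$w) + length(l$b) + length(l$gamma) + length(l$beta)
  d <- model$dense
  as.integer(n + length(d$wh) + length(d$bh) + length(d$wo) +
               length(d$bo))
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %dx%d input, channels %s, %d parameters%s\n",
              x$spec$input_size[1], x$spec$input_size[2],
              paste(x$spec$conv_channels, collapse = "-"),
              count_parameters(x),
              if (x$trained) " (trained)" else " (untrained)"))
  invisible(x)
}

# ---- array plumbing ----------------------------------------------------

# im2col gather indices for a same-padded k x k convolution on an
# (H, W, C) sample embedded in an (H+k-1, W+k-1, C) zero pad; one column
# per (dh, dw, c).
#' @noRd
im2col_index <- function(h, w, cc, k) {
  hp <- h + k - 1; wp <- w + k - 1
  base <- as.vector(outer(seq_len(h), (seq_len(w) - 1L) * hp, `+`))
  off <- as.vector(outer(as.vector(outer(0:(k - 1), (0:(k - 1)) * hp, `+`)),
                         (seq_len(cc) - 1L) * hp * wp, `+`))
  idx <- outer(base, off, `+`)  # (h*w) x (k^2*c)
  storage.mode(idx) <- "integer"
  idx
}

# gather-index cache: shapes recur every batch, the index build is the
# expensive part
.im2col_cache <- new.env(parent = emptyenv())

#' @noRd
im2col_full_index <- function(h, w, cc, k, n) {
  key <- paste(h, w, cc, k, n, sep = "_")
  got <- .im2col_cache[[key]]
  if (!is.null(got)) return(got)
  idx <- im2col_index(h, w, cc, k)
  hp <- h + k - 1; wp <- w + k - 1
  hw <- h * w
  full <- idx[rep(seq_len(hw), n), ] +
    rep(as.integer((seq_len(n) - 1) * hp * wp * cc), each = hw)
  .im2col_cache[[key]] <- full
  full
}

#' @noRd
conv_forward <- function(x, layer, k) {
  d <- dim(x)  # H W C N
  hp <- d[1] + k - 1; wp <- d[2] + k - 1
  xp <- array(0, c(hp, wp, d[3], d[4]))
  off <- (k - 1) / 2
  xp[off + seq_len(d[1]), off + seq_len(d[2]), , ] <- x
  full <- im2col_full_index(d[1], d[2], d[3], k, d[4])
  m <- xp[as.vector(full)]
  dim(m) <- dim(full)
  out <- m %*% layer$w
  if (!is.null(layer$b)) out <- out + rep(layer$b, each = nrow(out))
  list(out = out, m = m, pad_dim = c(hp, wp, d[3], d[4]))
}

# out/grad matrices are (H*W*N) x Cout with rows ordered h-fastest then
# w then sample.  The input gradient of a same-padded correlation is the
# same-padded correlation of the output gradient with the flipped
# kernels, so the backward pass reuses the fast im2col path instead of a
# scatter-add.
#' @noRd
conv_backward <- function(grad, cache, layer, k, in_dim) {
  dw <- crossprod(cache$m, grad)
  db <- if (!is.null(layer$b)) colSums(grad) else NULL
  cin <- in_dim[3]; cout <- ncol(grad); n <- in_dim[4]
  hw <- in_dim[1] * in_dim[2]
  grad_arr <- array(aperm(array(grad, c(hw, n, cout)), c(1, 3, 2)),
                    c(in_dim[1], in_dim[2], cout, n))
  warr <- array(layer$w, c(k, k, cin, cout))
  wb <- aperm(warr[k:1, k:1, , , drop = FALSE], c(1, 2, 4, 3))
  wback <- matrix(wb, k * k * cout, cin)
  dxm <- conv_forward(grad_arr, list(w = wback, b = NULL), k)$out
  dx <- array(aperm(array(dxm, c(hw, n, cin)), c(1, 3, 2)), in_dim)
  list(dw = dw, db = db, dx = dx)
}

# Batch norm over (H, W, N) per channel; x is (H*W*N) x C.
#' @noRd
bn_forward <- function(x, layer, training, momentum, eps = 1e-5) {
  if (is.null(layer$gamma)) return(list(out = x, layer = layer))
  if (training) {
    mu <- colMeans(x)
    xc <- x - rep(mu, each = nrow(x))
    va <- colMeans(xc^2)
    layer$run_mean <- (1 - momentum) * layer$run_mean + momentum * mu
    layer$run_var <- (1 - momentum) * layer$run_var + momentum * va
  } else {
    mu <- layer$run_mean; va <- layer$run_var
    xc <- x - rep(mu, each = nrow(x))
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * rep(inv, each = nrow(x))
  out <- xhat * rep(layer$gamma, each = nrow(x)) +
    rep(layer$beta, each = nrow(x))
  list(out = out, layer = layer, xhat = xhat, inv = inv)
}

#' @noRd
bn_backward <- function(grad, cache, layer) {
  if (is.null(layer$gamma)) return(list(dx = grad))
  n <- nrow(grad)
  dgamma <- colSums(grad * cache$xhat)
  dbeta <- colSums(grad)
  t1 <- grad * n
  t2 <- rep(dbeta, each = n)
  t3 <- cache$xhat * rep(dgamma, each = n)
  dx <- rep(layer$gamma * cache$inv / n, each = n) * (t1 - t2 - t3)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# quadrant gather indices for 2x2 max pooling of an (H, W, C, N) array
#' @noRd
pool_index <- function(h, w, cc, n) {
  hh <- h %/% 2L; ww <- w %/% 2L
  lapply(list(c(0, 0), c(1, 0), c(0, 1), c(1, 1)), function(d) {
    rep(2 * seq_len(hh) - 1 + d[1], times = ww * cc * n) +
      rep(rep((2 * seq_len(ww) - 2 + d[2]) * h, each = hh),
          times = cc * n) +
      rep(rep((seq_len(cc) - 1) * h * w, each = hh * ww), times = n) +
      rep((seq_len(n) - 1) * h * w * cc, each = hh * ww * cc)
  })
}

#' @noRd
maxpool_forward <- function(x) {
  d <- dim(x)
  qi <- pool_index(d[1], d[2], d[3], d[4])
  m4 <- cbind(x[qi[[1]]], x[qi[[2]]], x[qi[[3]]], x[qi[[4]]])
  arg <- max.col(m4, ties.method = "first")
  out <- array(m4[cbind(seq_len(nrow(m4)), arg)],
               c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4]))
  list(out = out, arg = arg, qi = qi, in_dim = d)
}

#' @noRd
maxpool_backward <- function(grad, cache) {
  dx <- array(0, cache$in_dim)
  g <- as.vector(grad)
  for (k in 1:4) {
    sel <- cache$arg == k
    dx[cache$qi[[k]][sel]] <- dx[cache$qi[[k]][sel]] + g[sel]
  }
  dx
}

# full forward pass; x is (H, W, N).  Returns logits and, when
# `training`, every cache needed for backprop.
#' @noRd
cnn_forward <- function(model, x, training = FALSE, drop_masks = NULL) {
  spec <- model$spec
  d <- dim(x)
  n <- d[3]
  a <- array(x, c(d[1], d[2], 1L, n))
  caches <- vector("list", 3)
  k <- spec$kernel_size
  for (l in 1:3) {
    in_dim <- dim(a)
    cv <- conv_forward(a, model$conv[[l]], k)
    bn <- bn_forward(cv$out, model$conv[[l]], training,
                     model$bn_momentum)
    model$conv[[l]] <- bn$layer
    relu_in <- bn$out
    act <- relu_in * (relu_in > 0)
    cout <- spec$conv_channels[l]
    # matrix (H*W*N) x C -> array (H, W, C, N)
    arr <- array(aperm(array(act, c(in_dim[1] * in_dim[2], n, cout)),
                       c(1, 3, 2)),
                 c(in_dim[1], in_dim[2], cout, n))
    pl <- maxpool_forward(arr)
    a <- pl$out
    dmask <- NULL
    if (training && spec$dropout_rate > 0) {
      dmask <- if (!is.null(drop_masks)) drop_masks[[l]] else
        array(runif(length(a)) >= spec$dropout_rate, dim(a))
      a <- a * dmask / (1 - spec$dropout_rate)
    }
    caches[[l]] <- list(conv = cv, bn = bn, relu_in = relu_in, pool = pl,
                        in_dim = in_dim, dmask = dmask)
  }
  flat_dim <- prod(dim(a)[1:3])
  xf <- t(matrix(a, flat_dim, n))
  hpre <- xf %*% model$dense$wh
  if (!is.null(model$dense$bh))
    hpre <- hpre + rep(model$dense$bh, each = n)
  # tanh, not ReLU: the flattened features are non-negative, so a
  # narrow ReLU bottleneck can initialize dead with an exactly-zero
  # gradient; tanh always propagates
  h <- tanh(hpre)
  z <- h %*% model$dense$wo
  if (!is.null(model$dense$bo)) z <- z + model$dense$bo
  list(z = as.vector(z), model = model, caches = caches, xf = xf,
       hpre = hpre, h = h, pooled_dim = dim(a))
}

# backward pass from dL/dz; returns gradient list mirroring the params
#' @noRd
cnn_backward <- function(model, fw, dz) {
  spec <- model$spec
  n <- length(dz)
  g <- list(conv = vector("list", 3), dense = list())
  dz <- matrix(dz, n, 1)
  g$dense$wo <- crossprod(fw$h, dz)
  if (!is.null(model$dense$bo)) g$dense$bo <- sum(dz)
  dh <- dz %*% t(model$dense$wo)
  dhpre <- dh * (1 - fw$h^2)
  g$dense$wh <- crossprod(fw$xf, dhpre)
  if (!is.null(model$dense$bh)) g$dense$bh <- colSums(dhpre)
  dxf <- dhpre %*% t(model$dense$wh)
  da <- array(t(dxf), c(fw$pooled_dim[1:3], n))
  k <- spec$kernel_size
  for (l in 3:1) {
    cc <- fw$caches[[l]]
    if (!is.null(cc$dmask))
      da <- da * cc$dmask / (1 - spec$dropout_rate)
    darr <- maxpool_backward(da, cc$pool)
    dd <- dim(darr)
    # array (H, W, C, N) -> matrix (H*W*N) x C
    dact <- matrix(aperm(array(darr, c(dd[1] * dd[2], dd[3], dd[4])),
                         c(1, 3, 2)), dd[1] * dd[2] * dd[4], dd[3])
    drelu <- dact * (cc$relu_in > 0)
    bnb <- bn_backward(drelu, cc$bn, model$conv[[l]])
    g$conv[[l]] <- list(dgamma = bnb$dgamma, dbeta = bnb$dbeta)
    cvb <- conv_backward(bnb$dx, cc$conv, model$conv[[l]], k, cc$in_dim)
    g$conv[[l]]$dw <- cvb$dw
    g$conv[[l]]$db <- cvb$db
    da <- array(cvb$dx, cc$in_dim)
  }
  g
}

#' Training configuration for the CNN
#'
#' @param epochs passes over the training set.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param optimizer only `"adam"` is implemented.
#' @param loss only `"bce"` (binary cross-entropy) is implemented.
#' @param rng_seed seed making shuffling, dropout and every weight update
#'   reproducible.
#' @param validation_fraction fraction of the training set held out for
#'   a per-epoch validation loss (0 = none).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 32L,
                         learning_rate = 1e-3, optimizer = "adam",
                         loss = "bce", rng_seed = 1L,
                         validation_fraction = 0) {
  stopifnot(epochs >= 0, batch_size >= 1,
            learning_rate > 0, identical(optimizer, "adam"),
            identical(loss, "bce"),
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 loss = loss, rng_seed = as.integer(rng_seed),
                 validation_fraction = validation_fraction),
            class = "train_config")
}

# flatten model params / grads into one numeric vector (fixed order);
# exact [[ ]] indexing everywhere -- a deleted NULL field must not
# partial-match another parameter name
#' @noRd
cnn_param_vec <- function(model) {
  unlist(c(lapply(model$conv, function(l)
    list(l[["w"]], l[["b"]], l[["gamma"]], l[["beta"]])),
    list(model$dense[["wh"]], model$dense[["bh"]],
         model$dense[["wo"]], model$dense[["bo"]])),
    use.names = FALSE)
}

#' @noRd
cnn_grad_vec <- function(model, g) {
  unlist(c(lapply(1:3, function(l)
    list(g$conv[[l]]$dw,
         if (!is.null(model$conv[[l]]$b)) g$conv[[l]]$db,
         if (!is.null(model$conv[[l]]$gamma)) g$conv[[l]]$dgamma,
         if (!is.null(model$conv[[l]]$beta)) g$conv[[l]]$dbeta)),
    list(g$dense$wh,
         if (!is.null(model$dense$bh)) g$dense$bh,
         g$dense$wo,
         if (!is.null(model$dense$bo)) g$dense$bo)),
    use.names = FALSE)
}

#' @noRd
cnn_set_params <- function(model, v) {
  pos <- 0L
  take <- function(x) {
    out <- v[pos + seq_along(x)]
    pos <<- pos + length(x)
    if (is.matrix(x)) matrix(out, nrow(x), ncol(x)) else out
  }
  for (l in 1:3) {
    for (nm in c("w", "b", "gamma", "beta"))
      if (!is.null(model$conv[[l]][[nm]]))
        model$conv[[l]][[nm]] <- take(model$conv[[l]][[nm]])
  }
  for (nm in c("wh", "bh", "wo", "bo"))
    if (!is.null(model$dense[[nm]]))
      model$dense[[nm]] <- take(model$dense[[nm]])
  model
}

#' Train the CNN on labelled feature images
#'
#' Minimizes binary cross-entropy with Adam.  Dropout is active and
#' batch statistics are used for normalization during training; running
#' statistics are accumulated for inference.  Fully reproducible from
#' `config$rng_seed`; zero epochs return the model unchanged with an
#' empty history.
#'
#' @param model a `cnn_model` from [build_cnn()].
#' @param images a [pattern_stack()] of feature images (or an
#'   `H x W x n` array) matching the spec input size.
#' @param labels 0/1 vector of length n (1 = single hit).
#' @param config a [train_config()].
#' @return the trained model, with a `history` data.frame
#'   (`epoch`, `loss`, `accuracy`) attached.
#' @export
train_cnn <- function(model, images, labels, config = train_config()) {
  stopifnot(inherits(model, "cnn_model"))
  x <- if (inherits(images, "pattern_stack")) images$values else images
  stopifnot(length(dim(x)) == 3,
            all(dim(x)[1:2] == model$spec$input_size))
  y <- as.integer(labels)
  n <- dim(x)[3]
  stopifnot(length(y) == n, all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2) stop("training set must contain both classes")
  if (min(table(y)) < 2) stop("need at least 2 examples per class")
  if (config$epochs == 0L) {
    model$history <- data.frame(epoch = integer(), loss = numeric(),
                                accuracy = numeric())
    return(model)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$rng_seed)

  mt <- vt <- numeric(length(cnn_param_vec(model)))
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8; step <- 0L
  hist_loss <- hist_acc <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (b0 in seq(1, n, by = config$batch_size)) {
      bi <- ord[b0:min(b0 + config$batch_size - 1, n)]
      xb <- x[, , bi, drop = FALSE]
      yb <- y[bi]
      fw <- cnn_forward(model, xb, training = TRUE)
      model <- fw$model   # running BN stats updated
      z <- fw$z
      # stable BCE with logits
      loss <- mean(pmax(z, 0) - z * yb + log1p(exp(-abs(z))))
      p <- 1 / (1 + exp(-z))
      dz <- (p - yb) / length(yb)
      g <- cnn_backward(model, fw, dz)
      gv <- cnn_grad_vec(model, g)
      step <- step + 1L
      mt <- beta1 * mt + (1 - beta1) * gv
      vt <- beta2 * vt + (1 - beta2) * gv^2
      mhat <- mt / (1 - beta1^step)
      vhat <- vt / (1 - beta2^step)
      pv <- cnn_param_vec(model) -
        config$learning_rate * mhat / (sqrt(vhat) + adam_eps)
      model <- cnn_set_params(model, pv)
      ep_loss <- ep_loss + loss * length(yb)
      ep_correct <- ep_correct + sum((p > 0.5) == (yb == 1))
    }
    hist_loss[ep] <- ep_loss / n
    hist_acc[ep] <- ep_correct / n
  }
  model$trained <- TRUE
  model$history <- data.frame(epoch = seq_len(config$epochs),
                              loss = hist_loss, accuracy = hist_acc)
  model
}

#' Score patterns with a trained CNN
#'
#' Inference mode: dropout off, batch norm using the stored running
#' statistics, hence deterministic.
#'
#' @param model a trained `cnn_model`.
#' @param images a [pattern_stack()] or `H x W x n` array.
#' @param theta score threshold for class 1 (strict inequality).
#' @return A [label_set()] with sigmoid scores in `[0, 1]`.
#' @export
predict_cnn <- function(model, images, theta = 0.5) {
  stopifnot(inherits(model, "cnn_model"))
  ids <- NULL
  x <- if (inherits(images, "pattern_stack")) {
    ids <- images$ids
    images$values
  } else images
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (!all(dim(x)[1:2] == model$spec$input_size))
    stop("image size ", paste(dim(x)[1:2], collapse = "x"),
         " does not match the model input ",
         paste(model$spec$input_size, collapse = "x"))
  if (is.null(ids)) ids <- sprintf("pat%06d", seq_len(dim(x)[3]))
  # score in chunks to bound memory
  n <- dim(x)[3]
  score <- numeric(n)
  for (b0 in seq(1, n, by = 64L)) {
    bi <- b0:min(b0 + 63L, n)
    z <- cnn_forward(model, x[, , bi, drop = FALSE], training = FALSE)$z
    score[bi] <- 1 / (1 + exp(-z))
  }
  label_set(ids, score, theta)
}
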