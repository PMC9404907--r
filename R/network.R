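# The U-shaped fully convolutional correspondence network. Forward and
# backward passes are written out explicitly (no autodiff framework): conv /
# transposed-conv / max-pool kernels live in src/layers.cpp, batch
# normalization and ReLU here. Tensors are [H, W, C, N] arrays throughout.

#' Network architecture configuration
#'
#' @param input_size Side length of the square input raster; must be
#'   divisible by `2^depth` so the pooling halvings are exact. Default 512,
#'   the full-scale working resolution.
#' @param depth Number of downsampling blocks (default 2).
#' @param base_filters Number of filters in the first convolution block;
#'   doubles at every downsampling level. Default 16 at full scale.
#' @param kernel_size Convolution kernel side (odd; default 3).
#' @return A `net_config` object.
#' @export
net_config <- function(input_size = 512, depth = 2, base_filters = 16,
                       kernel_size = 3) {
  if (depth < 1 || depth != round(depth)) stop_config("depth must be >= 1")
  if (base_filters < 1) stop_config("base_filters must be >= 1")
  if (kernel_size %% 2 != 1) stop_config("kernel_size must be odd")
  if (input_size < 2^depth || input_size %% 2^depth != 0)
    stop_config(sprintf("input_size must be divisible by 2^depth = %d", 2^depth))
  structure(list(input_size = as.integer(input_size), depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 kernel_size = as.integer(kernel_size)),
            class = "net_config")
}

ch_at <- function(cfg, d) cfg$base_filters * 2^d

he_init <- function(k1, k2, cin, cout) {
  array(rnorm(k1 * k2 * cin * cout, sd = sqrt(2 / (k1 * k2 * cin))),
        dim = c(k1, k2, cin, cout))
}

#' Build the correspondence-grid network
#'
#' Architecture: an input block of two convolutions; `depth` downsampling
#' blocks (2x2 max pooling followed by two convolutions, filter count
#' doubling); `depth` upsampling blocks (2x2 stride-2 transposed convolution
#' halving the filters, concatenation with the same-level encoder output,
#' then two convolutions); and a final 1x1 convolution with 2 output channels
#' and no activation. Every convolution except the last carries batch
#' normalization and ReLU. The final layer is zero-initialized so a fresh
#' model outputs the zero displacement field — i.e. starts at the identity
#' transform, a stable starting point for similarity-driven training.
#'
#' @param config A [net_config()].
#' @param seed Integer seed; two builds with the same seed have identical
#'   weights.
#' @return A `registration_model`: list with `config`, `params` (named list
#'   of arrays), `bn_state` (per-layer running mean/variance), and
#'   `training_curve`.
#' @export
build_model <- function(config, seed = 1L) {
  if (!inherits(config, "net_config")) config <- do.call(net_config, config)
  cfg <- config
  with_seed(seed, {
    params <- list()
    bn_state <- list()
    add_cbr <- function(name, cin, cout, k = cfg$kernel_size) {
      params[[paste0(name, "_W")]] <<- he_init(k, k, cin, cout)
      params[[paste0(name, "_b")]] <<- numeric(cout)
      params[[paste0(name, "_g")]] <<- rep(1, cout)
      params[[paste0(name, "_be")]] <<- numeric(cout)
      bn_state[[name]] <<- list(mean = numeric(cout), var = rep(1, cout))
    }
    add_cbr("enc0_c1", 2L, ch_at(cfg, 0))
    add_cbr("enc0_c2", ch_at(cfg, 0), ch_at(cfg, 0))
    for (d in seq_len(cfg$depth)) {
      add_cbr(sprintf("enc%d_c1", d), ch_at(cfg, d - 1), ch_at(cfg, d))
      add_cbr(sprintf("enc%d_c2", d), ch_at(cfg, d), ch_at(cfg, d))
    }
    for (d in rev(seq_len(cfg$depth))) {
      params[[sprintf("dec%d_t_W", d)]] <-
        array(rnorm(4 * ch_at(cfg, d) * ch_at(cfg, d - 1),
                    sd = sqrt(2 / (4 * ch_at(cfg, d)))),
              dim = c(2, 2, ch_at(cfg, d), ch_at(cfg, d - 1)))
      params[[sprintf("dec%d_t_b", d)]] <- numeric(ch_at(cfg, d - 1))
      params[[sprintf("dec%d_t_g", d)]] <- rep(1, ch_at(cfg, d - 1))
      params[[sprintf("dec%d_t_be", d)]] <- numeric(ch_at(cfg, d - 1))
      bn_state[[sprintf("dec%d_t", d)]] <-
        list(mean = numeric(ch_at(cfg, d - 1)), var = rep(1, ch_at(cfg, d - 1)))
      add_cbr(sprintf("dec%d_c1", d), 2 * ch_at(cfg, d - 1), ch_at(cfg, d - 1))
      add_cbr(sprintf("dec%d_c2", d), ch_at(cfg, d - 1), ch_at(cfg, d - 1))
    }
    # zero-initialized head: fresh model predicts the identity transform
    params[["final_W"]] <- array(0, dim = c(1, 1, ch_at(cfg, 0), 2L))
    params[["final_b"]] <- numeric(2L)
    structure(list(config = cfg, params = params, bn_state = bn_state,
                   training_curve = numeric(0)),
              class = "registration_model")
  })
}

#' @export
print.registration_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<registration_model> input %dx%d, depth %d, base filters %d, %d parameters%s\n",
    cfg$input_size, cfg$input_size, cfg$depth, cfg$base_filters,
    count_parameters(cfg),
    if (length(x$training_curve))
      sprintf(" | trained %d epochs (final NCC %.4f)",
              length(x$training_curve),
              x$training_curve[length(x$training_curve)])
    else " | untrained"
  ))
  invisible(x)
}

#' Number of trainable parameters
#'
#' Closed form, with `k` the kernel side and `f_d = base_filters * 2^d`:
#' each conv block at `cin -> cout` contributes `k^2*cin*cout + cout` conv
#' parameters plus `2*cout` batch-norm parameters; each transposed conv at
#' `cin -> cout` contributes `4*cin*cout + cout + 2*cout`; the 1x1 head
#' contributes `f_0*2 + 2`.
#'
#' @param config A [net_config()] (or a `registration_model`).
#' @return Integer parameter count.
#' @export
count_parameters <- function(config) {
  if (inherits(config, "registration_model")) config <- config$config
  cfg <- config
  k <- cfg$kernel_size
  cbr <- function(cin, cout) k^2 * cin * cout + cout + 2 * cout
  total <- cbr(2, ch_at(cfg, 0)) + cbr(ch_at(cfg, 0), ch_at(cfg, 0))
  for (d in seq_len(cfg$depth))
    total <- total + cbr(ch_at(cfg, d - 1), ch_at(cfg, d)) +
      cbr(ch_at(cfg, d), ch_at(cfg, d))
  for (d in seq_len(cfg$depth)) {
    total <- total + 4 * ch_at(cfg, d) * ch_at(cfg, d - 1) +
      3 * ch_at(cfg, d - 1)                      # tconv + its BN
    total <- total + cbr(2 * ch_at(cfg, d - 1), ch_at(cfg, d - 1)) +
      cbr(ch_at(cfg, d - 1), ch_at(cfg, d - 1))
  }
  as.integer(total + ch_at(cfg, 0) * 2 + 2)
}

# ---- batch normalization ----------------------------------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# Per-channel statistics over (H, W, N). Training mode uses batch statistics
# (population variance) and updates the running averages; inference mode uses
# the running averages.
bn_fwd <- function(z, gamma, beta, state, training) {
  d <- dim(z)
  C <- d[3]
  zp <- aperm(z, c(1, 2, 4, 3))
  dim(zp) <- c(d[1] * d[2] * d[4], C)
  if (training) {
    mu <- colMeans(zp)
    va <- colMeans(zp^2) - mu^2
    va <- pmax(va, 0)
    state$mean <- BN_MOMENTUM * state$mean + (1 - BN_MOMENTUM) * mu
    state$var <- BN_MOMENTUM * state$var + (1 - BN_MOMENTUM) * va
  } else {
    mu <- state$mean
    va <- state$var
  }
  inv_std <- 1 / sqrt(va + BN_EPS)
  n <- nrow(zp)
  xhat <- (zp - matrix(mu, n, C, byrow = TRUE)) *
    matrix(inv_std, n, C, byrow = TRUE)
  yp <- xhat * matrix(gamma, n, C, byrow = TRUE) +
    matrix(beta, n, C, byrow = TRUE)
  y <- yp
  dim(y) <- c(d[1], d[2], d[4], C)
  y <- aperm(y, c(1, 2, 4, 3))
  list(y = y, state = state,
       cache = list(xhat = xhat, inv_std = inv_std, dims = d))
}

bn_bwd <- function(dy, gamma, cache) {
  d <- cache$dims
  C <- d[3]
  dyp <- aperm(dy, c(1, 2, 4, 3))
  dim(dyp) <- c(d[1] * d[2] * d[4], C)
  n <- nrow(dyp)
  xhat <- cache$xhat
  dgamma <- colSums(dyp * xhat)
  dbeta <- colSums(dyp)
  dxhat <- dyp * matrix(gamma, n, C, byrow = TRUE)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dxp <- (dxhat - matrix(s1 / n, n, C, byrow = TRUE) -
            xhat * matrix(s2 / n, n, C, byrow = TRUE)) *
    matrix(cache$inv_std, n, C, byrow = TRUE)
  dx <- dxp
  dim(dx) <- c(d[1], d[2], d[4], C)
  dx <- aperm(dx, c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- conv / tconv blocks (conv -> BN -> ReLU) -------------------------------

cbr_fwd <- function(params, st, name, x, training, transposed = FALSE) {
  W <- params[[paste0(name, "_W")]]
  b <- params[[paste0(name, "_b")]]
  z <- if (transposed) cpp_tconv2_fwd(x, W, b) else cpp_conv2d_fwd(x, W, b)
  bn <- bn_fwd(z, params[[paste0(name, "_g")]], params[[paste0(name, "_be")]],
               st[[name]], training)
  a <- bn$y
  mask <- a > 0
  a[!mask] <- 0
  list(a = a, state = bn$state,
       cache = list(x = x, bnc = bn$cache, mask = mask))
}

cbr_bwd <- function(params, grads, name, cache, da, transposed = FALSE) {
  da[!cache$mask] <- 0
  bb <- bn_bwd(da, params[[paste0(name, "_g")]], cache$bnc)
  grads[[paste0(name, "_g")]] <- bb$dgamma
  grads[[paste0(name, "_be")]] <- bb$dbeta
  W <- params[[paste0(name, "_W")]]
  cb <- if (transposed) cpp_tconv2_bwd(cache$x, W, bb$dx)
        else cpp_conv2d_bwd(cache$x, W, bb$dx)
  grads[[paste0(name, "_W")]] <- cb$dw
  grads[[paste0(name, "_b")]] <- cb$db
  list(grads = grads, dx = cb$dx)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# ---- full network forward / backward ---------------------------------------

# x: [H, W, 2, N]. Returns the displacement output [H, W, 2, N], the updated
# BN state, and (optionally) the caches needed by net_backward().
net_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  st <- model$bn_state
  caches <- list()
  skips <- list()
  h <- x
  for (d in 0:cfg$depth) {
    if (d > 0) {
      mp <- cpp_maxpool2_fwd(h)
      caches[[sprintf("pool%d", d)]] <- list(argmax = mp$argmax, xdim = dim(h))
      h <- mp$y
    }
    for (ci in 1:2) {
      nm <- sprintf("enc%d_c%d", d, ci)
      r <- cbr_fwd(p, st, nm, h, training)
      st[[nm]] <- r$state
      if (keep_cache) caches[[nm]] <- r$cache
      h <- r$a
    }
    if (d < cfg$depth) skips[[d + 1]] <- h
  }
  for (d in rev(seq_len(cfg$depth))) {
    nm <- sprintf("dec%d_t", d)
    r <- cbr_fwd(p, st, nm, h, training, transposed = TRUE)
    st[[nm]] <- r$state
    if (keep_cache) caches[[nm]] <- r$cache
    h <- concat_ch(r$a, skips[[d]])
    for (ci in 1:2) {
      nm <- sprintf("dec%d_c%d", d, ci)
      r <- cbr_fwd(p, st, nm, h, training)
      st[[nm]] <- r$state
      if (keep_cache) caches[[nm]] <- r$cache
      h <- r$a
    }
  }
  if (keep_cache) caches[["final_x"]] <- h
  out <- cpp_conv2d_fwd(h, p$final_W, p$final_b)
  list(out = out, bn_state = st, caches = if (keep_cache) caches else NULL)
}

# dout: gradient w.r.t. the displacement output. Returns a named list of
# parameter gradients plus the gradient w.r.t. the network input.
net_backward <- function(model, caches, dout) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  fb <- cpp_conv2d_bwd(caches$final_x, p$final_W, dout)
  grads$final_W <- fb$dw
  grads$final_b <- fb$db
  dh <- fb$dx
  dskips <- list()
  for (d in seq_len(cfg$depth)) {
    for (ci in 2:1) {
      nm <- sprintf("dec%d_c%d", d, ci)
      r <- cbr_bwd(p, grads, nm, caches[[nm]], dh)
      grads <- r$grads
      dh <- r$dx
    }
    cskip <- ch_at(cfg, d - 1)
    dskips[[d]] <- dh[, , cskip + seq_len(cskip), , drop = FALSE]
    dup <- dh[, , seq_len(cskip), , drop = FALSE]
    nm <- sprintf("dec%d_t", d)
    r <- cbr_bwd(p, grads, nm, caches[[nm]], dup, transposed = TRUE)
    grads <- r$grads
    dh <- r$dx
  }
  for (d in cfg$depth:0) {
    if (d < cfg$depth) dh <- dh + dskips[[d + 1]]
    for (ci in 2:1) {
      nm <- sprintf("enc%d_c%d", d, ci)
      r <- cbr_bwd(p, grads, nm, caches[[nm]], dh)
      grads <- r$grads
      dh <- r$dx
    }
    if (d > 0) {
      pc <- caches[[sprintf("pool%d", d)]]
      dh <- cpp_maxpool2_bwd(dh, pc$argmax, pc$xdim)
    }
  }
  list(grads = grads, dx = dh)
}

#' Predict the correspondence (displacement) grid for an image pair
#'
#' Stacks the reference and moving vessel maps as a 2-channel input and runs
#' one forward pass in inference mode (batch normalization uses its running
#' averages). The result is a dense per-pixel displacement field in pixel
#' units, `(delta row, delta col)`, to be added to the identity grid to form
#' the sampling grid that moves each pixel of the moving map.
#'
#' @param model A `registration_model`.
#' @param b_ref,b_mov Reference and moving [vessel_map()]s (or matrices) at
#'   the model's `input_size`.
#' @return An `H x W x 2` displacement array.
#' @export
forward_grid <- function(model, b_ref, b_mov) {
  sz <- model$config$input_size
  ref <- soft_of(b_ref)
  mov <- soft_of(b_mov)
  if (!all(dim(ref) == c(sz, sz)) || !all(dim(mov) == c(sz, sz)))
    stop_shape(sprintf("vessel maps must be %d x %d for this model", sz, sz))
  x <- array(c(ref, mov), c(sz, sz, 2, 1))
  out <- net_forward(model, x, training = FALSE)$out
  array(out[, , , 1], c(sz, sz, 2))
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the architecture configuration, all
#' weight tensors, batch-normalization running statistics and the training
#' curve; the round-trip is bit-exact.
#'
#' @param model A `registration_model`.
#' @param path Checkpoint file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "registration_model"))
    stop_value("expected a registration_model")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  m <- readRDS(path)
  if (!inherits(m, "registration_model"))
    stop_format("file does not contain a registration_model")
  m
}
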