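#' Training configuration
#'
#' Defaults follow the full-scale protocol: batches of eight image pairs for
#' 5000 epochs, optimized with ADAM. The learning rate defaults to 1e-4 —
#' displacement-field outputs are sensitive to step size, and the common
#' 1e-3 default is prone to oscillation here; it remains configurable.
#'
#' @param epochs Number of passes over the dataset (default 5000).
#' @param batch_size Pairs per gradient step (default 8).
#' @param learning_rate ADAM step size (default 1e-4).
#' @param beta1,beta2 ADAM moment decay rates (defaults 0.9, 0.999).
#' @param seed Integer seed controlling shuffling (and hence the whole run).
#' @param checkpoint_every Save a checkpoint every this many epochs (0 = off).
#' @param checkpoint_path Path for periodic checkpoints.
#' @param smoothness_weight Optional penalty on squared forward differences
#'   of the displacement field. Off (0) by default: the reference protocol
#'   uses no regularization term, and field smoothness is left to the
#'   network's inductive bias. Provided as a clearly-marked extension.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 5000, batch_size = 8, learning_rate = 1e-4,
                         beta1 = 0.9, beta2 = 0.999, seed = 1L,
                         checkpoint_every = 0, checkpoint_path = NULL,
                         smoothness_weight = 0) {
  if (epochs < 1) stop_config("epochs must be >= 1")
  if (batch_size < 1) stop_config("batch_size must be >= 1")
  if (learning_rate < 0) stop_config("learning_rate must be >= 0")
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1)
    stop_config("beta parameters must lie in [0, 1)")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 checkpoint_path = checkpoint_path,
                 smoothness_weight = smoothness_weight),
            class = "train_config")
}

# Squared-forward-difference smoothness penalty on one displacement field
# and its gradient (used only when smoothness_weight > 0).
smoothness_penalty <- function(disp) {
  H <- dim(disp)[1]; W <- dim(disp)[2]
  val <- 0
  grad <- array(0, dim(disp))
  for (k in 1:2) {
    d <- disp[, , k]
    dr <- d[-1, , drop = FALSE] - d[-H, , drop = FALSE]
    dc <- d[, -1, drop = FALSE] - d[, -W, drop = FALSE]
    val <- val + (sum(dr^2) + sum(dc^2)) / (H * W)
    g <- matrix(0, H, W)
    g[-H, ] <- g[-H, ] - 2 * dr
    g[-1, ] <- g[-1, ] + 2 * dr
    g[, -W] <- g[, -W] - 2 * dc
    g[, -1] <- g[, -1] + 2 * dc
    grad[, , k] <- g / (H * W)
  }
  list(value = val, grad = grad)
}

#' Train the registration networks (unsupervised)
#'
#' Each epoch the pair list is shuffled (seeded) and processed in batches:
#' forward pass of the correspondence network, bilinear warping of each
#' moving map along its predicted grid, negated-NCC loss against the
#' reference map, full backpropagation through sampler and network, and an
#' ADAM update. No labels, landmarks or ground-truth deformations are used —
#' the similarity between warped and reference vessel maps is the only
#' training signal. The mean NCC (fitness) per epoch is recorded as the
#' learning curve. Runs are deterministic given the seed.
#'
#' @param model A `registration_model` from [build_model()].
#' @param pairs Non-empty list of `list(ref = , mov = )` [vessel_map()]s (or
#'   matrices) at the model's input size.
#' @param config A [train_config()].
#' @param verbose Print the fitness every 50 epochs.
#' @return The trained `registration_model`; the per-epoch mean NCC is in
#'   `$training_curve`.
#' @export
train_model <- function(model, pairs, config = train_config(),
                        verbose = FALSE) {
  if (!inherits(model, "registration_model"))
    stop_value("model must be a registration_model")
  if (!inherits(config, "train_config")) config <- do.call(train_config, config)
  n <- length(pairs)
  if (n == 0) stop_config("training dataset is empty")
  sz <- model$config$input_size
  refs <- lapply(pairs, function(p) soft_of(p$ref))
  movs <- lapply(pairs, function(p) soft_of(p$mov))
  ok <- vapply(seq_len(n), function(i)
    all(dim(refs[[i]]) == c(sz, sz)) && all(dim(movs[[i]]) == c(sz, sz)),
    logical(1))
  if (!all(ok)) stop_shape("all pairs must match the model input size")

  params <- model$params
  m1 <- lapply(params, function(p) p * 0)
  m2 <- lapply(params, function(p) p * 0)
  tstep <- 0
  idg <- identity_grid(sz, sz)
  curve <- numeric(config$epochs)

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      epoch_fit <- 0
      b0 <- 1
      while (b0 <= n) {
        idx <- perm[b0:min(b0 + config$batch_size - 1, n)]
        nb <- length(idx)
        x <- array(0, c(sz, sz, 2, nb))
        for (j in seq_len(nb)) {
          x[, , 1, j] <- refs[[idx[j]]]
          x[, , 2, j] <- movs[[idx[j]]]
        }
        model$params <- params
        fw <- net_forward(model, x, training = TRUE, keep_cache = TRUE)
        model$bn_state <- fw$bn_state
        disp <- fw$out
        ddisp <- array(0, dim(disp))
        batch_loss <- 0
        for (j in seq_len(nb)) {
          dj <- array(disp[, , , j], c(sz, sz, 2))
          grid <- idg + dj
          warped <- bilinear_sample(movs[[idx[j]]], grid)
          ng <- ncc_grad(warped, refs[[idx[j]]])
          batch_loss <- batch_loss - ng$value / nb
          epoch_fit <- epoch_fit + ng$value
          bwp <- bilinear_warp_backward(movs[[idx[j]]], grid,
                                        -ng$grad / nb)
          dd <- bwp$d_coords
          if (config$smoothness_weight > 0) {
            sp <- smoothness_penalty(dj)
            batch_loss <- batch_loss + config$smoothness_weight * sp$value / nb
            dd <- dd + config$smoothness_weight * sp$grad / nb
          }
          ddisp[, , , j] <- dd
        }
        if (!is.finite(batch_loss))
          stop_fr("fundusreg_divergence_error",
                  sprintf("non-finite loss at epoch %d", epoch))
        bk <- net_backward(model, fw$caches, ddisp)
        tstep <- tstep + 1
        corr1 <- 1 - config$beta1^tstep
        corr2 <- 1 - config$beta2^tstep
        for (nm in names(params)) {
          g <- bk$grads[[nm]]
          m1[[nm]] <- config$beta1 * m1[[nm]] + (1 - config$beta1) * g
          m2[[nm]] <- config$beta2 * m2[[nm]] + (1 - config$beta2) * g^2
          params[[nm]] <- params[[nm]] - config$learning_rate *
            (m1[[nm]] / corr1) / (sqrt(m2[[nm]] / corr2) + 1e-8)
        }
        b0 <- b0 + config$batch_size
      }
      curve[epoch] <- epoch_fit / n
      if (verbose && epoch %% 50 == 0)
        message(sprintf("epoch %d: mean NCC %.4f", epoch, curve[epoch]))
      if (config$checkpoint_every > 0 && !is.null(config$checkpoint_path) &&
          epoch %% config$checkpoint_every == 0) {
        model$params <- params
        model$training_curve <- c(model$training_curve, curve[seq_len(epoch)])
        save_model(model, config$checkpoint_path)
        model$training_curve <- model$training_curve[
          seq_len(length(model$training_curve) - epoch)]
      }
    }
  })
  model$params <- params
  model$training_curve <- c(model$training_curve, curve)
  model
}

#' One-shot registration of a fundus image pair
#'
#' Inference path of the trained framework: both images are brought to the
#' model's working resolution, reduced to their structure channel, segmented
#' with the IUWT, passed through the correspondence network, and the moving
#' vessel map is bilinearly warped along the predicted grid. No per-pair
#' optimization happens — registration is a single forward pass.
#'
#' @param model A trained `registration_model`.
#' @param i_ref,i_mov Reference and moving images (`fundus_image`, pixel
#'   array, or file path).
#' @param levels_used,threshold_fraction,min_speck Segmentation settings
#'   passed to [segment_vessels()].
#' @return A `registration_result`: list with `b_warp` (warped moving vessel
#'   map), `grid` (the `H x W x 2` displacement field), and the segmented
#'   `b_ref`, `b_mov`.
#' @export
register_pair <- function(model, i_ref, i_mov, levels_used = c(2, 3),
                          threshold_fraction = 0.15, min_speck = NULL) {
  if (!inherits(model, "registration_model"))
    stop_value("model must be a registration_model")
  prep <- function(im) {
    if (is.character(im)) im <- load_fundus(im)
    im <- to_working_resolution(as_fundus(im), model$config$input_size)
    segment_vessels(extract_structure_channel(im),
                    levels_used = levels_used,
                    threshold_fraction = threshold_fraction,
                    min_speck = min_speck)
  }
  b_ref <- prep(i_ref)
  b_mov <- prep(i_mov)
  disp <- forward_grid(model, b_ref, b_mov)
  b_warp <- warp_displacement(b_mov, disp)
  structure(list(b_warp = b_warp, grid = disp, b_ref = b_ref, b_mov = b_mov),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result> %d x %d | NCC(warp, ref) = %.4f | max |u| = %.2f px\n",
    nrow(x$b_warp$soft), ncol(x$b_warp$soft),
    tryCatch(ncc(x$b_warp, x$b_ref), error = function(e) NA_real_),
    max(sqrt(x$grid[, , 1]^2 + x$grid[, , 2]^2))
  ))
  invisible(x)
}
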