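#' Identity sampling grid
#'
#' Absolute sampling coordinates with no displacement: `coords[r, c, ] =
#' (r - 1, c - 1)` in 0-based pixel units, `(row, col)` ordering, origin at
#' the top-left pixel centre. Adding a displacement field (the network output)
#' to this grid yields the sampling grid consumed by [bilinear_warp()].
#'
#' @param H,W Grid dimensions in pixels.
#' @return An `H x W x 2` array of absolute coordinates.
#' @export
identity_grid <- function(H, W) {
  if (H < 1 || W < 1) stop_shape("grid dimensions must be >= 1")
  g <- array(0, c(H, W, 2))
  g[, , 1] <- matrix(seq_len(H) - 1, H, W)
  g[, , 2] <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
  g
}

# Core bilinear sampler on a plain matrix. coords is H' x W' x 2 of absolute
# (row, col) positions; positions outside the image are clamped to the border
# (so every output value is a convex combination of input values).
bilinear_sample <- function(m, coords) {
  H <- nrow(m); W <- ncol(m)
  r <- as.vector(coords[, , 1]); cc <- as.vector(coords[, , 2])
  if (any(!is.finite(r)) || any(!is.finite(cc)))
    stop_value("sampling coordinates must be finite")
  rcl <- pmin(pmax(r, 0), H - 1)
  ccl <- pmin(pmax(cc, 0), W - 1)
  r0 <- if (H > 1) pmin(floor(rcl), H - 2) else rep(0, length(rcl))
  c0 <- if (W > 1) pmin(floor(ccl), W - 2) else rep(0, length(ccl))
  fr <- rcl - r0; fc <- ccl - c0
  i00 <- r0 + 1 + H * c0
  v <- (1 - fr) * (1 - fc) * m[i00] +
    fr * (1 - fc) * m[i00 + 1] +
    (1 - fr) * fc * m[i00 + H] +
    fr * fc * m[i00 + H + 1]
  matrix(v, dim(coords)[1], dim(coords)[2])
}

#' Warp an image along a sampling grid (bilinear)
#'
#' The sampler of the spatial-transformer stage: `out[r, c]` is the bilinear
#' interpolation of `image` at `grid[r, c, ]`. Coordinates outside
#' `[0, H-1] x [0, W-1]` are clamped to the border, so the output range is
#' contained in the input range. The operation is differentiable with respect
#' to both the image values and the grid coordinates (see
#' [bilinear_warp_backward()]), which is what lets the correspondence network
#' train through it.
#'
#' @param image A `vessel_map`, `fundus_image`, or numeric matrix.
#' @param grid `H x W x 2` array of absolute sampling coordinates (see
#'   [identity_grid()]), matching the image size.
#' @param binary_threshold Threshold applied to the resampled binary view of
#'   a `vessel_map` (the mask is interpolated as a real-valued image and
#'   re-binarized; with the identity grid the round trip is exact).
#' @return Same type as `image`; for a `vessel_map` both the soft and the
#'   binary view are warped along the same grid.
#' @export
bilinear_warp <- function(image, grid, binary_threshold = 0.5) {
  if (inherits(image, "fundus_image")) {
    px <- image$pixels
    if (length(dim(px)) == 3) {
      check_grid(grid, dim(px)[1], dim(px)[2])
      out <- array(0, dim(px))
      for (k in seq_len(dim(px)[3])) out[, , k] <- bilinear_sample(px[, , k], grid)
      return(fundus_image(out, source_path = image$source_path))
    }
    check_grid(grid, nrow(px), ncol(px))
    return(fundus_image(bilinear_sample(px, grid)))
  }
  if (inherits(image, "vessel_map")) {
    check_grid(grid, nrow(image$soft), ncol(image$soft))
    soft <- bilinear_sample(image$soft, grid)
    bin <- (bilinear_sample(image$binary, grid) >= binary_threshold) * 1
    return(vessel_map(soft, binary = bin))
  }
  m <- as.matrix(image)
  check_grid(grid, nrow(m), ncol(m))
  bilinear_sample(m, grid)
}

check_grid <- function(grid, H, W) {
  d <- dim(grid)
  if (length(d) != 3 || d[3] != 2 || d[1] != H || d[2] != W)
    stop_shape("grid must be an H x W x 2 array matching the image")
  invisible(TRUE)
}

#' Gradients of the bilinear sampler
#'
#' Backward pass of [bilinear_warp()] for a plain matrix image: given the
#' gradient of some scalar loss with respect to the warped output, returns
#' its gradients with respect to the sampling coordinates and (optionally)
#' the input image. At the border-clamped region the coordinate gradient is
#' zero (the output is constant there); at exact integer coordinates the
#' right-sided derivative of the interpolation kink is used.
#'
#' @param m Numeric matrix that was sampled.
#' @param coords `H' x W' x 2` array of absolute sampling coordinates.
#' @param dout Gradient w.r.t. the sampler output (`H' x W'` matrix).
#' @param want_image Also compute the gradient w.r.t. the image values.
#' @return List with `d_coords` (`H' x W' x 2`) and `d_image` (matrix or
#'   `NULL`).
#' @export
bilinear_warp_backward <- function(m, coords, dout, want_image = FALSE) {
  H <- nrow(m); W <- ncol(m)
  r <- as.vector(coords[, , 1]); cc <- as.vector(coords[, , 2])
  g <- as.vector(dout)
  rcl <- pmin(pmax(r, 0), H - 1)
  ccl <- pmin(pmax(cc, 0), W - 1)
  r0 <- if (H > 1) pmin(floor(rcl), H - 2) else rep(0, length(rcl))
  c0 <- if (W > 1) pmin(floor(ccl), W - 2) else rep(0, length(ccl))
  fr <- rcl - r0; fc <- ccl - c0
  i00 <- r0 + 1 + H * c0
  v00 <- m[i00]; v10 <- m[i00 + 1]; v01 <- m[i00 + H]; v11 <- m[i00 + H + 1]
  in_r <- (r >= 0) & (r <= H - 1)
  in_c <- (cc >= 0) & (cc <= W - 1)
  dvdr <- ((1 - fc) * (v10 - v00) + fc * (v11 - v01)) * in_r
  dvdc <- ((1 - fr) * (v01 - v00) + fr * (v11 - v10)) * in_c
  d_coords <- array(0, dim(coords))
  d_coords[, , 1] <- matrix(g * dvdr, dim(coords)[1], dim(coords)[2])
  d_coords[, , 2] <- matrix(g * dvdc, dim(coords)[1], dim(coords)[2])
  d_image <- NULL
  if (want_image) {
    idx <- c(i00, i00 + 1, i00 + H, i00 + H + 1)
    wts <- c(
      g * (1 - fr) * (1 - fc), g * fr * (1 - fc),
      g * (1 - fr) * fc, g * fr * fc
    )
    acc <- rowsum(wts, idx)
    d_image <- matrix(0, H, W)
    d_image[as.integer(rownames(acc))] <- acc
  }
  list(d_coords = d_coords, d_image = d_image)
}

#' Warp along a displacement field
#'
#' Convenience composition of the grid generator and sampler: the sampling
#' grid is the identity grid plus the per-pixel displacement (in pixels),
#' i.e. `out[r, c] = image[r + disp[r, c, 1], c + disp[r, c, 2]]` with
#' bilinear interpolation.
#'
#' @param image Image or `vessel_map` to resample.
#' @param disp `H x W x 2` displacement field (`(delta row, delta col)` in
#'   pixel units).
#' @inheritParams bilinear_warp
#' @return Warped image of the same type as `image`.
#' @export
warp_displacement <- function(image, disp, binary_threshold = 0.5) {
  d <- dim(disp)
  bilinear_warp(image, identity_grid(d[1], d[2]) + disp,
                binary_threshold = binary_threshold)
}

#' Save / load a displacement or sampling grid
#'
#' Grids are written with R's native serialization, which round-trips
#' bit-exactly, so a stored grid re-applied to the same image reproduces the
#' warp bit for bit.
#'
#' @param grid `H x W x 2` array.
#' @param path File path.
#' @return `save_grid()` returns `path` invisibly; `load_grid()` the array.
#' @export
save_grid <- function(grid, path) {
  saveRDS(grid, path)
  invisible(path)
}

#' @rdname save_grid
#' @export
load_grid <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  readRDS(path)
}
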