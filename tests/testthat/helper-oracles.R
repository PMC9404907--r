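# Independent brute-force oracles used to validate the vectorized / compiled
# implementations, plus shared fixtures. Oracles are deliberately written in
# the most literal way possible (per-pixel loops), not via package internals.

# Direct 2-D correlation with zero padding (for interior-pixel checks).
oracle_conv2d <- function(img, kernel) {
  H <- nrow(img); W <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  rh <- (kh - 1) / 2; rw <- (kw - 1) / 2
  out <- matrix(0, H, W)
  for (r in 1:H) for (cl in 1:W) {
    acc <- 0
    for (i in 1:kh) for (j in 1:kw) {
      rr <- r + i - 1 - rh; cc <- cl + j - 1 - rw
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W)
        acc <- acc + kernel[i, j] * img[rr, cc]
    }
    out[r, cl] <- acc
  }
  out
}

# Per-pixel four-neighbour bilinear interpolation with border clamping.
oracle_bilinear <- function(m, coords) {
  H <- nrow(m); W <- ncol(m)
  Ho <- dim(coords)[1]; Wo <- dim(coords)[2]
  out <- matrix(0, Ho, Wo)
  for (r in 1:Ho) for (cl in 1:Wo) {
    y <- min(max(coords[r, cl, 1], 0), H - 1)
    x <- min(max(coords[r, cl, 2], 0), W - 1)
    y0 <- floor(y); x0 <- floor(x)
    if (y0 > H - 2) y0 <- H - 2
    if (x0 > W - 2) x0 <- W - 2
    if (H == 1) y0 <- 0
    if (W == 1) x0 <- 0
    fy <- y - y0; fx <- x - x0
    out[r, cl] <-
      (1 - fy) * (1 - fx) * m[y0 + 1, x0 + 1] +
      fy * (1 - fx) * m[min(y0 + 2, H), x0 + 1] +
      (1 - fy) * fx * m[y0 + 1, min(x0 + 2, W)] +
      fy * fx * m[min(y0 + 2, H), min(x0 + 2, W)]
  }
  out
}

# Whole-sample symmetric reflection, literal version.
oracle_reflect <- function(i, n) {
  while (i < 0 || i > n - 1) {
    if (i < 0) i <- -i
    if (i > n - 1) i <- 2 * (n - 1) - i
  }
  i
}

# Windowed SSIM by explicit per-pixel window sums with a Gaussian weight.
oracle_ssim_windowed <- function(x, y, window_size = 11, sigma = 1.5,
                                 K1 = 0.01, K2 = 0.03, L = 1) {
  H <- nrow(x); W <- ncol(x)
  rad <- (window_size - 1) / 2
  g1 <- exp(-(-rad:rad)^2 / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  wt <- outer(g1, g1)
  c1 <- (K1 * L)^2; c2 <- (K2 * L)^2
  total <- 0
  for (r in 1:H) for (cl in 1:W) {
    xs <- ys <- matrix(0, window_size, window_size)
    for (i in 1:window_size) for (j in 1:window_size) {
      rr <- oracle_reflect(r - 1 + i - 1 - rad, H) + 1
      cc <- oracle_reflect(cl - 1 + j - 1 - rad, W) + 1
      xs[i, j] <- x[rr, cc]
      ys[i, j] <- y[rr, cc]
    }
    mu1 <- sum(wt * xs); mu2 <- sum(wt * ys)
    v1 <- sum(wt * xs^2) - mu1^2
    v2 <- sum(wt * ys^2) - mu2^2
    cv <- sum(wt * xs * ys) - mu1 * mu2
    total <- total + ((2 * mu1 * mu2 + c1) * (2 * cv + c2)) /
      ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2))
  }
  total / (H * W)
}

# Queue-based flood fill labeling.
oracle_floodfill <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8)
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  nxt <- 0L
  for (cl in 1:W) for (r in 1:H) {
    if (mask[r, cl] == 0 || lab[r, cl] != 0) next
    nxt <- nxt + 1L
    queue <- list(c(r, cl))
    lab[r, cl] <- nxt
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        rr <- p[1] + nb[k, 1]; cc <- p[2] + nb[k, 2]
        if (rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            mask[rr, cc] != 0 && lab[rr, cc] == 0) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# Literal whole-image zero-mean NCC.
oracle_ncc <- function(t_, r_) {
  tc <- t_ - mean(t_); rc <- r_ - mean(r_)
  sum(tc * rc) / sqrt(sum(tc^2) * sum(rc^2))
}

# A small image with one dark ridge of the given width on a bright field.
ridge_image <- function(size = 48, width = 3, value = 0.2, bg = 0.8) {
  m <- matrix(bg, size, size)
  mid <- round(size / 2)
  half <- (width - 1) / 2
  rows <- (mid - floor(half)):(mid + ceiling(half))
  m[rows, ] <- value
  m
}

# Toy mask with connected components of the given sizes (horizontal runs on
# separate rows, so sizes are exact under either adjacency).
mask_with_sizes <- function(sizes, W = max(sizes) + 4, gap = 2) {
  H <- length(sizes) * gap + 2
  m <- matrix(0, H, W)
  for (i in seq_along(sizes)) m[1 + i * gap - gap + 1, 2:(1 + sizes[i])] <- 1
  m
}
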