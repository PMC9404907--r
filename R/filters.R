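# Separable filtering helpers shared by the SSIM window and the synthetic
# deformation/degradation code. Boundaries are symmetric reflection, matching
# the IUWT convention.

# Separable correlation with identical 1-d taps along rows then columns.
sep_filter <- function(m, taps) {
  H <- nrow(m); W <- ncol(m)
  rad <- (length(taps) - 1) / 2
  offs <- seq(-rad, rad)
  out <- matrix(0, H, W)
  rows0 <- seq_len(H) - 1L
  for (t in seq_along(taps))
    out <- out + taps[t] * m[reflect_index(rows0 + offs[t], H) + 1L, , drop = FALSE]
  m2 <- out
  out <- matrix(0, H, W)
  cols0 <- seq_len(W) - 1L
  for (t in seq_along(taps))
    out <- out + taps[t] * m2[, reflect_index(cols0 + offs[t], W) + 1L, drop = FALSE]
  out
}

gaussian_taps <- function(sigma, radius = NULL) {
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma))
  x <- seq(-radius, radius)
  w <- exp(-x^2 / (2 * sigma^2))
  w / sum(w)
}

gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  sep_filter(m, gaussian_taps(sigma))
}
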