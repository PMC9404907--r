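# Isotropic undecimated wavelet transform (a trous algorithm) and the vessel
# segmentation built on it. The IUWT is additive: the input equals the
# residual (coarsest smooth) plus the sum of the detail planes, which is what
# makes selected detail levels usable directly as a vesselness image.

# Whole-sample symmetric reflection of 0-based indices onto [0, n-1];
# period-(2n-2) folding handles offsets of any size.
reflect_index <- function(i, n) {
  if (n == 1) return(rep(0L, length(i)))
  p <- 2L * n - 2L
  r <- ((i %% p) + p) %% p
  ifelse(r > n - 1L, p - r, r)
}

# Separable convolution with the B3-spline taps (1,4,6,4,1)/16 dilated by
# `step`, symmetric-reflection boundaries.
b3_smooth <- function(m, step) {
  taps <- c(1, 4, 6, 4, 1) / 16
  offs <- c(-2L, -1L, 0L, 1L, 2L) * as.integer(step)
  H <- nrow(m); W <- ncol(m)
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

#' Isotropic undecimated wavelet transform
#'
#' Decomposes a grayscale image with the a trous algorithm: at level `j` the
#' previous smooth image is convolved with the separable cubic B3-spline
#' kernel `(1,4,6,4,1)/16` dilated by `2^(j-1)` (symmetric-reflection
#' boundaries), and the detail plane is the difference
#' `smooth_(j-1) - smooth_j`. The transform is undecimated (every plane keeps
#' the input's size) and exactly additive: `residual + sum(details) == input`
#' up to floating-point error. Low levels respond to thin structures (narrow
#' vessels), higher levels to progressively wider ones.
#'
#' @param gray Numeric matrix (finite values).
#' @param levels Number of detail levels `J >= 1`; must not exceed
#'   `log2(min(H, W))`.
#' @return An `iuwt_planes` object: list with `details` (list of `J`
#'   matrices), `residual` (matrix) and `levels`.
#' @export
iuwt_decompose <- function(gray, levels) {
  m <- as.matrix(gray)
  if (any(!is.finite(m))) stop_value("input must be finite")
  if (length(levels) != 1 || levels < 1 || levels != round(levels))
    stop_config("levels must be a positive integer")
  if (levels > log2(min(dim(m))))
    stop_config("levels exceeds log2(min(H, W)) for this image")
  details <- vector("list", levels)
  smooth <- m
  for (j in seq_len(levels)) {
    nxt <- b3_smooth(smooth, 2^(j - 1))
    details[[j]] <- smooth - nxt
    smooth <- nxt
  }
  structure(list(details = details, residual = smooth, levels = levels),
            class = "iuwt_planes")
}

#' @export
print.iuwt_planes <- function(x, ...) {
  cat(sprintf("<iuwt_planes> %d levels, %d x %d\n",
              x$levels, nrow(x$residual), ncol(x$residual)))
  invisible(x)
}

#' Segment vessels and eye structures
#'
#' Vesselness is the negated sum of the selected IUWT detail planes: vessels
#' are dark on the bright fundus, so they carry negative detail coefficients,
#' and negation makes them score high. The soft map is that sum clipped at
#' zero and rescaled to \[0, 1\]; the binary view keeps the top
#' `threshold_fraction` of pixels by value (ties at the cut value are all
#' kept), after which isolated specks below `min_speck` pixels are removed.
#' Because detail planes are differences of smoothings, the segmentation is
#' exactly invariant to adding a constant to the input.
#'
#' @param gray Grayscale image: numeric matrix, `fundus_image` (structure
#'   channel is taken) — values in \[0, 1\].
#' @param levels_used Integer set of detail levels to sum (default `c(2, 3)`:
#'   vessel-scale structures at typical fundus resolutions).
#' @param threshold_fraction Fraction of pixels kept in the binary view
#'   (default 0.15).
#' @param min_speck Minimum connected-component size (8-adjacency) kept in
#'   the binary view; `NULL` scales the default of 10 px at 512 x 512 with
#'   image area.
#' @return A [vessel_map()].
#' @export
segment_vessels <- function(gray, levels_used = c(2, 3),
                            threshold_fraction = 0.15, min_speck = NULL) {
  if (inherits(gray, "fundus_image")) gray <- extract_structure_channel(gray)
  m <- as.matrix(gray)
  if (length(levels_used) == 0) stop_config("levels_used must be non-empty")
  levels_used <- sort(unique(as.integer(levels_used)))
  if (any(levels_used < 1)) stop_config("levels_used must be >= 1")
  if (threshold_fraction <= 0 || threshold_fraction > 1)
    stop_config("threshold_fraction must be in (0, 1]")
  dec <- iuwt_decompose(m, max(levels_used))
  s <- Reduce(`+`, dec$details[levels_used])
  s <- pmax(-s, 0)  # vessels are dark: negate so they score high
  mx <- max(s)
  if (mx == 0) return(vessel_map(s, binary = s))
  soft <- s / mx
  n_keep <- max(1L, round(threshold_fraction * length(soft)))
  cut <- sort(as.vector(soft), decreasing = TRUE)[n_keep]
  binary <- (soft >= cut & soft > 0) * 1
  if (is.null(min_speck))
    min_speck <- max(1L, round(10 * length(soft) / 512^2))
  if (min_speck > 1 && any(binary > 0)) {
    lab <- label_components(binary, connectivity = 8)
    keep <- which(lab$sizes >= min_speck)
    binary <- matrix(as.numeric(lab$labels %in% keep), nrow(m), ncol(m))
  }
  vessel_map(soft, binary = binary)
}
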