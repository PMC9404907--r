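# Registration quality metrics: MSE, SSIM, Dice and gain coefficient. All
# four operate on the vessel maps (the B images), not on the raw intensity
# photographs.

#' Mean squared error
#'
#' `(1 / (H*W)) * sum((b_ref - b_warp)^2)` over all pixels. 0 for identical
#' images; lower is better.
#'
#' @param b_ref,b_warp Equal-sized [vessel_map()]s or numeric matrices.
#' @return Non-negative scalar.
#' @export
mse <- function(b_ref, b_warp) {
  a <- soft_of(b_ref)
  b <- soft_of(b_warp)
  if (!all(dim(a) == dim(b))) stop_shape("images must have equal dimensions")
  mean((a - b)^2)
}

#' SSIM parameters
#'
#' Stabilizers `c1 = (K1*L)^2`, `c2 = (K2*L)^2` with the conventional
#' `K1 = 0.01`, `K2 = 0.03`; the dynamic range is `L = 1` because all images
#' in the package live in \[0, 1\]. The default mode is the standard windowed
#' form (11 x 11 Gaussian window, sigma 1.5, per-pixel statistics averaged
#' over the image); `"global"` evaluates the same formula once from
#' whole-image statistics.
#'
#' @param K1,K2 Stabilizer constants.
#' @param L Dynamic range of the intensities.
#' @param window_size Gaussian window side (odd).
#' @param sigma Gaussian window standard deviation.
#' @param mode `"windowed"` (default) or `"global"`.
#' @return An `ssim_params` object.
#' @export
ssim_params <- function(K1 = 0.01, K2 = 0.03, L = 1, window_size = 11,
                        sigma = 1.5, mode = c("windowed", "global")) {
  mode <- match.arg(mode)
  if (window_size %% 2 != 1) stop_config("window_size must be odd")
  structure(list(c1 = (K1 * L)^2, c2 = (K2 * L)^2, window_size = window_size,
                 sigma = sigma, mode = mode),
            class = "ssim_params")
}

#' Structural similarity index
#'
#' `SSIM = ((2*mu1*mu2 + c1) * (2*cov + c2)) /
#'  ((mu1^2 + mu2^2 + c1) * (var1 + var2 + c2))`, where the means, variances
#' and covariance are local Gaussian-window statistics (windowed mode,
#' averaged over all pixels; symmetric-reflection boundaries) or whole-image
#' statistics (global mode). The score is 1 exactly for identical images.
#' Values below 0 can occur for strongly anti-correlated inputs and are
#' reported as-is — the nominal \[0, 1\] range describes typical, not
#' enforced, bounds.
#'
#' @param b_ref,b_warp Equal-sized [vessel_map()]s or numeric matrices with
#'   intensities in \[0, 1\].
#' @param params An [ssim_params()].
#' @return SSIM scalar (<= 1).
#' @export
ssim <- function(b_ref, b_warp, params = ssim_params()) {
  x <- soft_of(b_ref)
  y <- soft_of(b_warp)
  if (!all(dim(x) == dim(y))) stop_shape("images must have equal dimensions")
  c1 <- params$c1
  c2 <- params$c2
  if (params$mode == "global") {
    mu1 <- mean(x); mu2 <- mean(y)
    v1 <- mean(x^2) - mu1^2
    v2 <- mean(y^2) - mu2^2
    cv <- mean(x * y) - mu1 * mu2
    return(((2 * mu1 * mu2 + c1) * (2 * cv + c2)) /
             ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2)))
  }
  taps <- gaussian_taps(params$sigma, radius = (params$window_size - 1) / 2)
  gf <- function(m) sep_filter(m, taps)
  mu1 <- gf(x); mu2 <- gf(y)
  v1 <- gf(x^2) - mu1^2
  v2 <- gf(y^2) - mu2^2
  cv <- gf(x * y) - mu1 * mu2
  smap <- ((2 * mu1 * mu2 + c1) * (2 * cv + c2)) /
    ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2))
  mean(smap)
}

#' Dice overlap coefficient
#'
#' `2 * |A intersect B| / (|A| + |B|)` on the binary views: 1 means perfect
#' overlap, 0 none. Two empty masks agree perfectly and score 1.
#'
#' @param b_ref,b_warp [vessel_map()]s or binary matrices.
#' @return Dice score in \[0, 1\].
#' @export
dice <- function(b_ref, b_warp) {
  a <- binary_of(b_ref)
  b <- binary_of(b_warp)
  if (!all(dim(a) == dim(b))) stop_shape("masks must have equal dimensions")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Gain coefficient
#'
#' Ratio of the reference overlap after registration to the overlap before
#' it: `|BRef intersect BWarp| / |BRef intersect BMov|` on the binary views.
#' 1 means the transformation left the number of aligned pixels unchanged;
#' values above 1 mean the registration gained alignment.
#'
#' @param b_ref,b_mov,b_warp [vessel_map()]s or binary matrices.
#' @return Non-negative ratio.
#' @export
gain_coefficient <- function(b_ref, b_mov, b_warp) {
  r <- binary_of(b_ref)
  m <- binary_of(b_mov)
  w <- binary_of(b_warp)
  if (!all(dim(r) == dim(m)) || !all(dim(r) == dim(w)))
    stop_shape("masks must have equal dimensions")
  base <- sum(r * m)
  if (base == 0)
    stop_fr("fundusreg_undefined_baseline_error",
            "gain coefficient is undefined: no pre-registration overlap")
  sum(r * w) / base
}

#' Full metric report for one registered pair
#'
#' Computes MSE, SSIM, Dice and gain coefficient with a shared binarization.
#' By default all four are evaluated on the binary views of the maps: the
#' refinement stage acts on the binary vessel structures, and evaluating on
#' the binary views makes its effect visible to every metric (`on = "soft"`
#' evaluates MSE/SSIM on the soft maps instead; Dice and GC are binary by
#' definition).
#'
#' @param b_ref,b_mov,b_warp [vessel_map()]s (or matrices) of equal size.
#' @param params [ssim_params()] for the SSIM term.
#' @param on `"binary"` (default) or `"soft"` view for MSE/SSIM.
#' @return A `metric_report`: list with `mse`, `ssim`, `dice`, `gc`.
#' @export
evaluate_all <- function(b_ref, b_mov, b_warp, params = ssim_params(),
                         on = c("binary", "soft")) {
  on <- match.arg(on)
  pick <- function(x) if (on == "binary") binary_of(x) else soft_of(x)
  structure(list(
    mse = mse(pick(b_ref), pick(b_warp)),
    ssim = ssim(pick(b_ref), pick(b_warp), params),
    dice = dice(b_ref, b_warp),
    gc = gain_coefficient(b_ref, b_mov, b_warp)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> MSE %.5f | SSIM %.4f | Dice %.4f | GC %.4f\n",
              x$mse, x$ssim, x$dice, x$gc))
  invisible(x)
}
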