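#' Normalized cross-correlation
#'
#' Global zero-mean NCC over the full image domain: with
#' `T = warped - mean(warped)` and `R = ref - mean(ref)`,
#' `NCC = sum(T*R) / sqrt(sum(T^2) * sum(R^2))`. This is the cosine of the
#' angle between the two centred intensity vectors, so it lies in \[-1, 1\],
#' equals 1 for a perfect match, and is invariant to any positive affine
#' intensity transform `a*I + b` (`a > 0`) of either argument — which is what
#' makes it a usable similarity objective across exposure differences. The
#' template offset of the sliding-window NCC formulation is fixed at (0, 0)
#' with full-image overlap: training compares whole maps, not patches.
#'
#' @param warped,ref Equal-sized [vessel_map()]s or numeric matrices (soft
#'   views are used).
#' @return NCC value in \[-1, 1\].
#' @export
ncc <- function(warped, ref) {
  t_ <- soft_of(warped)
  r_ <- soft_of(ref)
  if (!all(dim(t_) == dim(r_))) stop_shape("images must have equal dimensions")
  tc <- t_ - mean(t_)
  rc <- r_ - mean(r_)
  st <- sum(tc^2)
  sr <- sum(rc^2)
  if (st == 0 || sr == 0)
    stop_fr("fundusreg_undefined_correlation_error",
            "NCC is undefined for a constant image (zero denominator)")
  sum(tc * rc) / sqrt(st * sr)
}

# Analytic gradient of ncc() w.r.t. the warped image (the reference is
# fixed). Mean-centring needs no explicit projection: the gradient already
# sums to zero.
ncc_grad <- function(warped, ref) {
  tc <- warped - mean(warped)
  rc <- ref - mean(ref)
  st <- sum(tc^2)
  sr <- sum(rc^2)
  a <- sum(tc * rc)
  val <- a / sqrt(st * sr)
  grad <- (rc - (a / st) * tc) / sqrt(st * sr)
  list(value = val, grad = grad)
}

#' Registration training loss
#'
#' The training objective is the negated NCC: the fitness (similarity) is
#' maximized by minimizing this loss, bounded below by -1 at a perfect match.
#'
#' @inheritParams ncc
#' @return Scalar loss in \[-1, 1\].
#' @export
registration_loss <- function(warped, ref) -ncc(warped, ref)
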