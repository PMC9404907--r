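#' Vessel map container
#'
#' A vessel map holds the segmented structural view of a fundus image: a soft
#' map in \[0, 1\] (high where vessels and other salient eye structures are)
#' and a binary view used by the overlap metrics (Dice, gain coefficient) and
#' by connected-component refinement. The soft map is what the registration
#' network consumes and the warper resamples; the binary view is derived from
#' it, either by the top-fraction rule of [segment_vessels()] or by a plain
#' 0.5 threshold.
#'
#' @param soft Numeric matrix with values in \[0, 1\].
#' @param binary Optional 0/1 matrix of the same size; when `NULL` the soft
#'   map is thresholded at `threshold`.
#' @param threshold Scalar threshold used when `binary` is `NULL`.
#' @return An object of class `vessel_map` with elements `soft` and `binary`.
#' @export
vessel_map <- function(soft, binary = NULL, threshold = 0.5) {
  soft <- as.matrix(soft)
  if (!is.numeric(soft) || any(!is.finite(soft)))
    stop_value("soft map must be finite numeric")
  if (min(soft) < -1e-9 || max(soft) > 1 + 1e-9)
    stop_value("soft map values must lie in [0, 1]")
  soft <- pmin(pmax(soft, 0), 1)
  if (is.null(binary)) {
    binary <- (soft >= threshold) * 1
  } else {
    binary <- as.matrix(binary) * 1
    if (!all(dim(binary) == dim(soft)))
      stop_shape("binary view must match the soft map's dimensions")
    if (!all(binary %in% c(0, 1)))
      stop_value("binary view must contain only 0 and 1")
  }
  structure(list(soft = soft, binary = binary), class = "vessel_map")
}

#' @export
print.vessel_map <- function(x, ...) {
  cat(sprintf(
    "<vessel_map> %d x %d | soft in [%.3f, %.3f] | %d foreground px (%.1f%%)\n",
    nrow(x$soft), ncol(x$soft), min(x$soft), max(x$soft),
    sum(x$binary), 100 * mean(x$binary)
  ))
  invisible(x)
}

#' @export
dim.vessel_map <- function(x) dim(x$soft)

# Accept either a vessel_map or a bare matrix where both views coincide.
as_vessel_map <- function(x, threshold = 0.5) {
  if (inherits(x, "vessel_map")) return(x)
  if (is.matrix(x)) return(vessel_map(x, threshold = threshold))
  stop_value("expected a vessel_map or a numeric matrix")
}

soft_of <- function(x) if (inherits(x, "vessel_map")) x$soft else as.matrix(x)

binary_of <- function(x) {
  if (inherits(x, "vessel_map")) return(x$binary)
  m <- as.matrix(x)
  if (all(m %in% c(0, 1))) m * 1 else (m >= 0.5) * 1
}
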