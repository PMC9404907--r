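# Synthetic fixtures: vessel-tree phantoms on a circular fundus background,
# smooth random ground-truth deformations, and acquisition degradations
# (blur, dimming, smooth dark occlusions) in the style of low-quality
# clinical captures. Everything is deterministic per seed.

#' Phantom specification
#'
#' @param size Image side in pixels (>= 32; default 512, the full working
#'   resolution).
#' @param n_trees Number of vessel trees grown from the optic-disc region.
#' @param branch_depth Recursive branching depth of each tree.
#' @param vessel_width Two-element range of vessel stroke widths in pixels at
#'   the tree roots (branches taper).
#' @param seed Integer seed; the phantom is a pure function of the spec.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(size = 512, n_trees = 4, branch_depth = 5,
                         vessel_width = c(3, 8), seed = 1L) {
  if (size < 32) stop_config("size must be >= 32")
  if (n_trees < 1 || branch_depth < 1) stop_config("counts must be >= 1")
  if (length(vessel_width) != 2 || any(vessel_width <= 0))
    stop_config("vessel_width must be a positive (min, max) pair")
  structure(list(size = as.integer(size), n_trees = as.integer(n_trees),
                 branch_depth = as.integer(branch_depth),
                 vessel_width = vessel_width, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Deformation specification
#'
#' @param amplitude Maximum displacement magnitude in pixels (>= 0).
#' @param smoothness Gaussian correlation length of the field in pixels
#'   (> 0).
#' @param seed Integer seed.
#' @return A `deformation_spec` object.
#' @export
deformation_spec <- function(amplitude = 4, smoothness = 8, seed = 1L) {
  if (amplitude < 0) stop_config("amplitude must be >= 0")
  if (smoothness <= 0) stop_config("smoothness must be > 0")
  structure(list(amplitude = amplitude, smoothness = smoothness,
                 seed = as.integer(seed)),
            class = "deformation_spec")
}

#' Synthetic fundus phantom with vessel trees
#'
#' Dark anti-aliased vessel trees on a bright circular fundus disc: each tree
#' grows from an optic-disc-like bright region by recursive branching of
#' curvilinear strokes whose width tapers down the tree; a mild smooth
#' intensity texture and radial shading are added so the background is not
#' constant. The phantom is a stand-in for a real fundus photograph at the
#' structural level the registration pipeline cares about (it is not
#' photorealistic).
#'
#' @param spec A [phantom_spec()].
#' @return A `fundus_image` (grayscale).
#' @export
vessel_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) spec <- do.call(phantom_spec, spec)
  s <- spec$size
  with_seed(spec$seed, {
    ctr <- (s + 1) / 2
    rr <- matrix(seq_len(s), s, s)
    cc <- matrix(seq_len(s), s, s, byrow = TRUE)
    D <- sqrt((rr - ctr)^2 + (cc - ctr)^2)
    R <- 0.47 * s
    inside <- D <= R

    bg <- 0.68 + 0.10 * pmax(1 - (D / R)^2, 0)
    tex <- gaussian_smooth(matrix(rnorm(s * s), s, s), s / 16)
    tex <- 0.04 * tex / max(abs(tex), 1e-12)
    bg <- bg + tex

    # optic-disc-like bright blob; vessel trees grow out of it
    od_ang <- runif(1, 0, 2 * pi)
    od_r <- ctr + 0.55 * R * c(sin(od_ang), cos(od_ang))
    od <- 0.14 * exp(-((rr - od_r[1])^2 + (cc - od_r[2])^2) / (2 * (s / 14)^2))
    bg <- bg + od

    # grow trees: collect (row, col, half-width) stroke points
    pts <- matrix(0, 0, 3)
    grow <- function(pos, ang, width, depth) {
      len <- runif(1, 0.35, 0.6) * R * 0.8^(spec$branch_depth - depth)
      nst <- max(3L, round(len))
      local_pts <- matrix(0, nst, 3)
      for (i in seq_len(nst)) {
        ang <- ang + rnorm(1, 0, 0.09)
        pos <- pos + c(sin(ang), cos(ang))
        local_pts[i, ] <- c(pos, width / 2)
        width <- width * (0.85)^(1 / nst)
        d <- sqrt(sum((pos - ctr)^2))
        if (d > 0.93 * R) {
          local_pts <- local_pts[seq_len(i), , drop = FALSE]
          break
        }
      }
      pts <<- rbind(pts, local_pts)
      d <- sqrt(sum((pos - ctr)^2))
      if (depth > 1 && d <= 0.93 * R) {
        spread <- runif(1, 0.35, 0.7)
        grow(pos, ang + spread, width * runif(1, 0.65, 0.85), depth - 1)
        grow(pos, ang - spread, width * runif(1, 0.65, 0.85), depth - 1)
      }
    }
    for (k in seq_len(spec$n_trees)) {
      w0 <- runif(1, spec$vessel_width[1], spec$vessel_width[2])
      ang0 <- atan2(ctr - od_r[1], ctr - od_r[2]) + rnorm(1, 0, 0.8)
      grow(od_r + rnorm(2, 0, s / 50), ang0, w0, spec$branch_depth)
    }

    # rasterize: soft circular stamps along the centerlines
    V <- matrix(0, s, s)
    for (i in seq_len(nrow(pts))) {
      p <- pts[i, ]
      rad <- p[3] + 0.5
      r0 <- max(1L, floor(p[1] - rad)); r1 <- min(s, ceiling(p[1] + rad))
      c0 <- max(1L, floor(p[2] - rad)); c1 <- min(s, ceiling(p[2] + rad))
      if (r0 > r1 || c0 > c1) next
      lr <- r0:r1; lc <- c0:c1
      dl <- sqrt(outer((lr - p[1])^2, (lc - p[2])^2, `+`))
      prof <- pmin(pmax(p[3] + 0.5 - dl, 0), 1)
      V[lr, lc] <- pmax(V[lr, lc], prof)
    }

    img <- ifelse(inside, bg - 0.60 * V, 0.04)
    out <- fundus_image(pmin(pmax(img, 0), 1))
    # ground-truth vessel mask, for diagnostics and generator tests
    attr(out, "vessel_mask") <- (V > 0.5 & inside) * 1
    out
  })
}

#' Smooth random deformation field
#'
#' Two independent Gaussian-smoothed white-noise fields (correlation length
#' `smoothness` pixels), each centred to zero mean, jointly rescaled so the
#' maximum displacement magnitude equals `amplitude` exactly.
#'
#' @param spec A [deformation_spec()].
#' @param H,W Field dimensions in pixels.
#' @return An `H x W x 2` displacement array (`(delta row, delta col)` in
#'   pixels).
#' @export
smooth_deformation <- function(spec = deformation_spec(), H, W) {
  if (!inherits(spec, "deformation_spec"))
    spec <- do.call(deformation_spec, spec)
  disp <- array(0, c(H, W, 2))
  if (spec$amplitude == 0) return(disp)
  with_seed(spec$seed, {
    for (k in 1:2) {
      f <- gaussian_smooth(matrix(rnorm(H * W), H, W), spec$smoothness)
      disp[, , k] <- f - mean(f)
    }
    mag <- sqrt(disp[, , 1]^2 + disp[, , 2]^2)
    mx <- max(mag)
    if (mx > 0) disp <- disp * (spec$amplitude / mx)
    disp
  })
}

#' Degradation options
#'
#' Acquisition degradations applied to the moving image, emulating
#' poor-quality clinical captures: Gaussian blur, global dimming, smooth
#' dark occlusion blobs (smoky artifacts), and granular sensor noise.
#' Defaults are mild — visible to the segmentation but not destructive. The
#' noise term matters structurally: it is what seeds the small spurious
#' clusters in the segmented (and hence warped) maps that the
#' connected-component refinement stage exists to remove.
#'
#' @param blur_sigma Gaussian blur standard deviation in pixels (0 = none).
#' @param dim_factor Global intensity multiplier in (0, 1\].
#' @param n_occlusions Number of dark occlusion blobs.
#' @param occlusion_strength Peak fractional darkening of each blob.
#' @param noise_sd Standard deviation of additive granular noise on the
#'   degraded image (0 = none).
#' @param noise_scale Correlation length of the noise grain in pixels;
#'   low-light captures show blotchy rather than pixel-white noise.
#' @param seed Integer seed for occlusion placement and noise.
#' @return A `degrade_options` object.
#' @export
degrade_options <- function(blur_sigma = 0.7, dim_factor = 0.85,
                            n_occlusions = 2, occlusion_strength = 0.35,
                            noise_sd = 0.05, noise_scale = 0.8, seed = 1L) {
  if (dim_factor <= 0 || dim_factor > 1)
    stop_config("dim_factor must be in (0, 1]")
  if (noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (noise_scale < 0) stop_config("noise_scale must be >= 0")
  structure(list(blur_sigma = blur_sigma, dim_factor = dim_factor,
                 n_occlusions = as.integer(n_occlusions),
                 occlusion_strength = occlusion_strength,
                 noise_sd = noise_sd, noise_scale = noise_scale,
                 seed = as.integer(seed)),
            class = "degrade_options")
}

#' Generate a synthetic registration pair with ground truth
#'
#' The reference image is a vessel phantom; the moving image is the phantom
#' resampled along a smooth random displacement field (so
#' `IMov(x) = IRef(x + u(x))`), optionally followed by blur, dimming and
#' occlusions. The true displacement field is returned for recovery
#' diagnostics — note that evaluating against it goes beyond the
#' similarity-only protocol the framework itself trains and is scored by.
#'
#' @param phantom A [phantom_spec()].
#' @param deform A [deformation_spec()] (or `NULL` for no deformation).
#' @param degrade A [degrade_options()] (or `NULL` for none).
#' @return List with `i_ref`, `i_mov` (`fundus_image`s) and `true_grid`
#'   (`H x W x 2` displacement array).
#' @export
make_pair <- function(phantom = phantom_spec(), deform = deformation_spec(),
                      degrade = NULL) {
  i_ref <- vessel_phantom(phantom)
  s <- phantom$size
  true_grid <- if (is.null(deform)) array(0, c(s, s, 2))
               else smooth_deformation(deform, s, s)
  mov <- bilinear_sample(i_ref$pixels, identity_grid(s, s) + true_grid)
  if (!is.null(degrade)) {
    if (!inherits(degrade, "degrade_options"))
      degrade <- do.call(degrade_options, degrade)
    with_seed(degrade$seed, {
      if (degrade$blur_sigma > 0)
        mov <- gaussian_smooth(mov, degrade$blur_sigma)
      mov <- mov * degrade$dim_factor
      if (degrade$n_occlusions > 0) {
        ctr <- (s + 1) / 2
        rr <- matrix(seq_len(s), s, s)
        cc <- matrix(seq_len(s), s, s, byrow = TRUE)
        for (k in seq_len(degrade$n_occlusions)) {
          ang <- runif(1, 0, 2 * pi)
          rad <- runif(1, 0.1, 0.45) * s / 2
          pos <- ctr + rad * c(sin(ang), cos(ang))
          sig <- runif(1, 0.06, 0.12) * s
          occ <- exp(-((rr - pos[1])^2 + (cc - pos[2])^2) / (2 * sig^2))
          mov <- mov * (1 - degrade$occlusion_strength * occ)
        }
      }
      if (degrade$noise_sd > 0) {
        gr <- matrix(rnorm(s * s), s, s)
        if (degrade$noise_scale > 0)
          gr <- gaussian_smooth(gr, degrade$noise_scale)
        mov <- mov + degrade$noise_sd * gr / stats::sd(gr)
      }
      mov
    })
  }
  list(i_ref = i_ref, i_mov = fundus_image(pmin(pmax(mov, 0), 1)),
       true_grid = true_grid)
}

#' Generate a reproducible suite of synthetic pairs
#'
#' Convenience wrapper producing `n` pairs with consecutive seeds derived
#' from `seed`, together with a manifest of the exact specs used, so a suite
#' is fully reproducible from its manifest.
#'
#' @param n Number of pairs.
#' @param size Image side in pixels.
#' @param amplitude Maximum deformation amplitude in pixels.
#' @param smoothness Deformation correlation length in pixels.
#' @param degrade A [degrade_options()] applied to every moving image
#'   (seeded per pair), or `NULL`.
#' @param seed Base seed.
#' @param ... Further arguments passed to [phantom_spec()].
#' @return List with `pairs` (list of [make_pair()] results) and `manifest`
#'   (data frame of seeds and parameters).
#' @export
synth_suite <- function(n, size = 64, amplitude = 4, smoothness = 8,
                        degrade = degrade_options(), seed = 1L, ...) {
  if (n < 1) stop_config("n must be >= 1")
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    ps <- phantom_spec(size = size, seed = seed + i, ...)
    ds <- deformation_spec(amplitude = amplitude, smoothness = smoothness,
                           seed = seed + 10000L + i)
    dg <- if (is.null(degrade)) NULL else {
      d <- degrade
      d$seed <- seed + 20000L + i
      d
    }
    pairs[[i]] <- make_pair(ps, ds, dg)
  }
  manifest <- data.frame(
    pair = seq_len(n), size = size, amplitude = amplitude,
    smoothness = smoothness,
    phantom_seed = seed + seq_len(n),
    deform_seed = seed + 10000L + seq_len(n),
    degrade_seed = if (is.null(degrade)) NA_integer_
                   else seed + 20000L + seq_len(n)
  )
  list(pairs = pairs, manifest = manifest)
}
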