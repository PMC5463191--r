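#' Scene configuration for the synthetic B-scan phantom
#'
#' Describes a piecewise-layered retina: five retinal layers with
#' distinct mean reflectivities, delimited by six smooth boundary curves
#' (low-order polynomial trend plus an optional foveal dip), flanked by a
#' dark vitreous above and a bright band below the ELM.  All intensities
#' are on the `[0, 1]` grey scale.
#'
#' Default layer means follow the qualitative reflectivity pattern of
#' healthy retina on SD-OCT: bright NFL and OPL, intermediate GCL+IPL,
#' darker nuclear layers (INL, ONL), near-black vitreous, bright outer
#' retina below the ELM.
#'
#' @param width number of A-scans (columns); default 512.
#' @param depth axial rows; default 496.
#' @param layer_means named numeric of length 5 (`layer_labels()`
#'   order), clean per-layer intensities in `[0, 1]`.
#' @param vitreous_mean,sub_elm_mean clean intensities of the flanking
#'   regions.
#' @param band sub-ELM band height in rows (the lower pseudo-neighbour
#'   of the ONL).
#' @param boundary_params list controlling the boundary geometry, with
#'   elements `base_frac` (6 increasing depth fractions), `tilt` and
#'   `bow` (rows, linear/quadratic trend across the scan), `fovea_center`
#'   and `fovea_width` (fractions of width), `dip_frac` (6 non-negative
#'   depth fractions, downward foveal displacement per boundary).
#' @param seed integer kept with the configuration.
#' @return A `scene_config` object.
#' @export
scene_config <- function(width = 512L, depth = 496L,
                         layer_means = c(NFL = 0.80, GCL_IPL = 0.55,
                                         INL = 0.35, OPL = 0.60, ONL = 0.22),
                         vitreous_mean = 0.06, sub_elm_mean = 0.65,
                         band = 20L,
                         boundary_params = NULL,
                         seed = 1L) {
  if (is.null(boundary_params)) {
    boundary_params <- list(
      base_frac = c(0.30, 0.34, 0.46, 0.52, 0.58, 0.68),
      tilt = 0.012 * depth, bow = -0.016 * depth,
      fovea_center = 0.5, fovea_width = 0.12,
      dip_frac = c(0.036, 0.028, 0.016, 0.008, 0.002, 0))
  }
  cfg <- structure(list(width = as.integer(width), depth = as.integer(depth),
                        layer_means = layer_means,
                        vitreous_mean = vitreous_mean,
                        sub_elm_mean = sub_elm_mean,
                        band = as.integer(band),
                        boundary_params = boundary_params,
                        seed = as.integer(seed)),
                   class = "scene_config")
  validate_scene(cfg)
  cfg
}

validate_scene <- function(cfg) {
  if (length(cfg$layer_means) != 5L ||
      any(cfg$layer_means < 0) || any(cfg$layer_means > 1)) {
    stop("layer_means must be 5 intensities in [0, 1]")
  }
  if (cfg$vitreous_mean < 0 || cfg$vitreous_mean > 1 ||
      cfg$sub_elm_mean < 0 || cfg$sub_elm_mean > 1) {
    stop("region means must lie in [0, 1]")
  }
  b <- boundary_curves(cfg)
  if (any(b < 0) || any(b >= cfg$depth)) {
    stop("boundary curves leave [0, depth)")
  }
  if (any(apply(b, 2L, diff) <= 0)) {
    stop("boundary curves must be strictly ordered top-to-bottom")
  }
  invisible(cfg)
}

# Real-valued boundary curves (6 x width) from the scene geometry.
boundary_curves <- function(cfg) {
  p <- cfg$boundary_params
  w <- cfg$width
  x <- seq_len(w) - 1L
  xn <- if (w > 1L) (x - (w - 1) / 2) / ((w - 1) / 2) else 0
  cx <- p$fovea_center * (w - 1)
  sw <- max(p$fovea_width * w, 1e-9)
  dip_shape <- exp(-0.5 * ((x - cx) / sw)^2)
  trend <- p$tilt * xn + p$bow * (xn^2 - 1 / 3)
  b <- matrix(0, nrow = 6L, ncol = w)
  for (k in 1:6) {
    b[k, ] <- p$base_frac[k] * cfg$depth + trend +
      p$dip_frac[k] * cfg$depth * dip_shape
  }
  b
}

# Round half-up: annotation rows are integer pixel positions.
round_half_up <- function(x) floor(x + 0.5)

#' Generate a noise-free B-scan with its ground-truth annotation
#'
#' Builds the piecewise-constant phantom: each pixel takes the mean
#' intensity of the region containing it, and the returned
#' [boundary_set()] is the exact generating geometry (real-valued curves
#' rounded half-up to pixel rows), so the clean image and the
#' rasterized mask agree exactly.
#'
#' @param cfg a [scene_config()].
#' @return List with elements `scan` (an [oct_scan()]) and `boundaries`
#'   (a [boundary_set()]).
#' @export
generate_clean_scan <- function(cfg) {
  validate_scene(cfg)
  b <- round_half_up(boundary_curves(cfg))
  bs <- boundary_set(b)
  mask <- rasterize_mask(bs, cfg$depth, cfg$band)
  means_by_code <- c(cfg$vitreous_mean, unname(cfg$layer_means),
                     cfg$sub_elm_mean, cfg$sub_elm_mean)
  img <- matrix(means_by_code[unclass(mask) + 1L],
                nrow = cfg$depth, ncol = cfg$width)
  list(scan = oct_scan(img), boundaries = bs)
}

#' Noise configuration for synthetic frame acquisition
#'
#' Models the noise of a single acquired frame.  The additive,
#' per-frame-independent component (`sigma_u`) stands for the speckle
#' residual of the displayed (log-compressed) image and averages down as
#' `1/sqrt(M)`; the frame-correlated floor (`sigma_c`) is a per-pixel
#' field drawn once per stack and shared by all frames, so it survives
#' averaging and caps the attainable SNR.  Media opacity (cataract) is
#' modelled as a signal attenuation factor plus an inflation of the
#' uncorrelated noise.  Multiplicative gamma speckle and per-frame axial
#' jitter are opt-in mechanisms.
#'
#' @param sigma_u standard deviation of the per-frame uncorrelated
#'   additive noise (> 0).
#' @param sigma_c standard deviation of the frame-correlated noise floor
#'   (>= 0; 0 disables it).
#' @param speckle_shape gamma shape of unit-mean multiplicative speckle,
#'   or `NULL` for none.
#' @param opacity signal attenuation in `(0, 1]`; 1 = clear media.
#' @param noise_inflation multiplier on `sigma_u` applied when
#'   `opacity < 1`.
#' @param jitter_px standard deviation (rows) of a per-frame sub-pixel
#'   axial shift; 0 disables it.
#' @return A `noise_config` object.
#' @export
noise_config <- function(sigma_u = 0.12, sigma_c = 0.07,
                         speckle_shape = NULL, opacity = 1,
                         noise_inflation = 1, jitter_px = 0) {
  if (sigma_u <= 0) stop("sigma_u must be > 0")
  if (sigma_c < 0) stop("sigma_c must be >= 0")
  if (opacity <= 0 || opacity > 1) stop("opacity must be in (0, 1]")
  if (!is.null(speckle_shape) && speckle_shape <= 0) {
    stop("speckle_shape must be > 0 (or NULL)")
  }
  if (jitter_px < 0) stop("jitter_px must be >= 0")
  structure(list(sigma_u = sigma_u, sigma_c = sigma_c,
                 speckle_shape = speckle_shape, opacity = opacity,
                 noise_inflation = noise_inflation, jitter_px = jitter_px),
            class = "noise_config")
}

#' Default noise configurations for the two media conditions
#'
#' `"post"` (clear media, after cataract surgery) uses the baseline
#' noise; `"pre"` (opaque media) attenuates the signal mildly and
#' inflates the uncorrelated noise strongly, reflecting that cataract
#' degrades OCT mainly by scattering.  With these defaults the averaged
#' SNR saturates by 16 frames in the clear condition but keeps rising to
#' 96 frames in the opaque condition.
#'
#' @param condition `"pre"` or `"post"`.
#' @return A [noise_config()].
#' @export
default_noise_config <- function(condition = c("post", "pre")) {
  condition <- match.arg(condition)
  if (condition == "post") {
    noise_config(sigma_u = 0.12, sigma_c = 0.07)
  } else {
    noise_config(sigma_u = 0.12, sigma_c = 0.07,
                 opacity = 0.95, noise_inflation = 2.5)
  }
}

# Shift an image down by dy rows (sub-pixel, linear interpolation,
# replicated edges).
shift_rows <- function(img, dy) {
  if (dy == 0) return(img)
  d <- nrow(img)
  src <- seq_len(d) - dy
  i0 <- floor(src)
  frac <- src - i0
  i0c <- pmin(pmax(i0, 1L), d)
  i1c <- pmin(pmax(i0 + 1L, 1L), d)
  img[i0c, , drop = FALSE] * (1 - frac) + img[i1c, , drop = FALSE] * frac
}

#' Simulate a stack of noisy frames of one clean scan
#'
#' Each frame is
#' `clip( jitter( clean * opacity * speckle_i + u_i ) + c )`
#' where `u_i` is per-frame additive Gaussian noise (scale
#' `sigma_u * noise_inflation` when `opacity < 1`), `speckle_i` optional
#' per-frame unit-mean gamma speckle, and `c` a single frame-correlated
#' Gaussian field (scale `sigma_c`) drawn once for the whole stack.
#' Values are clipped to `[0, 1]`, modelling 8-bit export saturation.
#'
#' @param clean an [oct_scan()] or numeric matrix (the noise-free scene).
#' @param M number of frames (>= 1).
#' @param noise a [noise_config()].
#' @param seed integer RNG seed; the same seed reproduces the stack
#'   bit-identically.
#' @return A `frame_stack`: numeric array `depth x width x M`.
#' @export
generate_frames <- function(clean, M, noise, seed = 1L) {
  stopifnot(inherits(noise, "noise_config"))
  if (M < 1) stop("M must be >= 1")
  M <- as.integer(M)
  img <- as_image(clean)
  d <- nrow(img); w <- ncol(img); n <- d * w
  set.seed(seed)
  sig_u <- noise$sigma_u * if (noise$opacity < 1) noise$noise_inflation else 1
  cfield <- if (noise$sigma_c > 0) {
    matrix(stats::rnorm(n, 0, noise$sigma_c), d, w)
  } else 0
  base <- img * noise$opacity
  out <- array(0, dim = c(d, w, M))
  for (i in seq_len(M)) {
    fr <- base
    if (!is.null(noise$speckle_shape)) {
      k <- noise$speckle_shape
      fr <- fr * matrix(stats::rgamma(n, shape = k, rate = k), d, w)
    }
    fr <- fr + matrix(stats::rnorm(n, 0, sig_u), d, w)
    if (noise$jitter_px > 0) {
      fr <- shift_rows(fr, stats::rnorm(1, 0, noise$jitter_px))
    }
    fr <- fr + cfield
    out[, , i] <- pmin(pmax(fr, 0), 1)
  }
  structure(out, class = c("frame_stack", "array"),
            noise = noise, seed = as.integer(seed))
}

#' Average a frame stack into a single B-scan
#'
#' Pixel-wise arithmetic mean over frames; the resulting scan records the
#' number of frames averaged.  Under purely uncorrelated noise the SNR of
#' the average grows as `sqrt(M)`; a frame-correlated floor breaks that
#' law and produces saturation.
#'
#' @param stack a `frame_stack` from [generate_frames()], or a list of
#'   same-shape matrices.
#' @param ... metadata passed to [oct_scan()] (`eye`, `condition`).
#' @return An [oct_scan()] with `frames` metadata set to the stack size.
#' @export
average_frames <- function(stack, ...) {
  if (is.list(stack)) {
    dims <- lapply(stack, dim)
    if (length(stack) == 0L) stop("empty frame stack")
    if (!all(vapply(dims, identical, logical(1), dims[[1L]]))) {
      stop("all frames must have the same shape")
    }
    stack <- array(unlist(stack), dim = c(dims[[1L]], length(stack)))
  }
  if (length(dim(stack)) != 3L) stop("expected a depth x width x M array")
  M <- dim(stack)[3L]
  oct_scan(rowMeans(stack, dims = 2L), frames = M, ...)
}

#' Study design: averaging settings, eyes and visits
#'
#' The acquisition design being emulated: each of `n_eyes` eyes is
#' scanned at both visits (`pre` = opaque media before cataract surgery,
#' `post` = clear media after) at every frame-averaging setting, with the
#' scan order randomized within each visit and all scans of an eye
#' aligned to the same retinal position (so one ground-truth boundary set
#' per eye).
#'
#' @param n_eyes number of eyes (default 13).
#' @param settings strictly increasing positive integer averaging counts
#'   (default 2, 4, 8, 16, 32, 48, 96).
#' @return A `study_design` object; fields include `conditions`
#'   (`c("pre", "post")`), `n_boundaries` (6) and `n_layers` (5).
#' @export
study_design <- function(n_eyes = 13L,
                         settings = c(2L, 4L, 8L, 16L, 32L, 48L, 96L)) {
  settings <- as.integer(settings)
  if (any(settings < 1L) || is.unsorted(settings, strictly = TRUE)) {
    stop("settings must be strictly increasing positive integers")
  }
  structure(list(n_eyes = as.integer(n_eyes), settings = settings,
                 conditions = c("pre", "post"),
                 n_boundaries = 6L, n_layers = 5L),
            class = "study_design")
}

# Eye-level random effect: global axial shift, log-normal thickness
# scaling (order-preserving), foveal dip scaling, log-normal layer mean
# perturbation.  Draws from the current RNG stream.
perturb_scene <- function(scene) {
  p <- scene$boundary_params
  shift <- stats::rnorm(1, 0, 0.01) * scene$depth
  thick <- diff(p$base_frac) * exp(stats::rnorm(5, 0, 0.08))
  base <- cumsum(c(p$base_frac[1L] + shift / scene$depth, thick))
  p$base_frac <- base
  p$dip_frac <- p$dip_frac * stats::runif(1, 0.8, 1.2)
  means <- pmin(pmax(scene$layer_means * exp(stats::rnorm(5, 0, 0.06)),
                     0.01), 0.99)
  out <- scene
  out$boundary_params <- p
  out$layer_means <- means
  validate_scene(out)
  out
}

#' Simulate the full frame-averaging study
#'
#' For each eye: draws an eye-level perturbation of the scene (layer
#' reflectivities and boundary geometry), generates one shared
#' ground-truth [boundary_set()] (all scans of an eye are aligned to the
#' identical retinal position, as with a device follow-up function), and
#' produces one averaged scan per (condition, averaging setting) cell —
#' `2 x length(settings)` scans per eye.  The randomized acquisition
#' order within each visit is recorded but, frames being synthesized
#' independently, has no effect on the images.
#'
#' @param design a [study_design()].
#' @param scene a [scene_config()] (the population-average scene).
#' @param noise_pre opaque-media [noise_config()] (`opacity < 1`).
#' @param noise_post clear-media [noise_config()] (`opacity = 1`).
#' @param seed integer master seed; the whole dataset is reproducible
#'   bit-identically from it.
#' @return An `oct_study_dataset`: list with `design`, `seed`, `eyes`
#'   (per-eye boundaries and acquisition orders) and `scans` (flat list
#'   of records with `eye`, `condition`, `frames`, `scan`).
#' @export
simulate_study <- function(design = study_design(),
                           scene = scene_config(),
                           noise_pre = default_noise_config("pre"),
                           noise_post = default_noise_config("post"),
                           seed = 1L) {
  stopifnot(inherits(design, "study_design"), inherits(scene, "scene_config"))
  if (noise_pre$opacity >= 1) {
    stop("noise_pre must model opaque media (opacity < 1)")
  }
  if (noise_post$opacity != 1) {
    stop("noise_post must model clear media (opacity = 1)")
  }
  S <- length(design$settings)
  set.seed(seed)
  eye_seeds <- sample.int(2147483646L, design$n_eyes)
  stack_seeds <- array(sample.int(2147483646L, design$n_eyes * 2L * S),
                       dim = c(design$n_eyes, 2L, S))
  noise_by_cond <- list(pre = noise_pre, post = noise_post)
  eyes <- vector("list", design$n_eyes)
  scans <- vector("list", design$n_eyes * 2L * S)
  idx <- 0L
  for (e in seq_len(design$n_eyes)) {
    set.seed(eye_seeds[e])
    scene_e <- perturb_scene(scene)
    order_pre <- sample(design$settings)
    order_post <- sample(design$settings)
    clean <- generate_clean_scan(scene_e)
    eyes[[e]] <- list(eye = e, boundaries = clean$boundaries,
                      scene = scene_e,
                      acquisition_order = list(pre = order_pre,
                                               post = order_post))
    for (ci in 1:2) {
      cond <- design$conditions[ci]
      for (si in seq_len(S)) {
        M <- design$settings[si]
        stack <- generate_frames(clean$scan, M, noise_by_cond[[cond]],
                                 seed = stack_seeds[e, ci, si])
        idx <- idx + 1L
        scans[[idx]] <- list(eye = e, condition = cond, frames = M,
                             scan = average_frames(stack, eye = e,
                                                   condition = cond))
      }
    }
  }
  structure(list(design = design, scene = scene,
                 noise = noise_by_cond, seed = as.integer(seed),
                 eyes = eyes, scans = scans),
            class = "oct_study_dataset")
}

#' @export
print.oct_study_dataset <- function(x, ...) {
  cat(sprintf(
    "<oct_study_dataset: %d eyes x %d conditions x %d settings = %d scans>\n",
    x$design$n_eyes, 2L, length(x$design$settings), length(x$scans)))
  invisible(x)
}
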