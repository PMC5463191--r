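#' Summary statistics of one layer's grey values
#'
#' Mean, sample standard deviation (divisor `n - 1`) and pixel count of
#' a region's intensity sample — the sufficient statistics for both the
#' per-layer SNR and Cohen's d.
#'
#' @param values numeric vector of grey values (length >= 2), e.g. from
#'   [layer_pixels()].
#' @return A `layer_stats` object: list with `mean`, `sd`, `n`.
#' @export
layer_stats <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 pixels to compute layer statistics")
  structure(list(mean = mean(values), sd = stats::sd(values), n = n),
            class = "layer_stats")
}

#' Per-layer signal-to-noise ratio
#'
#' `SNR = mu / sigma`, the ratio of the mean to the standard deviation
#' of the grey values within one annotated layer.  Because averaging M
#' uncorrelated frames leaves the mean unchanged and divides the noise
#' standard deviation by `sqrt(M)`, this SNR is expected to grow as
#' `sqrt(M)` when no frame-correlated noise is present.
#'
#' @param stats a [layer_stats()].
#' @return The ratio `mean / sd`.  A zero standard deviation (constant
#'   layer) is an error; callers may catch it and report the layer as
#'   saturated.
#' @export
snr_layer <- function(stats) {
  stopifnot(inherits(stats, "layer_stats"))
  if (stats$sd == 0) {
    stop("layer is constant (sd = 0): SNR undefined/saturated")
  }
  stats$mean / stats$sd
}

#' Cohen's d between two layer intensity distributions
#'
#' Standardized mean difference with the pooled, `(n-1)`-weighted sample
#' standard deviation:
#' `d = |m1 - m2| / sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#' The absolute value is taken: d is used as a separation magnitude
#' (large d = neighbouring layers well distinguished), so its sign
#' carries no information here.
#'
#' @param a,b [layer_stats()] of the two layers.
#' @return Non-negative effect size.  A zero pooled standard deviation
#'   returns 0 when the means are equal and is an error otherwise
#'   (infinite separation).
#' @export
cohens_d_pair <- function(a, b) {
  stopifnot(inherits(a, "layer_stats"), inherits(b, "layer_stats"))
  if (a$n + b$n < 3L) stop("need at least 3 pixels in total")
  pooled_var <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2)
  if (pooled_var == 0) {
    if (a$mean == b$mean) return(0)
    stop("zero pooled standard deviation with unequal means: ",
         "infinite separation")
  }
  abs(a$mean - b$mean) / sqrt(pooled_var)
}

#' Neighbour-averaged Cohen's d of one layer
#'
#' Each layer's d value is the mean of its d against the neighbouring
#' region above and the one below.  For the outermost layers the
#' flanking regions act as pseudo-neighbours: the vitreous above the
#' NFL, the sub-ELM band below the ONL.
#'
#' @param target,above,below [layer_stats()] of the layer and its two
#'   neighbouring regions.
#' @return Mean of the two pairwise d values.
#' @export
cohens_d_layer <- function(target, above, below) {
  (cohens_d_pair(target, above) + cohens_d_pair(target, below)) / 2
}

#' Per-scan quality report: SNR and Cohen's d
#'
#' Computes, for each of the five annotated layers, the layer SNR and the
#' neighbour-averaged Cohen's d, plus the image-level values (unweighted
#' mean over layers).  A degenerate layer (constant intensities or an
#' undefined pairwise d) yields `NA` for that layer, with a warning, and
#' the image mean is taken over the available layers.
#'
#' @param img an [oct_scan()] or numeric matrix.
#' @param mask a `layer_mask` from [rasterize_mask()].
#' @param neighbors `"flanked"` (default) uses vitreous / sub-ELM
#'   pseudo-neighbours for the outermost layers; `"one_sided"` uses only
#'   the inner neighbour for NFL and ONL.
#' @return A `quality_report`: list with per-layer vectors `snr` and
#'   `d`, scalars `snr_image` and `d_image`, slots `dice`/`dice_image`
#'   (filled by [image_dice()]), and scan metadata.
#' @export
image_quality <- function(img, mask, neighbors = c("flanked", "one_sided")) {
  neighbors <- match.arg(neighbors)
  layers <- layer_labels()
  all_regions <- region_sequence()
  st <- lapply(all_regions, function(lab) {
    tryCatch(layer_stats(layer_pixels(img, mask, lab)),
             error = function(e) NULL)
  })
  names(st) <- all_regions
  snr <- d <- stats::setNames(rep(NA_real_, 5L), layers)
  for (lab in layers) {
    s <- st[[lab]]
    if (is.null(s)) {
      warning("degenerate layer ", lab, ": metrics set to NA")
      next
    }
    snr[lab] <- tryCatch(snr_layer(s), error = function(e) {
      warning("layer ", lab, ": ", conditionMessage(e)); NA_real_
    })
    nb <- layer_neighbors(lab)
    pair_d <- function(other) {
      if (is.null(st[[other]])) return(NA_real_)
      tryCatch(cohens_d_pair(s, st[[other]]), error = function(e) NA_real_)
    }
    da <- pair_d(nb$above)
    db <- pair_d(nb$below)
    if (neighbors == "one_sided") {
      if (lab == "NFL") da <- NA_real_
      if (lab == "ONL") db <- NA_real_
    }
    dv <- mean(c(da, db), na.rm = TRUE)
    d[lab] <- if (is.nan(dv)) NA_real_ else dv
  }
  m <- scan_meta(img)
  structure(list(eye = m$eye, condition = m$condition, frames = m$frames,
                 snr = snr, snr_image = mean(snr, na.rm = TRUE),
                 d = d, d_image = mean(d, na.rm = TRUE),
                 dice = stats::setNames(rep(NA_real_, 5L), layers),
                 dice_image = NA_real_),
            class = "quality_report")
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report eye %s | %s | M = %s>\n",
              as.character(x$eye), x$condition, as.character(x$frames)))
  cat(sprintf("  image SNR %.3f | image d %.3f | image Dice %s\n",
              x$snr_image, x$d_image,
              ifelse(is.na(x$dice_image), "-",
                     sprintf("%.3f", x$dice_image))))
  invisible(x)
}

#' @export
as.data.frame.quality_report <- function(x, ...) {
  layers <- layer_labels()
  one <- function(metric, per_layer, image) {
    data.frame(eye = x$eye, condition = x$condition, M = x$frames,
               layer = c(layers, "image"), metric = metric,
               value = c(unname(per_layer), image))
  }
  rbind(one("snr", x$snr, x$snr_image),
        one("d", x$d, x$d_image),
        one("dice", x$dice, x$dice_image))
}

#' Normalize a measure series to its two-frame baseline
#'
#' Divides each value by the value at the baseline averaging setting
#' (2 frames) of the same eye and condition, so the baseline maps to 1
#' and curves from different eyes become comparable relative responses.
#'
#' @param df tidy data frame with columns `eye`, `condition`, `M`,
#'   `value` (e.g. one metric's image-level rows of a study table).
#' @param baseline_m baseline averaging setting (default 2).
#' @return The data frame with `value` replaced by `value / baseline`.
#' @export
relative_to_baseline <- function(df, baseline_m = 2L) {
  stopifnot(all(c("eye", "condition", "M", "value") %in% names(df)))
  key <- paste(df$eye, df$condition, sep = "\r")
  base <- df$value[df$M == baseline_m]
  base_key <- key[df$M == baseline_m]
  if (anyDuplicated(base_key)) {
    stop("multiple baseline rows per eye/condition; pass a single metric")
  }
  if (any(!key %in% base_key)) {
    stop("missing baseline (M = ", baseline_m, ") value for some ",
         "eye/condition")
  }
  df$value <- df$value / base[match(key, base_key)]
  df
}
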