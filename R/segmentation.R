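#' Dice overlap between two pixel sets
#'
#' `Dice(A, B) = 2 |A ∩ B| / (|A| + |B|)`, the standard overlap score
#' between an automatically segmented pixel set and the manually
#' annotated ground truth.  It is 1 iff the sets coincide and 0 iff they
#' are disjoint.
#'
#' @param a,b pixel sets given as integer index vectors (duplicates are
#'   ignored).
#' @return Overlap score in `[0, 1]`.  Two empty sets are an error.
#' @export
dice <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L) {
    stop("Dice undefined for two empty pixel sets")
  }
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Maximum-likelihood pixel classification among three intensity models
#'
#' Assigns every pixel of a region to the label whose fitted mixture
#' density at the pixel's grey value is largest.  Models must be given
#' in anatomical top-to-bottom order (above, target, below); density
#' ties are broken towards the anatomically upper label, which makes the
#' classification deterministic.
#'
#' @param img an [oct_scan()] or numeric matrix.
#' @param region integer vector of pixel indices (into `img`) to
#'   classify.
#' @param models named list of three `layer_gmm` objects in
#'   top-to-bottom order; names are the labels assigned.
#' @return Character vector of labels, one per region pixel (same order
#'   as `region`).
#' @export
classify_region <- function(img, region, models) {
  if (length(region) == 0L) stop("empty classification region")
  if (length(models) != 3L || is.null(names(models))) {
    stop("models must be a named list of three fitted intensity models")
  }
  x <- as_image(img)[region]
  logd <- vapply(models, function(m) gmm_density(m, x, log = TRUE),
                 numeric(length(x)))
  logd <- matrix(logd, nrow = length(x))
  names(models)[max.col(logd, ties.method = "first")]
}

#' Segment one retinal layer by per-pixel intensity classification
#'
#' Implements the per-layer segmentation evaluation: fit a
#' three-component Gaussian mixture ([fit_layer_gmm()]) to the manual
#' pixel sample of the target layer and of its two neighbouring regions
#' (vitreous / sub-ELM band acting as pseudo-neighbours for the
#' outermost layers), classify every pixel in the union of the three
#' manual regions by maximum likelihood, and score the pixels claimed by
#' the target model against the manual target region with the Dice
#' index.  Fitting and scoring use the same scan — the measure asks how
#' separable the layer's appearance is, not how a trained model
#' generalizes.
#'
#' @param img an [oct_scan()] or numeric matrix.
#' @param mask `layer_mask` from [rasterize_mask()] (the manual truth).
#' @param target_label one of `layer_labels()`.
#' @param seed integer seed controlling the mixture fits.
#' @param ... further arguments passed to [fit_layer_gmm()] (e.g.
#'   `max_n`).
#' @return A `segmentation_result`: list with `target`, pixel index sets
#'   `region`, `auto`, `manual`, the fitted `models`, and `dice`.
#' @export
segment_layer <- function(img, mask, target_label, seed = 1L, ...) {
  if (!target_label %in% layer_labels()) {
    stop("target_label must be one of: ",
         paste(layer_labels(), collapse = ", "))
  }
  imgm <- as_image(img)
  if (!all(dim(imgm) == dim(mask))) stop("image and mask shapes differ")
  nb <- layer_neighbors(target_label)
  labels3 <- c(nb$above, target_label, nb$below)
  codes <- region_labels()[labels3]
  maskv <- as.vector(unclass(mask))
  pix <- lapply(codes, function(code) which(maskv == code))
  names(pix) <- labels3
  sizes <- lengths(pix)
  if (any(sizes < 2L)) {
    stop("degenerate region(s) for layer ", target_label, ": ",
         paste(labels3[sizes < 2L], collapse = ", "))
  }
  models <- lapply(seq_along(labels3), function(j) {
    fit_layer_gmm(imgm[pix[[j]]], seed = seed + j - 1L, ...)
  })
  names(models) <- labels3
  region <- sort(unlist(pix, use.names = FALSE))
  assigned <- classify_region(imgm, region, models)
  auto <- region[assigned == target_label]
  manual <- pix[[target_label]]
  structure(list(target = target_label, region = region, auto = auto,
                 manual = manual, models = models,
                 dice = dice(auto, manual)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result %s: Dice %.4f (|auto| %d, |manual| %d)>\n",
    x$target, x$dice, length(x$auto), length(x$manual)))
  invisible(x)
}

#' Per-layer and image-level segmentation performance
#'
#' Runs [segment_layer()] for each of the five annotated layers and
#' averages the per-layer Dice indices (unweighted) into the image-level
#' score.  Layers whose segmentation is degenerate yield `NA` and are
#' excluded from the mean, with a warning.
#'
#' @inheritParams segment_layer
#' @return List with `dice` (named length-5 vector), `dice_image`, and
#'   `results` (the individual `segmentation_result` objects).
#' @export
image_dice <- function(img, mask, seed = 1L, ...) {
  layers <- layer_labels()
  results <- vector("list", length(layers))
  names(results) <- layers
  dv <- stats::setNames(rep(NA_real_, length(layers)), layers)
  for (i in seq_along(layers)) {
    res <- tryCatch(
      segment_layer(img, mask, layers[i], seed = seed + 10L * (i - 1L), ...),
      error = function(e) {
        warning("layer ", layers[i], ": ", conditionMessage(e))
        NULL
      })
    results[[i]] <- res
    if (!is.null(res)) dv[i] <- res$dice
  }
  list(dice = dv, dice_image = mean(dv, na.rm = TRUE), results = results)
}
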