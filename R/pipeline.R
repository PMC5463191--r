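#' Compute quality reports for every scan of a study dataset
#'
#' For each scan: rasterizes the eye's shared ground-truth boundaries,
#' computes per-layer and image-level SNR and Cohen's d
#' ([image_quality()]) and, unless disabled, the Gaussian-mixture
#' segmentation Dice ([image_dice()]).  Unreadable or failing scans are
#' recorded as gaps and the run continues.
#'
#' @param dataset an `oct_study_dataset` from [simulate_study()] or
#'   [read_dataset()].
#' @param seed integer seed; per-scan segmentation seeds are derived
#'   from it, so reruns are bit-identical.
#' @param dice compute segmentation Dice (default `TRUE`; the slowest
#'   part of a run).
#' @param gmm_max_n per-region subsample cap for the mixture fits,
#'   passed to [fit_layer_gmm()].
#' @param verbose log one line per eye.
#' @return An `oct_study` object: list with `design`, `reports` (one
#'   [image_quality()] report per scan, Dice slots filled), `table`
#'   (tidy data frame: eye, condition, M, layer, metric, value) and
#'   `gaps` (indices of scans that failed).
#' @export
run_study <- function(dataset, seed = 1L, dice = TRUE, gmm_max_n = 20000L,
                      verbose = interactive()) {
  stopifnot(inherits(dataset, "oct_study_dataset"))
  set.seed(seed)
  scan_seeds <- sample.int(2147483646L, length(dataset$scans))
  masks <- lapply(dataset$eyes, function(e) NULL)
  reports <- vector("list", length(dataset$scans))
  gaps <- integer(0)
  band <- if (!is.null(dataset$scene)) dataset$scene$band else 20L
  last_eye <- NA
  for (i in seq_along(dataset$scans)) {
    rec <- dataset$scans[[i]]
    if (isTRUE(verbose) && !identical(rec$eye, last_eye)) {
      message("analyzing eye ", rec$eye)
      last_eye <- rec$eye
    }
    rep_i <- tryCatch({
      if (is.null(rec$scan)) stop("scan missing")
      if (is.null(masks[[rec$eye]])) {
        masks[[rec$eye]] <- rasterize_mask(
          dataset$eyes[[rec$eye]]$boundaries, nrow(rec$scan), band)
      }
      mask <- masks[[rec$eye]]
      qr <- image_quality(rec$scan, mask)
      qr$eye <- rec$eye
      qr$condition <- rec$condition
      qr$frames <- rec$frames
      if (dice) {
        dd <- image_dice(rec$scan, mask, seed = scan_seeds[i],
                         max_n = gmm_max_n)
        qr$dice <- dd$dice
        qr$dice_image <- dd$dice_image
      }
      qr
    }, error = function(e) {
      warning("scan ", i, " (eye ", rec$eye, ", ", rec$condition,
              ", M=", rec$frames, ") skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(rep_i)) gaps <- c(gaps, i) else reports[[i]] <- rep_i
  }
  ok <- !vapply(reports, is.null, logical(1))
  tab <- do.call(rbind, lapply(reports[ok], as.data.frame))
  rownames(tab) <- NULL
  structure(list(design = dataset$design, reports = reports[ok],
                 table = tab, gaps = gaps, seed = as.integer(seed)),
            class = "oct_study")
}

#' @export
print.oct_study <- function(x, ...) {
  cat(sprintf("<oct_study: %d quality reports (%d gap(s))>\n",
              length(x$reports), length(x$gaps)))
  invisible(x)
}

#' @export
summary.oct_study <- function(object, ...) {
  for (m in c("snr", "d", "dice")) {
    cat("\n==", toupper(m), "image-level mean by condition x M ==\n")
    print(summarize_curves(object, m, relative = FALSE))
  }
  invisible(object)
}

# Image-level rows of one metric as a tidy data frame.
metric_table <- function(study, measure) {
  tab <- if (is.data.frame(study)) study else study$table
  out <- tab[tab$metric == measure & tab$layer == "image",
             c("eye", "condition", "M", "value")]
  rownames(out) <- NULL
  out
}

#' Mean averaging-response curve per condition
#'
#' Aggregates image-level values of one measure over eyes into a mean
#' curve per (condition, averaging setting).  SNR and Cohen's d are
#' normalized per eye to the two-frame baseline first
#' ([relative_to_baseline()]), so curves show relative response; Dice is
#' reported raw (it is already on an absolute `[0, 1]` scale).
#'
#' @param study an `oct_study` (or its tidy `table`).
#' @param measure `"snr"`, `"d"` or `"dice"`.
#' @param relative override the per-measure default normalization.
#' @return Data frame with `condition`, `M`, `value` (mean over eyes)
#'   and `n_eyes` (eyes contributing; gaps excluded).
#' @export
summarize_curves <- function(study, measure = c("snr", "d", "dice"),
                             relative = NULL) {
  measure <- match.arg(measure)
  df <- metric_table(study, measure)
  if (nrow(df) == 0L) stop("no values for measure ", measure)
  if (is.null(relative)) relative <- measure %in% c("snr", "d")
  df <- df[!is.na(df$value), , drop = FALSE]
  if (relative) df <- relative_to_baseline(df)
  agg <- stats::aggregate(value ~ condition + M, df, mean)
  cnt <- stats::aggregate(value ~ condition + M, df, length)
  agg$n_eyes <- cnt$value
  agg[order(agg$condition, agg$M), ]
}

#' Per-eye frame-matching analysis
#'
#' For each eye, finds the smallest opaque-media ("pre") averaging
#' setting whose raw image-level value reaches at least the clear-media
#' ("post") value at the reference setting (16 frames by default).  An
#' exact tie counts as reaching the target.  Eyes for which no setting
#' suffices are reported as not matched (`m_matched = NA`).
#'
#' @param study an `oct_study` (or its tidy `table`).
#' @param measure `"snr"`, `"d"` or `"dice"`.
#' @param target_m reference clear-media setting (default 16).
#' @return Data frame with one row per eye: `eye`, `measure`,
#'   `target` (the post value matched against), `m_matched` (integer
#'   setting, `NA` = none) and `matched` (logical).
#' @export
matching_analysis <- function(study, measure = c("snr", "d", "dice"),
                              target_m = 16L) {
  measure <- match.arg(measure)
  df <- metric_table(study, measure)
  eyes <- sort(unique(df$eye))
  out <- lapply(eyes, function(e) {
    target <- df$value[df$eye == e & df$condition == "post" &
                         df$M == target_m]
    if (length(target) != 1L || is.na(target)) {
      stop("missing post M=", target_m, " value for eye ", e)
    }
    pre <- df[df$eye == e & df$condition == "pre", , drop = FALSE]
    pre <- pre[order(pre$M), , drop = FALSE]
    hit <- which(!is.na(pre$value) & pre$value >= target)
    m <- if (length(hit) > 0L) pre$M[hit[1L]] else NA_integer_
    data.frame(eye = e, measure = measure, target = target,
               m_matched = m, matched = !is.na(m))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Design bookkeeping counts
#'
#' Scan, layer and boundary counts implied by a [study_design()]: per
#' patient, scans = conditions x settings, layers = 5 per scan,
#' boundaries = 6 per scan; total annotations = per-patient boundaries
#' x number of eyes.  With the default design (7 settings, 2 visits,
#' 13 eyes) this gives 14 scans, 70 layers and 84 boundaries per patient
#' and 1092 annotations in total.
#'
#' @param design a [study_design()].
#' @return A `design_counts` object (list of the four counts).
#' @export
design_counts <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  scans <- length(design$settings) * length(design$conditions)
  structure(list(scans_per_patient = scans,
                 layers_per_patient = scans * design$n_layers,
                 boundaries_per_patient = scans * design$n_boundaries,
                 total_annotations = scans * design$n_boundaries *
                   design$n_eyes),
            class = "design_counts")
}

#' @export
print.design_counts <- function(x, ...) {
  cat(sprintf(paste0(
    "per patient: %d scans, %d layers, %d boundaries; ",
    "total annotations: %d\n"),
    x$scans_per_patient, x$layers_per_patient, x$boundaries_per_patient,
    x$total_annotations))
  invisible(x)
}
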