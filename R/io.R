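#' Read and write B-scans as 8-bit greyscale TIFF
#'
#' Scans are exported as single-channel 8-bit TIFF: intensities in
#' `[0, 1]` are scaled by 255 and rounded half-up.  Reading maps the
#' stored byte `k` back to `k / 255`, so a write/read round trip equals
#' the 8-bit quantization of the image.  A frame stack can be written as
#' a multi-page TIFF with `write_scan_tiff(stack, ...)`.
#'
#' @param img an [oct_scan()], numeric matrix, or `frame_stack`.
#' @param path file path.
#' @param ... metadata passed to [oct_scan()] on read.
#' @return `read_scan_tiff()` returns an [oct_scan()];
#'   `write_scan_tiff()` returns `path` invisibly.
#' @export
write_scan_tiff <- function(img, path) {
  quantize <- function(m) round_half_up(pmin(pmax(m, 0), 1) * 255) / 255
  if (length(dim(img)) == 3L) {
    pages <- lapply(seq_len(dim(img)[3L]),
                    function(i) quantize(img[, , i]))
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    tiff::writeTIFF(quantize(as_image(img)), path, bits.per.sample = 8L)
  }
  invisible(path)
}

#' @rdname write_scan_tiff
#' @export
read_scan_tiff <- function(path, ...) {
  img <- tiff::readTIFF(path, all = FALSE)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  oct_scan(img, ...)
}

#' Export a label raster as an 8-bit TIFF for visual inspection
#'
#' Region codes (see [region_labels()]) are spread over the 8-bit range
#' (multiplied by 32) so the layer bands are distinguishable in any
#' image viewer.
#'
#' @param mask `layer_mask` or integer label matrix.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  m <- unclass(mask)
  attr(m, "labels") <- NULL
  tiff::writeTIFF(pmin(m * 32L, 255L) / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write a simulated study dataset to disk
#'
#' Lays out one directory per dataset: averaged scans as 8-bit TIFFs
#' (`eye<e>_<condition>_M<frames>.tiff`), one boundary CSV per eye
#' (`eye<e>_boundaries.csv`), and `manifest.json` describing the design,
#' the seed and every scan record.  [read_dataset()] restores an
#' `oct_study_dataset` from such a directory (scan intensities then
#' carry the 8-bit quantization of the export).
#'
#' @param dataset an `oct_study_dataset` from [simulate_study()].
#' @param dir output directory.
#' @param overwrite allow writing into an existing dataset directory;
#'   without it an existing manifest is an error, never silently
#'   replaced.
#' @return `write_dataset()` returns `dir` invisibly; `read_dataset()`
#'   an `oct_study_dataset`.
#' @export
write_dataset <- function(dataset, dir, overwrite = FALSE) {
  stopifnot(inherits(dataset, "oct_study_dataset"))
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("dataset already exists at ", dir,
         " (use overwrite = TRUE to replace it)")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (e in dataset$eyes) {
    write_boundaries(e$boundaries,
                     file.path(dir, sprintf("eye%02d_boundaries.csv", e$eye)))
  }
  records <- lapply(dataset$scans, function(rec) {
    fname <- sprintf("eye%02d_%s_M%03d.tiff", rec$eye, rec$condition,
                     rec$frames)
    write_scan_tiff(rec$scan, file.path(dir, fname))
    list(eye = rec$eye, condition = rec$condition, frames = rec$frames,
         file = fname)
  })
  manifest <- list(
    design = list(n_eyes = dataset$design$n_eyes,
                  settings = dataset$design$settings),
    scene = list(width = dataset$scene$width, depth = dataset$scene$depth,
                 band = dataset$scene$band),
    seed = dataset$seed,
    boundaries = lapply(dataset$eyes, function(e) {
      list(eye = e$eye, file = sprintf("eye%02d_boundaries.csv", e$eye),
           acquisition_order = e$acquisition_order)
    }),
    scans = records)
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop("no manifest.json in ", dir, " - not a dataset directory")
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  design <- study_design(n_eyes = man$design$n_eyes,
                         settings = man$design$settings)
  eyes <- lapply(man$boundaries, function(b) {
    list(eye = b$eye,
         boundaries = read_boundaries(file.path(dir, b$file)),
         acquisition_order = b$acquisition_order)
  })
  eyes <- eyes[order(vapply(eyes, function(e) e$eye, 0))]
  scans <- lapply(man$scans, function(rec) {
    scan <- tryCatch(
      read_scan_tiff(file.path(dir, rec$file), eye = rec$eye,
                     condition = rec$condition, frames = rec$frames),
      error = function(e) {
        warning("could not read ", rec$file, ": ", conditionMessage(e))
        NULL
      })
    list(eye = rec$eye, condition = rec$condition,
         frames = as.integer(rec$frames), scan = scan)
  })
  scene <- scene_config(width = man$scene$width, depth = man$scene$depth,
                        band = man$scene$band)
  structure(list(design = design, scene = scene, noise = NULL,
                 seed = man$seed, eyes = eyes, scans = scans),
            class = "oct_study_dataset")
}

#' Write study results and summary reports as CSV
#'
#' `write_report_csv()` writes the tidy per-scan metric table of an
#' `oct_study`.  `write_summary_csvs()` writes, for each measure, the
#' mean averaging-response curves ([summarize_curves()]) and the per-eye
#' frame-matching analysis ([matching_analysis()]).
#'
#' @param study an `oct_study` from [run_study()].
#' @param path,dir output file / directory.
#' @param overwrite allow replacing existing files.
#' @return The written path(s), invisibly.
#' @export
write_report_csv <- function(study, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) {
    stop("output file exists: ", path, " (use overwrite = TRUE)")
  }
  utils::write.csv(study$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_report_csv
#' @export
write_summary_csvs <- function(study, dir, overwrite = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (m in c("snr", "d", "dice")) {
    p1 <- file.path(dir, paste0("curves_", m, ".csv"))
    p2 <- file.path(dir, paste0("matching_", m, ".csv"))
    for (p in c(p1, p2)) {
      if (file.exists(p) && !overwrite) {
        stop("output file exists: ", p, " (use overwrite = TRUE)")
      }
    }
    utils::write.csv(summarize_curves(study, m), p1, row.names = FALSE,
                     quote = FALSE)
    utils::write.csv(matching_analysis(study, m), p2, row.names = FALSE,
                     quote = FALSE)
    paths <- c(paths, p1, p2)
  }
  invisible(paths)
}
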