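#' Construct a B-scan object
#'
#' An `oct_scan` is a numeric image matrix (rows = axial depth, columns =
#' A-scan positions, intensities in `[0, 1]`) carrying acquisition
#' metadata: eye identifier, media condition (`"pre"` = before cataract
#' surgery i.e. opaque media, `"post"` = after i.e. clear media) and the
#' number of averaged frames.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param eye eye identifier (any scalar).
#' @param condition `"pre"`, `"post"` or `NA`.
#' @param frames number of frames averaged into this scan (`NA` if not
#'   applicable, e.g. a noise-free phantom).
#' @return An `oct_scan` object.
#' @export
oct_scan <- function(image, eye = NA, condition = NA_character_,
                     frames = NA_integer_) {
  image <- as.matrix(image)
  storage.mode(image) <- "double"
  structure(image, class = c("oct_scan", "matrix", "array"),
            meta = list(eye = eye, condition = condition,
                        frames = as.integer(frames)))
}

#' @export
print.oct_scan <- function(x, ...) {
  m <- scan_meta(x)
  cat(sprintf("<oct_scan %d x %d | eye %s | condition %s | frames %s>\n",
              nrow(x), ncol(x), as.character(m$eye), m$condition,
              as.character(m$frames)))
  invisible(x)
}

#' @rdname oct_scan
#' @param x an `oct_scan`.
#' @export
scan_meta <- function(x) {
  m <- attr(x, "meta")
  if (is.null(m)) list(eye = NA, condition = NA_character_,
                       frames = NA_integer_) else m
}

#' @export
as.matrix.oct_scan <- function(x, ...) as_image(x)

# Coerce oct_scan or plain matrix to a bare numeric matrix.
as_image <- function(x) {
  x <- unclass(x)
  attr(x, "meta") <- NULL
  as.matrix(x)
}
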