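#' Boundary annotations for a B-scan
#'
#' A `boundary_set` holds six per-column boundary curves delimiting the
#' five annotated retinal layers.  Row coordinates are 0-based, matching
#' the on-disk CSV convention: boundary value `b_k` at a column is the
#' first image row of the region lying below boundary `k`, so retinal
#' layer `k` occupies the half-open row band `[b_k, b_{k+1})` in that
#' column, and the vitreous occupies `[0, b1)`.
#'
#' @param boundaries integer matrix with 6 rows (boundaries, top to
#'   bottom) and one column per image column, 0-based row coordinates.
#' @return An object of class `boundary_set`: a list with elements
#'   `width` and `boundaries` (6 x width integer matrix with rownames
#'   `boundary_labels()`).
#' @seealso [rasterize_mask()], [read_boundaries()], [write_boundaries()]
#' @export
boundary_set <- function(boundaries) {
  boundaries <- as.matrix(boundaries)
  if (nrow(boundaries) != 6L) {
    stop("a boundary_set needs exactly 6 boundary curves, got ",
         nrow(boundaries))
  }
  storage.mode(boundaries) <- "integer"
  if (anyNA(boundaries)) stop("boundary values must be finite integers")
  if (any(boundaries < 0L)) stop("boundary rows must be >= 0")
  bad <- which(apply(boundaries, 2L, is.unsorted))
  if (length(bad) > 0L) {
    stop(sprintf(
      "boundaries cross: ordering b1 <= ... <= b6 violated first at column %d",
      bad[1L] - 1L))
  }
  dimnames(boundaries) <- list(boundary_labels(), NULL)
  structure(list(width = ncol(boundaries), boundaries = boundaries),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat(sprintf("<boundary_set: 6 boundaries x %d columns, rows %d..%d>\n",
              x$width, min(x$boundaries), max(x$boundaries)))
  invisible(x)
}

#' @export
`==.boundary_set` <- function(e1, e2) {
  isTRUE(all.equal(e1$boundaries, e2$boundaries, check.attributes = FALSE)) &&
    e1$width == e2$width
}

#' Read and write boundary annotation CSV files
#'
#' The CSV schema has columns `column_index` (0-based) and `b1` .. `b6`
#' (0-based integer image rows).  Reading validates the top-to-bottom
#' ordering invariant and reports the first offending column on failure;
#' the write/read round trip is exact.
#'
#' @param path file path.
#' @param bs a [boundary_set()].
#' @return `read_boundaries()` returns a `boundary_set`;
#'   `write_boundaries()` returns `path` invisibly.
#' @export
read_boundaries <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  needed <- c("column_index", paste0("b", 1:6))
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("boundary CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[order(df$column_index), , drop = FALSE]
  if (!identical(as.integer(df$column_index), seq_len(nrow(df)) - 1L)) {
    stop("boundary CSV column_index must enumerate 0..width-1")
  }
  b <- t(as.matrix(df[, paste0("b", 1:6)]))
  bad <- which(apply(b, 2L, is.unsorted))
  if (length(bad) > 0L) {
    stop(sprintf(
      "boundaries cross: ordering b1 <= ... <= b6 violated first at column %d",
      df$column_index[bad[1L]]))
  }
  boundary_set(b)
}

#' @rdname read_boundaries
#' @export
write_boundaries <- function(bs, path) {
  stopifnot(inherits(bs, "boundary_set"))
  df <- data.frame(column_index = seq_len(bs$width) - 1L,
                   t(bs$boundaries))
  names(df) <- c("column_index", paste0("b", 1:6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Rasterize boundary curves to a per-pixel layer mask
#'
#' Converts a [boundary_set()] into a label raster over a `depth` x
#' `width` image.  Per column, the vitreous spans rows `[0, b1)`, retinal
#' layer k spans `[b_k, b_{k+1})`, and a band of `band` rows below the
#' last boundary is labelled `SUB_ELM` (the region used as the lower
#' pseudo-neighbour of the ONL).  Remaining rows are `BACKGROUND`.  The
#' half-open convention guarantees the labels partition the image with no
#' double counting.
#'
#' @param bs a [boundary_set()].
#' @param depth image depth (number of rows).
#' @param band height in rows of the sub-ELM band (default 20).
#' @return A `layer_mask`: an integer matrix (`depth` x `width`) of
#'   [region_labels()] codes with the label map stored in
#'   `attr(, "labels")`.
#' @export
rasterize_mask <- function(bs, depth, band = 20L) {
  stopifnot(inherits(bs, "boundary_set"), depth >= 1L, band >= 1L)
  b <- bs$boundaries
  if (any(b >= depth)) {
    stop("boundary rows must lie in [0, depth)")
  }
  if (any(b[6L, ] + band > depth)) {
    warning("sub-ELM band truncated at image bottom (b6 + band > depth)")
  }
  labs <- region_labels()
  # 0-based row index of every pixel, column-major like the image matrix
  row0 <- matrix(seq_len(depth) - 1L, nrow = depth, ncol = bs$width)
  mask <- matrix(labs[["BACKGROUND"]], nrow = depth, ncol = bs$width)
  upper <- matrix(rep(b[1L, ], each = depth), nrow = depth)
  mask[row0 < upper] <- labs[["VITREOUS"]]
  layer_names <- layer_labels()
  for (k in 1:5) {
    lo <- matrix(rep(b[k, ], each = depth), nrow = depth)
    hi <- matrix(rep(b[k + 1L, ], each = depth), nrow = depth)
    mask[row0 >= lo & row0 < hi] <- labs[[layer_names[k]]]
  }
  lo <- matrix(rep(b[6L, ], each = depth), nrow = depth)
  mask[row0 >= lo & row0 < lo + band] <- labs[["SUB_ELM"]]
  structure(mask, labels = labs, class = c("layer_mask", class(mask)))
}

#' Extract the grey values of one labelled region
#'
#' Returns the multiset of pixel intensities carrying `label` in the
#' mask, i.e. the sample over which per-layer statistics (mean, standard
#' deviation, pixel count) are computed.
#'
#' @param img numeric image matrix.
#' @param mask a `layer_mask` from [rasterize_mask()], same shape as `img`.
#' @param label region name, one of `names(region_labels())`.
#' @return Numeric vector of grey values; its length is the region pixel
#'   count.  An empty region is an error (it signals a degenerate
#'   annotation).
#' @export
layer_pixels <- function(img, mask, label) {
  img <- as_image(img)
  if (!all(dim(img) == dim(mask))) stop("image and mask shapes differ")
  code <- region_labels()[[label]]
  if (is.null(code)) stop("unknown region label: ", label)
  v <- img[unclass(mask) == code]
  if (length(v) == 0L) {
    stop("region '", label, "' is empty in this mask")
  }
  v
}
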