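#' Region labels used throughout octqc
#'
#' The annotated portion of a B-scan is divided into five retinal layers
#' (NFL, the GCL+IPL composite, INL, OPL, ONL) delimited by six boundary
#' curves, flanked above by the vitreous and below by a fixed-height band
#' under the external limiting membrane (ELM).  Rows below that band carry
#' an explicit background label so a layer mask is always a full partition
#' of the image.
#'
#' @return `region_labels()` returns a named integer vector mapping label
#'   names to mask codes; `layer_labels()` returns the five retinal layer
#'   names in anatomical top-to-bottom order; `boundary_labels()` the six
#'   boundary names; `region_sequence()` the full top-to-bottom ordering of
#'   regions used to resolve above/below neighbours.
#' @examples
#' region_labels()
#' layer_labels()
#' @export
region_labels <- function() {
  c(VITREOUS = 0L, NFL = 1L, GCL_IPL = 2L, INL = 3L, OPL = 4L, ONL = 5L,
    SUB_ELM = 6L, BACKGROUND = 7L)
}

#' @rdname region_labels
#' @export
layer_labels <- function() {
  c("NFL", "GCL_IPL", "INL", "OPL", "ONL")
}

#' @rdname region_labels
#' @export
boundary_labels <- function() {
  c("VITREOUS_NFL", "NFL_GCL", "IPL_INL", "INL_OPL", "OPL_ONL", "ONL_ELM")
}

#' @rdname region_labels
#' @export
region_sequence <- function() {
  c("VITREOUS", layer_labels(), "SUB_ELM")
}

# Above/below neighbours of a retinal layer in the anatomical sequence;
# the vitreous and sub-ELM band act as pseudo-neighbours of NFL and ONL.
layer_neighbors <- function(label) {
  seq_regions <- region_sequence()
  i <- match(label, seq_regions)
  if (is.na(i) || label %in% c("VITREOUS", "SUB_ELM")) {
    stop("not a retinal layer label: ", label)
  }
  list(above = seq_regions[i - 1L], below = seq_regions[i + 1L])
}
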