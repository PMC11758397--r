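#' Neuron morphology as a validated SWC node table
#'
#' Coordinate convention throughout the package: `x` = lateral position
#' (um), `y` = cortical depth (um, 0 at the pia, increasing toward the
#' white matter), `z` = slice-depth axis (um). Type codes follow SWC:
#' 1 soma, 2 axon, 3 basal dendrite, 4 apical dendrite.
#'
#' @param nodes Data frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent` (1-based ids, root parent -1, parents precede
#'   children).
#' @return An object of class `neuron_morphology` (a data frame).
#' @export
neuron_morphology <- function(nodes) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes))) {
    stop("node table lacks columns: ",
         paste(setdiff(need, names(nodes)), collapse = ", "), call. = FALSE)
  }
  nodes <- as.data.frame(nodes)[need]
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (!all(nodes$type %in% 1:4)) {
    stop("unknown SWC type code(s): ",
         paste(unique(setdiff(nodes$type, 1:4)), collapse = ", "),
         call. = FALSE)
  }
  if (any(nodes$radius < 0)) stop("negative radius", call. = FALSE)
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1L) {
    stop("exactly one root node (parent = -1) required, found ",
         length(roots), call. = FALSE)
  }
  pos <- match(nodes$parent, nodes$id)
  nonroot <- nodes$parent != -1
  if (anyNA(pos[nonroot])) {
    stop("orphan node(s): parent id not present", call. = FALSE)
  }
  if (any(pos[nonroot] >= seq_len(nrow(nodes))[nonroot])) {
    bad <- nodes$id[nonroot][which(pos[nonroot] >= seq_len(nrow(nodes))[nonroot])[1]]
    stop("node ", bad, ": parent appears after child (cycle or bad order)",
         call. = FALSE)
  }
  class(nodes) <- c("neuron_morphology", "data.frame")
  nodes
}

#' Read a morphology from an SWC file
#'
#' Standard 7-column SWC: `id type x y z radius parent`, `#` comments.
#'
#' @param path SWC file path.
#' @return A [neuron_morphology()].
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty SWC file: ", path, call. = FALSE)
  mat <- utils::read.table(text = lines)
  if (ncol(mat) != 7L) {
    stop("SWC file must have 7 columns, found ", ncol(mat), call. = FALSE)
  }
  names(mat) <- c("id", "type", "x", "y", "z", "radius", "parent")
  neuron_morphology(mat)
}

#' Write a morphology to an SWC file
#' @param m A [neuron_morphology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  stopifnot(inherits(m, "neuron_morphology"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# SWC written by l6ephys (id type x y z radius parent)", con)
  utils::write.table(as.data.frame(m), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cortical layer context for a reconstructed neuron
#'
#' @param wm_depth_um Pia-to-white-matter distance (um); pia is depth 0.
#' @param layer_boundaries_um Named numeric vector of lower boundaries
#'   (um) for `L4`, `L5`, `L6a`, `L6b`; strictly increasing, the last
#'   equal to `wm_depth_um`.
#' @param barrel_center_x_um Lateral position of the home barrel center
#'   (um) in the reconstruction frame.
#' @param slice_thickness_um Slice thickness along z (um).
#' @return An object of class `layer_context`.
#' @export
layer_context <- function(wm_depth_um = 1850,
                          layer_boundaries_um = c(L4 = 950, L5 = 1300,
                                                  L6a = 1665, L6b = 1850),
                          barrel_center_x_um = 0,
                          slice_thickness_um = 350) {
  if (wm_depth_um <= 0) stop("wm_depth_um must be > 0", call. = FALSE)
  b <- layer_boundaries_um
  if (any(diff(b) <= 0) || any(b <= 0) || max(b) > wm_depth_um + 1e-9) {
    stop("layer boundaries must be strictly increasing and <= wm depth",
         call. = FALSE)
  }
  structure(list(
    pia_depth_um = 0,
    wm_depth_um = wm_depth_um,
    layer_boundaries_um = b,
    barrel_center_x_um = barrel_center_x_um,
    slice_thickness_um = slice_thickness_um
  ), class = "layer_context")
}
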