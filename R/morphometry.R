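#' Correct a reconstruction for tissue shrinkage
#'
#' In-plane coordinates (x, y: the cutting plane containing the pia-WM
#' axis) are scaled by `f_xy`; the slice-depth coordinate z by `f_z`.
#' Radii are unchanged.
#'
#' @param m A [neuron_morphology()].
#' @param f_xy In-plane correction factor (nominally 1.1).
#' @param f_z Slice-depth correction factor (nominally 2.1).
#' @return Corrected [neuron_morphology()].
#' @export
shrinkage_correct <- function(m, f_xy = 1.1, f_z = 2.1) {
  stopifnot(inherits(m, "neuron_morphology"), f_xy > 0, f_z > 0)
  m$x <- m$x * f_xy
  m$y <- m$y * f_xy
  m$z <- m$z * f_z
  m
}

#' Normalise a reconstruction to a reference cortical thickness
#'
#' Depth coordinates (pia-WM axis) are scaled by
#' `target_thickness / ctx$wm_depth_um`; lateral and slice-depth
#' coordinates are unchanged; the layer boundaries scale identically, so
#' relative depths are preserved exactly.
#'
#' @param m A [neuron_morphology()].
#' @param ctx The neuron's [layer_context()].
#' @param target_thickness_um Reference pia-WM thickness (um).
#' @return List with scaled `morphology` and `ctx`.
#' @export
normalize_thickness <- function(m, ctx, target_thickness_um) {
  stopifnot(inherits(m, "neuron_morphology"), inherits(ctx, "layer_context"))
  if (target_thickness_um <= 0) {
    stop("target thickness must be > 0", call. = FALSE)
  }
  s <- target_thickness_um / ctx$wm_depth_um
  m$y <- m$y * s
  ctx2 <- layer_context(
    wm_depth_um = ctx$wm_depth_um * s,
    layer_boundaries_um = ctx$layer_boundaries_um * s,
    barrel_center_x_um = ctx$barrel_center_x_um,
    slice_thickness_um = ctx$slice_thickness_um
  )
  list(morphology = m, ctx = ctx2)
}

# number of children per node, in node order
child_counts <- function(m) {
  cc <- integer(nrow(m))
  pidx <- match(m$parent[m$parent != -1], m$id)
  tab <- table(pidx)
  cc[as.integer(names(tab))] <- as.integer(tab)
  cc
}

#' Morphometric parameters of a corrected, normalised reconstruction
#'
#' Total cable length per compartment is the sum of parent-child
#' Euclidean segment lengths (segments typed by the child node). A
#' branch is an unbranched section between soma, bifurcation and
#' termination points, counted as the number of nodes of the type whose
#' child count differs from one — a convention invariant under insertion
#' of continuation nodes. Horizontal field spans are the lateral
#' (max - min) extent of the compartment's nodes. Soma perimeter and
#' area are those of the circle with the soma node's radius in the
#' cutting plane. Compartments absent from the cell (e.g. no apical
#' dendrite on a multipolar neuron) yield `NA` fields and a flag.
#'
#' @param m A [neuron_morphology()] (already shrinkage-corrected and
#'   thickness-normalised).
#' @param ctx The matching [layer_context()].
#' @return One-row data frame with the soma, dendritic and axonal
#'   parameters; attribute `flags` lists absent compartments.
#' @export
morphometrics <- function(m, ctx) {
  stopifnot(inherits(m, "neuron_morphology"), inherits(ctx, "layer_context"))
  soma <- m[m$type == 1, ][1, ]
  segs <- segment_lengths(m)
  cc <- child_counts(m)
  flags <- character(0)

  type_stats <- function(types) {
    nodes <- m[m$type %in% types & m$type != 1, ]
    if (nrow(nodes) == 0L) {
      return(list(total = NA_real_, span = NA_real_, branches = NA_integer_,
                  absent = TRUE))
    }
    sel <- segs$type %in% types
    list(
      total = sum(segs$length_um[sel]),
      span = max(nodes$x) - min(nodes$x),
      branches = sum(cc[m$type %in% types] != 1L),
      absent = FALSE
    )
  }
  ax <- type_stats(2)
  ba <- type_stats(3)
  ap <- type_stats(4)
  de <- type_stats(c(3, 4))
  if (ap$absent) flags <- c(flags, "no_apical_dendrite")
  if (ax$absent) flags <- c(flags, "no_axon")
  if (ba$absent) flags <- c(flags, "no_basal_dendrite")

  # basal stems: type-3 children of the soma
  pidx <- match(m$parent, m$id)
  n_basal_stems <- sum(m$type == 3 & !is.na(pidx) & m$type[pidx] == 1)

  out <- data.frame(
    soma_depth_um = soma$y,
    relative_depth = soma$y / ctx$wm_depth_um,
    soma_perimeter_um = 2 * pi * soma$radius,
    soma_area_um2 = pi * soma$radius^2,
    n_apical_branches = ap$branches,
    apical_total_length_um = ap$total,
    n_basal_dendrites = n_basal_stems,
    n_basal_branches = ba$branches,
    basal_total_length_um = ba$total,
    dendritic_field_span_um = de$span,
    n_dendritic_branches = de$branches,
    dendritic_total_length_um = de$total,
    axonal_field_span_um = ax$span,
    n_axonal_branches = ax$branches,
    axonal_total_length_um = ax$total
  )
  attr(out, "flags") <- flags
  out
}
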