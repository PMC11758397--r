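#' Generate a synthetic layer-6 morphology archetype
#'
#' Builds an SWC-valid stochastic tree emulating the three reconstruction
#' classes seen in deep cortex: upright pyramidal cells with the apical
#' dendrite oriented toward the pia, inverted pyramidal cells with the
#' apical trunk pointing toward the white matter, and multipolar spiny
#' neurons without an apical dendrite. Branch paths are random walks with
#' directional persistence; totals are bookkept exactly from the node
#' table (sum of parent-child Euclidean segment lengths), giving every
#' generated cell a ground-truth cable length per compartment type.
#'
#' @param archetype One of `"upright_pc"`, `"inverted_pc"`, `"multipolar"`.
#' @param layer_ctx A [layer_context()].
#' @param seed RNG seed.
#' @param soma_depth_um Soma depth (um); default depends on archetype
#'   (upright cells sit in upper L6, inverted/multipolar cells in deep L6).
#' @param soma_lateral_um Lateral soma offset from the barrel center (um).
#' @return List with `morphology` ([neuron_morphology()]) and
#'   `ground_truth` (list: `total_length_um` named by compartment,
#'   `soma_depth_um`, `soma_xyz_um`, `tuft_depth_band_um` for cells with
#'   an apical tuft, `archetype`).
#' @export
generate_morphology <- function(archetype = c("upright_pc", "inverted_pc",
                                              "multipolar"),
                                layer_ctx = layer_context(), seed = 1L,
                                soma_depth_um = NULL, soma_lateral_um = NULL) {
  archetype <- match.arg(archetype)
  set.seed(seed)
  wm <- layer_ctx$wm_depth_um
  if (is.null(soma_depth_um)) {
    soma_depth_um <- switch(archetype,
      upright_pc = 0.78 * wm + stats::rnorm(1, 0, 0.02 * wm),
      inverted_pc = 0.92 * wm + stats::rnorm(1, 0, 0.015 * wm),
      multipolar = 0.92 * wm + stats::rnorm(1, 0, 0.015 * wm))
    soma_depth_um <- min(max(soma_depth_um, 0.6 * wm), wm - 40)
  }
  if (is.null(soma_lateral_um)) {
    soma_lateral_um <- stats::rnorm(1, 0, 40)
  }
  soma_x <- layer_ctx$barrel_center_x_um + soma_lateral_um

  env <- new.env()
  env$nodes <- vector("list", 4096)
  env$n <- 0L
  add_node <- function(type, x, y, z, radius, parent) {
    env$n <- env$n + 1L
    env$nodes[[env$n]] <- c(env$n, type, x, y, z, radius, parent)
    env$n
  }
  unitv <- function(v) v / sqrt(sum(v^2))
  # random walk with directional persistence; y reflected into [2, wm - 2]
  grow_path <- function(parent, dir, total_len, type, step = 15,
                        wiggle = 0.15, radius = 0.5) {
    pos <- env$nodes[[parent]][3:5]
    dir <- unitv(dir)
    remaining <- total_len
    id <- parent
    while (remaining > 1e-9) {
      s <- min(step, remaining)
      dir <- unitv(dir + stats::rnorm(3, 0, wiggle))
      nxt <- pos + dir * s
      if (nxt[2] < 2) { nxt[2] <- 4 - nxt[2]; dir[2] <- -dir[2] }
      if (nxt[2] > wm - 2) { nxt[2] <- 2 * (wm - 2) - nxt[2]; dir[2] <- -dir[2] }
      # reflection changes the step length; re-place at exact distance s
      nxt <- pos + unitv(nxt - pos) * s
      id <- add_node(type, nxt[1], nxt[2], nxt[3], radius, id)
      pos <- nxt
      remaining <- remaining - s
    }
    id
  }
  rand_lateral_dir <- function(y_comp = 0) {
    th <- stats::runif(1, 0, 2 * pi)
    unitv(c(cos(th), y_comp, sin(th)))
  }

  soma_r <- stats::runif(1, 6, 9)
  soma <- add_node(1, soma_x, soma_depth_um, 0, soma_r, -1)

  tuft_band <- NULL
  if (archetype != "multipolar") {
    up <- archetype == "upright_pc"
    tuft_depth <- if (up) {
      max(0.45 * soma_depth_um, soma_depth_um - stats::runif(1, 500, 700))
    } else {
      min(wm - 60, soma_depth_um + stats::runif(1, 80, 130))
    }
    trunk_len <- abs(soma_depth_um - tuft_depth) * 1.05
    trunk_dir <- c(0, if (up) -1 else 1, 0)
    # trunk with oblique side branches
    n_obl <- sample(3:5, 1)
    seg <- trunk_len / (n_obl + 1)
    tip <- soma
    for (i in seq_len(n_obl + 1)) {
      tip <- grow_path(tip, trunk_dir, seg, type = 4, wiggle = 0.05,
                       radius = 1.2)
      if (i <= n_obl) {
        grow_path(tip, rand_lateral_dir(stats::runif(1, -0.3, 0.3)),
                  stats::runif(1, 80, 150), type = 4, wiggle = 0.3)
      }
    }
    tuft_y <- env$nodes[[tip]][4]
    for (j in seq_len(sample(4:6, 1))) {
      grow_path(tip, rand_lateral_dir(if (up) stats::runif(1, -0.6, -0.1)
                                      else stats::runif(1, 0.1, 0.6)),
                stats::runif(1, 100, 160), type = 4, wiggle = 0.3)
    }
    tuft_band <- sort(c(tuft_y - 160, tuft_y + 40))
  }

  n_basal <- sample(5:8, 1)
  for (j in seq_len(n_basal)) {
    stem <- grow_path(soma, rand_lateral_dir(stats::runif(1, -0.5, 0.5)),
                      stats::runif(1, 60, 110), type = 3, wiggle = 0.25,
                      radius = 0.8)
    for (k in seq_len(sample(1:2, 1))) {
      grow_path(stem, rand_lateral_dir(stats::runif(1, -0.5, 0.5)),
                stats::runif(1, 60, 140), type = 3, wiggle = 0.3)
    }
  }

  # axon: descending main branch plus lateral collaterals
  ax_main_len <- max(wm - soma_depth_um - 30, 150)
  ax_tip <- soma
  n_coll <- sample(4:6, 1)
  seg <- ax_main_len / n_coll
  for (i in seq_len(n_coll)) {
    ax_tip <- grow_path(ax_tip, c(0, 1, 0), seg, type = 2, wiggle = 0.1,
                        radius = 0.4)
    grow_path(ax_tip, rand_lateral_dir(stats::runif(1, -0.4, 0.2)),
              stats::runif(1, 250, 500), type = 2, wiggle = 0.25,
              radius = 0.4)
  }

  nodes <- as.data.frame(do.call(rbind, env$nodes[seq_len(env$n)]))
  names(nodes) <- c("id", "type", "x", "y", "z", "radius", "parent")
  m <- neuron_morphology(nodes)

  seg_len <- segment_lengths(m)
  tot <- tapply(seg_len$length_um, factor(seg_len$type, levels = 1:4),
                sum, default = 0)
  total <- c(axon = unname(tot[2]), basal = unname(tot[3]),
             apical = unname(tot[4]))
  list(
    morphology = m,
    ground_truth = list(
      total_length_um = c(total, dendritic = unname(total["basal"] +
                                                      total["apical"])),
      soma_depth_um = soma_depth_um,
      soma_xyz_um = c(x = soma_x, y = soma_depth_um, z = 0),
      tuft_depth_band_um = tuft_band,
      archetype = archetype
    )
  )
}

#' Parent-child segment table of a morphology
#'
#' One row per non-root node: the segment from its parent, typed by the
#' child node, with its Euclidean length.
#'
#' @param m A [neuron_morphology()].
#' @return Data frame with endpoint coordinates, `type`, `length_um`.
#' @export
segment_lengths <- function(m) {
  stopifnot(inherits(m, "neuron_morphology"))
  child <- m[m$parent != -1, , drop = FALSE]
  pidx <- match(child$parent, m$id)
  data.frame(
    x0 = m$x[pidx], y0 = m$y[pidx], z0 = m$z[pidx],
    x1 = child$x, y1 = child$y, z1 = child$z,
    type = child$type,
    length_um = sqrt((child$x - m$x[pidx])^2 +
                     (child$y - m$y[pidx])^2 +
                     (child$z - m$z[pidx])^2)
  )
}
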