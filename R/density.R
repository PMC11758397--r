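#' Construct a density-map object
#'
#' A voxel grid holding cable length (um) per voxel. The origin is the
#' minimum-corner of the grid in the map's frame; voxel `[i, j, k]`
#' covers `origin + ((i,j,k) - 1) * edge` to `origin + (i,j,k) * edge`.
#'
#' @param values 3D numeric array (x, y, z order).
#' @param origin_um Length-3 grid corner (um).
#' @param voxel_edge_um Voxel edge (um), nominally 50.
#' @param frame `"soma_centered"` or `"barrel_centered"`.
#' @param compartment Label (e.g. `"axon"`, `"dendrite"`).
#' @param n_neurons Number of neurons averaged into the map.
#' @return An object of class `density_map`.
#' @export
density_map <- function(values, origin_um, voxel_edge_um = 50,
                        frame = "barrel_centered", compartment = "all",
                        n_neurons = 1L) {
  stopifnot(length(dim(values)) == 3L, length(origin_um) == 3L,
            voxel_edge_um > 0, all(values >= 0))
  structure(list(values = values, origin_um = as.numeric(origin_um),
                 voxel_edge_um = voxel_edge_um, frame = frame,
                 compartment = compartment, n_neurons = as.integer(n_neurons)),
            class = "density_map")
}

#' Total cable length held in a map (um)
#' @param map A [density_map()].
#' @return Sum of all voxel values.
#' @export
map_total <- function(map) sum(map$values)

#' Voxelize a morphology into a cable-length density map
#'
#' Each parent-child segment's length is apportioned to voxels by exact
#' parametric clipping of the segment against the voxel boundary planes,
#' so total length is conserved to machine precision. The grid covers
#' the morphology and auto-sizes to it (segments are never truncated).
#'
#' Frames: `"soma_centered"` places the soma at the origin (0, 0, 0);
#' `"barrel_centered"` places the lateral origin at the barrel center,
#' keeps the absolute cortical depth (pia = 0), and centers z on the
#' soma, so soma-centered per-neuron maps are translated by the stored
#' soma-to-barrel offset for group alignment.
#'
#' @param m A [neuron_morphology()] (corrected and normalised).
#' @param ctx The matching [layer_context()].
#' @param voxel_edge_um Voxel edge (um).
#' @param frame Target frame.
#' @param compartment `"axon"`, `"basal"`, `"apical"`, `"dendrite"`
#'   (basal + apical) or `"all"` (everything but the soma).
#' @return A [density_map()].
#' @export
voxelize <- function(m, ctx, voxel_edge_um = 50,
                     frame = c("barrel_centered", "soma_centered"),
                     compartment = c("all", "axon", "basal", "apical",
                                     "dendrite")) {
  frame <- match.arg(frame)
  compartment <- match.arg(compartment)
  types <- switch(compartment,
                  all = 2:4, axon = 2, basal = 3, apical = 4,
                  dendrite = c(3, 4))
  segs <- segment_lengths(m)
  segs <- segs[segs$type %in% types & segs$length_um > 0, , drop = FALSE]
  if (nrow(segs) == 0L) stop("no segments of compartment '", compartment,
                             "' in morphology", call. = FALSE)
  soma <- m[m$type == 1, ][1, ]
  shift <- if (frame == "soma_centered") {
    c(soma$x, soma$y, soma$z)
  } else {
    c(ctx$barrel_center_x_um, 0, soma$z)
  }
  p0 <- cbind(segs$x0 - shift[1], segs$y0 - shift[2], segs$z0 - shift[3])
  p1 <- cbind(segs$x1 - shift[1], segs$y1 - shift[2], segs$z1 - shift[3])

  e <- voxel_edge_um
  lo <- floor(pmin(apply(p0, 2, min), apply(p1, 2, min)) / e) * e
  hi <- ceiling(pmax(apply(p0, 2, max), apply(p1, 2, max)) / e + 1e-12) * e
  dims <- pmax(as.integer(round((hi - lo) / e)), 1L)
  vals <- array(0, dims)

  for (s in seq_len(nrow(segs))) {
    a <- p0[s, ]; b <- p1[s, ]
    len <- segs$length_um[s]
    # parametric crossings of voxel boundary planes on each axis
    ts <- c(0, 1)
    for (ax in 1:3) {
      if (b[ax] != a[ax]) {
        k0 <- ceiling(min(a[ax], b[ax]) / e)
        k1 <- floor(max(a[ax], b[ax]) / e)
        if (k1 >= k0) {
          planes <- (k0:k1) * e
          ts <- c(ts, (planes - a[ax]) / (b[ax] - a[ax]))
        }
      }
    }
    ts <- sort(unique(pmin(pmax(ts, 0), 1)))
    mid <- (ts[-length(ts)] + ts[-1]) / 2
    seg_frac <- diff(ts)
    pts <- outer(mid, b - a) + matrix(a, length(mid), 3, byrow = TRUE)
    idx <- floor(sweep(pts, 2, lo, "-") / e) + 1L
    idx[, 1] <- pmin(pmax(idx[, 1], 1L), dims[1])
    idx[, 2] <- pmin(pmax(idx[, 2], 1L), dims[2])
    idx[, 3] <- pmin(pmax(idx[, 3], 1L), dims[3])
    flat <- idx[, 1] + (idx[, 2] - 1L) * dims[1] +
      (idx[, 3] - 1L) * dims[1] * dims[2]
    add <- tapply(seg_frac * len, flat, sum)
    vals[as.integer(names(add))] <- vals[as.integer(names(add))] + add
  }
  density_map(vals, lo, e, frame, compartment, 1L)
}

# pad/translate a map onto a union grid defined by (origin, dims)
embed_map <- function(map, origin, dims) {
  out <- array(0, dims)
  off <- as.integer(round((map$origin_um - origin) / map$voxel_edge_um))
  d <- dim(map$values)
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]),
      off[3] + seq_len(d[3])] <- map$values
  out
}

#' Average density maps across a group
#'
#' Grids are unioned with zero padding (all maps must share voxel edge
#' and frame), then averaged voxel-wise.
#'
#' @param maps List of [density_map()]s.
#' @return A [density_map()] with `n_neurons = length(maps)`.
#' @export
average_group <- function(maps) {
  stopifnot(length(maps) >= 1L)
  e <- maps[[1]]$voxel_edge_um
  fr <- maps[[1]]$frame
  for (mp in maps) {
    if (mp$voxel_edge_um != e) stop("mixed voxel edges", call. = FALSE)
    if (mp$frame != fr) stop("mixed frames", call. = FALSE)
  }
  orig <- do.call(rbind, lapply(maps, function(mp) mp$origin_um))
  ends <- do.call(rbind, lapply(maps, function(mp) {
    mp$origin_um + dim(mp$values) * e
  }))
  o <- apply(orig, 2, min)
  dims <- as.integer(round((apply(ends, 2, max) - o) / e))
  acc <- array(0, dims)
  for (mp in maps) acc <- acc + embed_map(mp, o, dims)
  density_map(acc / length(maps), o, e, fr, maps[[1]]$compartment,
              length(maps))
}

# symmetric 1D convolution by FFT-free open convolution, trimmed to size
conv1d <- function(v, kern) {
  K <- (length(kern) - 1L) / 2L
  out <- stats::convolve(c(rep(0, K), v, rep(0, K)), rev(kern),
                         type = "open")
  out[(2 * K + 1):(2 * K + length(v))]
}

#' Gaussian-smooth a density map
#'
#' 3D Gaussian convolution (separable, kernel truncated at 4 sigma and
#' renormalised to unit sum) on a grid padded by 4 sigma, so total cable
#' length is conserved.
#'
#' @param map A [density_map()].
#' @param sigma_um Kernel SD (um), nominally 50.
#' @return Smoothed [density_map()] (grid enlarged by the padding).
#' @export
smooth_map <- function(map, sigma_um = 50) {
  stopifnot(sigma_um > 0)
  e <- map$voxel_edge_um
  K <- max(1L, as.integer(ceiling(4 * sigma_um / e)))
  kern <- stats::dnorm((-K:K) * e, sd = sigma_um)
  kern <- kern / sum(kern)
  d <- dim(map$values)
  dims <- d + 2L * K
  arr <- array(0, dims)
  arr[K + seq_len(d[1]), K + seq_len(d[2]), K + seq_len(d[3])] <- map$values
  for (ax in 1:3) {
    arr <- apply(arr, setdiff(1:3, ax), conv1d, kern = kern)
    # apply collapses the convolved axis to dim 1; restore order
    arr <- aperm(arr, order(c(ax, setdiff(1:3, ax))))
  }
  density_map(pmax(arr, 0), map$origin_um - K * e, e, map$frame,
              map$compartment, map$n_neurons)
}

#' Percentile threshold and isosurface mask
#'
#' The threshold is the `pct`-th percentile (linear interpolation) of
#' the strictly positive voxel values — the zero background is excluded
#' so sparse maps do not trivially threshold at 0 — and the mask marks
#' voxels at or above it.
#'
#' @param map A [density_map()].
#' @param pct Percentile (0-100), nominally 80.
#' @return List with `threshold` and `mask` (logical array).
#' @export
percentile_threshold <- function(map, pct = 80) {
  v <- map$values[map$values > 0]
  if (length(v) == 0L) stop("all-zero density map", call. = FALSE)
  thr <- unname(stats::quantile(v, pct / 100, type = 7))
  list(threshold = thr, mask = map$values >= thr)
}

#' Project a density map to 2D or 1D
#'
#' `"2d_slab"` sums along the slice-depth (z) axis, returning a lateral
#' x depth matrix. `"1d_depth"` sums over both lateral axes and reports
#' cable length against cortical depth, with the coordinate origin
#' shifted to the L6/WM border and increasing toward the pia.
#'
#' @param map A [density_map()] in the barrel-centered frame.
#' @param target `"2d_slab"` or `"1d_depth"`.
#' @param ctx A [layer_context()] supplying the L6/WM border depth (only
#'   needed for `"1d_depth"`).
#' @return For 2D, a matrix with `x_um`/`depth_um` dimnames-friendly
#'   attributes; for 1D, a data frame with `depth_um` (relative to the
#'   WM border, positive toward the pia) and `length_um`.
#' @export
project_map <- function(map, target = c("2d_slab", "1d_depth"),
                        ctx = NULL) {
  target <- match.arg(target)
  e <- map$voxel_edge_um
  if (target == "2d_slab") {
    out <- apply(map$values, c(1, 2), sum)
    attr(out, "x_um") <- map$origin_um[1] + (seq_len(dim(out)[1]) - 0.5) * e
    attr(out, "depth_um") <- map$origin_um[2] +
      (seq_len(dim(out)[2]) - 0.5) * e
    return(out)
  }
  if (is.null(ctx)) stop("1d_depth projection needs a layer_context",
                         call. = FALSE)
  prof <- apply(map$values, 2, sum)
  depth <- map$origin_um[2] + (seq_along(prof) - 0.5) * e
  data.frame(depth_um = ctx$wm_depth_um - depth, length_um = prof)
}
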