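#' Density-based clustering of fixation points (DBSCAN)
#'
#' A self-contained, deterministic DBSCAN. A point is a core point when its
#' closed eps-neighbourhood (including the point itself) contains at least
#' `min_pts` points. Clusters are the sets of points density-reachable from
#' core points; points reachable from no core point are noise (label 0).
#'
#' Determinism: points are visited in scan order sorted by `(x, y, input
#' index)`, and a border point reachable from several clusters is assigned to
#' the cluster whose core point reaches it first in that order. Cluster ids
#' are numbered in order of creation; the partition of points into clusters
#' and noise is invariant under permutations of the input (only ids change).
#'
#' @param points two-column matrix or data.frame of (x, y) coordinates.
#' @param eps neighbourhood radius in pixels (> 0).
#' @param min_pts core-point threshold (>= 1), counting the point itself.
#' @param diameter how the `optimal_diameter` field is filled: `"eps"` (the
#'   radius used, the density scale) or `"mean_cluster"` (mean over clusters
#'   of the maximal within-cluster pairwise distance).
#' @return object of class `cluster_result`: `labels` (integer per input
#'   point, 0 = noise), `eps`, `min_pts`, `cluster_diameters`,
#'   `optimal_diameter`.
#' @export
dbscan_cluster <- function(points, eps, min_pts,
                           diameter = c("eps", "mean_cluster")) {
  diameter <- match.arg(diameter)
  pts <- .as_points(points)
  n <- nrow(pts)
  if (n < 1L) stop("empty point set")
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0) {
    stop("eps must be a single positive number")
  }
  if (min_pts < 1L) stop("min_pts must be >= 1")

  scan <- order(pts[, 1], pts[, 2], seq_len(n))
  x <- pts[scan, 1]; y <- pts[scan, 2]
  eps2 <- eps^2
  neighbours <- function(i) which((x - x[i])^2 + (y - y[i])^2 <= eps2)
  # neighbourhood sizes in one pass (O(n^2), fine at fixation-cloud scale)
  nb_count <- integer(n)
  for (i in seq_len(n)) nb_count[i] <- sum((x - x[i])^2 + (y - y[i])^2 <= eps2)
  core <- nb_count >= min_pts

  labels <- integer(n)           # 0 = noise (or not yet claimed)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(neighbours(i), i)
    while (length(queue)) {
      j <- queue[1L]; queue <- queue[-1L]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) {
          nb <- neighbours(j)
          queue <- c(queue, nb[labels[nb] == 0L])
        }
      }
    }
  }

  out_labels <- integer(n)
  out_labels[scan] <- labels
  diams <- if (cl > 0L) vapply(seq_len(cl), function(k) {
    idx <- which(labels == k)
    if (length(idx) < 2L) return(0)
    max(stats::dist(cbind(x[idx], y[idx])))
  }, numeric(1)) else numeric(0)
  opt <- switch(diameter,
                eps = eps,
                mean_cluster = if (length(diams) && any(diams > 0)) {
                  mean(diams[diams > 0])
                } else {
                  warning("no multi-point cluster; optimal_diameter falls back to eps")
                  eps
                })
  structure(list(labels = out_labels, eps = eps, min_pts = as.integer(min_pts),
                 cluster_diameters = diams, optimal_diameter = opt),
            class = "cluster_result")
}

.as_points <- function(points) {
  pts <- as.matrix(points)
  if (!is.numeric(pts) || ncol(pts) != 2L) {
    stop("points must be a two-column numeric matrix of (x, y)")
  }
  pts
}

#' Select the DBSCAN radius from the k-distance curve
#'
#' Computes, for every point, the distance to its `min_pts`-th nearest
#' neighbour (excluding the point itself), sorts these distances, and returns
#' the value at the knee of the curve — the point of maximum perpendicular
#' deviation from the chord joining the curve's endpoints. On a flat curve
#' (uniform density) any value of the plateau is acceptable and the first
#' index is returned. Deterministic for fixed input.
#'
#' @param points two-column matrix of (x, y).
#' @param min_pts neighbour rank used for the curve (default 5).
#' @param max_points cap on the number of points entering the all-pairs
#'   distance computation; larger clouds are thinned deterministically
#'   (every k-th point in (x, y) scan order). Memory guard only.
#' @return the selected radius eps, in pixels.
#' @export
select_epsilon <- function(points, min_pts = 5L, max_points = 4000L) {
  pts <- .as_points(points)
  n <- nrow(pts)
  if (n < min_pts + 1L) stop("need at least min_pts + 1 points")
  if (n > max_points) {
    ord <- order(pts[, 1], pts[, 2])
    keep <- ord[seq(1L, n, length.out = max_points)]
    pts <- pts[sort(keep), , drop = FALSE]
    n <- nrow(pts)
  }
  d <- as.matrix(stats::dist(pts))
  kdist <- apply(d, 1L, function(r) sort(r)[min_pts + 1L]) # [1] is self (0)
  kdist <- sort(kdist)
  if (max(kdist) <= 0) stop("degenerate k-distance curve: all points coincide")
  # perpendicular distance from each curve point to the first-last chord
  m <- length(kdist)
  t <- seq_len(m)
  dx <- m - 1; dy <- kdist[m] - kdist[1]
  dev <- abs(dy * (t - 1) - dx * (kdist - kdist[1])) / sqrt(dx^2 + dy^2)
  kdist[which.max(dev)]
}

#' AOI set constructors
#'
#' An AOI set is a named segmentation of the stimulus plane. Two schemes are
#' supported: `"lead"` — the semantic regions of a [stimulus_layout()], with
#' an explicit label for fixations landing in no region — and `"grid"` — a
#' uniform grid tiling the whole canvas, every in-bounds point mapping to
#' exactly one cell.
#'
#' @param layout a [stimulus_layout()].
#' @param outside_label label used for fixations outside every lead region.
#' @return object of class `aoi_set` with `scheme`, `labels`, `regions`, and
#'   for grids `cell_side`, `n_cols`, `n_rows`.
#' @export
lead_aois <- function(layout, outside_label = "outside") {
  stopifnot(inherits(layout, "stimulus_layout"))
  if (outside_label %in% layout$regions$name) {
    stop("outside_label collides with a region name")
  }
  structure(list(scheme = "lead",
                 labels = c(layout$regions$name, outside_label),
                 regions = layout$regions,
                 outside_label = outside_label,
                 width = layout$width, height = layout$height,
                 stimulus_id = layout$stimulus_id),
            class = "aoi_set")
}

#' Derive the uniform grid AOI set from a clustering result
#'
#' The cell side is the clustering's optimal diameter; the grid is anchored
#' at the canvas origin and covers the full canvas with
#' `ceiling(width / side)` columns and `ceiling(height / side)` rows (edge
#' cells truncated at the canvas). Cell names encode the position as
#' `r<row>c<col>`, zero-based from the top-left.
#'
#' @param layout a [stimulus_layout()].
#' @param cluster a `cluster_result` (or a single positive number taken
#'   directly as the cell side in pixels).
#' @return an `aoi_set` with scheme `"grid"`.
#' @export
derive_grid <- function(layout, cluster) {
  stopifnot(inherits(layout, "stimulus_layout"))
  side <- if (inherits(cluster, "cluster_result")) cluster$optimal_diameter
          else as.numeric(cluster)
  if (!is.finite(side) || side <= 0) stop("optimal diameter must be positive")
  if (side > max(layout$width, layout$height)) {
    warning("cell side exceeds the canvas; using a single-cell grid")
  }
  n_cols <- max(1L, as.integer(ceiling(layout$width / side)))
  n_rows <- max(1L, as.integer(ceiling(layout$height / side)))
  rows <- rep(seq_len(n_rows) - 1L, each = n_cols)
  cols <- rep(seq_len(n_cols) - 1L, times = n_rows)
  regions <- data.frame(
    name = sprintf("r%dc%d", rows, cols),
    x0 = cols * side, y0 = rows * side,
    x1 = pmin((cols + 1) * side, layout$width),
    y1 = pmin((rows + 1) * side, layout$height))
  structure(list(scheme = "grid", labels = regions$name, regions = regions,
                 cell_side = side, n_cols = n_cols, n_rows = n_rows,
                 width = layout$width, height = layout$height,
                 stimulus_id = layout$stimulus_id),
            class = "aoi_set")
}

#' Map fixations to AOI labels
#'
#' Returns one label per fixation, in fixation order. Under the grid scheme
#' every in-bounds point maps to exactly one cell (half-open cells: a point
#' exactly on a cell's right/bottom edge belongs to the next cell). Under
#' the lead scheme a point in no region gets the AOI set's `outside_label`;
#' where regions overlap, the first region in definition order wins.
#'
#' @param fixations a data.frame with columns `x`, `y` (e.g. the fixation
#'   table of a [study_dataset()]), or a two-column coordinate matrix.
#' @param aois an `aoi_set`.
#' @return character vector of AOI labels.
#' @export
assign_fixations <- function(fixations, aois) {
  stopifnot(inherits(aois, "aoi_set"))
  if (is.data.frame(fixations) && all(c("x", "y") %in% names(fixations))) {
    x <- fixations$x; y <- fixations$y
  } else {
    pts <- .as_points(fixations); x <- pts[, 1]; y <- pts[, 2]
  }
  if (length(x) == 0L) return(character(0))
  if (any(x < 0 | y < 0 | x >= aois$width | y >= aois$height)) {
    stop("fixation out of stimulus bounds; validate the dataset first")
  }
  if (aois$scheme == "grid") {
    col <- pmin(floor(x / aois$cell_side), aois$n_cols - 1L)
    row <- pmin(floor(y / aois$cell_side), aois$n_rows - 1L)
    sprintf("r%dc%d", row, col)
  } else {
    r <- aois$regions
    lab <- rep(aois$outside_label, length(x))
    for (i in rev(seq_len(nrow(r)))) {   # reverse so earlier regions win
      inside <- x >= r$x0[i] & x < r$x1[i] & y >= r$y0[i] & y < r$y1[i]
      lab[inside] <- r$name[i]
    }
    lab
  }
}

#' Export an AOI set as a data.frame (name, x0, y0, x1, y1)
#' @param aois an `aoi_set`.
#' @export
aoi_table <- function(aois) {
  stopifnot(inherits(aois, "aoi_set"))
  aois$regions
}
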