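#' Time series of sampled velocity fields
#'
#' The central container: 3-component velocities (m/s) sampled at every grid
#' node for a strictly increasing sequence of time instants. Velocities are
#' finite on fluid nodes and identically zero on wall nodes (no-slip
#' convention); exterior nodes carry zeros and are never used.
#'
#' @param grid a [uniform_grid()].
#' @param mask a [fluid_mask()] on the same grid.
#' @param times numeric vector of sample instants (s), strictly increasing,
#'   length >= 1.
#' @param snapshots list of \code{n_nodes x 3} numeric matrices (columns
#'   u, v, w in m/s), one per time instant.
#' @param regions a [region_set()] (optional).
#' @param meta named list of provenance metadata (generator, parameters,
#'   seed); carried through file I/O.
#' @return An object of class \code{flow_field}.
#' @export
flow_field <- function(grid, mask, times, snapshots, regions = region_set(),
                       meta = list()) {
  stopifnot(inherits(grid, "uniform_grid"), inherits(mask, "fluid_mask"),
            inherits(regions, "region_set"))
  times <- as.numeric(times)
  if (length(times) < 1L || any(!is.finite(times)) ||
      (length(times) > 1L && any(diff(times) <= 0)))
    stop("flow_field: 'times' must be finite and strictly increasing")
  if (!is.list(snapshots) || length(snapshots) != length(times))
    stop("flow_field: snapshot count must equal time count")
  n <- grid_n_nodes(grid)
  fl <- mask$labels == 1L
  wl <- mask$labels == 2L
  for (s in seq_along(snapshots)) {
    u <- snapshots[[s]]
    if (!is.matrix(u) || nrow(u) != n || ncol(u) != 3L)
      stop(sprintf("flow_field: snapshot %d is not an %d x 3 matrix", s, n))
    if (any(!is.finite(u[fl, ])))
      stop(sprintf("flow_field: non-finite velocity on fluid nodes in snapshot %d", s))
    if (any(wl) && any(u[wl, ] != 0))
      stop(sprintf("flow_field: nonzero velocity on wall nodes in snapshot %d (no-slip)", s))
    storage.mode(snapshots[[s]]) <- "double"
    dimnames(snapshots[[s]]) <- NULL
  }
  structure(list(grid = grid, mask = mask, regions = regions,
                 times = times, snapshots = snapshots, meta = meta),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("flow_field: %d snapshot(s) on ", length(x$times)))
  print(x$grid)
  print(x$mask)
  if (length(x$regions$volumes) || length(x$regions$surfaces))
    cat(sprintf("  regions: volumes [%s], surfaces [%s]\n",
                paste(names(x$regions$volumes), collapse = ", "),
                paste(names(x$regions$surfaces), collapse = ", ")))
  invisible(x)
}

#' Number of snapshots of a flow field
#' @param field a \code{flow_field}.
#' @return integer count.
#' @export
n_snapshots <- function(field) length(field$times)

# extract one snapshot matrix, validating the index
get_snapshot <- function(field, snapshot) {
  if (snapshot < 1L || snapshot > length(field$snapshots))
    stop(sprintf("snapshot %d does not exist (field has %d)", snapshot,
                 length(field$snapshots)))
  field$snapshots[[snapshot]]
}

#' Trilinear interpolation of node values at arbitrary points
#'
#' Probes per-node quantities (velocity components, scalar fields) at
#' arbitrary coordinates inside the grid; points outside are clamped to
#' the hull.
#'
#' @param grid a [uniform_grid()].
#' @param values per-node vector or \code{n_nodes x m} matrix.
#' @param pts \code{k x 3} matrix of coordinates (m).
#' @return \code{k x m} matrix of interpolated values.
#' @export
trilinear_interp <- function(grid, values, pts) {
  d <- grid$dims; h <- grid$spacing; o <- grid$origin
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  r <- sweep(sweep(pts, 2, o), 2, h, "/")   # 0-based continuous index
  i0 <- floor(r)
  for (j in 1:3)                            # clamp lower cell corner per axis
    i0[, j] <- pmin(pmax(i0[, j], 0), d[j] - 2)
  w <- pmin(pmax(r - i0, 0), 1)             # in [0, 1] inside the grid
  out <- matrix(0, nrow(pts), ncol(values))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    wt <- (if (cx) w[, 1] else 1 - w[, 1]) *
          (if (cy) w[, 2] else 1 - w[, 2]) *
          (if (cz) w[, 3] else 1 - w[, 3])
    idx <- node_index(grid, i0[, 1] + cx + 1L, i0[, 2] + cy + 1L,
                      i0[, 3] + cz + 1L)
    out <- out + wt * values[idx, , drop = FALSE]
  }
  out
}
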