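#' Uniform Cartesian sampling grid
#'
#' Node-centred uniform grid on which flow fields are sampled. Nodes are
#' indexed in column-major order (x fastest), with node \code{(i, j, k)}
#' located at \code{origin + (i - 1, j - 1, k - 1) * spacing}. Each node owns
#' a voxel of volume \code{prod(spacing)}; that voxel volume is the cell
#' volume entering the subgrid length-scale limit.
#'
#' @param dims integer vector of length 3, nodes per axis (each >= 2).
#' @param spacing numeric length 3, node spacing per axis in metres (> 0).
#'   A scalar is recycled.
#' @param origin numeric length 3, coordinates of node (1, 1, 1) in metres.
#' @return An object of class \code{uniform_grid}.
#' @export
uniform_grid <- function(dims, spacing, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 2L))
    stop("uniform_grid: 'dims' must be three integers >= 2")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("uniform_grid: 'spacing' must be three positive lengths (m)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("uniform_grid: 'origin' must be three finite coordinates (m)")
  structure(list(dims = dims, spacing = spacing, origin = origin),
            class = "uniform_grid")
}

#' @export
print.uniform_grid <- function(x, ...) {
  cat(sprintf("uniform_grid: %d x %d x %d nodes, spacing (%g, %g, %g) m\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Number of nodes of a grid
#' @param grid a \code{uniform_grid}.
#' @return integer node count (product of \code{dims}).
#' @export
grid_n_nodes <- function(grid) prod(grid$dims)

#' Voxel (cell) volume of a grid
#' @param grid a \code{uniform_grid}.
#' @return cell volume in m^3.
#' @export
grid_cell_volume <- function(grid) prod(grid$spacing)

#' Node coordinates
#' @param grid a \code{uniform_grid}.
#' @param idx optional node indices; default all nodes.
#' @return matrix with columns x, y, z (m), rows in node order.
#' @export
node_coords <- function(grid, idx = NULL) {
  d <- grid$dims
  if (is.null(idx)) idx <- seq_len(prod(d))
  idx0 <- idx - 1L
  i <- idx0 %% d[1]
  j <- (idx0 %/% d[1]) %% d[2]
  k <- idx0 %/% (d[1] * d[2])
  cbind(x = grid$origin[1] + i * grid$spacing[1],
        y = grid$origin[2] + j * grid$spacing[2],
        z = grid$origin[3] + k * grid$spacing[3])
}

#' Linear node index from (i, j, k) triples
#' @param grid a \code{uniform_grid}.
#' @param i,j,k 1-based node coordinates along x, y, z (vectorised).
#' @return integer node index in column-major (x fastest) order.
#' @export
node_index <- function(grid, i, j, k) {
  d <- grid$dims
  (i - 1L) + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2] + 1L
}
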