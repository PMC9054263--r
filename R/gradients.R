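#' Velocity-gradient tensor field
#'
#' Computes the per-node velocity-gradient tensor
#' \eqn{g_{ij} = \partial u_i / \partial x_j} (1/s) for one snapshot.
#' Second-order central differences are used wherever both axis neighbours
#' are fluid; at fluid nodes adjacent to walls or the exterior a
#' second-order one-sided (three-point) stencil into the fluid is used,
#' degrading to a two-point stencil (using the no-slip zero at a wall
#' neighbour if that is all there is) only where fewer than three
#' consecutive fluid nodes exist along the axis. A fluid node with no
#' usable neighbour along any axis raises a stencil error.
#'
#' @param field a [flow_field()].
#' @param snapshot snapshot index.
#' @return An object of class \code{gradient_field}: list with \code{g},
#'   an \code{n_nodes x 3 x 3} array (zero rows on non-fluid nodes), and
#'   the originating \code{grid} and \code{mask}.
#' @export
velocity_gradient <- function(field, snapshot = 1L) {
  u <- get_snapshot(field, snapshot)
  grid <- field$grid
  d <- grid$dims
  lab3 <- array(field$mask$labels, dim = d)
  fluid3 <- lab3 == 1L
  wall3 <- lab3 == 2L
  g <- array(0, dim = c(grid_n_nodes(grid), 3L, 3L))
  covered <- array(FALSE, dim = d)   # has a stencil along >= 1 axis
  for (ax in 1:3) {
    res <- .axis_derivative(u, fluid3, wall3, grid, ax)
    g[, , ax] <- res$deriv
    covered <- covered | res$ok
  }
  if (any(fluid3 & !covered))
    stop("velocity_gradient: stencil error - isolated fluid node with no neighbours")
  structure(list(g = g, grid = grid, mask = field$mask),
            class = "gradient_field")
}

# d/dx_ax of all three components; returns list(deriv = n x 3, ok = array)
.axis_derivative <- function(u, fluid3, wall3, grid, ax) {
  d <- grid$dims
  h <- grid$spacing[ax]
  n <- prod(d)
  shift_arr <- function(a, k) {   # value of a at node offset +k along ax, NA outside
    out <- array(NA, dim = d)
    idx_src <- vector("list", 3); idx_dst <- vector("list", 3)
    for (j in 1:3) { idx_src[[j]] <- seq_len(d[j]); idx_dst[[j]] <- seq_len(d[j]) }
    if (k > 0) { idx_src[[ax]] <- (1 + k):d[ax]; idx_dst[[ax]] <- 1:(d[ax] - k) }
    if (k < 0) { idx_src[[ax]] <- 1:(d[ax] + k); idx_dst[[ax]] <- (1 - k):d[ax] }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  fp1 <- shift_arr(fluid3, 1L);  fp1[is.na(fp1)] <- FALSE
  fm1 <- shift_arr(fluid3, -1L); fm1[is.na(fm1)] <- FALSE
  fp2 <- shift_arr(fluid3, 2L);  fp2[is.na(fp2)] <- FALSE
  fm2 <- shift_arr(fluid3, -2L); fm2[is.na(fm2)] <- FALSE
  wp1 <- shift_arr(wall3, 1L);   wp1[is.na(wp1)] <- FALSE
  wm1 <- shift_arr(wall3, -1L);  wm1[is.na(wm1)] <- FALSE
  central <- fluid3 & fp1 & fm1
  fwd2 <- fluid3 & !central & fp1 & fp2
  bwd2 <- fluid3 & !central & !fwd2 & fm1 & fm2
  fwd1 <- fluid3 & !central & !fwd2 & !bwd2 & fp1
  bwd1 <- fluid3 & !central & !fwd2 & !bwd2 & !fwd1 & fm1
  # last resort: two-point stencil onto an adjacent wall node (velocity 0)
  wfwd <- fluid3 & !central & !fwd2 & !bwd2 & !fwd1 & !bwd1 & wp1
  wbwd <- fluid3 & !central & !fwd2 & !bwd2 & !fwd1 & !bwd1 & !wfwd & wm1
  ok <- central | fwd2 | bwd2 | fwd1 | bwd1 | wfwd | wbwd
  deriv <- matrix(0, n, 3L)
  for (comp in 1:3) {
    a <- array(u[, comp], dim = d)
    ap1 <- shift_arr(a, 1L); am1 <- shift_arr(a, -1L)
    ap2 <- shift_arr(a, 2L); am2 <- shift_arr(a, -2L)
    dv <- array(0, dim = d)
    dv[central] <- (ap1[central] - am1[central]) / (2 * h)
    dv[fwd2] <- (-3 * a[fwd2] + 4 * ap1[fwd2] - ap2[fwd2]) / (2 * h)
    dv[bwd2] <- (3 * a[bwd2] - 4 * am1[bwd2] + am2[bwd2]) / (2 * h)
    dv[fwd1] <- (ap1[fwd1] - a[fwd1]) / h
    dv[bwd1] <- (a[bwd1] - am1[bwd1]) / h
    dv[wfwd] <- (0 - a[wfwd]) / h
    dv[wbwd] <- (a[wbwd] - 0) / h
    deriv[, comp] <- as.vector(dv)
  }
  list(deriv = deriv, ok = ok)
}

#' Strain-rate tensor of a gradient field
#' @param grad a \code{gradient_field}.
#' @return \code{n x 3 x 3} array \eqn{S_{ij} = (g_{ij} + g_{ji})/2}.
#' @export
strain_tensor <- function(grad) {
  stopifnot(inherits(grad, "gradient_field"))
  g <- grad$g
  S <- g
  for (i in 1:3) for (j in 1:3) S[, i, j] <- (g[, i, j] + g[, j, i]) / 2
  S
}

#' Strain-rate modulus
#'
#' \eqn{S = \sqrt{2 S_{ij} S_{ij}}} (1/s); for simple shear of rate
#' \eqn{\dot\gamma} this equals \eqn{\dot\gamma}, making it the natural
#' shear-rate argument of a generalised-Newtonian viscosity.
#'
#' @param grad a \code{gradient_field}.
#' @return numeric vector, one value per node.
#' @export
strain_modulus <- function(grad) {
  S <- strain_tensor(grad)
  acc <- numeric(dim(S)[1])
  for (i in 1:3) for (j in 1:3) acc <- acc + S[, i, j]^2
  sqrt(2 * acc)
}

#' Distance to the nearest wall face
#'
#' Euclidean distance from every fluid node to the nearest wall-face
#' centroid, computed exactly (brute force over faces, chunked). With no
#' wall faces in the mask the distance is \code{Inf}, so the subgrid
#' length-scale limit falls back to its cell-volume branch.
#'
#' @param mask a [fluid_mask()].
#' @return numeric vector, one distance (m) per node; \code{NA} on
#'   non-fluid nodes, \code{Inf} if the mask has no walls.
#' @export
wall_distance <- function(mask) {
  stopifnot(inherits(mask, "fluid_mask"))
  n <- grid_n_nodes(mask$grid)
  out <- rep(NA_real_, n)
  fl <- fluid_nodes(mask)
  if (nrow(mask$faces) == 0L) { out[fl] <- Inf; return(out) }
  fc <- as.matrix(mask$faces[, c("cx", "cy", "cz")])
  pc <- node_coords(mask$grid, fl)
  chunk <- max(1L, floor(2e6 / nrow(fc)))
  for (s in seq(1L, length(fl), by = chunk)) {
    e <- min(s + chunk - 1L, length(fl))
    blk <- pc[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(fc^2), "+") - 2 * blk %*% t(fc)
    out[fl[s:e]] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}
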