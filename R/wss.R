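#' Wall shear stress on the voxelised wall
#'
#' Evaluates the viscous shear traction on every wall face for every
#' snapshot. The velocity-gradient tensor is taken at the face's adjacent
#' fluid node and at the next fluid node along the face axis and linearly
#' extrapolated to the face centroid (a second-order one-sided
#' evaluation); the traction \eqn{t = \mu (G + G^T)\hat n} is then
#' projected onto the wall tangent plane. Because a staircase wall's
#' axis-aligned face normals systematically under-resolve the shear on
#' curved walls, \eqn{\hat n} is the boundary normal estimated by
#' area-weighted averaging of wall-face normals within a small
#' neighbourhood (2.5 grid spacings); on flat axis-aligned walls this
#' reduces to the exact face normal.
#'
#' @param field a [flow_field()].
#' @param mu per-node dynamic viscosity (Pa s) or a single scalar.
#' @param snapshots snapshot indices to evaluate (default all).
#' @return An object of class \code{wall_shear_record}: list with
#'   \code{magnitude} (faces x snapshots matrix, Pa), \code{traction}
#'   (list of faces x 3 matrices, Pa), smoothed \code{normals}, the
#'   \code{faces} table and \code{times}.
#' @export
wall_shear_stress <- function(field, mu, snapshots = NULL) {
  stopifnot(inherits(field, "flow_field"))
  mask <- field$mask
  faces <- mask$faces
  if (nrow(faces) == 0L) stop("wall_shear_stress: the mask has no wall faces")
  if (is.null(snapshots)) snapshots <- seq_along(field$times)
  n <- grid_n_nodes(field$grid)
  if (length(mu) == 1L) mu <- rep(mu, n)
  if (length(mu) != n) stop("wall_shear_stress: 'mu' must be scalar or per-node")
  d <- field$grid$dims
  shift <- c(1L, d[1], d[1] * d[2])
  p1 <- faces$fluid
  p2 <- p1 - faces$dir * shift[faces$axis]
  p3 <- p2 - faces$dir * shift[faces$axis]
  inb <- function(i) i >= 1L & i <= n
  lab <- mask$labels
  ok <- inb(p2) & inb(p3)
  ok[ok] <- lab[p2[ok]] == 1L & lab[p3[ok]] == 1L
  if (any(!ok))
    stop(sprintf(paste("wall_shear_stress: stencil error - %d wall face(s)",
                       "have fewer than 3 fluid nodes along the wall normal"),
                 sum(!ok)))
  nrm <- .smoothed_wall_normals(mask)
  nf <- nrow(faces)
  mag <- matrix(0, nf, length(snapshots))
  trac <- vector("list", length(snapshots))
  for (q in seq_along(snapshots)) {
    grad <- velocity_gradient(field, snapshots[q])
    g <- grad$g
    t_vec <- matrix(0, nf, 3)
    for (i in 1:3) {
      acc <- 0
      for (j in 1:3) {
        sym1 <- g[p1, i, j] + g[p1, j, i]
        sym2 <- g[p2, i, j] + g[p2, j, i]
        sym_f <- 1.5 * sym1 - 0.5 * sym2      # extrapolated to the face
        acc <- acc + sym_f * nrm[, j]
      }
      t_vec[, i] <- mu[p1] * acc              # t_i = mu (g_ij + g_ji) n_j
    }
    tn <- rowSums(t_vec * nrm)
    t_vec <- t_vec - tn * nrm                  # tangential (shear) part
    trac[[q]] <- t_vec
    mag[, q] <- sqrt(rowSums(t_vec^2))
  }
  structure(list(magnitude = mag, traction = trac, normals = nrm,
                 faces = faces, times = field$times[snapshots]),
            class = "wall_shear_record")
}

# area-weighted average of wall-face normals within `radius` spacings
.smoothed_wall_normals <- function(mask, radius = 2.5) {
  faces <- mask$faces
  fc <- as.matrix(faces[, c("cx", "cy", "cz")])
  fn <- as.matrix(faces[, c("nx", "ny", "nz")])
  r <- radius * max(mask$grid$spacing)
  nf <- nrow(faces)
  out <- matrix(0, nf, 3)
  chunk <- max(1L, floor(4e6 / nf))
  aw <- faces$area
  for (s in seq(1L, nf, by = chunk)) {
    e <- min(s + chunk - 1L, nf)
    blk <- fc[s:e, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(fc^2), "+") - 2 * blk %*% t(fc)
    w <- (d2 <= r^2 + 1e-15) * rep(aw, each = nrow(blk))
    out[s:e, ] <- w %*% fn
  }
  len <- sqrt(rowSums(out^2))
  deg <- len < 1e-12
  out[deg, ] <- fn[deg, ]                    # isolated face: keep its own normal
  len[deg] <- 1
  out / len
}

#' Time-averaged wall shear stress (TAWSS)
#'
#' Applies the sliding-window average to the per-face shear magnitude
#' series and returns the time mean over the averaging horizon.
#'
#' @param record a [wall_shear_stress()] result.
#' @param spec a [time_average_spec()]; the window is clamped to the
#'   number of snapshots in the record.
#' @return numeric vector of per-face TAWSS (Pa).
#' @export
tawss <- function(record, spec = time_average_spec()) {
  stopifnot(inherits(record, "wall_shear_record"),
            inherits(spec, "time_average_spec"))
  m <- record$magnitude
  w <- min(spec$window, ncol(m))
  nw <- ncol(m) - w + 1L
  # moving average over valid windows, then the horizon mean
  acc <- numeric(nrow(m))
  run <- rowSums(m[, 1:w, drop = FALSE])
  acc <- acc + run
  if (nw > 1L) for (s in 2:nw) {
    run <- run - m[, s - 1L] + m[, s + w - 1L]
    acc <- acc + run
  }
  acc / (w * nw)
}
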