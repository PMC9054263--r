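#' Intersect a plane with the fluid domain
#'
#' Clips every fluid voxel (the cube of one grid spacing centred on a fluid
#' node) against the plane and returns, per cut voxel, the exact polygon
#' area of the intersection and the velocity interpolated (trilinearly) at
#' the polygon centroid. The area weights sum to the cross-sectional area
#' of the voxelised fluid domain, which converges to the analytic section
#' area under grid refinement.
#'
#' @param field a [flow_field()].
#' @param plane a [plane_section()].
#' @param snapshot snapshot index to interpolate velocities from.
#' @return data frame with columns \code{node}, \code{area} (m^2), centroid
#'   \code{cx, cy, cz} (m) and interpolated velocity \code{u, v, w} (m/s).
#' @export
extract_plane <- function(field, plane, snapshot = 1L) {
  stopifnot(inherits(field, "flow_field"), inherits(plane, "plane_section"))
  u <- get_snapshot(field, snapshot)
  sec <- .plane_polygons(field$grid, field$mask, plane)
  if (nrow(sec) == 0L)
    stop("extract_plane: empty section (plane does not intersect the fluid domain)")
  vel <- trilinear_interp(field$grid, u, as.matrix(sec[, c("cx", "cy", "cz")]))
  sec$u <- vel[, 1]; sec$v <- vel[, 2]; sec$w <- vel[, 3]
  sec
}

# polygon areas & centroids of plane-voxel intersections over fluid voxels
.plane_polygons <- function(grid, mask, plane) {
  h <- grid$spacing
  nrm <- plane$normal
  fl <- fluid_nodes(mask)
  ctr <- node_coords(grid, fl)
  sd_ctr <- as.numeric((ctr - matrix(plane$point, nrow(ctr), 3, byrow = TRUE)) %*% nrm)
  reach <- sum(abs(nrm) * h) / 2
  cand <- which(abs(sd_ctr) <= reach + 1e-15)
  empty <- data.frame(node = integer(), area = numeric(),
                      cx = numeric(), cy = numeric(), cz = numeric())
  if (!length(cand)) return(empty)
  # cube corner offsets and edge list (pairs of corner indices)
  corners <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1))) / 2
  corners <- sweep(corners, 2, h, "*")
  edges <- rbind(c(1, 2), c(3, 4), c(5, 6), c(7, 8),
                 c(1, 3), c(2, 4), c(5, 7), c(6, 8),
                 c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  # in-plane orthonormal basis
  a <- if (abs(nrm[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * nrm) * nrm; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  sc <- corners %*% nrm                  # corner-offset signed distances
  out_node <- integer(length(cand)); out_area <- numeric(length(cand))
  out_cen <- matrix(0, length(cand), 3)
  m <- 0L
  for (q in seq_along(cand)) {
    i <- cand[q]
    s <- sd_ctr[i] + sc                  # signed distances of the 8 corners
    s[s == 0] <- 1e-300                  # tie-break: on-plane corner counts positive
    cross <- s[edges[, 1]] * s[edges[, 2]] < 0
    if (sum(cross) < 3L) next
    ce <- edges[cross, , drop = FALSE]
    t <- s[ce[, 1]] / (s[ce[, 1]] - s[ce[, 2]])
    p <- corners[ce[, 1], , drop = FALSE] +
      t * (corners[ce[, 2], , drop = FALSE] - corners[ce[, 1], , drop = FALSE])
    # order polygon vertices by angle in the plane
    v1 <- p %*% e1; v2 <- p %*% e2
    o <- order(atan2(v2 - mean(v2), v1 - mean(v1)))
    v1 <- v1[o]; v2 <- v2[o]
    j <- c(seq_along(v1)[-1], 1L)
    crossterm <- v1 * v2[j] - v1[j] * v2
    a_signed <- sum(crossterm) / 2
    if (abs(a_signed) <= 0) next
    cx <- sum((v1 + v1[j]) * crossterm) / (6 * a_signed)
    cy <- sum((v2 + v2[j]) * crossterm) / (6 * a_signed)
    m <- m + 1L
    out_node[m] <- fl[i]
    out_area[m] <- abs(a_signed)
    # polygon points satisfy p . n = -sd_ctr[i] relative to the voxel centre
    out_cen[m, ] <- ctr[i, ] + cx * e1 + cy * e2 - sd_ctr[i] * nrm
  }
  if (m == 0L) return(empty)
  data.frame(node = out_node[seq_len(m)], area = out_area[seq_len(m)],
             cx = out_cen[seq_len(m), 1], cy = out_cen[seq_len(m), 2],
             cz = out_cen[seq_len(m), 3])
}
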