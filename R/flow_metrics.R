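#' Sliding-window time averaging specification
#'
#' @param window window length in samples (default 50, the averaging
#'   window used for velocity, WSS and TKE reporting).
#' @param stride stride between successive windows (samples).
#' @return An object of class \code{time_average_spec}.
#' @export
time_average_spec <- function(window = 50L, stride = 1L) {
  window <- as.integer(window); stride <- as.integer(stride)
  stopifnot(window >= 1L, stride >= 1L)
  structure(list(window = window, stride = stride),
            class = "time_average_spec")
}

#' Sliding-window mean of a velocity time series
#'
#' Centred moving average over \code{spec$window} consecutive snapshots
#' ("valid" windows only): with \code{n} snapshots and stride 1 the result
#' has \code{n - window + 1} averaged snapshots, timestamped at the window
#' centres.
#'
#' @param field a [flow_field()].
#' @param spec a [time_average_spec()].
#' @return A [flow_field()] of averaged snapshots.
#' @export
sliding_window_mean <- function(field, spec = time_average_spec()) {
  stopifnot(inherits(field, "flow_field"), inherits(spec, "time_average_spec"))
  n <- n_snapshots(field)
  w <- spec$window
  if (n < w) stop("sliding_window_mean: fewer snapshots than the window length")
  starts <- seq(1L, n - w + 1L, by = spec$stride)
  acc <- NULL
  means <- vector("list", length(starts))
  # running-sum evaluation for stride 1; direct sums otherwise
  for (q in seq_along(starts)) {
    s <- starts[q]
    if (q == 1L || spec$stride != 1L) {
      acc <- Reduce(`+`, field$snapshots[s:(s + w - 1L)])
    } else {
      acc <- acc - field$snapshots[[s - 1L]] + field$snapshots[[s + w - 1L]]
    }
    means[[q]] <- acc / w
  }
  tmid <- vapply(starts, function(s) mean(field$times[s:(s + w - 1L)]), 0)
  flow_field(field$grid, field$mask, tmid, means, field$regions,
             meta = c(field$meta, list(window = w, stride = spec$stride)))
}

#' Resolved turbulent kinetic energy
#'
#' Per-node resolved TKE
#' \eqn{k_r = \tfrac12(\overline{u'^2} + \overline{v'^2} +
#' \overline{w'^2})} (J/kg), with fluctuations \eqn{u' = u - \bar u} taken
#' against the sliding-window mean centred on each sample (windows clamped
#' at the ends of the horizon) and the variances averaged over all
#' samples.
#'
#' @param field a [flow_field()].
#' @param spec a [time_average_spec()]; a window of \code{n_snapshots}
#'   reduces to fluctuations about the global time mean.
#' @return numeric vector of per-node \eqn{k_r} (J/kg).
#' @export
resolved_tke <- function(field, spec = time_average_spec()) {
  stopifnot(inherits(field, "flow_field"), inherits(spec, "time_average_spec"))
  n <- n_snapshots(field)
  w <- min(spec$window, n)
  nw <- n - w + 1L
  # window sums via prefix accumulation
  sums <- vector("list", nw)
  acc <- Reduce(`+`, field$snapshots[1:w])
  sums[[1]] <- acc
  if (nw > 1L) for (s in 2:nw) {
    acc <- acc - field$snapshots[[s - 1L]] + field$snapshots[[s + w - 1L]]
    sums[[s]] <- acc
  }
  half <- (w - 1L) %/% 2L
  acc2 <- 0
  for (t in seq_len(n)) {
    ws <- min(max(t - half, 1L), nw)
    fl <- field$snapshots[[t]] - sums[[ws]] / w
    acc2 <- acc2 + fl^2
  }
  rowSums(acc2) / (2 * n)
}

#' Total turbulent kinetic energy and region aggregates
#'
#' Pointwise sum of resolved and subgrid TKE, with the region
#' volume-average (J/kg) and the region-integrated kinetic energy
#' \eqn{\rho \int k \, dV} reported in millijoules.
#'
#' @param k_r per-node resolved TKE (J/kg).
#' @param k_sgs per-node subgrid TKE (J/kg); scalar 0 allowed.
#' @param field a [flow_field()] (supplies cell volumes).
#' @param region node indices; defaults to all fluid nodes.
#' @param rho fluid density (kg/m^3).
#' @return list with \code{k} (per-node total, J/kg),
#'   \code{volume_average} (J/kg) and \code{energy_mJ}.
#' @export
total_tke <- function(k_r, k_sgs = 0, field, region = NULL, rho = 1050) {
  k <- k_r + k_sgs
  if (is.null(region)) region <- fluid_nodes(field$mask)
  if (!length(region)) stop("total_tke: empty region")
  vcell <- grid_cell_volume(field$grid)
  list(k = k,
       volume_average = mean(k[region]),
       energy_mJ = rho * sum(k[region]) * vcell * 1000)
}

#' Fluid volume exceeding a TKE threshold
#'
#' Summed voxel volume of fluid nodes whose TKE exceeds the threshold:
#' the scalar behind thresholded turbulence-volume maps (default
#' threshold 0.08 J/kg).
#'
#' @param k per-node TKE (J/kg).
#' @param field a [flow_field()].
#' @param threshold TKE threshold (J/kg).
#' @return volume (m^3).
#' @export
tke_exceedance_volume <- function(k, field, threshold = 0.08) {
  fl <- fluid_nodes(field$mask)
  sum(k[fl] > threshold) * grid_cell_volume(field$grid)
}

#' Vorticity field
#'
#' Curl of the velocity, \eqn{\omega = \nabla \times u} (1/s), from the
#' same stencils as [velocity_gradient()].
#'
#' @param field a [flow_field()].
#' @param snapshot snapshot index.
#' @param grad optional precomputed [velocity_gradient()].
#' @return \code{n_nodes x 3} matrix of vorticity components.
#' @export
vorticity <- function(field, snapshot = 1L, grad = NULL) {
  if (is.null(grad)) grad <- velocity_gradient(field, snapshot)
  g <- grad$g
  cbind(g[, 3, 2] - g[, 2, 3],
        g[, 1, 3] - g[, 3, 1],
        g[, 2, 1] - g[, 1, 2])
}

#' Volume-averaged vorticity component along an axis
#'
#' Cell-volume-weighted mean of \eqn{\omega \cdot \hat a} over a region:
#' the rotational-strength measure for a vortex whose core is aligned with
#' \eqn{\hat a} (sign follows the right-hand rule).
#'
#' @param omega \code{n x 3} vorticity matrix.
#' @param axis unit 3-vector (validated to unit length).
#' @param region node indices.
#' @return mean aligned vorticity (1/s).
#' @export
aligned_vorticity_average <- function(omega, axis, region) {
  axis <- as.numeric(axis)
  if (abs(sqrt(sum(axis^2)) - 1) > 1e-8)
    stop("aligned_vorticity_average: 'axis' must be a unit vector")
  if (!length(region)) stop("aligned_vorticity_average: empty region")
  mean(omega[region, ] %*% axis)
}

#' Helicity density
#'
#' Pointwise \eqn{h = u \cdot \omega} (m/s^2), the signed pseudoscalar
#' marking corkscrew-like alignment of velocity and vorticity.
#'
#' @param u \code{n x 3} velocity snapshot.
#' @param omega \code{n x 3} vorticity matrix.
#' @return numeric vector of per-node helicity density.
#' @export
helicity_density <- function(u, omega) rowSums(u * omega)

#' Area-averaged helicity on a plane section
#'
#' Interpolates a per-node helicity density onto the polygon centroids of
#' the plane's fluid intersection and returns the area-weighted mean.
#'
#' @param h per-node helicity density.
#' @param field a [flow_field()].
#' @param plane a [plane_section()].
#' @return area-averaged helicity (m/s^2).
#' @export
plane_average_helicity <- function(h, field, plane) {
  sec <- .plane_polygons(field$grid, field$mask, plane)
  if (nrow(sec) == 0L)
    stop("plane_average_helicity: empty section (plane misses the fluid domain)")
  hv <- trilinear_interp(field$grid, h, as.matrix(sec[, c("cx", "cy", "cz")]))
  sum(hv[, 1] * sec$area) / sum(sec$area)
}

#' Area-weighted surface averages with pairwise differences
#'
#' @param values per-wall-face values (e.g. TAWSS in Pa).
#' @param mask a [fluid_mask()] (supplies face areas).
#' @param surfaces named list of wall-face index vectors (e.g. from a
#'   [region_set()]).
#' @return list with \code{averages} (named numeric) and
#'   \code{differences}, a data frame of pairwise differences between
#'   named surfaces.
#' @export
surface_average <- function(values, mask, surfaces) {
  stopifnot(inherits(mask, "fluid_mask"), length(surfaces) >= 1)
  area <- mask$faces$area
  avg <- vapply(surfaces, function(ii) {
    if (!length(ii)) return(NA_real_)
    sum(values[ii] * area[ii]) / sum(area[ii])
  }, 0)
  nms <- names(surfaces)
  diffs <- NULL
  if (length(nms) >= 2) {
    cmb <- utils::combn(nms, 2)
    diffs <- data.frame(surface_a = cmb[1, ], surface_b = cmb[2, ],
                        difference = avg[cmb[1, ]] - avg[cmb[2, ]],
                        row.names = NULL)
  }
  list(averages = avg, differences = diffs)
}
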