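#' Analytic benchmark flow fields
#'
#' Generators for flow fields with closed-form vorticity, helicity, wall
#' shear and strain, used as oracles for every post-processing stage:
#' steady pipe (Hagen-Poiseuille) flow, solid-body rotation, the Lamb-Oseen
#' vortex, the Arnold-Beltrami-Childress (ABC) Beltrami field, a swirling
#' pipe with analytic helicity, plane-channel flow, and a two-vortex
#' chamber emulating the counter-rotating vortex pair seen in the right
#' atrium.
#'
#' @name analytic_fields
NULL

# circular-tube voxelisation shared by tube-like generators.
# Returns grid + mask with fluid where r < R, wall on axis-adjacent rim.
.tube_lattice <- function(R, nodes_per_diameter, n_axial) {
  h <- 2 * R / nodes_per_diameter
  half <- ceiling(nodes_per_diameter / 2) + 2L
  nx <- 2L * half + 1L                       # odd: node exactly on the axis
  grid <- uniform_grid(c(nx, nx, n_axial), h, c(-half * h, -half * h, 0))
  xy <- node_coords(grid)
  r2 <- xy[, 1]^2 + xy[, 2]^2
  fluid <- r2 < R^2
  codes <- integer(grid_n_nodes(grid))
  codes[fluid] <- 1L
  # wall = non-fluid nodes axis-adjacent to a fluid node
  d <- grid$dims
  f3 <- array(fluid, dim = d)
  nb <- array(FALSE, dim = d)
  nb[-1, , ] <- nb[-1, , ] | f3[-d[1], , ]
  nb[-d[1], , ] <- nb[-d[1], , ] | f3[-1, , ]
  nb[, -1, ] <- nb[, -1, ] | f3[, -d[2], ]
  nb[, -d[2], ] <- nb[, -d[2], ] | f3[, -1, ]
  codes[!fluid & as.vector(nb)] <- 2L
  list(grid = grid, codes = codes, r2 = r2, xy = xy, fluid = fluid)
}

#' @describeIn analytic_fields Steady Hagen-Poiseuille flow in a voxelised
#'   circular tube of radius \code{R} along z: axial velocity
#'   \code{U_max * (1 - r^2/R^2)}, repeated unchanged over
#'   \code{n_snapshots}. The analytic wall shear is \code{2 mu U_max / R}
#'   and the helicity density is identically zero.
#' @param R tube radius (m).
#' @param U_max centreline velocity (m/s).
#' @param nodes_per_diameter lattice resolution across the tube (>= 16).
#' @param n_snapshots number of (identical) time samples.
#' @param n_axial axial extent in nodes.
#' @param dt sample interval (s).
#' @export
poiseuille_field <- function(R, U_max, nodes_per_diameter, n_snapshots = 1L,
                             n_axial = 6L, dt = 1e-2) {
  stopifnot(R > 0, U_max > 0)
  if (nodes_per_diameter < 16)
    stop("poiseuille_field: resolution error - tube thinner than 16 nodes per diameter")
  lat <- .tube_lattice(R, nodes_per_diameter, n_axial)
  mask <- fluid_mask(lat$grid, lat$codes)
  n <- grid_n_nodes(lat$grid)
  u <- matrix(0, n, 3)
  u[lat$fluid, 3] <- U_max * (1 - lat$r2[lat$fluid] / R^2)
  snaps <- rep(list(u), n_snapshots)
  regions <- region_set(volumes = list(tube = which(lat$fluid)),
                        surfaces = list(wall = seq_len(nrow(mask$faces))),
                        mask = mask)
  flow_field(lat$grid, mask, seq(0, by = dt, length.out = n_snapshots),
             snaps, regions,
             meta = list(generator = "poiseuille_field", R = R, U_max = U_max,
                         nodes_per_diameter = nodes_per_diameter))
}

#' @describeIn analytic_fields Solid-body rotation \code{u = (-Omega y,
#'   Omega x, 0)} in an all-fluid cube (no walls): vorticity is exactly
#'   \code{(0, 0, 2 Omega)} and the strain-rate tensor vanishes.
#' @param Omega rotation rate (1/s).
#' @param extent cube edge length (m).
#' @param nodes nodes per axis.
#' @export
solid_body_rotation_field <- function(Omega, extent = 1, nodes = 16L) {
  stopifnot(is.finite(Omega), extent > 0, nodes >= 2)
  h <- extent / (nodes - 1)
  grid <- uniform_grid(rep(nodes, 3), h, rep(-extent / 2, 3))
  mask <- fluid_mask(grid, rep(1L, grid_n_nodes(grid)))
  xy <- node_coords(grid)
  u <- cbind(-Omega * xy[, 2], Omega * xy[, 1], 0)
  flow_field(grid, mask, 0, list(u),
             meta = list(generator = "solid_body_rotation_field", Omega = Omega))
}

#' @describeIn analytic_fields Lamb-Oseen vortex along z: azimuthal
#'   velocity \code{(Gamma / 2 pi r) (1 - exp(-r^2/r_c^2))} with peak axial
#'   vorticity \code{Gamma / (pi r_c^2)} on the axis and total circulation
#'   \code{Gamma} at radii well outside the core.
#' @param Gamma circulation (m^2/s).
#' @param r_c core radius (m).
#' @param nodes_per_core lattice resolution across one core radius.
#' @param extent_cores half-width of the box in core radii.
#' @export
lamb_oseen_field <- function(Gamma, r_c, nodes_per_core = 32L,
                             extent_cores = 3, n_axial = 5L) {
  stopifnot(r_c > 0, nodes_per_core >= 4)
  h <- r_c / nodes_per_core
  half <- ceiling(extent_cores * r_c / h)
  nx <- 2L * half + 1L
  grid <- uniform_grid(c(nx, nx, n_axial), h, c(-half * h, -half * h, 0))
  mask <- fluid_mask(grid, rep(1L, grid_n_nodes(grid)))
  xy <- node_coords(grid)
  r2 <- xy[, 1]^2 + xy[, 2]^2
  # u_theta / r, finite at the origin: Gamma/(2 pi) (1 - exp(-r^2/rc^2))/r^2
  f <- ifelse(r2 > 0, (1 - exp(-r2 / r_c^2)) / r2, 1 / r_c^2) * Gamma / (2 * pi)
  u <- cbind(-xy[, 2] * f, xy[, 1] * f, 0)
  flow_field(grid, mask, 0, list(u),
             meta = list(generator = "lamb_oseen_field", Gamma = Gamma, r_c = r_c))
}

#' @describeIn analytic_fields ABC (Arnold-Beltrami-Childress) flow on a
#'   2-pi-periodic box, sampled on \code{nodes^3} points covering one
#'   period: a Beltrami field with \code{curl(u) = u}, so the helicity
#'   density is \code{|u|^2} and its volume mean is \code{A^2 + B^2 + C^2}.
#' @param A,B,C mode amplitudes (m/s).
#' @export
abc_flow_field <- function(A, B, C, nodes = 48L) {
  stopifnot(nodes >= 8)
  h <- 2 * pi / nodes
  grid <- uniform_grid(rep(nodes, 3), h, c(0, 0, 0))
  mask <- fluid_mask(grid, rep(1L, grid_n_nodes(grid)))
  p <- node_coords(grid)
  u <- cbind(A * sin(p[, 3]) + C * cos(p[, 2]),
             B * sin(p[, 1]) + A * cos(p[, 3]),
             C * sin(p[, 2]) + B * cos(p[, 1]))
  flow_field(grid, mask, 0, list(u),
             meta = list(generator = "abc_flow_field", A = A, B = B, C = C))
}

#' @describeIn analytic_fields Swirling pipe flow with smooth no-slip
#'   profiles: axial \code{U0 (1 - r^2/R^2)} plus azimuthal rotation
#'   \code{Omega0 (1 - r^2/R^2)^2 r}. The helicity density on the axis is
#'   \code{2 Omega0 U0} and its exact area average over the cross-section
#'   is \code{Omega0 U0 / 3}.
#' @param U0 centreline axial velocity (m/s).
#' @param Omega0 centreline rotation rate (1/s).
#' @export
swirl_pipe_field <- function(R, U0, Omega0, nodes_per_diameter = 64L,
                             n_axial = 6L) {
  stopifnot(R > 0)
  if (nodes_per_diameter < 16)
    stop("swirl_pipe_field: resolution error - tube thinner than 16 nodes per diameter")
  lat <- .tube_lattice(R, nodes_per_diameter, n_axial)
  mask <- fluid_mask(lat$grid, lat$codes)
  n <- grid_n_nodes(lat$grid)
  s <- 1 - lat$r2 / R^2
  u <- matrix(0, n, 3)
  om <- Omega0 * s^2
  u[lat$fluid, 1] <- (-lat$xy[lat$fluid, 2]) * om[lat$fluid]
  u[lat$fluid, 2] <- lat$xy[lat$fluid, 1] * om[lat$fluid]
  u[lat$fluid, 3] <- U0 * s[lat$fluid]
  regions <- region_set(volumes = list(tube = which(lat$fluid)), mask = mask)
  flow_field(lat$grid, mask, 0, list(u), regions,
             meta = list(generator = "swirl_pipe_field", R = R, U0 = U0,
                         Omega0 = Omega0))
}

#' @describeIn analytic_fields Plane-channel flow between no-slip walls at
#'   \code{y = -H} and \code{y = +H}, aligned exactly on voxel faces so the
#'   wall-shear truncation error is free of voxelisation noise. Profile
#'   \code{U_max (1 - (y/H)^p)} with \code{p = 2} (parabolic, analytic wall
#'   shear \code{2 mu U_max / H}) or \code{p = 4} (quartic,
#'   \code{4 mu U_max / H}).
#' @param H channel half-height (m).
#' @param nodes_across fluid nodes across the channel.
#' @param profile \code{"parabolic"} or \code{"quartic"}.
#' @export
channel_field <- function(H, U_max, nodes_across = 32L,
                          profile = c("parabolic", "quartic"),
                          n_snapshots = 1L, n_axial = 6L, dt = 1e-2) {
  profile <- match.arg(profile)
  stopifnot(H > 0, nodes_across >= 8)
  h <- 2 * H / nodes_across
  ny <- nodes_across + 2L                     # one wall row each side
  grid <- uniform_grid(c(n_axial, ny, n_axial), h,
                       c(0, -H - h / 2, 0))   # fluid rows at -H+h/2 ... H-h/2
  y <- node_coords(grid)[, 2]
  codes <- rep(1L, grid_n_nodes(grid))
  codes[abs(y) > H] <- 2L
  mask <- fluid_mask(grid, codes)
  p <- if (profile == "parabolic") 2 else 4
  u <- matrix(0, grid_n_nodes(grid), 3)
  fl <- codes == 1L
  u[fl, 1] <- U_max * (1 - (y[fl] / H)^p)
  snaps <- rep(list(u), n_snapshots)
  regions <- region_set(surfaces = list(walls = seq_len(nrow(mask$faces))),
                        mask = mask)
  flow_field(grid, mask, seq(0, by = dt, length.out = n_snapshots), snaps,
             regions, meta = list(generator = "channel_field", H = H,
                                  U_max = U_max, profile = profile))
}

#' @describeIn analytic_fields Two counter-rotating planar vortices in a
#'   walled box chamber, built from a superposed Gaussian stream function
#'   (hence divergence-free): a qualitative stand-in for the central-atrium
#'   vortex and the smaller counter-rotating auricular vortex. Named volume
#'   regions \code{"vortex1"} and \code{"vortex2"} cover the two halves.
#' @param jet_speeds length-2 velocity scales of the two vortices (m/s);
#'   positive values give opposite senses of rotation.
#' @param chamber length-3 box dimensions (m).
#' @export
two_jet_chamber_field <- function(jet_speeds, chamber = c(0.06, 0.09, 0.05),
                                  nodes = c(20L, 30L, 16L)) {
  stopifnot(length(jet_speeds) == 2, all(is.finite(jet_speeds)),
            length(chamber) == 3, all(chamber > 0))
  if (length(nodes) == 1L) nodes <- rep(nodes, 3)
  h <- chamber / (nodes - 1)
  grid <- uniform_grid(nodes, h, c(0, 0, 0))
  p <- node_coords(grid)
  d <- grid$dims
  codes <- rep(1L, grid_n_nodes(grid))
  ijk <- cbind((seq_along(codes) - 1L) %% d[1],
               ((seq_along(codes) - 1L) %/% d[1]) %% d[2],
               (seq_along(codes) - 1L) %/% (d[1] * d[2]))
  on_shell <- ijk[, 1] %in% c(0L, d[1] - 1L) | ijk[, 2] %in% c(0L, d[2] - 1L) |
    ijk[, 3] %in% c(0L, d[3] - 1L)
  codes[on_shell] <- 2L
  mask <- fluid_mask(grid, codes)
  sig <- chamber[2] / 12
  c1 <- c(chamber[1] / 2, chamber[2] / 3)
  c2 <- c(chamber[1] / 2, 2 * chamber[2] / 3)
  # stream function psi = s1 sig G1 - s2 sig G2; u = dpsi/dy, v = -dpsi/dx
  g1 <- exp(-((p[, 1] - c1[1])^2 + (p[, 2] - c1[2])^2) / sig^2)
  g2 <- exp(-((p[, 1] - c2[1])^2 + (p[, 2] - c2[2])^2) / sig^2)
  dpsi_dx <- jet_speeds[1] * sig * g1 * (-2 * (p[, 1] - c1[1]) / sig^2) -
    jet_speeds[2] * sig * g2 * (-2 * (p[, 1] - c2[1]) / sig^2)
  dpsi_dy <- jet_speeds[1] * sig * g1 * (-2 * (p[, 2] - c1[2]) / sig^2) -
    jet_speeds[2] * sig * g2 * (-2 * (p[, 2] - c2[2]) / sig^2)
  u <- cbind(dpsi_dy, -dpsi_dx, 0)
  u[codes != 1L, ] <- 0
  fl <- which(codes == 1L)
  regions <- region_set(
    volumes = list(chamber = fl,
                   vortex1 = fl[p[fl, 2] < chamber[2] / 2],
                   vortex2 = fl[p[fl, 2] >= chamber[2] / 2]),
    surfaces = list(walls = seq_len(nrow(mask$faces))),
    mask = mask)
  flow_field(grid, mask, 0, list(u), regions,
             meta = list(generator = "two_jet_chamber_field",
                         jet_speeds = jet_speeds, chamber = chamber))
}
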