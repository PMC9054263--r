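# small helper: field whose single component alternates +A/-A in time
alternating_field <- function(A, n = 20, nodes = 5L) {
  base <- uniform_field(c(0, 0, 0), nodes = nodes)
  snaps <- lapply(seq_len(n), function(s) {
    u <- matrix(0, grid_n_nodes(base$grid), 3)
    u[, 1] <- A * (-1)^s
    u
  })
  flow_field(base$grid, base$mask, seq(0, by = 0.01, length.out = n), snaps)
}

test_that("sliding-window means reduce correctly", {
  f <- uniform_field(c(0.3, 0.1, -0.2), nodes = 5L)
  f5 <- flow_field(f$grid, f$mask, seq(0, 0.4, by = 0.1), rep(f$snapshots, 5))
  m <- sliding_window_mean(f5, time_average_spec(3))
  expect_equal(n_snapshots(m), 3)                 # n - window + 1
  expect_equal(m$snapshots[[1]], f$snapshots[[1]])
  m1 <- sliding_window_mean(f5, time_average_spec(1))
  expect_identical(m1$snapshots, f5$snapshots)    # window 1 is the identity
  expect_error(sliding_window_mean(f, time_average_spec(2)), "fewer snapshots")
  # sinusoid over an integer number of periods averages to its offset
  nodes <- 4L; n <- 40
  grid <- uniform_grid(rep(nodes, 3), 0.1)
  mask <- fluid_mask(grid, rep(1L, grid_n_nodes(grid)))
  snaps <- lapply(seq_len(n), function(s) {
    u <- matrix(0, grid_n_nodes(grid), 3)
    u[, 2] <- 0.25 + 0.6 * sin(2 * pi * (s - 1) / 10)
    u
  })
  fs <- flow_field(grid, mask, seq(0, by = 0.01, length.out = n), snaps)
  ms <- sliding_window_mean(fs, time_average_spec(10))  # one full period
  for (q in c(1, 15, 31))
    expect_equal(max(abs(ms$snapshots[[q]][, 2] - 0.25)), 0, tolerance = 1e-10)
})

test_that("resolved TKE recovers variance-based closed forms", {
  f <- uniform_field(c(0.3, 0.1, -0.2), nodes = 5L)
  f5 <- flow_field(f$grid, f$mask, seq(0, 0.4, by = 0.1), rep(f$snapshots, 5))
  expect_equal(max(resolved_tke(f5, time_average_spec(5))), 0)
  A <- 0.4
  fa <- alternating_field(A, n = 20)
  kr <- resolved_tke(fa, time_average_spec(20))   # window = whole horizon
  expect_equal(unique(round(kr, 12)), A^2 / 2)
})

test_that("total TKE aggregates volumes, energies and thresholds", {
  grid <- uniform_grid(c(6, 6, 6), 0.01)      # 1e-6 m^3 voxels
  mask <- fluid_mask(grid, rep(1L, grid_n_nodes(grid)))
  uf <- flow_field(grid, mask, 0, list(matrix(0, grid_n_nodes(grid), 3)))
  n <- grid_n_nodes(uf$grid)
  fl <- fluid_nodes(uf$mask)
  vcell <- grid_cell_volume(uf$grid)
  k <- rep(0.01, n)
  # uniform 0.01 J/kg over a 100-cell (1e-4 m^3) region: 1.05 mJ
  tt <- total_tke(k, 0, uf, region = fl[1:100], rho = 1050)
  expect_equal(tt$energy_mJ, 1.05)
  expect_equal(tt$volume_average, 0.01)
  expect_equal(total_tke(0 * k, 0, uf)$volume_average, 0)
  # exceedance volume: half at 0.1, half at 0, threshold 0.08
  k2 <- rep(0, n)
  k2[fl[seq_len(length(fl) %/% 2)]] <- 0.1
  expect_equal(tke_exceedance_volume(k2, uf, 0.08),
               (length(fl) %/% 2) * vcell)
  expect_equal(tke_exceedance_volume(k2, uf, 1), 0)
  # brute-force oracle on a continuous synthetic field
  set.seed(11)
  k3 <- rep(0, n); k3[fl] <- runif(length(fl), 0, 0.2)
  expect_equal(tke_exceedance_volume(k3, uf, 0.08),
               sum(k3[fl] > 0.08) * vcell)
})

test_that("aligned vorticity averages respect sign, axis and cancellation", {
  f <- two_jet_chamber_field(c(0.5, 0.2))
  om <- vorticity(f, 1)
  v1 <- aligned_vorticity_average(om, c(0, 0, 1), f$regions$volumes$vortex1)
  v2 <- aligned_vorticity_average(om, c(0, 0, 1), f$regions$volumes$vortex2)
  expect_lt(v1 * v2, 0)
  # planar flow has no in-plane vorticity: a perpendicular axis reads zero
  vx <- aligned_vorticity_average(om, c(1, 0, 0), f$regions$volumes$chamber)
  expect_lt(abs(vx) / abs(v1), 1e-8)
  expect_error(aligned_vorticity_average(om, c(0, 0, 2),
                                         f$regions$volumes$chamber),
               "unit vector")
  fe <- two_jet_chamber_field(c(0.3, 0.3))
  net <- aligned_vorticity_average(vorticity(fe, 1), c(0, 0, 1),
                                   fe$regions$volumes$chamber)
  expect_lt(abs(net), 1e-12)
})

test_that("plane-averaged helicity matches closed forms", {
  # constant helicity field averages to the constant
  uf <- uniform_field(c(0.1, 0, 0), nodes = 7L)
  h <- rep(3.21, grid_n_nodes(uf$grid))
  pl <- plane_section(c(0, 0, 0.05), c(0, 0, 1))
  expect_equal(plane_average_helicity(h, uf, pl), 3.21, tolerance = 1e-12)
  # Poiseuille: identically zero
  f <- poiseuille_field(0.005, 0.3, 32)
  hp <- helicity_density(f$snapshots[[1]], vorticity(f, 1))
  zmid <- f$grid$origin[3] + 2.5 * f$grid$spacing[3]
  expect_equal(plane_average_helicity(hp, f,
                                      plane_section(c(0, 0, zmid), c(0, 0, 1))), 0)
  # swirling pipe: exact area average Omega0 * U0 / 3, axis value 2 Omega0 U0
  U0 <- 0.3; Om0 <- 50
  fs <- swirl_pipe_field(0.01, U0, Om0, nodes_per_diameter = 64)
  hs <- helicity_density(fs$snapshots[[1]], vorticity(fs, 1))
  ctr <- node_index(fs$grid, (fs$grid$dims[1] + 1) / 2,
                    (fs$grid$dims[2] + 1) / 2, 3)
  expect_rel(hs[ctr], 2 * Om0 * U0, 0.02)
  zmid <- fs$grid$origin[3] + 2.5 * fs$grid$spacing[3]
  pah <- plane_average_helicity(hs, fs,
                                plane_section(c(0, 0, zmid), c(0, 0, 1)))
  expect_rel(pah, Om0 * U0 / 3, 0.03)
})

test_that("wall shear stress matches the Poiseuille oracle and is linear in mu", {
  R <- 0.01; Umax <- 0.4; mu <- 3e-3
  f <- poiseuille_field(R, Umax, 64, n_snapshots = 2)
  rec <- wall_shear_stress(f, mu)
  tw <- tawss(rec, time_average_spec(2))
  sa <- surface_average(tw, f$mask, f$regions$surfaces)
  expect_rel(sa$averages[["wall"]], 2 * mu * Umax / R, 0.03)
  # the analytic identity 2 mu U_max / R = 4 mu U_mean / R
  expect_equal(2 * mu * Umax / R, 4 * mu * (Umax / 2) / R)
  rec2 <- wall_shear_stress(f, 2 * mu)
  expect_equal(rec2$magnitude, 2 * rec$magnitude, tolerance = 1e-12)
  # zero flow -> zero shear
  fz <- flow_field(f$grid, f$mask, 0, list(matrix(0, grid_n_nodes(f$grid), 3)))
  expect_equal(max(wall_shear_stress(fz, mu)$magnitude), 0)
})

test_that("wall shear errors on walls thinner than the one-sided stencil", {
  g <- uniform_grid(c(5, 4, 4), 0.01)
  codes <- rep(2L, grid_n_nodes(g))
  xi <- (seq_len(grid_n_nodes(g)) - 1L) %% 5L
  codes[xi %in% c(1L, 2L)] <- 1L          # only two fluid planes deep
  mask <- fluid_mask(g, codes)
  u <- matrix(0, grid_n_nodes(g), 3)
  f <- flow_field(g, mask, 0, list(u))
  expect_error(wall_shear_stress(f, 1e-3), "stencil error")
})

test_that("TAWSS time-averages shear magnitudes", {
  R <- 0.008; Umax <- 0.3; mu <- 2.5e-3
  f <- poiseuille_field(R, Umax, 32, n_snapshots = 4)
  rec <- wall_shear_stress(f, mu)
  expect_equal(tawss(rec, time_average_spec(4)), rec$magnitude[, 1])
  # alternating magnitudes 1, 3 average to 2
  rec2 <- rec
  rec2$magnitude <- matrix(rep(c(1, 3), each = nrow(rec$magnitude)),
                           nrow(rec$magnitude), 2)
  expect_equal(unique(tawss(rec2, time_average_spec(2))), 2)
  expect_true(all(tawss(rec, time_average_spec(2)) <=
                  apply(rec$magnitude, 1, max) + 1e-15))
})

test_that("quasi-steady pulsatile Poiseuille TAWSS matches the analytic mean", {
  R <- 0.01; mu <- 3e-3
  base <- poiseuille_field(R, 1, 48)
  scale <- 1 + 0.5 * sin(2 * pi * (0:9) / 10)
  snaps <- lapply(scale, function(s) s * base$snapshots[[1]])
  f <- flow_field(base$grid, base$mask, seq(0, by = 0.01, length.out = 10),
                  snaps, base$regions)
  rec <- wall_shear_stress(f, mu)
  tw <- tawss(rec, time_average_spec(10))
  sa <- surface_average(tw, f$mask, f$regions$surfaces)
  expect_rel(sa$averages[["wall"]], mean(scale) * 2 * mu * 1 / R, 0.03)
})

test_that("surface averages are area-weighted with pairwise differences", {
  f <- channel_field(0.005, 0.2, nodes_across = 16)
  nf <- nrow(f$mask$faces)
  vals <- rep(2.5, nf)
  sa <- surface_average(vals, f$mask, list(walls = seq_len(nf)))
  expect_equal(sa$averages[["walls"]], 2.5)
  top <- which(f$mask$faces$ny > 0); bot <- which(f$mask$faces$ny < 0)
  vals[top] <- 3; vals[bot] <- 1
  sa2 <- surface_average(vals, f$mask, list(upper = top, lower = bot))
  expect_equal(unname(sa2$differences$difference), 2)
  # equal-area checkerboard equals the arithmetic mean
  vals3 <- rep(c(1, 2), length.out = length(top))
  sa3 <- surface_average(vals3, f$mask, list(s = top))
  expect_equal(sa3$averages[["s"]], mean(vals3))
})

test_that("region aggregation is conservative under splitting", {
  f <- two_jet_chamber_field(c(0.5, 0.2))
  om <- vorticity(f, 1)
  all_n <- f$regions$volumes$chamber
  a <- f$regions$volumes$vortex1; b <- f$regions$volumes$vortex2
  va <- aligned_vorticity_average(om, c(0, 0, 1), a)
  vb <- aligned_vorticity_average(om, c(0, 0, 1), b)
  vall <- aligned_vorticity_average(om, c(0, 0, 1), all_n)
  expect_equal((va * length(a) + vb * length(b)) / length(all_n), vall,
               tolerance = 1e-14)
})

test_that("mirror reflection flips helicity and preserves TKE", {
  spec <- turbulence_spec(0.03, n_modes = 16, seed = 8)
  f <- synthetic_turbulence(spec, nodes = 12, n_snapshots = 30)
  fm <- mirror_field_x(f)
  kr <- resolved_tke(f, time_average_spec(30))
  krm <- resolved_tke(fm, time_average_spec(30))
  expect_equal(sort(krm), sort(kr), tolerance = 1e-12)
  h <- helicity_density(f$snapshots[[1]], vorticity(f, 1))
  hm <- helicity_density(fm$snapshots[[1]], vorticity(fm, 1))
  fl <- fluid_nodes(f$mask)
  expect_equal(mean(hm[fl]), -mean(h[fl]), tolerance = 1e-10)
})

test_that("vorticity, helicity and wall shear converge at second order", {
  # vorticity: Lamb-Oseen peak
  hs <- c(8, 16, 32)
  err_v <- vapply(hs, function(npc) {
    f <- lamb_oseen_field(2e-3, 0.003, nodes_per_core = npc, extent_cores = 2)
    om <- vorticity(f, 1)
    ctr <- node_index(f$grid, (f$grid$dims[1] + 1) / 2,
                      (f$grid$dims[2] + 1) / 2, 3)
    abs(om[ctr, 3] / (2e-3 / (pi * 0.003^2)) - 1)
  }, 0)
  expect_gt(convergence_slope(1 / hs, err_v), 1.8)
  # helicity: ABC interior nodes against the pointwise Beltrami identity
  # h = |u|^2 (one-sided boundary stencils would mix in a lower-order rim)
  ns <- c(12, 24, 48)
  err_h <- vapply(ns, function(n) {
    f <- abc_flow_field(1, 0.8, 0.6, nodes = n)
    h <- helicity_density(f$snapshots[[1]], vorticity(f, 1))
    d <- f$grid$dims
    sel <- array(FALSE, d)
    sel[4:(d[1] - 3), 4:(d[2] - 3), 4:(d[3] - 3)] <- TRUE
    idx <- which(as.vector(sel))
    tgt <- mean(rowSums(f$snapshots[[1]][idx, ]^2))
    abs(mean(h[idx]) / tgt - 1)
  }, 0)
  expect_gt(convergence_slope(1 / ns, err_h), 1.8)
  # wall shear: quartic channel profile on face-aligned walls
  ms <- c(8, 16, 32)
  err_w <- vapply(ms, function(m) {
    f <- channel_field(0.005, 0.3, nodes_across = m, profile = "quartic")
    rec <- wall_shear_stress(f, 2e-3)
    tw <- tawss(rec, time_average_spec(1))
    sa <- surface_average(tw, f$mask, f$regions$surfaces)
    abs(sa$averages[["walls"]] / (4 * 2e-3 * 0.3 / 0.005) - 1)
  }, 0)
  expect_gt(convergence_slope(1 / ms, err_w), 1.8)
})
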