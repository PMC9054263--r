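test_that("Poiseuille generator matches its closed form", {
  R <- 0.005; Umax <- 0.3
  f <- poiseuille_field(R, Umax, 32)
  u <- f$snapshots[[1]]
  ctr <- node_index(f$grid, (f$grid$dims[1] + 1) / 2,
                    (f$grid$dims[2] + 1) / 2, 3)
  expect_equal(u[ctr, 3], Umax)                      # centreline velocity
  expect_true(all(u[, 1] == 0) && all(u[, 2] == 0))  # purely axial
  # helicity density vanishes identically: u is axial, omega azimuthal
  h <- helicity_density(u, vorticity(f, 1))
  expect_equal(max(abs(h)), 0)
  expect_error(poiseuille_field(R, Umax, 8), "resolution error")
})

test_that("solid-body rotation has curl 2*Omega and zero strain", {
  Om <- 7.5
  f <- solid_body_rotation_field(Om, extent = 0.5, nodes = 12)
  om <- vorticity(f, 1)
  expect_true(all(abs(om[, 3] - 2 * Om) < 1e-10 * abs(Om)))
  expect_true(all(abs(om[, 1:2]) < 1e-10))
  expect_lt(max(strain_modulus(velocity_gradient(f, 1))), 1e-9)
  f0 <- solid_body_rotation_field(0, nodes = 8)
  expect_equal(max(abs(f0$snapshots[[1]])), 0)
})

test_that("Lamb-Oseen vortex reproduces peak vorticity and circulation", {
  G <- 2e-3; rc <- 0.003
  f <- lamb_oseen_field(G, rc, nodes_per_core = 32, extent_cores = 3)
  om <- vorticity(f, 1)
  ctr <- node_index(f$grid, (f$grid$dims[1] + 1) / 2,
                    (f$grid$dims[2] + 1) / 2, 3)
  expect_rel(om[ctr, 3], G / (pi * rc^2), 0.02)
  # line-integral circulation on a loop well outside the core
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  rr <- 2.5 * rc
  pts <- cbind(rr * cos(th), rr * sin(th),
               f$grid$origin[3] + 2 * f$grid$spacing[3])
  uu <- trilinear_interp(f$grid, f$snapshots[[1]], pts)
  circ <- sum(rowSums(uu * cbind(-sin(th), cos(th), 0))) *
    (2 * pi * rr / length(th))
  expect_rel(circ, G, 0.02)
  f0 <- lamb_oseen_field(0, rc, nodes_per_core = 8)
  expect_equal(max(abs(f0$snapshots[[1]])), 0)
})

test_that("ABC flow is Beltrami: mean helicity A^2+B^2+C^2, odd under parity", {
  A <- 1.1; B <- 0.7; C <- 0.9
  f <- abc_flow_field(A, B, C, nodes = 48)
  h <- helicity_density(f$snapshots[[1]], vorticity(f, 1))
  fl <- fluid_nodes(f$mask)
  expect_rel(mean(h[fl]), A^2 + B^2 + C^2, 0.02)
  f0 <- abc_flow_field(0, 0, 0, nodes = 8)
  expect_equal(max(abs(f0$snapshots[[1]])), 0)
  fm <- mirror_field_x(f)
  hm <- helicity_density(fm$snapshots[[1]], vorticity(fm, 1))
  expect_equal(mean(hm[fl]), -mean(h[fl]), tolerance = 1e-10)
})

test_that("synthetic turbulence hits its ensemble TKE and is seed-stable", {
  spec <- turbulence_spec(0.05, n_modes = 32, seed = 42)
  f <- synthetic_turbulence(spec, nodes = 20, n_snapshots = 200)
  kr <- resolved_tke(f, time_average_spec(50))
  expect_rel(mean(kr[fluid_nodes(f$mask)]), 0.05, 0.05)
  # snapshots are zero-mean by construction
  em <- Reduce(`+`, f$snapshots) / length(f$snapshots)
  expect_lt(max(abs(em)), 0.2 * sqrt(2 * 0.05))
  f2 <- synthetic_turbulence(spec, nodes = 20, n_snapshots = 200)
  expect_identical(f$snapshots, f2$snapshots)
  fz <- synthetic_turbulence(turbulence_spec(0, seed = 1), nodes = 8,
                             n_snapshots = 3)
  expect_equal(max(abs(fz$snapshots[[3]])), 0)
  expect_error(
    synthetic_turbulence(turbulence_spec(0.01, n_modes = 400, seed = 1),
                         nodes = 8, n_snapshots = 2),
    "spectral error")
})

test_that("pulsatile waveforms hit the target pulsatility index exactly", {
  for (shape in c("sine", "two_harmonic")) {
    w <- pulsatile_waveform(waveform_spec(1, 6.5e-5, 2.45, shape))
    expect_lt(abs(pulsatility_index(w) - 2.45), 1e-6)
    expect_equal(mean(w$q), 6.5e-5, tolerance = 1e-12)
  }
  wc <- pulsatile_waveform(waveform_spec(1, 1e-4, 0, "sine"))
  expect_equal(max(wc$q) - min(wc$q), 0)
  # sine closed form: PI = 2a/m
  ws <- pulsatile_waveform(waveform_spec(1, 2e-4, 1.2, "sine", samples = 400))
  a <- (max(ws$q) - min(ws$q)) / 2
  expect_equal(2 * a / mean(ws$q), 1.2, tolerance = 1e-9)
})

test_that("morphometry generator recovers its CV targets and is seeded", {
  vs <- data.frame(vessel = letters[1:8],
                   mean_min = c(0.84, 0.56, 0.96, 0.80, 1.03, 1.00, 0.42, 0.32),
                   mean_max = c(2.90, 1.74, 1.70, 1.55, 2.05, 1.81, 1.15, 1.03),
                   cv_min = 0.33, cv_max = 0.17)
  tab <- morphometry_table_generator(500, vs, seed = 7)
  cmp <- compare_min_max_variability(tab)
  expect_rel(cmp$mean_cv_min, 0.33, 0.05)
  expect_rel(cmp$mean_cv_max, 0.17, 0.05)
  expect_true(all(tab$a_min <= tab$a_max))
  expect_true(all(as.matrix(tab[, -1]) > 0))
  tab2 <- morphometry_table_generator(500, vs, seed = 7)
  expect_identical(tab, tab2)
  vs0 <- transform(vs, cv_min = 0, cv_max = 0)
  t0 <- morphometry_table_generator(20, vs0, seed = 1)
  expect_equal(sd_population(t0$a_min), 0)
  expect_equal(t0$b_max, rep(vs$mean_max[2], 20))
})

test_that("two-jet chamber holds two counter-rotating vortices", {
  f <- two_jet_chamber_field(c(0.5, 0.2))
  om <- vorticity(f, 1)
  v1 <- aligned_vorticity_average(om, c(0, 0, 1), f$regions$volumes$vortex1)
  v2 <- aligned_vorticity_average(om, c(0, 0, 1), f$regions$volumes$vortex2)
  expect_lt(v1 * v2, 0)
  fe <- two_jet_chamber_field(c(0.4, 0.4))
  net <- aligned_vorticity_average(vorticity(fe, 1), c(0, 0, 1),
                                   fe$regions$volumes$chamber)
  expect_lt(abs(net), 1e-12)
  f0 <- two_jet_chamber_field(c(0, 0))
  expect_equal(max(abs(f0$snapshots[[1]])), 0)
})

test_that("analytic fields are discretely divergence-free at second order", {
  # ABC flow: each component is constant along its own axis, so the
  # discrete divergence vanishes identically
  fa <- abc_flow_field(1, 0.8, 0.6, nodes = 16)
  ga <- velocity_gradient(fa, 1)
  diva <- ga$g[, 1, 1] + ga$g[, 2, 2] + ga$g[, 3, 3]
  expect_lt(max(abs(diva)), 1e-10)
  # Lamb-Oseen: nontrivial cancellation, second-order residual
  err <- vapply(c(8, 16, 32), function(npc) {
    f <- lamb_oseen_field(2e-3, 0.003, nodes_per_core = npc, extent_cores = 2)
    g <- velocity_gradient(f, 1)
    div <- g$g[, 1, 1] + g$g[, 2, 2] + g$g[, 3, 3]
    sqrt(mean(div[fluid_nodes(f$mask)]^2))
  }, 0)
  expect_gt(convergence_slope(1 / c(8, 16, 32), err), 1.8)
})
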