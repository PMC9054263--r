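# shared fixture helpers: small hand-built fields and transformations

# all-fluid cube with a velocity given by fun(x, y, z) -> n x 3
make_cube_field <- function(fun, nodes = 8L, extent = 1, n_snapshots = 1L) {
  h <- extent / (nodes - 1)
  grid <- uniform_grid(rep(nodes, 3), h, rep(-extent / 2, 3))
  mask <- fluid_mask(grid, rep(1L, grid_n_nodes(grid)))
  p <- node_coords(grid)
  u <- fun(p[, 1], p[, 2], p[, 3])
  flow_field(grid, mask, seq(0, by = 0.01, length.out = n_snapshots),
             rep(list(u), n_snapshots))
}

uniform_field <- function(vel = c(0.3, -0.1, 0.2), nodes = 8L) {
  make_cube_field(function(x, y, z)
    cbind(rep(vel[1], length(x)), vel[2], vel[3]), nodes = nodes)
}

# simple shear u = (gamma * y, 0, 0)
shear_field <- function(gamma = 100, nodes = 8L, extent = 0.01) {
  make_cube_field(function(x, y, z) cbind(gamma * y, 0, 0),
                  nodes = nodes, extent = extent)
}

# mirror a field through the x = const mid-plane (x -> -x, u_x -> -u_x):
# a parity transformation that flips the sign of any pseudoscalar
mirror_field_x <- function(field) {
  d <- field$grid$dims
  perm <- as.vector(array(seq_len(prod(d)), dim = d)[d[1]:1, , ])
  mask <- fluid_mask(field$grid, field$mask$labels[perm])
  snaps <- lapply(field$snapshots, function(u) {
    v <- u[perm, , drop = FALSE]
    v[, 1] <- -v[, 1]
    v
  })
  flow_field(field$grid, mask, field$times, snaps)
}

# log-log least-squares convergence slope from errors at spacings h
convergence_slope <- function(h, err) {
  unname(coef(lm(log(err) ~ log(h)))[2])
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
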