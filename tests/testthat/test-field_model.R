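test_that("grid, mask and plane constructors enforce their invariants", {
  expect_error(uniform_grid(c(1, 4, 4), 0.1), "dims")
  expect_error(uniform_grid(c(4, 4, 4), c(0.1, -0.1, 0.1)), "spacing")
  g <- uniform_grid(c(3, 4, 5), c(0.1, 0.2, 0.3))
  expect_equal(grid_n_nodes(g), 60)
  expect_equal(grid_cell_volume(g), 0.1 * 0.2 * 0.3)
  expect_error(fluid_mask(g, rep(0L, 60)), "at least one fluid")
  expect_error(fluid_mask(g, rep(1L, 59)), "labels")
  pl <- plane_section(c(0, 0, 0), c(0, 0, 5))
  expect_equal(sqrt(sum(pl$normal^2)), 1, tolerance = 1e-12)
  expect_error(plane_section(c(0, 0, 0), c(0, 0, 0)), "nonzero")
})

test_that("every wall face separates exactly one fluid and one wall node", {
  f <- poiseuille_field(0.005, 0.2, 16)
  faces <- f$mask$faces
  expect_true(all(f$mask$labels[faces$fluid] == 1L))
  expect_true(all(f$mask$labels[faces$wall] == 2L))
  # wall-face centroid sits between the two nodes along the face axis
  d <- abs(node_coords(f$grid, faces$fluid) - node_coords(f$grid, faces$wall))
  expect_true(all(abs(rowSums(d) - f$grid$spacing[1]) < 1e-12))
})

test_that("write/read round-trips are bitwise lossless on both formats", {
  f <- poiseuille_field(0.005, 0.3, 16, n_snapshots = 2)
  for (fmt in c("vtk_legacy", "array_archive")) {
    path <- tempfile(fileext = if (fmt == "array_archive") ".rds" else "")
    write_field(f, path, fmt)
    f2 <- read_field(path, fmt)
    expect_identical(f2$snapshots, f$snapshots)
    expect_identical(f2$times, f$times)
    expect_identical(f2$mask$labels, f$mask$labels)
    expect_identical(f2$grid$spacing, f$grid$spacing)
    expect_identical(lapply(f2$regions$volumes, as.integer),
                     lapply(f$regions$volumes, as.integer))
    unlink(path, recursive = TRUE)
  }
})

test_that("an empty-region two-snapshot field writes and reads back", {
  f <- uniform_field(nodes = 6L)
  f2 <- flow_field(f$grid, f$mask, c(0, 0.1), rep(f$snapshots, 2))
  path <- tempfile()
  write_field(f2, path, "vtk_legacy")
  man <- jsonlite::read_json(file.path(path, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$n_snapshots, 2L)
  expect_length(man$regions$volumes, 0)
  f3 <- read_field(path, "vtk_legacy")
  expect_identical(f3$snapshots, f2$snapshots)
  unlink(path, recursive = TRUE)
})

test_that("malformed files raise errors naming the offending record", {
  f <- uniform_field(nodes = 6L)
  path <- tempfile()
  write_field(f, path, "vtk_legacy")
  snap <- file.path(path, "snapshot_0001.vtk")
  lines <- readLines(snap)
  # corrupt the velocity payload
  bad <- lines
  bad[grep("^VECTORS", lines) + 3] <- "not numbers here"
  writeLines(bad, snap)
  expect_error(read_field(path, "vtk_legacy"), "VECTORS velocity")
  # node-count mismatch between payload and grid
  bad <- lines
  bad[grep("^POINT_DATA", lines)] <- "POINT_DATA 9999"
  writeLines(bad, snap)
  expect_error(read_field(path, "vtk_legacy"), "node count")
  unlink(path, recursive = TRUE)
  expect_error(read_field(tempfile(), "array_archive"), "no such file")
})

test_that("generator round-trip preserves peak velocity and vorticity", {
  f <- poiseuille_field(0.004, 0.37, 24)
  path <- tempfile()
  write_field(f, path, "vtk_legacy")
  f2 <- read_field(path, "vtk_legacy")
  expect_equal(max(f2$snapshots[[1]][, 3]), 0.37)
  unlink(path, recursive = TRUE)
  lo <- lamb_oseen_field(1e-3, 0.002, nodes_per_core = 16, extent_cores = 3)
  pth <- tempfile(fileext = ".rds")
  write_field(lo, pth, "array_archive")
  lo2 <- read_field(pth, "array_archive")
  peak <- function(fl) max(vorticity(fl, 1)[, 3])
  expect_identical(peak(lo2), peak(lo))
  unlink(pth)
})

test_that("plane sections recover analytic areas and constant fields", {
  R <- 0.01
  f <- poiseuille_field(R, 0.4, 64, n_axial = 6)
  zmid <- f$grid$origin[3] + 2.5 * f$grid$spacing[3]
  sec <- extract_plane(f, plane_section(c(0, 0, zmid), c(0, 0, 1)))
  expect_rel(sum(sec$area), pi * R^2, 0.02)
  # plane outside the domain
  expect_error(extract_plane(f, plane_section(c(0, 0, 1), c(0, 0, 1))),
               "empty section")
  # uniform velocity interpolates to the constant
  uf <- uniform_field(c(0.2, -0.3, 0.15), nodes = 9L)
  su <- extract_plane(uf, plane_section(c(0, 0, 0.01), c(1, 1, 1)))
  expect_true(all(abs(su$u - 0.2) < 1e-12))
  expect_true(all(abs(su$v + 0.3) < 1e-12))
  expect_true(all(abs(su$w - 0.15) < 1e-12))
})

test_that("plane-section area error shrinks under grid refinement", {
  R <- 0.01
  err <- vapply(c(24, 48, 96), function(npd) {
    f <- poiseuille_field(R, 0.1, npd, n_axial = 5)
    zmid <- f$grid$origin[3] + 2 * f$grid$spacing[3]
    sec <- extract_plane(f, plane_section(c(0, 0, zmid), c(0, 0, 1)))
    abs(sum(sec$area) / (pi * R^2) - 1)
  }, 0)
  expect_lt(err[2], err[1])
  expect_lt(err[3], 0.02)
})
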