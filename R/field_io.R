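#' Write a sampled flow field to disk
#'
#' Two on-disk forms are supported. \code{"vtk_legacy"} writes a directory
#' of ASCII VTK legacy structured-points files (one per snapshot, velocity
#' as a 3-component point-data vector field, the fluid/wall/exterior mask as
#' point scalars) plus a JSON manifest indexing times, regions and
#' metadata; numbers are printed with 17 significant digits so doubles
#' round-trip bitwise. \code{"array_archive"} bundles the whole object into
#' a single RDS archive (grid, mask, regions, times, snapshots), trivially
#' lossless.
#'
#' @param field a [flow_field()].
#' @param path output directory (\code{vtk_legacy}) or file
#'   (\code{array_archive}).
#' @param format \code{"vtk_legacy"} or \code{"array_archive"}.
#' @return \code{path}, invisibly.
#' @seealso [read_field()]
#' @export
write_field <- function(field, path, format = c("vtk_legacy", "array_archive")) {
  stopifnot(inherits(field, "flow_field"))
  format <- match.arg(format)
  if (format == "array_archive") {
    ok <- tryCatch({ saveRDS(field, path); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop(sprintf("write_field: cannot write '%s'", path))
    return(invisible(path))
  }
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("write_field: cannot create directory '%s'", path))
  }
  files <- sprintf("snapshot_%04d.vtk", seq_along(field$times))
  for (s in seq_along(field$times))
    .write_vtk_snapshot(field, s, file.path(path, files[s]))
  manifest <- list(
    format = "atriumflow-vtk-legacy", version = 1L,
    n_snapshots = length(field$times),
    times = field$times, files = files, units = "SI (m, s, m/s)",
    regions = list(volumes = field$regions$volumes,
                   surfaces = field$regions$surfaces),
    meta = field$meta)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.write_vtk_snapshot <- function(field, s, file) {
  g <- field$grid
  n <- grid_n_nodes(g)
  u <- field$snapshots[[s]]
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("atriumflow velocity snapshot %d, t = %.17g s",
                       s, field$times[s]),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", g$dims[1], g$dims[2], g$dims[3]),
               sprintf("ORIGIN %.17g %.17g %.17g",
                       g$origin[1], g$origin[2], g$origin[3]),
               sprintf("SPACING %.17g %.17g %.17g",
                       g$spacing[1], g$spacing[2], g$spacing[3]),
               sprintf("POINT_DATA %d", n),
               "SCALARS mask int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(format(field$mask$labels, trim = TRUE, scientific = FALSE), con)
  writeLines("VECTORS velocity double", con)
  writeLines(sprintf("%.17g %.17g %.17g", u[, 1], u[, 2], u[, 3]), con)
}

#' Read a sampled flow field from disk
#'
#' Inverse of [write_field()]; validates all container invariants on load
#' (snapshot shapes, strictly increasing times, no-slip zeros on wall
#' nodes).
#'
#' @param path directory (\code{vtk_legacy}) or file (\code{array_archive})
#'   produced by [write_field()].
#' @param format \code{"vtk_legacy"} or \code{"array_archive"}.
#' @return A [flow_field()].
#' @export
read_field <- function(path, format = c("vtk_legacy", "array_archive")) {
  format <- match.arg(format)
  if (format == "array_archive") {
    if (!file.exists(path)) stop(sprintf("read_field: no such file '%s'", path))
    f <- readRDS(path)
    if (!inherits(f, "flow_field"))
      stop("read_field: archive does not contain a flow_field")
    # re-validate invariants
    return(flow_field(f$grid, f$mask, f$times, f$snapshots, f$regions, f$meta))
  }
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf))
    stop(sprintf("read_field: manifest.json not found under '%s'", path))
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(man$format) || man$format != "atriumflow-vtk-legacy")
    stop("read_field: manifest record 'format' is not atriumflow-vtk-legacy")
  times <- as.numeric(man$times)
  files <- as.character(man$files)
  if (length(files) != length(times))
    stop("read_field: manifest records 'times' and 'files' disagree in length")
  first <- .read_vtk_snapshot(file.path(path, files[1]))
  grid <- first$grid
  n <- grid_n_nodes(grid)
  mask <- fluid_mask(grid, first$labels)
  snaps <- vector("list", length(files))
  snaps[[1]] <- first$velocity
  for (s in seq_along(files)[-1]) {
    sn <- .read_vtk_snapshot(file.path(path, files[s]))
    if (!identical(sn$grid$dims, grid$dims))
      stop(sprintf("read_field: snapshot '%s' grid dims differ from '%s'",
                   files[s], files[1]))
    if (nrow(sn$velocity) != n)
      stop(sprintf("read_field: snapshot '%s' has %d nodes, grid has %d",
                   files[s], nrow(sn$velocity), n))
    snaps[[s]] <- sn$velocity
  }
  vols <- lapply(man$regions$volumes, as.integer)
  surf <- lapply(man$regions$surfaces, as.integer)
  regions <- region_set(volumes = as.list(vols), surfaces = as.list(surf),
                        mask = mask)
  meta <- if (is.null(man$meta)) list() else man$meta
  flow_field(grid, mask, times, snaps, regions, meta)
}

.read_vtk_snapshot <- function(file) {
  if (!file.exists(file)) stop(sprintf("read_field: no such file '%s'", file))
  lines <- readLines(file, warn = FALSE)
  need <- function(pat, what) {
    i <- grep(pat, lines)[1]
    if (is.na(i)) stop(sprintf("read_field: '%s' missing record '%s'", file, what))
    i
  }
  if (!grepl("STRUCTURED_POINTS", lines[need("^DATASET", "DATASET")]))
    stop(sprintf("read_field: '%s' DATASET is not STRUCTURED_POINTS", file))
  parse3 <- function(i, what, integer = FALSE) {
    v <- strsplit(trimws(lines[i]), "\\s+")[[1]][-1]
    v <- suppressWarnings(as.numeric(v))
    if (length(v) != 3 || anyNA(v))
      stop(sprintf("read_field: '%s' malformed record '%s'", file, what))
    if (integer) as.integer(v) else v
  }
  dims <- parse3(need("^DIMENSIONS", "DIMENSIONS"), "DIMENSIONS", TRUE)
  origin <- parse3(need("^ORIGIN", "ORIGIN"), "ORIGIN")
  spacing <- parse3(need("^SPACING", "SPACING"), "SPACING")
  grid <- uniform_grid(dims, spacing, origin)
  n <- prod(dims)
  ipd <- need("^POINT_DATA", "POINT_DATA")
  npd <- as.integer(strsplit(trimws(lines[ipd]), "\\s+")[[1]][2])
  if (is.na(npd) || npd != n)
    stop(sprintf("read_field: '%s' POINT_DATA count %s does not match grid node count %d",
                 file, npd, n))
  isc <- need("^SCALARS mask", "SCALARS mask")
  labels <- suppressWarnings(as.integer(lines[(isc + 2):(isc + 1 + n)]))
  if (anyNA(labels))
    stop(sprintf("read_field: '%s' malformed record 'SCALARS mask'", file))
  ive <- need("^VECTORS velocity", "VECTORS velocity")
  vel_lines <- lines[(ive + 1):(ive + n)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(vel_lines), "\\s+"))))
  if (length(vals) != 3 * n || anyNA(vals))
    stop(sprintf("read_field: '%s' malformed record 'VECTORS velocity'", file))
  list(grid = grid, labels = labels,
       velocity = matrix(vals, ncol = 3, byrow = TRUE))
}
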