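#' Fluid/wall/exterior mask on a uniform grid
#'
#' Labels every grid node as \code{"fluid"} (blood), \code{"wall"}
#' (no-slip solid boundary; velocity is identically zero there) or
#' \code{"exterior"} (outside the modelled domain, no data). Wall faces --
#' the axis-aligned voxel faces separating a fluid node from a wall node --
#' are derived on construction; they carry outward (into-wall) unit normals
#' and are where wall shear stress is evaluated.
#'
#' @param grid a [uniform_grid()].
#' @param labels character or integer vector, one entry per node, in
#'   \code{c("exterior", "fluid", "wall")} (or codes 0/1/2).
#' @return An object of class \code{fluid_mask} with elements
#'   \code{labels} (integer codes 0/1/2) and \code{faces}, a data frame of
#'   wall faces: \code{fluid} and \code{wall} node indices, \code{axis}
#'   (1-3), \code{dir} (+1 if the wall node lies in the +axis direction),
#'   face centroid \code{cx, cy, cz} (m), \code{area} (m^2) and outward
#'   normal \code{nx, ny, nz}.
#' @export
fluid_mask <- function(grid, labels) {
  stopifnot(inherits(grid, "uniform_grid"))
  n <- grid_n_nodes(grid)
  if (is.character(labels)) {
    codes <- match(labels, c("exterior", "fluid", "wall")) - 1L
    if (anyNA(codes)) stop("fluid_mask: unknown label(s)")
  } else {
    codes <- as.integer(labels)
    if (any(!codes %in% 0:2)) stop("fluid_mask: codes must be 0, 1 or 2")
  }
  if (length(codes) != n)
    stop(sprintf("fluid_mask: %d labels for %d nodes", length(codes), n))
  if (!any(codes == 1L)) stop("fluid_mask: at least one fluid node required")
  faces <- .derive_wall_faces(grid, codes)
  structure(list(grid = grid, labels = codes, faces = faces),
            class = "fluid_mask")
}

.derive_wall_faces <- function(grid, codes) {
  d <- grid$dims
  lab <- array(codes, dim = d)
  out <- vector("list", 6L)
  m <- 0L
  for (ax in 1:3) {
    # pairs (a, b) adjacent along ax, b on the +ax side
    ia <- slice.index(array(seq_len(prod(d)), dim = d), ax)
    keep_a <- ia < d[ax]
    idx_all <- array(seq_len(prod(d)), dim = d)
    a <- idx_all[keep_a]
    shift <- c(1L, d[1], d[1] * d[2])[ax]
    b <- a + shift
    la <- codes[a]; lb <- codes[b]
    for (s in c(1L, -1L)) {
      if (s == 1L) sel <- la == 1L & lb == 2L else sel <- la == 2L & lb == 1L
      if (!any(sel)) next
      m <- m + 1L
      fl <- if (s == 1L) a[sel] else b[sel]
      wl <- if (s == 1L) b[sel] else a[sel]
      out[[m]] <- data.frame(fluid = fl, wall = wl, axis = ax, dir = s)
    }
  }
  if (m == 0L) {
    faces <- data.frame(fluid = integer(), wall = integer(),
                        axis = integer(), dir = integer(),
                        cx = numeric(), cy = numeric(), cz = numeric(),
                        area = numeric(),
                        nx = numeric(), ny = numeric(), nz = numeric())
    return(faces)
  }
  faces <- do.call(rbind, out[seq_len(m)])
  pf <- node_coords(grid, faces$fluid)
  h <- grid$spacing
  cen <- pf
  nrm <- matrix(0, nrow(faces), 3)
  for (ax in 1:3) {
    sel <- faces$axis == ax
    cen[sel, ax] <- cen[sel, ax] + faces$dir[sel] * h[ax] / 2
    nrm[sel, ax] <- faces$dir[sel]
  }
  area <- c(h[2] * h[3], h[1] * h[3], h[1] * h[2])[faces$axis]
  faces$cx <- cen[, 1]; faces$cy <- cen[, 2]; faces$cz <- cen[, 3]
  faces$area <- area
  faces$nx <- nrm[, 1]; faces$ny <- nrm[, 2]; faces$nz <- nrm[, 3]
  rownames(faces) <- NULL
  faces
}

#' @export
print.fluid_mask <- function(x, ...) {
  cat(sprintf("fluid_mask: %d fluid, %d wall, %d exterior nodes; %d wall faces\n",
              sum(x$labels == 1L), sum(x$labels == 2L), sum(x$labels == 0L),
              nrow(x$faces)))
  invisible(x)
}

#' Indices of fluid nodes
#' @param mask a \code{fluid_mask}.
#' @return integer vector of node indices labelled fluid.
#' @export
fluid_nodes <- function(mask) which(mask$labels == 1L)

#' Named volume and surface regions
#'
#' Named subsets of grid nodes (volumes, e.g. \code{"atrium"},
#' \code{"auricle"}) and of wall faces (surfaces, e.g. the auricular wall
#' vs the remaining atrial wall) over which metrics are aggregated.
#'
#' @param volumes named list of node index vectors.
#' @param surfaces named list of wall-face row indices (rows of
#'   \code{mask$faces}).
#' @param mask optional \code{fluid_mask} used to validate indices.
#' @return An object of class \code{region_set}.
#' @export
region_set <- function(volumes = list(), surfaces = list(), mask = NULL) {
  chk_names <- function(l, what) {
    if (length(l) && (is.null(names(l)) || anyDuplicated(names(l)) ||
                      any(!nzchar(names(l)))))
      stop(sprintf("region_set: %s must have unique non-empty names", what))
  }
  chk_names(volumes, "volumes"); chk_names(surfaces, "surfaces")
  if (!is.null(mask)) {
    n <- grid_n_nodes(mask$grid)
    for (nm in names(volumes)) {
      v <- volumes[[nm]]
      if (length(v) && (min(v) < 1L || max(v) > n))
        stop(sprintf("region_set: volume '%s' references nodes outside the grid", nm))
    }
    nf <- nrow(mask$faces)
    for (nm in names(surfaces)) {
      s <- surfaces[[nm]]
      if (length(s) && (min(s) < 1L || max(s) > nf))
        stop(sprintf("region_set: surface '%s' references unknown wall faces", nm))
    }
  }
  structure(list(volumes = volumes, surfaces = surfaces), class = "region_set")
}

#' Planar cross-section
#'
#' A plane given by a point on it and its unit normal; used to take caval
#' cross-sections for helicity and flux metrics. The normal is normalised on
#' construction.
#'
#' @param point numeric length 3, a point on the plane (m).
#' @param normal numeric length 3, plane normal (normalised internally).
#' @return An object of class \code{plane_section}.
#' @export
plane_section <- function(point, normal) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  if (length(point) != 3L || any(!is.finite(point)))
    stop("plane_section: 'point' must be three finite coordinates")
  nn <- sqrt(sum(normal^2))
  if (length(normal) != 3L || !is.finite(nn) || nn == 0)
    stop("plane_section: 'normal' must be a nonzero 3-vector")
  structure(list(point = point, normal = normal / nn), class = "plane_section")
}
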