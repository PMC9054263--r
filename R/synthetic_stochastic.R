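#' Specification for a synthetic turbulence field
#'
#' Parameters of the random divergence-free Fourier-mode generator used as
#' the recovery target for the resolved-TKE pipeline.
#'
#' @param target_tke ensemble turbulent kinetic energy per unit mass
#'   (J/kg), >= 0.
#' @param n_modes number of Fourier modes (>= 1).
#' @param slope spectral slope of the per-mode energy weights (energy
#'   proportional to |k|^slope; -5/3 gives an inertial-range-like spread).
#' @param seed integer random seed; recorded in the output metadata.
#' @return An object of class \code{turbulence_spec}.
#' @export
turbulence_spec <- function(target_tke, n_modes = 32L, slope = -5 / 3, seed) {
  stopifnot(is.numeric(target_tke), target_tke >= 0, n_modes >= 1)
  if (missing(seed) || is.null(seed)) stop("turbulence_spec: 'seed' must be set")
  structure(list(target_tke = as.numeric(target_tke),
                 n_modes = as.integer(n_modes), slope = slope,
                 seed = as.integer(seed)), class = "turbulence_spec")
}

# run expr with a locally seeded RNG, restoring the caller's stream
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Synthetic homogeneous turbulence on a periodic box
#'
#' Zero-mean random velocity snapshots built from divergence-free Fourier
#' modes (each mode's polarisation vector is perpendicular to its
#' wavevector): per snapshot the mode amplitudes are independent standard
#' normal draws scaled so that the ensemble turbulent kinetic energy equals
#' \code{spec$target_tke}. Snapshots are mutually independent, so
#' time-sample statistics converge to the ensemble target at rate
#' \code{1/sqrt(n_snapshots * n_modes)}.
#'
#' @param spec a [turbulence_spec()].
#' @param nodes nodes per axis of the (all-fluid, periodic-by-sampling)
#'   cube.
#' @param box_size cube edge length (m).
#' @param n_snapshots number of snapshots.
#' @param dt sample interval (s).
#' @return A [flow_field()]; metadata records spec and seed.
#' @export
synthetic_turbulence <- function(spec, nodes = 24L, box_size = 0.05,
                                 n_snapshots = 100L, dt = 1e-2) {
  stopifnot(inherits(spec, "turbulence_spec"), nodes >= 8)
  h <- box_size / nodes
  grid <- uniform_grid(rep(nodes, 3), h, c(0, 0, 0))
  mask <- fluid_mask(grid, rep(1L, grid_n_nodes(grid)))
  n <- grid_n_nodes(grid)
  times <- seq(0, by = dt, length.out = n_snapshots)
  if (spec$target_tke == 0) {
    snaps <- rep(list(matrix(0, n, 3)), n_snapshots)
    return(flow_field(grid, mask, times, snaps,
                      meta = list(generator = "synthetic_turbulence",
                                  spec = unclass(spec))))
  }
  mmax <- nodes %/% 2 - 1L                  # integer modes below Nyquist
  # candidate wavevectors are the grid-representable low-wavenumber shells
  mrange <- min(3L, mmax)
  cand <- as.matrix(expand.grid(mx = -mrange:mrange, my = -mrange:mrange,
                                mz = -mrange:mrange))
  cand <- cand[rowSums(cand^2) > 0, , drop = FALSE]
  if (spec$n_modes > nrow(cand))
    stop(sprintf(paste("synthetic_turbulence: spectral error - %d modes",
                       "requested but only %d grid-representable modes below",
                       "the Nyquist limit"), spec$n_modes, nrow(cand)))
  with_local_seed(spec$seed, {
    modes <- cand[sample.int(nrow(cand), spec$n_modes,
                             prob = rowSums(cand^2)^(spec$slope / 2)), ,
                  drop = FALSE]
    K <- 2 * pi * modes / box_size                  # M x 3 wavevectors
    kmag <- sqrt(rowSums(K^2))
    w <- kmag^spec$slope; w <- w / sum(w)
    cm <- sqrt(2 * spec$target_tke * w)             # per-mode RMS amplitude
    # unit polarisations perpendicular to k (divergence-free)
    rv <- matrix(stats::rnorm(3 * nrow(K)), ncol = 3)
    sig <- rv - K * (rowSums(rv * K) / kmag^2)
    deg <- sqrt(rowSums(sig^2)) < 1e-8
    while (any(deg)) {
      rv[deg, ] <- matrix(stats::rnorm(3 * sum(deg)), ncol = 3)
      sig[deg, ] <- rv[deg, , drop = FALSE] -
        K[deg, , drop = FALSE] * (rowSums(rv[deg, , drop = FALSE] *
                                          K[deg, , drop = FALSE]) / kmag[deg]^2)
      deg <- sqrt(rowSums(sig^2)) < 1e-8
    }
    sig <- sig / sqrt(rowSums(sig^2))
    ph <- node_coords(grid) %*% t(K)                # n x M phases
    cosP <- cos(ph); sinP <- sin(ph)
    snaps <- vector("list", n_snapshots)
    for (s in seq_len(n_snapshots)) {
      a <- stats::rnorm(nrow(K)); b <- stats::rnorm(nrow(K))
      snaps[[s]] <- cosP %*% (cm * a * sig) + sinP %*% (cm * b * sig)
    }
    flow_field(grid, mask, times, snaps,
               meta = list(generator = "synthetic_turbulence",
                           spec = unclass(spec), modes = modes))
  })
}

#' Specification for a pulsatile inlet waveform
#'
#' @param period cycle period (s).
#' @param mean_flow cycle-mean flow rate (m^3/s), > 0.
#' @param pi_target target pulsatility index (peak - trough)/mean, >= 0.
#' @param shape \code{"sine"} (single harmonic) or \code{"two_harmonic"}
#'   (fundamental plus a phase-shifted second harmonic, giving an
#'   asymmetric venous-like cycle).
#' @param samples samples per period (>= 8).
#' @return An object of class \code{waveform_spec}.
#' @export
waveform_spec <- function(period, mean_flow, pi_target,
                          shape = c("sine", "two_harmonic"), samples = 200L) {
  shape <- match.arg(shape)
  stopifnot(period > 0, mean_flow > 0, pi_target >= 0, samples >= 8)
  structure(list(period = period, mean_flow = mean_flow,
                 pi_target = pi_target, shape = shape,
                 samples = as.integer(samples)), class = "waveform_spec")
}

#' Generate a pulsatile flow waveform with a prescribed pulsatility index
#'
#' The base shape is centred to zero sample mean and scaled so that the
#' generated series has exactly the requested pulsatility index
#' \code{(max - min)/mean} and exactly the requested mean on its sample
#' grid. A pulsatility index above 2 implies transient flow reversal, as
#' venous waveforms can show.
#'
#' @param spec a [waveform_spec()].
#' @return A tibble with columns \code{t} (s) and \code{q} (m^3/s) covering
#'   one period (the end point \code{t = period} is excluded; the series is
#'   periodic).
#' @export
pulsatile_waveform <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  t <- spec$period * (seq_len(spec$samples) - 1L) / spec$samples
  w <- 2 * pi * t / spec$period
  s <- switch(spec$shape,
              sine = sin(w),
              two_harmonic = sin(w) + 0.4 * sin(2 * w + pi / 6))
  s <- s - mean(s)
  span <- max(s) - min(s)
  q <- if (spec$pi_target == 0 || span == 0) {
    rep(spec$mean_flow, spec$samples)
  } else {
    spec$mean_flow * (1 + (spec$pi_target / span) * s)
  }
  tibble::tibble(t = t, q = q)
}

#' Generate a multi-subject vein morphometry table
#'
#' Emulates a minimum/maximum vessel-diameter table: per vessel, diameters
#' are lognormal across subjects with prescribed means and coefficients of
#' variation (population-SD convention), the minimum and maximum sharing
#' one latent per-subject factor so that min <= max holds per entry.
#' Lognormality guarantees positive diameters; the lognormal population CV
#' equals the requested target, so sample CVs converge to it as the number
#' of subjects grows.
#'
#' @param n_subjects number of subjects (rows).
#' @param vessels data frame with columns \code{vessel}, \code{mean_min},
#'   \code{mean_max} (cm), \code{cv_min}, \code{cv_max}.
#' @param seed integer random seed.
#' @return A tibble, one row per subject, columns \code{subject} then
#'   \code{<vessel>_min} and \code{<vessel>_max} (cm). Attribute
#'   \code{"spec"} records the generator inputs and seed.
#' @export
morphometry_table_generator <- function(n_subjects, vessels, seed) {
  stopifnot(n_subjects >= 1,
            all(c("vessel", "mean_min", "mean_max", "cv_min", "cv_max")
                %in% names(vessels)),
            all(vessels$mean_min > 0), all(vessels$mean_max > 0),
            all(vessels$cv_min >= 0), all(vessels$cv_max >= 0),
            all(vessels$mean_min <= vessels$mean_max))
  lpar <- function(m, cv) {
    s2 <- log(1 + cv^2)
    list(mu = log(m) - s2 / 2, sigma = sqrt(s2))
  }
  with_local_seed(seed, {
    out <- list(subject = seq_len(n_subjects))
    for (i in seq_len(nrow(vessels))) {
      z <- stats::rnorm(n_subjects)
      p1 <- lpar(vessels$mean_min[i], vessels$cv_min[i])
      p2 <- lpar(vessels$mean_max[i], vessels$cv_max[i])
      dmin <- exp(p1$mu + p1$sigma * z)
      dmax <- exp(p2$mu + p2$sigma * z)
      # shared z makes crossings rare; guard the tail anyway
      lo <- pmin(dmin, dmax); hi <- pmax(dmin, dmax)
      out[[paste0(vessels$vessel[i], "_min")]] <- lo
      out[[paste0(vessels$vessel[i], "_max")]] <- hi
    }
    tab <- tibble::as_tibble(out)
    attr(tab, "spec") <- list(n_subjects = n_subjects, vessels = vessels,
                              seed = seed)
    tab
  })
}
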