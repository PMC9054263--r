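#' Quemada blood rheology parameters
#'
#' Shear-thinning blood viscosity in the Quemada form
#' \deqn{\mu = \mu_p (1 - \tfrac12 k(\dot\gamma) Hct)^{-2}, \quad
#'       k = \frac{k_0 + k_\infty\sqrt{\dot\gamma/\dot\gamma_c}}
#'                {1 + \sqrt{\dot\gamma/\dot\gamma_c}}}
#' where \eqn{\mu_p} is plasma viscosity, \eqn{Hct} the haematocrit (red
#' cell volume fraction) and \eqn{k_0, k_\infty, \dot\gamma_c} intrinsic
#' viscosity parameters. Defaults use the classical haematocrit-dependent
#' exponential-polynomial fits to Cokelet's human blood data; at
#' \eqn{Hct = 0.35} and physiological shear they give viscosities in the
#' 3-4 mPa s band. All parameters are overridable.
#'
#' @param hct haematocrit, volume fraction in [0, 0.9].
#' @param mu_plasma plasma viscosity (Pa s).
#' @param k0,k_inf,gamma_c optional overrides of the intrinsic-viscosity
#'   coefficients and critical shear rate (1/s); defaults are evaluated
#'   from \code{hct} by the closed-form fits.
#' @param rho blood density (kg/m^3); 1050 by default.
#' @param shear_floor lower clamp on shear rate (1/s) regularising the
#'   \eqn{\dot\gamma = 0} evaluation.
#' @return An object of class \code{rheology_params}.
#' @export
rheology_params <- function(hct = 0.35, mu_plasma = 1.2e-3,
                            k0 = NULL, k_inf = NULL, gamma_c = NULL,
                            rho = 1050, shear_floor = 1e-3) {
  stopifnot(hct >= 0, hct <= 0.9, mu_plasma > 0, rho > 0, shear_floor > 0)
  if (is.null(k0))
    k0 <- exp(3.874 - 10.41 * hct + 13.8 * hct^2 - 6.738 * hct^3)
  if (is.null(k_inf))
    k_inf <- exp(1.3435 - 2.803 * hct + 2.711 * hct^2 - 0.6479 * hct^3)
  if (is.null(gamma_c))
    gamma_c <- exp(-6.1508 + 27.923 * hct - 25.6 * hct^2 + 3.697 * hct^3)
  if (gamma_c <= 0) stop("rheology_params: gamma_c must be positive")
  # hard validity bound: the infinite-shear branch must stay regular
  # (Hct < 2/k_inf); the zero-shear branch may legitimately diverge for
  # aggregating blood at stasis and is guarded at evaluation time instead
  if (1 - k_inf * hct / 2 <= 0)
    stop("rheology_params: singularity - Hct must stay below 2/k_inf")
  structure(list(hct = hct, mu_plasma = mu_plasma, k0 = k0, k_inf = k_inf,
                 gamma_c = gamma_c, rho = rho, shear_floor = shear_floor),
            class = "rheology_params")
}

#' @export
print.rheology_params <- function(x, ...) {
  cat(sprintf(paste0("Quemada rheology: Hct = %.2f, mu_p = %.4g Pa s, ",
                     "k0 = %.3f, k_inf = %.3f, gamma_c = %.3f 1/s, ",
                     "rho = %g kg/m^3\n"),
              x$hct, x$mu_plasma, x$k0, x$k_inf, x$gamma_c, x$rho))
  invisible(x)
}

#' Quemada viscosity at given shear rates
#'
#' @param shear_rate shear rate(s), 1/s, >= 0; values below
#'   \code{params$shear_floor} are clamped to it.
#' @param params a [rheology_params()].
#' @return viscosity (Pa s), same length as \code{shear_rate}.
#' @export
quemada_viscosity <- function(shear_rate, params) {
  stopifnot(inherits(params, "rheology_params"), all(shear_rate >= 0))
  g <- pmax(shear_rate, params$shear_floor)
  s <- sqrt(g / params$gamma_c)
  k <- (params$k0 + params$k_inf * s) / (1 + s)
  denom <- 1 - k * params$hct / 2
  if (any(denom <= 0))
    stop("quemada_viscosity: singularity - 1 - k*Hct/2 <= 0 for these parameters")
  params$mu_plasma / denom^2
}

#' Per-node viscosity from the local strain-rate modulus
#'
#' Evaluates the Quemada viscosity at every fluid node with the local shear
#' rate taken as the strain-rate modulus \eqn{S = \sqrt{2 S_{ij} S_{ij}}}
#' of the velocity gradient.
#'
#' @param field a [flow_field()].
#' @param params a [rheology_params()].
#' @param snapshot snapshot index.
#' @return numeric vector, one viscosity (Pa s) per node; \code{NA} on
#'   non-fluid nodes.
#' @export
viscosity_field <- function(field, params, snapshot = 1L) {
  grad <- velocity_gradient(field, snapshot)
  s <- strain_modulus(grad)
  mu <- rep(NA_real_, length(s))
  fl <- fluid_nodes(field$mask)
  mu[fl] <- quemada_viscosity(s[fl], params)
  mu
}

#' Cell-volume-weighted mean viscosity over a region
#'
#' @param mu per-node viscosity vector (Pa s).
#' @param field a [flow_field()] (supplies cell volumes).
#' @param region node indices; defaults to all fluid nodes.
#' @return mean viscosity (Pa s). With uniform voxels the volume weighting
#'   reduces to the arithmetic mean over the region's nodes.
#' @export
volume_average_viscosity <- function(mu, field, region = NULL) {
  if (is.null(region)) region <- fluid_nodes(field$mask)
  if (!length(region)) stop("volume_average_viscosity: empty region")
  mean(mu[region])
}
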