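#' WALE / subgrid turbulence constants
#'
#' Constants of the wall-adapting local eddy-viscosity (WALE) subgrid
#' operator and of the subgrid kinetic-energy estimate, with the customary
#' defaults: von Karman constant 0.41, WALE coefficient 0.544,
#' subgrid-TKE coefficient 3.5, blood density 1050 kg/m^3.
#'
#' @param kappa von Karman constant.
#' @param c_w WALE model coefficient.
#' @param c_t subgrid kinetic-energy coefficient.
#' @param rho fluid density (kg/m^3).
#' @return An object of class \code{turbulence_params}.
#' @export
turbulence_params <- function(kappa = 0.41, c_w = 0.544, c_t = 3.5,
                              rho = 1050) {
  stopifnot(kappa > 0, c_w > 0, c_t > 0, rho > 0)
  structure(list(kappa = kappa, c_w = c_w, c_t = c_t, rho = rho),
            class = "turbulence_params")
}

#' WALE turbulent (eddy) viscosity
#'
#' Diagnostic evaluation of the WALE subgrid eddy viscosity
#' \deqn{\mu_t = \rho \Delta^2 S_W, \qquad
#'       \Delta = \min(\kappa d, C_W V^{1/3})}
#' with \eqn{d} the wall distance, \eqn{V} the cell volume and the
#' deformation parameter
#' \deqn{S_W = \frac{(S^d\!:\!S^d)^{3/2}}
#'                  {(S\!:\!S)^{5/2} + (S^d\!:\!S^d)^{5/4}}}
#' where \eqn{S} is the strain-rate tensor and \eqn{S^d} the traceless
#' symmetric part of the squared velocity-gradient tensor. \eqn{S_W}
#' vanishes for uniform flow and for pure shear (the wall-adapting
#' property) and equals \eqn{(2/3)^{1/4}\Omega} for solid-body rotation at
#' rate \eqn{\Omega}. The denominator is guarded by a tiny epsilon so that
#' \eqn{S_W = 0} when both contractions vanish.
#'
#' @param grad a [velocity_gradient()] result.
#' @param d per-node wall distance from [wall_distance()] (m).
#' @param params a [turbulence_params()].
#' @param eps denominator guard (SI).
#' @return numeric vector of eddy viscosities (Pa s), >= 0, zero on
#'   non-fluid nodes.
#' @export
wale_eddy_viscosity <- function(grad, d, params = turbulence_params(),
                                eps = 1e-30) {
  stopifnot(inherits(grad, "gradient_field"),
            inherits(params, "turbulence_params"))
  n <- dim(grad$g)[1]
  if (length(d) != n)
    stop("wale_eddy_viscosity: wall distance and gradient field are not co-registered")
  g <- grad$g
  # squared gradient tensor g2_ij = g_ik g_kj
  g2 <- array(0, dim = c(n, 3, 3))
  for (i in 1:3) for (j in 1:3)
    g2[, i, j] <- g[, i, 1] * g[, 1, j] + g[, i, 2] * g[, 2, j] +
      g[, i, 3] * g[, 3, j]
  tr3 <- (g2[, 1, 1] + g2[, 2, 2] + g2[, 3, 3]) / 3
  sdsd <- numeric(n); ss <- numeric(n)
  for (i in 1:3) for (j in 1:3) {
    sd_ij <- (g2[, i, j] + g2[, j, i]) / 2 - if (i == j) tr3 else 0
    sdsd <- sdsd + sd_ij^2
    s_ij <- (g[, i, j] + g[, j, i]) / 2
    ss <- ss + s_ij^2
  }
  sw <- sdsd^1.5 / (ss^2.5 + sdsd^1.25 + eps)
  delta <- pmin(params$kappa * ifelse(is.na(d), Inf, d),
                params$c_w * grid_cell_volume(grad$grid)^(1 / 3))
  mu_t <- params$rho * delta^2 * sw
  mu_t[grad$mask$labels != 1L] <- 0
  mu_t
}

#' Subgrid-scale turbulent kinetic energy
#'
#' \eqn{k_{SGS} = C_t (\mu_t/\rho) S} (J/kg), the dimensionally consistent
#' subgrid kinetic-energy estimate from the eddy viscosity and the
#' strain-rate modulus.
#'
#' @param mu_t per-node eddy viscosity (Pa s).
#' @param s per-node strain-rate modulus (1/s), e.g. [strain_modulus()].
#' @param params a [turbulence_params()].
#' @return numeric vector of subgrid TKE (J/kg), >= 0.
#' @export
sgs_tke <- function(mu_t, s, params = turbulence_params()) {
  stopifnot(inherits(params, "turbulence_params"))
  if (length(mu_t) != length(s))
    stop("sgs_tke: inputs are not co-registered")
  params$c_t * (mu_t / params$rho) * s
}
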