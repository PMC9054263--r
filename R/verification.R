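#' Grid convergence index from three mesh solutions
#'
#' Richardson-extrapolation-based discretisation-error estimate from one
#' scalar metric computed on three systematically refined meshes. With
#' solutions \code{f1, f2, f3} on cell sizes \code{h1 < h2 < h3} the
#' apparent order p solves
#' \deqn{\varepsilon_{32}/\varepsilon_{21} = \frac{r_{21}^p - s}{r_{32}^p - s}
#'       \, r_{21}^p \cdot r_{21}^{-p}}
#' (constant-ratio case: \eqn{p = \ln(\varepsilon_{32}/\varepsilon_{21}) /
#' \ln r}; mixed ratios by fixed-point iteration), and
#' \deqn{GCI_{fine} = F_s \frac{|f_1 - f_2|}{|f_1|\,(r_{21}^p - 1)} \times 100\%.}
#'
#' @param f numeric length 3, the metric on the fine, medium and coarse
#'   mesh (in order of increasing \code{h}).
#' @param h numeric length 3, representative cell sizes, strictly
#'   increasing; see [representative_cell_size()].
#' @param fs safety factor (1.25, the three-grid convention).
#' @return list with \code{p} (apparent order), \code{f_exact}
#'   (extrapolated value), \code{gci_fine} and \code{gci_coarse} (percent),
#'   \code{oscillatory} flag, and \code{r21}, \code{r32}.
#' @export
gci <- function(f, h, fs = 1.25) {
  stopifnot(length(f) == 3, length(h) == 3, all(is.finite(f)),
            all(h > 0), fs > 0)
  if (!(h[1] < h[2] && h[2] < h[3]))
    stop("gci: cell sizes must be strictly increasing (fine to coarse)")
  r21 <- h[2] / h[1]; r32 <- h[3] / h[2]
  e21 <- f[2] - f[1]; e32 <- f[3] - f[2]
  if (e21 == 0 && e32 == 0)
    return(list(p = NA_real_, f_exact = f[1], gci_fine = 0, gci_coarse = 0,
                oscillatory = FALSE, r21 = r21, r32 = r32))
  if (e21 == 0 || e32 == 0)
    stop("gci: one grid-to-grid difference is exactly zero; order undefined")
  osc <- (e32 / e21) < 0
  s <- sign(e32 / e21)
  ratio <- abs(e32 / e21)
  if (abs(r21 - r32) < 1e-12) {
    p <- log(ratio) / log(r21)
  } else {
    p <- log(ratio) / log(r21)              # initial guess
    for (it in 1:200) {
      q <- log((r21^p - s) / (r32^p - s))
      p_new <- abs(log(ratio) + q) / log(r21)
      if (!is.finite(p_new)) break
      if (abs(p_new - p) < 1e-14) { p <- p_new; break }
      p <- p_new
    }
  }
  f_exact <- (r21^p * f[1] - f[2]) / (r21^p - 1)
  rel <- function(num, den) if (den != 0) abs(num / den) else abs(num)
  gci_fine <- fs * rel(e21, f[1]) / (r21^p - 1) * 100
  gci_coarse <- fs * rel(e32, f[2]) / (r32^p - 1) * 100
  list(p = p, f_exact = f_exact, gci_fine = gci_fine,
       gci_coarse = gci_coarse, oscillatory = osc, r21 = r21, r32 = r32)
}

#' Representative cell size of an unstructured mesh
#'
#' \eqn{h = (V_{total} / N_{cells})^{1/3}}: how meshes reported by total
#' cell count are placed on a refinement axis.
#'
#' @param volume total meshed volume (m^3).
#' @param n_cells cell count.
#' @return representative cell size (m).
#' @export
representative_cell_size <- function(volume, n_cells) {
  stopifnot(volume > 0, n_cells > 0)
  (volume / n_cells)^(1 / 3)
}

#' Welch-averaged power spectral density of a probe series
#'
#' Splits the series into segments, applies a window, averages the
#' one-sided periodograms, and (optionally) fits the log-log spectral
#' slope over a frequency band, reporting it alongside the -5/3
#' inertial-range reference. In single-segment rectangular mode the
#' integrated PSD equals the series variance (Parseval).
#'
#' @param x numeric velocity-component samples at one probe point
#'   (>= 64).
#' @param dt sample interval (s), > 0.
#' @param n_segments number of equal non-overlapping segments.
#' @param window \code{"rectangular"} or \code{"hann"}.
#' @param slope_band optional length-2 frequency band (Hz) for the
#'   inertial-range slope fit.
#' @return list with \code{frequency} (Hz), \code{psd} (one-sided,
#'   units^2/Hz), \code{slope} (or NA), \code{slope_reference = -5/3},
#'   \code{n_segments}.
#' @export
power_spectrum <- function(x, dt, n_segments = 1L,
                           window = c("rectangular", "hann"),
                           slope_band = NULL) {
  window <- match.arg(window)
  x <- as.numeric(x)
  if (length(x) < 64) stop("power_spectrum: need at least 64 samples")
  stopifnot(dt > 0, n_segments >= 1)
  seg_len <- length(x) %/% n_segments
  if (seg_len < 16) stop("power_spectrum: segments too short")
  fs <- 1 / dt
  w <- if (window == "hann") {
    0.5 * (1 - cos(2 * pi * seq_len(seg_len) / (seg_len + 1)))
  } else rep(1, seg_len)
  nf <- seg_len %/% 2
  acc <- numeric(nf)
  for (s in seq_len(n_segments)) {
    seg <- x[((s - 1) * seg_len + 1):(s * seg_len)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    pxx <- (Mod(X)^2) / (fs * sum(w^2))
    one <- pxx[2:(nf + 1)]
    # double the interior bins to fold the negative frequencies in
    dbl <- rep(2, nf)
    if (seg_len %% 2 == 0) dbl[nf] <- 1     # Nyquist bin appears once
    acc <- acc + one * dbl
  }
  psd <- acc / n_segments
  freq <- (1:nf) * fs / seg_len
  slope <- NA_real_
  if (!is.null(slope_band)) {
    sel <- freq >= slope_band[1] & freq <= slope_band[2] & psd > 0
    if (sum(sel) < 3) stop("power_spectrum: slope band contains < 3 bins")
    ft <- stats::lm(log(psd[sel]) ~ log(freq[sel]))
    slope <- unname(stats::coef(ft)[2])
  }
  list(frequency = freq, psd = psd, slope = slope,
       slope_reference = -5 / 3, n_segments = n_segments)
}

#' Synthesise a probe signal with a power-law spectrum
#'
#' Random-phase Fourier synthesis with amplitude proportional to
#' \code{f^(slope/2)}, giving a one-sided PSD proportional to
#' \code{f^slope} -- the turbulence-like probe signal used to validate the
#' spectral-slope fit.
#'
#' @param n number of samples.
#' @param dt sample interval (s).
#' @param slope spectral slope (default -5/3).
#' @param seed integer seed.
#' @return numeric series of length \code{n}.
#' @export
power_law_signal <- function(n, dt, slope = -5 / 3, seed) {
  stopifnot(n >= 64, dt > 0)
  if (missing(seed)) stop("power_law_signal: 'seed' must be set")
  with_local_seed(seed, {
    nf <- n %/% 2
    fs <- 1 / dt
    freq <- (1:nf) * fs / n
    amp <- freq^(slope / 2)
    phase <- stats::runif(nf, 0, 2 * pi)
    spec <- complex(modulus = amp, argument = phase)
    full <- complex(real = numeric(n))
    full[2:(nf + 1)] <- spec
    if (n %% 2 == 0) {
      full[nf + 1] <- complex(real = amp[nf] * cos(phase[nf]))
      full[seq(n, nf + 2)] <- Conj(spec[1:(nf - 1)])
    } else {
      full[seq(n, nf + 1)] <- Conj(spec)
    }
    Re(stats::fft(full, inverse = TRUE)) / n
  })
}
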