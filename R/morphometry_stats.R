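#' Packaged venous morphometry table
#'
#' Loads the packaged four-subject vein morphometry fixture: per subject,
#' demographics plus minimum and maximum diameters (cm) of the IVC, SVC
#' and six major branching veins, and the right-atrial major/minor axial
#' axis lengths (cm).
#'
#' @return A tibble, one row per subject.
#' @export
morphometry_fixture <- function() {
  path <- system.file("extdata", "morphometry_4subjects.csv",
                      package = "atriumflow", mustWork = TRUE)
  read_morphometry(path)
}

#' Read a morphometry CSV
#'
#' Schema: one row per subject; a \code{subject} identifier column;
#' optional demographic columns; measurement columns named
#' \code{<vessel>_min} / \code{<vessel>_max} (cm). Diameters must be
#' positive and min <= max per entry.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_morphometry <- function(path) {
  if (!file.exists(path)) stop(sprintf("read_morphometry: no such file '%s'", path))
  tab <- tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  prs <- vein_measure_pairs(tab)
  for (v in prs) {
    lo <- tab[[paste0(v, "_min")]]; hi <- tab[[paste0(v, "_max")]]
    if (any(!is.finite(lo)) || any(!is.finite(hi)))
      stop(sprintf("read_morphometry: missing cells for vessel '%s'", v))
    if (any(lo <= 0) || any(hi <= 0))
      stop(sprintf("read_morphometry: non-positive diameter for vessel '%s'", v))
    if (any(lo > hi))
      stop(sprintf("read_morphometry: min > max for vessel '%s'", v))
  }
  tab
}

#' Vessels with paired min/max columns
#' @param table a morphometry table.
#' @return character vector of vessel stems having both \code{_min} and
#'   \code{_max} columns.
#' @export
vein_measure_pairs <- function(table) {
  nms <- names(table)
  stems <- sub("_min$", "", nms[grepl("_min$", nms)])
  stems[paste0(stems, "_max") %in% nms]
}

#' Population standard deviation (n divisor)
#' @param x numeric vector.
#' @return numeric scalar.
#' @export
sd_population <- function(x) sqrt(mean((x - mean(x))^2))

#' Descriptive statistics of a morphometry table
#'
#' Mean and standard deviation of every numeric column (all measurements
#' and numeric demographics). The population convention (divide by n) is
#' the default, matching summary rows computed over a complete set of
#' studied subjects rather than a sample estimate.
#'
#' @param table a morphometry tibble.
#' @param sd \code{"population"} (n divisor) or \code{"sample"} (n - 1).
#' @return tibble with columns \code{measure}, \code{mean}, \code{sd},
#'   \code{n}.
#' @export
descriptive_stats <- function(table, sd = c("population", "sample")) {
  sd <- match.arg(sd)
  num <- vapply(table, is.numeric, TRUE)
  num[names(num) == "subject"] <- FALSE
  sdfun <- if (sd == "population") sd_population else stats::sd
  cols <- names(table)[num]
  tibble::tibble(measure = cols,
                 mean = vapply(cols, function(cn) mean(table[[cn]]), 0,
                               USE.NAMES = FALSE),
                 sd = vapply(cols, function(cn) sdfun(table[[cn]]), 0,
                             USE.NAMES = FALSE),
                 n = nrow(table))
}

#' Coefficient of variation
#'
#' SD over mean; scale-invariant between-subject variability. Population
#' SD convention by default.
#'
#' @param values numeric vector.
#' @param sd \code{"population"} or \code{"sample"}.
#' @return dimensionless CV.
#' @export
coefficient_of_variation <- function(values, sd = c("population", "sample")) {
  sd <- match.arg(sd)
  f <- if (sd == "population") sd_population else stats::sd
  f(values) / mean(values)
}

#' Compare minimum- vs maximum-diameter variability across vessels
#'
#' Per vessel with paired \code{_min}/\code{_max} columns, computes the
#' between-subject coefficient of variation of the minimum and of the
#' maximum diameter, then compares the paired per-vessel CVs with a
#' Wilcoxon signed-rank test. The continuity-corrected normal
#' approximation is the headline P value; the exact enumeration P is also
#' reported.
#'
#' @param table a morphometry tibble (vessels detected from paired
#'   \code{_min}/\code{_max} columns; axis-length columns without such a
#'   pair are ignored).
#' @param sd CV convention, \code{"population"} (default) or
#'   \code{"sample"}.
#' @return list with \code{per_vessel} (tibble: vessel, cv_min, cv_max),
#'   \code{mean_cv_min}, \code{mean_cv_max}, \code{p_normal_cc},
#'   \code{p_exact}, \code{statistic}.
#' @export
compare_min_max_variability <- function(table, sd = "population") {
  vessels <- vein_measure_pairs(table)
  if (length(vessels) < 2)
    stop("compare_min_max_variability: need at least 2 vessels with min/max pairs")
  cv_min <- vapply(vessels, function(v)
    coefficient_of_variation(table[[paste0(v, "_min")]], sd), 0)
  cv_max <- vapply(vessels, function(v)
    coefficient_of_variation(table[[paste0(v, "_max")]], sd), 0)
  wn <- wilcoxon_signed_rank(cv_min, cv_max, method = "normal_cc")
  we <- wilcoxon_signed_rank(cv_min, cv_max, method = "exact")
  list(per_vessel = tibble::tibble(vessel = vessels, cv_min = unname(cv_min),
                                   cv_max = unname(cv_max)),
       mean_cv_min = mean(cv_min), mean_cv_max = mean(cv_max),
       p_normal_cc = wn$p_value, p_exact = we$p_value,
       statistic = wn$statistic)
}

#' Wilcoxon signed-rank test
#'
#' Paired two-sided test on \code{x - y} (or on \code{x} directly when
#' \code{y} is \code{NULL}). Zero differences are dropped; tied absolute
#' differences get average ranks. \code{"normal_cc"} uses the normal
#' approximation with continuity correction and tie-corrected variance;
#' \code{"exact"} enumerates all \code{2^n} sign assignments of the
#' observed ranks (n <= 25) and reports
#' \eqn{P(|W - \mu_W| \ge |W_{obs} - \mu_W|)}.
#'
#' @param x numeric vector (first member of pairs, or differences).
#' @param y optional second member of pairs.
#' @param method \code{"normal_cc"} or \code{"exact"}.
#' @return list with \code{statistic} (W+, the positive-rank sum),
#'   \code{p_value}, \code{n_used}, \code{method}.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, method = c("normal_cc", "exact")) {
  method <- match.arg(method)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(statistic = 0, p_value = 1, n_used = 0L, method = method))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (method == "exact") {
    if (n > 25L)
      stop("wilcoxon_signed_rank: exact enumeration limited to n <= 25")
    # distribution of W+ over all 2^n sign patterns of the observed ranks
    allw <- numeric(1L)
    for (ri in r) allw <- as.vector(outer(allw, c(0, ri), "+"))
    p <- mean(abs(allw - mu) >= abs(w - mu) - 1e-12)
  } else {
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sigma2 <= 0) return(list(statistic = w, p_value = 1,
                                 n_used = n, method = method))
    z <- (w - mu - 0.5 * sign(w - mu)) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = w, p_value = p, n_used = n, method = method)
}

#' Student's t test
#'
#' Classical two-sided t test: pooled-variance two-sample form, or paired
#' on difference scores. Degenerate zero-variance inputs are resolved
#' explicitly (t = 0, P = 1 for identical samples; P = 0 sentinel for a
#' nonzero constant difference with zero variance).
#'
#' @param a,b numeric samples.
#' @param paired logical.
#' @return list with \code{t}, \code{df}, \code{p_value}.
#' @export
students_t_test <- function(a, b, paired = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  degenerate <- if (paired) stats::var(a - b) == 0 else
    (stats::var(a) + stats::var(b)) == 0
  if (degenerate) {
    delta <- mean(a) - mean(b)
    df <- if (paired) length(a) - 1 else length(a) + length(b) - 2
    if (delta == 0) return(list(t = 0, df = df, p_value = 1))
    return(list(t = sign(delta) * Inf, df = df, p_value = 0))
  }
  ht <- stats::t.test(a, b, paired = paired, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Shapiro-Wilk normality test
#'
#' Standard Shapiro-Wilk W with the published coefficient approximation,
#' for sample sizes 3 to 50.
#'
#' @param values numeric sample.
#' @return list with \code{W}, \code{p_value}, \code{n}.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3 || n > 50)
    stop("shapiro_wilk: sample size must be between 3 and 50")
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p_value = ht$p.value, n = n)
}

#' Relative diameter change over the cardiac cycle
#'
#' \eqn{(\max - \min)/\mathrm{mean}} of a gated diameter series sampled at
#' equally spaced cardiac-cycle time points; scale-invariant.
#'
#' @param series numeric diameter samples (>= 2, positive).
#' @return dimensionless relative change.
#' @export
diameter_change <- function(series) {
  series <- as.numeric(series)
  if (length(series) < 2 || any(series <= 0))
    stop("diameter_change: need >= 2 positive samples")
  (max(series) - min(series)) / mean(series)
}
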