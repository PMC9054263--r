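#' Inlet flow scenario
#'
#' Describes how a constant total venous inflow is split across the named
#' inlets: the coronary sinus receives a fixed fraction of the total, the
#' remaining (caval) flow is split between the IVC and SVC inlet trees by
#' the IVC fraction \code{f}, and within each tree flow is allocated
#' proportionally to inlet cross-sectional area.
#'
#' @param ivc_fraction IVC share \code{f} of the caval (non-coronary-sinus)
#'   flow, in [0, 1]; the SVC share is \code{1 - f}.
#' @param total_flow total inflow (m^3/s); default 6 L/min.
#' @param cs_fraction coronary-sinus fraction of the total flow (default
#'   0.02).
#' @param inlets data frame with columns \code{name}, \code{area} (m^2)
#'   and \code{tree} in \code{c("IVC", "SVC", "CS")}.
#' @param label optional scenario label; default \code{"<ivc>/<svc>"} in
#'   percent of caval flow, e.g. \code{"65/35"}.
#' @return An object of class \code{flow_scenario}.
#' @export
flow_scenario <- function(ivc_fraction, total_flow = 6 / 60000,
                          cs_fraction = 0.02, inlets = default_inlets(),
                          label = NULL) {
  stopifnot(ivc_fraction >= 0, ivc_fraction <= 1,
            cs_fraction >= 0, cs_fraction <= 1, total_flow > 0,
            all(c("name", "area", "tree") %in% names(inlets)),
            all(inlets$area > 0),
            all(inlets$tree %in% c("IVC", "SVC", "CS")))
  if (is.null(label))
    label <- sprintf("%d/%d", round(100 * ivc_fraction),
                     round(100 * (1 - ivc_fraction)))
  structure(list(ivc_fraction = ivc_fraction, total_flow = total_flow,
                 cs_fraction = cs_fraction, inlets = inlets, label = label),
            class = "flow_scenario")
}

#' Default inlet set
#'
#' A minimal inlet configuration: one IVC trunk, one SVC trunk and a
#' coronary sinus, with areas from representative trunk diameters (IVC
#' 2.9 cm, SVC 1.7 cm, coronary sinus 0.7 cm, circular sections).
#'
#' @return data frame of inlets (\code{name}, \code{area} in m^2,
#'   \code{tree}).
#' @export
default_inlets <- function() {
  dia_cm <- c(ivc = 2.90, svc = 1.74, coronary_sinus = 0.7)
  data.frame(name = names(dia_cm),
             area = pi * (dia_cm / 100 / 2)^2,
             tree = c("IVC", "SVC", "CS"),
             row.names = NULL)
}

#' Assign per-inlet flow rates for a scenario
#'
#' @param scenario a [flow_scenario()].
#' @return data frame \code{name}, \code{tree}, \code{area}, \code{flow}
#'   (m^3/s), \code{flow_lmin} (L/min). The flows sum to the scenario
#'   total to machine precision.
#' @export
assign_inlet_flows <- function(scenario) {
  stopifnot(inherits(scenario, "flow_scenario"))
  inl <- scenario$inlets
  q_cs <- scenario$cs_fraction * scenario$total_flow
  q_caval <- scenario$total_flow - q_cs
  tree_q <- c(CS = q_cs,
              IVC = scenario$ivc_fraction * q_caval,
              SVC = (1 - scenario$ivc_fraction) * q_caval)
  flow <- numeric(nrow(inl))
  for (tr in names(tree_q)) {
    sel <- inl$tree == tr
    if (!any(sel)) {
      if (tree_q[[tr]] > 0)
        stop(sprintf("assign_inlet_flows: configuration error - no inlet in tree '%s' but its flow fraction is nonzero", tr))
      next
    }
    flow[sel] <- tree_q[[tr]] * inl$area[sel] / sum(inl$area[sel])
  }
  data.frame(name = inl$name, tree = inl$tree, area = inl$area,
             flow = flow, flow_lmin = flow * 60000, row.names = NULL)
}

#' Evaluate a metric pipeline over the caval flow-split sweep
#'
#' Runs a user-supplied fixture family and metric pipeline at each IVC
#' fraction of the sweep (default the nine scenarios 30/70 to 70/30 in
#' steps of 5 percentage points), with identical settings except the split
#' and with a fixed, recorded per-scenario seed.
#'
#' @param f_values IVC caval-flow fractions; default
#'   \code{seq(0.30, 0.70, by = 0.05)}.
#' @param metric_fn \code{function(scenario, seed)} returning a named list
#'   or vector of metric values; \code{NULL} records the flow assignment
#'   only.
#' @param seed base seed; scenario \code{i} uses \code{seed + i}.
#' @param ... further arguments passed to [flow_scenario()].
#' @return A tibble, one row per scenario: \code{label},
#'   \code{ivc_fraction}, \code{svc_fraction}, \code{seed}, per-inlet
#'   flows in L/min, then any metric columns.
#' @export
scenario_sweep <- function(f_values = seq(0.30, 0.70, by = 0.05),
                           metric_fn = NULL, seed = 1L, ...) {
  if (!length(f_values))
    return(tibble::tibble(label = character(), ivc_fraction = numeric(),
                          svc_fraction = numeric(), seed = numeric()))
  rows <- vector("list", length(f_values))
  for (i in seq_along(f_values)) {
    sc <- flow_scenario(f_values[i], ...)
    fl <- assign_inlet_flows(sc)
    row <- c(list(label = sc$label, ivc_fraction = sc$ivc_fraction,
                  svc_fraction = 1 - sc$ivc_fraction, seed = seed + i),
             stats::setNames(as.list(fl$flow_lmin),
                             paste0("q_", fl$name, "_lmin")))
    if (!is.null(metric_fn)) {
      mv <- metric_fn(sc, seed + i)
      row <- c(row, as.list(mv))
    }
    rows[[i]] <- tibble::as_tibble(row)
  }
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$label)) stop("scenario_sweep: scenario labels not unique")
  out
}

#' Linear trend of a metric across scenarios
#'
#' Ordinary least-squares regression of a metric on the IVC caval-flow
#' fraction (or any other predictor column), with the two-sided P value
#' from the t distribution on n - 2 degrees of freedom. Degenerate exact
#' fits are resolved explicitly: an exactly constant metric reports slope
#' 0 with P = 1; an exactly linear metric with nonzero slope reports P = 0.
#'
#' @param table a [scenario_sweep()] result (or any data frame).
#' @param metric metric column name.
#' @param predictor predictor column name; default \code{"ivc_fraction"}.
#' @return list with \code{slope}, \code{intercept}, \code{p_value},
#'   \code{r_squared}, \code{n}.
#' @export
trend_regression <- function(table, metric, predictor = "ivc_fraction") {
  x <- table[[predictor]]; y <- table[[metric]]
  if (is.null(x) || is.null(y))
    stop("trend_regression: predictor or metric column not found")
  n <- length(x)
  if (n < 3) stop("trend_regression: need at least 3 scenarios")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  slope <- unname(cf[2]); intercept <- unname(cf[1])
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  scale2 <- mean(y^2) + 1e-300
  if (rss / scale2 < 1e-24) {            # numerically exact fit
    p <- if (abs(slope) * stats::sd(x) / sqrt(scale2) < 1e-12) 1 else 0
  } else {
    p <- summary(fit)$coefficients[2, 4]
  }
  list(slope = slope, intercept = intercept, p_value = p,
       r_squared = if (tss > 0) 1 - rss / tss else 0, n = n)
}

#' Pulsatility index of a flow waveform
#'
#' \eqn{PI = (\max - \min)/\mathrm{mean}} over the supplied samples
#' (assumed to cover an integer number of periods).
#'
#' @param waveform numeric flow series, or a data frame with column
#'   \code{q} as produced by [pulsatile_waveform()].
#' @return dimensionless pulsatility index.
#' @export
pulsatility_index <- function(waveform) {
  q <- if (is.data.frame(waveform)) waveform$q else as.numeric(waveform)
  if (!length(q) || any(!is.finite(q))) stop("pulsatility_index: bad series")
  m <- mean(q)
  if (m == 0) stop("pulsatility_index: zero-mean waveform")
  (max(q) - min(q)) / m
}
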