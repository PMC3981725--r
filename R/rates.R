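#' Bacterial production from thymidine incorporation
#'
#' Converts blank-corrected 3H-thymidine incorporation (mol TdR per litre
#' per hour) to cell production using the empirical factor 2e18 cells per
#' mol thymidine, and to carbon production using 25 fg C per cell.
#'
#' @param incorporation mol thymidine L^-1 h^-1, non-negative (negative
#'   values indicate the blank exceeded the sample and are rejected).
#' @param cells_per_mol conversion factor (default 2e18 cells/mol).
#' @param fg_c_per_cell carbon content per cell (default 25 fg C).
#' @return data.frame with `cells_per_l_h` and `ug_c_per_l_h`.
#' @export
bp_from_thymidine <- function(incorporation, cells_per_mol = 2e18,
                              fg_c_per_cell = 25) {
  if (any(incorporation < 0))
    stop("negative incorporation: blank correction exceeded the sample signal")
  cells <- incorporation * cells_per_mol
  ug_c <- cells * fg_c_per_cell * 1e-9        # fg -> ug
  data.frame(cells_per_l_h = cells, ug_c_per_l_h = ug_c)
}

#' Bacterial respiration from an oxygen-drawdown series
#'
#' Fits a least-squares linear slope to dissolved O2 vs time, subtracts the
#' slope of a parallel ultrapure-water blank series, negates to an oxygen
#' consumption rate, and converts to carbon respired with a respiratory
#' quotient (mol CO2 per mol O2; 0.88 by default).
#'
#' @param series data.frame with columns `time_h` (strictly increasing, >= 2
#'   points) and `o2` (umol O2 L^-1).
#' @param blank_series blank measurement in the same format, or NULL for no
#'   blank correction.
#' @param rq respiratory quotient (default 0.88).
#' @return list with `br_umol_c_per_l_h`, `o2_slope`, `blank_slope`,
#'   `consumption_umol_o2_per_l_h`. Net O2 production after blank correction
#'   is flagged with a warning and returned as a rate of 0.
#' @export
br_from_oxygen <- function(series, blank_series = NULL, rq = 0.88) {
  slope <- function(s) {
    stopifnot(is.data.frame(s), all(c("time_h", "o2") %in% names(s)))
    if (nrow(s) < 2) stop("need >= 2 points for a slope fit")
    if (any(diff(s$time_h) <= 0)) stop("timestamps must be strictly increasing")
    unname(stats::coef(stats::lm(o2 ~ time_h, data = s))[2])
  }
  s_obs <- slope(series)
  s_blank <- if (is.null(blank_series)) 0 else slope(blank_series)
  consumption <- -(s_obs - s_blank)
  if (consumption < 0) {
    warning("net O2 production after blank correction; respiration set to 0")
    consumption <- 0
  }
  list(br_umol_c_per_l_h = consumption * rq, o2_slope = s_obs,
       blank_slope = s_blank, consumption_umol_o2_per_l_h = consumption)
}

#' Bacterial growth efficiency
#'
#' BGE = BP / (BP + BR), with BP and BR in the same carbon units.
#'
#' @param bp,br non-negative production and respiration rates; not both zero.
#' @return fraction in [0, 1].
#' @export
bge <- function(bp, br) {
  if (any(bp < 0) || any(br < 0)) stop("bp and br must be non-negative")
  if (any(bp + br == 0)) stop("BGE undefined when bp + br = 0")
  bp / (bp + br)
}

#' Bacterial carbon demand
#'
#' BCD = BP + BR (same units).
#'
#' @inheritParams bge
#' @return rate in the input units.
#' @export
bcd <- function(bp, br) {
  if (any(bp < 0) || any(br < 0)) stop("bp and br must be non-negative")
  bp + br
}

#' DOC percent change per treatment with one-way ANOVA
#'
#' Per replicate, the relative DOC loss 100 * (t0 - tf)/t0 over the
#' incubation; summarized as treatment mean and sample standard deviation,
#' and compared across treatments by a one-way ANOVA on the per-replicate
#' relative changes (only relative changes are comparable because starting
#' DOC differs between treatments).
#'
#' @param doc data.frame with columns `treatment`, `replicate`, `doc_t0`,
#'   `doc_tf` (umol C L^-1; `doc_t0` must be positive).
#' @return list with `per_replicate` (data.frame incl. `percent_loss`),
#'   `summary` (treatment, mean_percent_loss, sd_percent_loss, n) and
#'   `anova` (F, df1, df2, p).
#' @export
doc_percent_change <- function(doc) {
  need <- c("treatment", "replicate", "doc_t0", "doc_tf")
  miss <- setdiff(need, names(doc))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(doc$doc_t0 <= 0)) stop("doc_t0 must be positive")
  doc$percent_loss <- 100 * (doc$doc_t0 - doc$doc_tf) / doc$doc_t0
  agg <- do.call(rbind, lapply(split(doc, doc$treatment), function(d)
    data.frame(treatment = d$treatment[1],
               mean_percent_loss = mean(d$percent_loss),
               sd_percent_loss = stats::sd(d$percent_loss),
               n = nrow(d))))
  rownames(agg) <- NULL
  if (length(unique(doc$treatment)) >= 2 &&
      nrow(doc) > length(unique(doc$treatment))) {
    fit <- stats::aov(percent_loss ~ factor(treatment), data = doc)
    s <- summary(fit)[[1]]
    anova <- list(F = s[["F value"]][1], df1 = s[["Df"]][1],
                  df2 = s[["Df"]][2], p = s[["Pr(>F)"]][1])
  } else {
    anova <- list(F = NA_real_, df1 = NA_integer_, df2 = NA_integer_,
                  p = NA_real_)
  }
  list(per_replicate = doc, summary = agg, anova = anova)
}

#' Preparation recovery rate
#'
#' Percentage of dissolved organic carbon recovered by a concentration step:
#' 100 * (v_out * c_out) / (v_in * c_in).
#'
#' @param v_in,c_in input volume (L) and DOC concentration (umol C L^-1).
#' @param v_out,c_out output volume and concentration; all inputs > 0.
#' @return recovery percentage (unrounded; round only for reporting).
#' @export
recovery_rate <- function(v_in, c_in, v_out, c_out) {
  if (any(c(v_in, c_in, v_out, c_out) <= 0)) stop("all inputs must be positive")
  100 * (v_out * c_out) / (v_in * c_in)
}

#' Two-endmember tDOM mixing fraction
#'
#' Carbon-weighted terrigenous fraction of a mixture: given components with
#' volume v_i, DOC concentration c_i, and tDOM fraction f_i of their DOC,
#' the mixture's tDOM percentage is 100 * sum(v c f) / sum(v c). The result
#' is bounded by the minimum and maximum component fractions (convexity).
#'
#' @param components data.frame with columns `volume` (L), `doc`
#'   (umol C L^-1) and `tdom_fraction` (in [0, 1]).
#' @return tDOM percentage of mixture DOC.
#' @export
tdom_mixing_fraction <- function(components) {
  need <- c("volume", "doc", "tdom_fraction")
  miss <- setdiff(need, names(components))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(components) < 1) stop("need at least one component")
  if (any(components$volume < 0) || any(components$doc < 0))
    stop("volumes and concentrations must be non-negative")
  if (any(components$tdom_fraction < 0 | components$tdom_fraction > 1))
    stop("tdom_fraction must lie in [0, 1]")
  carbon <- components$volume * components$doc
  if (sum(carbon) == 0) stop("zero total DOC in mixture")
  100 * sum(carbon * components$tdom_fraction) / sum(carbon)
}
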