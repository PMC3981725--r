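#' Composition parameters for a synthetic formula pool
#'
#' Describes the elemental-composition distribution of one DOM endmember:
#' a carbon-count range and target H/C and O/C distributions (normal,
#' truncated to chemically sensible windows), plus probabilities of drawing
#' a heteroatom class (N, S or P; at most one per formula, respecting the
#' assignment rules).
#'
#' @param c_range integer length-2 carbon range.
#' @param hc_mean,hc_sd target H/C distribution.
#' @param oc_mean,oc_sd target O/C distribution.
#' @param p_n,p_s,p_p probability that a formula carries N (1-4), S (1-2) or
#'   P (1); the remainder is CHO-only. Set all to 0 for a CHO pool.
#' @return list of class `composition_params`.
#' @export
composition_params <- function(c_range = c(8, 40), hc_mean = 1.3, hc_sd = 0.25,
                               oc_mean = 0.45, oc_sd = 0.15,
                               p_n = 0.10, p_s = 0.03, p_p = 0.02) {
  stopifnot(length(c_range) == 2, c_range[1] >= 1, c_range[1] <= c_range[2],
            hc_sd >= 0, oc_sd >= 0, p_n + p_s + p_p <= 1,
            min(p_n, p_s, p_p) >= 0)
  structure(list(c_range = as.integer(c_range), hc_mean = hc_mean,
                 hc_sd = hc_sd, oc_mean = oc_mean, oc_sd = oc_sd,
                 p_n = p_n, p_s = p_s, p_p = p_p),
            class = "composition_params")
}

## Marine vs terrigenous endmember composition defaults: terrigenous DOM is
## more aromatic (lower H/C) and more oxygenated (higher O/C).
.marine_composition <- function() composition_params(hc_mean = 1.5, hc_sd = 0.2,
                                                     oc_mean = 0.35, oc_sd = 0.10)
.terrigenous_composition <- function() composition_params(hc_mean = 1.05, hc_sd = 0.2,
                                                          oc_mean = 0.55, oc_sd = 0.12)

#' Generate a pool of valid molecular formulas
#'
#' Draws `n_formulas` distinct CHNOSP formulas obeying the assignment rules
#' (O<=C, N<O, N<=4, S<=2, P<=1, single heteroatom class, integer
#' non-negative DBE) with neutral masses inside `mass_range`. Carbon counts
#' are uniform on `composition$c_range`; O and H are chosen to match the
#' target O/C and H/C distributions, then snapped to the lattice (parity for
#' integer DBE, rule caps).
#'
#' @param n_formulas number of distinct formulas (>= 1).
#' @param composition a [composition_params()] object.
#' @param seed RNG seed.
#' @param mass_range allowed neutral mass window (default c(150, 1800)).
#' @param rules rule set the pool must satisfy.
#' @return data.frame with columns `c,h,n,o,s,p,mass`, all rows distinct and
#'   rule-conformant.
#' @export
generate_formula_library <- function(n_formulas, composition = composition_params(),
                                     seed = 1, mass_range = c(150, 1800),
                                     rules = assignment_rules(mass_range = mass_range)) {
  stopifnot(n_formulas >= 1)
  .local_seed(seed)
  cp <- composition
  got <- data.frame()
  tries <- 0L
  while (nrow(got) < n_formulas) {
    tries <- tries + 1L
    if (tries > 200L)
      stop("infeasible composition ranges: could not draw ", n_formulas,
           " distinct formulas satisfying O<=C, N<O and the mass window [",
           mass_range[1], ", ", mass_range[2], "] Da; widen c_range or the ",
           "H/C / O/C distributions")
    m <- max(2L * (n_formulas - nrow(got)), 50L)
    c_vals <- seq(cp$c_range[1], cp$c_range[2])
    cc <- c_vals[sample.int(length(c_vals), m, replace = TRUE)]
    u <- stats::runif(m)
    nn <- ifelse(u < cp$p_n, sample(1:4, m, replace = TRUE), 0L)
    ss <- ifelse(u >= cp$p_n & u < cp$p_n + cp$p_s, 1L, 0L)
    pp <- ifelse(u >= cp$p_n + cp$p_s & u < cp$p_n + cp$p_s + cp$p_p, 1L, 0L)
    oc <- pmin(pmax(stats::rnorm(m, cp$oc_mean, cp$oc_sd), 0.05), 1)
    hc <- pmin(pmax(stats::rnorm(m, cp$hc_mean, cp$hc_sd), 0.3), 2.2)
    oo <- pmin(pmax(round(oc * cc), nn + 1L), cc)   # N < O and O <= C
    hh <- round(hc * cc)
    hmax <- 2L * cc + 2L + nn + pp
    hh <- pmin(pmax(hh, 0L), hmax)
    ## fix parity so DBE = (2c+2+n+p-h)/2 is an integer
    bad_par <- (hmax - hh) %% 2L != 0L
    hh[bad_par] <- hh[bad_par] - 1L
    hh <- pmax(hh, 0L)
    f <- data.frame(c = cc, h = as.integer(hh), n = as.integer(nn),
                    o = as.integer(oo), s = as.integer(ss), p = as.integer(pp))
    f$mass <- formula_mass(f)
    ok <- check_rules(f, rules)$pass & f$mass >= mass_range[1] & f$mass <= mass_range[2]
    got <- unique(rbind(got, f[ok, , drop = FALSE]))
  }
  got <- got[seq_len(n_formulas), , drop = FALSE]
  rownames(got) <- NULL
  got
}

#' Simulation design for a mesocosm DOM experiment
#'
#' Bundles the experimental layout and the generator's noise model. The
#' defaults follow the study design being emulated: five treatments (cBS,
#' RB, ULTRA, LYO, cRW) in triplicate over days 0 and 28, with terrigenous
#' DOM fractions of 0.43 (Baltic Sea control), 0.81 (river + Baltic), 0.84
#' (ultrafiltrate and lyophilisate additions) and 1.0 (river control), a
#' constant +0.3 ppm calibration drift, 0.01 ppm random mass error, and
#' irreproducible low-intensity noise peaks at S/N in [3, 5].
#'
#' @param treatments character vector of treatment labels.
#' @param tdom_fraction named numeric in [0, 1], one per treatment.
#' @param replicates replicates per treatment (default 3).
#' @param days integer vector of sampling days (default c(0, 28)).
#' @param n_true_formulas formulas per endmember pool (default 3000).
#' @param shared_fraction fraction of each endmember pool shared with the
#'   other (DOM background; default 0.4).
#' @param noise_peaks_per_sample irreproducible noise peaks per sample.
#' @param mass_error_ppm_sd random mass error sd (ppm).
#' @param calib_drift_ppm constant calibration drift (ppm).
#' @param calib_drift_slope drift slope in ppm per Da (default 0).
#' @param intensity_sdlog per-peak lognormal intensity scatter (sdlog).
#' @param noise_floor instrument noise level in intensity units; S/N =
#'   intensity / noise_floor.
#' @param degrade_fraction,degrade_effect optional injected temporal signal:
#'   a random `degrade_fraction` of true formulas lose `degrade_effect`
#'   (relative) intensity by the final day. Defaults 0 (no temporal DOM
#'   trend, as observed).
#' @param seed master RNG seed.
#' @return list of class `sim_design`.
#' @export
sim_design <- function(treatments = c("cBS", "RB", "ULTRA", "LYO", "cRW"),
                       tdom_fraction = c(cBS = 0.43, RB = 0.81, ULTRA = 0.84,
                                         LYO = 0.84, cRW = 1.00),
                       replicates = 3, days = c(0, 28),
                       n_true_formulas = 3000, shared_fraction = 0.4,
                       noise_peaks_per_sample = 1500,
                       mass_error_ppm_sd = 0.01, calib_drift_ppm = 0.3,
                       calib_drift_slope = 0, intensity_sdlog = 0.4,
                       noise_floor = 10,
                       degrade_fraction = 0, degrade_effect = 0,
                       seed = 1) {
  stopifnot(length(treatments) >= 1, replicates >= 1, length(days) >= 1,
            n_true_formulas >= 1, noise_peaks_per_sample >= 0,
            mass_error_ppm_sd >= 0, shared_fraction >= 0, shared_fraction <= 1,
            degrade_fraction >= 0, degrade_fraction <= 1,
            degrade_effect >= 0, degrade_effect <= 1)
  tdom_fraction <- tdom_fraction[treatments]
  if (any(is.na(tdom_fraction)))
    stop("tdom_fraction must be named and cover every treatment")
  if (any(tdom_fraction < 0 | tdom_fraction > 1))
    stop("tdom fractions must lie in [0, 1]")
  structure(list(treatments = treatments, tdom_fraction = tdom_fraction,
                 replicates = as.integer(replicates), days = as.integer(days),
                 n_true_formulas = as.integer(n_true_formulas),
                 shared_fraction = shared_fraction,
                 noise_peaks_per_sample = as.integer(noise_peaks_per_sample),
                 mass_error_ppm_sd = mass_error_ppm_sd,
                 calib_drift_ppm = calib_drift_ppm,
                 calib_drift_slope = calib_drift_slope,
                 intensity_sdlog = intensity_sdlog,
                 noise_floor = noise_floor,
                 degrade_fraction = degrade_fraction,
                 degrade_effect = degrade_effect,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Generate the two-endmember formula pool of a design
#'
#' Builds marine and terrigenous endmember pools of `n_true_formulas` each,
#' overlapping in a shared background of `shared_fraction * n_true_formulas`
#' formulas drawn from intermediate composition. Each formula carries an
#' endmember affinity (1 marine-only, 0 terrigenous-only, 0.5 shared) and a
#' lognormal base abundance.
#'
#' @param design a [sim_design()].
#' @param marine,terrigenous [composition_params()] for the two endmembers.
#' @param mass_range neutral mass window for the pool.
#' @return data.frame `c,h,n,o,s,p,mass,affinity,base_intensity`, all
#'   formulas distinct.
#' @export
generate_endmember_pools <- function(design,
                                     marine = .marine_composition(),
                                     terrigenous = .terrigenous_composition(),
                                     mass_range = c(150, 800)) {
  n <- design$n_true_formulas
  n_shared <- round(design$shared_fraction * n)
  n_unique <- n - n_shared
  mid <- composition_params(
    c_range = marine$c_range,
    hc_mean = (marine$hc_mean + terrigenous$hc_mean) / 2, hc_sd = marine$hc_sd,
    oc_mean = (marine$oc_mean + terrigenous$oc_mean) / 2, oc_sd = marine$oc_sd,
    p_n = marine$p_n, p_s = marine$p_s, p_p = marine$p_p)
  ## oversample then deduplicate across the three blocks
  mar <- generate_formula_library(n_unique + n_shared, marine,
                                  seed = design$seed + 101L, mass_range = mass_range)
  ter <- generate_formula_library(n_unique + n_shared, terrigenous,
                                  seed = design$seed + 202L, mass_range = mass_range)
  shr <- generate_formula_library(max(n_shared, 1L), mid,
                                  seed = design$seed + 303L, mass_range = mass_range)
  if (n_shared == 0) shr <- shr[0, , drop = FALSE]
  key <- function(f) formula_string(f)
  shr <- shr[!key(shr) %in% c(key(mar), key(ter)), , drop = FALSE]
  mar <- mar[!key(mar) %in% key(ter), , drop = FALSE][seq_len(min(n_unique, nrow(mar))), ]
  ter <- ter[seq_len(min(n_unique, nrow(ter))), , drop = FALSE]
  pool <- rbind(cbind(mar, affinity = 1), cbind(ter, affinity = 0),
                cbind(shr, affinity = 0.5))
  .local_seed(design$seed + 404L)
  pool$base_intensity <- stats::rlnorm(nrow(pool), meanlog = log(300), sdlog = 1)
  rownames(pool) <- NULL
  pool
}

#' Simulate one sample's peak list
#'
#' Every pool formula is emitted as an [M-H]- ion whose expected intensity
#' is its base abundance times the mixture weight
#' w = affinity * (1 - f) + (1 - affinity) * f (f = tDOM fraction of the
#' sample), scattered lognormally; peaks falling below S/N 1 are not
#' recorded. The observed m/z carries a systematic affine ppm drift plus
#' Gaussian ppm error. Calibrant ions are added at high intensity, and
#' `noise_peaks` irreproducible noise peaks are drawn at uniform random
#' masses (rejected within 3 ppm of any true/calibrant mass or of
#' `exclude_noise_masses`, so noise never recurs across replicates) with
#' S/N uniform in [3, 5].
#'
#' @param pool formula pool from [generate_endmember_pools()] (needs columns
#'   `mass`, `affinity`, `base_intensity`).
#' @param tdom_fraction sample tDOM fraction in [0, 1].
#' @param design a [sim_design()] supplying the noise model.
#' @param seed per-sample RNG seed.
#' @param calibrants calibrant data.frame (or NULL to omit calibrant ions).
#' @param exclude_noise_masses neutral masses noise may not approach
#'   (within 3 ppm); used by the experiment driver to keep noise disjoint
#'   across replicates.
#' @param degrade_multiplier per-formula intensity multipliers (temporal
#'   signal injection); default all 1.
#' @return list with `peaks` (data.frame mz, intensity, snr, sorted by mz)
#'   and `truth` (data.frame kind = formula/calibrant/noise, pool_index,
#'   true_neutral_mass, aligned with `peaks`).
#' @export
simulate_sample_peaklist <- function(pool, tdom_fraction, design = sim_design(),
                                     seed = 1, calibrants = default_calibrants(),
                                     exclude_noise_masses = numeric(),
                                     degrade_multiplier = NULL) {
  stopifnot(nrow(pool) >= 1, tdom_fraction >= 0, tdom_fraction <= 1)
  .local_seed(seed)
  f <- tdom_fraction
  w <- pool$affinity * (1 - f) + (1 - pool$affinity) * f
  if (is.null(degrade_multiplier)) degrade_multiplier <- rep(1, nrow(pool))
  intensity <- pool$base_intensity * w * degrade_multiplier *
    stats::rlnorm(nrow(pool), 0, design$intensity_sdlog)
  snr <- intensity / design$noise_floor
  keep <- snr >= 1
  true_mass <- pool$mass[keep]
  rows <- list(data.frame(true_neutral_mass = true_mass,
                          intensity = intensity[keep], snr = snr[keep],
                          kind = "formula", pool_index = which(keep)))
  if (!is.null(calibrants)) {
    cal_int <- stats::rlnorm(nrow(calibrants), meanlog = log(5000), sdlog = 0.3)
    rows <- c(rows, list(data.frame(true_neutral_mass = calibrants$neutral_mass_da,
                                    intensity = cal_int,
                                    snr = cal_int / design$noise_floor,
                                    kind = "calibrant", pool_index = NA_integer_)))
  }
  if (design$noise_peaks_per_sample > 0) {
    avoid <- sort(c(pool$mass,
                    if (!is.null(calibrants)) calibrants$neutral_mass_da,
                    exclude_noise_masses))
    nm <- numeric(0)
    while (length(nm) < design$noise_peaks_per_sample) {
      cand <- stats::runif(2 * (design$noise_peaks_per_sample - length(nm)), 150, 800)
      near <- function(x) {
        i <- findInterval(x, avoid)
        lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(avoid))
        pmin(abs(x - avoid[lo]), abs(x - avoid[hi])) / x * 1e6 <= 3
      }
      cand <- cand[!near(cand)]
      nm <- c(nm, cand)
      avoid <- sort(c(avoid, cand))   # noise must not recur within the sample either
    }
    nm <- nm[seq_len(design$noise_peaks_per_sample)]
    nsnr <- stats::runif(length(nm), 3, 5)
    rows <- c(rows, list(data.frame(true_neutral_mass = nm,
                                    intensity = nsnr * design$noise_floor,
                                    snr = nsnr, kind = "noise",
                                    pool_index = NA_integer_)))
  }
  all <- do.call(rbind, rows)
  ion <- mz_from_neutral_mass(all$true_neutral_mass)
  ppm_err <- design$calib_drift_ppm + design$calib_drift_slope * ion +
    stats::rnorm(nrow(all), 0, design$mass_error_ppm_sd)
  mz <- ion * (1 + ppm_err * 1e-6)
  ord <- order(mz)
  peaks <- data.frame(mz = mz, intensity = all$intensity, snr = all$snr)[ord, ]
  truth <- all[ord, c("kind", "pool_index", "true_neutral_mass")]
  rownames(peaks) <- rownames(truth) <- NULL
  list(peaks = peaks, truth = truth)
}

#' Simulate a full mesocosm FT-ICR-MS experiment
#'
#' Generates the endmember pools and one peak list per treatment x day x
#' replicate, with noise masses kept disjoint across all samples, and
#' returns the ground truth needed to score downstream stages.
#'
#' @param design a [sim_design()].
#' @param calibrants calibrant list (or NULL).
#' @param pool optional pre-built pool (from [generate_endmember_pools()]).
#' @return list of class `sim_experiment`: `peaklists` (named list),
#'   `meta` (sample_id, treatment, day, replicate), `truth` (named list of
#'   per-sample truth tables), `pool`, `design`, `calibrants`.
#' @export
simulate_experiment <- function(design = sim_design(),
                                calibrants = default_calibrants(),
                                pool = NULL) {
  if (is.null(pool)) pool <- generate_endmember_pools(design)
  ## optional injected temporal signal on a fixed random subset
  .local_seed(design$seed + 505L)
  degrade_idx <- if (design$degrade_fraction > 0)
    sample(nrow(pool), round(design$degrade_fraction * nrow(pool))) else integer()
  meta <- expand.grid(replicate = seq_len(design$replicates),
                      day = design$days, treatment = design$treatments,
                      stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_d%d_r%d", meta$treatment, meta$day, meta$replicate)
  meta <- meta[, c("sample_id", "treatment", "day", "replicate")]
  peaklists <- truth <- stats::setNames(vector("list", nrow(meta)), meta$sample_id)
  noise_registry <- numeric()
  final_day <- max(design$days)
  for (i in seq_len(nrow(meta))) {
    mult <- rep(1, nrow(pool))
    if (length(degrade_idx) && meta$day[i] == final_day)
      mult[degrade_idx] <- 1 - design$degrade_effect
    sim <- simulate_sample_peaklist(
      pool, design$tdom_fraction[[meta$treatment[i]]], design,
      seed = design$seed + 1000L + i, calibrants = calibrants,
      exclude_noise_masses = noise_registry, degrade_multiplier = mult)
    peaklists[[i]] <- sim$peaks
    truth[[i]] <- sim$truth
    noise_registry <- c(noise_registry, sim$truth$true_neutral_mass[sim$truth$kind == "noise"])
  }
  structure(list(peaklists = peaklists, meta = meta, truth = truth,
                 pool = pool, design = design, calibrants = calibrants),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("sim_experiment: %d samples (%d treatments x %d days x %d replicates), pool %d formulas\n",
              length(x$peaklists), length(x$design$treatments),
              length(x$design$days), x$design$replicates, nrow(x$pool)))
  invisible(x)
}

#' Simulate OTU count tables
#'
#' Emulates the observed community dynamics: in "collapsing" communities
#' (the mesohaline mesocosms) one gammaproteobacterial OTU comes to dominate
#' the final-day reads so evenness drops sharply, while "stable" communities
#' (the freshwater control) keep their diverse composition. Counts are
#' multinomial draws with lognormal replicate noise, so singleton reads
#' occur naturally for filter testing.
#'
#' @param treatments character vector of treatment labels.
#' @param profile named character: "collapsing" or "stable" per treatment.
#' @param replicates,days experiment layout (defaults 3; c(0, 28)).
#' @param n_otus community richness of the base pool (default 300).
#' @param library_size reads per sample (default 3000).
#' @param dominance final-day read share of the dominant OTU in collapsing
#'   communities (default 0.5).
#' @param seed RNG seed.
#' @return list: `counts` (OTU x sample integer matrix), `taxonomy`
#'   (character per OTU), `meta` (sample_id, treatment, day, replicate).
#' @export
simulate_otu_table <- function(treatments = c("cBS", "RB", "ULTRA", "LYO", "cRW"),
                               profile = c(cBS = "collapsing", RB = "collapsing",
                                           ULTRA = "collapsing", LYO = "collapsing",
                                           cRW = "stable"),
                               replicates = 3, days = c(0, 28),
                               n_otus = 300, library_size = 3000,
                               dominance = 0.5, seed = 1) {
  profile <- profile[treatments]
  if (any(is.na(profile)) || !all(profile %in% c("collapsing", "stable")))
    stop("profile must name every treatment as 'collapsing' or 'stable'")
  .local_seed(seed)
  base <- sort(stats::rlnorm(n_otus, 0, 1), decreasing = TRUE)
  base <- base / sum(base)
  dom <- 1L                                   # the OTU that takes over
  meta <- expand.grid(replicate = seq_len(replicates), day = as.integer(days),
                      treatment = treatments, stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_d%d_r%d", meta$treatment, meta$day, meta$replicate)
  meta <- meta[, c("sample_id", "treatment", "day", "replicate")]
  final_day <- max(days)
  counts <- matrix(0L, n_otus, nrow(meta),
                   dimnames = list(sprintf("OTU_%03d", seq_len(n_otus)),
                                   meta$sample_id))
  for (i in seq_len(nrow(meta))) {
    lambda <- if (profile[[meta$treatment[i]]] == "collapsing")
      meta$day[i] / final_day else 0
    p <- base * (1 - lambda * dominance)
    p[dom] <- p[dom] + lambda * dominance
    p <- p * stats::rlnorm(n_otus, 0, 0.3)    # replicate-level scatter
    counts[, i] <- as.integer(stats::rmultinom(1, library_size, p / sum(p)))
  }
  taxonomy <- c("Gammaproteobacteria;Paraperlucidibaca",
                sample(c("Alphaproteobacteria", "Actinobacteria", "Bacteroidetes",
                         "Betaproteobacteria", "Verrucomicrobia", "Planctomycetes",
                         "Cyanobacteria"), n_otus - 1, replace = TRUE))
  list(counts = counts, taxonomy = taxonomy, meta = meta)
}

#' Simulate microbial rate and DOC inputs with known truth
#'
#' Produces thymidine-incorporation values, oxygen time series (sample and
#' ultrapure-water blank), and per-replicate day-0 / final-day DOC
#' concentrations. Defaults carry the study's observed DOC conditions
#' (starting DOC 310-400 umol C/L by treatment; relative losses of 6, 16,
#' 7, 4 and 7 % for cBS, RB, ULTRA, LYO and cRW).
#'
#' @param treatments treatment labels.
#' @param replicates replicates per treatment (default 3).
#' @param doc0 named starting DOC (umol C L^-1) per treatment.
#' @param doc_loss named relative DOC loss by the final day per treatment.
#' @param doc_loss_sd named replicate sd of the relative loss (0 = exact).
#' @param thymidine_true true incorporation (mol TdR L^-1 h^-1).
#' @param thymidine_cv replicate coefficient of variation.
#' @param o2_slope_true true O2 slope (umol L^-1 h^-1, negative =
#'   consumption).
#' @param o2_noise_sd Gaussian noise sd on the O2 readings (umol L^-1).
#' @param o2_times measurement times in hours (default 0..12).
#' @param seed RNG seed.
#' @return list: `thymidine` (treatment, replicate, incorporation), `oxygen`
#'   (named list per treatment x replicate of data.frames time_h, o2),
#'   `oxygen_blank` (data.frame time_h, o2), `doc` (treatment, replicate,
#'   doc_t0, doc_tf), `truth` (the parameters used).
#' @export
simulate_rate_inputs <- function(treatments = c("cBS", "RB", "ULTRA", "LYO", "cRW"),
                                 replicates = 3,
                                 doc0 = c(cBS = 310, RB = 380, ULTRA = 360,
                                          LYO = 340, cRW = 400),
                                 doc_loss = c(cBS = 0.06, RB = 0.16, ULTRA = 0.07,
                                              LYO = 0.04, cRW = 0.07),
                                 doc_loss_sd = c(cBS = 0.03, RB = 0.06, ULTRA = 0.03,
                                                 LYO = 0.01, cRW = 0.01),
                                 thymidine_true = 2e-11, thymidine_cv = 0.1,
                                 o2_slope_true = -0.5, o2_noise_sd = 0.05,
                                 o2_times = 0:12, seed = 1) {
  fill <- function(x, default) {
    out <- x[treatments]
    names(out) <- treatments
    out[is.na(out)] <- default
    out
  }
  ## treatments outside the study defaults get generic DOC conditions
  doc0 <- fill(doc0, 350)
  doc_loss <- fill(doc_loss, 0.08)
  doc_loss_sd <- fill(doc_loss_sd, 0.03)
  .local_seed(seed)
  grid <- expand.grid(replicate = seq_len(replicates), treatment = treatments,
                      stringsAsFactors = FALSE)[, c("treatment", "replicate")]
  thy <- grid
  thy$incorporation <- pmax(thymidine_true *
    (1 + stats::rnorm(nrow(grid), 0, thymidine_cv)), 0)
  oxygen <- stats::setNames(vector("list", nrow(grid)),
                            sprintf("%s_r%d", grid$treatment, grid$replicate))
  o2_0 <- 350
  for (i in seq_len(nrow(grid)))
    oxygen[[i]] <- data.frame(
      time_h = o2_times,
      o2 = o2_0 + o2_slope_true * o2_times + stats::rnorm(length(o2_times), 0, o2_noise_sd))
  oxygen_blank <- data.frame(
    time_h = o2_times,
    o2 = o2_0 + stats::rnorm(length(o2_times), 0, o2_noise_sd))
  doc <- grid
  doc$doc_t0 <- doc0[doc$treatment]
  loss_rep <- doc_loss[doc$treatment] +
    stats::rnorm(nrow(doc), 0, 1) * doc_loss_sd[doc$treatment]
  doc$doc_tf <- doc$doc_t0 * (1 - loss_rep)
  rownames(doc) <- NULL
  list(thymidine = thy, oxygen = oxygen, oxygen_blank = oxygen_blank, doc = doc,
       truth = list(thymidine_true = thymidine_true,
                    o2_slope_true = o2_slope_true, doc_loss = doc_loss))
}
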