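test_that("a fully constrained composition yields exactly C6H12O6", {
  cp <- composition_params(c_range = c(6, 6), hc_mean = 2, hc_sd = 0,
                           oc_mean = 1, oc_sd = 0, p_n = 0, p_s = 0, p_p = 0)
  f <- generate_formula_library(1, cp, seed = 1)
  expect_equal(f[1, c("c", "h", "n", "o", "s", "p")],
               data.frame(c = 6L, h = 12L, n = 0L, o = 6L, s = 0L, p = 0L))
  expect_equal(f$mass, 180.0633881, tolerance = 1e-6)
})

test_that("generated pools are distinct, rule-conformant and in the mass window", {
  f <- generate_formula_library(1000, composition_params(), seed = 7)
  expect_identical(nrow(f), 1000L)
  expect_false(any(duplicated(formula_string(f))))
  expect_true(all(check_rules(f)$pass))
  expect_true(all(f$mass >= 150 & f$mass <= 1800))
  # determinism
  f2 <- generate_formula_library(1000, composition_params(), seed = 7)
  expect_identical(f, f2)
  # infeasible ranges fail with an explanation
  tiny <- composition_params(c_range = c(1, 2), p_n = 0, p_s = 0, p_p = 0)
  expect_error(generate_formula_library(10, tiny, seed = 1), "infeasible")
})

test_that("endmember pools overlap in a shared background and carry affinities", {
  d <- tiny_design(seed = 5)
  pool <- generate_endmember_pools(d)
  expect_false(any(duplicated(formula_string(pool))))
  expect_setequal(unique(pool$affinity), c(0, 0.5, 1))
  expect_gt(sum(pool$affinity == 0.5), 0)
  expect_true(all(pool$base_intensity > 0))
})

test_that("noise-free simulation hits pool masses exactly; drift shows on calibrants", {
  d <- tiny_design(seed = 2, noise_peaks_per_sample = 0,
                   calib_drift_ppm = 0, mass_error_ppm_sd = 0)
  pool <- generate_endmember_pools(d)
  sim <- simulate_sample_peaklist(pool, 0.5, d, seed = 9, calibrants = NULL)
  expect_true(all(sim$truth$kind == "formula"))
  neutral <- neutral_mass_from_mz(sim$peaks$mz)
  expect_equal(neutral, pool$mass[sim$truth$pool_index], tolerance = 1e-12)
  # a +0.3 ppm constant drift appears as the mean signed calibrant error
  cal <- default_calibrants()
  d3 <- tiny_design(seed = 2, noise_peaks_per_sample = 0,
                    calib_drift_ppm = 0.3, mass_error_ppm_sd = 0.01)
  sim3 <- simulate_sample_peaklist(pool, 0.5, d3, seed = 9, calibrants = cal)
  iscal <- sim3$truth$kind == "calibrant"
  err <- (sim3$peaks$mz[iscal] - mz_from_neutral_mass(sim3$truth$true_neutral_mass[iscal])) /
    sim3$peaks$mz[iscal] * 1e6
  expect_equal(mean(err), 0.3, tolerance = 0.02)
})

test_that("replicates share true masses but never share noise masses", {
  d <- tiny_design(seed = 6)
  pool <- generate_endmember_pools(d)
  r1 <- simulate_sample_peaklist(pool, 0.5, d, seed = 11, calibrants = NULL)
  noise1 <- r1$truth$true_neutral_mass[r1$truth$kind == "noise"]
  r2 <- simulate_sample_peaklist(pool, 0.5, d, seed = 12, calibrants = NULL,
                                 exclude_noise_masses = noise1)
  noise2 <- r2$truth$true_neutral_mass[r2$truth$kind == "noise"]
  # noise disjoint by construction (3 ppm exclusion radius)
  for (m in noise2) expect_gt(min(abs(noise1 - m) / m * 1e6), 3)
  # shared true formulas agree within the mass-error scale
  shared <- intersect(r1$truth$pool_index[r1$truth$kind == "formula"],
                      r2$truth$pool_index[r2$truth$kind == "formula"])
  expect_gt(length(shared), 0)
  m1 <- neutral_mass_from_mz(r1$peaks$mz[match(shared, r1$truth$pool_index)])
  m2 <- neutral_mass_from_mz(r2$peaks$mz[match(shared, r2$truth$pool_index)])
  expect_lt(max(abs(m1 - m2) / m1 * 1e6), 0.1)
})

test_that("a full experiment is deterministic and keeps noise sample-unique", {
  d <- tiny_design(seed = 8)
  ex1 <- simulate_experiment(d, calibrants = NULL)
  ex2 <- simulate_experiment(d, calibrants = NULL)
  expect_identical(ex1$peaklists, ex2$peaklists)
  expect_identical(ex1$truth, ex2$truth)
  # every non-noise peak maps to exactly one pool formula
  for (t in ex1$truth) {
    isf <- t$kind == "formula"
    expect_false(anyNA(t$pool_index[isf]))
    expect_false(any(duplicated(t$pool_index[isf])))
  }
  # pooled noise masses never collide across the whole experiment
  all_noise <- sort(unlist(lapply(ex1$truth, function(t)
    t$true_neutral_mass[t$kind == "noise"])))
  gaps_ppm <- diff(all_noise) / all_noise[-length(all_noise)] * 1e6
  expect_gt(min(gaps_ppm), 3)
})

test_that("drift-free error-free simulation is 100% assignable", {
  cp_m <- cho_composition(1.5, 0.35)
  cp_t <- cho_composition(1.05, 0.55)
  d <- sim_design(treatments = "A", tdom_fraction = c(A = 0.5), days = 0,
                  replicates = 1, n_true_formulas = 150,
                  noise_peaks_per_sample = 0, calib_drift_ppm = 0,
                  mass_error_ppm_sd = 0, seed = 14)
  pool <- generate_endmember_pools(d, marine = cp_m, terrigenous = cp_t,
                                   mass_range = c(150, 400))
  sim <- simulate_sample_peaklist(pool, 0.5, d, seed = 3, calibrants = NULL)
  a <- assign_peaklist(sim$peaks, assignment_rules(tol_ppm = 0.2))
  pf <- pool[sim$truth$pool_index, ]
  ok <- a$assignments$status == "unique" &
    a$assignments$c == pf$c & a$assignments$h == pf$h & a$assignments$o == pf$o
  expect_identical(mean(ok), 1)
})

test_that("OTU simulation produces collapsing and stable community dynamics", {
  sim <- simulate_otu_table(treatments = c("M", "F"),
                            profile = c(M = "collapsing", F = "stable"),
                            seed = 21)
  expect_identical(sim$counts, simulate_otu_table(treatments = c("M", "F"),
                   profile = c(M = "collapsing", F = "stable"), seed = 21)$counts)
  expect_true(any(sim$counts == 1))   # singletons exist for filter testing
  rel <- relative_abundance(sim$counts)
  ev <- shannon_evenness(rel)
  ev_by <- function(trt, day)
    mean(ev$evenness[sim$meta$treatment == trt & sim$meta$day == day])
  # stable community: evenness change within +/- 0.1
  expect_lt(abs(ev_by("F", 28) - ev_by("F", 0)), 0.1)
  # collapsing community: evenness drops and one OTU exceeds 30% of final reads
  expect_lt(ev_by("M", 28), ev_by("M", 0))
  final_m <- sim$meta$sample_id[sim$meta$treatment == "M" & sim$meta$day == 28]
  expect_true(all(apply(rel[, final_m], 2, max) > 0.3))
  expect_match(sim$taxonomy[1], "Gammaproteobacteria")
})

test_that("rate-input simulation recovers its own truth", {
  # zero noise: exact recovery
  ri <- simulate_rate_inputs(treatments = c("cBS", "RB"), o2_noise_sd = 0,
                             doc_loss_sd = c(cBS = 0, RB = 0),
                             thymidine_cv = 0, seed = 2)
  r <- br_from_oxygen(ri$oxygen[[1]], ri$oxygen_blank, rq = 1)
  expect_equal(r$o2_slope, ri$truth$o2_slope_true, tolerance = 1e-10)
  doc_rb <- ri$doc[ri$doc$treatment == "RB", ]
  expect_equal(doc_rb$doc_tf, 0.84 * doc_rb$doc_t0, tolerance = 1e-12)
  expect_equal(unique(ri$thymidine$incorporation), 2e-11)
  # noisy: Monte-Carlo recovery of the O2 slope within 2 sd over 100 repeats
  slopes <- vapply(1:100, function(s) {
    rin <- simulate_rate_inputs(treatments = "cBS", replicates = 1,
                                o2_noise_sd = 0.05, seed = s)
    br_from_oxygen(rin$oxygen[[1]], NULL, rq = 1)$o2_slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - (-0.5)), 2 * sd(slopes) / sqrt(100))
})
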