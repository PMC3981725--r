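## Shared small fixtures, built in code (no stored data).

## A tiny two-treatment design used across module tests.
tiny_design <- function(seed = 3, ...) {
  args <- utils::modifyList(
    list(treatments = c("A", "B"), tdom_fraction = c(A = 0.2, B = 0.8),
         n_true_formulas = 200, noise_peaks_per_sample = 50, seed = seed),
    list(...))
  do.call(sim_design, args)
}

## CHO-only composition with a given H/C and O/C centre.
cho_composition <- function(hc, oc, c_range = c(6, 28), hc_sd = 0.3, oc_sd = 0.15) {
  composition_params(c_range = c_range, hc_mean = hc, hc_sd = hc_sd,
                     oc_mean = oc, oc_sd = oc_sd, p_n = 0, p_s = 0, p_p = 0)
}

## Hand-built feature table: 4 features x 6 samples (2 treatments x 3 reps).
toy_feature_table <- function(intensity = NULL) {
  meta <- data.frame(sample_id = c("A1", "A2", "A3", "B1", "B2", "B3"),
                     treatment = rep(c("A", "B"), each = 3),
                     day = 0L, replicate = rep(1:3, 2))
  if (is.null(intensity)) {
    intensity <- matrix(c(
      10, 12, 11, 20, 22, 21,   # present everywhere
      5,  6,  0,  0,  0,  0,    # 2/3 in group A only
      7,  8,  9,  0,  0,  0,    # 3/3 in group A, absent in B
      0,  0,  3,  0,  4,  0),   # scattered singles
      nrow = 4, byrow = TRUE,
      dimnames = list(NULL, meta$sample_id))
  }
  feature_table(c(200.1, 250.2, 300.3, 350.4), intensity, meta)
}

## Exact monoisotopic masses used to build synthetic peaks in tests.
test_mass <- function(c, h, o, n = 0, s = 0, p = 0)
  formula_mass(data.frame(c = c, h = h, n = n, o = o, s = s, p = p))
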