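---
title: "Methods: FT-ICR-MS DOM processing and mesocosm statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FT-ICR-MS DOM processing and mesocosm statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fticrdom)
```

# Scope

`fticrdom` implements the computational chain used to analyse terrigenous
dissolved organic matter (tDOM) decomposition mesocosms: ultrahigh-resolution
mass-spectral peak lists are internally recalibrated, decomposed into CHNOSP
molecular formulas, aligned into a cross-sample feature matrix with
replicate-based noise filtering, and analysed with multivariate community
statistics; alongside, microbial rate measurements are converted into
production/respiration/growth-efficiency budgets and a two-endmember mixing
model quantifies the terrigenous share of the DOC pool. A seeded synthetic-data
generator with complete ground truth makes every stage testable without
instrument data.

This vignette records the models, the tunable parameters, and the design
decisions taken where the procedure was genuinely open.

# Internal mass calibration

FT-ICR mass axes drift on the ppm scale. The calibration model treats the
*signed relative error* (ppm) of known calibrant ions as an affine function of
m/z:

$$\varepsilon(m/z) = a + b \cdot m/z \quad [\mathrm{ppm}],$$

fitted by ordinary least squares over calibrants matched within a search
window (default 1 ppm, nearest match by |ppm|, exact ties broken by higher
intensity, at most one peak per calibrant). Correction replaces every
$m/z$ by $m/z\,(1 - \hat\varepsilon(m/z)\cdot 10^{-6})$.

Decisions:

* **Affine in ppm, not in Da.** Instrument drift in ICR cells is closer to
  multiplicative than additive; an affine ppm model captures both a constant
  offset and a mild mass-dependent trend and is standard practice. A
  constant-offset fallback (with a warning) covers the degenerate case of
  coincident calibrant m/z.
* **At least two matches are required**; fewer aborts with a diagnostic
  rather than returning an unusable model.
* The correction is idempotent to first order: refitting on corrected data
  yields a near-zero model (verified in the test suite to below
  $10^{-4}$ ppm).
* The bundled calibrant list (68 CHO entries spanning roughly 160–700 Da,
  `inst/extdata/calibrants_synthetic.tsv`) is a *synthetic* stand-in for an
  instrument laboratory's in-house calibration database; its masses are exact
  monoisotopic formula masses. Any two-column TSV (label, neutral mass) can
  be supplied instead.

The test suite measures the contract on seeded synthetic lists: with a
+0.3 ppm drift and 0.01 ppm Gaussian mass noise, the maximum post-calibration
residual over the 68 calibrants stays below 0.05 ppm, and for random affine
drifts within ±2 ppm the post-calibration RMS error stays within 1.5× the
injected noise sd.

# Molecular-formula assignment

Neutral masses (measured m/z + one proton mass; only singly deprotonated
[M−H]⁻ ions are supported, multiply charged ions are not considered) are
decomposed exhaustively over the constrained integer lattice of elemental
compositions C$_c$H$_h$N$_n$O$_o$S$_s$P$_p$ with the rules:

* O ≤ C; N < O; N ≤ 4; S ≤ 2; P ≤ 1;
* at most one of N, S, P nonzero (heteroatom classes are not combined);
* 0 ≤ H ≤ 2C + 2 + N + P and DBE = (2C + 2 + N + P − H)/2 a non-negative
  integer (even-electron neutral molecules);
* neutral mass within the instrument window, 150–1800 Da.

The enumerator loops over the allowed heteroatom blocks and (C, O) pairs and
*solves* for H by rounding, which is exhaustive because the tolerance window
(sub-ppm, i.e. sub-mDa) is several orders of magnitude narrower than one
hydrogen mass. The test suite proves completeness by comparing, candidate for
candidate, against an independent brute-force sweep of the full lattice on
100 random masses in 150–700 Da.

Decisions:

* **N < O is read literally**, so oxygen-free formulas (pure hydrocarbons,
  CH$_x$N$_y$) are excluded by default. The rule is chemically debatable, so a
  flag relaxes it to N ≤ O.
* **Tolerance defaults to 0.5 ppm** for the assignment search window.
  Sub-0.05 ppm *calibration residuals* are a different quantity than the
  search window; both are exposed. In CHO-dominated pools below 400 Da,
  uniqueness typically emerges at 0.2 ppm (the smallest CHO lattice spacing,
  O vs CH$_4$, is 36.4 mDa — far wider than any sub-ppm window).
* **Ambiguity is never silently resolved**: a peak with several candidates is
  reported as `ambiguous` with all candidates; only single-candidate peaks
  receive formula annotations.
* Isotopologues (¹³C, ¹⁵N, ¹⁸O, ³⁴S) are not assigned.

# Feature matrix and noise filtering

The processing order is fixed and logged: S/N filter → cross-sample mass
alignment → blank subtraction → presence filter → per-sample standardization.

* **S/N filter**: peaks with signal-to-noise ≥ 3 (inclusive) are retained.
* **Alignment** pools all calibrated neutral masses, sorts them, and breaks
  single-linkage clusters where the gap between consecutive masses exceeds
  the alignment tolerance (default 1 ppm). The consensus mass is the
  intensity-weighted mean; if one sample contributes two peaks to a feature,
  the larger intensity is used and the event is counted. With calibration
  residuals held below 0.05 ppm, a 1 ppm gap tolerance is conservative and
  the procedure is deterministic.
* **Blank subtraction** removes features whose consensus mass matches a
  process-blank feature within the alignment tolerance. Matching is by mass,
  not by assigned formula, since blank peaks need not be assignable.
* **Presence filtering** implements the two alternative noise-reduction
  rules: the *triplicate* rule (a feature's presence counts in a
  treatment × day group only if detected in **all** replicates of that group;
  masses seen in only one or two of three parallel mesocosms are zeroed; a
  feature survives globally if it survives in at least one group) and the
  *prevalence* rule (keep features present in strictly more than 80% of all
  samples — more restrictive but agnostic about replicate similarity). Both
  are selectable; the pipeline default is the triplicate rule.
* **Presence means a detected peak** (nonzero intensity after the S/N
  filter), not an intensity threshold.
* **Standardization** z-scores each sample column over its *detected* peaks
  only ((x − mean)/sd, sample sd), then sets undetected entries to 0.
  Including absent peaks as zeros before standardization would corrupt the
  per-sample mean and sd; setting them to 0 afterwards places them at the
  sample average, which is neutral for covariance-based analyses. Samples
  with fewer than two detected peaks or zero variance are refused by name.

# Multivariate and diversity statistics

* **Bray–Curtis** dissimilarity, $d(x,y)=\sum_i |x_i-y_i| / \sum_i (x_i+y_i)$,
  is computed on per-sample **relative intensities** (or relative OTU
  proportions), which are non-negative by construction. The z-scored matrix
  contains negative values, for which Bray–Curtis is undefined; it is used
  for PCA and the paired t-tests instead. This split resolves an ambiguity in
  the source procedure, which standardizes intensities but also speaks of
  relative abundances for the dissimilarity analysis.
* **NMDS** minimizes Kruskal stress-1 (monotone regression, majorization) via
  `vegan::metaMDS`/`monoMDS`, best of 20 seeded random starts, tolerance
  1e−6, at most 300 iterations; coordinates are centred. Non-convergence
  returns the best solution found, with a warning.
* **ANOSIM** uses mid-ranked dissimilarities,
  $R = (\bar r_B - \bar r_W) / (n(n-1)/4)$, with the permutation p-value
  computed under the +1 convention, $p = (1 + \#\{R^\ast \ge R\})/(1 + n_{perm})$,
  so p = 0 is impossible. A pairwise mode applies the same test per group
  pair. Ties receive mid-ranks.
* **Covariance PCA** (no variable scaling) with the sign of each component
  fixed so its largest-magnitude loading is positive; variables are screened
  by |loading| ≥ 0.05 (inclusive) on any of the first three components.
* **Evenness**: Buzas–Gibson $e^{H'}/S$, with $H'$ the Shannon index (natural
  log) over nonzero proportions and $S$ the number of nonzero taxa.
* **Paired differential test**: per feature, a two-sided paired Student's
  t-test between day-0 and final-day replicates (mesocosm 1 ↔ 1, 2 ↔ 2, …),
  df = n_pairs − 1, raw p < α (no multiplicity correction, matching the
  original analysis; Benjamini–Hochberg is available behind a flag).
  Zero-variance differences are flagged degenerate and excluded with a log
  message. Significant features are annotated with van Krevelen (O/C, H/C)
  coordinates when formulas are available.
* **Randomization null**: the same paired design applied to artificial
  samples with iid **Uniform(0, 1)** intensities. Under this null the paired
  t-test is exact, so the significant fraction concentrates at α — the
  control that shows an observed count of "changed" molecules is
  indistinguishable from random data. Uniform was chosen over lognormal
  deliberately: with n = 3 pairs the t-test is noticeably conservative under
  heavy-tailed differences, which would make the null control *under*-count
  and overstate any real signal. The test suite verifies the α-level
  behaviour over 100 seeds.

# Rates and budgets

Deterministic unit arithmetic, kept separate from reporting-time rounding:

* **Bacterial production**: thymidine incorporation (mol TdR L⁻¹ h⁻¹,
  blank-corrected upstream) × 2×10¹⁸ cells mol⁻¹ → cell production;
  × 25 fg C cell⁻¹ → carbon production. Negative incorporation (blank
  exceeding sample) is rejected, not clamped.
* **Bacterial respiration**: least-squares O₂ slope over the incubation,
  minus the slope of an ultrapure-water blank series, negated to a
  consumption rate and multiplied by a respiratory quotient of 0.88
  (mol CO₂ per mol O₂). Net O₂ production after blank correction is flagged
  and reported as zero respiration.
* **BGE** = BP/(BP + BR) (undefined and refused when both are zero);
  **BCD** = BP + BR.
* **DOC change**: per replicate, 100 × (DOC₀ − DOC_f)/DOC₀, summarized as
  treatment mean ± sd, compared across treatments by one-way ANOVA on the
  relative changes (absolute concentrations differ between treatments by
  design, so only relative changes are comparable). Endpoints only (day 0 vs
  final day), matching how the changes are reported.
* **Recovery rate**: 100 × (V_out·C_out)/(V_in·C_in), rounded only at the
  reporting layer.
* **Mixing model**: the terrigenous share of a mixture's DOC is the
  carbon-weighted mean of component tDOM fractions,
  $100 \cdot \sum v_i c_i f_i / \sum v_i c_i$ — convex, hence bounded by the
  endmember fractions (0.43 for mesohaline Baltic Sea water, 1.0 for river
  water).

# The synthetic-data generator

The generator emulates the statistical structure of the study — it is the
fixed set of conditions under which the pipeline's guarantees are tested,
not a tuning knob.

* **Design**: five treatments (cBS, RB, ULTRA, LYO, cRW) × 3 replicate
  mesocosms × days {0, 28}; per-treatment tDOM fractions 0.43, 0.81, 0.84,
  0.84, 1.00.
* **Chemistry**: two endmember formula pools (3000 each by default) drawn
  from CHNOSP space under the assignment rules, marine compositions centred
  at H/C 1.5 / O/C 0.35 and terrigenous at H/C 1.05 / O/C 0.55 (terrigenous
  DOM is more aromatic and more oxygenated), sharing a 40% common background
  so that ordination must separate treatments against a realistic shared
  signal. Pool masses are kept below 800 Da, reflecting that high-mass DOM
  ions are rarely observed.
* **Intensities**: per-formula lognormal base abundance; a sample's expected
  intensity weights each formula by its endmember affinity and the sample's
  tDOM fraction, with lognormal scatter (sdlog 0.4). Peaks falling below
  S/N 1 are not recorded, so presence varies realistically across replicates.
* **Mass axis**: a constant +0.3 ppm calibration drift (optionally
  mass-dependent) plus 0.01 ppm Gaussian error; 68 calibrant ions are
  injected at high intensity.
* **Noise**: 1500 irreproducible noise peaks per sample at uniform random
  masses, S/N uniform in [3, 5] — deliberately straddling the S/N cutoff so
  the presence filters, not the S/N filter, must remove them. Noise masses
  are rejection-sampled at least 3 ppm away from every true mass and every
  noise mass of other samples, so recurrence across replicates has
  probability zero by construction.
* **Time**: no temporal DOM trend by default (matching the study's finding);
  an optional "degrading subset" injects a known day-28 intensity loss for
  power analyses.
* **Communities**: OTU tables (300 OTUs, 3000 reads/sample) where mesohaline
  treatments *collapse* — one gammaproteobacterial OTU rises to ~50% of
  final-day reads and evenness drops — while the freshwater control stays
  diverse; multinomial sampling produces singletons naturally.
* **Rates**: O₂ drawdown series (slope −0.5 µmol L⁻¹ h⁻¹, noise sd 0.05,
  hourly over 12 h) plus a flat blank; thymidine incorporation
  2×10⁻¹¹ mol L⁻¹ h⁻¹ (10% CV), giving BP ≈ 1 µg C L⁻¹ h⁻¹ and BGE ≈ 0.16,
  inside the observed ranges; per-treatment day-0 DOC of 310–400 µmol C L⁻¹
  with relative losses of 6, 16, 7, 4 and 7% (±3, 6, 3, 1, 1) for cBS, RB,
  ULTRA, LYO, cRW.

What the generator does **not** emulate: isotopologue patterns, ionization
efficiency differences, chromatography or instrument physics, read-level 16S
error profiles, and intensity distributions of real DOM (unknown; lognormal
is an assumption exposed as configuration). Passing tests therefore
demonstrate the correctness and statistical calibration of the *pipeline*,
not instrument-level fidelity.

Determinism: every stochastic function takes an explicit seed, restores the
caller's RNG state, and reproduces byte-identical output under the same seed;
the pipeline driver writes per-stage in/out counts and seeds to a
line-delimited JSON run log.

# Numerical choices and degenerate inputs

* Monoisotopic element masses to 10⁻⁸ Da precision; proton mass 1.00727646 Da.
* Tolerances are relative (ppm) throughout; nothing is matched in absolute Da.
* Alignment tie-break: clusters split at the largest gap first is *not* used;
  the deterministic single-linkage gap rule needs no tie-break.
* Degenerate inputs fail loudly and by name: zero-variance samples in
  standardization, zero-sum columns in normalization, singleton groups in
  ANOSIM, both-zero rates in BGE, non-positive DOC baselines.
* Example problem sizes used by the test suite (chosen as desk-scale
  exercises of the same code paths): pools of 150–3000 formulas, 6–30
  samples, 100-seed null batteries, 500-replicate type-I simulations, and a
  100-mass enumeration-vs-oracle sweep.

# Known limitations

* Only [M−H]⁻ singly charged ions; no adducts, no isotope-pattern scoring.
* Blank subtraction is mass-based; formula-based matching is not offered.
* The NMDS stress scale follows `vegan::monoMDS` (0–1); other software
  reports percentages.
* The prevalence filter's strict ">" at the 80% boundary follows the stated
  rule; a sample count exactly at 80% presence is excluded.
* rmANOVA over production time series is out of scope (the inputs it needs
  are not part of the data model).
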