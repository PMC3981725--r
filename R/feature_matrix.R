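#' Signal-to-noise filter
#'
#' Keeps peaks whose signal-to-noise ratio is at least `k` (inclusive),
#' mirroring the acquisition rule of retaining peak intensities at least
#' three times the noise.
#'
#' @param peaks data.frame with a numeric `snr` column.
#' @param k S/N threshold (> 0, default 3).
#' @return filtered peak data.frame.
#' @export
sn_filter <- function(peaks, k = 3) {
  stopifnot(is.data.frame(peaks), k > 0)
  if (!"snr" %in% names(peaks))
    stop("peak list has no 'snr' column; cannot apply the S/N filter")
  peaks[peaks$snr >= k, , drop = FALSE]
}

#' Construct a feature table
#'
#' @param mass numeric vector of consensus neutral masses (one per feature).
#' @param intensity numeric matrix, features x samples, column names = sample
#'   ids.
#' @param meta data.frame with columns `sample_id`, `treatment`, `day`,
#'   `replicate` covering every intensity column.
#' @param formula optional data.frame of assigned formulas (rows align with
#'   features).
#' @return object of class `feature_table`.
#' @export
feature_table <- function(mass, intensity, meta, formula = NULL) {
  intensity <- as.matrix(intensity)
  stopifnot(length(mass) == nrow(intensity), !is.null(colnames(intensity)))
  need <- c("sample_id", "treatment", "day", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (!all(colnames(intensity) %in% meta$sample_id))
    stop("metadata does not cover sample column(s): ",
         paste(setdiff(colnames(intensity), meta$sample_id), collapse = ", "))
  if (any(intensity < 0)) stop("feature intensities must be non-negative")
  meta <- meta[match(colnames(intensity), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  ord <- order(mass)
  structure(list(mass = mass[ord], intensity = intensity[ord, , drop = FALSE],
                 meta = meta, formula = if (!is.null(formula)) formula[ord, , drop = FALSE]),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features x %d samples (%s)\n",
              nrow(x$intensity), ncol(x$intensity),
              paste(unique(x$meta$treatment), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensity)

#' Presence mask of a feature table
#'
#' Presence means a detected peak, i.e. nonzero intensity after the S/N
#' filter; no intensity threshold is applied here.
#'
#' @param ft a `feature_table`.
#' @return logical matrix, features x samples.
#' @export
presence_mask <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  ft$intensity > 0
}

#' Align per-sample peak lists into a feature table
#'
#' Neutral masses of all samples are pooled, sorted, and split by
#' single-linkage: a new feature starts wherever the gap to the previous
#' mass exceeds `align_tol_ppm`. The consensus mass of a feature is the
#' intensity-weighted mean of its member masses. If one sample contributes
#' several peaks to a feature the maximum intensity is used (counted in the
#' `n_multi` attribute).
#'
#' @param peaklists named list of calibrated peak data.frames (columns `mz`,
#'   `intensity`; names are sample ids).
#' @param meta sample metadata data.frame (`sample_id`, `treatment`, `day`,
#'   `replicate`).
#' @param align_tol_ppm gap-break tolerance in ppm (default 1).
#' @return a [feature_table()].
#' @export
align_masses <- function(peaklists, meta, align_tol_ppm = 1) {
  stopifnot(is.list(peaklists), length(peaklists) >= 1,
            !is.null(names(peaklists)), align_tol_ppm > 0)
  sample_ids <- names(peaklists)
  mass <- unlist(lapply(peaklists, function(p) neutral_mass_from_mz(p$mz)),
                 use.names = FALSE)
  intensity <- unlist(lapply(peaklists, function(p) p$intensity), use.names = FALSE)
  sample <- rep(sample_ids, vapply(peaklists, nrow, integer(1)))
  ord <- order(mass)
  mass <- mass[ord]; intensity <- intensity[ord]; sample <- sample[ord]
  if (length(mass) == 0) stop("no peaks to align")
  gap_ppm <- diff(mass) / mass[-length(mass)] * 1e6
  feat <- cumsum(c(1L, as.integer(gap_ppm > align_tol_ppm)))
  nfeat <- feat[length(feat)]
  consensus <- vapply(split(seq_along(mass), feat), function(ix)
    stats::weighted.mean(mass[ix], pmax(intensity[ix], .Machine$double.eps)),
    numeric(1))
  mat <- matrix(0, nfeat, length(sample_ids),
                dimnames = list(NULL, sample_ids))
  n_multi <- 0L
  idx <- cbind(feat, match(sample, sample_ids))
  dup <- duplicated(idx)
  if (any(dup)) {
    n_multi <- sum(dup)
    ## keep per (feature, sample) the maximum intensity
    key <- paste(idx[, 1], idx[, 2])
    intensity <- stats::ave(intensity, key, FUN = max)
  }
  mat[idx[!dup, , drop = FALSE]] <- intensity[!dup]
  ft <- feature_table(unname(consensus), mat, meta)
  attr(ft, "n_multi") <- n_multi
  ft
}

#' Remove features present in a process blank
#'
#' Features whose consensus mass lies within `tol_ppm` of any blank feature
#' mass are removed entirely from the table.
#'
#' @param ft a `feature_table`.
#' @param blank_mass numeric vector of blank feature neutral masses (or a
#'   `feature_table` whose masses are used).
#' @param tol_ppm match tolerance in ppm (default 1).
#' @return filtered `feature_table`; warns when nothing survives.
#' @export
subtract_blank <- function(ft, blank_mass, tol_ppm = 1) {
  stopifnot(inherits(ft, "feature_table"))
  if (inherits(blank_mass, "feature_table")) blank_mass <- blank_mass$mass
  if (length(blank_mass) == 0) return(ft)
  hit <- vapply(ft$mass, function(m)
    any(abs(blank_mass - m) / m * 1e6 <= tol_ppm), logical(1))
  if (all(hit)) warning("blank subtraction removed every feature")
  .subset_features(ft, !hit)
}

.subset_features <- function(ft, keep) {
  structure(list(mass = ft$mass[keep],
                 intensity = ft$intensity[keep, , drop = FALSE],
                 meta = ft$meta,
                 formula = if (!is.null(ft$formula)) ft$formula[keep, , drop = FALSE]),
            class = "feature_table")
}

#' Triplicate presence filter
#'
#' Within every treatment x day group, a feature's presence is retained only
#' when it is detected in all replicates of that group; masses detected in
#' only one or two of the parallel mesocosms are treated as irreproducible
#' noise and zeroed in that group. A feature survives globally if it
#' survives in at least one group.
#'
#' @param ft a `feature_table`.
#' @return filtered `feature_table` with failing groups zeroed. Groups with
#'   other than 3 replicates still require presence in all of their
#'   replicates (all-of-n), with a message.
#' @export
triplicate_presence_filter <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  grp <- interaction(ft$meta$treatment, ft$meta$day, drop = TRUE)
  sizes <- table(grp)
  if (any(sizes != 3))
    message("group(s) with != 3 replicates (", paste(names(sizes)[sizes != 3], collapse = ", "),
            "): requiring presence in all replicates of each group")
  pres <- presence_mask(ft)
  intensity <- ft$intensity
  keep_any <- rep(FALSE, nrow(intensity))
  for (g in levels(grp)) {
    cols <- which(grp == g)
    all_present <- rowSums(pres[, cols, drop = FALSE]) == length(cols)
    intensity[!all_present, cols] <- 0
    keep_any <- keep_any | all_present
  }
  ft$intensity <- intensity
  .subset_features(ft, keep_any)
}

#' Prevalence filter
#'
#' Keeps features present in strictly more than `threshold` of the samples
#' (the study's alternative, more restrictive noise-reduction rule with
#' threshold 0.8, i.e. presence in >80% of samples).
#'
#' @param ft a `feature_table`.
#' @param threshold presence fraction in (0, 1); strict inequality.
#' @return filtered `feature_table`.
#' @export
prevalence_filter <- function(ft, threshold = 0.8) {
  stopifnot(inherits(ft, "feature_table"), threshold > 0, threshold < 1)
  frac <- rowMeans(presence_mask(ft))
  .subset_features(ft, frac > threshold)
}

#' Per-sample standardization (z-scoring) of detected intensities
#'
#' Within every sample column, detected (nonzero) intensities are replaced
#' by (x - mean)/sd, where mean and sd (n-1 denominator) are computed over
#' the detected peaks of that sample only; undetected entries are set to 0
#' after standardization. The output contains both negative and positive
#' values.
#'
#' @param ft a `feature_table`.
#' @return numeric matrix, features x samples, of z-scores.
#' @export
standardize_within_sample <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  pres <- presence_mask(ft)
  out <- matrix(0, nrow(ft$intensity), ncol(ft$intensity),
                dimnames = dimnames(ft$intensity))
  for (j in seq_len(ncol(out))) {
    x <- ft$intensity[pres[, j], j]
    if (length(x) < 2)
      stop("sample ", colnames(out)[j], " has fewer than 2 detected peaks")
    s <- stats::sd(x)
    if (s == 0)
      stop("sample ", colnames(out)[j], " has zero intensity variance; cannot standardize")
    out[pres[, j], j] <- (x - mean(x)) / s
  }
  out
}

#' Per-sample relative intensities
#'
#' Each sample column is divided by its total detected intensity, giving
#' non-negative values that sum to 1 per sample — the input convention for
#' Bray-Curtis dissimilarity.
#'
#' @param ft a `feature_table` (or non-negative matrix).
#' @return matrix of per-sample proportions.
#' @export
relative_intensity <- function(ft) {
  m <- if (inherits(ft, "feature_table")) ft$intensity else as.matrix(ft)
  relative_abundance(m)
}
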