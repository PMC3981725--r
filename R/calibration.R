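#' Read a calibrant list
#'
#' Two-column TSV with header `label`, `neutral_mass_da`. Masses must be
#' positive and unique; the list is returned sorted by mass.
#'
#' @param path file path.
#' @return data.frame with columns `label`, `neutral_mass_da`, `ion_mz`
#'   (the [M-H]- ion m/z at which the calibrant is observed).
#' @export
read_calibrants <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "neutral_mass_da")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("calibrant list missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(x$neutral_mass_da) || any(!is.finite(x$neutral_mass_da)) ||
      any(x$neutral_mass_da <= 0))
    stop("calibrant masses must be positive finite numbers")
  if (anyDuplicated(x$neutral_mass_da)) stop("calibrant masses must be unique")
  x <- x[order(x$neutral_mass_da), , drop = FALSE]
  x$ion_mz <- mz_from_neutral_mass(x$neutral_mass_da)
  rownames(x) <- NULL
  x
}

#' Bundled synthetic calibrant database
#'
#' Returns the 68-entry synthetic CHO calibrant list shipped with the
#' package (a stand-in for an instrument lab's in-house calibration
#' database; masses are exact monoisotopic formula masses).
#'
#' @return data.frame as from [read_calibrants()].
#' @export
default_calibrants <- function() {
  read_calibrants(system.file("extdata", "calibrants_synthetic.tsv",
                              package = "fticrdom", mustWork = TRUE))
}

#' Match peaks to calibrant masses
#'
#' Each calibrant is matched to the nearest peak (in signed ppm at the
#' [M-H]- ion m/z) within `search_tol_ppm`; ties on |ppm| are broken by
#' higher peak intensity. Each calibrant matches at most one peak.
#'
#' @param peaks data.frame with columns `mz` and (optionally) `intensity`.
#' @param calibrants data.frame from [read_calibrants()].
#' @param search_tol_ppm match window in ppm (default 1).
#' @return data.frame with one row per matched calibrant: `label`,
#'   `calibrant_mz`, `peak_mz`, `intensity`, `ppm_error` (signed,
#'   peak relative to calibrant). Unmatched calibrants are reported in the
#'   `unmatched` attribute.
#' @export
match_calibrants <- function(peaks, calibrants, search_tol_ppm = 1) {
  stopifnot(is.data.frame(peaks), "mz" %in% names(peaks), search_tol_ppm > 0)
  intens <- if ("intensity" %in% names(peaks)) peaks$intensity else rep(0, nrow(peaks))
  rows <- lapply(seq_len(nrow(calibrants)), function(i) {
    cm <- calibrants$ion_mz[i]
    ppm <- (peaks$mz - cm) / cm * 1e6
    ok <- which(abs(ppm) <= search_tol_ppm)
    if (!length(ok)) return(NULL)
    ## nearest |ppm|, ties broken by intensity (descending)
    ok <- ok[order(abs(ppm[ok]), -intens[ok])]
    j <- ok[1]
    data.frame(label = calibrants$label[i], calibrant_mz = cm,
               peak_mz = peaks$mz[j], intensity = intens[j],
               ppm_error = ppm[j], stringsAsFactors = FALSE)
  })
  matched <- do.call(rbind, rows)
  if (is.null(matched))
    matched <- data.frame(label = character(), calibrant_mz = numeric(),
                          peak_mz = numeric(), intensity = numeric(),
                          ppm_error = numeric(), stringsAsFactors = FALSE)
  attr(matched, "unmatched") <- setdiff(calibrants$label, matched$label)
  matched
}

#' Fit an internal calibration model
#'
#' Least-squares fit of the signed ppm mass error as an affine function of
#' m/z over matched calibrants. When all matched m/z coincide the model
#' degenerates to a constant offset (slope 0), with a warning.
#'
#' @param matches data.frame from [match_calibrants()]; at least 2 rows.
#' @return object of class `calibration_model`: list with `intercept`,
#'   `slope` (ppm per Da), `residual_ppm` (per matched calibrant, after the
#'   fit), `n_matched`, and the `matches` used.
#' @export
fit_calibration <- function(matches) {
  if (nrow(matches) < 2)
    stop("calibration refused: need at least 2 matched calibrants, got ",
         nrow(matches))
  if (length(unique(matches$peak_mz)) < 2) {
    warning("all matched calibrants share one m/z; falling back to constant-offset model")
    intercept <- mean(matches$ppm_error); slope <- 0
  } else {
    fit <- stats::lm(ppm_error ~ peak_mz, data = matches)
    intercept <- unname(stats::coef(fit)[1]); slope <- unname(stats::coef(fit)[2])
  }
  pred <- intercept + slope * matches$peak_mz
  structure(list(intercept = intercept, slope = slope,
                 residual_ppm = matches$ppm_error - pred,
                 n_matched = nrow(matches), matches = matches),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Internal calibration: ppm error = %.5f + %.2e * m/z (%d calibrants)\n",
              x$intercept, x$slope, x$n_matched))
  cat(sprintf("  residual ppm: rms %.5f, max |.| %.5f\n",
              sqrt(mean(x$residual_ppm^2)), max(abs(x$residual_ppm))))
  invisible(x)
}

#' Apply a calibration model to a peak list
#'
#' Every m/z is corrected by its predicted ppm error:
#' mz_corrected = mz * (1 - predicted_ppm * 1e-6). Refitting on corrected
#' data yields a near-zero model, so the correction is idempotent to first
#' order in ppm.
#'
#' @param peaks data.frame with an `mz` column.
#' @param model a `calibration_model`.
#' @return `peaks` with corrected `mz` and the raw values in `mz_raw`.
#' @export
apply_calibration <- function(peaks, model) {
  stopifnot(inherits(model, "calibration_model"), "mz" %in% names(peaks))
  pred_ppm <- model$intercept + model$slope * peaks$mz
  out <- peaks
  out$mz_raw <- peaks$mz
  out$mz <- peaks$mz * (1 - pred_ppm * 1e-6)
  out
}

#' Internally calibrate a peak list against a calibrant database
#'
#' Convenience wrapper: match, fit, apply, then re-match on the corrected
#' list to report post-calibration residuals.
#'
#' @inheritParams match_calibrants
#' @return list with `peaks` (corrected), `model`, and `post_residual_ppm`
#'   (signed ppm error of each calibrant re-matched after correction).
#' @export
calibrate_peaklist <- function(peaks, calibrants = default_calibrants(),
                               search_tol_ppm = 1) {
  matches <- match_calibrants(peaks, calibrants, search_tol_ppm)
  model <- fit_calibration(matches)
  corrected <- apply_calibration(peaks, model)
  post <- match_calibrants(corrected, calibrants, search_tol_ppm)
  list(peaks = corrected, model = model, post_residual_ppm = post$ppm_error)
}

#' Write a calibration report as JSON
#'
#' @param model a `calibration_model`.
#' @param path output path.
#' @export
write_calibration_report <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  rep <- list(intercept_ppm = model$intercept, slope_ppm_per_da = model$slope,
              n_matched = model$n_matched,
              calibrants = data.frame(label = model$matches$label,
                                      ppm_error = model$matches$ppm_error,
                                      residual_ppm = model$residual_ppm))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
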