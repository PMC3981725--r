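## Schema validation helper: locate problems by row/column, never coerce.
.check_columns <- function(x, need, what, path) {
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(what, " '", path, "' missing column(s): ", paste(miss, collapse = ", "))
}

.check_numeric <- function(x, cols, what, path) {
  for (cl in cols) {
    v <- x[[cl]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop(what, " '", path, "': non-numeric value in column '", cl,
           "' at row ", if (is.na(bad)) "?" else bad)
    }
    if (anyNA(v))
      stop(what, " '", path, "': missing value in column '", cl,
           "' at row ", which(is.na(v))[1])
  }
}

#' Read / write peak lists
#'
#' CSV with columns `sample_id`, `mz`, `intensity`, `snr`. `read_peaklist`
#' returns a named list of per-sample data.frames (columns mz, intensity,
#' snr); `write_peaklist` accepts such a list. Round-trips are numerically
#' exact (values serialized at full double precision).
#'
#' @param path file path.
#' @return named list of peak data.frames.
#' @export
read_peaklist <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_columns(x, c("sample_id", "mz", "intensity", "snr"), "peak list", path)
  .check_numeric(x, c("mz", "intensity", "snr"), "peak list", path)
  lapply(split(x[c("mz", "intensity", "snr")], x$sample_id),
         function(d) { rownames(d) <- NULL; d })
}

#' @rdname read_peaklist
#' @param peaklists named list of data.frames with columns mz, intensity, snr.
#' @export
write_peaklist <- function(peaklists, path) {
  stopifnot(is.list(peaklists), !is.null(names(peaklists)))
  rows <- lapply(names(peaklists), function(id) {
    p <- peaklists[[id]]
    data.frame(sample_id = id, mz = p$mz, intensity = p$intensity, snr = p$snr)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write sample metadata
#'
#' TSV with columns `sample_id`, `treatment`, `day`, `replicate`; sample ids
#' must be unique.
#'
#' @param path file path.
#' @return metadata data.frame.
#' @export
read_metadata <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check_columns(x, c("sample_id", "treatment", "day", "replicate"), "metadata", path)
  dup <- x$sample_id[duplicated(x$sample_id)]
  if (length(dup))
    stop("metadata '", path, "': duplicated sample id(s): ",
         paste(unique(dup), collapse = ", "))
  .check_numeric(x, c("day", "replicate"), "metadata", path)
  x
}

#' @rdname read_metadata
#' @param meta metadata data.frame.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write feature tables
#'
#' TSV matrix: first column `mass_da` (consensus neutral mass), remaining
#' columns one per sample id. Metadata travels in a separate TSV (see
#' [read_metadata()]).
#'
#' @param path feature-table TSV path.
#' @param meta metadata data.frame (or path to a metadata TSV).
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, meta) {
  if (is.character(meta)) meta <- read_metadata(meta)
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .check_columns(x, "mass_da", "feature table", path)
  .check_numeric(x, names(x), "feature table", path)
  dup <- x$mass_da[duplicated(x$mass_da)]
  if (length(dup))
    stop("feature table '", path, "': duplicated feature mass(es): ",
         paste(utils::head(unique(dup), 3), collapse = ", "))
  m <- as.matrix(x[setdiff(names(x), "mass_da")])
  feature_table(x$mass_da, m, meta)
}

#' @rdname read_feature_table
#' @param ft a `feature_table`.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.frame(mass_da = ft$mass, ft$intensity, check.names = FALSE)
  utils::write.table(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write OTU tables
#'
#' TSV matrix: first column `otu_id` (unique), optional `taxonomy` column,
#' remaining columns integer counts per sample.
#'
#' @param path file path.
#' @return list with `counts` (integer matrix, OTU x sample) and `taxonomy`
#'   (character vector or NULL).
#' @export
read_otu_table <- function(path) {
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  .check_columns(x, "otu_id", "OTU table", path)
  dup <- x$otu_id[duplicated(x$otu_id)]
  if (length(dup))
    stop("OTU table '", path, "': duplicated OTU id(s): ",
         paste(unique(dup), collapse = ", "))
  tax <- x$taxonomy
  cnt_cols <- setdiff(names(x), c("otu_id", "taxonomy"))
  .check_numeric(x, cnt_cols, "OTU table", path)
  m <- as.matrix(x[cnt_cols])
  if (any(m != round(m))) stop("OTU table '", path, "': non-integer counts")
  storage.mode(m) <- "integer"
  rownames(m) <- x$otu_id
  list(counts = m, taxonomy = tax)
}

#' @rdname read_otu_table
#' @param counts OTU x sample integer matrix with rownames.
#' @param taxonomy optional character vector per OTU.
#' @export
write_otu_table <- function(counts, path, taxonomy = NULL) {
  df <- data.frame(otu_id = rownames(counts), check.names = FALSE)
  if (!is.null(taxonomy)) df$taxonomy <- taxonomy
  df <- cbind(df, as.data.frame(counts, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Structured run log
#'
#' Collects per-stage bookkeeping (counts in/out of every filter, seeds,
#' parameters) and writes it as line-delimited JSON so pipelines can report
#' the "n masses / n formulas per sample" style accounting.
#'
#' @return an environment with `add(stage, ...)`, `records()` and
#'   `write(path)` functions.
#' @export
run_log <- function() {
  .recs <- list()
  add <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    .recs[[length(.recs) + 1]] <<- rec
    invisible(rec)
  }
  records <- function() .recs
  write <- function(path) {
    con <- file(path, "w"); on.exit(close(con))
    for (r in .recs)
      writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA), con)
    invisible(path)
  }
  environment()
}

#' Run the full synthetic pipeline
#'
#' Chains the complete analysis on synthetic data: simulate ->
#' calibrate -> assign -> feature matrix (S/N filter, alignment, presence
#' filter, standardization) -> multivariate statistics (Bray-Curtis, NMDS,
#' ANOSIM, paired day-0 vs final-day t-test with randomization null) ->
#' rate/budget arithmetic. Deterministic given `design` (which carries the
#' seed); all artifacts are written to `out_dir` as TSV/JSON.
#'
#' @param design a [sim_design()].
#' @param out_dir output directory (created if needed); NULL to skip writing.
#' @param filter_mode "triplicate" (presence in all replicates of a group)
#'   or "prevalence" (presence in > `prevalence_threshold` of all samples).
#' @param prevalence_threshold see [prevalence_filter()].
#' @param assign_tol_ppm formula-assignment tolerance (ppm).
#' @param align_tol_ppm mass-alignment tolerance (ppm).
#' @param n_perm ANOSIM permutations.
#' @param verbose print stage progress.
#' @return list with `experiment`, `calibration`, `assignment_summary`,
#'   `features` (filtered `feature_table`), `zscores`, `nmds`, `anosim`,
#'   `ttest`, `null_comparison`, `rates`, `log` (records list).
#' @export
run_pipeline <- function(design = sim_design(), out_dir = NULL,
                         filter_mode = c("triplicate", "prevalence"),
                         prevalence_threshold = 0.8,
                         assign_tol_ppm = 0.5, align_tol_ppm = 1,
                         n_perm = 999, verbose = FALSE) {
  filter_mode <- match.arg(filter_mode)
  log <- run_log()
  say <- function(...) if (verbose) message(...)
  log$add("config", seed = design$seed, filter_mode = filter_mode,
          assign_tol_ppm = assign_tol_ppm, align_tol_ppm = align_tol_ppm,
          n_perm = n_perm)

  say("simulating experiment")
  ex <- simulate_experiment(design)
  log$add("simulate", n_samples = length(ex$peaklists),
          pool_size = nrow(ex$pool), seed = design$seed)

  say("calibrating peak lists")
  calibrated <- list(); cal_models <- list()
  for (id in names(ex$peaklists)) {
    filt <- sn_filter(ex$peaklists[[id]], 3)
    log$add("sn_filter", sample = id, n_before = nrow(ex$peaklists[[id]]),
            n_after = nrow(filt))
    cal <- calibrate_peaklist(filt, ex$calibrants)
    calibrated[[id]] <- cal$peaks
    cal_models[[id]] <- cal$model
    log$add("calibrate", sample = id, n_matched = cal$model$n_matched,
            max_abs_residual_ppm = max(abs(cal$post_residual_ppm)))
  }

  say("assigning formulas")
  rules <- assignment_rules(tol_ppm = assign_tol_ppm)
  assignment_summary <- lapply(calibrated, function(p) {
    a <- assign_peaklist(p, rules); a$summary
  })
  for (id in names(assignment_summary))
    log$add("assign", sample = id, n_peaks = assignment_summary[[id]]$n_peaks,
            n_unique = assignment_summary[[id]]$n_unique,
            n_ambiguous = assignment_summary[[id]]$n_ambiguous,
            n_unassigned = assignment_summary[[id]]$n_unassigned)

  say("building feature matrix")
  ft <- align_masses(calibrated, ex$meta, align_tol_ppm)
  n0 <- nrow(ft$intensity)
  ft <- switch(filter_mode,
               triplicate = triplicate_presence_filter(ft),
               prevalence = prevalence_filter(ft, prevalence_threshold))
  log$add("presence_filter", mode = filter_mode, n_before = n0,
          n_after = nrow(ft$intensity))
  z <- standardize_within_sample(ft)

  say("multivariate statistics")
  rel <- relative_intensity(ft)
  d <- bray_curtis(rel)
  ord <- nmds(d, k = 2, seed = design$seed)
  an <- anosim_test(d, ft$meta$treatment, n_perm = n_perm, seed = design$seed)
  days <- sort(unique(ft$meta$day))
  tt <- nullcmp <- NULL
  if (length(days) >= 2) {
    sel0 <- ft$meta$day == days[1]
    sel1 <- ft$meta$day == days[length(days)]
    m0 <- z[, sel0, drop = FALSE][, order(ft$meta$treatment[sel0], ft$meta$replicate[sel0])]
    m1 <- z[, sel1, drop = FALSE][, order(ft$meta$treatment[sel1], ft$meta$replicate[sel1])]
    tt <- paired_feature_ttest(m0, m1)
    nullcmp <- random_null_comparison(n_features = nrow(z), n_samples = 6,
                                      seed = design$seed)
    log$add("paired_ttest", n_features = nrow(tt),
            n_significant = sum(tt$significant),
            null_n_significant = nullcmp$n_significant)
  }

  say("rates and budgets")
  ri <- simulate_rate_inputs(treatments = design$treatments,
                             replicates = design$replicates,
                             seed = design$seed + 9000L)
  bp <- bp_from_thymidine(mean(ri$thymidine$incorporation))
  br <- br_from_oxygen(ri$oxygen[[1]], ri$oxygen_blank)
  bp_umol_c <- bp$ug_c_per_l_h / 12.011       # ug C -> umol C
  rates <- list(bp = bp, br = br,
                bge = bge(bp_umol_c, br$br_umol_c_per_l_h),
                bcd_umol_c_per_l_h = bcd(bp_umol_c, br$br_umol_c_per_l_h),
                doc = doc_percent_change(ri$doc))
  log$add("rates", bge = rates$bge, doc_anova_p = rates$doc$anova$p)

  res <- list(experiment = ex, calibration = cal_models,
              assignment_summary = assignment_summary,
              features = ft, zscores = z, nmds = ord, anosim = an,
              ttest = tt, null_comparison = nullcmp, rates = rates,
              log = log$records())

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_table(ft, file.path(out_dir, "feature_table.tsv"))
    write_metadata(ft$meta, file.path(out_dir, "metadata.tsv"))
    coords <- data.frame(sample_id = ft$meta$sample_id, ord$points)
    utils::write.table(coords, file.path(out_dir, "nmds_coordinates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(R = an$R, p = an$p, n_permutations = an$n_permutations),
                         file.path(out_dir, "anosim.json"), auto_unbox = TRUE,
                         digits = NA)
    if (!is.null(tt))
      utils::write.table(tt, file.path(out_dir, "paired_ttest.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(bge = rates$bge,
                              bcd_umol_c_per_l_h = rates$bcd_umol_c_per_l_h,
                              doc_summary = rates$doc$summary,
                              doc_anova = rates$doc$anova),
                         file.path(out_dir, "budgets.json"), auto_unbox = TRUE,
                         digits = NA)
    log$write(file.path(out_dir, "run_log.ndjson"))
  }
  res
}
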