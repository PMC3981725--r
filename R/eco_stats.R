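#' Relative abundances per sample
#'
#' Converts a counts (or intensity) matrix with samples in columns to
#' per-sample proportions; every column sums to 1.
#'
#' @param mat non-negative matrix, rows = taxa/features, columns = samples.
#' @return matrix of proportions.
#' @export
relative_abundance <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("counts/intensities must be non-negative")
  tot <- colSums(mat)
  if (any(tot == 0))
    stop("zero-sum sample column(s): ",
         paste(colnames(mat)[tot == 0], collapse = ", "))
  sweep(mat, 2, tot, "/")
}

#' Remove singleton reads from an OTU table
#'
#' Sequencer reads present only once per library are treated as background
#' noise: cells equal to 1 are set to 0 per library (sample), and OTUs whose
#' rows become all-zero are dropped.
#'
#' @param otu integer count matrix, OTUs x samples.
#' @return filtered count matrix.
#' @export
remove_singletons <- function(otu) {
  otu <- as.matrix(otu)
  if (any(otu != round(otu))) stop("OTU table must contain integer counts")
  otu[otu == 1] <- 0
  otu[rowSums(otu) > 0, , drop = FALSE]
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i) between non-negative
#' composition vectors (relative abundances or relative intensities).
#' Computed via [vegan::vegdist()].
#'
#' @param mat non-negative matrix with samples in columns.
#' @return object of class `dist` over the sample columns, values in [0, 1].
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat < 0))
    stop("Bray-Curtis is undefined for negative values; use relative ",
         "abundances/intensities (e.g. relative_intensity()), not z-scores")
  vegan::vegdist(t(mat), method = "bray")
}

#' Nonmetric multidimensional scaling
#'
#' Kruskal stress-1 NMDS of a dissimilarity matrix via [vegan::metaMDS()]
#' (monoMDS engine, no transformation), best of `n_restarts` random starts
#' under a fixed seed; coordinates are centered.
#'
#' @param d a `dist` object (n >= 4 samples).
#' @param k number of dimensions (default 2).
#' @param n_restarts random starts (default 20).
#' @param max_iter maximum iterations per start (default 300).
#' @param tol convergence tolerance (default 1e-6).
#' @param seed RNG seed for restarts (default 1).
#' @return list of class `nmds_result`: `points` (n x k, centered), `stress`
#'   (Kruskal stress-1, 0-1 scale), `k`, `n_restarts`, `seed`, `converged`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, max_iter = 300, tol = 1e-6, seed = 1) {
  stopifnot(inherits(d, "dist"), attr(d, "Size") >= 4, k >= 1)
  .local_seed(seed)
  fit <- suppressWarnings(suppressMessages(
    vegan::metaMDS(d, k = k, try = n_restarts, trymax = n_restarts,
                   maxit = max_iter, sfgrmin = tol, trace = 0,
                   autotransform = FALSE, wascores = FALSE)
  ))
  if (!isTRUE(fit$converged))
    warning("NMDS did not converge in ", n_restarts, " restarts; returning best solution found")
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  structure(list(points = pts, stress = fit$stress, k = k,
                 n_restarts = n_restarts, seed = seed,
                 converged = isTRUE(fit$converged)),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS: %d samples in %d dimensions, stress %.4f (%d restarts)\n",
              nrow(x$points), x$k, x$stress, x$n_restarts))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group separation on a dissimilarity
#' matrix: R = (mean between-group rank - mean within-group rank) /
#' (n(n-1)/4), with permutation p = (1 + #{perm R >= observed}) /
#' (1 + n_perm). Backed by [vegan::anosim()]; the pairwise mode applies the
#' same test to every pair of groups on the corresponding submatrix.
#'
#' @param d a `dist` object.
#' @param groups factor (or vector) of group labels, one per sample; every
#'   group must have >= 2 members.
#' @param n_perm number of permutations (>= 99, default 999).
#' @param seed RNG seed (default 1).
#' @param pairwise also compute per-pair R and p (default FALSE).
#' @return list of class `anosim_result`: `R`, `p`, `n_permutations`,
#'   `seed`, and optionally `pairwise` (data.frame group1, group2, R, p).
#' @export
anosim_test <- function(d, groups, n_perm = 999, seed = 1, pairwise = FALSE) {
  stopifnot(inherits(d, "dist"), n_perm >= 99)
  groups <- factor(groups)
  if (length(groups) != attr(d, "Size"))
    stop("groups length must match the distance matrix")
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2))
    stop("every group needs >= 2 members; singleton group(s): ",
         paste(names(which(table(groups) < 2)), collapse = ", "))
  .local_seed(seed)
  fit <- vegan::anosim(d, groups, permutations = n_perm)
  out <- list(R = unname(fit$statistic), p = unname(fit$signif),
              n_permutations = n_perm, seed = seed)
  if (pairwise) {
    lev <- levels(groups)
    m <- as.matrix(d)
    pairs <- utils::combn(lev, 2)
    out$pairwise <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
      sel <- groups %in% pairs[, i]
      sub <- stats::as.dist(m[sel, sel])
      fit_i <- vegan::anosim(sub, droplevels(groups[sel]), permutations = n_perm)
      data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
                 R = unname(fit_i$statistic), p = unname(fit_i$signif),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(out, class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations)\n",
              x$R, x$p, x$n_permutations))
  if (!is.null(x$pairwise)) {
    cat("pairwise:\n"); print(x$pairwise)
  }
  invisible(x)
}

#' Covariance-matrix principal component analysis
#'
#' Eigendecomposition of the sample variance-covariance matrix (samples are
#' observations, features/OTUs are variables; no scaling). The sign of each
#' component is fixed so that its largest-magnitude loading is positive.
#'
#' @param mat matrix with samples in columns (variables in rows).
#' @return list of class `pca_result`: `scores` (samples x components),
#'   `loadings` (variables x components), `eigenvalues`,
#'   `percent_variance`.
#' @export
pca_covariance <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 samples")
  x <- t(mat)                                 # samples as rows
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  ev <- pc$sdev^2
  structure(list(scores = scores, loadings = rot, eigenvalues = ev,
                 percent_variance = 100 * ev / sum(ev)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(3, length(x$percent_variance))
  cat("Covariance PCA:",
      paste(sprintf("PC%d %.1f%%", seq_len(k), x$percent_variance[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Select variables by PCA loading magnitude
#'
#' Variables whose absolute loading reaches `threshold` on any of the first
#' `n_components` components are reported — the +/-0.05 loading screen used
#' to find OTUs driving community variation.
#'
#' @param pca a `pca_result`.
#' @param threshold absolute loading cutoff, inclusive (default 0.05).
#' @param n_components number of leading components to screen (default 3).
#' @return list with `selected` (variable names/indices) and `by_component`
#'   (list per component).
#' @export
select_loadings <- function(pca, threshold = 0.05, n_components = 3) {
  stopifnot(inherits(pca, "pca_result"))
  k <- min(n_components, ncol(pca$loadings))
  vars <- rownames(pca$loadings)
  if (is.null(vars)) vars <- seq_len(nrow(pca$loadings))
  by_comp <- lapply(seq_len(k), function(j)
    vars[abs(pca$loadings[, j]) >= threshold])
  names(by_comp) <- colnames(pca$loadings)[seq_len(k)]
  list(selected = unique(unlist(by_comp)), by_component = by_comp)
}

#' Shannon index and Buzas-Gibson evenness
#'
#' H' = -sum(p_i ln p_i) over taxa with nonzero proportion; evenness =
#' exp(H')/S with S the number of nonzero taxa. Evenness lies in (0, 1] and
#' equals 1 for a perfectly even (or single-taxon) community.
#'
#' @param proportions non-negative vector of relative abundances (rescaled
#'   to sum to 1 if needed), or a matrix with samples in columns.
#' @return for a vector, list with `shannon` and `evenness`; for a matrix, a
#'   data.frame with one row per sample.
#' @export
shannon_evenness <- function(proportions) {
  if (is.matrix(proportions) || is.data.frame(proportions)) {
    res <- apply(as.matrix(proportions), 2, function(p) {
      r <- shannon_evenness(p); c(r$shannon, r$evenness)
    })
    return(data.frame(sample_id = colnames(proportions),
                      shannon = res[1, ], evenness = res[2, ],
                      row.names = NULL))
  }
  p <- proportions[proportions > 0]
  if (length(p) == 0) stop("empty community: no nonzero proportions")
  p <- p / sum(p)
  H <- unname(vegan::diversity(p, index = "shannon"))
  list(shannon = H, evenness = exp(H) / length(p))
}

#' Paired per-feature t-test between two time points
#'
#' For every feature a two-sided paired Student's t-test on the replicate
#' pairs (mesocosm 1 vs 1, 2 vs 2, ...) with df = n_pairs - 1. Raw p-values
#' are used by default (no multiplicity correction); Benjamini-Hochberg
#' adjustment is available behind `adjust`. Features with zero-variance
#' differences are flagged degenerate and excluded from the significant set.
#'
#' @param x0,x1 numeric matrices features x replicates for the two time
#'   points, columns paired by position.
#' @param alpha significance level (default 0.05).
#' @param adjust "none" (default, matching raw-p practice) or "BH".
#' @param formulas optional data.frame of feature formulas; when given, van
#'   Krevelen coordinates (oc, hc) are annotated on the result.
#' @return data.frame per feature: `mean_diff`, `t`, `df`, `p`,
#'   `significant`, `degenerate`, plus `oc`/`hc` when formulas are supplied.
#' @export
paired_feature_ttest <- function(x0, x1, alpha = 0.05, adjust = c("none", "BH"),
                                 formulas = NULL) {
  adjust <- match.arg(adjust)
  x0 <- as.matrix(x0); x1 <- as.matrix(x1)
  if (!all(dim(x0) == dim(x1)))
    stop("time-point matrices must have identical dimensions (columns paired by replicate)")
  n <- ncol(x0)
  if (n < 2) stop("need at least 2 replicate pairs")
  d <- x1 - x0
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  degenerate <- s == 0
  tstat <- ifelse(degenerate, NA_real_, m / (s / sqrt(n)))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  p_use <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  out <- data.frame(mean_diff = m, t = tstat, df = n - 1, p = p,
                    significant = !degenerate & !is.na(p_use) & p_use < alpha,
                    degenerate = degenerate)
  if (any(degenerate))
    message(sum(degenerate), " feature(s) with zero-variance differences excluded as degenerate")
  if (!is.null(formulas)) out <- cbind(out, van_krevelen_coords(formulas))
  out
}

#' Significant-feature count under a randomization null
#'
#' Reproduces the random-data control of the differential analysis: `n_samples`
#' artificial samples are generated with iid Uniform(0, 1) intensities for
#' `n_features` features, the first half is tested (paired t) against the
#' second half, and the number of features significant at `alpha` is
#' returned. Under this true null the significant fraction concentrates
#' near `alpha`.
#'
#' @param n_features number of features (default 4000).
#' @param n_samples total artificial samples, even (default 6: 3 paired vs 3).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed.
#' @return list with `n_significant`, `fraction`, `n_features`, `alpha`,
#'   `seed`.
#' @export
random_null_comparison <- function(n_features = 4000, n_samples = 6,
                                   alpha = 0.05, seed = 1) {
  stopifnot(n_samples >= 4, n_samples %% 2 == 0)
  .local_seed(seed)
  x <- matrix(stats::runif(n_features * n_samples), n_features, n_samples)
  half <- n_samples / 2
  res <- paired_feature_ttest(x[, seq_len(half), drop = FALSE],
                              x[, half + seq_len(half), drop = FALSE],
                              alpha = alpha)
  list(n_significant = sum(res$significant),
       fraction = mean(res$significant),
       n_features = n_features, alpha = alpha, seed = seed)
}
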