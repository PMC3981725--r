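test_that("relative abundance normalizes columns to 1 and rejects zero columns", {
  m <- matrix(c(2, 2, 0, 5), 2, 2, dimnames = list(NULL, c("a", "b")))
  r <- relative_abundance(m)
  expect_equal(unname(r[, 1]), c(0.5, 0.5))
  expect_equal(unname(r[, 2]), c(0, 1))
  expect_equal(unname(colSums(r)), c(1, 1))
  m[, 2] <- 0
  expect_error(relative_abundance(m), "zero-sum.*b")
  expect_error(relative_abundance(matrix(-1)), "non-negative")
})

test_that("singleton removal zeroes per-library single reads and drops empty OTUs", {
  m <- matrix(c(1, 5,
                1, 1,
                0, 3), 3, 2, byrow = TRUE,
              dimnames = list(c("o1", "o2", "o3"), c("l1", "l2")))
  out <- remove_singletons(m)
  expect_identical(rownames(out), c("o1", "o3"))
  expect_equal(unname(out["o1", ]), c(0, 5))
  # no singletons: identity
  m2 <- matrix(c(2, 5, 3, 4), 2, 2)
  expect_equal(remove_singletons(m2), m2)
  # all singletons: empty table
  expect_identical(nrow(remove_singletons(matrix(1, 2, 2))), 0L)
  expect_error(remove_singletons(matrix(1.5)), "integer")
})

test_that("Bray-Curtis equals the direct formula and behaves like a dissimilarity", {
  bc <- function(x, y) sum(abs(x - y)) / sum(x + y)   # independent closed form
  x <- c(1, 2, 3); y <- c(3, 2, 1)
  d <- bray_curtis(cbind(a = x, b = y))
  expect_equal(as.numeric(d), bc(x, y), tolerance = 1e-12)
  expect_equal(as.numeric(d), 1/3, tolerance = 1e-12)
  # identical samples -> 0; disjoint supports -> 1
  expect_equal(as.numeric(bray_curtis(cbind(x, x))), 0)
  expect_equal(as.numeric(bray_curtis(cbind(c(1, 0), c(0, 2)))), 1)
  expect_error(bray_curtis(cbind(c(-1, 1), c(1, 1))), "negative")
  # random compositions: symmetry, zero diagonal, range, formula agreement
  set.seed(5)
  m <- matrix(rexp(40), 8, 5, dimnames = list(NULL, paste0("s", 1:5)))
  dm <- as.matrix(bray_curtis(m))
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), rep(0, 5), ignore_attr = TRUE)
  expect_true(all(dm >= 0 & dm <= 1))
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(dm[i, j], bc(m[, i], m[, j]), tolerance = 1e-12)
})

test_that("NMDS embeds exactly embeddable configurations and is seeded", {
  # 4 points on a line: a perfect 2-D (even 1-D) embedding exists
  d <- dist(matrix(c(0, 1, 2, 4), 4, 1))
  o <- suppressWarnings(nmds(d, k = 2, seed = 2))
  expect_lt(o$stress, 0.01)
  expect_equal(unname(colMeans(o$points)), c(0, 0), tolerance = 1e-8)
  o2 <- suppressWarnings(nmds(d, k = 2, seed = 2))
  expect_identical(o$points, o2$points)
  # stress is non-increasing in k
  set.seed(9)
  m <- matrix(runif(60), 6, 10)
  dd <- bray_curtis(relative_abundance(m))
  s2 <- suppressWarnings(nmds(dd, k = 2, seed = 3))$stress
  s3 <- suppressWarnings(nmds(dd, k = 3, seed = 3))$stress
  expect_lte(s3, s2 + 1e-8)
})

test_that("ANOSIM statistic matches a closed-form rank computation", {
  ## independent oracle: R = (rb - rw) / (n(n-1)/4) on mid-ranked dissimilarities
  anosim_oracle <- function(d, g) {
    m <- as.matrix(d)
    ut <- upper.tri(m)
    r <- rank(m[ut])
    within <- outer(g, g, "==")[ut]
    n <- length(g)
    (mean(r[!within]) - mean(r[within])) / (n * (n - 1) / 4)
  }
  set.seed(31)
  for (i in 1:5) {
    m <- matrix(rexp(48), 8, 6, dimnames = list(NULL, paste0("s", 1:6)))
    g <- rep(c("a", "b"), each = 3)
    d <- bray_curtis(relative_abundance(m))
    fit <- anosim_test(d, g, n_perm = 99, seed = i)
    expect_equal(fit$R, anosim_oracle(d, g), tolerance = 1e-10)
  }
})

test_that("ANOSIM separates separated groups and is centred under the null", {
  # all between-distances above all within-distances -> R = 1
  m <- cbind(a1 = c(10, 0), a2 = c(11, 0), b1 = c(0, 10), b2 = c(0, 11))
  fit <- anosim_test(bray_curtis(m), c("a", "a", "b", "b"), n_perm = 99)
  expect_equal(fit$R, 1)
  # permutation p respects the +1 convention: minimum attainable is 1/(n_perm+1)
  expect_gte(fit$p, 1 / 100)
  # null: random labels give mean R near 0
  set.seed(13)
  rs <- replicate(200, {
    mm <- matrix(rexp(60), 10, 6)
    anosim_test(bray_curtis(relative_abundance(mm)),
                sample(rep(c("a", "b"), each = 3)), n_perm = 99, seed = 1)$R
  })
  expect_lt(abs(mean(rs)), 0.1)
  # singleton group refused
  expect_error(anosim_test(bray_curtis(m), c("a", "a", "b", "c"), n_perm = 99),
               "singleton")
})

test_that("pairwise ANOSIM reports per-pair R and p", {
  set.seed(41)
  m <- matrix(rexp(90), 10, 9, dimnames = list(NULL, paste0("s", 1:9)))
  m[1:3, 1:3] <- m[1:3, 1:3] + 5
  m[4:6, 4:6] <- m[4:6, 4:6] + 5
  g <- rep(c("a", "b", "c"), each = 3)
  fit <- anosim_test(bray_curtis(relative_abundance(m)), g, n_perm = 99,
                     pairwise = TRUE)
  expect_identical(nrow(fit$pairwise), 3L)
  expect_true(all(fit$pairwise$R >= -1 & fit$pairwise$R <= 1))
  expect_true(all(fit$pairwise$p > 0 & fit$pairwise$p <= 1))
})

test_that("covariance PCA matches the analytic eigendecomposition", {
  # collinear points: first component carries all variance
  m <- rbind(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8))
  pc <- pca_covariance(m)
  expect_equal(pc$percent_variance[1], 100, tolerance = 1e-10)
  # eigenvalue percentages always sum to 100 (trace identity)
  set.seed(8)
  m <- matrix(rnorm(30), 5, 6)
  pc <- pca_covariance(m)
  expect_equal(sum(pc$percent_variance), 100, tolerance = 1e-10)
  # against closed-form eigen() of the covariance matrix
  ev <- eigen(cov(t(m)), symmetric = TRUE)
  k <- ncol(pc$loadings)
  expect_equal(pc$eigenvalues[1:k], ev$values[1:k], tolerance = 1e-10)
  for (j in 1:k)
    expect_equal(abs(pc$loadings[, j]), abs(ev$vectors[, j]), tolerance = 1e-8,
                 ignore_attr = TRUE)
  # sign convention: the largest-magnitude loading of each component is positive
  expect_true(all(apply(pc$loadings, 2, function(v) v[which.max(abs(v))] > 0)))
})

test_that("loading screen is inclusive at the threshold and sign-blind", {
  m <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("v", 1:10), NULL))
  pc <- pca_covariance(m)
  pc$loadings[, 1] <- 0
  pc$loadings[1, 1] <- 0.05       # exactly at the threshold
  pc$loadings[2, 1] <- -0.05      # negative, same magnitude
  pc$loadings[, 2:ncol(pc$loadings)] <- 0
  sel <- select_loadings(pc, 0.05)
  expect_setequal(sel$selected, c("v1", "v2"))
  pc$loadings[, 1] <- 0.01
  expect_length(select_loadings(pc, 0.05)$selected, 0)
})

test_that("Shannon index and Buzas-Gibson evenness match the closed forms", {
  # uniform community: evenness exactly 1 for any richness
  for (S in c(2, 7, 30)) {
    r <- shannon_evenness(rep(1 / S, S))
    expect_equal(r$shannon, log(S), tolerance = 1e-12)
    expect_equal(r$evenness, 1, tolerance = 1e-12)
  }
  # single taxon: H' = 0, evenness 1
  r <- shannon_evenness(c(1, 0, 0))
  expect_equal(r$shannon, 0)
  expect_equal(r$evenness, 1)
  # closed form for p = (0.9, 0.1)
  p <- c(0.9, 0.1)
  H <- -sum(p * log(p))
  r <- shannon_evenness(p)
  expect_equal(r$shannon, H, tolerance = 1e-10)
  expect_equal(r$evenness, exp(H) / 2, tolerance = 1e-10)
  expect_equal(r$shannon, 0.3250829734, tolerance = 1e-8)
  expect_equal(r$evenness, 0.6920727442, tolerance = 1e-8)
  expect_error(shannon_evenness(c(0, 0)), "empty community")
  # matrix input gives one row per sample
  tab <- shannon_evenness(cbind(s1 = c(0.5, 0.5), s2 = c(0.9, 0.1)))
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$evenness[1], 1, tolerance = 1e-12)
})

test_that("paired feature t-test agrees with t.test and handles degeneracy", {
  set.seed(19)
  x0 <- matrix(rnorm(50 * 3), 50, 3)
  x1 <- matrix(rnorm(50 * 3), 50, 3)
  res <- paired_feature_ttest(x0, x1)
  for (i in c(1, 17, 50)) {
    tt <- t.test(x1[i, ], x0[i, ], paired = TRUE)
    expect_equal(res$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
  }
  # identical matrices: all degenerate, nothing significant
  expect_message(res0 <- paired_feature_ttest(x0, x0), "degenerate")
  expect_true(all(res0$degenerate))
  expect_false(any(res0$significant))
  expect_error(paired_feature_ttest(x0, x1[, 1:2]), "identical dimensions")
  # BH adjustment is available and can only reduce the significant set
  raw <- paired_feature_ttest(x0, x1, adjust = "none")
  bh <- paired_feature_ttest(x0, x1, adjust = "BH")
  expect_lte(sum(bh$significant), sum(raw$significant))
  # van Krevelen annotation carries O/C, H/C through
  f <- data.frame(c = rep(10, 50), h = 12, o = 5)
  ann <- paired_feature_ttest(x0, x1, formulas = f)
  expect_equal(ann$oc, rep(0.5, 50))
})

test_that("an injected shift is detected with high power", {
  set.seed(23)
  n <- 2000; shifted <- 1:100
  x0 <- matrix(rnorm(n * 3), n, 3)
  x1 <- x0 + matrix(rnorm(n * 3, 0, 0.3), n, 3)
  x1[shifted, ] <- x1[shifted, ] + 3
  res <- paired_feature_ttest(x0, x1)
  expect_gte(sum(res$significant[shifted]), 90)
})

test_that("the randomization null is seeded and vanishes as alpha does", {
  r1 <- random_null_comparison(1000, 6, 0.05, seed = 7)
  r2 <- random_null_comparison(1000, 6, 0.05, seed = 7)
  expect_identical(r1$n_significant, r2$n_significant)
  expect_equal(r1$fraction, r1$n_significant / 1000)
  expect_identical(random_null_comparison(1000, 6, 1e-12, seed = 7)$n_significant, 0L)
})
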