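# two-class Gaussian toy data with correlated within-class spread
toy_two_class <- function(n = 60, seed = 3) {
  set.seed(seed)
  rot <- cbind(c(1, 0.6), c(0, 1))
  Xa <- t(rot %*% rbind(rnorm(n, 0, 1), rnorm(n, 0, 2)))
  Xb <- t(rot %*% rbind(rnorm(n, 3, 1), rnorm(n, 1, 2)))
  vals <- rbind(Xa, Xb)
  colnames(vals) <- c("100.05", "100.15")
  rownames(vals) <- sprintf("ev%03d", seq_len(2 * n))
  list(x = as_intensity_matrix(vals), labels = rep(c("a", "b"), each = n))
}

test_that("fitted Fisher direction matches closed form and brute force", {
  tc <- toy_two_class()
  fit <- fit_pcalda(tc$x, tc$labels, n_components = 2)
  b <- drop(fit$W %*% fit$A)  # composed back to feature space

  X <- tc$x$values
  m1 <- colMeans(X[tc$labels == "a", ]); m2 <- colMeans(X[tc$labels == "b", ])
  Sw <- (cov(X[tc$labels == "a", ]) + cov(X[tc$labels == "b", ])) / 2
  closed <- solve(Sw, m2 - m1)
  cosine <- function(u, v) abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  expect_gt(cosine(b, closed), 0.999)

  # brute-force scatter-ratio maximization over unit directions
  angles <- seq(0, pi, length.out = 20001)
  ratio <- vapply(angles, function(th) {
    u <- c(cos(th), sin(th))
    (sum(u * (m2 - m1)))^2 / drop(t(u) %*% Sw %*% u)
  }, 0)
  ubest <- c(cos(angles[which.max(ratio)]), sin(angles[which.max(ratio)]))
  expect_gt(cosine(b, ubest), 0.999)
})

test_that("renaming classes leaves scores unchanged up to axis sign", {
  tc <- toy_two_class(seed = 5)
  f1 <- fit_pcalda(tc$x, tc$labels, n_components = 2)
  f2 <- fit_pcalda(tc$x, c(a = "x", b = "y")[tc$labels], n_components = 2)
  z1 <- project_events(f1, tc$x)
  z2 <- project_events(f2, tc$x)
  expect_equal(abs(z1), abs(z2), tolerance = 1e-9)
})

test_that("3-class cohort yields 2 discriminant axes with separated centroids", {
  hs <- high_sep()
  fit <- fit_pcalda(hs$mg)
  expect_equal(fit$d, length(fit$classes) - 1)  # at most C-1 dims, here exactly
  # pairwise centroid separation beyond the SD gate
  for (i in 1:2) for (j in (i + 1):3) {
    dx <- fit$centroids[i, ] - fit$centroids[j, ]
    d2 <- drop(t(dx) %*% solve(fit$covs[[i]], dx))
    expect_gt(sqrt(d2), fit$sd_gate)
  }
})

test_that("projection is a deterministic row-wise centered linear map", {
  hs <- high_sep()
  fit <- fit_pcalda(hs$mg)
  z1 <- project_events(fit, hs$mg)
  expect_equal(z1, project_events(fit, hs$mg), tolerance = 1e-15)
  # the global-mean event scores at the origin
  mu_row <- matrix(fit$mu, nrow = 1,
                   dimnames = list("mean", names(fit$mu)))
  z0 <- project_events(fit, as_intensity_matrix(mu_row, grid = hs$mg$grid))
  expect_equal(unname(drop(z0)), rep(0, fit$d), tolerance = 1e-9)
  # duplicated rows project to duplicated scores
  dup <- subset_rows(hs$mg, c(1, 1, 2))
  zd <- project_events(fit, dup)
  expect_equal(unname(zd[1, ]), unname(zd[2, ]))
})

test_that("loading ranking finds an informative bin and breaks ties by label", {
  set.seed(8)
  n <- 40
  vals <- matrix(rnorm(n * 5, 100, 1e-3), n, 5)
  vals[, 3] <- rep(c(0, 10), each = n / 2)  # the only informative bin
  colnames(vals) <- c("100.05", "100.15", "100.25", "100.35", "100.45")
  # near-constant noise columns make the within-class scatter ill-conditioned
  expect_warning(
    fit <- fit_pcalda(as_intensity_matrix(vals),
                      rep(c("a", "b"), each = n / 2), n_components = 5),
    "ridge")
  rk <- rank_loadings(fit, top_n = 5)
  expect_equal(rk$bin[1], 100.25)
  # exact ties order by ascending bin label
  expect_warning(rk_all <- rank_loadings(fit, top_n = 10), "exceeds")
  tied <- rk_all[duplicated(rk_all$score) |
                   duplicated(rk_all$score, fromLast = TRUE), ]
  if (nrow(tied) > 1) expect_false(is.unsorted(tied$bin))
})

test_that("specimen-level permutation mixes classes evenly and reproduces", {
  hs <- high_sep()
  lab <- hs$mg$meta$class_label
  grp <- hs$mg$meta$specimen_id
  p1 <- permute_labels(lab, grp, seed = 5)
  expect_identical(p1, permute_labels(lab, grp, seed = 5))
  # a rearrangement: the multiset of labels is conserved at specimen level
  expect_setequal(unique(p1), unique(lab))
  spec_n <- table(tapply(p1, grp, `[`, 1))
  expect_true(max(spec_n) - min(spec_n) <= 1)
  # each pseudo-class is ~1/3 from each true class
  comp <- prop.table(table(lab, p1), margin = 2)
  expect_true(all(abs(comp - 1 / 3) < 0.12))
  # events of one specimen stay together
  expect_true(all(tapply(p1, grp, function(l) length(unique(l))) == 1))
  expect_error(permute_labels(c("a", "b", "b"), c("s1", "s2", "s3")),
               ">= 2 specimens")
})

test_that("learning curve is anchored at full-data CV and rises with cohort size", {
  lowsep <- cached("lowsep", make_cohort(separation = 0.15, seed = 13))
  lc <- learning_curve(lowsep$mg, fractions = c(0.25, 0.5, 0.75, 1),
                       reps = 3, seed = 7)
  full <- crossval_fullgroup(lowsep$mg)
  expect_equal(lc$mean_accuracy[lc$fraction == 1], full$accuracy,
               tolerance = 1e-12)
  rho <- suppressWarnings(cor(lc$fraction, lc$mean_accuracy,
                              method = "spearman"))
  expect_gt(rho, 0)
  expect_error(learning_curve(lowsep$mg, fractions = c(0.5)), "include 1")
})

test_that("feature restriction subsets columns and tolerates one dimension", {
  hs <- high_sep()
  arr <- lipid_marker_array()
  sparse <- restrict_features(hs$mg, arr$bin)
  expect_equal(ncol(sparse$values), 41)
  expect_equal(colnames(sparse$values), sprintf("%.2f", arr$bin))
  # restriction to every column is the identity
  all_bins <- restrict_features(hs$mg, colnames(hs$mg$values))
  expect_identical(all_bins$values, hs$mg$values)
  expect_error(restrict_features(hs$mg, c(100.05, 99.99)), "unknown bin")
  # a single-bin model degenerates to a 1-D threshold classifier but runs
  one <- restrict_features(hs$mg, arr$bin[1])
  fit1 <- fit_pcalda(one)
  expect_equal(fit1$d, 1)
  expect_true(is.finite(crossval_fullgroup(one)$accuracy))
})

test_that("refitting on discriminant scores does not change CV accuracy", {
  hs <- high_sep()
  fit <- fit_pcalda(hs$mg)
  Z <- project_events(fit, hs$mg)
  colnames(Z) <- c("100.05", "100.15")
  zm <- as_intensity_matrix(Z, meta = hs$mg$meta)
  a1 <- crossval_fullgroup(hs$mg)$accuracy
  a2 <- crossval_fullgroup(zm)$accuracy
  expect_lt(abs(a1 - a2), 1e-6)
})

test_that("models round-trip through JSON", {
  hs <- high_sep()
  fit <- fit_pcalda(hs$mg)
  path <- file.path(tempdir(), "model.json")
  write_model(fit, path, manifest = "manifest_fit.json")
  fit2 <- read_model(path)
  expect_equal(project_events(fit2, hs$mg), project_events(fit, hs$mg),
               tolerance = 1e-12)
  expect_equal(fit2$covs, fit$covs, tolerance = 1e-12)
  expect_equal(fit2$prob_threshold, fit$prob_threshold)
})
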