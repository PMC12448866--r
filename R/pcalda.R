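#' Fit a PCA-LDA model to binned spectra
#'
#' Mean-centers the event-by-bin matrix, reduces it to k principal axes, then
#' fits Fisher linear discriminant axes maximizing between- over within-class
#' scatter with equal class priors. Per-class centroids and covariances are
#' estimated in the discriminant space; they drive the Mahalanobis class
#' calls and posteriors in [call_event()].
#'
#' Bad (short-duration) events must already be removed. Constant (all-equal)
#' bins carry no information and are dropped; the retained feature subset is
#' recorded in the model. By default k is the smallest number of principal
#' axes explaining >= 95% of variance, capped at
#' \code{min(100, n_events - n_classes - 1)} and floored at
#' \code{n_classes - 1}.
#'
#' @param x an \code{intensity_matrix} (TIC-normalize first if desired).
#' @param labels per-event class labels aligned with rows; defaults to
#'   \code{x$meta$class_label}.
#' @param n_components either a fraction in (0,1) (variance explained) or an
#'   integer number of principal axes.
#' @param sd_gate standard-deviation gate for the outlier call (see
#'   [call_event()]).
#' @param prob_threshold posterior cutoff for thresholded reporting.
#' @return object of class \code{pcalda_model}: feature subset, global mean,
#'   principal loadings \code{W} (bins x k), discriminant axes \code{A}
#'   (k x d), class list, per-class centroids and covariances in discriminant
#'   space, gate and threshold.
#' @export
fit_pcalda <- function(x, labels = NULL, n_components = 0.95,
                       sd_gate = 3, prob_threshold = 0.95) {
  stopifnot(inherits(x, "intensity_matrix"))
  labels <- as.character(labels %||% x$meta$class_label)
  if (length(labels) != nrow(x$values))
    stopf("labels length does not match number of events")
  classes <- sort(unique(labels))
  C <- length(classes)
  if (C < 2) stopf("need at least 2 classes")
  tab <- table(labels)
  if (any(tab < 2)) stopf("every class needs >= 2 events")

  vals <- x$values
  # drop constant columns; they cannot discriminate and break scaling
  keep <- apply(vals, 2, function(v) max(v) > min(v))
  if (!any(keep)) stopf("all bins are constant")
  vals <- vals[, keep, drop = FALSE]
  features <- colnames(vals)

  mu <- colMeans(vals)
  Xc <- sweep(vals, 2, mu)
  n <- nrow(Xc)

  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2
  pos <- ev > max(ev) * 1e-12
  ev <- ev[pos]
  kmax <- length(ev)
  cap <- max(C - 1L, min(100L, n - C - 1L))
  if (n_components >= 1) {
    k <- as.integer(n_components)
  } else {
    k <- which(cumsum(ev) / sum(ev) >= n_components)[1]
  }
  k <- min(max(k, C - 1L), cap, kmax)

  W <- sv$v[, seq_len(k), drop = FALSE]
  rownames(W) <- features
  scores <- Xc %*% W

  # Fisher axes with equal class priors
  means <- do.call(rbind, lapply(classes, function(cl)
    colMeans(scores[labels == cl, , drop = FALSE])))
  covs_pc <- lapply(classes, function(cl)
    stats::cov(scores[labels == cl, , drop = FALSE]))
  Sw <- Reduce(`+`, covs_pc) / C
  mbar <- colMeans(means)
  Sb <- crossprod(sweep(means, 2, mbar)) / C
  Sw <- regularize_cov(Sw, warn = TRUE,
                       what = "within-class scatter")
  R <- chol(Sw)
  Rinv <- backsolve(R, diag(k))
  M <- t(Rinv) %*% Sb %*% Rinv
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  d <- min(C - 1L, k)
  A <- Rinv %*% eg$vectors[, seq_len(d), drop = FALSE]
  # deterministic orientation and scale
  for (j in seq_len(d)) {
    A[, j] <- A[, j] / sqrt(sum(A[, j]^2))
    piv <- which.max(abs(A[, j]))
    if (A[piv, j] < 0) A[, j] <- -A[, j]
  }

  Z <- scores %*% A
  centroids <- do.call(rbind, lapply(classes, function(cl)
    colMeans(Z[labels == cl, , drop = FALSE])))
  rownames(centroids) <- classes
  pooled <- regularize_cov(Reduce(`+`, lapply(classes, function(cl)
    stats::cov(Z[labels == cl, , drop = FALSE]))) / C)
  covs <- lapply(classes, function(cl) {
    Zc <- Z[labels == cl, , drop = FALSE]
    if (nrow(Zc) <= d) {
      warnf("class '%s' has too few events for its own covariance; using pooled",
            cl)
      return(pooled)
    }
    regularize_cov(stats::cov(Zc))
  })
  names(covs) <- classes

  structure(list(grid = x$grid, features = features, mu = mu,
                 W = W, A = A, k = k, d = d,
                 var_explained = sum(ev[seq_len(k)]) / sum(ev),
                 classes = classes, centroids = centroids, covs = covs,
                 pooled_cov = pooled,
                 sd_gate = sd_gate, prob_threshold = prob_threshold),
            class = "pcalda_model")
}

# ridge-regularize a covariance that is not safely positive definite
regularize_cov <- function(S, warn = FALSE, what = "covariance") {
  S <- (S + t(S)) / 2
  for (i in 0:6) {
    ok <- tryCatch({
      ee <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      min(ee) > max(ee) * 1e-10 && min(ee) > 0
    }, error = function(e) FALSE)
    if (ok) return(S)
    if (warn && i == 0) warnf("near-singular %s; ridge-regularizing", what)
    ridge <- max(sum(diag(S)), .Machine$double.eps) * 1e-8 * 10^i
    S <- S + diag(ridge, nrow(S))
  }
  S
}

#' @export
print.pcalda_model <- function(x, ...) {
  cat(sprintf(
    "<pcalda_model> %d classes (%s); %d features -> %d PCs (%.1f%% var) -> %d LD axes\n",
    length(x$classes), paste(x$classes, collapse = ", "),
    length(x$features), x$k, 100 * x$var_explained, x$d))
  cat(sprintf("  sd_gate = %g SD, prob_threshold = %g\n",
              x$sd_gate, x$prob_threshold))
  invisible(x)
}

#' Project events into a model's discriminant space
#'
#' Deterministic linear map: subtract the model's global mean over its
#' feature subset, apply the principal loadings, then the discriminant axes.
#' Training events reproduce their fitted scores exactly.
#'
#' @param model a \code{pcalda_model}.
#' @param x an \code{intensity_matrix} binned on the model's grid (its
#'   columns must contain the model's feature subset).
#' @return numeric matrix of discriminant scores, events x d.
#' @export
project_events <- function(model, x) {
  stopifnot(inherits(model, "pcalda_model"), inherits(x, "intensity_matrix"))
  if (!is.null(model$grid) && !is.null(x$grid) &&
      !grids_equal(model$grid, x$grid))
    stopf("matrix grid does not match the model grid")
  miss <- setdiff(model$features, colnames(x$values))
  if (length(miss))
    stopf("matrix lacks %d feature(s) used by the model (e.g. %s)",
          length(miss), miss[1])
  Xc <- sweep(x$values[, model$features, drop = FALSE], 2, model$mu)
  Z <- Xc %*% model$W %*% model$A
  rownames(Z) <- rownames(x$values)
  Z
}

#' Rank bins by their contribution to the discrimination
#'
#' Composes the principal loadings with the discriminant weights back to bin
#' space and scores every retained bin by the Euclidean norm of its
#' coefficients across all discriminant axes, i.e. how strongly the bin
#' drives the between-class separation. This is the loading-plot rank order
#' from which marker candidates (the identified 41-lipid array among them)
#' are drawn.
#'
#' @param model a \code{pcalda_model}.
#' @param top_n how many bins to return (default 100, the usual candidate
#'   list size for downstream lipid identification).
#' @return data.frame with columns \code{bin} (numeric label) and
#'   \code{score}, sorted by descending score, ties broken by ascending bin
#'   label.
#' @export
rank_loadings <- function(model, top_n = 100) {
  stopifnot(inherits(model, "pcalda_model"))
  B <- model$W %*% model$A
  score <- sqrt(rowSums(B^2))
  bins <- as.numeric(model$features)
  ord <- order(-score, bins)
  if (top_n > length(score)) {
    warnf("top_n = %d exceeds the %d retained bins; returning all",
          top_n, length(score))
    top_n <- length(score)
  }
  out <- data.frame(bin = bins[ord], score = score[ord])[seq_len(top_n), ]
  rownames(out) <- NULL
  out
}

#' Specimen-level label permutation
#'
#' Builds the null-model annotation used to check that apparent class
#' separation is not an overfitting artifact: specimens (not events) are
#' reassigned to pseudo-classes such that each pseudo-class is composed of
#' approximately equal numbers of specimens — hence approximately equal
#' numbers of sampling events — from every true class, while pseudo-class
#' sizes stay within one specimen of balance.
#'
#' @param labels per-event true class labels.
#' @param groups per-event specimen ids.
#' @param seed integer seed; the same seed reproduces the permutation.
#' @return character vector of permuted per-event labels (same multiset of
#'   label values, reassigned at specimen level).
#' @export
permute_labels <- function(labels, groups, seed = 1) {
  labels <- as.character(labels)
  groups <- as.character(groups)
  classes <- sort(unique(labels))
  C <- length(classes)
  if (C < 2) stopf("need at least 2 classes to permute")
  spec_class <- tapply(labels, groups, function(l) l[1])
  if (any(tapply(labels, groups, function(l) length(unique(l))) > 1))
    stopf("a specimen maps to more than one class")
  if (any(table(spec_class) < 2))
    stopf("every class needs >= 2 specimens to mix")
  set.seed(seed)
  assign <- character(0)
  for (cl in classes) {
    sp <- sample(names(spec_class)[spec_class == cl])
    # deal this class's specimens round-robin over pseudo-classes, starting
    # at a random offset so no pseudo-class systematically gets more
    start <- sample.int(C, 1)
    pseudo <- classes[((seq_along(sp) + start - 2) %% C) + 1]
    assign[sp] <- pseudo
  }
  unname(assign[groups])
}

#' Learning curve by specimen subsampling
#'
#' Measures how full-group (leave-one-specimen-out) cross-validation accuracy
#' grows with cohort size: for each fraction, specimens are subsampled
#' without replacement (stratified by class) \code{reps} times and the CV
#' accuracy recorded; fraction 1.0 uses all data once. A plateau well before
#' 1.0 indicates the cohort already captures the inter-specimen variance.
#'
#' @param x an \code{intensity_matrix}.
#' @param labels per-event class labels.
#' @param groups per-event specimen ids.
#' @param fractions increasing vector of specimen fractions in (0, 1];
#'   must include 1.
#' @param reps subsampling repeats per fraction below 1.
#' @param seed integer seed.
#' @param ... passed to [fit_pcalda()] via the CV driver.
#' @return data.frame with \code{fraction}, \code{mean_accuracy},
#'   \code{sd_accuracy}, \code{n_specimens}.
#' @export
learning_curve <- function(x, labels = NULL, groups = NULL,
                           fractions = c(0.25, 0.5, 0.75, 1),
                           reps = 3, seed = 1, ...) {
  labels <- as.character(labels %||% x$meta$class_label)
  groups <- as.character(groups %||% x$meta$specimen_id)
  if (is.unsorted(fractions) || any(fractions <= 0) || any(fractions > 1))
    stopf("fractions must be ascending within (0, 1]")
  if (!any(fractions == 1)) stopf("fractions must include 1.0")
  spec_class <- tapply(labels, groups, function(l) l[1])
  out <- list()
  set.seed(seed)
  for (f in fractions) {
    if (f == 1) {
      acc <- crossval_fullgroup(x, labels, groups, ...)$accuracy
      out[[length(out) + 1]] <- data.frame(
        fraction = f, mean_accuracy = acc, sd_accuracy = 0,
        n_specimens = length(spec_class))
      next
    }
    sizes <- table(spec_class)
    take <- round(f * sizes)
    take[take < 2] <- 2L
    if (any(take > sizes)) {
      warnf("fraction %.2f leaves < 2 specimens in a class; skipped", f)
      next
    }
    by_class <- split(names(spec_class), spec_class)
    accs <- numeric(reps)
    nsp <- 0L
    for (r in seq_len(reps)) {
      chosen <- unlist(lapply(names(by_class), function(cl)
        sample(by_class[[cl]], take[[cl]])))
      rows <- groups %in% chosen
      xs <- subset_events(x, rows)
      accs[r] <- crossval_fullgroup(xs, labels[rows], groups[rows],
                                    ...)$accuracy
      nsp <- length(chosen)
    }
    out[[length(out) + 1]] <- data.frame(
      fraction = f, mean_accuracy = mean(accs),
      sd_accuracy = stats::sd(accs) * sqrt((reps - 1) / reps),
      n_specimens = nsp)
  }
  do.call(rbind, out)
}

# row-subset an intensity_matrix, keeping metadata aligned
subset_events <- function(x, rows) {
  out <- x
  out$values <- x$values[rows, , drop = FALSE]
  if (!is.null(x$meta)) out$meta <- x$meta[rows, , drop = FALSE]
  out$zero_rows <- x$zero_rows[rows]
  out$dropped_peaks <- x$dropped_peaks[rows]
  out
}

#' Restrict an intensity matrix to a feature subset
#'
#' Column subset in the requested order, used for sparse (low-complexity)
#' classification on the identified 41-lipid marker array instead of the
#' full 100-1000 Da feature set.
#'
#' @param x an \code{intensity_matrix}.
#' @param bins numeric or character bin labels; all must exist on the grid.
#' @return the restricted \code{intensity_matrix}.
#' @export
restrict_features <- function(x, bins) {
  stopifnot(inherits(x, "intensity_matrix"))
  labs <- if (is.numeric(bins) && !is.null(x$grid))
    x$grid$label_chr[label_index(x$grid, bins)] else as.character(bins)
  unknown <- is.na(labs) | !(labs %in% colnames(x$values))
  if (any(unknown))
    stopf("unknown bin label: %s", as.character(bins)[which(unknown)[1]])
  out <- x
  out$values <- x$values[, labs, drop = FALSE]
  out
}

#' Serialize a fitted model to JSON
#'
#' @param model a \code{pcalda_model}.
#' @param path output path.
#' @param manifest optional manifest filename recorded in the document.
#' @return invisibly, \code{path}.
#' @export
write_model <- function(model, path, manifest = NULL) {
  doc <- list(
    type = "pcalda_model",
    grid = if (!is.null(model$grid))
      list(lo = model$grid$lo, hi = model$grid$hi, width = model$grid$width),
    features = model$features, mu = unname(model$mu),
    W = unname(model$W), A = unname(model$A), k = model$k, d = model$d,
    var_explained = model$var_explained,
    classes = model$classes,
    centroids = unname(model$centroids),
    covs = lapply(model$covs, unname),
    pooled_cov = unname(model$pooled_cov),
    sd_gate = model$sd_gate, prob_threshold = model$prob_threshold,
    manifest = manifest)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model written by [write_model()]
#'
#' @param path JSON path.
#' @return a \code{pcalda_model}.
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$type, "pcalda_model")) stopf("not a pcalda_model file")
  as_mat <- function(m) matrix(unlist(m), nrow = length(m), byrow = TRUE)
  W <- doc$W; if (is.list(W)) W <- as_mat(W)
  A <- doc$A; if (is.list(A)) A <- as_mat(A)
  if (doc$d == 1) { A <- matrix(A, ncol = 1) }
  centroids <- doc$centroids; if (is.list(centroids)) centroids <- as_mat(centroids)
  if (doc$d == 1) centroids <- matrix(centroids, ncol = 1)
  covs <- lapply(doc$covs, function(m) {
    if (is.list(m)) m <- as_mat(m)
    matrix(m, nrow = doc$d)
  })
  pooled <- doc$pooled_cov
  if (is.list(pooled)) pooled <- as_mat(pooled)
  pooled <- matrix(pooled, nrow = doc$d)
  rownames(W) <- doc$features
  rownames(centroids) <- doc$classes
  names(covs) <- doc$classes
  structure(list(
    grid = if (!is.null(doc$grid)) bin_grid(doc$grid$lo, doc$grid$hi,
                                            doc$grid$width),
    features = doc$features, mu = stats::setNames(doc$mu, doc$features),
    W = W, A = A, k = doc$k, d = doc$d,
    var_explained = doc$var_explained, classes = doc$classes,
    centroids = centroids, covs = covs, pooled_cov = pooled,
    sd_gate = doc$sd_gate, prob_threshold = doc$prob_threshold),
    class = "pcalda_model")
}
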