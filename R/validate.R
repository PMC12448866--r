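#' Confusion matrix over classifiable events
#'
#' Rows are actual classes, columns predicted classes.
#'
#' @param actual,predicted character vectors of equal length.
#' @param classes class order; defaults to the sorted union.
#' @return integer C x C matrix.
#' @export
confusion_matrix <- function(actual, predicted,
                             classes = sort(union(actual, predicted))) {
  cm <- table(factor(actual, levels = classes),
              factor(predicted, levels = classes))
  m <- matrix(as.integer(cm), nrow = length(classes),
              dimnames = list(actual = classes, predicted = classes))
  m
}

cm_accuracy <- function(cm) 100 * sum(diag(cm)) / sum(cm)

# shared CV engine: iterate over held-out index sets, fit on the rest,
# score held-out events unthresholded; accuracy over classifiable events
cv_engine <- function(x, labels, holdouts, ...) {
  classes <- sort(unique(labels))
  actual <- character(0)
  predicted <- character(0)
  n_outlier <- 0L
  for (ho in holdouts) {
    train <- setdiff(seq_along(labels), ho)
    if (length(unique(labels[train])) < length(classes))
      stopf("a class is absent from a training split")
    fit <- fit_pcalda(subset_events(x, train), labels[train], ...)
    Z <- project_events(fit, subset_events(x, ho))
    for (i in seq_along(ho)) {
      call <- call_event(fit, Z[i, ])
      if (call$status == "classified") {
        actual <- c(actual, labels[ho[i]])
        predicted <- c(predicted, call$called_class)
      } else n_outlier <- n_outlier + 1L
    }
  }
  cm <- confusion_matrix(actual, predicted, classes)
  list(accuracy = cm_accuracy(cm), cm = cm,
       n_classifiable = length(actual), n_outlier = n_outlier)
}

#' Event-level stratified k-fold cross-validation ("20% leave-out")
#'
#' Events are partitioned into \code{folds} stratified random folds; each
#' fold is scored by a model fitted on the remaining events through the full
#' fit + call pipeline (unthresholded), and accuracy is correct /
#' classifiable test events. Caveat, by design: sampling events from the same
#' specimen can populate both the model and the test set, so this estimate is
#' optimistically biased when intra-specimen correlation is high — contrast
#' it with [crossval_fullgroup()].
#'
#' @param x an \code{intensity_matrix}.
#' @param labels per-event class labels (default \code{x$meta$class_label}).
#' @param folds number of folds (default 5, i.e. 20% held out per fold).
#' @param seed integer seed for the fold assignment.
#' @param ... passed to [fit_pcalda()].
#' @return list: \code{accuracy} (percent), \code{cm} (confusion matrix),
#'   \code{n_classifiable}, \code{n_outlier}.
#' @export
crossval_event <- function(x, labels = NULL, folds = 5, seed = 1, ...) {
  labels <- as.character(labels %||% x$meta$class_label)
  if (folds < 2) stopf("folds must be >= 2")
  set.seed(seed)
  for (attempt in 1:10) {
    fold_of <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold_of[idx] <- rep_len(seq_len(folds), length(idx))
    }
    ok <- all(vapply(seq_len(folds), function(f)
      length(unique(labels[fold_of != f])) == length(unique(labels)) &&
        all(table(labels[fold_of != f]) >= 2), TRUE))
    if (ok) break
    if (attempt == 10) stopf("could not build folds covering every class")
  }
  cv_engine(x, labels, split(seq_along(labels), fold_of), ...)
}

#' Leave-one-specimen-out cross-validation ("full group leave-out")
#'
#' All sampling events of one specimen are held out per iteration, so no
#' specimen contributes to both model and test set; the number of iterations
#' equals the number of specimens. This is the unbiased counterpart of
#' [crossval_event()].
#'
#' @param x an \code{intensity_matrix}.
#' @param labels per-event class labels (default \code{x$meta$class_label}).
#' @param groups per-event specimen ids (default \code{x$meta$specimen_id}).
#' @param ... passed to [fit_pcalda()].
#' @return list as in [crossval_event()], plus \code{n_iterations}.
#' @export
crossval_fullgroup <- function(x, labels = NULL, groups = NULL, ...) {
  labels <- as.character(labels %||% x$meta$class_label)
  groups <- as.character(groups %||% x$meta$specimen_id)
  if (any(table(tapply(labels, groups, `[`, 1)) < 2))
    stopf("every class needs >= 2 specimens")
  holdouts <- split(seq_along(groups), groups)
  res <- cv_engine(x, labels, holdouts, ...)
  res$n_iterations <- length(holdouts)
  res
}

#' One-vs-rest sensitivity and specificity
#'
#' Standard definitions: sensitivity = 100 TP / (TP + FN), specificity =
#' 100 TN / (TN + FP), reported to 2 decimals. A zero denominator yields
#' \code{NA} with a warning rather than a silent 0.
#'
#' @param tp,fn,fp,tn nonnegative counts (vectorized).
#' @return data.frame with columns \code{sensitivity} and \code{specificity}
#'   in percent.
#' @export
sensitivity_specificity <- function(tp, fn, fp, tn) {
  sens <- ifelse(tp + fn > 0, round_half_away(100 * tp / (tp + fn), 2), NA)
  spec <- ifelse(tn + fp > 0, round_half_away(100 * tn / (tn + fp), 2), NA)
  if (any(is.na(sens)) || any(is.na(spec)))
    warnf("zero denominator: undefined sensitivity or specificity set to NA")
  data.frame(sensitivity = sens, specificity = spec)
}

#' Cohort-averaged metric with population SD
#'
#' Arithmetic mean and population standard deviation (divide by n) of
#' per-class percentages, each rounded half away from zero to integer
#' percent — the convention that reproduces headline "(mean +/- SD)%"
#' summaries from per-class values.
#'
#' @param values numeric vector of per-class percentages.
#' @return list with integer \code{mean} and \code{sd}.
#' @export
average_metrics <- function(values) {
  if (!length(values)) stopf("need at least one value")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  list(mean = round_half_away(m), sd = round_half_away(s))
}

#' Spatial concordance of predictions across a specimen's surface
#'
#' Two readings of "spatially invariant correct classification":
#' the fraction of classifiable events called correctly (event level), and
#' the fraction of specimens whose classifiable events are all correct
#' (unanimous-specimen level). Specimens with no classifiable events are
#' excluded from the second denominator.
#'
#' @param pred a \code{prediction_table} carrying \code{class_label} truth.
#' @return list with \code{event_pct} and \code{specimen_pct} (percent).
#' @export
spatial_concordance <- function(pred) {
  cls <- pred$status == "classified"
  if (!any(cls)) {
    warnf("no classifiable events; concordance undefined")
    return(list(event_pct = NA_real_, specimen_pct = NA_real_))
  }
  correct <- pred$predicted_class[cls] == pred$class_label[cls]
  event_pct <- round_half_away(100 * mean(correct), 2)
  by_spec <- tapply(correct, pred$specimen_id[cls], all)
  specimen_pct <- round_half_away(100 * mean(by_spec), 2)
  list(event_pct = event_pct, specimen_pct = specimen_pct)
}

#' Full metrics report from a prediction table
#'
#' Computes per-class one-vs-rest contingency counts twice — unthresholded
#' (all classifiable events) and thresholded (only events whose posterior
#' strictly exceeds \code{prob_threshold}) — with sensitivity/specificity per
#' class, cohort-averaged metrics, event accounting and spatial concordance.
#' Bad and outlier events appear in the counts but in no metric denominator.
#'
#' @param pred a \code{prediction_table} with truth in \code{class_label}.
#' @param prob_threshold posterior cutoff for the thresholded block.
#' @param classes class order; defaults to sorted truth labels.
#' @return object of class \code{metrics_report}: \code{counts},
#'   \code{unthresholded} and \code{thresholded} blocks (each with a
#'   per-class table, confusion matrix and averaged metrics) and
#'   \code{concordance}.
#' @export
build_report <- function(pred, prob_threshold = 0.95, classes = NULL) {
  stopifnot(is.data.frame(pred))
  classes <- classes %||% sort(unique(stats::na.omit(pred$class_label)))
  cls <- pred$status == "classified"
  block <- function(rows) {
    actual <- pred$class_label[rows]
    predicted <- pred$predicted_class[rows]
    per <- do.call(rbind, lapply(classes, function(cl) {
      tp <- sum(actual == cl & predicted == cl)
      fn <- sum(actual == cl & predicted != cl)
      fp <- sum(actual != cl & predicted == cl)
      tn <- sum(actual != cl & predicted != cl)
      data.frame(class = cl, TP = tp, FN = fn, FP = fp, TN = tn)
    }))
    per <- cbind(per, sensitivity_specificity(per$TP, per$FN, per$FP, per$TN))
    list(per_class = per,
         cm = confusion_matrix(actual, predicted, classes),
         n = sum(rows),
         avg_sensitivity = average_metrics(per$sensitivity),
         avg_specificity = average_metrics(per$specificity))
  }
  thr <- cls & !is.na(pred$posterior) & pred$posterior > prob_threshold
  counts <- list(total = nrow(pred),
                 bad = sum(pred$status == "bad"),
                 outlier = sum(pred$status == "outlier"),
                 classifiable = sum(cls),
                 below_threshold = sum(cls) - sum(thr))
  structure(list(counts = counts,
                 unthresholded = block(cls),
                 thresholded = block(thr),
                 concordance = spatial_concordance(pred),
                 prob_threshold = prob_threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  ct <- x$counts
  cat(sprintf(
    "<metrics_report> %d events: %d bad, %d outlier, %d classifiable (%d below %.0f%% threshold)\n",
    ct$total, ct$bad, ct$outlier, ct$classifiable, ct$below_threshold,
    100 * x$prob_threshold))
  for (nm in c("unthresholded", "thresholded")) {
    b <- x[[nm]]
    cat(sprintf("%s (n = %d):\n", nm, b$n))
    print(b$per_class, row.names = FALSE)
    cat(sprintf("  averaged: sensitivity (%d +/- %d)%%, specificity (%d +/- %d)%%\n",
                b$avg_sensitivity$mean, b$avg_sensitivity$sd,
                b$avg_specificity$mean, b$avg_specificity$sd))
  }
  cat(sprintf("concordance: %.2f%% of classifiable events, %.2f%% of specimens unanimous\n",
              x$concordance$event_pct, x$concordance$specimen_pct))
  invisible(x)
}

#' Write a metrics report as TSV (per-class blocks) and JSON
#'
#' @param report a \code{metrics_report}.
#' @param prefix output path prefix; writes \code{<prefix>.tsv} and
#'   \code{<prefix>.json}.
#' @param manifest optional manifest filename recorded in the TSV header.
#' @return invisibly, the two paths.
#' @export
write_report <- function(report, prefix, manifest = NULL) {
  tsv <- paste0(prefix, ".tsv")
  js <- paste0(prefix, ".json")
  tab <- rbind(cbind(variant = "unthresholded",
                     report$unthresholded$per_class),
               cbind(variant = "thresholded", report$thresholded$per_class))
  con <- file(tsv, "w")
  if (!is.null(manifest)) writeLines(paste("# manifest:", manifest), con)
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  close(con)
  doc <- list(counts = report$counts,
              unthresholded = list(
                per_class = report$unthresholded$per_class,
                cm = report$unthresholded$cm,
                avg_sensitivity = report$unthresholded$avg_sensitivity,
                avg_specificity = report$unthresholded$avg_specificity),
              thresholded = list(
                per_class = report$thresholded$per_class,
                cm = report$thresholded$cm,
                avg_sensitivity = report$thresholded$avg_sensitivity,
                avg_specificity = report$thresholded$avg_specificity),
              concordance = report$concordance,
              prob_threshold = report$prob_threshold,
              manifest = manifest)
  jsonlite::write_json(doc, js, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(tsv, js))
}
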