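#' Squared Mahalanobis distances to every class centroid
#'
#' \eqn{d^2_c = (x - \mu_c)' \Sigma_c^{-1} (x - \mu_c)} in the model's
#' discriminant space, using each class's own covariance (pooled fallback was
#' resolved at fit time).
#'
#' @param model a \code{pcalda_model}.
#' @param score numeric vector (one event) or matrix (events x d) of
#'   discriminant scores from [project_events()].
#' @return matrix of squared distances, events x classes.
#' @export
mahalanobis_d2 <- function(model, score) {
  if (is.null(dim(score))) score <- matrix(score, nrow = 1)
  if (any(!is.finite(score))) stopf("non-finite discriminant score")
  if (ncol(score) != model$d)
    stopf("score has %d dims; model space has %d", ncol(score), model$d)
  d2 <- vapply(model$classes, function(cl) {
    dx <- sweep(score, 2, model$centroids[cl, ])
    rowSums(dx * t(solve(model$covs[[cl]], t(dx))))
  }, numeric(nrow(score)))
  matrix(d2, nrow = nrow(score),
         dimnames = list(rownames(score), model$classes))
}

#' Class posteriors from Mahalanobis distances
#'
#' Normalized Gaussian posterior with equal class priors:
#' \eqn{p_c \propto |\Sigma_c|^{-1/2} \exp(-d^2_c / 2)}, stabilized by
#' max-subtraction in the exponent. This is the "probability of prediction"
#' compared against the 95% threshold.
#'
#' @param model a \code{pcalda_model}.
#' @param d2 matrix (or vector) of per-class squared distances from
#'   [mahalanobis_d2()].
#' @return matrix of posteriors, rows summing to 1.
#' @export
class_posterior <- function(model, d2) {
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1,
                                     dimnames = list(NULL, model$classes))
  logdet <- vapply(model$classes, function(cl)
    determinant(model$covs[[cl]], logarithm = TRUE)$modulus[1], 0)
  lw <- sweep(-d2 / 2, 2, logdet[colnames(d2)] / 2)
  lw <- lw - apply(lw, 1, max)
  p <- exp(lw)
  p / rowSums(p)
}

#' Call one event: class, posterior, or outlier
#'
#' Implements the cluster-overlap rule: an event is accepted into a class
#' only if it lies within the model's standard-deviation gate of some class
#' cluster. The gate is the chi-square quantile with d degrees of freedom at
#' the two-sided normal level of \code{sd_gate} (3 SD -> 0.9973), applied to
#' squared Mahalanobis distance. If every class is farther than the gate the
#' event is an outlier (unclassifiable); otherwise the nearest class (ties
#' broken by model class order) is called and its posterior computed.
#'
#' @param model a \code{pcalda_model}.
#' @param score length-d discriminant score for one event.
#' @return list with \code{status} ("classified"/"outlier"),
#'   \code{called_class} (or NA), \code{posterior}, \code{passes_threshold}
#'   (strict \code{> prob_threshold}) and \code{d2} (named per-class vector).
#' @export
call_event <- function(model, score) {
  d2 <- mahalanobis_d2(model, score)[1, ]
  gate <- chisq_gate(model$sd_gate, model$d)
  if (min(d2) > gate)
    return(list(status = "outlier", called_class = NA_character_,
                posterior = NA_real_, passes_threshold = NA, d2 = d2))
  called <- model$classes[which.min(d2)]
  post <- class_posterior(model, d2)[1, ]
  list(status = "classified", called_class = called,
       posterior = unname(post[called]),
       passes_threshold = unname(post[called]) > model$prob_threshold,
       d2 = d2)
}

chisq_gate <- function(sd_gate, df) {
  stats::qchisq(2 * stats::pnorm(sd_gate) - 1, df = df)
}

#' Score a whole cohort against a fitted model
#'
#' Applies QC (bad events get no scores), projects the remaining events and
#' calls each one. The result mirrors a blind-test report: expected class,
#' predicted class, status, posterior, duration and TIC per event, with
#' summary counts of total / bad / outlier / classifiable events, where
#' classifiable = total - bad - outlier.
#'
#' @param model a \code{pcalda_model}.
#' @param x an \code{intensity_matrix} binned on the model's grid.
#' @param meta event metadata; defaults to \code{x$meta}. Needs
#'   \code{duration_s} for QC; \code{class_label} (if present) is carried
#'   through as the expected class.
#' @param max_bad_duration_s QC duration threshold in seconds.
#' @return data.frame of class \code{prediction_table} with attribute
#'   \code{"counts"}.
#' @export
classify_cohort <- function(model, x, meta = NULL, max_bad_duration_s = 3) {
  meta <- meta %||% x$meta
  if (is.null(meta)) stopf("event metadata required (duration QC)")
  flags <- qc_flag_bad(meta, max_bad_duration_s)
  pred <- data.frame(
    event_id = meta$event_id,
    specimen_id = meta$specimen_id,
    class_label = meta$class_label %||% NA_character_,
    status = unname(flags),
    predicted_class = NA_character_,
    posterior = NA_real_,
    passes_threshold = NA,
    duration_s = meta$duration_s,
    tic = meta$tic,
    stringsAsFactors = FALSE)
  good <- flags == "good"
  if (any(good)) {
    Z <- project_events(model, subset_events(x, good))
    calls <- lapply(seq_len(nrow(Z)), function(i) call_event(model, Z[i, ]))
    pred$status[good] <- vapply(calls, `[[`, "", "status")
    pred$predicted_class[good] <- vapply(calls, `[[`, "", "called_class")
    pred$posterior[good] <- vapply(calls, `[[`, 0, "posterior")
    pred$passes_threshold[good] <- vapply(calls, function(z)
      isTRUE(z$passes_threshold), NA)
  }
  counts <- list(total = nrow(pred),
                 bad = sum(pred$status == "bad"),
                 outlier = sum(pred$status == "outlier"),
                 classifiable = sum(pred$status == "classified"),
                 below_threshold = sum(pred$status == "classified" &
                                         !pred$passes_threshold,
                                       na.rm = TRUE))
  attr(pred, "counts") <- counts
  class(pred) <- c("prediction_table", "data.frame")
  pred
}

#' Write a prediction table as TSV
#'
#' @param pred a \code{prediction_table}.
#' @param path output path.
#' @param manifest optional manifest filename recorded in a comment header.
#' @return invisibly, \code{path}.
#' @export
write_predictions <- function(pred, path, manifest = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(manifest)) writeLines(paste("# manifest:", manifest), con)
  utils::write.table(as.data.frame(pred), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a prediction table written by [write_predictions()]
#'
#' @param path TSV path.
#' @return a \code{prediction_table}.
#' @export
read_predictions <- function(path) {
  pred <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
  pred$event_id <- as.character(pred$event_id)
  counts <- list(total = nrow(pred),
                 bad = sum(pred$status == "bad"),
                 outlier = sum(pred$status == "outlier"),
                 classifiable = sum(pred$status == "classified"),
                 below_threshold = sum(pred$status == "classified" &
                                         !pred$passes_threshold,
                                       na.rm = TRUE))
  attr(pred, "counts") <- counts
  class(pred) <- c("prediction_table", "data.frame")
  pred
}
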