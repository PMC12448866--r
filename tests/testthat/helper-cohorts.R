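# shared synthetic cohorts, built once per test run
.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cohort_cache[[key]])) assign(key, force(expr), .cohort_cache)
  .cohort_cache[[key]]
}

# simulate, bin, TIC-normalize; returns cohort plus full and good-only
# (bad events removed) matrices
make_cohort <- function(..., seed = 42) {
  coh <- simulate_cohort(sim_config(..., seed = seed))
  m <- tic_normalize(bin_events(coh$peaklists, bin_grid(), coh$meta))
  good <- coh$truth$artifact != "bad"
  list(cohort = coh, m = m, mg = subset_rows(m, good),
       truth = coh$truth, good = good)
}

# row subset helper mirroring the internal used by the CV engine
subset_rows <- function(x, rows) {
  out <- x
  out$values <- x$values[rows, , drop = FALSE]
  if (!is.null(x$meta)) out$meta <- x$meta[rows, , drop = FALSE]
  out$zero_rows <- x$zero_rows[rows]
  out$dropped_peaks <- x$dropped_peaks[rows]
  out
}

# default high-separation desk-scale cohort used across files
high_sep <- function() cached("high_sep", make_cohort(separation = 2))

# a hand-assembled model for closed-form Mahalanobis / posterior oracles
toy_model <- function(centroids, covs, sd_gate = 3, prob_threshold = 0.95) {
  classes <- rownames(centroids)
  names(covs) <- classes
  structure(list(classes = classes, centroids = centroids, covs = covs,
                 d = ncol(centroids), sd_gate = sd_gate,
                 prob_threshold = prob_threshold),
            class = "pcalda_model")
}

# tiny deterministic two-event peak fixture
tiny_peaks <- function() {
  list(
    peaklists = list(
      ev1 = data.frame(mz = c(271.2226, 574.4844, 860.6646),
                       intensity = c(10, 20, 30)),
      ev2 = data.frame(mz = c(150.05, 500.55, 999.95),
                       intensity = c(1, 2, 3))),
    meta = data.frame(event_id = c("ev1", "ev2"),
                      specimen_id = c("sp1", "sp1"),
                      class_label = c("a", "a"),
                      duration_s = c(12, 9), tic = c(60, 6),
                      stringsAsFactors = FALSE))
}
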