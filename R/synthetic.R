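#' Simulation configuration for synthetic cohorts
#'
#' Collects the parameters of the hierarchical generative model used to
#' emulate ambient-MS tumor cohorts. Defaults encode the conditions the
#' profiling study reports: signal duration 13 +/- 2 s, total ion counts
#' (3 +/- 2) x 10^6, ~5% bad acquisitions (duration <= 3 s) and ~3% outlier
#' events, with a desk-scale cohort of 3 classes x 12 specimens x 8 events
#' so that cross-validation and permutation runs finish in seconds.
#'
#' @param classes named integer vector: specimens per class (>= 2 classes for
#'   classification runs).
#' @param events_per_specimen length-2 integer range (inclusive) of sampling
#'   events per specimen.
#' @param separation class-signature separation on the log-abundance scale;
#'   0 gives identical class signatures (a pure null), ~1 a realistic
#'   overlap, >= 2 nearly separable classes.
#' @param n_discriminating number of marker bins on which class signatures
#'   actually differ (the "planted" markers); the remaining marker bins are
#'   shared background chemistry.
#' @param signatures optional per-class signature list from
#'   [default_signatures()]; built automatically when NULL.
#' @param sigma_specimen log-scale SD of the per-specimen (inter-specimen
#'   heterogeneity) random effect on each bin.
#' @param sigma_event log-scale SD of per-event (intratumoral heterogeneity)
#'   multiplicative noise.
#' @param mz_jitter_sd Gaussian m/z jitter SD in Da around each bin center
#'   (small against the 0.1 Da bin width, but enough to exercise bin edges).
#' @param baseline_n number of uninformative background bins shared by all
#'   classes.
#' @param baseline_scale intensity scale of background bins relative to the
#'   marker chemistry.
#' @param tic_mean,tic_sd total ion count distribution (arbitrary units),
#'   truncated below at \code{tic_mean/30}.
#' @param frac_bad proportion of events given duration <= 3 s.
#' @param frac_outlier proportion of events with a class-unrelated profile.
#' @param duration_mean_s,duration_sd_s duration distribution for good
#'   events, in seconds.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(classes = c(meningioma = 12, schwannoma = 12,
                                   metastatic = 12),
                       events_per_specimen = c(8, 8),
                       separation = 1,
                       n_discriminating = NULL,
                       signatures = NULL,
                       sigma_specimen = 0.25,
                       sigma_event = 0.15,
                       mz_jitter_sd = 0.02,
                       baseline_n = 150,
                       baseline_scale = 0.3,
                       tic_mean = 3e6, tic_sd = 2e6,
                       frac_bad = 0.05, frac_outlier = 0.03,
                       duration_mean_s = 13, duration_sd_s = 2,
                       seed = 1) {
  if (length(classes) < 1 || any(classes <= 0) || any(classes != round(classes)))
    stopf("classes must be positive integer specimen counts")
  if (is.null(names(classes)) || anyDuplicated(names(classes)))
    stopf("classes must have unique names")
  if (length(events_per_specimen) == 1)
    events_per_specimen <- rep(events_per_specimen, 2)
  if (any(events_per_specimen <= 0))
    stopf("events_per_specimen must be positive")
  for (p in c(frac_bad, frac_outlier))
    if (p < 0 || p > 1) stopf("proportions must lie in [0, 1]")
  if (any(c(sigma_specimen, sigma_event, mz_jitter_sd, tic_sd,
            duration_sd_s) < 0))
    stopf("all SDs must be >= 0")
  structure(list(classes = classes,
                 events_per_specimen = as.integer(events_per_specimen),
                 separation = separation,
                 n_discriminating = n_discriminating,
                 signatures = signatures,
                 sigma_specimen = sigma_specimen, sigma_event = sigma_event,
                 mz_jitter_sd = mz_jitter_sd,
                 baseline_n = as.integer(baseline_n),
                 baseline_scale = baseline_scale,
                 tic_mean = tic_mean, tic_sd = tic_sd,
                 frac_bad = frac_bad, frac_outlier = frac_outlier,
                 duration_mean_s = duration_mean_s,
                 duration_sd_s = duration_sd_s,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Per-class lipid signatures anchored on the marker array
#'
#' Builds one relative-abundance vector per class over the 41-bin marker
#' array (or any supplied bin list). All classes share a common log-normal
#' base abundance per bin; each class additionally gets an independent
#' Gaussian log-effect of SD \code{separation} on the first
#' \code{n_discriminating} bins, so classes differ in mean profile exactly
#' there. \code{separation = 0} returns identical signatures.
#'
#' @param class_names character vector of class names.
#' @param marker_bins numeric bin labels to anchor signatures on; defaults to
#'   the 41-lipid array.
#' @param separation log-scale SD of the class effect.
#' @param n_discriminating how many of \code{marker_bins} are planted as
#'   discriminating (default: all).
#' @param seed integer seed.
#' @return named list of data.frames (\code{bin}, \code{abundance}), one per
#'   class, with attribute \code{"discriminating_bins"} holding the planted
#'   bin labels.
#' @export
default_signatures <- function(class_names,
                               marker_bins = lipid_marker_array()$bin,
                               separation = 1,
                               n_discriminating = length(marker_bins),
                               seed = 1) {
  n_discriminating <- min(n_discriminating, length(marker_bins))
  set.seed(derive_seed(seed, 11L))
  base <- stats::rnorm(length(marker_bins), mean = 0, sd = 0.75)
  disc <- marker_bins[seq_len(n_discriminating)]
  sigs <- lapply(seq_along(class_names), function(ci) {
    eff <- numeric(length(marker_bins))
    eff[seq_len(n_discriminating)] <-
      stats::rnorm(n_discriminating, 0, 1) * separation
    data.frame(bin = marker_bins, abundance = exp(base + eff))
  })
  names(sigs) <- class_names
  attr(sigs, "discriminating_bins") <- disc
  sigs
}

#' Simulate a synthetic ambient-MS cohort
#'
#' Hierarchical generative model: per class a lipid signature (see
#' [default_signatures()]); per specimen a log-normal random effect per bin
#' (\code{sigma_specimen}); per event log-normal noise (\code{sigma_event});
#' per peak an m/z placed at its bin center plus Gaussian jitter; event
#' intensities scaled to a drawn TIC; duration drawn per event, with a
#' \code{frac_bad} fraction forced to <= 3 s and a \code{frac_outlier}
#' fraction replaced by a class-unrelated uniform profile (so the
#' Mahalanobis outlier gate has something to catch). The same seed yields a
#' byte-identical cohort.
#'
#' @param config a [sim_config()].
#' @return list with \code{peaklists}, \code{meta} (both in the
#'   spectra-io formats) and \code{truth}, a data.frame with per-event
#'   \code{true_class} and \code{artifact} in \{clean, bad, outlier\} plus
#'   attribute \code{"planted_bins"} (the discriminating bin labels).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  grid <- bin_grid()

  sigs <- config$signatures %||%
    default_signatures(names(config$classes),
                       separation = config$separation,
                       n_discriminating = config$n_discriminating %||%
                         nrow(lipid_marker_array()),
                       seed = config$seed)
  marker_bins <- sigs[[1]]$bin

  # shared uninformative background chemistry
  free <- setdiff(seq_len(grid$n), label_index(grid, marker_bins))
  bg_idx <- sort(sample(free, config$baseline_n))
  bg_bins <- grid$labels[bg_idx]
  bg_ab <- exp(stats::rnorm(config$baseline_n, 0, 0.75)) * config$baseline_scale

  all_bins <- c(marker_bins, bg_bins)
  nb <- length(all_bins)

  peaklists <- list()
  meta_rows <- list()
  truth_rows <- list()
  for (cl in names(config$classes)) {
    class_ab <- c(sigs[[cl]]$abundance, bg_ab)
    for (sp in seq_len(config$classes[[cl]])) {
      spec_id <- sprintf("%s_sp%02d", cl, sp)
      spec_eff <- exp(stats::rnorm(nb, 0, config$sigma_specimen))
      n_ev <- if (config$events_per_specimen[1] == config$events_per_specimen[2])
        config$events_per_specimen[1]
      else sample(seq(config$events_per_specimen[1],
                      config$events_per_specimen[2]), 1)
      for (ev in seq_len(n_ev)) {
        ev_id <- sprintf("%s_ev%02d", spec_id, ev)
        outlier <- stats::runif(1) < config$frac_outlier
        bad <- stats::runif(1) < config$frac_bad
        ab <- if (outlier) stats::runif(nb, 0, 1)
        else class_ab * spec_eff * exp(stats::rnorm(nb, 0, config$sigma_event))
        tic <- max(stats::rnorm(1, config$tic_mean, config$tic_sd),
                   config$tic_mean / 30)
        intensity <- ab / sum(ab) * tic
        mz <- all_bins + stats::rnorm(nb, 0, config$mz_jitter_sd)
        mz <- pmin(pmax(mz, grid$lo), grid$hi - 1e-6)
        dur <- if (bad) stats::runif(1, 0.5, 3) else
          max(stats::rnorm(1, config$duration_mean_s, config$duration_sd_s),
              3.5)
        ord <- order(mz)
        peaklists[[ev_id]] <- data.frame(mz = mz[ord],
                                         intensity = intensity[ord])
        meta_rows[[ev_id]] <- data.frame(
          event_id = ev_id, specimen_id = spec_id, class_label = cl,
          duration_s = dur, tic = tic, stringsAsFactors = FALSE)
        truth_rows[[ev_id]] <- data.frame(
          event_id = ev_id, true_class = cl,
          artifact = if (bad) "bad" else if (outlier) "outlier" else "clean",
          stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, meta_rows)
  truth <- do.call(rbind, truth_rows)
  rownames(meta) <- rownames(truth) <- NULL
  attr(truth, "planted_bins") <- attr(sigs, "discriminating_bins")
  list(peaklists = peaklists, meta = meta, truth = truth)
}

#' Read a flat key:value simulation config file
#'
#' The on-disk format is one \code{key: value} pair per line (a strict subset
#' of YAML); vector values are comma-separated, the \code{classes} entry is
#' written \code{name=count} pairs.
#'
#' @param path config file path.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", lines))
  if (any(lengths(kv) != 3))
    stopf("unparseable config line: %s", lines[which(lengths(kv) != 3)[1]])
  vals <- stats::setNames(lapply(kv, `[`, 3), vapply(kv, `[`, "", 2))
  args <- list()
  for (key in names(vals)) {
    v <- vals[[key]]
    if (key == "classes") {
      parts <- strsplit(strsplit(v, ",")[[1]], "=")
      cc <- vapply(parts, function(p) as.integer(trimws(p[2])), 1L)
      names(cc) <- vapply(parts, function(p) trimws(p[1]), "")
      args$classes <- cc
    } else if (key == "events_per_specimen") {
      args[[key]] <- as.integer(strsplit(v, ",")[[1]])
    } else {
      args[[key]] <- as.numeric(v)
    }
  }
  do.call(sim_config, args)
}

#' Write a simulation config in the flat key:value format
#'
#' @param config a [sim_config()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_sim_config <- function(config, path) {
  cls <- paste(sprintf("%s=%d", names(config$classes), config$classes),
               collapse = ",")
  scalar <- c("separation", "sigma_specimen", "sigma_event", "mz_jitter_sd",
              "baseline_n", "baseline_scale", "tic_mean", "tic_sd",
              "frac_bad", "frac_outlier", "duration_mean_s", "duration_sd_s",
              "seed")
  lines <- c(paste("classes:", cls),
             paste("events_per_specimen:",
                   paste(config$events_per_specimen, collapse = ",")),
             vapply(scalar, function(k)
               sprintf("%s: %.15g", k, config[[k]]), ""))
  writeLines(lines, path)
  invisible(path)
}
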