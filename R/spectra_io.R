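#' Read per-event peak lists and event metadata
#'
#' Reads centroided peak lists (one row per peak, columns \code{event_id},
#' \code{mz}, \code{intensity}) and the event metadata table (columns
#' \code{event_id}, \code{specimen_id}, \code{class_label},
#' \code{duration_s}, \code{tic}). Each sampling event is one ~10-second
#' averaged acquisition from one site on a specimen. Peaks are sorted
#' ascending by m/z on read; input order does not matter.
#'
#' @param peaks_path path to the peaks file.
#' @param meta_path path to the metadata file (TSV).
#' @param format \code{"csv"} or \code{"tsv"} for the peaks file.
#' @return list with \code{peaklists} (named list of data.frames with columns
#'   \code{mz}, \code{intensity}, one per event, in metadata order) and
#'   \code{meta} (data.frame of event metadata).
#' @details An event present in the peaks file but missing from the metadata
#'   is a hard error naming the event; a non-numeric \code{mz} or
#'   \code{intensity} is a hard error naming the offending line. Events in
#'   the metadata with no peaks get empty peak lists (all-zero rows after
#'   binning).
#' @export
read_peak_lists <- function(peaks_path, meta_path,
                            format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  if (!file.exists(peaks_path)) stopf("peaks file not found: %s", peaks_path)
  if (!file.exists(meta_path)) stopf("metadata file not found: %s", meta_path)

  raw <- utils::read.table(peaks_path, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character", quote = "\"")
  need <- c("event_id", "mz", "intensity")
  if (!all(need %in% names(raw)))
    stopf("peaks file must have columns %s", paste(need, collapse = ", "))
  mz <- suppressWarnings(as.numeric(raw$mz))
  it <- suppressWarnings(as.numeric(raw$intensity))
  bad_row <- which(is.na(mz) | is.na(it))
  if (length(bad_row))
    stopf("unparseable peak row at data line %d of %s",
          bad_row[1], peaks_path)
  if (any(mz <= 0)) stopf("m/z values must be strictly positive")
  if (any(it < 0)) stopf("intensities must be nonnegative")

  meta <- read_event_meta(meta_path)

  extra <- setdiff(unique(raw$event_id), meta$event_id)
  if (length(extra))
    stopf("event '%s' present in peaks but absent from metadata", extra[1])

  peaks <- data.frame(event_id = raw$event_id, mz = mz, intensity = it,
                      stringsAsFactors = FALSE)
  peaklists <- lapply(meta$event_id, function(ev) {
    p <- peaks[peaks$event_id == ev, c("mz", "intensity"), drop = FALSE]
    p <- p[order(p$mz), , drop = FALSE]
    rownames(p) <- NULL
    p
  })
  names(peaklists) <- meta$event_id
  list(peaklists = peaklists, meta = meta)
}

read_event_meta <- function(meta_path) {
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
  need <- c("event_id", "specimen_id", "class_label", "duration_s", "tic")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stopf("metadata is missing column(s): %s", paste(miss, collapse = ", "))
  meta$event_id <- as.character(meta$event_id)
  meta$specimen_id <- as.character(meta$specimen_id)
  meta$class_label <- as.character(meta$class_label)
  if (anyDuplicated(meta$event_id))
    stopf("duplicate event_id in metadata: %s",
          meta$event_id[duplicated(meta$event_id)][1])
  if (any(is.na(meta$duration_s)) || any(meta$duration_s < 0))
    stopf("duration_s must be present and nonnegative for every event")
  if (any(is.na(meta$tic)) || any(meta$tic < 0))
    stopf("tic must be present and nonnegative for every event")
  meta[need]
}

#' Write peak lists and metadata to disk
#'
#' Inverse of [read_peak_lists()]; writes the long-format peaks table and the
#' metadata TSV.
#'
#' @param peaklists named list of peak data.frames (\code{mz},
#'   \code{intensity}).
#' @param meta event metadata data.frame.
#' @param peaks_path,meta_path output paths.
#' @param format \code{"csv"} or \code{"tsv"} for the peaks file.
#' @return invisibly, the two paths.
#' @export
write_peak_lists <- function(peaklists, meta, peaks_path, meta_path,
                             format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  long <- do.call(rbind, lapply(names(peaklists), function(ev) {
    p <- peaklists[[ev]]
    if (!nrow(p)) return(NULL)
    data.frame(event_id = ev, mz = p$mz, intensity = p$intensity,
               stringsAsFactors = FALSE)
  }))
  if (is.null(long))
    long <- data.frame(event_id = character(), mz = numeric(),
                       intensity = numeric())
  utils::write.table(long, peaks_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  utils::write.table(meta, meta_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(peaks_path, meta_path))
}

#' Construct an intensity matrix container
#'
#' Events-by-bins container used by every downstream stage. Usually produced
#' by [bin_events()]; this constructor also lets tests and the
#' fit-on-scores pathway wrap an arbitrary numeric matrix.
#'
#' @param values numeric matrix, events in rows, features in columns; needs
#'   column names (bin labels) and row names (event ids).
#' @param meta event metadata data.frame aligned with rows (or NULL).
#' @param grid the [bin_grid()] the columns live on (or NULL for free-form
#'   feature matrices such as discriminant scores).
#' @param normalized logical, whether rows are TIC-normalized.
#' @return object of class \code{intensity_matrix}.
#' @export
as_intensity_matrix <- function(values, meta = NULL, grid = NULL,
                                normalized = FALSE) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("ev%04d", seq_len(nrow(values)))
  if (!is.null(meta) && nrow(meta) != nrow(values))
    stopf("meta has %d rows but matrix has %d", nrow(meta), nrow(values))
  structure(list(values = values, meta = meta, grid = grid,
                 normalized = normalized,
                 dropped_peaks = integer(nrow(values)),
                 zero_rows = rowSums(values) == 0),
            class = "intensity_matrix")
}

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("<intensity_matrix> %d events x %d bins%s; %d all-zero row(s)\n",
              nrow(x$values), ncol(x$values),
              if (x$normalized) " (TIC-normalized)" else "",
              sum(x$zero_rows)))
  invisible(x)
}

#' Bin peak lists onto a fixed m/z grid
#'
#' Sums each peak's intensity into the half-open 0.1-Da (by default) bin
#' containing its m/z. Peaks outside \code{[lo, hi)} are dropped and counted
#' per event in the \code{dropped_peaks} element; total in-range intensity is
#' conserved exactly. An empty peak list yields an all-zero row, flagged in
#' \code{zero_rows}, not an error.
#'
#' @param peaklists named list of peak data.frames (\code{mz},
#'   \code{intensity}).
#' @param grid a [bin_grid()].
#' @param meta optional event metadata (rows reordered to metadata order).
#' @return an \code{intensity_matrix} (see [as_intensity_matrix()]).
#' @export
bin_events <- function(peaklists, grid = bin_grid(), meta = NULL) {
  ids <- if (!is.null(meta)) meta$event_id else names(peaklists)
  if (is.null(ids)) stopf("peaklists must be named by event_id")
  # metadata-only events (no peaks) are legitimate empty acquisitions
  vals <- matrix(0, nrow = length(ids), ncol = grid$n,
                 dimnames = list(ids, grid$label_chr))
  dropped <- integer(length(ids))
  for (i in seq_along(ids)) {
    p <- peaklists[[ids[i]]]
    if (is.null(p) || !nrow(p)) next
    idx <- bin_index(grid, p$mz)
    keep <- !is.na(idx)
    dropped[i] <- sum(!keep)
    if (any(keep)) {
      agg <- rowsum(p$intensity[keep], idx[keep])
      vals[i, as.integer(rownames(agg))] <- agg[, 1]
    }
  }
  out <- as_intensity_matrix(vals, meta = meta, grid = grid)
  out$dropped_peaks <- stats::setNames(dropped, ids)
  out
}

#' Total-ion-count normalization
#'
#' Divides every nonzero row by its own sum so that each spectrum becomes a
#' relative-abundance profile summing to 1. Ambient-MS TIC varies by an order
#' of magnitude between sampling events, so this is the minimal correction
#' applied before multivariate modeling. All-zero rows are left untouched and
#' remain flagged.
#'
#' @param x an \code{intensity_matrix}.
#' @return the normalized \code{intensity_matrix}.
#' @export
tic_normalize <- function(x) {
  stopifnot(inherits(x, "intensity_matrix"))
  rs <- rowSums(x$values)
  nz <- rs > 0
  x$values[nz, ] <- x$values[nz, , drop = FALSE] / rs[nz]
  x$normalized <- TRUE
  x$zero_rows <- !nz
  x
}

#' Flag bad sampling events by signal duration
#'
#' An acquisition with signal duration less than or equal to the threshold
#' (default 3 seconds) is "bad" data: it is excluded from model fitting and
#' from every accuracy, sensitivity and specificity denominator, since no
#' clinical call would be made from it. The boundary is inclusive: exactly
#' 3 s is bad.
#'
#' @param meta event metadata with a \code{duration_s} column.
#' @param max_bad_duration_s inclusive duration threshold in seconds.
#' @return character vector, \code{"good"} or \code{"bad"}, named by event.
#' @export
qc_flag_bad <- function(meta, max_bad_duration_s = 3) {
  if (any(is.na(meta$duration_s)))
    stopf("duration_s missing for some events")
  if (any(meta$duration_s < 0)) stopf("negative duration_s")
  stats::setNames(ifelse(meta$duration_s <= max_bad_duration_s, "bad", "good"),
                  meta$event_id)
}

#' Persist a binned intensity matrix as TSV plus a grid sidecar
#'
#' @param x an \code{intensity_matrix} on a real bin grid.
#' @param path output TSV path; the grid (and normalization flag) goes to
#'   \code{paste0(path, ".grid.json")}.
#' @param manifest optional manifest filename recorded in a comment header.
#' @return invisibly, \code{path}.
#' @export
write_intensity_matrix <- function(x, path, manifest = NULL) {
  stopifnot(inherits(x, "intensity_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(manifest)) writeLines(paste("# manifest:", manifest), con)
  df <- data.frame(event_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(lo = x$grid$lo, hi = x$grid$hi, width = x$grid$width,
               normalized = x$normalized)
  if (!is.null(x$meta)) side$meta <- x$meta
  jsonlite::write_json(side, paste0(path, ".grid.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read an intensity matrix written by [write_intensity_matrix()]
#'
#' @param path TSV path (expects the \code{.grid.json} sidecar next to it).
#' @return an \code{intensity_matrix}.
#' @export
read_intensity_matrix <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".grid.json"),
                              simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$event_id
  meta <- if (!is.null(side$meta)) as.data.frame(side$meta) else NULL
  as_intensity_matrix(vals, meta = meta,
                      grid = bin_grid(side$lo, side$hi, side$width),
                      normalized = isTRUE(side$normalized))
}
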