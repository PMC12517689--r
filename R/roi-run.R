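#' Construct a regional time-series run
#'
#' An `roi_run` bundles one scanning run's region-by-time matrix with its
#' acquisition metadata (subject, condition, montage, stimulation phase, run
#' id) and the repetition time. It is the unit of analysis throughout the
#' package: runs are conditioned with [regress_global_signal()],
#' [temporal_filter()] and [zscore_run()], and converted to instantaneous
#' phases with [analytic_phase()].
#'
#' @param values numeric matrix, regions in rows, time points in columns.
#' @param roi_names character vector of unique region identifiers; defaults
#'   to `ROI001`, `ROI002`, ...
#' @param tr_seconds repetition time (sampling interval) in seconds.
#' @param metadata named list; recognised entries are `run_id`, `subject`,
#'   `condition`, `montage`, `stim_phase`. Free-form extras are kept.
#' @return an object of class `roi_run`.
#' @export
roi_run <- function(values, roi_names = NULL, tr_seconds, metadata = list()) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_invalid("values must be a numeric matrix (regions x time)")
  }
  if (nrow(values) < 2L) stop_invalid("an roi_run needs at least 2 regions")
  if (ncol(values) < 3L) stop_invalid("an roi_run needs at least 3 time points")
  if (anyNA(values) || any(!is.finite(values))) {
    stop_invalid("values must be finite with no missing entries")
  }
  if (is.null(roi_names)) {
    roi_names <- sprintf("ROI%03d", seq_len(nrow(values)))
  }
  if (length(roi_names) != nrow(values) || anyDuplicated(roi_names)) {
    stop_invalid("roi_names must be unique and match the number of rows")
  }
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop_invalid("tr_seconds must be a positive scalar")
  }
  rownames(values) <- roi_names
  structure(
    list(values = values, roi_names = as.character(roi_names),
         tr_seconds = as.numeric(tr_seconds), metadata = metadata),
    class = "roi_run")
}

#' @export
print.roi_run <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<roi_run> %d regions x %d volumes, TR %.3g s\n",
              nrow(x$values), ncol(x$values), x$tr_seconds))
  if (length(md)) {
    keys <- intersect(c("run_id", "subject", "condition", "montage",
                        "stim_phase"), names(md))
    for (k in keys) cat(sprintf("  %s: %s\n", k, as.character(md[[k]])))
  }
  invisible(x)
}

#' @export
print.phase_run <- function(x, ...) {
  cat(sprintf("<phase_run> %d regions x %d retained volumes (edges trimmed)\n",
              nrow(x$phases), ncol(x$phases)))
  invisible(x)
}

new_phase_run <- function(phases, amplitudes, roi_names, tr_seconds,
                          metadata, tr_index) {
  structure(
    list(phases = phases, amplitudes = amplitudes,
         roi_names = roi_names, tr_seconds = tr_seconds,
         metadata = metadata, tr_index = tr_index),
    class = "phase_run")
}

run_id_of <- function(run, default) {
  id <- run$metadata$run_id
  if (is.null(id)) default else as.character(id)
}

#' Read and write regional runs as delimited text
#'
#' Runs are stored one file per run as tab-separated text: a header row of
#' volume indices and a first column of region names. A study directory pairs
#' these files with a JSON `manifest.json` recording per-run metadata and the
#' repetition time (see [write_study()]).
#'
#' @param run an [roi_run()].
#' @param path file path.
#' @return `write_run()` returns `path` invisibly; `read_run()` an `roi_run`
#'   (metadata must be supplied separately or through a study manifest).
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "roi_run"))
  df <- data.frame(roi = run$roi_names, run$values, check.names = FALSE)
  colnames(df) <- c("roi", seq_len(ncol(run$values)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_run
#' @param tr_seconds repetition time to attach to the run read back.
#' @param metadata metadata list to attach.
#' @export
read_run <- function(path, tr_seconds, metadata = list()) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  roi_run(values, roi_names = as.character(df[[1]]),
          tr_seconds = tr_seconds, metadata = metadata)
}

#' Persist or load a whole synthetic/empirical study
#'
#' `write_study()` writes one delimited-text matrix per run plus a JSON
#' manifest (run id, subject, condition, montage, stimulation phase, TR,
#' generator seed); `read_study()` reconstructs the list of runs from the
#' manifest.
#'
#' @param runs list of [roi_run()] objects.
#' @param dir output directory, created if needed.
#' @param connectome optional structural matrix written as `connectome.tsv`.
#' @param seed optional generator seed recorded in the manifest.
#' @return `write_study()` the directory invisibly; `read_study()` a list
#'   with elements `runs` and (if present) `connectome`.
#' @export
write_study <- function(runs, dir, connectome = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- vector("list", length(runs))
  for (i in seq_along(runs)) {
    id <- run_id_of(runs[[i]], sprintf("run%03d", i))
    file <- sprintf("%s.tsv", id)
    write_run(runs[[i]], file.path(dir, file))
    md <- runs[[i]]$metadata
    entries[[i]] <- list(
      run_id = id, file = file,
      subject = md$subject, condition = md$condition,
      montage = md$montage, stim_phase = md$stim_phase,
      tr_seconds = runs[[i]]$tr_seconds)
  }
  manifest <- list(runs = entries, seed = seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(connectome)) {
    write_connectome(connectome, file.path(dir, "connectome.tsv"))
  }
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  runs <- lapply(manifest$runs, function(e) {
    md <- e[setdiff(names(e), c("file", "tr_seconds"))]
    read_run(file.path(dir, e$file), tr_seconds = e$tr_seconds, metadata = md)
  })
  out <- list(runs = runs)
  cpath <- file.path(dir, "connectome.tsv")
  if (file.exists(cpath)) out$connectome <- read_connectome(cpath)
  out
}

#' Read and write a structural connectome as square delimited text
#'
#' @param connectome symmetric non-negative numeric matrix with region names.
#' @param path file path.
#' @export
write_connectome <- function(connectome, path) {
  check_square(connectome, "connectome")
  if (is.null(rownames(connectome))) {
    rownames(connectome) <- colnames(connectome) <-
      sprintf("ROI%03d", seq_len(nrow(connectome)))
  }
  df <- data.frame(roi = rownames(connectome), connectome,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  colnames(m) <- rownames(m)
  m
}
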