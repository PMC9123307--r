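# Plain-text I/O: traces as (time_s, value) CSV, sweep amplitude tables,
# long-format group tables.

#' Write a sampled trace as CSV
#'
#' Two columns, `time_s` and `value`.
#'
#' @param trace numeric samples.
#' @param fs_hz sampling rate.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(trace, fs_hz, path) {
  check_number(fs_hz, "fs_hz", lower = 0, strict_lower = TRUE)
  write.csv(data.frame(time_s = (seq_along(trace) - 1) / fs_hz,
                       value = trace),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a sampled trace from CSV
#'
#' @param path CSV with columns `time_s`, `value`.
#' @return list with `trace` and the inferred `fs_hz`.
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path))
    abort(sprintf("trace file not found: %s", path), "synq_io_error")
  d <- read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    abort("trace CSV must have columns time_s and value", "synq_validation_error",
          field = setdiff(c("time_s", "value"), names(d))[1])
  if (nrow(d) < 2L) abort("trace CSV too short", "synq_validation_error")
  list(trace = d$value, fs_hz = 1 / median(diff(d$time_s)))
}

#' Write a train recording as a sweep table CSV
#'
#' One row per sweep: columns `stim_001` ... `stim_NNN`, plus `rs_mohm` and
#' `has_ap`.
#'
#' @param recording a [train_recording()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_train_csv <- function(recording, path) {
  stopifnot(inherits(recording, "train_recording"))
  amp <- as.data.frame(recording$amplitudes)
  names(amp) <- sprintf("stim_%03d", seq_len(recording$n_pulses))
  amp$rs_mohm <- recording$rs_mohm
  amp$has_ap <- recording$has_ap
  write.csv(amp, path, row.names = FALSE)
  invisible(path)
}

#' Read a train recording from a sweep table CSV
#'
#' @param path CSV produced by [write_train_csv()] (or matching its layout).
#' @param rate_hz stimulation rate (not stored in the table; default 20).
#' @return a [train_recording()].
#' @export
read_train_csv <- function(path, rate_hz = 20) {
  if (!file.exists(path))
    abort(sprintf("sweep table not found: %s", path), "synq_io_error")
  d <- read.csv(path)
  stim_cols <- grep("^stim_[0-9]+$", names(d), value = TRUE)
  if (!length(stim_cols))
    abort("sweep table has no stim_NNN columns", "synq_validation_error",
          field = "stim_001")
  stim_cols <- stim_cols[order(as.integer(sub("stim_", "", stim_cols)))]
  train_recording(as.matrix(d[stim_cols]), rate_hz = rate_hz,
                  rs_mohm = if (is.null(d$rs_mohm)) 15 else d$rs_mohm,
                  has_ap = if (is.null(d$has_ap)) FALSE else d$has_ap)
}

#' Read a long-format two-group table
#'
#' @param path CSV with columns `value`, `group` (exactly two levels) and
#'   optionally `unit`.
#' @return list with `group1`, `group2`, `labels`, `units`.
#' @export
read_groups_csv <- function(path) {
  if (!file.exists(path))
    abort(sprintf("group table not found: %s", path), "synq_io_error")
  d <- read.csv(path)
  for (col in c("value", "group"))
    if (is.null(d[[col]]))
      abort(sprintf("group table is missing column `%s`", col),
            "synq_validation_error", field = col)
  if (!is.numeric(d$value))
    abort("column `value` must be numeric", "synq_validation_error",
          field = "value")
  lv <- unique(d$group)
  if (length(lv) != 2L)
    abort("column `group` must have exactly two levels", "synq_validation_error",
          field = "group")
  list(group1 = d$value[d$group == lv[1]], group2 = d$value[d$group == lv[2]],
       labels = as.character(lv),
       units = if (is.null(d$unit)) "" else as.character(d$unit[1]))
}
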