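# write a tibble as CSV, preceded by "# key: value" provenance lines
write_csv_with_header <- function(df, path, provenance = NULL) {
  body <- sub("\\n$", "", readr::format_csv(df))
  header <- if (is.null(provenance))
    character(0) else sprintf("# %s: %s", names(provenance), provenance)
  writeLines(c(header, strsplit(body, "\n")[[1]]), path)
  invisible(path)
}

trial_log_cols <- c("animal_id", "group", "phase_label", "task_kind",
                    "session_index", "trial_index", "left_stim",
                    "right_stim", "chosen_stim", "chosen_side", "rewarded",
                    "response_time_s", "aborted_session", "intertrial_s")

#' Read and validate a trial-log CSV
#'
#' The schema is that of [simulate_task_battery()]. Validation rejects
#' missing columns, invalid side/abort enumerations, non-increasing trial
#' indices within a session, and inconsistent reward mapping (the same
#' stimulus both rewarded and unrewarded within one phase), reporting row
#' numbers.
#'
#' @param path CSV file path. Lines starting with `#` are treated as a
#'   provenance header and skipped.
#' @return A validated trial-log tibble.
#' @export
read_trial_log <- function(path) {
  log <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  validate_trial_log(log)
  log
}

#' @rdname read_trial_log
#' @param records Trial-log tibble to write.
#' @param provenance Optional named character vector written as `# key: value`
#'   header lines.
#' @export
write_trial_log <- function(records, path, provenance = NULL) {
  validate_trial_log(records)
  write_csv_with_header(records, path, provenance)
}

validate_trial_log <- function(log) {
  miss <- setdiff(trial_log_cols, names(log))
  if (length(miss) > 0)
    stop("trial log missing columns: ", paste(miss, collapse = ", "))
  if (nrow(log) == 0) return(invisible(log))
  bad_side <- which(!(log$chosen_side %in% c("left", "right") |
                        is.na(log$chosen_side)))
  if (length(bad_side) > 0)
    stop("invalid chosen_side at row(s) ",
         paste(utils::head(bad_side, 5), collapse = ", "))
  bad_ab <- which(!log$aborted_session %in% c(0, 1))
  if (length(bad_ab) > 0)
    stop("invalid aborted_session at row(s) ",
         paste(utils::head(bad_ab, 5), collapse = ", "))
  key <- paste(log$animal_id, log$phase_label, log$session_index, sep = "\r")
  for (k in unique(key)) {
    ti <- log$trial_index[key == k]
    if (any(diff(ti) <= 0)) {
      row <- which(key == k)[which(diff(ti) <= 0)[1] + 1]
      stop("non-increasing trial_index at row ", row)
    }
  }
  # reward-map consistency: within a phase a stimulus is either rewarded or
  # not; the same chosen_stim may not carry both outcomes
  pk <- paste(log$animal_id, log$phase_label, sep = "\r")
  done <- !is.na(log$rewarded) & !is.na(log$chosen_stim)
  tab <- unique(data.frame(pk = pk[done], stim = log$chosen_stim[done],
                           rewarded = log$rewarded[done]))
  dup <- duplicated(tab[, c("pk", "stim")])
  if (any(dup)) {
    bad <- tab[dup, ][1, ]
    row <- which(pk == bad$pk & log$chosen_stim == bad$stim &
                   log$rewarded == bad$rewarded & done)[1]
    stop("inconsistent reward mapping for stimulus '", bad$stim,
         "' (row ", row, ")")
  }
  invisible(log)
}

#' Read/write a time-activity curve CSV
#'
#' Columns `frame_start_s`, `frame_duration_s`, `concentration_kBq_per_mL`.
#'
#' @param path CSV path.
#' @return A [tac()].
#' @export
read_tac <- function(path) {
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  need <- c("frame_start_s", "frame_duration_s", "concentration_kBq_per_mL")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0)
    stop("TAC file missing columns: ", paste(miss, collapse = ", "))
  tac(x$frame_duration_s, x$concentration_kBq_per_mL, x$frame_start_s)
}

#' @rdname read_tac
#' @param x A [tac()] to write.
#' @param provenance Optional named character vector of header lines.
#' @export
write_tac <- function(x, path, provenance = NULL) {
  write_csv_with_header(tibble::as_tibble(x), path, provenance)
}

#' Read/write NIfTI volumes
#'
#' Thin wrappers over RNifti preserving the data array, voxel sizes and
#' affine. Images are written as 64-bit floats so round trips are
#' bit-identical.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return For `read_volume`, an array with RNifti attributes.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  img
}

#' @rdname read_volume
#' @param image Numeric array (3D or 4D).
#' @param voxel_size_mm Voxel edge lengths (mm), recycled to the spatial
#'   dimensions.
#' @export
write_volume <- function(image, path, voxel_size_mm = 0.7) {
  vs <- rep(voxel_size_mm, length.out = 3)
  img <- RNifti::asNifti(unclass(image))
  RNifti::pixdim(img) <- vs
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read/write an actigraphy CSV
#'
#' Columns `timestamp` (ISO 8601, stored as UTC) and `counts`.
#'
#' @param path CSV path.
#' @param lights_on,lights_off Light schedule attached to the series.
#' @return An [activity_series()].
#' @export
read_actigraphy <- function(path, lights_on = 7, lights_off = 19) {
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  if (!all(c("timestamp", "counts") %in% names(x)))
    stop("actigraphy file needs columns timestamp, counts")
  ts <- as.POSIXct(x$timestamp, tz = "UTC")
  activity_series(ts, x$counts, lights_on, lights_off)
}

#' @rdname read_actigraphy
#' @param series An [activity_series()] to write.
#' @param provenance Optional named character vector of header lines.
#' @export
write_actigraphy <- function(series, path, provenance = NULL) {
  out <- tibble::tibble(
    timestamp = format(series$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    counts = series$counts)
  write_csv_with_header(out, path, provenance)
}
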