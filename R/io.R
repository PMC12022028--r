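## Trial-table CSV input/output.

.trial_cols <- c("observer", "session", "condition", "center_dir_deg",
                 "surround_moving", "n_surround_patches", "report_deg")

.trial_cols_extra <- c("inner_offset_deg", "report_target")

#' Read a trial table from CSV
#'
#' Expects the header
#' `observer,session,condition,center_dir_deg,surround_moving,n_surround_patches,report_deg`.
#' The three-element design variant may add `inner_offset_deg,report_target`,
#' which are preserved when present. Rows with non-finite numerics or reports
#' outside `[0, 360)` are rejected; rejected rows are collected (with
#' reasons) in the attribute `"rejected"`.
#'
#' @param path CSV file path.
#' @return validated trial table (data frame).
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(.trial_cols, names(df))
  if (length(missing))
    stop("trial file is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, c(.trial_cols, intersect(.trial_cols_extra, names(df)))]
  df$surround_moving <- as.logical(df$surround_moving)
  reasons <- character(nrow(df))
  bad <- rep(FALSE, nrow(df))
  num_ok <- is.finite(df$report_deg) & is.finite(df$center_dir_deg) &
    is.finite(df$n_surround_patches) & !is.na(df$surround_moving)
  reasons[!num_ok] <- "non-finite or missing field"
  bad <- bad | !num_ok
  range_bad <- num_ok & (df$report_deg < 0 | df$report_deg >= 360)
  reasons[range_bad] <- "report_deg outside [0, 360)"
  bad <- bad | range_bad
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  if (any(bad)) {
    rej <- df[bad, , drop = FALSE]
    rej$reason <- reasons[bad]
    attr(out, "rejected") <- rej
    warning(sprintf("%d malformed row(s) rejected; see attr(., 'rejected')",
                    sum(bad)))
  }
  out
}

#' Write a trial table to CSV
#'
#' Deterministic column order matching the [read_trials()] schema; an empty
#' table produces a header-only file.
#'
#' @param data trial table.
#' @param path output path.
#' @export
write_trials <- function(data, path) {
  missing <- setdiff(.trial_cols, names(data))
  if (length(missing))
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  cols <- c(.trial_cols, intersect(.trial_cols_extra, names(data)))
  utils::write.csv(data[, cols, drop = FALSE], path,
                   row.names = FALSE, fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}
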