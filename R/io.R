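# Export helpers: NIfTI volumes/series, BIDS-style events, report tables.

#' Write a 3D map or 4D series as NIfTI
#'
#' @param x A [ts_image], `gfactor_map`, or plain 3D/4D array.
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param voxel_size_mm Voxel dimensions in mm.
#' @param tr_s Repetition time for 4D data (taken from a `ts_image`).
#' @return The path, invisibly.
#' @export
write_nifti_map <- function(x, path, voxel_size_mm = c(3, 3, 3),
                            tr_s = NULL) {
  if (inherits(x, "ts_image")) {
    tr_s <- tr_s %||% x$tr_s
    x <- x$data
  } else if (inherits(x, "gfactor_map")) {
    x <- x$g
  }
  img <- RNifti::asNifti(x)
  pd <- c(voxel_size_mm, tr_s %||% 1)[seq_len(length(dim(x)))]
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a stimulus schedule as a BIDS-style events TSV
#'
#' Columns `onset`, `duration`, `trial_type`.
#'
#' @param schedule A `stim_schedule`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_events_tsv <- function(schedule, path) {
  ev <- data.frame(onset = schedule$blocks$onset,
                   duration = schedule$blocks$duration,
                   trial_type = schedule$blocks$condition)
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a sensitivity report as TSV plus JSON
#'
#' @param report A `sensitivity_report` from [run_factorial()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_sensitivity_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$metrics, file.path(dir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(report$tables))
    utils::write.table(report$tables[[nm]],
                       file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(metrics = report$metrics, tables = report$tables),
                       file.path(dir, "report.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
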