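# On-disk formats. One recording = paired CSV files plus a JSON metadata
# sidecar; numbers are written with 17 significant digits so write/read
# round-trips are bit-exact. Models serialize to a single JSON file.

write_matrix_csv <- function(mat, path, colnames) {
  df <- as.data.frame(mat)
  names(df) <- colnames
  df[] <- lapply(df, format_full_precision)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  as.matrix(vapply(df, as.numeric, numeric(nrow(df))))
}

#' Write a recording to disk
#'
#' Stores one trial as `<stem>_emg.csv` (N x 6), `<stem>_position.csv`
#' (M x 3, cm) and `<stem>_meta.json` (sample rates and trial metadata).
#'
#' @param rec An `emg_recording`.
#' @param dir Output directory (created if missing).
#' @param stem File-name stem; default derived from the metadata.
#' @return The stem path, invisibly.
#' @export
write_recording <- function(rec, dir, stem = NULL) {
  if (!inherits(rec, "emg_recording")) {
    stop_emg("`rec` must be an emg_recording.", "emgdecode_input_error")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  md <- rec$metadata
  if (is.null(stem)) {
    stem <- sprintf("%s_%s_trial%02d", md$task_id, md$speed, md$trial_index)
  }
  base <- file.path(dir, stem)
  write_matrix_csv(rec$emg, paste0(base, "_emg.csv"), paste0("ch", 1:6))
  write_matrix_csv(rec$position, paste0(base, "_position.csv"),
                   c("x", "y", "z"))
  meta <- c(md, list(fs_emg = rec$fs_emg, fs_pos = rec$fs_pos))
  jsonlite::write_json(meta, paste0(base, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(base)
}

#' Read a recording from disk
#'
#' @param stem Path stem as returned by [write_recording()] (without the
#'   `_emg.csv` suffix).
#' @return An `emg_recording`.
#' @export
read_recording <- function(stem) {
  paths <- paste0(stem, c("_emg.csv", "_position.csv", "_meta.json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop_emg(sprintf("Recording file(s) missing: %s.",
                     paste(basename(missing), collapse = ", ")),
             "emgdecode_schema_error")
  }
  meta <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  emg <- read_matrix_csv(paths[1])
  pos <- read_matrix_csv(paths[2])
  if (ncol(emg) != 6L || ncol(pos) != 3L) {
    stop_emg("Recording files have unexpected column counts.",
             "emgdecode_schema_error")
  }
  fs_emg <- meta$fs_emg %||% 1000
  fs_pos <- meta$fs_pos %||% 60
  meta$fs_emg <- NULL
  meta$fs_pos <- NULL
  structure(
    list(emg = emg, position = pos, fs_emg = fs_emg, fs_pos = fs_pos,
         metadata = meta),
    class = "emg_recording"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a feature matrix to CSV
#'
#' @param features Tibble from [build_feature_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(features, path) {
  write_matrix_csv(as.matrix(features), path, names(features))
  invisible(path)
}

#' Read a feature matrix CSV
#'
#' @param path CSV written by [write_feature_matrix()].
#' @return Tibble with `t_ms` plus feature columns.
#' @export
read_feature_matrix <- function(path) {
  tibble::as_tibble(as.data.frame(read_matrix_csv(path)))
}

#' Serialize a fitted RFNN to JSON
#'
#' Centers, widths, recurrent ratios, weights, normalizers, training
#' history and the learning configuration are stored losslessly in a
#' single JSON file.
#'
#' @param model A fitted `rfnn`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rfnn <- function(model, path) {
  payload <- list(
    m = model$m, sigma = model$sigma, lambda = model$lambda, w = model$w,
    norm_x = model$norm_x, norm_y = model$norm_y,
    config = unclass(model$config), history = model$history
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a fitted RFNN from JSON
#'
#' @param path File written by [write_rfnn()].
#' @return An `rfnn`.
#' @export
read_rfnn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(rfnn_config, p$config[names(p$config) %in%
                                         names(formals(rfnn_config))])
  new_rfnn(as.matrix(p$m), as.matrix(p$sigma), as.numeric(p$lambda),
           as.matrix(p$w),
           lapply(p$norm_x, as.numeric), lapply(p$norm_y, as.numeric),
           cfg, history = as.numeric(p$history))
}
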