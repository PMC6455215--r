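#' Write a recording to a directory container
#'
#' The container is a `meta.json` sidecar (sampling rate, grid geometry,
#' montage, units, storage layout) plus the signal as either row-major
#' float32 binary (`signal.f32`) or tab-separated text (`signal.tsv`, one
#' column per channel).
#'
#' @param rec An [emg_recording()].
#' @param dir Output directory (created if needed).
#' @param format `"f32"` or `"tsv"`.
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir, format = c("f32", "tsv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    fs_hz = rec$fs_hz,
    rows = rec$grid$rows, cols = rec$grid$cols, ied_mm = rec$grid$ied_mm,
    montage = rec$montage, units = "a.u.",
    channels = nrow(rec$data), samples = ncol(rec$data),
    storage = format, layout = "row_major_channels_x_samples"
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (format == "f32") {
    con <- file(file.path(dir, "signal.f32"), "wb")
    on.exit(close(con))
    writeBin(as.numeric(t(rec$data)), con, size = 4)
  } else {
    utils::write.table(t(rec$data), file.path(dir, "signal.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a recording container written by [write_recording()]
#'
#' @param dir Container directory.
#' @return An [emg_recording()].
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  grid <- electrode_grid(meta$rows, meta$cols, meta$ied_mm, meta$fs_hz)
  if (identical(meta$storage, "f32")) {
    con <- file(file.path(dir, "signal.f32"), "rb")
    on.exit(close(con))
    n <- meta$channels * meta$samples
    x <- readBin(con, numeric(), n = n, size = 4)
    data <- matrix(x, nrow = meta$channels, byrow = TRUE)
  } else {
    data <- t(as.matrix(utils::read.table(file.path(dir, "signal.tsv"),
                                          sep = "\t")))
  }
  dimnames(data) <- NULL
  emg_recording(data, meta$fs_hz, grid, meta$montage)
}

#' Write firing times as tab-separated text
#'
#' Two columns, `mu_id` and `firing_time_s`, sorted by time.
#'
#' @param firings Tibble with `mu_id` and `time_s` columns, or a
#'   `ground_truth`, or a `gss_decomposition`.
#' @param path Output file.
#' @export
write_firings_tsv <- function(firings, path) {
  if (inherits(firings, "ground_truth")) firings <- firings$firings
  if (inherits(firings, "gss_decomposition")) firings <- tidy(firings)
  df <- data.frame(mu_id = firings$mu_id, firing_time_s = firings$time_s)
  df <- df[order(df$firing_time_s), ]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a firing-times TSV
#'
#' @param path File written by [write_firings_tsv()].
#' @return Tibble with `mu_id`, `time_s`.
#' @export
read_firings_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  tibble::tibble(mu_id = df$mu_id, time_s = df$firing_time_s)
}
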