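#' Electrode grid geometry
#'
#' Describes the rectangular HD-sEMG electrode grid. `rows` counts electrodes
#' along the muscle-fiber direction (the direction of action-potential
#' propagation and of single-differential derivation), `cols` across it.
#'
#' @param rows Number of electrodes along the fiber direction.
#' @param cols Number of electrodes across the fiber direction.
#' @param ied_mm Inter-electrode distance in millimetres (same in both
#'   directions).
#' @param fs_hz Sampling rate in Hz.
#' @return An object of class `electrode_grid`.
#' @examples
#' grid_full <- electrode_grid(rows = 10, cols = 9)
#' n_electrodes(grid_full)
#' @export
electrode_grid <- function(rows = 10, cols = 9, ied_mm = 5, fs_hz = 4096) {
  stopifnot(rows >= 1, cols >= 1, ied_mm > 0, fs_hz > 0)
  structure(
    list(rows = as.integer(rows), cols = as.integer(cols),
         ied_mm = ied_mm, fs_hz = fs_hz),
    class = "electrode_grid"
  )
}

#' @rdname electrode_grid
#' @param grid An `electrode_grid`.
#' @export
n_electrodes <- function(grid) grid$rows * grid$cols

#' Electrode positions in millimetres
#'
#' Channel ordering is column-major: channel index `(c - 1) * rows + r` for
#' column `c` and row `r`. `y` runs along the fiber direction and is centered
#' on the grid; `x` runs across fibers, also centered.
#'
#' @param grid An `electrode_grid`.
#' @return A tibble with columns `channel`, `row`, `col`, `x_mm`, `y_mm`.
#' @export
electrode_positions <- function(grid) {
  r <- rep(seq_len(grid$rows), times = grid$cols)
  c_ <- rep(seq_len(grid$cols), each = grid$rows)
  tibble::tibble(
    channel = seq_len(grid$rows * grid$cols),
    row = r, col = c_,
    x_mm = (c_ - (grid$cols + 1) / 2) * grid$ied_mm,
    y_mm = (r - (grid$rows + 1) / 2) * grid$ied_mm
  )
}

#' @export
print.electrode_grid <- function(x, ...) {
  cat(sprintf("<electrode_grid> %d x %d, ied %.1f mm, fs %.0f Hz\n",
              x$rows, x$cols, x$ied_mm, x$fs_hz))
  invisible(x)
}

#' Multichannel surface EMG recording
#'
#' A thin container for a channels-by-samples signal matrix plus its sampling
#' rate, grid geometry, and montage.
#'
#' @param data Numeric matrix, channels x samples.
#' @param fs_hz Sampling rate in Hz.
#' @param grid An [electrode_grid()].
#' @param montage `"monopolar"` or `"single_differential"`.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(data, fs_hz, grid,
                          montage = c("monopolar", "single_differential")) {
  montage <- match.arg(montage)
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("EMG data must be finite")
  expected <- switch(montage,
    monopolar = n_electrodes(grid),
    single_differential = (grid$rows - 1L) * grid$cols
  )
  if (nrow(data) != expected) {
    stop(sprintf("expected %d channels for %s montage, got %d",
                 expected, montage, nrow(data)))
  }
  structure(
    list(data = data, fs_hz = fs_hz, grid = grid, montage = montage),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d ch x %d samples (%.2f s @ %.0f Hz), %s\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$fs_hz,
              x$fs_hz, x$montage))
  invisible(x)
}

#' @export
dim.emg_recording <- function(x) dim(x$data)

duration_s <- function(rec) ncol(rec$data) / rec$fs_hz
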