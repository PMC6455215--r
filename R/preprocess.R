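#' Zero-phase band-pass filtering
#'
#' First-order Butterworth band-pass applied forward and backward
#' (zero-phase) to every channel.
#'
#' @param rec An [emg_recording()].
#' @param low,high Cut-off frequencies in Hz.
#' @return The filtered recording.
#' @export
bandpass <- function(rec, low = 20, high = 500) {
  if (rec$fs_hz <= 2 * high) {
    stop("sampling rate must exceed twice the upper cut-off")
  }
  bf <- signal::butter(1, c(low, high) / (rec$fs_hz / 2), type = "pass")
  out <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  emg_recording(out, rec$fs_hz, rec$grid, rec$montage)
}

#' Single-differential montage
#'
#' Differences of adjacent electrodes along the fiber (row) direction within
#' each column: `out[r, c] = in[r + 1, c] - in[r, c]`, giving
#' `(rows - 1) * cols` channels. Suppresses common-mode components.
#'
#' @param rec A monopolar [emg_recording()].
#' @return A single-differential recording.
#' @export
make_single_differential <- function(rec) {
  if (rec$montage != "monopolar") stop("recording is already differential")
  g <- rec$grid
  idx <- matrix(seq_len(n_electrodes(g)), nrow = g$rows)  # column-major
  out <- matrix(0, (g$rows - 1L) * g$cols, ncol(rec$data))
  k <- 0L
  for (c_ in seq_len(g$cols)) {
    for (r in seq_len(g$rows - 1L)) {
      k <- k + 1L
      out[k, ] <- rec$data[idx[r + 1L, c_], ] - rec$data[idx[r, c_], ]
    }
  }
  emg_recording(out, rec$fs_hz, g, "single_differential")
}

#' Extend an observation with delayed repetitions
#'
#' Stacks `R` delayed repetitions of every channel (delays 0..R-1 samples,
#' leading zeros), converting the convolutive mixture into an approximately
#' instantaneous one. Each row is mean-removed.
#'
#' @param rec An [emg_recording()].
#' @param R Extension factor (number of delayed repetitions per channel).
#' @return An object of class `extended_obs`: list with the `N x M` matrix
#'   `X` (`N = channels * R`), `R`, `fs_hz`, `channels`, `montage` and
#'   (after [whiten()]) the whitening model.
#' @export
extend <- function(rec, R = 30) {
  if (R < 1) stop("extension factor must be >= 1")
  R <- as.integer(R)
  C <- nrow(rec$data); M <- ncol(rec$data)
  X <- matrix(0, C * R, M)
  for (d in 0:(R - 1L)) {
    rows <- seq_len(C) + d * C
    if (d == 0L) X[rows, ] <- rec$data
    else X[rows, (d + 1L):M] <- rec$data[, seq_len(M - d), drop = FALSE]
  }
  X <- X - rowMeans(X)
  structure(
    list(X = X, R = R, fs_hz = rec$fs_hz, channels = C,
         montage = rec$montage, whitening = NULL),
    class = "extended_obs"
  )
}

#' @export
print.extended_obs <- function(x, ...) {
  cat(sprintf("<extended_obs> %d x %d (R = %d, %s)%s\n",
              nrow(x$X), ncol(x$X), x$R, x$montage,
              if (is.null(x$whitening)) "" else ", whitened"))
  invisible(x)
}

#' Whiten an extended observation (convolutive sphering)
#'
#' Eigen-decomposes the sample covariance E{ZZ'} = U D U', forms the
#' whitening matrix W = U D^(-1/2) U' and returns W Z. Eigenvalues below
#' `reg_rel` times the largest are clamped to that floor (rank-deficiency
#' regularization). After whitening the sample covariance of the rows is the
#' identity.
#'
#' @param obs An `extended_obs` from [extend()].
#' @param reg_rel Relative eigenvalue floor.
#' @return The whitened `extended_obs`, with element `whitening` holding
#'   `W`, `U`, `d` (eigenvalues after clamping) and `regularized` (count of
#'   clamped eigenvalues).
#' @export
whiten <- function(obs, reg_rel = 1e-8) {
  Z <- obs$X
  M <- ncol(Z)
  Cz <- tcrossprod(Z) / M
  eg <- eigen(Cz, symmetric = TRUE)
  d <- eg$values
  floor_val <- reg_rel * max(d)
  n_reg <- sum(d < floor_val)
  d <- pmax(d, floor_val)
  W <- eg$vectors %*% (t(eg$vectors) / sqrt(d))
  obs$X <- W %*% Z
  obs$whitening <- list(W = W, U = eg$vectors, d = d, regularized = n_reg)
  obs
}
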