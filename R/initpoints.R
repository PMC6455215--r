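#' Band-limited upsampling by Fourier zero-insertion
#'
#' Resamples a signal to a higher rate by inserting zeros into its discrete
#' Fourier transform. The signal is mirror-padded before the transform to
#' mitigate end effects; the padding is removed after resampling. The
#' spectrum below the original Nyquist frequency is preserved.
#'
#' @param x Numeric vector.
#' @param fs Original sampling rate, Hz.
#' @param target Target sampling rate, Hz (> fs).
#' @return Numeric vector at the target rate, with attribute `fs` giving the
#'   realized output rate (equal to `target` whenever
#'   `(length + padding) * target / fs` is an integer).
#' @export
upsample_vec <- function(x, fs, target = 10000) {
  if (target <= fs) stop("target rate must exceed the original rate")
  n <- length(x)
  # choose mirror padding so the resampled length is an integer
  frac <- target / fs
  # both the left padding and the total length must map to whole output
  # samples, otherwise the returned grid is offset by a fraction of a sample
  is_int <- function(v) abs(v - round(v)) < 1e-9
  pad <- NA_integer_
  for (p in 128:4096) {
    if (is_int(p * frac) && is_int((n + 2 * p) * frac)) {
      pad <- p; break
    }
  }
  if (is.na(pad)) pad <- 256L
  pad <- min(pad, n - 1L)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  np <- length(xp)
  n2 <- round(np * frac)
  X <- stats::fft(xp)
  Y <- complex(n2)
  half <- floor(np / 2)
  Y[1:(half + 1)] <- X[1:(half + 1)]
  if (half > 1) Y[(n2 - half + 2):n2] <- X[(np - half + 2):np]
  if (np %% 2 == 0) {
    # split the Nyquist bin to keep the output real-symmetric
    Y[half + 1] <- X[half + 1] / 2
    Y[n2 - half + 1] <- X[half + 1] / 2
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / np
  fs_out <- fs * n2 / np
  lo <- round(pad * frac) + 1L
  out <- y[lo:(lo + round(n * frac) - 1L)]
  attr(out, "fs") <- fs_out
  out
}

#' Upsample every channel of a recording
#'
#' @param rec An [emg_recording()].
#' @param target Target rate, Hz.
#' @return The upsampled recording.
#' @export
upsample <- function(rec, target = 10000) {
  rows <- lapply(seq_len(nrow(rec$data)),
                 function(i) upsample_vec(rec$data[i, ], rec$fs_hz, target))
  fs_out <- attr(rows[[1]], "fs")
  out <- do.call(rbind, rows)
  emg_recording(out, fs_out, rec$grid, rec$montage)
}

#' Adaptive spike detection threshold
#'
#' Sorts the absolute sample values ascending (`s`), computes their running
#' RMS (`ss`), and returns `s(i*)` for the largest index `i*` at which
#' `K * ss(i)` still exceeds `s(i)`. For a signal consisting of a baseline
#' plus sparse large spikes this lands at about `K` times the baseline RMS:
#' spikes inflate `s` far faster than the running RMS.
#'
#' @param samples Numeric vector.
#' @param K Threshold multiplier (default 4.0).
#' @return A non-negative amplitude threshold.
#' @export
detection_threshold <- function(samples, K = 4.0) {
  if (length(samples) == 0) stop("empty input")
  s <- sort(abs(samples))
  if (s[length(s)] == 0) {
    warning("all-zero input; detection threshold is 0")
    return(0)
  }
  ss <- sqrt(cumsum(s^2) / seq_along(s))
  idx <- which(K * ss > s)
  s[max(idx)]
}

#' Detect active segments on one channel
#'
#' Finds non-overlapping windows of length `win_ms` centered on local maxima
#' of the absolute signal that exceed the detection threshold. Collisions
#' within one window length are resolved toward the larger peak.
#'
#' @param samples Numeric vector (typically at 10 kHz).
#' @param fs Sampling rate of `samples`, Hz.
#' @param thr Detection threshold (see [detection_threshold()]).
#' @param win_ms Window length in milliseconds.
#' @param channel Channel index recorded in the output.
#' @return A list of active segments; each has `channel`, `peak_index`
#'   (1-based sample of the peak), `peak_time` (s), `waveform` (window
#'   samples) and `fs`.
#' @export
detect_active_segments <- function(samples, fs, thr, win_ms = 2,
                                   channel = 1L) {
  stopifnot(thr >= 0)
  win <- round(win_ms / 1000 * fs)
  half <- win %/% 2
  a <- abs(samples)
  n <- length(a)
  if (n < win + 2) return(list())
  cand <- which(a >= thr)
  cand <- cand[cand > half & cand <= n - half]
  is_max <- a[cand] >= a[pmax(cand - 1, 1)] & a[cand] >= a[pmin(cand + 1, n)]
  cand <- cand[is_max]
  if (length(cand) == 0) return(list())
  cand <- cand[order(a[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in cand) {
    if (length(kept) == 0 || min(abs(kept - i)) >= win) kept <- c(kept, i)
  }
  kept <- sort(kept)
  lapply(kept, function(i) {
    list(channel = channel, peak_index = i, peak_time = (i - 1) / fs,
         waveform = samples[(i - half + 1):(i + half)], fs = fs)
  })
}

fourier_shift <- function(w, shift) {
  n <- length(w)
  k <- c(0:(floor(n / 2)), -(ceiling(n / 2) - 1):-1)
  ph <- exp(-2i * pi * k * shift / n)
  if (n %% 2 == 0) ph[n / 2 + 1] <- Re(ph[n / 2 + 1])
  Re(stats::fft(stats::fft(w) * ph, inverse = TRUE)) / n
}

#' Align active segments on their highest peak
#'
#' Estimates the sub-sample peak location by parabolic interpolation of the
#' absolute waveform around its maximum and applies a band-limited (Fourier)
#' fractional shift so the peak sits at the window center. `peak_time` is
#' updated with sub-sample precision.
#'
#' @param segments List of active segments from [detect_active_segments()].
#' @return The aligned segments.
#' @export
align_segments <- function(segments) {
  if (length(segments) == 0) return(segments)
  lapply(segments, function(seg) {
    w <- seg$waveform
    n <- length(w)
    ctr <- n %/% 2  # waveform index holding the detected peak sample
    a <- abs(w)
    p <- which.max(a)
    delta <- 0
    if (p > 1 && p < n) {
      den <- a[p - 1] - 2 * a[p] + a[p + 1]
      if (den < 0) delta <- 0.5 * (a[p - 1] - a[p + 1]) / den
      delta <- max(min(delta, 0.5), -0.5)
    }
    shift <- (p + delta) - ctr
    seg$waveform <- fourier_shift(w, -shift)
    # peak_time tracks the channel time of waveform index ctr, so the
    # update is relative and re-alignment is idempotent
    seg$peak_time <- seg$peak_time + shift / seg$fs
    seg
  })
}

#' OPTICS ordering with unbounded neighborhood radius
#'
#' The modified OPTICS variant in which the neighborhood radius is set to the
#' maximum pairwise distance, so every point is a core point and only
#' `min_pts` remains as a parameter. The core distance of a point is the
#' Euclidean distance to its `min_pts`-th nearest neighbor. The ordering
#' starts at the first point (reachability `Inf`) and repeatedly emits the
#' unprocessed point with the smallest reachability, breaking ties toward the
#' lowest original index.
#'
#' @param features Numeric matrix, one row per point (or a list of equal
#'   length vectors).
#' @param min_pts Minimum cluster size.
#' @return An object of class `optics_ordering`: list with `order`
#'   (permutation of point indices), `reachability` (per emitted point,
#'   first = `Inf`), `min_pts`.
#' @export
optics_order <- function(features, min_pts = 40) {
  if (is.list(features) && !is.data.frame(features)) {
    features <- do.call(rbind, features)
  }
  features <- as.matrix(features)
  S <- nrow(features)
  if (S < min_pts + 1) {
    warning("fewer than min_pts + 1 points; empty ordering")
    return(structure(list(order = integer(0), reachability = numeric(0),
                          min_pts = min_pts),
                     class = "optics_ordering"))
  }
  D <- as.matrix(stats::dist(features))
  core <- vapply(seq_len(S), function(i) sort(D[i, -i])[min_pts], numeric(1))
  processed <- logical(S)
  reach <- rep(Inf, S)
  ord <- integer(S)
  rd <- numeric(S)
  current <- 1L
  for (step in seq_len(S)) {
    ord[step] <- current
    rd[step] <- if (step == 1L) Inf else reach[current]
    processed[current] <- TRUE
    todo <- which(!processed)
    if (length(todo) == 0) break
    newr <- pmax(core[current], D[current, todo])
    reach[todo] <- pmin(reach[todo], newr)
    current <- todo[which.min(reach[todo])]
  }
  structure(list(order = ord, reachability = rd, min_pts = min_pts),
            class = "optics_ordering")
}

#' @export
print.optics_ordering <- function(x, ...) {
  cat(sprintf("<optics_ordering> %d points, min_pts = %d\n",
              length(x$order), x$min_pts))
  invisible(x)
}

#' Extract reachability valleys and their cluster representatives
#'
#' A valley is a maximal run of ordered points whose reachability stays below
#' `theta` times the smaller of its two bounding reachability peaks, with
#' run length at least `min_width`. Bounding peaks are the sharp interior
#' maxima of the profile — points exceeding `1/theta` times both neighbors
#' — plus the leading `Inf` sentinel; minor within-cluster bumps do not
#' split a valley. The representative of a valley is the point with the
#' minimum reachability inside it.
#'
#' @param ordering An [optics_order()] result.
#' @param theta Valley depth factor relative to the bounding peak.
#' @param min_width Minimum valley width (defaults to `min_pts`).
#' @return A list of cluster representatives: each has `segment_index`
#'   (original point index), `valley` (index range in the ordering),
#'   `members` (original indices of valley points), `rd_at_rep`.
#' @export
extract_valleys <- function(ordering, theta = 0.75, min_width = NULL) {
  rd <- ordering$reachability
  S <- length(rd)
  if (is.null(min_width)) min_width <- ordering$min_pts
  if (S < 2) return(list())
  interior <- which(vapply(seq_len(S), function(i) {
    i > 1 && i < S && rd[i] > rd[i - 1] && rd[i] > rd[i + 1] &&
      rd[i] > max(rd[i - 1], rd[i + 1]) / theta
  }, logical(1)))
  peaks <- unique(c(1L, interior))
  reps <- list()
  bounds <- c(peaks, S + 1L)
  for (j in seq_along(peaks)) {
    lo <- peaks[j] + 1L
    hi <- bounds[j + 1L] - 1L
    if (hi < lo) next
    p_left <- rd[peaks[j]]
    p_right <- if (j < length(peaks)) rd[peaks[j + 1L]] else p_left
    lim <- theta * min(p_left, p_right)
    inside <- rd[lo:hi] < lim
    runs <- rle(inside)
    pos <- lo
    for (k in seq_along(runs$lengths)) {
      len <- runs$lengths[k]
      if (runs$values[k] && len >= min_width) {
        run_idx <- pos:(pos + len - 1L)
        best <- run_idx[which.min(rd[run_idx])]
        reps[[length(reps) + 1L]] <- list(
          segment_index = ordering$order[best],
          valley = c(run_idx[1], run_idx[len]),
          members = ordering$order[run_idx],
          rd_at_rep = rd[best]
        )
      }
      pos <- pos + len
    }
  }
  reps
}

#' Convert cluster representatives to decomposition initial points
#'
#' Decimates each representative's sub-sample peak time to the decomposition
#' sampling rate and pools points across channels, dropping any point within
#' `dedup_ms` of an already kept one. Points are kept in order of increasing
#' reachability (densest clusters first).
#'
#' @param reps List of cluster representatives (each with `peak_time`,
#'   `channel`, `rd_at_rep`, and optionally `waveform`/`fs`).
#' @param fs_decomp Decomposition sampling rate, Hz.
#' @param dedup_ms Minimum separation between kept points, ms.
#' @param n_samples Optional number of samples at `fs_decomp`; points are
#'   clamped inside `[0, n_samples - 1]`.
#' @return A tibble with `sample_index` (0-based, at `fs_decomp`),
#'   `channel`, `rd`, `peak_time_s`, `cluster` (provenance index) and a
#'   list-column `template` (the representative waveform, resampled to
#'   `fs_decomp`).
#' @export
representatives_to_initial_points <- function(reps, fs_decomp, dedup_ms = 1,
                                              n_samples = NULL) {
  if (length(reps) == 0) {
    return(tibble::tibble(sample_index = integer(), channel = integer(),
                          rd = numeric(), peak_time_s = numeric(),
                          cluster = integer(), template = list()))
  }
  ord <- order(vapply(reps, function(r) r$rd_at_rep, numeric(1)))
  kept_t <- numeric(0)
  rows <- list()
  for (j in ord) {
    rp <- reps[[j]]
    t0 <- rp$peak_time
    if (length(kept_t) > 0 && min(abs(kept_t - t0)) < dedup_ms / 1000) next
    kept_t <- c(kept_t, t0)
    idx <- round(t0 * fs_decomp)
    if (!is.null(n_samples)) idx <- max(0L, min(n_samples - 1L, idx))
    tmpl <- NULL
    if (!is.null(rp$waveform) && !is.null(rp$fs)) {
      n <- length(rp$waveform)
      tt <- (seq_len(n) - 1) / rp$fs
      t_out <- seq(0, tt[n], by = 1 / fs_decomp)
      tmpl <- stats::approx(tt, rp$waveform, xout = t_out)$y
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      sample_index = as.integer(idx), channel = as.integer(rp$channel),
      rd = rp$rd_at_rep, peak_time_s = t0, cluster = j,
      template = list(tmpl)
    )
  }
  dplyr::bind_rows(rows)
}

#' Find decomposition initial points from a recording
#'
#' The template side of guided source separation: per channel the signal is
#' upsampled to `upsample_hz`, thresholded adaptively, segmented into 2-ms
#' active segments, peak-aligned, and clustered with the modified OPTICS
#' ordering; reachability valleys yield cluster representatives whose peak
#' samples become the initial points for the CKC stage.
#'
#' @param rec The recording used for segmentation (typically the band-passed
#'   single-differential montage at the decomposition rate).
#' @param K Detection-threshold multiplier.
#' @param min_pts_per10s `MinPts` for a 10-s epoch; scaled linearly with the
#'   epoch duration (minimum 5).
#' @param upsample_hz Segmentation rate.
#' @param theta Valley depth factor.
#' @param win_ms Active-segment length, ms.
#' @param max_segments Per-channel cap on segments entering OPTICS (largest
#'   peaks kept).
#' @param max_points Optional cap on the number of pooled initial points.
#' @return A list with `points` (see
#'   [representatives_to_initial_points()]), `reps` (per-representative
#'   details incl. cluster member peak times) and `min_pts`.
#' @export
find_initial_points <- function(rec, K = 4.0, min_pts_per10s = 40,
                                upsample_hz = 10000, theta = 0.75,
                                win_ms = 2, max_segments = 800,
                                max_points = Inf) {
  dur <- duration_s(rec)
  min_pts <- max(5L, as.integer(round(min_pts_per10s * dur / 10)))
  all_reps <- list()
  for (ch in seq_len(nrow(rec$data))) {
    x <- upsample_vec(rec$data[ch, ], rec$fs_hz, upsample_hz)
    fs_up <- attr(x, "fs")
    thr <- detection_threshold(x, K)
    segs <- detect_active_segments(x, fs_up, thr, win_ms, channel = ch)
    if (length(segs) > max_segments) {
      pk <- vapply(segs, function(s) max(abs(s$waveform)), numeric(1))
      segs <- segs[order(pk, decreasing = TRUE)[seq_len(max_segments)]]
      segs <- segs[order(vapply(segs, `[[`, numeric(1), "peak_time"))]
    }
    if (length(segs) < min_pts + 1) next
    segs <- align_segments(segs)
    feat <- do.call(rbind, lapply(segs, `[[`, "waveform"))
    ordering <- optics_order(feat, min_pts)
    vr <- extract_valleys(ordering, theta = theta)
    for (v in vr) {
      seg <- segs[[v$segment_index]]
      all_reps[[length(all_reps) + 1L]] <- list(
        channel = ch,
        peak_time = seg$peak_time,
        waveform = seg$waveform,
        fs = seg$fs,
        rd_at_rep = v$rd_at_rep,
        member_times = vapply(segs[v$members], `[[`, numeric(1), "peak_time")
      )
    }
  }
  pts <- representatives_to_initial_points(all_reps, rec$fs_hz,
                                           n_samples = ncol(rec$data))
  if (nrow(pts) > 0) {
    # round-robin across channels (best representative of each channel
    # first) so a capped budget still samples diverse motor units
    pts <- pts |>
      dplyr::group_by(.data$channel) |>
      dplyr::mutate(.rank = rank(.data$rd, ties.method = "first")) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$.rank, .data$rd) |>
      dplyr::select(-".rank")
  }
  if (nrow(pts) > max_points) pts <- pts[seq_len(max_points), ]
  list(points = pts, reps = all_reps, min_pts = min_pts)
}
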