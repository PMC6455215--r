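#' Build a motor-unit pool
#'
#' Draws a pool of motor units with physiologically plausible properties:
#' fiber counts uniform on 24..2048, circular territories at 20 fibers/mm^2,
#' conduction velocities Normal(4.0, 0.3) m/s truncated below at 2.5 m/s, and
#' recruitment thresholds on a Fuglevand-style exponential ladder spanning a
#' 30-fold range with the last unit recruited at 60% MVC. Thresholds are
#' assigned by the size principle (smaller units recruited first). Territory
#' centers are uniform over the muscle cross-section; units deeper than
#' `scoreable_depth_mm` act as physiological background noise rather than
#' decomposition targets.
#'
#' @param n_mus Number of motor units (>= 1).
#' @param seed Integer seed; the pool is deterministic given the seed.
#' @param muscle_halfwidth_mm Half-width of the transversal extent over which
#'   territory centers are drawn (default 15, i.e. a 30 mm cross-section).
#' @param depth_range_mm Range of territory depths below the skin, mm.
#' @param scoreable_depth_mm Depth below which a unit counts as a superficial
#'   decomposition target.
#' @return A tibble with one row per MU: `mu_id`, `n_fibers`,
#'   `territory_radius_mm`, `x_mm`, `y_mm`, `depth_mm`, `cv_ms`
#'   (conduction velocity, m/s), `recruitment_threshold` (fraction of MVC),
#'   `shape_scale_mm`, `polarity`, `scoreable`.
#' @examples
#' pool <- build_mu_pool(20, seed = 1)
#' mean(pool$cv_ms)
#' @export
build_mu_pool <- function(n_mus, seed,
                          muscle_halfwidth_mm = 15,
                          depth_range_mm = c(1, 14),
                          scoreable_depth_mm = 6) {
  if (length(n_mus) != 1 || !is.finite(n_mus) || n_mus < 1) {
    stop("n_mus must be a positive count")
  }
  n_mus <- as.integer(n_mus)
  withr::with_seed(as.integer(seed), {
    n_fibers <- sample(24:2048, n_mus, replace = TRUE)
    cv <- stats::rnorm(n_mus, mean = 4.0, sd = 0.3)
    while (any(cv < 2.5)) cv[cv < 2.5] <- stats::rnorm(sum(cv < 2.5), 4.0, 0.3)
    x <- stats::runif(n_mus, -muscle_halfwidth_mm, muscle_halfwidth_mm)
    y <- stats::runif(n_mus, -10, 10)
    depth <- stats::runif(n_mus, depth_range_mm[1], depth_range_mm[2])
    # fiber-count-dependent waveform time scale with mild jitter: the spatial
    # extent of the source sets the temporal support once divided by CV
    shape_scale <- 2.0 * exp(stats::rnorm(n_mus, 0, 0.1))
    polarity <- ifelse(stats::runif(n_mus) < 0.9, 1, -1)
  })
  # exponential recruitment ladder over (0, 0.6] of MVC, 30-fold range,
  # assigned by the size principle
  ladder <- exp(seq_len(n_mus) * log(30) / n_mus) / 30 * 0.6
  thr <- numeric(n_mus)
  thr[order(n_fibers)] <- ladder
  tibble::tibble(
    mu_id = seq_len(n_mus),
    n_fibers = as.integer(n_fibers),
    territory_radius_mm = sqrt(n_fibers / (20 * pi)),
    x_mm = x, y_mm = y, depth_mm = depth,
    cv_ms = cv,
    recruitment_threshold = thr,
    shape_scale_mm = shape_scale,
    polarity = polarity,
    scoreable = depth < scoreable_depth_mm
  )
}

#' Generate motor-unit firing trains
#'
#' Units whose recruitment threshold lies below the excitation level are
#' active. Each active unit fires at a target rate of 8 pps at recruitment,
#' increasing by 0.3 pps per percent of excitation above its threshold and
#' capped at 35 pps. Inter-spike intervals are Gaussian with the requested
#' coefficient of variation; intervals below 20 ms are rejected and redrawn
#' (refractoriness).
#'
#' @param pool A MU pool from [build_mu_pool()].
#' @param excitation Excitation level in percent of MVC, in (0, 100].
#' @param duration Signal duration in seconds.
#' @param isi_cov Coefficient of variation of the inter-spike intervals
#'   (default 0.14).
#' @param seed Integer seed.
#' @return An object of class `ground_truth`: a list with `firings` (tibble
#'   `mu_id`, `time_s`), `excitation`, `active_mu_ids`, `rates` (tibble of
#'   per-MU target rates) and the `pool`.
#' @export
generate_firing_trains <- function(pool, excitation, duration,
                                   isi_cov = 0.14, seed = 1) {
  if (nrow(pool) == 0) stop("empty MU pool")
  stopifnot(excitation > 0, excitation <= 100, duration > 0,
            isi_cov >= 0, isi_cov < 0.5)
  active <- pool[pool$recruitment_threshold < excitation / 100, , drop = FALSE]
  trains <- list()
  rates <- numeric(nrow(active))
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(nrow(active))) {
      rate <- 8 + 0.3 * (excitation - active$recruitment_threshold[i] * 100)
      rate <- min(rate, 35)
      rates[i] <- rate
      mu_isi <- 1 / rate
      times <- stats::runif(1, 0, mu_isi)
      repeat {
        isi <- stats::rnorm(1, mu_isi, isi_cov * mu_isi)
        if (isi < 0.02) next
        nxt <- times[length(times)] + isi
        if (nxt >= duration) break
        times <- c(times, nxt)
      }
      trains[[i]] <- times
    }
  })
  firings <- tibble::tibble(
    mu_id = rep(active$mu_id, lengths(trains)),
    time_s = unlist(trains, use.names = FALSE)
  )
  if (nrow(firings) == 0) {
    firings <- tibble::tibble(mu_id = integer(), time_s = numeric())
  }
  structure(
    list(
      firings = firings,
      excitation = excitation,
      duration = duration,
      active_mu_ids = active$mu_id,
      rates = tibble::tibble(mu_id = active$mu_id, rate_pps = rates),
      pool = pool
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d active MUs, %d firings, %g%% MVC, %.1f s\n",
              length(x$active_mu_ids), nrow(x$firings), x$excitation,
              x$duration))
  invisible(x)
}

#' Synthesize spatio-temporal MUAP templates
#'
#' A parametric surrogate for the surface action-potential of each unit: the
#' temporal waveform is the second derivative of a Gaussian whose width scales
#' with 1/CV (and widens with depth, mimicking tissue low-pass filtering); the
#' waveform propagates along the fiber direction with an inter-row delay of
#' `ied_mm / CV`; spatial amplitude decays exponentially with the 3-D
#' electrode-to-territory distance; peak-to-peak amplitude scales linearly
#' with fiber count.
#'
#' @param pool MU pool tibble.
#' @param grid An [electrode_grid()].
#' @param decay_mm Spatial decay constant of the amplitude, mm.
#' @param amp_per_fiber Amplitude (a.u.) contributed per fiber at zero
#'   distance.
#' @return A named list (by `mu_id`) of channels x lags matrices, each with
#'   attribute `ref_lag`: the lag index (1-based) of the template's global
#'   absolute peak, used as the firing-time alignment reference.
#' @export
synthesize_muaps <- function(pool, grid, decay_mm = 4, amp_per_fiber = 1e-3) {
  pos <- electrode_positions(grid)
  fs <- grid$fs_hz
  cv_mm_s <- pool$cv_ms * 1000  # mm/s
  # lag axis long enough for full propagation plus waveform support
  max_span_s <- (grid$rows - 1) * grid$ied_mm / min(cv_mm_s) +
    8 * max(pool$shape_scale_mm / cv_mm_s * (1 + pool$depth_mm / 8))
  n_lags <- ceiling(max_span_s * fs) + 1
  t_axis <- (seq_len(n_lags) - 1) / fs
  templates <- vector("list", nrow(pool))
  names(templates) <- as.character(pool$mu_id)
  for (i in seq_len(nrow(pool))) {
    sigma <- pool$shape_scale_mm[i] / cv_mm_s[i] * (1 + pool$depth_mm[i] / 8)
    delay_per_row <- grid$ied_mm / cv_mm_s[i]
    t0 <- 4 * sigma
    dx <- pos$x_mm - pool$x_mm[i]
    dy <- pos$y_mm - pool$y_mm[i]
    dist <- sqrt(dx^2 + dy^2 + pool$depth_mm[i]^2)
    amp <- pool$polarity[i] * amp_per_fiber * pool$n_fibers[i] *
      exp(-dist / decay_mm)
    tmpl <- matrix(0, nrow(pos), n_lags)
    for (ch in seq_len(nrow(pos))) {
      tt <- t_axis - t0 - (pos$row[ch] - 1) * delay_per_row
      u <- tt / sigma
      tmpl[ch, ] <- amp[ch] * (1 - u^2) * exp(-u^2 / 2)
    }
    ref <- which.max(apply(abs(tmpl), 2, max))
    attr(tmpl, "ref_lag") <- ref
    templates[[i]] <- tmpl
  }
  templates
}

#' Render a clean (noise-free) HD-sEMG recording
#'
#' Convolutive mixing: each channel is the sum, over motor units, of the
#' unit's template convolved with its binary firing train. The template's
#' reference lag (its global peak) is aligned to the firing sample, so a
#' simulated firing time marks the MUAP peak.
#'
#' @param truth A [generate_firing_trains()] result.
#' @param templates Templates from [synthesize_muaps()].
#' @param grid An [electrode_grid()].
#' @param duration Duration in seconds.
#' @return A monopolar [emg_recording()].
#' @export
render_emg <- function(truth, templates, grid, duration = truth$duration) {
  fs <- grid$fs_hz
  n_samp <- round(duration * fs)
  if (nrow(truth$firings) > 0 && any(truth$firings$time_s >= duration)) {
    stop("firing times must lie within the recording duration")
  }
  data <- matrix(0, n_electrodes(grid), n_samp)
  for (id in truth$active_mu_ids) {
    tmpl <- templates[[as.character(id)]]
    if (is.null(tmpl)) stop("missing template for MU ", id)
    ref <- attr(tmpl, "ref_lag")
    n_lags <- ncol(tmpl)
    times <- truth$firings$time_s[truth$firings$mu_id == id]
    for (t in times) {
      s0 <- round(t * fs) + 1 - (ref - 1)
      lo <- max(1, s0); hi <- min(n_samp, s0 + n_lags - 1)
      if (hi < lo) next
      data[, lo:hi] <- data[, lo:hi] + tmpl[, (lo - s0 + 1):(hi - s0 + 1)]
    }
  }
  emg_recording(data, fs, grid, "monopolar")
}

#' Add band-limited colored Gaussian noise at a prescribed SNR
#'
#' White Gaussian noise is band-limited to `band` by a zero-phase Butterworth
#' filter and scaled so the global signal-to-noise power ratio equals
#' `snr_db` exactly (by construction, to machine precision).
#'
#' @param rec A clean [emg_recording()].
#' @param snr_db Target SNR in dB.
#' @param band Noise bandwidth in Hz (default 20-500).
#' @param seed Integer seed.
#' @return The noisy recording.
#' @export
add_colored_noise <- function(rec, snr_db, band = c(20, 500), seed = 1) {
  stopifnot(is.finite(snr_db))
  p_sig <- mean(rec$data^2)
  if (p_sig <= 0) stop("clean signal has zero power; SNR undefined")
  bf <- signal::butter(2, band / (rec$fs_hz / 2), type = "pass")
  withr::with_seed(as.integer(seed), {
    noise <- matrix(stats::rnorm(length(rec$data)), nrow(rec$data))
  })
  noise <- t(apply(noise, 1, function(x) signal::filtfilt(bf, x)))
  p_noise <- mean(noise^2)
  noise <- noise * sqrt(p_sig / (p_noise * 10^(snr_db / 10)))
  emg_recording(rec$data + noise, rec$fs_hz, rec$grid, rec$montage)
}

#' Simulate a complete HD-sEMG trial
#'
#' Convenience wrapper: pool, firing trains, templates, rendering and noise
#' in one call.
#'
#' @param excitation Percent MVC.
#' @param snr_db SNR of the added colored noise, dB; `Inf` skips noise.
#' @param duration Seconds.
#' @param grid An [electrode_grid()].
#' @param n_mus Pool size.
#' @param isi_cov ISI coefficient of variation.
#' @param seed Integer seed (drives pool, trains, and noise).
#' @return A list with `recording` (noisy), `clean` (noise-free),
#'   `truth`, `templates`, and `pool`.
#' @examples
#' sim <- simulate_hdsemg(10, 30, duration = 1,
#'                        grid = electrode_grid(4, 4), n_mus = 10, seed = 1)
#' sim$recording
#' @export
simulate_hdsemg <- function(excitation, snr_db, duration = 16,
                            grid = electrode_grid(), n_mus = 60,
                            isi_cov = 0.14, seed = 1) {
  seed <- as.integer(seed)
  pool <- build_mu_pool(n_mus, seed = seed)
  truth <- generate_firing_trains(pool, excitation, duration,
                                  isi_cov = isi_cov, seed = seed + 1L)
  templates <- synthesize_muaps(pool, grid)
  clean <- render_emg(truth, templates, grid, duration)
  rec <- if (is.finite(snr_db)) {
    add_colored_noise(clean, snr_db, seed = seed + 2L)
  } else {
    clean
  }
  list(recording = rec, clean = clean, truth = truth,
       templates = templates, pool = pool)
}
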