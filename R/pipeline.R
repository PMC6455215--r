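#' Full pipeline configuration
#'
#' @param montage Montage the decomposition operates on.
#' @param bandpass_low,bandpass_high Band-pass cut-offs, Hz.
#' @param extension_factor Delayed repetitions per channel.
#' @param init_method `"clusters"` (guided, OPTICS representatives) or
#'   `"peaks"` (plain gCKC comparator: largest whitened-observation peaks).
#' @param n_peak_points Number of peak-based initial points for
#'   `init_method = "peaks"`.
#' @param max_initial_points Cap on pooled initial points.
#' @param initpoints Named list of [find_initial_points()] arguments
#'   (`K`, `min_pts_per10s`, `upsample_hz`, `theta`, `max_segments`).
#' @param gckc A [gckc_config()].
#' @param seed Integer seed (bootstrap CIs; decomposition is otherwise
#'   deterministic).
#' @return List of class `gss_config`.
#' @export
gss_config <- function(montage = "single_differential",
                       bandpass_low = 20, bandpass_high = 500,
                       extension_factor = 30,
                       init_method = c("clusters", "peaks"),
                       n_peak_points = 50,
                       max_initial_points = Inf,
                       initpoints = list(),
                       gckc = gckc_config(),
                       seed = 1L) {
  init_method <- match.arg(init_method)
  ip_defaults <- list(K = 4.0, min_pts_per10s = 40, upsample_hz = 10000,
                      theta = 0.75, max_segments = 800)
  ip <- utils::modifyList(ip_defaults, initpoints)
  structure(
    list(montage = montage, bandpass_low = bandpass_low,
         bandpass_high = bandpass_high,
         extension_factor = extension_factor,
         init_method = init_method, n_peak_points = n_peak_points,
         max_initial_points = max_initial_points,
         initpoints = ip, gckc = gckc, seed = as.integer(seed)),
    class = "gss_config"
  )
}

#' Desk-scale configuration
#'
#' A reduced configuration sized so a full benchmark grid runs in minutes on
#' a single CPU: extension factor 8 and at most 25 initial points. Use with
#' [desk_grid()] and short (about 4 s) simulations.
#'
#' @param ... Overrides passed to [gss_config()].
#' @export
desk_config <- function(...) {
  defaults <- list(extension_factor = 8, max_initial_points = 25,
                   n_peak_points = 30,
                   gckc = gckc_config(max_iters = 60))
  do.call(gss_config, utils::modifyList(defaults, list(...)))
}

#' @rdname desk_config
#' @export
desk_grid <- function() electrode_grid(rows = 5, cols = 5)

# initial points for the plain gCKC comparator: local maxima of the whitened
# observation column norms, largest first, 1-ms dedup
peak_initial_points <- function(obs, n = 50, dedup_ms = 1) {
  energy <- sqrt(colSums(obs$X^2))
  pk <- local_peaks(energy)
  pk <- pk[order(energy[pk], decreasing = TRUE)]
  min_gap <- round(dedup_ms / 1000 * obs$fs_hz)
  kept <- integer(0)
  for (i in pk) {
    if (length(kept) == 0 || min(abs(kept - i)) >= min_gap) kept <- c(kept, i)
    if (length(kept) >= n) break
  }
  tibble::tibble(sample_index = as.integer(kept - 1L),
                 channel = NA_integer_, rd = NA_real_,
                 peak_time_s = (kept - 1) / obs$fs_hz,
                 cluster = seq_along(kept),
                 template = vector("list", length(kept)))
}

make_correlator <- function(rec, template, channel) {
  if (is.null(template) || is.na(channel)) return(NULL)
  x <- rec$data[channel, ]
  len <- length(template)
  off <- which.max(abs(template))
  force(off)
  function(m) {
    lo <- m - off + 1L
    hi <- lo + len - 1L
    if (lo < 1 || hi > length(x)) return(NA_real_)
    suppressWarnings(stats::cor(x[lo:hi], template))
  }
}

#' Decompose an HD-sEMG recording into motor-unit firing trains
#'
#' The complete guided-source-separation chain: band-pass filtering,
#' single-differential derivation, observation extension and whitening,
#' initial-point estimation (OPTICS cluster representatives, or
#' whitened-signal peaks for the comparator), per-point CKC decomposition
#' with EM-Kalman acceleration and adaptive soft-thresholding, physiological
#' exclusion, and duplicate removal.
#'
#' @param rec A monopolar (or already single-differential)
#'   [emg_recording()].
#' @param config A [gss_config()].
#' @return An object of class `gss_decomposition`: `mus` (tibble, one row
#'   per decomposed initial point, with list-column `times`), `patterns`
#'   (kept, deduplicated `firing_pattern`s), `recording` (the preprocessed
#'   single-differential recording), `config`, `n_initial_points`.
#' @export
decompose_hdsemg <- function(rec, config = gss_config()) {
  if (rec$montage == "monopolar" && config$montage == "single_differential") {
    rec <- make_single_differential(rec)
  }
  rec_f <- bandpass(rec, config$bandpass_low, config$bandpass_high)
  obs <- whiten(extend(rec_f, config$extension_factor))
  if (config$init_method == "clusters") {
    ip <- find_initial_points(
      rec_f, K = config$initpoints$K,
      min_pts_per10s = config$initpoints$min_pts_per10s,
      upsample_hz = config$initpoints$upsample_hz,
      theta = config$initpoints$theta,
      max_segments = config$initpoints$max_segments,
      max_points = config$max_initial_points
    )
    points <- ip$points
  } else {
    n <- min(config$n_peak_points, config$max_initial_points)
    points <- peak_initial_points(obs, n = n)
    ip <- list(points = points, reps = list())
  }
  rows <- list()
  patterns <- list()
  for (i in seq_len(nrow(points))) {
    correlator <- make_correlator(rec_f, points$template[[i]],
                                  points$channel[i])
    est <- decompose_mu(obs, points$sample_index[i], config$gckc,
                        correlator = correlator,
                        seed = config$seed + i)
    pat <- firing_stats(extract_firings(est, rec_f$fs_hz, mu_id = i))
    exc <- exclude_mu(pat)
    rows[[i]] <- tibble::tibble(
      mu_id = i,
      source_channel = points$channel[i],
      init_sample = points$sample_index[i],
      n_firings = length(pat$times),
      pnr_db = pat$pnr_db, mdr_hz = pat$mdr_hz, cov_isi = pat$cov_isi,
      n_inconsistent = pat$n_inconsistent, p_d = pat$p_d,
      iterations = est$iterations,
      converged = isTRUE(est$converged),
      kept = exc$keep,
      reasons = paste(exc$reasons, collapse = ","),
      times = list(pat$times)
    )
    if (exc$keep) patterns[[length(patterns) + 1L]] <- pat
  }
  mus <- if (length(rows) > 0) dplyr::bind_rows(rows) else tibble::tibble()
  patterns <- deduplicate(patterns)
  kept_ids <- vapply(patterns, function(p) p$mu_id, numeric(1))
  if (nrow(mus) > 0) {
    mus$kept <- mus$kept & mus$mu_id %in% kept_ids
  }
  structure(
    list(mus = mus, patterns = patterns, recording = rec_f,
         config = config, n_initial_points = nrow(points),
         initpoints = ip),
    class = "gss_decomposition"
  )
}

#' @export
print.gss_decomposition <- function(x, ...) {
  cat(sprintf(
    "<gss_decomposition> %d initial points -> %d kept MUs (%s init)\n",
    x$n_initial_points, length(x$patterns), x$config$init_method))
  invisible(x)
}

#' Score a decomposition against simulated ground truth
#'
#' Each kept motor unit is matched (constant lag compensated, then the
#' +/- 0.5 ms rule) against every simulated train; the best-agreeing
#' simulated MU is reported together with rate of agreement, sensitivity,
#' precision, the 30% identification flag, and firing-statistic biases.
#'
#' @param decomp A [decompose_hdsemg()] result.
#' @param truth A `ground_truth`.
#' @param tol_s Matching tolerance, s.
#' @param quota Identification quota.
#' @return A tibble, one row per kept MU.
#' @export
score_decomposition <- function(decomp, truth, tol_s = 5e-4, quota = 0.30) {
  true_ids <- unique(truth$firings$mu_id)
  rows <- list()
  for (pat in decomp$patterns) {
    if (length(pat$times) < 2) next
    best <- NULL; best_id <- NA_integer_
    for (id in true_ids) {
      tt <- truth$firings$time_s[truth$firings$mu_id == id]
      if (length(tt) < 2) next
      m <- match_firings_aligned(pat$times, tt, tol_s = tol_s)
      if (is.null(best) || m$roa > best$roa) { best <- m; best_id <- id }
    }
    if (is.null(best)) next
    tt <- truth$firings$time_s[truth$firings$mu_id == best_id]
    true_pat <- firing_stats(structure(list(mu_id = best_id, times = tt),
                                       class = "firing_pattern"))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      est_mu = pat$mu_id, true_mu = best_id,
      tp = best$tp, fp = best$fp, fn = best$fn,
      roa = best$roa, sensitivity = best$sensitivity,
      precision = best$precision,
      identified = is_identified(best, length(tt), quota),
      pnr_db = pat$pnr_db,
      mdr_est = pat$mdr_hz, mdr_true = true_pat$mdr_hz,
      cov_est = pat$cov_isi, cov_true = true_pat$cov_isi
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      est_mu = integer(), true_mu = integer(), tp = integer(),
      fp = integer(), fn = integer(), roa = numeric(),
      sensitivity = numeric(), precision = numeric(),
      identified = logical(), pnr_db = numeric(), mdr_est = numeric(),
      mdr_true = numeric(), cov_est = numeric(), cov_true = numeric()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Run the synthetic benchmark grid
#'
#' Simulates every SNR x excitation condition with seeded replicates, runs
#' the guided decomposition (and optionally the plain gCKC comparator on the
#' identical signals), and scores both against the simulated firings.
#'
#' @param snr_list SNR levels, dB.
#' @param mvc_list Excitation levels, percent MVC.
#' @param replicates Replicates per condition.
#' @param replicate_ids Optional explicit replicate indices (overrides
#'   `replicates`); the signal of condition (snr, mvc, replicate) is
#'   identical across calls with the same base seed, so sub-grids and
#'   added replicates reuse the same simulated recordings.
#' @param duration_s Signal duration, s.
#' @param grid An [electrode_grid()].
#' @param n_mus Simulated pool size.
#' @param config A [gss_config()] for the guided method.
#' @param baseline Also run the plain gCKC comparator.
#' @param seed Base seed; each condition/replicate derives its own.
#' @return A `gss_benchmark`: list with `per_mu` (per identified MU rows
#'   across all runs, with `method`, `snr_db`, `mvc`, `replicate`),
#'   `runs` (per-run summaries) and `summary` (per condition x method).
#' @export
run_benchmark <- function(snr_list = c(10, 20, 30),
                          mvc_list = c(10, 30, 50),
                          replicates = 2,
                          duration_s = 4,
                          grid = desk_grid(),
                          n_mus = 60,
                          config = desk_config(),
                          baseline = TRUE,
                          seed = 1L,
                          replicate_ids = NULL) {
  per_mu <- list(); runs <- list()
  if (is.null(replicate_ids)) replicate_ids <- seq_len(replicates)
  for (snr in snr_list) for (mvc in mvc_list) {
    for (rep_i in replicate_ids) {
      seed_r <- as.integer(seed + 1009 * snr + 101 * mvc + 7919 * rep_i)
      sim <- simulate_hdsemg(mvc, snr, duration = duration_s, grid = grid,
                             n_mus = n_mus, seed = seed_r)
      methods <- list(gss = config)
      if (baseline) {
        base_cfg <- config
        base_cfg$init_method <- "peaks"
        base_cfg$gckc$use_kalman <- FALSE
        base_cfg$gckc$soft_threshold <- FALSE
        methods$gckc <- base_cfg
      }
      for (meth in names(methods)) {
        cfg <- methods[[meth]]
        cfg$seed <- seed_r
        dec <- decompose_hdsemg(sim$recording, cfg)
        sc <- score_decomposition(dec, sim$truth)
        iters <- dec$mus$iterations[dec$mus$kept]
        if (nrow(sc) > 0) {
          sc$method <- meth; sc$snr_db <- snr; sc$mvc <- mvc
          sc$replicate <- rep_i
          per_mu[[length(per_mu) + 1L]] <- sc
        }
        idf <- sc[sc$identified, , drop = FALSE]
        runs[[length(runs) + 1L]] <- tibble::tibble(
          method = meth, snr_db = snr, mvc = mvc, replicate = rep_i,
          n_kept = length(dec$patterns),
          n_identified = nrow(idf),
          mean_roa = mean(idf$roa),
          mean_precision = mean(idf$precision),
          mean_sensitivity = mean(idf$sensitivity),
          mean_iterations = mean(iters),
          mdr_bias = mean(abs(idf$mdr_est - idf$mdr_true)),
          cov_bias = mean(abs(idf$cov_est - idf$cov_true))
        )
      }
    }
  }
  per_mu <- dplyr::bind_rows(per_mu)
  runs <- dplyr::bind_rows(runs)
  summary <- runs |>
    dplyr::group_by(.data$method, .data$snr_db, .data$mvc) |>
    dplyr::summarise(
      dplyr::across(c("n_kept", "n_identified", "mean_roa",
                      "mean_precision", "mean_sensitivity",
                      "mean_iterations", "mdr_bias", "cov_bias"),
                    ~ mean(.x, na.rm = TRUE)),
      .groups = "drop")
  structure(list(per_mu = per_mu, runs = runs, summary = summary),
            class = "gss_benchmark")
}

#' @export
print.gss_benchmark <- function(x, ...) {
  cat("<gss_benchmark>\n")
  print(x$summary)
  invisible(x)
}
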