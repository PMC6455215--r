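#' Match an estimated firing train against a reference train
#'
#' One-to-one greedy matching: candidate pairs within `tol_s` are accepted
#' in order of increasing absolute time difference (ties toward the earlier
#' firing), each firing used at most once. An optional constant lag is added
#' to the estimate first (see [best_lag()] for why a lag arises).
#'
#' @param est_times,true_times Sorted firing times in seconds.
#' @param tol_s Matching tolerance (default 0.5 ms).
#' @param lag_s Constant lag added to `est_times` before matching.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `roa`, `sensitivity`,
#'   `precision`, `lag_s`.
#' @export
match_firings <- function(est_times, true_times, tol_s = 5e-4, lag_s = 0) {
  est <- est_times + lag_s
  ne <- length(est); nt <- length(true_times)
  tp <- 0L
  if (ne > 0 && nt > 0) {
    d <- abs(outer(true_times, est, "-"))
    pairs <- which(d <= tol_s, arr.ind = TRUE)
    if (nrow(pairs) > 0) {
      ord <- order(d[pairs], true_times[pairs[, 1]])
      used_t <- logical(nt); used_e <- logical(ne)
      for (k in ord) {
        it <- pairs[k, 1]; ie <- pairs[k, 2]
        if (!used_t[it] && !used_e[ie]) {
          used_t[it] <- TRUE; used_e[ie] <- TRUE
          tp <- tp + 1L
        }
      }
    }
  }
  fp <- ne - tp
  fn <- nt - tp
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    roa = if (tp + fn + fp > 0) tp / (tp + fn + fp) else NA_real_,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    lag_s = lag_s
  )
}

#' Match with automatic constant-lag compensation
#'
#' @inheritParams match_firings
#' @param max_lag_s Half-range of the lag search.
#' @return As [match_firings()].
#' @export
match_firings_aligned <- function(est_times, true_times, tol_s = 5e-4,
                                  max_lag_s = 0.01) {
  lag <- best_lag(est_times, true_times, max_lag_s = max_lag_s, tol_s = tol_s)
  match_firings(est_times, true_times, tol_s = tol_s, lag_s = lag)
}

#' Identification rule
#'
#' A motor unit counts as identified when at least 30% of the reference
#' firings are time-locked within the tolerance.
#'
#' @param match A [match_firings()] row.
#' @param truth_count Number of reference firings.
#' @param quota Identification quota (default 0.30).
#' @return Logical flag.
#' @export
is_identified <- function(match, truth_count, quota = 0.30) {
  if (truth_count == 0) stop("reference train is empty")
  match$tp / truth_count >= quota
}

#' Cluster correctness
#'
#' A cluster (representative plus its nearby spikes in the reachability
#' ordering) is correct when at least `quota` of its proxy times are
#' time-locked within `tol_s` to the firings of a single simulated MU
#' (constant lag compensated).
#'
#' @param proxy_times Firing-time proxies of the cluster, seconds.
#' @param truth_firings Tibble `mu_id`, `time_s` of simulated firings.
#' @param quota Required locked fraction (default 0.75).
#' @param tol_s Tolerance, s.
#' @return Logical flag (with attribute `best_mu`).
#' @export
cluster_correct <- function(proxy_times, truth_firings, quota = 0.75,
                            tol_s = 5e-4) {
  stopifnot(length(proxy_times) >= 1)
  best <- 0; best_mu <- NA_integer_
  for (id in unique(truth_firings$mu_id)) {
    tt <- truth_firings$time_s[truth_firings$mu_id == id]
    lag <- best_lag(proxy_times, tt, tol_s = tol_s)
    fr <- match_fraction(proxy_times + lag, tt, tol_s)
    if (fr > best) { best <- fr; best_mu <- id }
  }
  structure(best >= quota, best_mu = best_mu, fraction = best)
}

#' Spike-triggered average MUAP
#'
#' Averages signal windows centered on the firing times, per channel.
#' Windows crossing the recording bounds are dropped.
#'
#' @param rec An [emg_recording()].
#' @param times Firing times, seconds.
#' @param half_window_s Half window length, seconds.
#' @return A channels x lags matrix with attribute `ref_lag` (the center).
#' @export
sta_muap <- function(rec, times, half_window_s = 0.01) {
  if (length(times) < 5) stop("need at least 5 firings for a stable STA")
  hw <- round(half_window_s * rec$fs_hz)
  M <- ncol(rec$data)
  centers <- round(times * rec$fs_hz) + 1L
  centers <- centers[centers - hw >= 1 & centers + hw <= M]
  if (length(centers) == 0) stop("all STA windows cross the recording bounds")
  out <- matrix(0, nrow(rec$data), 2L * hw + 1L)
  for (c0 in centers) {
    out <- out + rec$data[, (c0 - hw):(c0 + hw), drop = FALSE]
  }
  out <- out / length(centers)
  attr(out, "ref_lag") <- hw + 1L
  out
}

#' Signal-to-interference ratio of a decomposition
#'
#' Reconstructs every channel as the sum of the per-MU spike-triggered
#' average templates convolved with the estimated firing trains, and reports
#' the percentage of signal variance explained:
#' `SIR(i) = (1 - E[(x_i - sum_j z_ij)^2] / E[x_i^2]) * 100`.
#'
#' @param rec The single-differential recording being explained.
#' @param firing_list List of firing-time vectors (seconds), one per MU.
#' @param templates Optional list of channel x lag templates with
#'   `ref_lag` attributes; computed by [sta_muap()] when `NULL`.
#' @param half_window_s STA half window when templates are computed here.
#' @return List with `per_channel` (percent), `mean` (percent), `residual`
#'   (channels x samples matrix).
#' @export
sir <- function(rec, firing_list, templates = NULL, half_window_s = 0.01) {
  M <- ncol(rec$data)
  recon <- matrix(0, nrow(rec$data), M)
  if (is.null(templates)) {
    templates <- lapply(firing_list, function(tt) sta_muap(rec, tt,
                                                           half_window_s))
  }
  for (j in seq_along(firing_list)) {
    tmpl <- templates[[j]]
    if (is.null(tmpl)) next
    ref <- attr(tmpl, "ref_lag")
    L <- ncol(tmpl)
    for (t in firing_list[[j]]) {
      s0 <- round(t * rec$fs_hz) + 1L - (ref - 1L)
      lo <- max(1L, s0); hi <- min(M, s0 + L - 1L)
      if (hi < lo) next
      recon[, lo:hi] <- recon[, lo:hi] + tmpl[, (lo - s0 + 1L):(hi - s0 + 1L)]
    }
  }
  resid <- rec$data - recon
  per_ch <- (1 - rowMeans(resid^2) / rowMeans(rec$data^2)) * 100
  list(per_channel = per_ch, mean = mean(per_ch), residual = resid)
}

#' Decomposability indices
#'
#' For each MU `k` and channel `i`,
#' `DI_ki = min(||m_ki||, ||m_ki - m_k*i||) / V_i_RMS`, where `m_k*i` is the
#' nearest competitor MUAP in that channel (Euclidean norm) and `V_i_RMS`
#' the per-channel noise RMS. The compound index `cDI_k` is the sum of a
#' unit's channel indices normalized by the number of channels.
#'
#' @param templates List of channels x lags MUAP templates (equal sizes).
#' @param noise_rms Per-channel noise RMS (recycled if scalar).
#' @return List with `di` (MUs x channels matrix) and `cdi` (per-MU).
#' @export
decomposability <- function(templates, noise_rms) {
  K <- length(templates)
  stopifnot(K >= 1, all(noise_rms > 0))
  nch <- nrow(templates[[1]])
  noise_rms <- rep_len(noise_rms, nch)
  di <- matrix(0, K, nch)
  for (k in seq_len(K)) {
    for (i in seq_len(nch)) {
      m <- templates[[k]][i, ]
      nm <- sqrt(sum(m^2))
      dist_min <- Inf
      for (k2 in seq_len(K)) {
        if (k2 == k) next
        d <- sqrt(sum((m - templates[[k2]][i, ])^2))
        dist_min <- min(dist_min, d)
      }
      if (!is.finite(dist_min)) dist_min <- nm  # no competitor
      di[k, i] <- min(nm, dist_min) / noise_rms[i]
    }
  }
  list(di = di, cdi = rowSums(di) / nch)
}
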