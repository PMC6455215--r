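#' Extract a firing pattern from a spike-train estimate
#'
#' Detected firings are the local maxima retained by the adaptive
#' soft-thresholding decision (above the upper CI bound, or marginal with a
#' template-matched segment, i.e. `alpha = 1`); attenuated marginal spikes
#' (`alpha = 0.9`) are excluded.
#'
#' @param est A `spike_train_estimate` from [decompose_mu()].
#' @param fs Sampling rate of the decomposition, Hz.
#' @param mu_id Identifier carried through.
#' @return A `firing_pattern`: list with `mu_id`, `times` (sorted seconds),
#'   `pnr_db`, and statistics filled by [firing_stats()].
#' @export
extract_firings <- function(est, fs, mu_id = NA_integer_) {
  if (isTRUE(est$failed)) {
    times <- numeric(0)
  } else {
    times <- sort((est$kept - 1) / fs)
  }
  structure(
    list(mu_id = mu_id, times = times,
         pnr_db = if (isTRUE(est$failed)) NA_real_ else est$pnr_db,
         mdr_hz = NA_real_, cov_isi = NA_real_,
         n_inconsistent = NA_integer_, p_d = NA_real_),
    class = "firing_pattern"
  )
}

#' Compute firing-pattern statistics
#'
#' Firing statistics are computed on the physiologically plausible subset
#' of inter-spike intervals: ISIs below the refractory floor (doublets from
#' false detections) and above twice the median (gaps from missed
#' detections) are trimmed first. The mean discharge rate is the rate
#' implied by the plausible intervals, `1 / mean(trimmed ISI)`, and the
#' coefficient of variation is computed on the same subset — both are
#' thereby robust to isolated detection errors, which distort a naive
#' `(count - 1) / span` rate in direct proportion to the miss rate. The
#' inconsistent-firing count `n_I` (ISIs shorter than `n_i_window_ms`,
#' i.e. more than one pulse inside the refractory window) is kept raw.
#'
#' The detection probability `p_d` is the probability that the train is
#' consistent with a physiological unimodal near-Gaussian ISI
#' distribution: the product of a shape factor (the Shapiro-Wilk W
#' statistic of the trimmed ISIs) and a dispersion factor
#' `pnorm((0.35 - CoV) / 0.05)` encoding the bounded ISI variability of
#' constant-force contractions (CoV about 0.1-0.3). Both factors stay
#' near 1 for regular trains; doublets and shape distortions pull down W,
#' while merged multi-unit trains — whose widely dispersed ISIs are *not*
#' outliers and therefore survive trimming — are caught by the dispersion
#' factor. A plain normality p-value would be uniform for perfectly
#' regular trains and therefore unusable with a fixed 50% exclusion bound.
#'
#' @param pattern A `firing_pattern`.
#' @param n_i_window_ms ISI below which a firing counts as inconsistent.
#' @return The pattern with `mdr_hz`, `cov_isi`, `n_inconsistent`, `p_d`
#'   filled (sentinel `NA` when too few firings).
#' @export
firing_stats <- function(pattern, n_i_window_ms = 20) {
  t <- pattern$times
  if (length(t) < 2) return(pattern)
  isi <- diff(t)
  pattern$n_inconsistent <- sum(isi < n_i_window_ms / 1000)
  trimmed <- isi[isi >= 0.02 & isi <= 2 * stats::median(isi)]
  if (length(trimmed) < 2) trimmed <- isi
  pattern$mdr_hz <- 1 / mean(trimmed)
  pattern$cov_isi <- stats::sd(trimmed) / mean(trimmed)
  pattern$p_d <- if (length(trimmed) >= 3 && stats::sd(trimmed) > 0) {
    w <- unname(stats::shapiro.test(trimmed)$statistic)
    w * stats::pnorm((0.35 - pattern$cov_isi) / 0.05)
  } else {
    NA_real_
  }
  pattern
}

#' Physiological exclusion rules
#'
#' A unit is kept only when its PNR is at least 20 dB, its
#' inconsistent-firing count stays within the physiological allowance, its
#' ISI distribution is plausibly normal (`p_d >= 0.5`), and its mean
#' discharge rate does not exceed 35 Hz. The inconsistency allowance is 50
#' per 16 s of firing span, scaled linearly with the span: the count of
#' refractory-violating intervals grows with recording length, so a fixed
#' count would be meaningless on shorter epochs (it would never bind) and
#' overly harsh on longer ones.
#'
#' @param pattern A `firing_pattern` with statistics computed.
#' @param n_i_max Inconsistent-firing allowance; defaults to
#'   `50 * span / 16` with `span` the first-to-last firing interval in
#'   seconds.
#' @return List with `keep` (flag) and `reasons` (character vector of
#'   violated rules, empty when kept).
#' @export
exclude_mu <- function(pattern, n_i_max = NULL) {
  if (is.null(n_i_max)) {
    span <- if (length(pattern$times) >= 2) diff(range(pattern$times)) else 0
    n_i_max <- 50 * span / 16
  }
  reasons <- character(0)
  if (is.na(pattern$pnr_db) || pattern$pnr_db < 20) reasons <- c(reasons, "PNR")
  if (is.na(pattern$n_inconsistent) || pattern$n_inconsistent > n_i_max) {
    reasons <- c(reasons, "n_I")
  }
  if (is.na(pattern$p_d) || pattern$p_d < 0.5) reasons <- c(reasons, "p_d")
  if (is.na(pattern$mdr_hz) || pattern$mdr_hz > 35) reasons <- c(reasons, "MDR")
  list(keep = length(reasons) == 0, reasons = reasons)
}

match_fraction <- function(a, b, tol_s) {
  if (length(a) == 0) return(0)
  hit <- vapply(a, function(t) any(abs(b - t) <= tol_s), logical(1))
  mean(hit)
}

#' Remove duplicate motor units
#'
#' Two patterns are duplicates when at least `quota` of the smaller train's
#' firings match the other within `tol_ms` after compensating a constant lag
#' (extension-based CKC recovers each source at an arbitrary constant delay
#' of up to roughly the extension window plus the MUAP support, so the lag
#' is searched over `lag_ms`). Among duplicates the pattern with
#' the highest PNR survives (ties toward the lower `mu_id`).
#'
#' @param patterns List of `firing_pattern`s.
#' @param quota Match fraction declaring a duplicate.
#' @param tol_ms Matching tolerance, ms.
#' @param lag_ms Half-range of the constant-lag search, ms.
#' @return The deduplicated list, in the original order.
#' @export
deduplicate <- function(patterns, quota = 0.5, tol_ms = 0.5, lag_ms = 10) {
  n <- length(patterns)
  if (n <= 1) return(patterns)
  pnrs <- vapply(patterns, function(p) {
    ifelse(is.na(p$pnr_db), -Inf, p$pnr_db)
  }, numeric(1))
  ids <- vapply(patterns, function(p) as.numeric(p$mu_id), numeric(1))
  rank_order <- order(-pnrs, ids)
  keep <- logical(n)
  for (i in rank_order) {
    dup <- FALSE
    ti <- patterns[[i]]$times
    for (j in which(keep)) {
      tj <- patterns[[j]]$times
      if (length(ti) == 0 || length(tj) == 0) next
      small <- if (length(ti) <= length(tj)) ti else tj
      big <- if (length(ti) <= length(tj)) tj else ti
      lag <- best_lag(small, big, max_lag_s = lag_ms / 1000)
      if (match_fraction(small + lag, big, tol_ms / 1000) >= quota) {
        dup <- TRUE
        break
      }
    }
    keep[i] <- !dup
  }
  patterns[keep]
}

# TP-maximizing constant lag between two sorted firing trains, found from the
# mode of the pairwise time differences within +/- max_lag_s.
best_lag <- function(est, truth, max_lag_s = 0.01, tol_s = 5e-4) {
  if (length(est) == 0 || length(truth) == 0) return(0)
  d <- outer(truth, est, "-")
  d <- d[abs(d) <= max_lag_s]
  if (length(d) == 0) return(0)
  cand <- unique(round(d / tol_s) * tol_s)
  hits <- vapply(cand, function(l) sum(abs(d - l) <= tol_s), numeric(1))
  best <- cand[which.max(hits)]
  stats::median(d[abs(d - best) <= tol_s])
}
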