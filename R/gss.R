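#' Decomposition configuration
#'
#' Collects every tunable of the CKC stage. Defaults follow standard
#' practice for offline HD-sEMG decomposition; see the methods vignette for
#' the rationale behind each value.
#'
#' @param eta0 Initial gradient step size.
#' @param eta_tau Step-size decay constant: `eta(g) = eta0 / (1 + g / eta_tau)`.
#' @param contrast Update nonlinearity: `"sqsign"` (signed square
#'   `f(x) = alpha x |x|`, the sparse-source skewness contrast; default) or
#'   `"log"` (`f(x) = alpha log(1 + x^2)`). See the methods vignette for why
#'   the signed square is the default at reduced channel counts.
#' @param max_iters Hard iteration cap per motor unit.
#' @param use_kalman Use the EM-Kalman accelerated update.
#' @param corr_threshold Pearson correlation above which a marginal spike's
#'   sEMG segment counts as matching the cluster-representative template.
#' @param pnr_stop_db Stop when PNR improves by less than this over
#'   `pnr_window` iterations.
#' @param pnr_window Window (iterations) for the PNR plateau stop.
#' @param stable_iters Stop when the detected firing set is unchanged for
#'   this many consecutive iterations.
#' @param cw Diagonal entry of the Kalman process-noise covariance.
#' @param n_candidates Number of threshold candidates in the greedy search.
#' @param n_boot Bootstrap resamples for the threshold 95% CI.
#' @param pnr_squared Use squared samples in the PNR (the cited PNR
#'   convention); `FALSE` uses raw values.
#' @param soft_threshold Apply the adaptive soft-thresholding rule (CI band
#'   plus template correlation); `FALSE` reduces to a plain threshold, as in
#'   the unmodified gCKC comparator.
#' @return A list of class `gckc_config`.
#' @export
gckc_config <- function(eta0 = 1.0, eta_tau = 20, max_iters = 150,
                        use_kalman = TRUE, corr_threshold = 0.8,
                        pnr_stop_db = 0.1, pnr_window = 5,
                        stable_iters = 3, cw = 1e-4,
                        n_candidates = 25, n_boot = 200,
                        pnr_squared = TRUE, soft_threshold = TRUE,
                        contrast = c("sqsign", "log")) {
  stopifnot(max_iters >= 1)
  contrast <- match.arg(contrast)
  structure(as.list(environment()), class = "gckc_config")
}

eta_schedule <- function(g, cfg) cfg$eta0 / (1 + g / cfg$eta_tau)

#' CKC spike-train estimate
#'
#' The linear minimum-mean-square estimate of a source train:
#' `t = r' Rxx^-1 X`. On whitened observations `Rxx` is the identity and the
#' estimate reduces to `r' X`.
#'
#' @param obs An `extended_obs` (whitened, or carrying `Rxx_inv`).
#' @param r The MU filter (cross-correlation vector), length `N`.
#' @return Numeric vector of length `M`.
#' @export
ckc_estimate <- function(obs, r) {
  if (is.null(obs$whitening)) {
    if (is.null(obs$Rxx_inv)) {
      Rxx <- tcrossprod(obs$X) / ncol(obs$X)
      obs$Rxx_inv <- tryCatch(solve(Rxx), error = function(e) {
        stop("singular correlation matrix; whiten() the observation ",
             "or supply regularization")
      })
    }
    drop(crossprod(r, obs$Rxx_inv) %*% obs$X)
  } else {
    drop(crossprod(r, obs$X))
  }
}

#' Initialize a MU filter from an initial point
#'
#' The filter is seeded with the observation column at the initial point:
#' the instantaneous spatial signature of whatever fired there.
#'
#' @param obs An `extended_obs`.
#' @param sample_index 0-based sample index of the initial point.
#' @return Numeric filter vector of length `N`.
#' @export
init_filter <- function(obs, sample_index) {
  m <- as.integer(sample_index) + 1L
  if (m < 1 || m > ncol(obs$X)) stop("initial point outside the recording")
  obs$X[, m]
}

#' Pulse-to-noise ratio
#'
#' `10 log10` of the mean (squared) spike-train value at and above the
#' threshold over the mean below it.
#'
#' @param values Spike-train estimate.
#' @param thr Detection threshold.
#' @param squared Use squared samples (default).
#' @return PNR in dB; `NA` if either class is empty.
#' @export
pnr <- function(values, thr, squared = TRUE) {
  hi <- values >= thr
  if (!any(hi) || all(hi)) return(NA_real_)
  if (squared) {
    10 * log10(mean(values[hi]^2) / mean(values[!hi]^2))
  } else {
    10 * log10(mean(values[hi]) / mean(values[!hi]))
  }
}

local_peaks <- function(values) {
  n <- length(values)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  1L + which(values[i] > values[i - 1] & values[i] >= values[i + 1] &
               values[i] > 0)
}

pnr_of_peaks <- function(amp, thr, squared = TRUE, floor_ms = 0) {
  hi <- amp >= thr
  if (!any(hi) || all(hi)) return(NA_real_)
  if (squared) {
    10 * log10(mean(amp[hi]^2) / max(mean(amp[!hi]^2), floor_ms))
  } else {
    10 * log10(mean(amp[hi]) / max(mean(amp[!hi]), sqrt(floor_ms)))
  }
}

# Evaluate the floored peak-class PNR at every split between consecutive
# upper order statistics of amp, in one vectorized pass; returns the best
# split's threshold (midpoint of the gap) and PNR.
best_split <- function(amp, n_top, squared = TRUE) {
  n <- length(amp)
  s <- sort(amp)
  floor_ms <- if (squared) s[(n + 1L) %/% 2L]^2 else s[(n + 1L) %/% 2L]
  v <- if (squared) s^2 else s
  cs <- cumsum(v)
  i <- seq.int(max(1L, n - n_top), n - 1L)  # noise class = s[1..i]
  ms_lo <- pmax(cs[i] / i, floor_ms)
  ms_hi <- (cs[n] - cs[i]) / (n - i)
  p <- 10 * log10(ms_hi / ms_lo)
  k <- which.max(p)
  list(thr = (s[i[k]] + s[i[k] + 1L]) / 2, pnr_db = p[k])
}

#' Greedy PNR-maximizing threshold search
#'
#' Evaluates the pulse-to-noise ratio over candidate thresholds placed at
#' the midpoints between consecutive upper order statistics of the peak
#' amplitudes (adaptively spaced tail quantiles: a candidate falls inside
#' every amplitude gap, however wide) and returns the maximizer. The pulse
#' and noise classes are the local maxima of the estimate at or above versus
#' below the candidate — the pulse/baseline-peak dichotomy of the PNR
#' literature — with the noise-class power floored at the typical (median)
#' noise-peak power so that near-empty noise classes cannot inflate the
#' ratio. A nonparametric bootstrap (resampling the peak amplitudes and
#' re-running the search) yields the 95% confidence interval of the
#' threshold.
#'
#' @param values Spike-train estimate.
#' @param cfg A [gckc_config()].
#' @param n_top Number of upper order statistics considered as candidate
#'   split points.
#' @return List with `thr`, `ci` (length-2), `pnr_db`, `peaks` (indices of
#'   local maxima).
#' @export
optimize_threshold <- function(values, cfg = gckc_config(), n_top = 400) {
  pk <- local_peaks(values)
  if (length(pk) < 3 || stats::sd(values) == 0) {
    stop("degenerate spike-train estimate: no usable peaks")
  }
  amp <- values[pk]
  opt <- best_split(amp, n_top, cfg$pnr_squared)
  thr_b <- numeric(cfg$n_boot)
  for (b in seq_len(cfg$n_boot)) {
    ra <- amp[sample.int(length(amp), replace = TRUE)]
    thr_b[b] <- best_split(ra, n_top, cfg$pnr_squared)$thr
  }
  ci <- unname(stats::quantile(thr_b, c(0.025, 0.975)))
  ci[1] <- min(ci[1], opt$thr); ci[2] <- max(ci[2], opt$thr)
  list(thr = opt$thr, ci = ci, pnr_db = opt$pnr_db, peaks = pk)
}

#' Per-spike attenuation for adaptive soft-thresholding
#'
#' Spikes above the upper 95% CI of the threshold get `alpha = 1`. Marginal
#' spikes (inside the CI band) get `alpha = 1` only when the Pearson
#' correlation between their 2-ms sEMG segment and the cluster-representative
#' template reaches `cfg$corr_threshold`; otherwise `alpha = 0.9`.
#'
#' @param values Spike-train estimate.
#' @param thr_info Result of [optimize_threshold()].
#' @param correlator `function(sample_index)` returning the segment-template
#'   Pearson correlation, or `NULL` (all marginal spikes then keep
#'   `alpha = 1`).
#' @param cfg A [gckc_config()].
#' @return List with `alpha` (length-M vector, 1 except at attenuated
#'   spikes), `kept` (sample indices of detected firings) and `marginal`.
#' @export
assign_alpha <- function(values, thr_info, correlator = NULL,
                         cfg = gckc_config()) {
  alpha <- rep(1, length(values))
  pk <- thr_info$peaks
  if (!cfg$soft_threshold) {
    return(list(alpha = alpha, kept = pk[values[pk] >= thr_info$thr],
                marginal = integer(0)))
  }
  ci <- thr_info$ci
  above <- pk[values[pk] > ci[2]]
  marginal <- pk[values[pk] >= ci[1] & values[pk] <= ci[2]]
  kept <- above
  for (m in marginal) {
    rho <- if (is.null(correlator)) 1 else correlator(m)
    if (!is.na(rho) && rho >= cfg$corr_threshold) {
      kept <- c(kept, m)
    } else {
      alpha[m] <- 0.9
    }
  }
  list(alpha = alpha, kept = sort(kept), marginal = marginal)
}

f_ckc <- function(x, alpha = 1, contrast = "sqsign") {
  switch(contrast,
         sqsign = alpha * x * abs(x),
         log = alpha * log1p(x^2),
         stop("unknown contrast"))
}

#' One gradient-CKC update
#'
#' The cross-correlation update `r_g = r_{g-1} + eta(g) * X f(t)` with the
#' attenuated contrast `f` applied element-wise. With `normalize = TRUE`
#' (the pipeline's mode) the gradient is scaled to unit norm before the step
#' and the filter renormalized afterwards, so `eta` is a rotation angle and
#' the iteration is well conditioned regardless of the estimate's scale;
#' with `normalize = FALSE` the raw update is applied verbatim.
#'
#' @param r Current filter.
#' @param obs An `extended_obs`.
#' @param values Current spike-train estimate.
#' @param alpha Per-sample attenuation vector.
#' @param eta Step size.
#' @param contrast Update nonlinearity (see [gckc_config()]).
#' @param normalize Normalize gradient and filter (default `TRUE`).
#' @return The updated filter.
#' @export
gckc_update <- function(r, obs, values, alpha = rep(1, length(values)),
                        eta = 1.0, contrast = "sqsign", normalize = TRUE) {
  g <- drop(obs$X %*% f_ckc(values, alpha, contrast))
  if (normalize) {
    ng <- sqrt(sum(g^2))
    if (ng > 0) g <- g / ng
  }
  r <- r + eta * g
  if (normalize) {
    nr <- sqrt(sum(r^2))
    if (nr > 0) r <- r / nr
  }
  r
}

#' Initialize the EM-Kalman state
#'
#' State vector `x = [r; 1]`, error covariance `P = I`, observation-noise
#' variance 0.
#'
#' @param r Current MU filter.
#' @param cfg A [gckc_config()].
#' @return A `kalman_state` list.
#' @export
kalman_init <- function(r, cfg = gckc_config()) {
  N <- length(r)
  structure(
    list(x = c(r, 1), P = diag(N + 1), sigma2 = 0, cw = cfg$cw, k = 0L),
    class = "kalman_state"
  )
}

#' One EM-Kalman step of the accelerated gCKC update
#'
#' Predicts the augmented state `[r; 1]` through the same gradient
#' transition as [gckc_update()] (with state-coupled process noise
#' `w = C_w x`), output-normalizes the prediction to unit spike-train
#' standard deviation, re-estimates the observation-noise variance from the
#' predicted train and the error covariance (EM step), and applies the
#' measurement update for all M samples simultaneously in information
#' (batch least-squares) form — the exact simultaneous solution of the
#' per-sample gain equations, which sequential gains would otherwise
#' double-count. The innovation is measured against the adaptively
#' soft-thresholded spike train (detected spikes kept, attenuated marginal
#' spikes damped, baseline zeroed), so each step regresses the filter onto
#' the denoised spike hypothesis while the covariance tracks the remaining
#' uncertainty. The homogeneous state entry is re-pinned to 1 and the
#' covariance re-symmetrized (PSD-projected if numerically indefinite).
#'
#' @param state A `kalman_state`.
#' @param obs An `extended_obs` (whitened; the update exploits
#'   `XX' = M I`).
#' @param values_prev Spike-train estimate of the previous iteration
#'   (unit sd).
#' @param alpha Per-sample attenuation.
#' @param eta Step size for this iteration.
#' @param contrast Update nonlinearity (see [gckc_config()]).
#' @param target Soft-thresholded measurement train; defaults to
#'   `alpha * values_prev` at its suprathreshold support when supplied by
#'   [decompose_mu()], or to `values_prev` (pure tracking) when `NULL`.
#' @return The updated `kalman_state`; element `values` holds the predicted
#'   spike train used for the innovation.
#' @export
kalman_step <- function(state, obs, values_prev, alpha, eta,
                        contrast = "sqsign", target = NULL) {
  X <- obs$X
  N <- nrow(X); M <- ncol(X)
  r <- state$x[1:N]
  b <- drop(X %*% f_ckc(values_prev, alpha, contrast))
  nb <- sqrt(sum(b^2))
  if (nb > 0) b <- b / nb
  r_pred <- r + eta * b
  x_pred <- c(r_pred, 1)
  x_pred <- x_pred + state$cw * x_pred  # w_k = C_w x_pred
  # P_pred = F P F' + Cw Cw'
  P <- state$P
  Fp <- P
  Fp[1:N, ] <- Fp[1:N, ] + eta * tcrossprod(b, P[N + 1L, ])
  P_pred <- Fp
  P_pred[, 1:N] <- P_pred[, 1:N] + eta * tcrossprod(Fp[, N + 1L], b)
  diag(P_pred) <- diag(P_pred) + state$cw^2
  P_pred <- (P_pred + t(P_pred)) / 2
  t_pred <- drop(crossprod(X, x_pred[1:N]))
  # output normalization: innovations compare unit-variance spike trains,
  # so rescale the predicted state (covariance quadratically) to unit
  # output sd; keeps the filter scale bounded across iterations
  s <- stats::sd(t_pred)
  if (s > 0) {
    x_pred[1:N] <- x_pred[1:N] / s
    P_pred[1:N, ] <- P_pred[1:N, ] / s
    P_pred[, 1:N] <- P_pred[, 1:N] / s
    t_pred <- t_pred / s
  }
  # EM noise-variance estimate; for whitened X the mean quadratic form
  # H'(m) P H(m) over samples equals tr(P_rr) exactly
  q_bar <- sum(diag(P_pred)[1:N])
  sigma2 <- max(mean(t_pred^2) + q_bar - mean(t_pred), 1e-8)
  if (is.null(target)) target <- values_prev
  delta <- target - t_pred
  # information-form simultaneous measurement update:
  # P_new = (P_pred^-1 + H H' / sigma2)^-1 with H H' = [[M I, 0], [0, 0]]
  info <- tryCatch(solve(P_pred), error = function(e) {
    solve(P_pred + 1e-8 * diag(N + 1L))
  })
  diag(info)[1:N] <- diag(info)[1:N] + M / sigma2
  P_new <- solve(info)
  P_new <- (P_new + t(P_new)) / 2
  u <- c(drop(X %*% delta), 0) / sigma2
  x_new <- x_pred + drop(P_new %*% u)
  ch <- tryCatch(chol(P_new + 1e-10 * diag(N + 1L)), error = function(e) NULL)
  if (is.null(ch)) {
    eg <- eigen(P_new, symmetric = TRUE)
    P_new <- eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors))
    P_new <- (P_new + t(P_new)) / 2
  }
  x_new[N + 1L] <- 1
  state$x <- x_new
  state$P <- P_new
  state$sigma2 <- sigma2
  state$k <- state$k + 1L
  state$values <- t_pred
  state
}

#' Decompose one motor unit from an initial point
#'
#' Seeds the MU filter at the initial point, performs one plain gradient-CKC
#' iteration, then iterates estimate / threshold-optimize / soft-threshold /
#' update (Kalman-accelerated or plain gradient) until the detected firing
#' set stabilizes, the PNR plateaus, or the iteration cap is reached.
#'
#' @param obs A whitened `extended_obs`.
#' @param sample_index 0-based initial point.
#' @param cfg A [gckc_config()].
#' @param correlator Optional segment-template correlator for marginal
#'   spikes (see [assign_alpha()]).
#' @param seed Integer seed for the bootstrap CI (deterministic per MU).
#' @return A list of class `spike_train_estimate`: `values`, `thr`, `ci`,
#'   `pnr_db`, `kept` (firing sample indices, 1-based), `alpha`, `filter`,
#'   `iterations`, `converged`.
#' @export
decompose_mu <- function(obs, sample_index, cfg = gckc_config(),
                         correlator = NULL, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    r <- init_filter(obs, sample_index)
    r <- r / sqrt(sum(r^2))
    values <- ckc_estimate(obs, r)
    if (cfg$use_kalman) {
      r_plain <- gckc_update(r, obs, values, eta = eta_schedule(1, cfg),
                             contrast = cfg$contrast)
      state <- kalman_init(r_plain, cfg)
    } else {
      r <- gckc_update(r, obs, values, eta = eta_schedule(1, cfg),
                       contrast = cfg$contrast)
    }
    prev_kept <- NULL
    stable <- 0L
    pnr_hist <- numeric(0)
    kept <- integer(0)
    thr_info <- NULL
    al <- NULL
    iterations <- 1L
    converged <- FALSE
    for (g in 2:cfg$max_iters) {
      if (cfg$use_kalman) r <- state$x[seq_len(nrow(obs$X))]
      values <- ckc_estimate(obs, r)
      if (!all(is.finite(values))) {
        return(structure(list(values = values, failed = TRUE,
                              iterations = iterations),
                         class = "spike_train_estimate"))
      }
      sv <- stats::sd(values)
      if (sv > 0) values <- values / sv
      thr_info <- tryCatch(optimize_threshold(values, cfg),
                           error = function(e) NULL)
      if (is.null(thr_info)) {
        return(structure(list(values = values, failed = TRUE,
                              iterations = iterations),
                         class = "spike_train_estimate"))
      }
      al <- assign_alpha(values, thr_info, correlator, cfg)
      kept <- al$kept
      iterations <- g
      pnr_hist <- c(pnr_hist, thr_info$pnr_db)
      # stability is judged on the deterministic suprathreshold-peak set;
      # the bootstrap CI adds jitter to the soft-thresholded set that would
      # mask convergence
      stab_set <- thr_info$peaks[values[thr_info$peaks] >= thr_info$thr]
      if (!is.null(prev_kept) && identical(stab_set, prev_kept)) {
        stable <- stable + 1L
      } else {
        stable <- 0L
      }
      prev_kept <- stab_set
      if (stable >= cfg$stable_iters) { converged <- TRUE; break }
      np <- length(pnr_hist)
      if (np > cfg$pnr_window &&
          pnr_hist[np] - pnr_hist[np - cfg$pnr_window] < cfg$pnr_stop_db) {
        converged <- TRUE
        break
      }
      eta <- eta_schedule(g, cfg)
      if (cfg$use_kalman) {
        z <- numeric(length(values))
        z[al$kept] <- values[al$kept]
        att <- setdiff(al$marginal, al$kept)
        z[att] <- 0.9 * values[att]
        state <- kalman_step(state, obs, values, al$alpha, eta,
                             contrast = cfg$contrast, target = z)
      } else {
        r <- gckc_update(r, obs, values, al$alpha, eta,
                         contrast = cfg$contrast)
      }
    }
    structure(
      list(values = values, thr = thr_info$thr, ci = thr_info$ci,
           pnr_db = thr_info$pnr_db, kept = kept, alpha = al$alpha,
           marginal = al$marginal, filter = r, iterations = iterations,
           converged = converged, failed = FALSE),
      class = "spike_train_estimate"
    )
  })
}

#' @export
print.spike_train_estimate <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat("<spike_train_estimate> failed (degenerate or divergent)\n")
  } else {
    cat(sprintf(
      "<spike_train_estimate> %d firings, PNR %.1f dB, %d iterations%s\n",
      length(x$kept), x$pnr_db, x$iterations,
      if (x$converged) "" else " (cap reached)"))
  }
  invisible(x)
}
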