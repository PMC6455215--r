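test_that("the CKC estimator reduces to algebra on a single source", {
  withr::with_seed(10, t_src <- rnorm(500))
  t_src <- t_src - mean(t_src)
  g <- electrode_grid(rows = 1, cols = 1, fs_hz = 1000)
  obs <- extend(emg_recording(matrix(t_src, 1), 1000, g, "monopolar"), 1)
  # r = E[t^2]: with Rxx = E[t^2] the estimate is t itself
  est <- ckc_estimate(obs, mean(t_src^2))
  expect_equal(est, t_src, tolerance = 1e-6)
  # r = 0 -> zero estimate
  expect_equal(ckc_estimate(obs, 0), rep(0, 500))
})

test_that("filters initialize from observation columns", {
  obs <- fix_toy_obs()
  r <- init_filter(obs, 100)          # 0-based index
  expect_equal(r, obs$X[, 101])
  expect_identical(init_filter(obs, 100), init_filter(obs, 100))
  expect_error(init_filter(obs, ncol(obs$X)), "outside")
})

test_that("initialization at a true firing beats a baseline sample", {
  toy <- fix_toy()
  obs <- fix_toy_obs()
  cfg <- gckc_config(n_boot = 50)
  pnr_of <- function(col) {
    r <- obs$X[, col]
    v <- drop(crossprod(r, obs$X)); v <- v / stats::sd(v)
    optimize_threshold(v, cfg)$pnr_db
  }
  spikes <- toy$spikes[[1]]
  all_spk <- sort(unlist(toy$spikes))
  base_cols <- setdiff(200:2800, outer(all_spk, -6:6, "+"))
  withr::with_seed(11, {
    p_spk <- vapply(sample(spikes, 10), pnr_of, numeric(1))
    p_base <- vapply(sample(base_cols, 20), pnr_of, numeric(1))
  })
  expect_gt(stats::median(p_spk), stats::median(p_base))
})

test_that("PNR matches direct computation and its conventions", {
  values <- c(rep(0.2, 90), rep(2, 10))
  expect_equal(pnr(values, 1), 10 * log10(4 / 0.04), tolerance = 1e-12)
  # equal class energies give 0 dB
  expect_equal(pnr(c(rep(1, 5), rep(-1, 5)), 0.5), 0, tolerance = 1e-12)
  # scale invariance
  withr::with_seed(12, v <- abs(rnorm(1000)))
  expect_equal(pnr(3 * v, 3 * 0.8), pnr(v, 0.8), tolerance = 1e-12)
  # empty class -> NA sentinel
  expect_true(is.na(pnr(values, 10)))
})

test_that("threshold search separates bimodal peak amplitudes", {
  withr::with_seed(13, {
    v <- abs(rnorm(5000)) * 0.5
    idx <- seq(25, 4975, by = 50)
    v[idx] <- 10 + rnorm(length(idx), sd = 0.3)
  })
  cfg <- gckc_config()
  withr::with_seed(1, ti <- optimize_threshold(v, cfg))
  expect_gt(ti$thr, 3)
  expect_lt(ti$thr, 9)
  expect_true(ti$ci[1] <= ti$thr && ti$thr <= ti$ci[2])
  # detected pulse class is exactly the injected spikes
  kept <- ti$peaks[v[ti$peaks] >= ti$thr]
  expect_setequal(kept, idx)
  # homogeneity: scaling values scales the threshold and CI
  withr::with_seed(1, ti2 <- optimize_threshold(2.5 * v, cfg))
  expect_equal(ti2$thr, 2.5 * ti$thr, tolerance = 1e-10)
  expect_equal(ti2$ci, 2.5 * ti$ci, tolerance = 1e-10)
  # PNR is invariant to that scaling
  expect_equal(ti2$pnr_db, ti$pnr_db, tolerance = 1e-10)
  expect_error(optimize_threshold(rep(1, 100), cfg), "degenerate")
})

test_that("returned threshold maximizes the PNR objective over splits", {
  withr::with_seed(14, {
    v <- abs(rnorm(3000)) * 0.4
    v[seq(10, 2990, by = 40)] <- 8 + rnorm(75, sd = 0.5)
  })
  cfg <- gckc_config(n_boot = 20)
  withr::with_seed(2, ti <- optimize_threshold(v, cfg))
  amp <- v[ti$peaks]
  # compare against a grid of alternative thresholds
  floor_ms <- stats::median(amp)^2
  for (th in stats::quantile(amp, c(0.5, 0.9, 0.97, 0.999))) {
    hi <- amp >= th
    if (!any(hi) || all(hi)) next
    p_alt <- 10 * log10(mean(amp[hi]^2) / max(mean(amp[!hi]^2), floor_ms))
    expect_gte(ti$pnr_db + 1e-9, p_alt)
  }
})

test_that("marginal spikes are kept or attenuated by template correlation", {
  withr::with_seed(15, v <- abs(rnorm(2000)) * 0.3)
  spikes <- seq(50, 1950, by = 100)
  v[spikes] <- 5
  marg <- c(400, 900)
  v[marg] <- 2.2
  thr_info <- list(thr = 2.0, ci = c(1.8, 3.0),
                   peaks = find_peaks(v))
  cfg <- gckc_config()
  # correlator that recognizes one marginal spike but not the other
  correlator <- function(m) if (m == 400) 0.95 else 0.1
  al <- assign_alpha(v, thr_info, correlator, cfg)
  expect_true(400 %in% al$kept)
  expect_false(900 %in% al$kept)
  expect_equal(al$alpha[900], 0.9)
  expect_equal(al$alpha[400], 1)
  # spikes far above the upper CI are always alpha = 1 and kept
  expect_true(all(spikes %in% al$kept))
  expect_true(all(al$alpha[spikes] == 1))
  # without a correlator, marginal spikes pass
  al2 <- assign_alpha(v, thr_info, NULL, cfg)
  expect_true(all(marg %in% al2$kept))
})

test_that("one raw gradient update equals the hand-evaluated formula", {
  # 5-sample instance, both contrasts, exact to machine tolerance
  X <- matrix(c(1, -2, 0.5, 3, -1,
                0.2, 1, -1, 0.4, 2), nrow = 2, byrow = TRUE)
  g <- electrode_grid(rows = 2, cols = 1, fs_hz = 10)
  obs <- list(X = X, R = 1L, fs_hz = 10, channels = 2L,
              montage = "monopolar", whitening = NULL)
  class(obs) <- "extended_obs"
  r0 <- c(0.3, -0.7)
  tt <- c(0.5, -1, 2, 0.1, -0.3)
  alpha <- c(1, 0.9, 1, 1, 0.9)
  eta <- 0.37
  by_hand_sq <- r0 + eta * as.numeric(X %*% (alpha * tt * abs(tt)))
  got_sq <- gckc_update(r0, obs, tt, alpha, eta, contrast = "sqsign",
                        normalize = FALSE)
  expect_equal(got_sq, by_hand_sq, tolerance = 1e-14)
  by_hand_log <- r0 + eta * as.numeric(X %*% (alpha * log(1 + tt^2)))
  got_log <- gckc_update(r0, obs, tt, alpha, eta, contrast = "log",
                         normalize = FALSE)
  expect_equal(got_log, by_hand_log, tolerance = 1e-14)
})

test_that("trivial update cases leave the filter unchanged", {
  obs <- fix_toy_obs()
  r <- init_filter(obs, 500); r <- r / sqrt(sum(r^2))
  v <- drop(crossprod(r, obs$X))
  expect_equal(gckc_update(r, obs, v, eta = 0), r, tolerance = 1e-12)
  expect_equal(gckc_update(r, obs, rep(0, ncol(obs$X)), eta = 1), r,
               tolerance = 1e-12)
})

test_that("decomposition recovers a toy source from a true-firing seed", {
  toy <- fix_toy()
  obs <- fix_toy_obs()
  cfg <- gckc_config(max_iters = 40, n_boot = 50)
  est <- decompose_mu(obs, toy$spikes[[1]][4] - 1, cfg, seed = 5)
  expect_false(est$failed)
  got <- sort(est$kept)
  m <- match_firings_aligned((got - 1) / obs$fs_hz,
                             (toy$spikes[[1]] - 1) / obs$fs_hz)
  expect_gte(m$roa, 0.9)
})

test_that("a single update is applied when the iteration cap is 1", {
  obs <- fix_toy_obs()
  cfg <- gckc_config(max_iters = 1)
  est <- decompose_mu(obs, 500, cfg, seed = 1)
  expect_lte(est$iterations, 1)
})

test_that("PNR is non-decreasing over early iterations from good seeds", {
  toy <- fix_toy()
  obs <- fix_toy_obs()
  cfg <- gckc_config(n_boot = 30)
  pnr_trace <- function(m0, iters) {
    r <- init_filter(obs, m0); r <- r / sqrt(sum(r^2))
    out <- numeric(iters)
    for (g in seq_len(iters)) {
      v <- drop(crossprod(r, obs$X)); v <- v / stats::sd(v)
      ti <- optimize_threshold(v, cfg)
      out[g] <- ti$pnr_db
      r <- gckc_update(r, obs, v, eta = cfg$eta0 / (1 + g / cfg$eta_tau))
    }
    out
  }
  withr::with_seed(16, {
    traces <- lapply(toy$spikes[[2]][2:6] - 1, pnr_trace, iters = 12)
  })
  med <- apply(do.call(rbind, traces), 2, stats::median)
  expect_gte(med[12], med[1] - 0.5)
  expect_gt(med[12], 15)
})
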