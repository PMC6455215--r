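test_that("matching reproduces the signal-detection identities", {
  truth <- seq(0.1, 0.9, by = 0.1)            # 9 reference firings
  est <- c(truth[1:8] + 2e-4, 0.95)           # 8 matches + 1 extra
  m <- match_firings(est, truth)
  expect_equal(m$tp, 8L)
  expect_equal(m$fp, 1L)
  expect_equal(m$fn, 1L)
  expect_equal(m$roa, 0.8)
  expect_equal(m$sensitivity, 8 / 9)
  expect_equal(m$precision, 8 / 9)
  # identical trains are perfect
  m2 <- match_firings(truth, truth)
  expect_equal(c(m2$roa, m2$sensitivity, m2$precision), c(1, 1, 1))
  # a uniform 1-ms shift breaks every match at the 0.5-ms tolerance
  m3 <- match_firings(truth + 1e-3, truth)
  expect_equal(m3$tp, 0L)
  # and the aligned matcher recovers it
  m4 <- match_firings_aligned(truth + 1e-3, truth)
  expect_equal(m4$tp, 9L)
})

test_that("RoA is bounded by sensitivity and precision on random matches", {
  for (s in 1:20) {
    withr::with_seed(s, {
      truth <- sort(runif(30, 0, 5))
      est <- sort(c(truth[runif(30) < 0.7] + rnorm(30, 0, 2e-4)[1],
                    runif(8, 0, 5)))
    })
    m <- match_firings(est, truth)
    if (m$tp + m$fp == 0 || m$tp + m$fn == 0) next
    expect_lte(m$roa, min(m$sensitivity, m$precision) + 1e-12)
  }
})

test_that("matching is symmetric in FP and FN under train swap", {
  withr::with_seed(23, {
    truth <- sort(runif(25, 0, 4))
    est <- sort(c(truth[1:15] + 1e-4, runif(6, 0, 4)))
  })
  m_ab <- match_firings(est, truth)
  m_ba <- match_firings(truth, est)
  expect_equal(m_ab$tp, m_ba$tp)
  expect_equal(m_ab$fp, m_ba$fn)
  expect_equal(m_ab$fn, m_ba$fp)
  expect_equal(m_ab$roa, m_ba$roa)
})

test_that("the 30% rule decides identification", {
  truth <- seq(0.1, 1.0, by = 0.1)
  m3 <- list(tp = 3L); m2 <- list(tp = 2L); m10 <- list(tp = 10L)
  expect_true(is_identified(m3, 10))
  expect_false(is_identified(m2, 10))
  expect_true(is_identified(m10, 10))
  expect_error(is_identified(m3, 0), "empty")
})

test_that("cluster correctness follows the 75% time-locked rule", {
  truth <- tibble::tibble(mu_id = rep(c(1L, 2L), each = 40),
                          time_s = c(seq(0.05, 3.95, by = 0.1),
                                     seq(0.07, 3.97, by = 0.1)))
  on1 <- truth$time_s[truth$mu_id == 1][1:21]
  expect_true(cluster_correct(on1, truth))
  split <- c(truth$time_s[truth$mu_id == 1][1:10],
             truth$time_s[truth$mu_id == 2][30:40] + 0.004)
  expect_false(cluster_correct(split, truth))
  # 16 of 21 locked (76%) passes the quota
  mix <- c(on1[1:16], seq(10.0, 10.4, by = 0.1))
  expect_true(cluster_correct(mix, truth))
  expect_equal(attr(cluster_correct(on1, truth), "best_mu"), 1L)
})

test_that("spike-triggered averaging recovers the template", {
  sim <- fix_sim()
  grid <- sim$recording$grid
  id <- sim$truth$active_mu_ids[1]
  tmpl <- sim$templates[[as.character(id)]]
  single <- structure(list(
    firings = sim$truth$firings[sim$truth$firings$mu_id == id, ],
    excitation = 10, duration = 2.5, active_mu_ids = id, pool = sim$pool
  ), class = "ground_truth")
  rec1 <- render_emg(single, sim$templates, grid, 2.5)
  tt <- single$firings$time_s
  sta <- sta_muap(rec1, tt, half_window_s = ncol(tmpl) / 2 / grid$fs_hz)
  ref_t <- attr(tmpl, "ref_lag"); ref_s <- attr(sta, "ref_lag")
  L <- min(ref_t, ref_s) - 1
  Rn <- min(ncol(tmpl) - ref_t, ncol(sta) - ref_s)
  a <- tmpl[, (ref_t - L):(ref_t + Rn)]
  b <- sta[, (ref_s - L):(ref_s + Rn)]
  expect_lt(sqrt(mean((a - b)^2)) / sqrt(mean(a^2)), 0.01)
  # zero signal averages to zero
  zero <- emg_recording(matrix(0, nrow(rec1$data), ncol(rec1$data)),
                        grid$fs_hz, grid, "monopolar")
  expect_equal(sum(sta_muap(zero, tt)^2), 0)
  expect_error(sta_muap(rec1, tt[1:3]), "at least 5")
})

test_that("STA error shrinks with the number of averaged firings", {
  sim <- fix_sim()
  grid <- sim$recording$grid
  id <- sim$truth$active_mu_ids[1]
  single <- structure(list(
    firings = sim$truth$firings[sim$truth$firings$mu_id == id, ],
    excitation = 10, duration = 2.5, active_mu_ids = id, pool = sim$pool
  ), class = "ground_truth")
  clean <- render_emg(single, sim$templates, grid, 2.5)
  noisy <- add_colored_noise(clean, 20, seed = 9)
  tt <- single$firings$time_s
  err <- function(n) {
    sta_n <- sta_muap(noisy, tt[seq_len(n)], 0.005)
    sta_c <- sta_muap(clean, tt[seq_len(n)], 0.005)
    sqrt(mean((sta_n - sta_c)^2))
  }
  # averaging law: error at n = 20 is about half the error at n = 5
  expect_lt(err(20), err(5) * 0.75)
})

test_that("SIR spans its closed-form anchor points", {
  withr::with_seed(24, x <- matrix(rnorm(3 * 2000), 3))
  g <- electrode_grid(rows = 3, cols = 1, fs_hz = 1000)
  # build a recording that is exactly one template train
  tmpl <- matrix(rnorm(3 * 21), 3); attr(tmpl, "ref_lag") <- 11L
  firings <- c(0.2, 0.5, 0.8, 1.2, 1.6)
  rec0 <- emg_recording(matrix(0, 3, 2000), 1000, g, "monopolar")
  recon <- sir(rec0, list(firings), templates = list(tmpl))
  sig <- emg_recording(-recon$residual, 1000, g, "monopolar")
  # perfect reconstruction: SIR = 100%
  s_perf <- sir(sig, list(firings), templates = list(tmpl))
  expect_equal(s_perf$mean, 100, tolerance = 1e-9)
  # empty decomposition: SIR = 0%
  s_empty <- sir(sig, list(), templates = list())
  expect_equal(s_empty$mean, 0, tolerance = 1e-9)
  # half-power residual: scale the template by 1 - 1/sqrt(2)
  tmpl_h <- tmpl * (1 - 1 / sqrt(2)); attr(tmpl_h, "ref_lag") <- 11L
  s_half <- sir(sig, list(firings), templates = list(tmpl_h))
  expect_equal(s_half$mean, 50, tolerance = 1e-9)
  # channel permutation leaves the mean unchanged
  perm <- sample(3)
  sig_p <- emg_recording(sig$data[perm, ], 1000, g, "monopolar")
  tmpl_p <- tmpl[perm, ]; attr(tmpl_p, "ref_lag") <- 11L
  s_perm <- sir(sig_p, list(firings), templates = list(tmpl_p))
  expect_equal(sort(s_perm$per_channel), sort(s_perf$per_channel),
               tolerance = 1e-9)
})

test_that("decomposability indices follow the printed formula", {
  t1 <- matrix(0, 2, 10); t1[1, ] <- sqrt(0.4)  # ||m_11|| = 2
  t2 <- t1; t2[1, ] <- t1[1, ] - sqrt(0.1)      # ||m_11 - m_21|| = 1
  di <- decomposability(list(t1, t2), noise_rms = 0.5)
  expect_equal(di$di[1, 1], min(2, 1) / 0.5, tolerance = 1e-9)
  # identical competitor zeroes the index
  di0 <- decomposability(list(t1, t1), noise_rms = 0.5)
  expect_equal(di0$di[1, 1], 0)
  # no competitor: ||m|| / V_RMS
  di1 <- decomposability(list(t1), noise_rms = 0.5)
  expect_equal(di1$di[1, 1], 2 / 0.5)
  expect_equal(di1$cdi[1], (2 / 0.5 + 0) / 2)
})
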