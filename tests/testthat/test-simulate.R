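test_that("motor-unit pool reproduces the prescribed distributions", {
  pool <- build_mu_pool(1000, seed = 1)
  expect_equal(mean(pool$cv_ms), 4.0, tolerance = 0.05 / 4.0)
  expect_gte(min(pool$n_fibers), 24)
  expect_lte(max(pool$n_fibers), 2048)
  expect_gte(min(pool$cv_ms), 2.5)
  # exponential recruitment ladder spans (0, 0.6] of MVC
  expect_lte(max(pool$recruitment_threshold), 0.6 + 1e-12)
  expect_gt(min(pool$recruitment_threshold), 0)
  # size principle: fiber count and threshold co-monotone
  expect_gt(stats::cor(pool$n_fibers, pool$recruitment_threshold,
                       method = "spearman"), 0.99)
  # territory area consistent with 20 fibers/mm^2
  expect_equal(pool$n_fibers / (pi * pool$territory_radius_mm^2),
               rep(20, 1000), tolerance = 1e-8)
})

test_that("pool generation is deterministic for a fixed seed", {
  expect_identical(build_mu_pool(5, seed = 7), build_mu_pool(5, seed = 7))
  expect_false(identical(build_mu_pool(5, seed = 7),
                         build_mu_pool(5, seed = 8)))
  expect_error(build_mu_pool(0, seed = 1), "positive")
})

test_that("firing trains follow the linear rate-coding rule", {
  pool <- build_mu_pool(3, seed = 2)
  pool$recruitment_threshold <- c(0, 0.05, 0.95)
  truth <- generate_firing_trains(pool, excitation = 10, duration = 16,
                                  seed = 4)
  # MU with threshold 0 at 10% MVC fires at 8 + 0.3 * 10 = 11 pps
  t1 <- truth$firings$time_s[truth$firings$mu_id == 1]
  mdr <- (length(t1) - 1) / (max(t1) - min(t1))
  expect_equal(mdr, 11, tolerance = 0.02)
  # MU above the excitation level stays silent
  expect_false(3 %in% truth$firings$mu_id)
  expect_true(all(diff(t1) > 0))
})

test_that("excitation below every threshold recruits no one", {
  pool <- build_mu_pool(4, seed = 2)
  pool$recruitment_threshold <- rep(0.5, 4)
  truth <- generate_firing_trains(pool, excitation = 10, duration = 2,
                                  seed = 1)
  expect_length(truth$active_mu_ids, 0)
  expect_equal(nrow(truth$firings), 0)
  expect_error(generate_firing_trains(pool[0, ], 10, 2), "empty")
})

test_that("ISI variability matches the requested coefficient of variation", {
  pool <- build_mu_pool(1, seed = 5)
  pool$recruitment_threshold <- 0
  # ~10,000 ISIs at ~11 pps
  truth <- generate_firing_trains(pool, excitation = 10, duration = 910,
                                  isi_cov = 0.14, seed = 6)
  isi <- diff(truth$firings$time_s)
  expect_gt(length(isi), 9000)
  expect_equal(stats::sd(isi) / mean(isi), 0.14, tolerance = 0.01 / 0.14)
  expect_gte(min(isi), 0.02)
  # rate cap at 35 pps
  truth_hi <- generate_firing_trains(pool, excitation = 100, duration = 20,
                                     seed = 6)
  t_hi <- truth_hi$firings$time_s
  expect_lte((length(t_hi) - 1) / (max(t_hi) - min(t_hi)), 35 * 1.02)
})

test_that("MUAP templates decay with depth and scale with fiber count", {
  grid <- electrode_grid(rows = 5, cols = 3)
  pool <- build_mu_pool(2, seed = 9)
  pool$x_mm <- 0; pool$y_mm <- 0
  pool$n_fibers <- 500L
  pool$cv_ms <- 4; pool$shape_scale_mm <- 2; pool$polarity <- 1
  pool$depth_mm <- c(3, 9)
  tm <- synthesize_muaps(pool, grid)
  p2p <- vapply(tm, function(t) max(t) - min(t), numeric(1))
  expect_gt(p2p[1], p2p[2])
  # doubling the fiber count doubles the template linearly
  pool2 <- pool; pool2$n_fibers <- 1000L
  tm2 <- synthesize_muaps(pool2, grid)
  expect_equal(tm2[[1]][, ], 2 * tm[[1]][, ], tolerance = 1e-12)
})

test_that("propagation delay between rows equals ied / CV", {
  grid <- electrode_grid(rows = 5, cols = 1, ied_mm = 5, fs_hz = 40960)
  pool <- build_mu_pool(1, seed = 9)
  pool$x_mm <- 0; pool$y_mm <- 0; pool$depth_mm <- 3
  pool$cv_ms <- 5; pool$shape_scale_mm <- 2; pool$polarity <- 1
  tm <- synthesize_muaps(pool, grid)[[1]]
  # CV = 5 m/s, ied = 5 mm -> 1 ms inter-row peak delay
  peaks <- apply(abs(tm), 1, which.max)
  expect_equal(diff(peaks) / grid$fs_hz, rep(1e-3, 4), tolerance = 0.02)
})

test_that("rendering is linear and respects the firing-time reference", {
  grid <- electrode_grid(rows = 4, cols = 3, fs_hz = 4096)
  pool <- build_mu_pool(2, seed = 11)
  pool$depth_mm <- c(2, 4)
  templates <- synthesize_muaps(pool, grid)
  mk_truth <- function(ids, times) {
    structure(list(
      firings = tibble::tibble(
        mu_id = rep(ids, lengths(times)),
        time_s = unlist(times)),
      excitation = 10, duration = 1, active_mu_ids = ids, pool = pool
    ), class = "ground_truth")
  }
  t1 <- mk_truth(1L, list(0.5))
  rec1 <- render_emg(t1, templates, grid, 1)
  # the template sits at the firing with its reference lag on the peak
  tmpl <- templates[["1"]]
  ref <- attr(tmpl, "ref_lag")
  s0 <- round(0.5 * 4096) + 1
  expect_equal(rec1$data[, (s0 - ref + 1):(s0 - ref + ncol(tmpl))],
               tmpl[, ], tolerance = 1e-12)
  # superposition: two-MU render equals the sum of single-MU renders
  t2 <- mk_truth(2L, list(0.52))
  t12 <- mk_truth(c(1L, 2L), list(0.5, 0.52))
  rec12 <- render_emg(t12, templates, grid, 1)
  rec2 <- render_emg(t2, templates, grid, 1)
  expect_equal(rec12$data, rec1$data + rec2$data, tolerance = 1e-12)
  # no firings -> zero energy
  t0 <- mk_truth(integer(0), list())
  expect_equal(sum(render_emg(t0, templates, grid, 1)$data^2), 0)
  expect_error(render_emg(mk_truth(1L, list(1.5)), templates, grid, 1),
               "duration")
})

test_that("colored noise hits the requested SNR by construction", {
  sim <- fix_sim()
  clean <- sim$clean
  noisy10 <- add_colored_noise(clean, 10, seed = 2)
  noise <- noisy10$data - clean$data
  snr_meas <- 10 * log10(mean(clean$data^2) / mean(noise^2))
  expect_equal(snr_meas, 10, tolerance = 0.1 / 10)
  # 60 dB leaves the signal essentially untouched (power ratio 1e-6)
  noisy60 <- add_colored_noise(clean, 60, seed = 2)
  rel <- sqrt(mean((noisy60$data - clean$data)^2) / mean(clean$data^2))
  expect_lt(rel, 0.002)
  # seeded determinism
  expect_identical(add_colored_noise(clean, 10, seed = 2)$data, noisy10$data)
  zero <- emg_recording(matrix(0, nrow(clean$data), 100), clean$fs_hz,
                        clean$grid, clean$montage)
  expect_error(add_colored_noise(zero, 10), "zero power")
  # noise is band-limited: power above 700 Hz far below power in 20-500 Hz
  sp <- abs(stats::fft(noise[1, ]))^2
  fr <- seq(0, clean$fs_hz, length.out = length(sp) + 1)[seq_along(sp)]
  in_band <- mean(sp[fr > 20 & fr < 500])
  out_band <- mean(sp[fr > 700 & fr < 1500])
  expect_gt(in_band / out_band, 50)
})

test_that("simulated mean discharge rates follow the rate rule within 2%", {
  sim <- fix_sim()
  truth <- sim$truth
  for (id in truth$active_mu_ids[1:5]) {
    tt <- truth$firings$time_s[truth$firings$mu_id == id]
    if (length(tt) < 5) next
    mdr <- (length(tt) - 1) / (max(tt) - min(tt))
    target <- truth$rates$rate_pps[truth$rates$mu_id == id]
    expect_equal(mdr, target, tolerance = 0.06)
  }
})
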