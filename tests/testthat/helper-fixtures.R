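# Shared fixtures, built once per test run and memoized. Everything is
# generated in code; sizes are kept small so the whole suite stays fast.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# small desk-scale simulation at 30 dB / 10% MVC
fix_sim <- function() {
  memo("sim", simulate_hdsemg(10, 30, duration = 2.5, grid = desk_grid(),
                              n_mus = 40, seed = 3))
}

# its preprocessed single-differential recording
fix_rec_sd <- function() {
  memo("rec_sd", bandpass(make_single_differential(fix_sim()$recording)))
}

# whitened extended observation (R = 6 keeps the suite fast)
fix_obs <- function() {
  memo("obs", whiten(extend(fix_rec_sd(), 6)))
}

# a toy instantaneous-mixture observation with 3 sparse sources whose
# ground truth is known exactly; used as the small-scale oracle for the
# CKC stage
fix_toy <- function() {
  memo("toy", {
    withr::with_seed(42, {
      M <- 3000
      n_src <- 3
      spikes <- lapply(1:n_src, function(j) {
        s <- sort(sample(50:(M - 50), 28))
        s[c(diff(s) > 40, TRUE)]
      })
      # short biphasic kernels on 12 channels
      A <- matrix(stats::rnorm(12 * n_src), 12, n_src)
      kern <- c(0.3, 1, -0.8, -0.2)
      data <- matrix(0, 12, M)
      for (j in 1:n_src) {
        train <- numeric(M)
        train[spikes[[j]]] <- 1
        sig <- stats::filter(train, kern, sides = 1)
        sig[is.na(sig)] <- 0
        data <- data + A[, j] %o% as.numeric(sig)
      }
      data <- data + 0.05 * matrix(stats::rnorm(12 * M), 12)
      grid <- electrode_grid(rows = 12, cols = 1, fs_hz = 2048)
      rec <- emg_recording(data, 2048, grid, "monopolar")
      list(rec = rec, spikes = spikes, A = A)
    })
  })
}

fix_toy_obs <- function() {
  memo("toy_obs", {
    toy <- fix_toy()
    obs <- extend(toy$rec, 4)
    whiten(obs)
  })
}

# matched ("oracle") filter for toy source j: mean whitened column at the
# source's firing samples
toy_oracle_filter <- function(j) {
  toy <- fix_toy()
  obs <- fix_toy_obs()
  cols <- toy$spikes[[j]]
  rowMeans(obs$X[, cols, drop = FALSE])
}

# positive local maxima (same convention as the decomposition stage)
find_peaks <- function(v) {
  n <- length(v)
  i <- 2:(n - 1)
  1L + which(v[i] > v[i - 1] & v[i] >= v[i + 1] & v[i] > 0)
}
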