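# Shared fixtures and independent oracles. Oracles deliberately use naive,
# direct computations (per-sample scans, Riemann sums, regression fits) so
# they stay independent of the implementation paths they check.

# noiseless evoked sweep mirroring the generator's waveform family:
# stimulus artifact, 1.5 ms latency, raised-cosine rise, exponential decay
make_fepsp_sweep_trace_local <- function(fs, dur, stim, amp,
                                         rise = 0.002, decay = 0.008) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  v <- numeric(length(t))
  art <- t >= stim & t < stim + 4e-4
  v[art] <- 2 * sin(2 * pi * (t[art] - stim) / 4e-4)
  u <- t - (stim + 0.0015)
  r <- u >= 0 & u < rise
  v[r] <- v[r] - amp * (1 - cos(pi * u[r] / rise)) / 2
  d <- u >= rise
  v[d] <- v[d] - amp * exp(-(u[d] - rise) / decay)
  v
}

make_sine_rec <- function(freq_hz, fs_hz = 10000, duration_s = 2,
                          amplitude = 1, phase = 0) {
  t <- (seq_len(duration_s * fs_hz) - 1) / fs_hz
  lfp_recording(amplitude * sin(2 * pi * freq_hz * t + phase), fs_hz)
}

# amplitude-fit oracle: least-squares amplitude of a known-frequency sinusoid
fit_sine_amplitude <- function(x, fs_hz, freq_hz, trim_s = 0.2) {
  n <- length(x)
  i <- seq.int(ceiling(trim_s * fs_hz), n - ceiling(trim_s * fs_hz))
  t <- (i - 1) / fs_hz
  fit <- lm.fit(cbind(sin(2 * pi * freq_hz * t), cos(2 * pi * freq_hz * t)),
                x[i])
  sqrt(sum(fit$coefficients^2))
}

# brute-force sharp-wave detector: tests every sample against the rules
# (local max of the polarity-resolved 45 Hz low-passed mean-subtracted trace
# above 2.5 SD; larger-amplitude peak wins under the 80 ms rule; full-window
# events only)
brute_force_sw_detect <- function(rec, params = swr_params()) {
  lp <- lowpass(rec, params$sw_lowpass_hz)
  x <- lp$samples - mean(lp$samples)
  d <- switch(params$polarity, absolute = abs(x), positive = x, negative = -x)
  if (sd(x) == 0) return(integer(0))
  thr <- params$sw_threshold_sd * sd(x)
  n <- length(d)
  cand <- integer(0)
  for (i in 2:(n - 1)) {
    if (d[i] > thr && d[i] > d[i - 1] && d[i] >= d[i + 1]) cand <- c(cand, i)
  }
  gap <- params$min_interval_ms / 1000 * rec$fs_hz
  kept <- integer(0)
  for (i in cand[order(d[cand], decreasing = TRUE)]) {
    ok <- TRUE
    for (j in kept) if (abs(i - j) < gap) ok <- FALSE
    if (ok) kept <- c(kept, i)
  }
  half <- as.integer(round(params$sw_window_ms / 1000 * rec$fs_hz)) %/% 2L
  sort(kept[kept - half >= 1 & kept + half <= n])
}

# fine-Riemann integration oracle for sharp-wave area: midpoint rule on a
# dense linear interpolation of the window, integrating (x - mean) clipped
# at zero between the mean crossings around the central peak
riemann_sw_area <- function(window, fs_hz, upsample = 50L) {
  n <- length(window)
  m <- mean(window)
  t_ms <- (seq_len(n) - 1) / fs_hz * 1000
  fine_t <- seq(t_ms[1], t_ms[n], length.out = n * upsample)
  fine <- approx(t_ms, window - m, xout = fine_t)$y
  peak <- which.min(abs(fine_t - t_ms[(n + 1) %/% 2]))
  lo <- peak
  while (lo > 1 && fine[lo - 1] > 0) lo <- lo - 1
  hi <- peak
  while (hi < length(fine) && fine[hi + 1] > 0) hi <- hi + 1
  sum(pmax(fine[lo:hi], 0)) * (fine_t[2] - fine_t[1])
}

# the standard synthetic SWR benchmark: 120 s at 10 kHz, ~20 implanted
# events at 6x the (white) noise SD, fixed seed
benchmark_swr_sim <- function(seed = 7) {
  simulate_lfp(lfp_sim_config(
    duration_s = 120, fs_hz = 10000, noise_model = "white",
    noise_amplitude_mv = 0.05, sw_rate_hz = 0.18, sw_amplitude_mv = 0.3,
    ripple_freq_hz = 200, ripple_amplitude_mv = 0.1, seed = seed))
}

# match detections to ground truth within a tolerance; returns recall,
# precision and the worst matched peak-time error
match_events <- function(detected_s, truth_s, tol_s = 0.005) {
  used <- rep(FALSE, length(truth_s))
  errs <- c()
  tp <- 0
  for (p in detected_s) {
    d <- abs(truth_s - p)
    d[used] <- Inf
    j <- which.min(d)
    if (length(j) && d[j] <= tol_s) {
      used[j] <- TRUE
      tp <- tp + 1
      errs <- c(errs, d[j])
    }
  }
  list(recall = tp / length(truth_s), precision = tp / length(detected_s),
       max_err_s = if (length(errs)) max(errs) else NA_real_)
}
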