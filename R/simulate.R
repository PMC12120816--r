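## Synthetic-data generators. Each generator emulates the statistical
## structure of one input type consumed by the pipeline and returns the
## implanted ground truth alongside the data, so detector/quantifier recall
## and precision can be measured exactly. The generators are stated worlds,
## not biophysical models: waveform shapes (difference-of-Gaussians sharp
## waves, cosine-enveloped ripple bursts, alpha-function fEPSPs, Gaussian
## puncta) are plumbing chosen for smoothness and analytic tractability.

# Per-component substream seeds derived from one global seed, so adding a
# generator never perturbs the draws of another. Kept below 2^31 - 1.
sub_seed <- function(seed, component) {
  offs <- c(noise = 101L, events = 211L, ripple = 307L, gamma = 401L,
            fepsp = 503L, spines = 601L, puncta = 701L, pipeline = 809L)
  if (!component %in% names(offs)) stop("unknown seed component: ", component)
  as.integer((as.double(seed) %% 2147483647 * 1103 + offs[[component]]) %%
               2147483647)
}

# pink (1/f amplitude) or white noise with a target standard deviation
make_noise <- function(n, fs, sd_mv, model = c("pink", "white")) {
  model <- match.arg(model)
  z <- stats::rnorm(n)
  if (model == "white" || sd_mv == 0) return(z * sd_mv)
  m <- stats::nextn(n, c(2L, 3L, 5L))
  Z <- stats::fft(c(z, numeric(m - n)))
  f <- (seq_len(m) - 1L) / m * fs
  f <- pmin(f, fs - f)
  # 1/sqrt(f) amplitude shaping above a 0.5 Hz knee keeps power finite at DC
  shape <- 1 / sqrt(pmax(f, 0.5))
  x <- Re(stats::fft(Z * shape, inverse = TRUE))[seq_len(n)] / m
  x <- x - mean(x)
  x / stats::sd(x) * sd_mv
}

#' Configuration for the sharp-wave ripple LFP simulator
#'
#' @param duration_s trace duration in seconds (default 120, the standard
#'   2-min artifact-free analysis stretch).
#' @param fs_hz sampling rate (default 10000, the acquisition rate).
#' @param noise_model background noise model, \code{"pink"} (1/f, default --
#'   broadband like real LFP) or \code{"white"} (for analytic tests).
#' @param noise_amplitude_mv background noise SD in mV.
#' @param sw_rate_hz sharp-wave event rate (events/second, >= 0).
#' @param sw_amplitude_mv peak sharp-wave deflection in mV.
#' @param sw_halfwidth_ms full width at half maximum of the sharp-wave
#'   template in ms.
#' @param ripple_freq_hz ripple carrier frequency, in [120, 300] Hz.
#' @param ripple_amplitude_mv peak ripple-burst amplitude in mV.
#' @param polarity sharp-wave deflection sign, \code{"positive"} or
#'   \code{"negative"} (the deflection sign in stratum pyramidale is not
#'   constrained here; detection defaults to polarity-agnostic).
#' @param seed integer seed; identical config + seed gives identical output.
#' @return validated list of class \code{lfp_sim_config}.
#' @export
lfp_sim_config <- function(duration_s = 120, fs_hz = 10000,
                           noise_model = c("pink", "white"),
                           noise_amplitude_mv = 0.05,
                           sw_rate_hz = 0.2, sw_amplitude_mv = 0.3,
                           sw_halfwidth_ms = 40, ripple_freq_hz = 200,
                           ripple_amplitude_mv = 0.1,
                           polarity = c("positive", "negative"),
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  polarity <- match.arg(polarity)
  if (duration_s <= 0) stop("duration_s must be positive")
  if (sw_rate_hz < 0) stop("sw_rate_hz must be nonnegative")
  if (sw_amplitude_mv < 0 || ripple_amplitude_mv < 0 || noise_amplitude_mv < 0)
    stop("amplitudes must be nonnegative")
  if (fs_hz < 2 * ripple_freq_hz)
    stop("fs_hz below Nyquist for ripple_freq_hz")
  structure(list(duration_s = duration_s, fs_hz = fs_hz,
                 noise_model = noise_model,
                 noise_amplitude_mv = noise_amplitude_mv,
                 sw_rate_hz = sw_rate_hz, sw_amplitude_mv = sw_amplitude_mv,
                 sw_halfwidth_ms = sw_halfwidth_ms,
                 ripple_freq_hz = ripple_freq_hz,
                 ripple_amplitude_mv = ripple_amplitude_mv,
                 polarity = polarity, seed = as.integer(seed)),
            class = "lfp_sim_config")
}

# homogeneous Poisson arrivals thinned to an 80 ms dead time, kept clear of
# the trace edges so every implanted event admits a full 125 ms window
draw_sw_times <- function(duration_s, rate_hz, min_gap_s = 0.08,
                          edge_margin_s = 0.1) {
  if (rate_hz <= 0 || duration_s <= 2 * edge_margin_s) return(numeric(0))
  t <- 0
  out <- numeric(0)
  last <- -Inf
  repeat {
    t <- t + stats::rexp(1L, rate_hz)
    if (t >= duration_s) break
    if (t - last >= min_gap_s &&
        t >= edge_margin_s && t <= duration_s - edge_margin_s) {
      out <- c(out, t)
      last <- t
    }
  }
  out
}

#' Simulate a CA1 LFP trace with implanted sharp-wave ripple events
#'
#' Background noise plus smooth biphasic (difference-of-Gaussians) sharp-wave
#' deflections, each carrying an amplitude-modulated ripple burst at the
#' configured carrier frequency confined to +/- 12.5 ms around the sharp-wave
#' peak. Event times follow a homogeneous Poisson process thinned to an
#' 80 ms dead time, so the ground truth respects the detector's refractory
#' contract and recall on clean data can legitimately reach 100%.
#'
#' @param config an \code{\link{lfp_sim_config}}.
#' @return list with \code{recording} (an \code{\link{lfp_recording}}) and
#'   \code{truth}: \code{event_times_s} (sorted sharp-wave peak times),
#'   \code{amplitude_mv}, \code{ripple_freq_hz}, \code{ripple_amplitude_mv},
#'   \code{ripple_cycles} per event.
#' @export
simulate_lfp <- function(config) {
  if (!inherits(config, "lfp_sim_config"))
    stop("config must be an lfp_sim_config")
  n <- as.integer(round(config$duration_s * config$fs_hz))
  dt <- 1 / config$fs_hz

  set.seed(sub_seed(config$seed, "noise"))
  x <- make_noise(n, config$fs_hz, config$noise_amplitude_mv,
                  config$noise_model)

  set.seed(sub_seed(config$seed, "events"))
  times <- draw_sw_times(config$duration_s, config$sw_rate_hz)

  sgn <- if (config$polarity == "positive") 1 else -1
  sigma <- config$sw_halfwidth_ms / 1000 / 2.355     # FWHM -> SD
  half_span <- ceiling(max(4 * sigma, 0.015) / dt)
  tt <- (-half_span:half_span) * dt
  dog <- exp(-tt^2 / (2 * sigma^2)) - 0.3 * exp(-tt^2 / (2 * (2.5 * sigma)^2))
  dog <- dog / max(dog)                              # unit peak
  # ripple burst confined to +/- 12.5 ms: flat-top (Tukey) envelope, flat over
  # +/- 7.5 ms with cosine tapers, so the implanted carrier frequency is not
  # distorted by amplitude modulation around the detected (central) peaks
  rip_half <- 0.0125
  rip_flat <- 0.0100
  rip_env <- numeric(length(tt))
  at <- abs(tt)
  rip_env[at <= rip_flat] <- 1
  tap <- at > rip_flat & at <= rip_half
  rip_env[tap] <- cos(pi * (at[tap] - rip_flat) / (2 * (rip_half - rip_flat)))^2

  for (tc in times) {
    i0 <- as.integer(round(tc / dt)) + 1L
    idx <- i0 + (-half_span:half_span)
    keep <- idx >= 1L & idx <= n
    burst <- config$ripple_amplitude_mv * rip_env * cos(2 * pi *
               config$ripple_freq_hz * tt)
    x[idx[keep]] <- x[idx[keep]] +
      sgn * config$sw_amplitude_mv * dog[keep] + burst[keep]
  }

  ne <- length(times)
  truth <- list(
    event_times_s = times,
    amplitude_mv = rep(config$sw_amplitude_mv, ne),
    ripple_freq_hz = rep(config$ripple_freq_hz, ne),
    ripple_amplitude_mv = rep(config$ripple_amplitude_mv, ne),
    ripple_cycles = rep(2 * rip_half * config$ripple_freq_hz, ne))
  list(recording = lfp_recording(x, config$fs_hz, 0, "simulated SWR LFP"),
       truth = truth, config = config)
}

#' Simulate a carbachol-type gamma oscillation recording
#'
#' A stationary sinusoid with slow random amplitude modulation plus 1/f
#' noise, emulating the steady-state network oscillation 50-70 min after
#' carbachol perfusion. Frequencies outside 20-60 Hz are permitted so the
#' slice-exclusion rules can be exercised.
#'
#' @param duration_s trace duration in seconds (default 120).
#' @param fs_hz sampling rate (default 10000).
#' @param osc_freq_hz oscillation frequency in Hz.
#' @param osc_amplitude_mv mean oscillation amplitude (0 gives pure noise).
#' @param noise_amplitude_mv noise SD in mV.
#' @param mod_depth fractional depth of the slow (~0.5 Hz) amplitude
#'   modulation, in [0, 1).
#' @param seed integer seed.
#' @return list with \code{recording} and \code{truth} (\code{osc_freq_hz},
#'   \code{osc_amplitude_mv}).
#' @export
simulate_gamma <- function(duration_s = 120, fs_hz = 10000, osc_freq_hz = 40,
                           osc_amplitude_mv = 0.05, noise_amplitude_mv = 0.02,
                           mod_depth = 0.2, seed = 1L) {
  if (duration_s <= 0) stop("duration_s must be positive")
  if (osc_amplitude_mv < 0 || noise_amplitude_mv < 0)
    stop("amplitudes must be nonnegative")
  if (fs_hz < 2 * osc_freq_hz) stop("fs_hz below Nyquist for osc_freq_hz")
  if (mod_depth < 0 || mod_depth >= 1) stop("mod_depth must lie in [0, 1)")
  n <- as.integer(round(duration_s * fs_hz))
  t <- (seq_len(n) - 1L) / fs_hz
  set.seed(sub_seed(seed, "gamma"))
  osc <- numeric(n)
  if (osc_amplitude_mv > 0) {
    # slow modulation: smoothed white noise, ~0.5 Hz bandwidth
    env_n <- max(4L, as.integer(ceiling(duration_s * 2)))
    knots <- stats::rnorm(env_n)
    env <- stats::approx(seq(0, duration_s, length.out = env_n), knots,
                         xout = t)$y
    env <- 1 + mod_depth * env / max(stats::sd(env), 1e-12)
    env <- pmax(env, 0)
    ph <- stats::runif(1L, 0, 2 * pi)
    osc <- osc_amplitude_mv * env * sin(2 * pi * osc_freq_hz * t + ph)
  }
  noise <- make_noise(n, fs_hz, noise_amplitude_mv, "pink")
  truth <- list(osc_freq_hz = osc_freq_hz, osc_amplitude_mv = osc_amplitude_mv)
  list(recording = lfp_recording(osc + noise, fs_hz, 0, "simulated gamma"),
       truth = truth)
}

# noiseless evoked field EPSP: raised-cosine rising phase (near-linear over
# its 20-80% span, so a straight-line fit there recovers the maximal slope
# to within ~7%) followed by a mono-exponential decay (which makes the
# paired-pulse tail correction exact by construction); negative-going
epsp_template <- function(t_s, onset_s, amp_mv, rise_s = 0.002,
                          decay_s = 0.008) {
  v <- numeric(length(t_s))
  u <- t_s - onset_s
  r <- u >= 0 & u < rise_s
  v[r] <- -amp_mv * (1 - cos(pi * u[r] / rise_s)) / 2
  d <- u >= rise_s
  v[d] <- -amp_mv * exp(-(u[d] - rise_s) / decay_s)
  v
}

make_fepsp_sweep_trace <- function(fs_hz, dur_s, stim_times_s, amps_mv,
                                   rise_s = 0.002, decay_s = 0.008,
                                   latency_s = 0.0015, artifact_mv = 2) {
  n <- as.integer(round(dur_s * fs_hz))
  t <- (seq_len(n) - 1L) / fs_hz
  v <- numeric(n)
  for (k in seq_along(stim_times_s)) {
    st <- stim_times_s[k]
    # brief biphasic stimulus artifact (0.4 ms)
    art <- t >= st & t < st + 4e-4
    v[art] <- v[art] + artifact_mv * sin(2 * pi * (t[art] - st) / 4e-4)
    v <- v + epsp_template(t, st + latency_s, amps_mv[k], rise_s, decay_s)
  }
  # true maximal slope of the raised-cosine rise: A*pi/(2*rise), in mV/ms
  true_slopes <- amps_mv * pi / (2 * rise_s * 1000)
  list(t = t, v = v, true_slopes_mv_ms = true_slopes)
}

#' Simulate an evoked fEPSP experiment (baseline, HFS, paired pulses)
#'
#' Baseline sweeps share one true maximal slope; sweeps after the HFS marker
#' scale it by \code{potentiation_factor}; paired-pulse sweeps scale the
#' second response by the per-ISI facilitation factor. HFS itself is a time
#' marker at timestamp 0, not a simulated waveform.
#'
#' @param n_baseline,n_post number of baseline / post-HFS sweeps, delivered
#'   at \code{sweeps_per_min} evenly spaced test pulses per minute before
#'   and after the HFS marker at time 0.
#' @param sweep_params list overriding sweep synthesis defaults:
#'   \code{fs_hz} (10000), \code{dur_s} (0.1), \code{amp_mv} (1),
#'   \code{rise_s} (0.002), \code{decay_s} (0.008), \code{stim_time_s}
#'   (0.01), \code{stim_intensity_ua} (70).
#' @param potentiation_factor multiplicative slope change after HFS (> 0).
#' @param ppr_factors_per_isi named numeric vector of facilitation factors;
#'   names are ISIs in ms from \{10, 20, 50, 100, 200\}.
#' @param noise_sd additive Gaussian noise SD in mV (0 for noiseless).
#' @param seed integer seed.
#' @return list with \code{sweeps} (list of \code{fepsp_sweep} objects) and
#'   \code{truth} (true baseline slope, potentiation factor, per-ISI factors).
#' @export
#' @param sweeps_per_min test-pulse rate (default 3, i.e. one pulse every
#'   20 s, the standard low-frequency monitoring rate).
simulate_fepsp_series <- function(n_baseline = 30, n_post = 180,
                                  sweep_params = list(),
                                  potentiation_factor = 1.5,
                                  ppr_factors_per_isi = c(`50` = 1.5),
                                  noise_sd = 0, seed = 1L,
                                  sweeps_per_min = 3) {
  if (potentiation_factor <= 0) stop("potentiation_factor must be positive")
  isis <- as.numeric(names(ppr_factors_per_isi))
  if (length(ppr_factors_per_isi) &&
      (anyNA(isis) || !all(isis %in% c(10, 20, 50, 100, 200))))
    stop("ISIs must come from {10, 20, 50, 100, 200} ms")
  p <- utils::modifyList(list(fs_hz = 10000, dur_s = 0.1, amp_mv = 1,
                              rise_s = 0.002, decay_s = 0.008,
                              stim_time_s = 0.01,
                              stim_intensity_ua = 70), sweep_params)
  set.seed(sub_seed(seed, "fepsp"))
  mk <- function(stims, amps, ts_min, dur = p$dur_s) {
    base <- make_fepsp_sweep_trace(p$fs_hz, dur, stims, amps,
                                   p$rise_s, p$decay_s)
    v <- base$v
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), 0, noise_sd)
    fepsp_sweep(v, p$fs_hz, stim_times_s = stims,
                stim_intensity_ua = p$stim_intensity_ua,
                timestamp_s = ts_min * 60)
  }
  sweeps <- list()
  for (i in seq_len(n_baseline))
    sweeps[[length(sweeps) + 1L]] <-
      mk(p$stim_time_s, p$amp_mv,
         ts_min = -(n_baseline - i + 1) / sweeps_per_min)
  for (i in seq_len(n_post))
    sweeps[[length(sweeps) + 1L]] <-
      mk(p$stim_time_s, p$amp_mv * potentiation_factor,
         ts_min = i / sweeps_per_min)
  paired <- list()
  for (k in seq_along(ppr_factors_per_isi)) {
    isi_s <- isis[k] / 1000
    dur <- max(p$dur_s, p$stim_time_s + isi_s + 0.05)
    paired[[as.character(isis[k])]] <-
      mk(c(p$stim_time_s, p$stim_time_s + isi_s),
         c(p$amp_mv, p$amp_mv * ppr_factors_per_isi[k]),
         ts_min = -9999, dur = dur)
  }
  tmpl <- make_fepsp_sweep_trace(p$fs_hz, p$dur_s, p$stim_time_s, p$amp_mv,
                                 p$rise_s, p$decay_s)
  list(sweeps = sweeps, paired_sweeps = paired,
       truth = list(baseline_slope_mv_ms = tmpl$true_slopes_mv_ms[1L],
                    potentiation_factor = potentiation_factor,
                    ppr_factors_per_isi = ppr_factors_per_isi))
}

# geometry boxes sampled strictly inside each class's decision region, with
# margins wide enough that the jitter below cannot cross a boundary
spine_class_boxes <- list(
  filopodia = list(len = c(2.2, 4.0), wid = c(0.10, 0.45), heads = 1L),
  long_thin = list(len = c(1.10, 1.90), wid = c(0.15, 0.50), heads = 1L),
  thin      = list(len = c(0.50, 0.90), wid = c(0.15, 0.40), heads = 1L),
  stubby    = list(len = NULL,          wid = c(0.35, 0.55), heads = 1L),
  mushroom  = list(len = c(0.80, 1.80), wid = c(0.70, 1.20), heads = 1L),
  branched  = list(len = c(0.80, 1.80), wid = c(0.30, 0.90), heads = 2L))

#' Simulate a population of dendritic spines with known classes
#'
#' Samples (length, width, head count) uniformly inside each morphological
#' class's decision region, with a safety margin so that the added jitter can
#' never move a spine across a classification boundary: the recorded true
#' class always equals the region the spine was drawn from.
#'
#' @param n_per_class named integer vector; names from \{filopodia,
#'   long_thin, thin, stubby, mushroom, branched\}.
#' @param jitter half-width of the uniform geometric jitter in micrometres
#'   (capped at 0.04 so margins hold).
#' @param seed integer seed.
#' @return data.frame with \code{length_um}, \code{width_um}, \code{heads},
#'   \code{true_class}.
#' @export
simulate_spines <- function(n_per_class, jitter = 0.03, seed = 1L) {
  if (jitter < 0 || jitter > 0.04) stop("jitter must lie in [0, 0.04]")
  bad <- setdiff(names(n_per_class), names(spine_class_boxes))
  if (length(bad)) stop("unknown spine class: ", paste(bad, collapse = ", "))
  set.seed(sub_seed(seed, "spines"))
  rows <- list()
  for (cls in names(n_per_class)) {
    k <- n_per_class[[cls]]
    if (k == 0) next
    b <- spine_class_boxes[[cls]]
    wid <- stats::runif(k, b$wid[1], b$wid[2])
    len <- if (cls == "stubby") {
      wid * stats::runif(k, 0.55, 0.85)       # ratio < 1 with margin
    } else {
      stats::runif(k, b$len[1], b$len[2])
    }
    heads <- if (cls == "branched") sample(2:3, k, replace = TRUE)
             else rep(1L, k)
    len <- len + stats::runif(k, -jitter, jitter)
    wid <- wid + stats::runif(k, -jitter, jitter)
    rows[[cls]] <- data.frame(length_um = len, width_um = wid,
                              heads = heads, true_class = cls,
                              stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(length_um = numeric(0), width_um = numeric(0),
                      heads = integer(0), true_class = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a two-channel synaptic puncta field
#'
#' Gaussian spots on two channels (e.g. post- and pre-synaptic markers). A
#' \code{coloc_fraction} share of channel-A puncta receive a channel-B
#' partner within the colocalization radius; all remaining B puncta are
#' placed farther than twice that radius from every A punctum, so the true
#' pair count is exactly \code{round(coloc_fraction * n_puncta_a)}.
#'
#' @param field_um square field side length in micrometres.
#' @param px_size_um pixel size (micrometres per pixel).
#' @param n_puncta_a,n_puncta_b puncta counts per channel
#'   (\code{n_puncta_b >=} the implied pair count).
#' @param coloc_fraction fraction of A puncta with a B partner, in [0, 1].
#' @param coloc_radius_um colocalization radius (default 0.5).
#' @param psf_sigma Gaussian spot SD in micrometres.
#' @param seed integer seed.
#' @return list with \code{channel_a}, \code{channel_b} (intensity matrices,
#'   row = y), \code{px_size_um}, and \code{truth} (centroid tables,
#'   \code{n_pairs}, \code{coloc_fraction}).
#' @export
simulate_puncta_image <- function(field_um = 20, px_size_um = 0.1,
                                  n_puncta_a = 50, n_puncta_b = 50,
                                  coloc_fraction = 0.6,
                                  coloc_radius_um = 0.5,
                                  psf_sigma = 0.15, seed = 1L) {
  if (coloc_fraction < 0 || coloc_fraction > 1)
    stop("coloc_fraction must lie in [0, 1]")
  n_pairs <- as.integer(round(coloc_fraction * n_puncta_a))
  if (n_puncta_b < n_pairs)
    stop("n_puncta_b smaller than the implied pair count")
  set.seed(sub_seed(seed, "puncta"))
  margin <- 1
  min_sep <- max(4 * coloc_radius_um, 1.5)   # keeps greedy matching unambiguous
  draw_sep <- function(k, existing = NULL) {
    pts <- existing
    out <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(out) < k) {
      cand <- stats::runif(2, margin, field_um - margin)
      ok <- is.null(pts) || nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= min_sep
      if (ok) {
        out <- rbind(out, cand)
        pts <- rbind(pts, cand)
      }
      tries <- tries + 1L
      if (tries > 20000L) stop("field too crowded for the separation rule")
    }
    out
  }
  a_xy <- draw_sep(n_puncta_a)
  b_list <- list()
  if (n_pairs > 0) {
    ang <- stats::runif(n_pairs, 0, 2 * pi)
    rad <- stats::runif(n_pairs, 0, 0.4 * coloc_radius_um)
    b_list$paired <- a_xy[seq_len(n_pairs), , drop = FALSE] +
      cbind(rad * cos(ang), rad * sin(ang))
  }
  n_free <- n_puncta_b - n_pairs
  if (n_free > 0) {
    free <- matrix(numeric(0), ncol = 2)
    tries <- 0L
    while (nrow(free) < n_free) {
      cand <- stats::runif(2, margin, field_um - margin)
      d_a <- sqrt((a_xy[, 1] - cand[1])^2 + (a_xy[, 2] - cand[2])^2)
      ok <- min(d_a) > 2 * coloc_radius_um
      if (nrow(free) && ok)
        ok <- min(sqrt((free[, 1] - cand[1])^2 +
                         (free[, 2] - cand[2])^2)) >= min_sep / 2
      if (ok) free <- rbind(free, cand)
      tries <- tries + 1L
      if (tries > 50000L) stop("field too crowded for the separation rule")
    }
    b_list$free <- free
  }
  b_xy <- do.call(rbind, b_list)
  npx <- as.integer(round(field_um / px_size_um))
  render <- function(xy) {
    img <- matrix(0, nrow = npx, ncol = npx)   # row = y (down), col = x
    if (is.null(xy) || nrow(xy) == 0) return(img)
    cx <- (seq_len(npx) - 0.5) * px_size_um
    for (i in seq_len(nrow(xy))) {
      gx <- exp(-(cx - xy[i, 1])^2 / (2 * psf_sigma^2))
      gy <- exp(-(cx - xy[i, 2])^2 / (2 * psf_sigma^2))
      img <- img + outer(gy, gx)
    }
    img
  }
  list(channel_a = render(a_xy), channel_b = render(b_xy),
       px_size_um = px_size_um,
       truth = list(
         a_centroids_um = data.frame(x_um = a_xy[, 1], y_um = a_xy[, 2]),
         b_centroids_um = data.frame(x_um = b_xy[, 1], y_um = b_xy[, 2]),
         n_pairs = n_pairs, coloc_fraction = coloc_fraction))
}
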