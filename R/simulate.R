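#' Simulation parameters for synthetic bilateral cohorts
#'
#' Bundles and validates the parameters of [generate_cohort()]. Defaults
#' mirror the study conditions of a resting-state bilateral transillumination
#' scan: 63 subjects with 18 cancer-positive, a 32 x 64 optode grid, 400
#' frames at 1.8 Hz, channel gains spanning several decades, and shared
#' sub-0.1 Hz vasomotion rhythms riding on each channel's baseline.
#'
#' @param n_subjects number of subjects.
#' @param prevalence fraction of cancer-positive subjects in `[0,1]`;
#'   `round(prevalence * n_subjects)` subjects are positive.
#' @param n_sources,n_detectors,n_frames block dimensions.
#' @param frame_rate_hz sampling rate in Hz.
#' @param gain_log10_range channel gains are drawn log-uniformly over this
#'   many decades (dynamic range of the source-detector couplings).
#' @param n_vasomotion_components number of shared sinusoidal vasomotion
#'   components per subject.
#' @param vasomotion_band_hz length-2 interval inside `(0, frame_rate/2)`
#'   from which component frequencies are drawn; default `c(0.01, 0.1)`,
#'   the very-low-frequency band where breast hemodynamics concentrate.
#' @param vasomotion_rel_amplitude summed component amplitude relative to the
#'   channel baseline (peak fluctuation fraction).
#' @param noise_rel_amplitude amplitude of additive white (uniform) noise
#'   relative to the baseline.
#' @param effect_size tumor effect: low-frequency fluctuation variance in
#'   affected channels is multiplied by `1 + effect_size` (0 = null model).
#' @param tumor_channel_fraction fraction of channels of the tumor-bearing
#'   breast that are affected, in `(0, 1]`.
#' @param wavelength_correlation correlation in `[0,1]` between the shared
#'   fluctuation time courses of the two wavelengths of one breast.
#' @param seed integer driving all randomness; generation is a pure function
#'   of the parameters including the seed.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(n_subjects = 63L, prevalence = 18 / 63,
                       n_sources = 32L, n_detectors = 64L, n_frames = 400L,
                       frame_rate_hz = 1.8, gain_log10_range = 5,
                       n_vasomotion_components = 3L,
                       vasomotion_band_hz = c(0.01, 0.1),
                       vasomotion_rel_amplitude = 0.05,
                       noise_rel_amplitude = 0.02,
                       effect_size = 2, tumor_channel_fraction = 0.15,
                       wavelength_correlation = 0.8, seed = 1L) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stop_validation(sprintf("invalid '%s': %s", field, what))
  }
  chk(is.numeric(n_subjects) && n_subjects >= 1, "n_subjects", "must be >= 1")
  chk(is.numeric(prevalence) && prevalence >= 0 && prevalence <= 1,
      "prevalence", "must be in [0,1]")
  chk(n_sources >= 1 && n_detectors >= 1, "n_sources/n_detectors", "must be positive")
  chk(n_frames >= 1, "n_frames", "must be positive")
  chk(frame_rate_hz > 0, "frame_rate_hz", "must be positive")
  chk(gain_log10_range >= 0, "gain_log10_range", "must be >= 0")
  chk(n_vasomotion_components >= 1, "n_vasomotion_components", "must be >= 1")
  chk(length(vasomotion_band_hz) == 2 && vasomotion_band_hz[1] > 0 &&
        vasomotion_band_hz[2] > vasomotion_band_hz[1] &&
        vasomotion_band_hz[2] < frame_rate_hz / 2,
      "vasomotion_band_hz", "must be an interval inside (0, frame_rate/2)")
  chk(vasomotion_rel_amplitude >= 0, "vasomotion_rel_amplitude", "must be >= 0")
  chk(noise_rel_amplitude >= 0, "noise_rel_amplitude", "must be >= 0")
  chk(effect_size >= 0, "effect_size", "must be >= 0")
  chk(tumor_channel_fraction > 0 && tumor_channel_fraction <= 1,
      "tumor_channel_fraction", "must be in (0,1]")
  chk(wavelength_correlation >= 0 && wavelength_correlation <= 1,
      "wavelength_correlation", "must be in [0,1]")
  # strict positivity: the crest factor of an RMS-normalized sum of K
  # sinusoids is at most sqrt(2K), so the worst-case peak fluctuation is
  # bounded by v * sqrt(K) * (1 + sqrt(effect_size)) + noise
  peak <- vasomotion_rel_amplitude * sqrt(n_vasomotion_components) *
    (1 + sqrt(effect_size)) + noise_rel_amplitude
  chk(peak < 1, "vasomotion_rel_amplitude/effect_size/noise_rel_amplitude",
      "combined worst-case fluctuation amplitude must stay below 1 (positivity)")
  structure(list(
    n_subjects = as.integer(n_subjects), prevalence = prevalence,
    n_sources = as.integer(n_sources), n_detectors = as.integer(n_detectors),
    n_frames = as.integer(n_frames), frame_rate_hz = frame_rate_hz,
    gain_log10_range = gain_log10_range,
    n_vasomotion_components = as.integer(n_vasomotion_components),
    vasomotion_band_hz = vasomotion_band_hz,
    vasomotion_rel_amplitude = vasomotion_rel_amplitude,
    noise_rel_amplitude = noise_rel_amplitude,
    effect_size = effect_size,
    tumor_channel_fraction = tumor_channel_fraction,
    wavelength_correlation = wavelength_correlation,
    seed = as.integer(seed)), class = "sim_params")
}

# sum of sinusoids: amplitudes amps, frequencies freqs (Hz), phases (rad);
# returns length-n_frames time course sampled at frame_rate_hz
sinusoid_sum <- function(amps, freqs, phases, n_frames, frame_rate_hz) {
  t_sec <- (seq_len(n_frames) - 1L) / frame_rate_hz
  drop(sin(outer(t_sec, 2 * pi * freqs) +
             matrix(phases, n_frames, length(freqs), byrow = TRUE)) %*% amps)
}

# scale a mean-removed time course so its REALIZED root-mean-square equals
# `rms`. Very-low-frequency components cover few cycles in a finite window,
# so their realized variance depends strongly on phase; normalizing the
# realized RMS makes fluctuation variance an exact, window-independent
# quantity (the premise behind the tumor effect multiplying variance by
# exactly 1 + effect_size, and behind the statistical left/right symmetry of
# healthy subjects).
scale_to_rms <- function(x, rms) {
  x <- x - mean(x)
  r0 <- sqrt(mean(x^2))
  if (r0 == 0) return(x)
  x * (rms / r0)
}

#' Generate a synthetic bilateral cohort
#'
#' Draws a cohort with the statistical structure the downstream analysis
#' assumes. Per channel `r`, side `b` and wavelength, the signal is
#' `x(r,t) = g_r * (1 + S_b(t) + T_r(t) + eps(r,t))` where `g_r` is a
#' log-uniform channel gain shared between the two sides (mirrored optode
#' geometry), `S_b` is a sum of shared low-frequency vasomotion sinusoids
#' with side-specific phases (the two wavelengths of one breast mix a shared
#' and an independent copy according to `wavelength_correlation`), `T_r` is
#' an extra independent low-frequency fluctuation present only in a
#' contiguous source-major block of channels of the tumor-bearing breast
#' (scaled so fluctuation variance there is multiplied by exactly
#' `1 + effect_size`), and `eps` is bounded white noise. Every fluctuation
#' time course is scaled to its realized root-mean-square within the
#' acquisition window: sub-0.02 Hz components cover only a fraction of a
#' cycle in short recordings, so without this the two breasts of a healthy
#' subject would differ in temporal variance by phase accident,
#' contradicting the statistical left/right symmetry the cohort emulates.
#' `round(prevalence * n_subjects)`
#' subjects are cancer-positive with tumor laterality assigned uniformly at
#' random.
#'
#' @param params a [sim_params()] object.
#' @return A [cohort()].
#' @export
#' @examples
#' co <- generate_cohort(sim_params(n_subjects = 4, n_sources = 4,
#'                                  n_detectors = 4, n_frames = 32, seed = 1))
#' co
generate_cohort <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  R <- p$n_sources * p$n_detectors
  n_pos <- round(p$prevalence * p$n_subjects)

  # global stream: labels and tumor sides
  assign_ <- with_seed(p$seed, {
    pos_ids <- sample.int(p$n_subjects, n_pos)
    sides <- sample(c("left", "right"), p$n_subjects, replace = TRUE)
    list(pos = pos_ids, sides = sides)
  })

  records <- vector("list", p$n_subjects)
  for (i in seq_len(p$n_subjects)) {
    positive <- i %in% assign_$pos
    tumor_side <- if (positive) assign_$sides[i] else "none"
    subject_seed <- (p$seed %% 100000L) * 20011L + i * 7L
    records[[i]] <- with_seed(subject_seed, {
      simulate_subject(sprintf("S%03d", i), tumor_side, p, R)
    })
  }
  cohort(records, frame_rate_hz = p$frame_rate_hz)
}

simulate_subject <- function(subject_id, tumor_side, p, R) {
  K <- p$n_vasomotion_components
  freqs <- stats::runif(K, p$vasomotion_band_hz[1], p$vasomotion_band_hz[2])
  w <- stats::runif(K, 0.5, 1)
  amps <- p$vasomotion_rel_amplitude * w / sum(w)
  # realized RMS target: a single sinusoid of amplitude v has RMS v/sqrt(2)
  v_rms <- p$vasomotion_rel_amplitude / sqrt(2)
  rho <- p$wavelength_correlation

  # gains: per (wavelength, channel), shared between sides
  gains <- list(
    "760" = 10^stats::runif(R, 0, p$gain_log10_range),
    "830" = 10^stats::runif(R, 0, p$gain_log10_range))

  # tumor channel block (contiguous, source-major)
  n_tum <- if (tumor_side == "none") 0L else ceiling(p$tumor_channel_fraction * R)
  tum_start <- if (n_tum > 0L && n_tum < R) sample.int(R - n_tum + 1L, 1L) else 1L
  tum_idx <- if (n_tum > 0L) seq.int(tum_start, length.out = n_tum) else integer(0)

  blocks <- list()
  for (side in c("left", "right")) {
    phases_a <- stats::runif(K, 0, 2 * pi)
    phases_b <- stats::runif(K, 0, 2 * pi)
    S_shared <- scale_to_rms(
      sinusoid_sum(amps, freqs, phases_a, p$n_frames, p$frame_rate_hz), v_rms)
    S_indep <- scale_to_rms(
      sinusoid_sum(amps, freqs, phases_b, p$n_frames, p$frame_rate_hz), v_rms)
    S <- list("760" = S_shared,
              "830" = scale_to_rms(rho * S_shared + sqrt(1 - rho^2) * S_indep,
                                   v_rms))

    # tumor fluctuation: per-channel independent components whose realized
    # variance is effect_size times the shared fluctuation variance (so the
    # affected channels' fluctuation variance is multiplied by exactly
    # 1 + effect_size); identical time course at both wavelengths
    tumorM <- NULL
    if (side == tumor_side && n_tum > 0L && p$effect_size > 0) {
      t_rms <- sqrt(p$effect_size) * v_rms
      tumorM <- matrix(0, nrow = n_tum, ncol = p$n_frames)
      for (j in seq_len(n_tum)) {
        fj <- stats::runif(K, p$vasomotion_band_hz[1], p$vasomotion_band_hz[2])
        pj <- stats::runif(K, 0, 2 * pi)
        tumorM[j, ] <- scale_to_rms(
          sinusoid_sum(amps, fj, pj, p$n_frames, p$frame_rate_hz), t_rms)
      }
    }

    for (wl in c("760", "830")) {
      base <- matrix(rep(S[[wl]], each = R), nrow = R)
      if (!is.null(tumorM)) base[tum_idx, ] <- base[tum_idx, ] + tumorM
      if (p$noise_rel_amplitude > 0) {
        base <- base + matrix(
          stats::runif(R * p$n_frames, -p$noise_rel_amplitude,
                       p$noise_rel_amplitude), nrow = R)
      }
      vals <- gains[[wl]] * (1 + base)
      if (min(vals) <= 0)
        stop_validation("generated intensities are not strictly positive; reduce fluctuation/noise amplitudes")
      blocks[[block_key(side, as.numeric(wl))]] <-
        scan_block(vals, n_sources = p$n_sources, n_detectors = p$n_detectors,
                   wavelength_nm = as.numeric(wl), side = side)
    }
  }
  subject_record(subject_id, blocks,
                 cancer_positive = tumor_side != "none",
                 tumor_side = tumor_side)
}

#' Fraction of signal power inside a frequency band
#'
#' Computes, by discrete Fourier transform, the fraction of total
#' mean-removed signal power (pooled over channels) that falls inside
#' `band_hz`. Bin frequencies are `k * frame_rate_hz / T`; the DC bin is
#' excluded and aliased bins are folded onto `[0, fs/2]`.
#'
#' @param block a `scan_block` (or matrix) with at least 8 frames.
#' @param band_hz length-2 interval inside `(0, frame_rate_hz / 2)`.
#' @param frame_rate_hz sampling rate in Hz.
#' @return Scalar in `[0, 1]`.
#' @export
spectral_check <- function(block, band_hz, frame_rate_hz) {
  x <- if (inherits(block, "scan_block")) block$values else block
  T <- ncol(x)
  if (T < 8L) stop_insufficient("spectral_check needs at least 8 frames")
  if (band_hz[1] <= 0 || band_hz[2] >= frame_rate_hz / 2 ||
      band_hz[2] <= band_hz[1])
    stop_range("band_hz must be an interval inside (0, frame_rate_hz/2)")
  xc <- x - rowMeans(x)
  P <- Mod(stats::mvfft(t(xc)))^2          # T x R, bin k-1 at freq (k-1)*fs/T
  f <- (seq_len(T) - 1L) * frame_rate_hz / T
  f_folded <- pmin(f, frame_rate_hz - f)
  keep <- seq(2L, T)                        # drop DC
  inband <- keep[f_folded[keep] >= band_hz[1] & f_folded[keep] <= band_hz[2]]
  tot <- sum(P[keep, ])
  if (tot == 0) return(0)
  sum(P[inband, ]) / tot
}
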