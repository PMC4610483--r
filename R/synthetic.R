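# Synthetic spiral-tracing simulator. The generator targets the statistical
# signatures the feature panel measures — slow, arrest-broken tracing for
# bradykinesia; fast tracing with band-limited high-frequency radial
# irregularity for dyskinesia; rhythmic radial oscillation for tremor —
# not a biomechanical model of the arm.

#' Simulation profile for one tracing class
#'
#' Parameter defaults per class are chosen to reproduce the qualitative
#' signatures of the two symptom archetypes: bradykinetic tracings are slow
#' (several-fold lower mean speed), hesitant (Poisson-placed arrests followed
#' by brief festinating bursts) and more asymmetric; dyskinetic tracings are
#' fast with a band-limited 2.5-5 Hz radial perturbation that lands in the
#' level-1 wavelet detail band by construction. Tremor adds a sinusoidal
#' radial oscillation below the 5 Hz Nyquist limit of 10 Hz sampling.
#'
#' @param label One of `"healthy"`, `"bradykinetic"`, `"dyskinetic"`,
#'   `"tremor"`.
#' @param base_angular_rate Baseline tracing rate (rad/s).
#' @param pitch Template pitch (px/rad).
#' @param turns Template revolutions; the trial ends when the tracing
#'   completes them or the duration elapses, whichever is first.
#' @param speed_scale Multiplier on the angular rate (< 1 slow, > 1 fast).
#' @param speed_noise_sd Standard deviation of the smooth (AR(1),
#'   lag-correlation 0.9) log speed modulation.
#' @param hesitation_rate Expected number of arrests per trial (Poisson).
#' @param hesitation_duration Arrest length (s).
#' @param hf_irregularity_amp RMS amplitude (px) of the band-limited
#'   2.5-5 Hz radial perturbation.
#' @param tremor_freq,tremor_amp Radial oscillation frequency (Hz, must stay
#'   below 5 Hz) and amplitude (px).
#' @param asymmetry_bias Lateral drift of the tracing centre as a fraction of
#'   the current radius.
#' @param jitter_sd Isotropic white positional noise (px).
#' @param seed Default seed of [simulate_trial()].
#' @return List of class `sim_profile`.
#' @export
sim_profile <- function(label = c("healthy", "bradykinetic", "dyskinetic",
                                  "tremor"),
                        base_angular_rate = 1.9, pitch = 10, turns = 3,
                        speed_scale = NULL, speed_noise_sd = NULL,
                        hesitation_rate = NULL, hesitation_duration = NULL,
                        hf_irregularity_amp = NULL,
                        tremor_freq = NULL, tremor_amp = NULL,
                        asymmetry_bias = NULL, jitter_sd = NULL,
                        seed = 101L) {
  label <- match.arg(label)
  defaults <- switch(label,
    healthy = list(speed_scale = 1.0, speed_noise_sd = 0.10,
                   hesitation_rate = 0, hesitation_duration = 0,
                   hf_irregularity_amp = 0, tremor_freq = 0, tremor_amp = 0,
                   asymmetry_bias = 0.02, jitter_sd = 0.8),
    bradykinetic = list(speed_scale = 0.5, speed_noise_sd = 0.04,
                        hesitation_rate = 2, hesitation_duration = 0.7,
                        hf_irregularity_amp = 0.2, tremor_freq = 0,
                        tremor_amp = 0, asymmetry_bias = 0.12,
                        jitter_sd = 0.1),
    dyskinetic = list(speed_scale = 1.5, speed_noise_sd = 0.20,
                      hesitation_rate = 0, hesitation_duration = 0,
                      hf_irregularity_amp = 2.5, tremor_freq = 0,
                      tremor_amp = 0, asymmetry_bias = 0.02,
                      jitter_sd = 2.0),
    tremor = list(speed_scale = 0.7, speed_noise_sd = 0.15,
                  hesitation_rate = 1, hesitation_duration = 0.5,
                  hf_irregularity_amp = 0.2, tremor_freq = 4, tremor_amp = 6,
                  asymmetry_bias = 0.05, jitter_sd = 1.0)
  )
  p <- list(label = label, base_angular_rate = base_angular_rate,
            pitch = pitch, turns = turns,
            speed_scale = speed_scale %||% defaults$speed_scale,
            speed_noise_sd = speed_noise_sd %||% defaults$speed_noise_sd,
            hesitation_rate = hesitation_rate %||% defaults$hesitation_rate,
            hesitation_duration =
              hesitation_duration %||% defaults$hesitation_duration,
            hf_irregularity_amp =
              hf_irregularity_amp %||% defaults$hf_irregularity_amp,
            tremor_freq = tremor_freq %||% defaults$tremor_freq,
            tremor_amp = tremor_amp %||% defaults$tremor_amp,
            asymmetry_bias = asymmetry_bias %||% defaults$asymmetry_bias,
            jitter_sd = jitter_sd %||% defaults$jitter_sd,
            seed = seed)
  if (p$base_angular_rate <= 0 || p$pitch <= 0 || p$turns <= 0) {
    stop("base_angular_rate, pitch and turns must be positive", call. = FALSE)
  }
  checks <- c("speed_scale", "speed_noise_sd", "hesitation_rate",
              "hesitation_duration", "hf_irregularity_amp", "tremor_freq",
              "tremor_amp", "jitter_sd")
  for (nm in checks) {
    if (p[[nm]] < 0) stop(sprintf("%s must be non-negative", nm), call. = FALSE)
  }
  if (p$tremor_freq >= 5) {
    stop("tremor_freq must stay below the 5 Hz Nyquist limit of 10 Hz sampling",
         call. = FALSE)
  }
  structure(p, class = "sim_profile")
}

# Band-limited (2.5-5 Hz at `rate` Hz) Gaussian noise with unit RMS,
# synthesised by zeroing all Fourier components outside the band.
band_limited_noise <- function(n, rate = 10) {
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  freq <- (seq_len(n) - 1L) / n * rate
  freq <- pmin(freq, rate - freq)  # two-sided
  keep <- freq >= rate / 4 & freq <= rate / 2
  sp[!keep] <- 0
  out <- Re(stats::fft(sp, inverse = TRUE)) / n
  s <- stats::sd(out)
  if (s == 0) rep(0, n) else out / s
}

#' Simulate one spiral tracing
#'
#' Generates a timestamped trajectory at the device sampling rate. The
#' unwrapped angle advances at `base_angular_rate * speed_scale`, modulated
#' by a smooth lognormal speed process, arrests (angular rate collapses to 5%
#' for `hesitation_duration`, followed by a 0.5 s festinating burst at 180%)
#' and truncation when the template's turns are completed. The radius is
#' `pitch * angle` plus the class-specific radial perturbations; the centre
#' drifts laterally with `asymmetry_bias`; white positional jitter is added
#' last. Deterministic given the profile and seed.
#'
#' @param profile A [sim_profile()].
#' @param duration Maximum trial duration (s, protocol target 10).
#' @param rate Sampling rate (Hz, device rate 10).
#' @param seed Seed; defaults to the profile's.
#' @param center Template centre on screen (px).
#' @param ... Metadata passed to [spiral_trial()] (`subject_id`, ...).
#' @return A [spiral_trial()] with `label` set from the profile.
#' @export
simulate_trial <- function(profile, duration = 10, rate = 10,
                           seed = profile$seed, center = c(400, 400),
                           mean_impairment = NULL, ...) {
  stopifnot(inherits(profile, "sim_profile"))
  n <- floor(duration * rate) + 1L
  if (n < 22L) stop("duration * rate too small: need >= 21 samples", call. = FALSE)
  t <- (seq_len(n) - 1L) / rate
  dt <- 1 / rate

  with_seed(seed, {
    # smooth multiplicative speed modulation: AR(1) on the log scale
    ar <- numeric(n - 1L)
    innov <- stats::rnorm(n - 1L)
    rho <- 0.9
    ar[1L] <- innov[1L]
    for (i in 2:(n - 1L)) ar[i] <- rho * ar[i - 1L] + sqrt(1 - rho^2) * innov[i]
    mult <- exp(profile$speed_noise_sd * ar)

    # arrests and festinating bursts
    n_arr <- stats::rpois(1L, profile$hesitation_rate)
    if (n_arr > 0L && profile$hesitation_duration > 0) {
      starts <- stats::runif(n_arr, 0.5, max(0.6, duration - 1))
      for (s0 in starts) {
        in_arrest <- t[-n] >= s0 & t[-n] < s0 + profile$hesitation_duration
        burst <- t[-n] >= s0 + profile$hesitation_duration &
          t[-n] < s0 + profile$hesitation_duration + 0.5
        mult[in_arrest] <- mult[in_arrest] * 0.05
        mult[burst] <- mult[burst] * 1.8
      }
    }

    omega <- profile$base_angular_rate * profile$speed_scale * mult
    theta <- c(0, cumsum(omega * dt))
    # stop once the template is completed (fast tracers finish early)
    total <- 2 * pi * profile$turns
    done <- which(theta >= total)
    if (length(done)) {
      keep <- max(22L, done[1L])
      keep <- min(keep, n)
      t <- t[seq_len(keep)]; theta <- theta[seq_len(keep)]
      n <- keep
    }

    r <- profile$pitch * theta
    if (profile$hf_irregularity_amp > 0) {
      r <- r + profile$hf_irregularity_amp * band_limited_noise(n, rate)
    }
    if (profile$tremor_amp > 0 && profile$tremor_freq > 0) {
      r <- r + profile$tremor_amp * sin(2 * pi * profile$tremor_freq * t)
    }

    x <- center[1L] + r * cos(theta) + profile$asymmetry_bias * r +
      stats::rnorm(n, 0, profile$jitter_sd)
    y <- center[2L] + r * sin(theta) + stats::rnorm(n, 0, profile$jitter_sd)

    group <- if (profile$label == "healthy") "HE" else "PD"
    impairment <- mean_impairment %||% switch(profile$label,
                                              healthy = stats::runif(1L, 0, 2),
                                              bradykinetic = stats::runif(1L, 5, 9),
                                              dyskinetic = stats::runif(1L, 5, 9),
                                              tremor = stats::runif(1L, 3, 7))
    spiral_trial(x, y, t, group = group, label = profile$label,
                 nominal_rate = rate, mean_impairment = impairment, ...)
  })
}

#' Simulate a labelled cohort of spiral tracings
#'
#' Simulates `n_per_class` subjects per class, three tracings per subject
#' (one test occasion each, mirroring the recording protocol), with
#' between-subject heterogeneity: each subject's `speed_scale` is perturbed
#' on the log scale (sd 0.3), the high-frequency irregularity amplitude on
#' the log scale (sd 0.2), and the asymmetry bias additively (sd 0.02).
#' The heterogeneity keeps the classes overlapping but separable.
#'
#' @param n_per_class Subjects per class (>= 1).
#' @param classes Character vector of profile labels to simulate.
#' @param base_seed Master seed; the full cohort is reproducible from it.
#' @param duration,rate Passed to [simulate_trial()].
#' @return List with `trials` (list of [spiral_trial()]) and `truth`
#'   (data frame: `subject_id`, `occasion_id`, `trial_index`, `label`,
#'   `mean_impairment`, `speed_scale`).
#' @export
simulate_cohort <- function(n_per_class = 10L,
                            classes = c("healthy", "bradykinetic",
                                        "dyskinetic", "tremor"),
                            base_seed = 2026L, duration = 10, rate = 10) {
  stopifnot(n_per_class >= 1L)
  trials <- list()
  truth <- list()
  with_seed(base_seed, {
    subj <- 0L
    for (cls in classes) {
      for (i in seq_len(n_per_class)) {
        subj <- subj + 1L
        base <- sim_profile(cls)
        prof <- sim_profile(
          cls,
          speed_scale = base$speed_scale * exp(stats::rnorm(1L, 0, 0.3)),
          hf_irregularity_amp =
            base$hf_irregularity_amp * exp(stats::rnorm(1L, 0, 0.2)),
          asymmetry_bias = max(0, base$asymmetry_bias +
                                 stats::rnorm(1L, 0, 0.02))
        )
        sid <- sprintf("S%03d", subj)
        occ <- sprintf("%s_O1", sid)
        imp <- switch(cls,
                      healthy = stats::runif(1L, 0, 2),
                      bradykinetic = stats::runif(1L, 5, 9),
                      dyskinetic = stats::runif(1L, 5, 9),
                      tremor = stats::runif(1L, 3, 7))
        for (k in 1:3) {
          tseed <- sample.int(.Machine$integer.max - 1L, 1L)
          tr <- simulate_trial(prof, duration = duration, rate = rate,
                               seed = tseed, subject_id = sid,
                               occasion_id = occ, trial_index = k,
                               mean_impairment = imp)
          trials[[length(trials) + 1L]] <- tr
          truth[[length(truth) + 1L]] <- data.frame(
            subject_id = sid, occasion_id = occ, trial_index = k,
            label = cls, mean_impairment = tr$mean_impairment,
            speed_scale = prof$speed_scale, stringsAsFactors = FALSE)
        }
      }
    }
  })
  list(trials = trials, truth = do.call(rbind, truth))
}
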