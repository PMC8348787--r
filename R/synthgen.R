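# Seeded synthetic maternal-activity signal generator.
#
# Stands in for the clinical recordings (available only on request from
# the original study's authors) so the whole pipeline is testable offline.
# Each activity class is a sum of a gravity projection, one fundamental
# sinusoid plus a second harmonic on every axis, and Gaussian noise — the
# simplest family rich enough for the window statistics (moments, zero
# crossings, spectral bins, entropy) to discriminate classes. Per-bout
# random phases and small amplitude/frequency jitter keep bouts of one
# class similar but not identical.
#
# Profiles are engineered so the synthetic confusion structure mirrors the
# clinical one: stair walking (MPA1) is deliberately close to walking
# (MPA7) — pregnant subjects climb stairs slowly and carefully, so the
# wrist signal resembles an ordinary walk; side bending (MPA9) and
# standing (MPA10) sit near hands exercise (MPA4) in wrist-motion energy;
# laying (MPA6) is nearly static and far from every dynamic class.

#' Built-in activity profiles
#'
#' One signal-model profile per activity class MPA1..MPA10. Fields per
#' profile: `acc_base` (gravity projection per axis, g), `acc_amp`
#' (fundamental sinusoid amplitude per axis, g), `acc_harmonic` (second
#' harmonic amplitude as a fraction of the fundamental), `freq_hz`
#' (fundamental frequency), `acc_noise` (Gaussian noise sd, g),
#' `gyro_amp` (dps), `gyro_noise` (dps), `temp_base` (deg C), `temp_drift`
#' (deg C per minute) and `duration_range` (seconds, the 2-5 min bouts of
#' the emulated study design).
#'
#' @return Named list of 10 `activity_profile` objects.
#' @export
default_profiles <- function() {
  p <- function(label, freq, acc_amp, acc_base, acc_noise,
                gyro_amp, gyro_noise, harmonic = 0.4,
                temp_base = 33.5, temp_drift = 0.01) {
    structure(
      list(label = label, activity = activity_labels()[[label]],
           freq_hz = freq, acc_amp = acc_amp, acc_base = acc_base,
           acc_harmonic = harmonic, acc_noise = acc_noise,
           gyro_amp = gyro_amp, gyro_noise = gyro_noise,
           temp_base = temp_base, temp_drift = temp_drift,
           duration_range = c(120, 300)),
      class = "activity_profile"
    )
  }
  wrist <- c(0.10, -0.60, 0.78)  # resting wrist gravity projection, |.| ~ 1 g
  list(
    MPA1  = p("MPA1", 1.60, c(0.30, 0.35, 0.25), wrist, 0.08,
              c(50, 60, 40), 8),
    MPA2  = p("MPA2", 0.80, c(0.12, 0.18, 0.10), wrist, 0.12,
              c(25, 30, 20), 12, harmonic = 0.25),
    MPA3  = p("MPA3", 0.45, c(0.10, 0.14, 0.08), wrist, 0.05,
              c(18, 25, 15), 6, harmonic = 0.2),
    MPA4  = p("MPA4", 1.00, c(0.18, 0.22, 0.15), wrist, 0.05,
              c(35, 40, 30), 6),
    MPA5  = p("MPA5", 1.25, c(0.22, 0.28, 0.20), wrist, 0.15,
              c(45, 55, 40), 15),
    MPA6  = p("MPA6", 0.25, c(0.008, 0.010, 0.006), c(0.05, 0.98, 0.10),
              0.008, c(1.5, 2.0, 1.0), 0.8, harmonic = 0,
              temp_base = 34.5),
    MPA7  = p("MPA7", 1.90, c(0.35, 0.40, 0.30), wrist, 0.08,
              c(60, 70, 50), 8),
    MPA8  = p("MPA8", 0.30, c(0.45, 0.55, 0.40), c(0.30, -0.50, 0.60),
              0.05, c(70, 85, 60), 6, harmonic = 0.15),
    MPA9  = p("MPA9", 0.95, c(0.16, 0.20, 0.14), wrist, 0.05,
              c(32, 38, 28), 6),
    MPA10 = p("MPA10", 1.05, c(0.14, 0.18, 0.12), wrist, 0.06,
              c(30, 36, 26), 7)
  )
}

#' Scale the noise terms of a profile set
#'
#' Multiplies every accelerometer and gyroscope noise sd by `factor`,
#' leaving the deterministic signal components untouched. Inflating the
#' noise degrades class separability; shrinking it sharpens it.
#'
#' @param profiles list of `activity_profile` objects.
#' @param factor positive multiplier.
#' @return The modified profile list.
#' @export
scale_profile_noise <- function(profiles, factor) {
  stopifnot(factor > 0)
  lapply(profiles, function(pr) {
    pr$acc_noise <- pr$acc_noise * factor
    pr$gyro_noise <- pr$gyro_noise * factor
    pr
  })
}

#' Generate one synthetic activity bout
#'
#' Synthesises a 50 Hz recording of one subject-activity bout from an
#' activity profile: per axis, gravity baseline + fundamental sinusoid +
#' second harmonic + Gaussian noise for the accelerometer; zero-baseline
#' sinusoids + noise for the gyroscope; and a slowly drifting 1 Hz
#' temperature forward-filled onto the 50 Hz grid. Phases are random per
#' bout; amplitude and frequency get a few percent of per-bout jitter.
#' Bitwise deterministic given `seed`.
#'
#' @param profile an `activity_profile`.
#' @param duration bout length in whole seconds (>= 1); default: drawn
#'   uniformly from the profile's `duration_range`.
#' @param seed integer seed.
#' @param subject_id subject identifier attached to the recording.
#' @param metadata named list of subject metadata.
#' @return A validated `sensor_recording`.
#' @export
generate_bout <- function(profile, duration = NULL, seed = 1L,
                          subject_id = "S01", metadata = list()) {
  stopifnot(inherits(profile, "activity_profile"))
  if (!is.null(duration) && duration < 1) {
    stop("duration must be >= 1 second", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    if (is.null(duration)) {
      duration <- sample(profile$duration_range[1]:profile$duration_range[2], 1)
    }
    duration <- as.integer(round(duration))
    fs <- IMU_RATE_HZ
    n <- duration * fs
    t <- (seq_len(n) - 1) / fs
    freq <- profile$freq_hz * stats::runif(1, 0.98, 1.02)
    amp_jit <- stats::runif(1, 0.9, 1.1)
    chan <- function(base, amp, noise_sd, harmonic) {
      base +
        amp * amp_jit * sin(2 * pi * freq * t + stats::runif(1, 0, 2 * pi)) +
        amp * amp_jit * harmonic *
          sin(2 * pi * 2 * freq * t + stats::runif(1, 0, 2 * pi)) +
        stats::rnorm(n, 0, noise_sd)
    }
    acc <- vapply(1:3, function(a) {
      chan(profile$acc_base[a], profile$acc_amp[a], profile$acc_noise,
           profile$acc_harmonic)
    }, numeric(n))
    gyr <- vapply(1:3, function(a) {
      chan(0, profile$gyro_amp[a], profile$gyro_noise, profile$acc_harmonic)
    }, numeric(n))
    temp_1hz <- profile$temp_base +
      profile$temp_drift * (seq_len(duration) - 1) / 60 +
      stats::rnorm(duration, 0, 0.02)
    d <- data.frame(
      t = t,
      acc_x = acc[, 1], acc_y = acc[, 2], acc_z = acc[, 3],
      gyro_x = gyr[, 1], gyro_y = gyr[, 2], gyro_z = gyr[, 3],
      temp = rep(temp_1hz, each = fs)
    )
    sensor_recording(subject_id, profile$label, d, metadata = metadata)
  })
}

#' Cohort specification
#'
#' Describes a synthetic study cohort: how many subjects, how many
#' activities each performs (a random subset of the ten classes), and the
#' master seed from which all cohort randomness derives. The default is a
#' desk-scale cohort of 10 subjects with 6 activities each — the same
#' per-subject design as the emulated study (whose cohort had 61 subjects
#' averaging six activities each) at a size that keeps a full pipeline run
#' interactive.
#'
#' @param n_subjects number of subjects (default 10).
#' @param activities_per_subject activities per subject, at most 10
#'   (default 6).
#' @param seed master integer seed (default 1).
#' @param duration_range optional `c(lo, hi)` seconds overriding every
#'   profile's bout-duration range (e.g. for quick smoke runs).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 10L, activities_per_subject = 6L,
                        seed = 1L, duration_range = NULL) {
  stopifnot(n_subjects >= 1, activities_per_subject >= 1,
            activities_per_subject <= 10)
  structure(
    list(n_subjects = as.integer(n_subjects),
         activities_per_subject = as.integer(activities_per_subject),
         seed = as.integer(seed),
         duration_range = duration_range),
    class = "cohort_spec"
  )
}

#' Generate a synthetic cohort of labelled recordings
#'
#' Draws each subject's activity subset, metadata (trimester, age band,
#' occupation, anemia flag) and per-bout seeds from the master seed, then
#' synthesises every bout with [generate_bout()]. Identical spec and seed
#' reproduce the cohort bitwise.
#'
#' @param spec a [cohort_spec()].
#' @param profiles activity profiles (default [default_profiles()]).
#' @return List of `sensor_recording` objects, one per bout.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            profiles = default_profiles()) {
  stopifnot(inherits(spec, "cohort_spec"))
  labels <- names(profiles)
  plan <- withr::with_seed(spec$seed, {
    lapply(seq_len(spec$n_subjects), function(s) {
      acts <- sample(labels, spec$activities_per_subject)
      meta <- list(
        trimester = sample(1:3, 1, prob = c(0.25, 0.40, 0.35)),
        age_band = sample(c("18-25", "26-30", "31-35", "36-40"), 1,
                          prob = c(0.3, 0.35, 0.25, 0.1)),
        occupation = sample(c("housewife", "working"), 1, prob = c(0.6, 0.4)),
        anemia = stats::runif(1) < 0.3
      )
      bout_seeds <- sample.int(2147483646L, length(acts))
      list(subject = sprintf("S%02d", s), acts = acts, meta = meta,
           bout_seeds = bout_seeds)
    })
  })
  out <- list()
  for (sp in plan) {
    for (j in seq_along(sp$acts)) {
      pr <- profiles[[sp$acts[j]]]
      if (!is.null(spec$duration_range)) pr$duration_range <- spec$duration_range
      out[[length(out) + 1L]] <- generate_bout(
        pr, duration = NULL, seed = sp$bout_seeds[j],
        subject_id = sp$subject, metadata = sp$meta)
    }
  }
  out
}

#' Run the full pipeline on a cohort of recordings
#'
#' Convenience wrapper: segment every recording with one windowing
#' configuration and extract the pooled feature table.
#'
#' @param recordings list of `sensor_recording` objects.
#' @param cfg a [windowing_config()].
#' @param spec a [feature_spec()].
#' @return Feature table (data.frame) pooling all windows.
#' @export
cohort_feature_table <- function(recordings, cfg = windowing_config(1, FALSE),
                                 spec = feature_spec()) {
  windows <- unlist(lapply(recordings, segment, cfg = cfg), recursive = FALSE)
  extract_feature_table(windows, spec)
}
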