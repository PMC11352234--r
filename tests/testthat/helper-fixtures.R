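# Small shared fixtures, built in code at test time.

sine_recording <- function(freq, amp = 1, duration_s = 4, fs = 512,
                           phase = "before", subject = "S01") {
  t <- (0:(duration_s * fs - 1)) / fs
  eeg_recording(amp * sin(2 * pi * freq * t), fs = fs, phase = phase,
                subject = subject)
}

# 2-subject miniature cohort with clearly distinct rest/therapy profiles
tiny_cohort <- function(seed = 11, duration = 16) {
  generate_cohort(cohort_spec(
    n_subjects = 2,
    durations = c(before = duration, during = duration, after = duration),
    rest = band_profile(alpha = 6, beta = 1, noise_sd = 1),
    therapy = band_profile(alpha = 1, beta = 6, gamma = 2, noise_sd = 1),
    seed = seed))
}

# a fast training configuration for unit tests
tiny_train_config <- function(seed = 5, epochs = 4) {
  train_config(epochs = epochs, seed = seed, channels = c(8, 16),
               n_embed = 16, batch_size = 16)
}

rms <- function(x) sqrt(mean(x^2))
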