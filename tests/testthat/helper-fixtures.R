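# Shared fixture builders. Everything is generated in code at test time.

# Desk-scale synthetic EEG configuration; override any field via ...
tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(
      n_channels = 4, sampling_rate = 128,
      n_trials_offline = 8, n_trials_online = 8,
      trial_duration = 1,
      discriminative_channels = 1:2, discriminative_band = c(8, 16),
      class_power_gap = 3, seed = seed
    ),
    list(...)
  )
  do.call(synth_config, args)
}

# The centroid-swap / class-asymmetric drift study conditions used by the
# acceptance suite: 8 channels, 2 s trials, 40 offline + 60 online trials,
# class gap 3 SD, drift completing the centroid swap by the last online trial.
drift_study_config <- function(seed, asym = 0) {
  gap <- 3; n_on <- 60
  synth_config(
    n_channels = 8, sampling_rate = 256,
    n_trials_offline = 40, n_trials_online = n_on,
    trial_duration = 2,
    discriminative_channels = 1:4, discriminative_band = c(8, 16),
    class_power_gap = gap,
    mean_drift_rate = 2 * gap / ((2 - asym) * n_on),
    bias_drift_asymmetry = asym,
    seed = seed
  )
}

# preprocess + PSD features + phase split, with desk-scale spectral settings
phase_features <- function(eeg, band = c(2, 30), bin_width = 4,
                           window_len = 0.5, window_step = 0.1) {
  split_by_phase(extract_psd_features(
    preprocess(eeg),
    window_len = window_len, window_step = window_step,
    band = band, bin_width = bin_width
  ))
}

# Feature settings used with drift_study_config (finer bins, replay-rate step)
drift_features <- function(eeg) {
  split_by_phase(extract_psd_features(
    preprocess(eeg),
    window_len = 0.5, window_step = 0.05, band = c(1, 33), bin_width = 2
  ))
}

# Plain Gaussian feature-matrix stream with per-trial class means given by
# mu_fun(class, trial_index) - a transparent oracle-friendly generator.
gauss_features <- function(labels, mu_fun, n_windows = 10, d = 4, sd = 1,
                           phase = "offline", first_trial = 1,
                           window_step = 0.05) {
  n_tr <- length(labels)
  X <- do.call(rbind, lapply(seq_len(n_tr), function(i) {
    sweep(matrix(stats::rnorm(n_windows * d, sd = sd), n_windows, d),
          2, mu_fun(labels[i], i), "+")
  }))
  feature_matrix(
    X = X,
    window_trial = rep(first_trial + seq_len(n_tr) - 1L, each = n_windows),
    window_label = rep(as.integer(labels), each = n_windows),
    window_time = rep((seq_len(n_windows) - 1) * window_step, n_tr),
    window_phase = rep(phase, n_tr * n_windows)
  )
}

# Two-feature model with w = (1, 0), b = 0 (mu1 = (-.5, 0), mu2 = (.5, 0),
# sigma = I), handy for crafting exact window probabilities: a window at
# x = (qlogis(p), 0) has class-2 probability exactly p.
unit_model <- function(d = 2) {
  mu1 <- c(-0.5, rep(0, d - 1))
  mu2 <- c(0.5, rep(0, d - 1))
  new_lda_model(mu1, mu2, diag(d), diag(d), n_samples = 100,
                class_counts = c(`1` = 50, `2` = 50))
}

# Feature matrix of one trial whose class-2 window probabilities equal `probs`
trial_with_probs <- function(probs, trial = 1L, label = 2L, d = 2) {
  X <- cbind(stats::qlogis(probs), matrix(0, length(probs), d - 1))
  feature_matrix(
    X = X,
    window_trial = rep(trial, length(probs)),
    window_label = rep(label, length(probs)),
    window_time = (seq_along(probs) - 1) * 0.05,
    window_phase = rep("online", length(probs))
  )
}

# Independent direct-solve LDA oracle: per-class covariances pooled by hand,
# hyperplane from base::solve. Kept free of any package internals.
oracle_lda <- function(X, y) {
  X1 <- X[y == 1, , drop = FALSE]
  X2 <- X[y == 2, , drop = FALSE]
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  S <- ((nrow(X1) - 1) * stats::cov(X1) + (nrow(X2) - 1) * stats::cov(X2)) /
    (nrow(X1) + nrow(X2) - 2)
  w <- solve(S, mu2 - mu1)
  list(w = w, b = -sum(w * (mu1 + mu2)) / 2)
}

# Random symmetric positive-definite matrix with eigenvalues in [lo, hi]
random_spd <- function(d, lo = 0.5, hi = 2) {
  q <- qr.Q(qr(matrix(stats::rnorm(d * d), d)))
  q %*% diag(stats::runif(d, lo, hi), d) %*% t(q)
}

# Permute class labels at the trial level (windows inherit the trial's label)
permute_trial_labels <- function(fm, seed) {
  trials <- sort(unique(fm$window_trial))
  labs <- vapply(trials, function(tr) fm$window_label[fm$window_trial == tr][1],
                 integer(1))
  new_labs <- withr::with_seed(seed, sample(labs))
  fm$window_label <- new_labs[match(fm$window_trial, trials)]
  fm
}
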