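# Brute-force oracle for the covariance recursion: form the updated covariance
# explicitly and invert it with a dense solver.
explicit_update_inverse <- function(sigma, d, uc_sigma, n, a_coef = 1 - uc_sigma) {
  B <- a_coef * sigma + (uc_sigma / (n - 1)) * tcrossprod(d)
  solve(B)
}

random_model <- function(d, seed = NULL) {
  build <- function() {
    sigma <- random_spd(d)
    new_lda_model(
      mu1 = rnorm(d), mu2 = rnorm(d),
      sigma = sigma, sigma_inv = solve(sigma),
      n_samples = 50, class_counts = c(`1` = 25, `2` = 25)
    )
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

test_that("the mean update is the stated convex combination", {
  m <- unit_model()
  expect_identical(update_mean(m, c(9, 9), 1, 0)$mu1, m$mu1)
  expect_equal(update_mean(m, c(9, 9), 1, 1)$mu1, c(9, 9))
  m2 <- new_lda_model(c(0, 0), c(5, 5), diag(2), diag(2), 10, c(`1` = 5, `2` = 5))
  expect_equal(update_mean(m2, c(2, 4), 1, 0.5)$mu1, c(1, 2))
  # the other class mean is untouched and the hyperplane is refreshed
  up <- update_mean(m2, c(2, 4), 1, 0.5)
  expect_identical(up$mu2, m2$mu2)
  expect_equal(up$w, drop(up$sigma_inv %*% (up$mu2 - up$mu1)))
  # convex combination coordinatewise for any uc in [0,1]
  for (uc in c(0.1, 0.4, 0.9)) {
    mu_new <- update_mean(m2, c(2, 4), 1, uc)$mu1
    expect_true(all(mu_new >= pmin(m2$mu1, c(2, 4)) - 1e-12))
    expect_true(all(mu_new <= pmax(m2$mu1, c(2, 4)) + 1e-12))
  }
  expect_error(update_mean(m2, c(2, 4), 1, 1.2), "uc_mu")
  expect_error(update_mean(m2, c(2, 4), 3, 0.5), "class_id")
  expect_error(update_mean(m2, c(2, 4, 1), 1, 0.5), "dimensionality")
})

test_that("the Woodbury inverse matches brute-force inversion of the explicit update", {
  withr::with_seed(31, {
    for (rep in 1:50) {
      d <- sample(2:8, 1)
      m <- random_model(d)
      x <- rnorm(d)
      cl <- sample(1:2, 1)
      uc <- runif(1, 0.01, 0.6)
      up <- update_covariance_woodbury(m, x, cl, uc, n = m$n_samples)
      mu <- if (cl == 1) m$mu1 else m$mu2
      oracle <- explicit_update_inverse(m$sigma, x - mu, uc, m$n_samples)
      expect_lt(max(abs(up$sigma_inv - oracle)), 1e-8)
      # the explicitly tracked covariance equals the recursion's matrix
      expect_lt(max(abs(
        up$sigma - ((1 - uc) * m$sigma +
                      (uc / (m$n_samples - 1)) * tcrossprod(x - mu))
      )), 1e-12)
    }
  })
})

test_that("uc_sigma = 0 leaves the inverse covariance untouched", {
  m <- random_model(4, seed = 5)
  up <- update_covariance_woodbury(m, rnorm(4), 2, 0)
  expect_identical(up$sigma_inv, m$sigma_inv)
  expect_identical(up$sigma, m$sigma)
})

test_that("a long update stream keeps sigma_inv consistent and symmetric", {
  withr::with_seed(77, {
    m <- random_model(5)
    uc <- uc_pair(0.05, 0.05)
    for (t in 1:25) {
      f1 <- gauss_features(1L, function(cl, i) rep(-0.5, 5), n_windows = 1, d = 5)
      f2 <- gauss_features(2L, function(cl, i) rep(0.5, 5), n_windows = 1, d = 5,
                           first_trial = 2)
      m <- update_on_trial_pair(m, f1, f2, uc)
      expect_lt(max(abs(m$sigma %*% m$sigma_inv - diag(5))), 1e-5)
      expect_lt(max(abs(m$sigma_inv - t(m$sigma_inv))), 1e-10)
    }
    expect_equal(m$n_samples, 100)
  })
})

test_that("the printed-form variant differs as documented and has its own brute-force oracle", {
  m <- random_model(4, seed = 9)
  x <- withr::with_seed(10, rnorm(4))
  default <- update_covariance_woodbury(m, x, 1, uc_sigma = 0.2)
  printed <- update_covariance_woodbury(m, x, 1, uc_sigma = 0.2,
                                        printed_variant = TRUE, uc_mu = 0.05)
  expect_gt(max(abs(default$sigma_inv - printed$sigma_inv)), 1e-6)
  oracle <- explicit_update_inverse(m$sigma, x - m$mu1, 0.2, m$n_samples,
                                    a_coef = 1 - 0.05)
  expect_lt(max(abs(printed$sigma_inv - oracle)), 1e-8)
  expect_error(
    update_covariance_woodbury(m, x, 1, 0.2, printed_variant = TRUE),
    "uc_mu"
  )
})

test_that("a zero update pair is a strict no-op on the decision rule", {
  withr::with_seed(14, {
    m <- random_model(3)
    f1 <- gauss_features(1L, function(cl, i) c(-1, 0, 0), n_windows = 6, d = 3)
    f2 <- gauss_features(2L, function(cl, i) c(1, 0, 0), n_windows = 6, d = 3,
                         first_trial = 2)
    up <- update_on_trial_pair(m, f1, f2, uc_pair(0, 0))
    expect_identical(up$w, m$w)
    expect_identical(up$b, m$b)
    expect_identical(up$sigma_inv, m$sigma_inv)
    expect_identical(up$mu1, m$mu1)
    expect_equal(up$n_samples, m$n_samples + 12)
  })
})

test_that("trial-pair updates validate their inputs", {
  m <- random_model(3, seed = 2)
  f1 <- gauss_features(1L, function(cl, i) rep(0, 3), n_windows = 4, d = 3)
  f2 <- gauss_features(2L, function(cl, i) rep(0, 3), n_windows = 4, d = 3,
                       first_trial = 2)
  expect_error(update_on_trial_pair(m, f2, f1, uc_pair(0.1, 0.1)), "class")
  empty <- subset_windows(f1, integer(0))
  expect_error(update_on_trial_pair(m, empty, f2, uc_pair(0.1, 0.1)), "empty")
  two_trials <- gauss_features(c(1L, 1L), function(cl, i) rep(0, 3),
                               n_windows = 2, d = 3)
  expect_error(update_on_trial_pair(m, two_trials, f2, uc_pair(0.1, 0.1)),
               "exactly one trial")
})

test_that("means stay near the truth on a stationary stream and track a drifting one", {
  d <- 4
  true_mu <- function(cl, i) c(ifelse(cl == 1, -1, 1), rep(0, d - 1))
  withr::with_seed(55, {
    off1 <- gauss_features(rep(1L, 10), true_mu, n_windows = 8, d = d)
    off2 <- gauss_features(rep(2L, 10), true_mu, n_windows = 8, d = d,
                           first_trial = 11)
    m0 <- train_lda(feature_matrix(
      rbind(off1$X, off2$X),
      c(off1$window_trial, off2$window_trial),
      c(off1$window_label, off2$window_label)
    ))
    # stationary: 100 trial pairs, moderate uc; tracking error stays bounded
    m <- m0
    errs <- numeric(100)
    for (t in 1:100) {
      f1 <- gauss_features(1L, true_mu, n_windows = 8, d = d)
      f2 <- gauss_features(2L, true_mu, n_windows = 8, d = d, first_trial = 2)
      m <- update_on_trial_pair(m, f1, f2, uc_pair(0.05, 0.02))
      errs[t] <- sqrt(sum((m$mu1 - true_mu(1, t))^2))
    }
    expect_lt(max(errs), 1.5)

    # drifting means: the selected nonzero uc tracks better than uc = 0
    drift_mu <- function(cl, j) {
      s <- 2 * (1 - 2 * j / 60)
      c(ifelse(cl == 1, -s / 2, s / 2), rep(0, d - 1))
    }
    track_err <- function(uc_mu) {
      m <- m0
      err <- 0
      for (p in 1:30) {
        f1 <- gauss_features(1L, function(cl, i) drift_mu(cl, 2 * p - 1),
                             n_windows = 31, d = d)
        f2 <- gauss_features(2L, function(cl, i) drift_mu(cl, 2 * p),
                             n_windows = 31, d = d, first_trial = 2)
        m <- update_on_trial_pair(m, f1, f2, uc_pair(uc_mu, 0))
        err <- err + sqrt(sum((m$mu1 - drift_mu(1, 2 * p))^2))
      }
      err / 30
    }
    expect_lt(track_err(0.4 * 2^-6), track_err(0))
  })
})
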