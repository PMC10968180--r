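# Build a sim_matrices tibble by hand (grid results with known values)
fake_sim <- function(mod_pa, mod_bias = -mod_pa / 2, static_pa = 50,
                     id = "d1", grid = c(0.1, 0.2)) {
  cells <- tidyr::crossing(uc_mu = grid, uc_sigma = grid)
  out <- dplyr::mutate(cells,
    adaptive_pa = static_pa + mod_pa,
    adaptive_bias = 10 + mod_bias,
    modulated_pa = mod_pa,
    modulated_bias = mod_bias
  )
  attr(out, "static_pa") <- static_pa
  attr(out, "static_bias") <- 10
  attr(out, "dataset_id") <- id
  class(out) <- c("sim_matrices", class(out))
  out
}

test_that("the canonical lattice is exactly 0.4 * 2^(k-14), k = 0..14", {
  g <- uc_grid()
  expect_length(g, 15)
  expect_identical(g, 0.4 * 2^((0:14) - 14))
  expect_equal(g[1], 0.4 * 2^-14)
  expect_equal(g[15], 0.4)
  expect_true(all(diff(g) > 0))
  expect_equal(uc_grid(n = 4, top = 0.8), 0.8 * 2^(-3:0))
})

test_that("grid search restricted to the zero pair has exactly zero modulated PA", {
  eeg <- generate_dataset(tiny_config(seed = 2))
  ph <- phase_features(eeg)
  sm <- grid_search(ph$offline, ph$online, grid_mu = 0, grid_sigma = 0,
                    timeout = 1, dataset_id = "zero")
  expect_equal(nrow(sm), 1L)
  expect_identical(sm$modulated_pa, 0)
  expect_identical(sm$modulated_bias, 0)
  expect_equal(sm$adaptive_pa, attr(sm, "static_pa"))
})

test_that("grid search fills every cell with replay-consistent quantities", {
  eeg <- generate_dataset(tiny_config(seed = 6))
  ph <- phase_features(eeg)
  grid <- c(0, 0.05)
  sm <- grid_search(ph$offline, ph$online, grid_mu = grid, grid_sigma = grid,
                    timeout = 1)
  expect_equal(nrow(sm), 4L)
  expect_true(all(sm$adaptive_pa >= 0 & sm$adaptive_pa <= 100))
  expect_equal(sm$modulated_pa, sm$adaptive_pa - attr(sm, "static_pa"))
  expect_equal(sm$modulated_bias, sm$adaptive_bias - attr(sm, "static_bias"))
  # one cell must be the zero pair with exactly zero modulation
  zero <- sm[sm$uc_mu == 0 & sm$uc_sigma == 0, ]
  expect_identical(zero$modulated_pa, 0)
})

test_that("aggregation averages matrices and recounts positives exactly", {
  s1 <- fake_sim(mod_pa = c(2, -1, 0, 4))
  s2 <- fake_sim(mod_pa = c(-2, 1, 0, -4), id = "d2")
  agg <- aggregate_sim(list(s1, s2))
  expect_equal(agg$mean_modulated_pa, rep(0, 4))
  # +a / -a across two datasets: each cell positive in exactly one (zero in none)
  expect_equal(agg$consistency, c(1, 1, 0, 1))
  expect_equal(attr(agg, "n_datasets"), 2)
  expect_true(all(agg$consistency <= 2))
  # consistency equals an independent recount of positive cells
  recount <- colSums(rbind(s1$modulated_pa > 0, s2$modulated_pa > 0))
  expect_equal(agg$consistency, unname(recount))
  one <- aggregate_sim(list(fake_sim(mod_pa = rep(3, 4))))
  expect_true(all(one$consistency == 1))
  expect_error(aggregate_sim(list(s1, fake_sim(mod_pa = 1:9, grid = c(1, 2, 3) / 10))),
               "same UC grid")
})

test_that("bias identities hold: stored bias equals the recomputed class-PA gap", {
  eeg <- generate_dataset(tiny_config(seed = 12))
  ph <- phase_features(eeg)
  res <- replay_adaptive(ph$offline, ph$online, uc_pair(0.05, 0.05), timeout = 1)
  pt <- res$per_trial
  pa1 <- 100 * mean(pt$correct[pt$cued_class == 1])
  pa2 <- 100 * mean(pt$correct[pt$cued_class == 2])
  expect_equal(res$bias, abs(pa1 - pa2))
})

test_that("a dominant cell is selected regardless of the other criteria", {
  mod <- c(0, 1, 2, 8); bias <- c(0, -1, -2, -8)
  s <- fake_sim(mod_pa = mod, mod_bias = bias)
  agg <- aggregate_sim(list(s))
  sel <- select_uc_pair(agg)
  best <- s[which.max(s$modulated_pa), ]
  expect_equal(sel$uc_mu, best$uc_mu)
  expect_equal(sel$uc_sigma, best$uc_sigma)
  ranking <- attr(sel, "ranking")
  expect_equal(nrow(ranking), 4L)
})

test_that("degenerate all-zero matrices still select deterministically (smallest pair)", {
  agg <- aggregate_sim(list(fake_sim(mod_pa = rep(0, 4), mod_bias = rep(0, 4))))
  sel <- select_uc_pair(agg)
  expect_equal(sel$uc_mu, 0.1)
  expect_equal(sel$uc_sigma, 0.1)
})

test_that("the tri-criterion policy breaks near-ties by consistency then bias", {
  # cell 1 has the highest mean (4.8) but improves only one dataset;
  # cell 2 sits 0.2 points below yet improves both -> consistency wins
  s1 <- fake_sim(mod_pa = c(9.8, 4.6, 0, 0), mod_bias = c(0, 0, 0, 0))
  s2 <- fake_sim(mod_pa = c(-0.2, 4.6, 0, 0), mod_bias = c(0, 0, 0, 0), id = "d2")
  agg <- aggregate_sim(list(s1, s2))
  expect_equal(agg$mean_modulated_pa[1:2], c(4.8, 4.6))
  sel <- select_uc_pair(agg, pa_tolerance = 0.5)
  expect_equal(sel$mean_modulated_pa, 4.6)
  expect_equal(sel$consistency, 2)
  # with a zero-width band the raw maximum wins instead
  strict <- select_uc_pair(agg, pa_tolerance = 0)
  expect_equal(strict$mean_modulated_pa, 4.8)
})

test_that("individual selection takes each dataset's argmax and dominates the group pair", {
  s1 <- fake_sim(mod_pa = c(1, 7, 2, 3))
  s2 <- fake_sim(mod_pa = c(6, 1, 2, 3), id = "d2")
  ind <- select_individual_uc(list(s1, s2))
  expect_equal(nrow(ind), 2L)
  expect_equal(ind$modulated_pa, c(7, 6))
  group <- select_uc_pair(aggregate_sim(list(s1, s2)))
  for (s in list(s1, s2)) {
    ipa <- ind$adaptive_pa[ind$dataset_id == attr(s, "dataset_id")]
    gpa <- s$adaptive_pa[s$uc_mu == group$uc_mu & s$uc_sigma == group$uc_sigma]
    expect_gte(ipa, gpa)
  }
  # deterministic tie-break toward the smallest pair
  tie <- fake_sim(mod_pa = rep(5, 4))
  sel <- select_individual_uc(tie)
  expect_equal(sel$uc_mu, 0.1)
  expect_equal(sel$uc_sigma, 0.1)
})

test_that("individual-pair advantage shrinks on held-out data from the same process", {
  grid <- c(0, 0.4 * 2^-6, 0.05)
  run_grid <- function(seed) {
    eeg <- generate_dataset(tiny_config(seed = seed, n_trials_offline = 12,
                                        n_trials_online = 12, class_power_gap = 1))
    ph <- phase_features(eeg)
    grid_search(ph$offline, ph$online, grid_mu = grid, grid_sigma = grid,
                timeout = 1, dataset_id = as.character(seed))
  }
  sel_gain <- numeric(0); holdout_gain <- numeric(0)
  for (seed in c(101, 202, 303)) {
    a <- run_grid(seed)
    b <- run_grid(seed + 1000) # held-out replay of the same process
    pick <- select_individual_uc(a)
    sel_gain <- c(sel_gain, pick$modulated_pa)
    holdout_gain <- c(holdout_gain,
                      b$modulated_pa[b$uc_mu == pick$uc_mu &
                                       b$uc_sigma == pick$uc_sigma])
  }
  expect_gte(mean(sel_gain), mean(holdout_gain))
})
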