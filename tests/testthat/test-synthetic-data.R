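test_that("generator is deterministic and respects the configured geometry", {
  cfg <- neural_sim_config(n_subjects = 6, n_videos = 2, n_regions = 4,
                           timepoints_per_video = c(30, 40), seed = 11)
  a <- simulate_neural_panel(cfg)
  b <- simulate_neural_panel(cfg)
  expect_identical(a, b)
  c <- simulate_neural_panel(neural_sim_config(n_subjects = 6, n_videos = 2,
                                               n_regions = 4,
                                               timepoints_per_video = c(30, 40),
                                               seed = 12))
  expect_false(identical(a$panel$value, c$panel$value))

  expect_equal(length(unique(a$panel$subject)), 6)
  expect_equal(length(unique(a$panel$region)), 4)
  expect_equal(nrow(a$panel), 6 * 4 * (30 + 40))
  expect_true(all(a$ratings$rating %in% 1:5))
  expect_equal(nrow(a$ratings), 6 * 2)
  expect_true(all(a$attributes$age > 0))
  expect_equal(nrow(a$attributes), 6)
})

test_that("per-cell sub-streams are stable when the region count changes", {
  base <- neural_sim_config(n_subjects = 4, n_videos = 2, n_regions = 2,
                            timepoints_per_video = 25, seed = 5)
  wide <- neural_sim_config(n_subjects = 4, n_videos = 2, n_regions = 3,
                            timepoints_per_video = 25, seed = 5)
  a <- simulate_neural_panel(base)$panel
  b <- simulate_neural_panel(wide)$panel
  shared <- c("r001", "r002")
  a <- a[a$region %in% shared, ]
  b <- b[b$region %in% shared, ]
  expect_equal(a$value, b$value)
})

test_that("dropping a subject-video cell yields partial data", {
  cfg <- neural_sim_config(n_subjects = 4, n_videos = 2, n_regions = 2,
                           timepoints_per_video = 20, seed = 2,
                           drop_cells = data.frame(subject = "s02",
                                                   video = "v01"))
  sim <- simulate_neural_panel(cfg)
  held <- unique(sim$panel[c("subject", "video")])
  expect_false(any(held$subject == "s02" & held$video == "v01"))
  expect_true(any(held$subject == "s02" & held$video == "v02"))
})

test_that("invalid configurations are refused with the offending field named", {
  expect_error(neural_sim_config(coupling_high = 0.2, coupling_low = 0.5),
               "coupling_high")
  expect_error(neural_sim_config(noise_sd = 0), "noise_sd")
  expect_error(neural_sim_config(timepoints_per_video = 2),
               "timepoints_per_video")
  expect_error(neural_sim_config(signal_regions = "nowhere"),
               "signal_regions")
  expect_error(neural_sim_config(rating_rule = list(cuts = c(0.5, 0.4, 0.8,
                                                             0.9))),
               "rating_rule")
  expect_error(behavioral_sim_config(n_participants = 1), "n_participants")
  expect_error(behavioral_sim_config(n_items = 1), "n_items")
  expect_error(behavioral_sim_config(sd_residual = 0), "sd_residual")
  expect_error(behavioral_sim_config(condition_means = c(odd = 1)),
               "condition_means")
})

test_that("matched couplings with vanishing noise give near-perfect ISC", {
  cfg <- neural_sim_config(n_subjects = 3, n_videos = 1, n_regions = 2,
                           timepoints_per_video = 100,
                           coupling_high = 1, coupling_low = 1,
                           noise_sd = 1e-6, seed = 3)
  isc <- compute_dyadic_isc(simulate_neural_panel(cfg)$panel,
                            normalize = FALSE)
  expect_true(all(isc$r > 0.999))
})

test_that("uncoupled panels have near-zero ISC that shrinks with series length", {
  mean_abs_r <- function(tp) {
    cfg <- neural_sim_config(n_subjects = 6, n_videos = 1, n_regions = 2,
                             timepoints_per_video = tp,
                             coupling_high = 0, coupling_low = 0, seed = 4)
    mean(abs(compute_dyadic_isc(simulate_neural_panel(cfg)$panel,
                                normalize = FALSE)$r))
  }
  short <- mean_abs_r(30)
  long <- mean_abs_r(3000)
  expect_lt(long, short)
  expect_lt(long, 0.05)
})

test_that("empirical ISC converges to the closed-form coupling ratio", {
  lambda <- 0.8
  sigma <- 1.0
  target <- population_isc(lambda, lambda, sigma)
  expect_equal(target, lambda^2 / (lambda^2 + sigma^2))

  # long-series convergence for every dyad
  cfg <- neural_sim_config(n_subjects = 4, n_videos = 1, n_regions = 1,
                           timepoints_per_video = 10000,
                           coupling_high = lambda, coupling_low = lambda,
                           noise_sd = sigma, seed = 8)
  isc <- compute_dyadic_isc(simulate_neural_panel(cfg)$panel,
                            normalize = FALSE)
  expect_true(all(abs(isc$r - target) < 0.02))

  # Monte-Carlo mean over independent replicate signal draws
  rs <- vapply(1:400, function(s) {
    cfg <- neural_sim_config(n_subjects = 2, n_videos = 1, n_regions = 1,
                             timepoints_per_video = 150,
                             coupling_high = lambda, coupling_low = lambda,
                             noise_sd = sigma, seed = s)
    compute_dyadic_isc(simulate_neural_panel(cfg)$panel,
                       normalize = FALSE)$r
  }, numeric(1))
  expect_lt(abs(mean(rs) - target), 0.02)
})

test_that("mixed couplings follow the asymmetric closed form", {
  lh <- 1.2
  ll <- 0.4
  sigma <- 0.9
  cfg <- neural_sim_config(n_subjects = 8, n_videos = 1, n_regions = 1,
                           timepoints_per_video = 10000,
                           coupling_high = lh, coupling_low = ll,
                           noise_sd = sigma, seed = 21)
  sim <- simulate_neural_panel(cfg)
  isc <- compute_dyadic_isc(sim$panel, normalize = FALSE)
  high <- sim$ratings$subject[sim$ratings$rating >= 3]
  lam <- function(s) if (s %in% high) lh else ll
  expected <- mapply(function(a, b) population_isc(lam(a), lam(b), sigma),
                     isc$subject_a, isc$subject_b)
  expect_true(all(abs(isc$r - expected) < 0.03))
})

test_that("study-2 generator is deterministic with the declared shape", {
  cfg <- behavioral_sim_config(n_participants = 30, n_items = 10,
                               items_per_participant = 5, seed = 6)
  a <- simulate_study2_table(cfg)
  expect_identical(a, simulate_study2_table(cfg))
  expect_equal(nrow(a), 30 * 5)
  expect_true(all(table(a$participant) == 5))
  expect_true(all(a$similarity >= 0 & a$similarity <= 100))
})

test_that("null similarity slope is recovered as approximately zero", {
  cfg <- behavioral_sim_config(n_participants = 200, n_items = 20,
                               items_per_participant = NULL,
                               slope_similarity = 0, seed = 7)
  fit <- fit_study2(simulate_study2_table(cfg), scale = "predictors")
  expect_lt(abs(fit$slope$estimate), 3 * fit$slope$se)
})

test_that("zero item-intercept variance yields a boundary variance component", {
  cfg <- behavioral_sim_config(n_participants = 150, n_items = 15,
                               items_per_participant = NULL,
                               sd_item_intercept = 0, seed = 9)
  fit <- fit_study2(simulate_study2_table(cfg))
  vc <- fit$variance_components
  item_var <- vc$vcov[vc$grp == "article"]
  expect_lt(item_var, 0.01)
})

test_that("study-3 generator allocates conditions in balance and recovers the mean gap", {
  cfg <- behavioral_sim_config(n_per_condition = 75, seed = 10)
  tab <- simulate_study3_table(cfg)
  expect_equal(nrow(tab), 300)
  expect_true(all(table(tab$condition) == 75))
  expect_true(all(tab$interest >= 1 & tab$interest <= 5))

  gaps <- vapply(1:50, function(s) {
    cfg <- behavioral_sim_config(
      condition_means = c(similar = 3.0, dissimilar = 2.4, unclear = 2.4,
                          mixed = 2.8),
      n_per_condition = 75, sd_residual = 1, seed = s)
    tab <- simulate_study3_table(cfg)
    mean(tab$sharing[tab$condition == "similar"]) -
      mean(tab$sharing[tab$condition == "dissimilar"])
  }, numeric(1))
  expect_lt(abs(mean(gaps) - 0.6), 0.07)
})

test_that("missing condition means are refused", {
  cfg <- behavioral_sim_config(condition_means = c(similar = 3,
                                                   dissimilar = 2.4))
  expect_error(simulate_study3_table(cfg), "unclear")
})
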