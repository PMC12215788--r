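test_that("doubling emits exactly two role-ordered copies of each row", {
  joined <- data.frame(subject_a = c("a", "a"), subject_b = c("b", "c"),
                       video = "v1", z_norm = c(0.5, -0.2),
                       stringsAsFactors = FALSE)
  doubled <- double_dyadic_data(joined)
  expect_equal(nrow(doubled), 4)
  expect_equal(attr(doubled, "n_unique"), 2)
  one <- doubled[doubled$role1 == "b" | doubled$role2 == "b", ]
  expect_equal(nrow(one), 2)
  expect_setequal(one$role1, c("a", "b"))
  expect_equal(unique(one$z_norm), 0.5)

  expect_error(double_dyadic_data(rbind(joined, joined[1, ])),
               "pre-doubled")
  # orientation-flipped input doubles to the identical canonical table
  flipped <- joined
  flipped$subject_a <- joined$subject_b
  flipped$subject_b <- joined$subject_a
  expect_identical(double_dyadic_data(flipped), doubled)
})

test_that("corrected df is the undoubled count minus the coefficient count", {
  expect_equal(corrected_df(100, 6), 94)
  expect_equal(corrected_df(29770, 6), 29764)
  expect_error(corrected_df(6, 6), "<= 0")
  expect_error(corrected_df(5, 6), "<= 0")
})

test_that("k matches the design-matrix column count of the fitted model", {
  chain <- sim_chain(seed = 23)
  joined <- merge(chain$design,
                  chain$isc[chain$isc$region == "r001",
                            c("subject_a", "subject_b", "video", "z_norm")],
                  by = c("subject_a", "subject_b", "video"))
  fit <- fit_crossed_lmm(double_dyadic_data(joined))
  X <- model.matrix(~ sharing_category + age_similarity + gender_match +
                      country_match, data = joined)
  expect_equal(fit$k, ncol(X))
  expect_equal(fit$df_corrected, nrow(joined) - fit$k)
  expect_equal(fit$n_unique, nrow(joined))
})

test_that("fixed effects are invariant to dyad re-orientation before doubling", {
  chain <- sim_chain(seed = 29, n_subjects = 6, n_videos = 2, n_regions = 1,
                     timepoints_per_video = 60)
  joined <- merge(chain$design,
                  chain$isc[, c("subject_a", "subject_b", "video",
                                "z_norm")],
                  by = c("subject_a", "subject_b", "video"))
  set.seed(1)
  flip <- runif(nrow(joined)) < 0.5
  reoriented <- joined
  reoriented$subject_a[flip] <- joined$subject_b[flip]
  reoriented$subject_b[flip] <- joined$subject_a[flip]
  reoriented <- reoriented[sample(nrow(reoriented)), ]

  fit1 <- suppressWarnings(fit_crossed_lmm(double_dyadic_data(joined)))
  fit2 <- suppressWarnings(fit_crossed_lmm(double_dyadic_data(reoriented)))
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-8)
})

test_that("contrasts are linear, symmetric, and honest about identity", {
  chain <- sim_chain(seed = 37)
  joined <- merge(chain$design,
                  chain$isc[chain$isc$region == "r002",
                            c("subject_a", "subject_b", "video", "z_norm")],
                  by = c("subject_a", "subject_b", "video"))
  fit <- fit_crossed_lmm(double_dyadic_data(joined))
  hh_ll <- planned_contrast(fit, c("HH", "LL"))
  hh_lh <- planned_contrast(fit, c("HH", "LH"))
  lh_ll <- planned_contrast(fit, c("LH", "LL"))
  expect_equal(hh_ll$estimate, hh_lh$estimate + lh_ll$estimate,
               tolerance = 1e-12)
  expect_equal(planned_contrast(fit, c("LL", "HH"))$estimate,
               -hh_ll$estimate, tolerance = 1e-12)
  ident <- planned_contrast(fit, c("LH", "LH"))
  expect_equal(ident$estimate, 0)
  expect_equal(ident$p_raw, 1)
  expect_equal(hh_ll$df, fit$df_corrected)
  expect_true(hh_ll$ci_low <= hh_ll$estimate &
                hh_ll$estimate <= hh_ll$ci_high)
  expect_error(planned_contrast(fit, c("HH", "XX")), "unknown level")
})

test_that("every reported p uses the corrected df, not the doubled row count", {
  chain <- sim_chain(seed = 41)
  res <- region_wise_analysis(chain$isc, chain$design,
                              contrasts = list(c("HH", "LL")))
  expect_true(all(res$df == nrow(chain$design) - 6))
  expect_equal(2 * pt(-abs(res$t), res$df), res$p_raw, tolerance = 1e-12)
})

test_that("zero in-sample random-effect variance reduces the fit to OLS", {
  chain <- sim_chain(seed = 43, n_subjects = 12, n_videos = 3, n_regions = 1,
                     timepoints_per_video = 30)
  design <- simulate_dyadic_outcome(
    chain$design, beta = c(intercept = 0.2, HH = 0.5, LH = 0.3,
                           age_similarity = 0.1),
    sd_residual = 0.5, seed = 77, exact_zero_re = TRUE)
  fit <- suppressWarnings(
    fit_crossed_lmm(double_dyadic_data(design),
                    model_spec(standardize = FALSE)))
  terms <- sub("^cat_", "sharing_category == '", names(fit$coefficients)[-1])
  rhs <- ifelse(grepl("==", terms), paste0("I(", terms, "')"), terms)
  ols <- lm(as.formula(paste("z_norm ~", paste(rhs, collapse = " + "))),
            data = design)
  expect_lt(max(abs(fit$coefficients_per_unit - coef(ols))), 1e-4)
  expect_lt(sum(fit$variance_components$vcov[
    fit$variance_components$grp != "Residual"]), 1e-10)
})

test_that("constant outcomes and constant predictors are never silently fit", {
  joined <- data.frame(subject_a = c("a", "a", "b"),
                       subject_b = c("b", "c", "c"),
                       video = "v1",
                       sharing_category = c("HH", "LH", "LL"),
                       age_similarity = c(1, 0.5, 0),
                       gender_match = c(1L, 1L, 1L),
                       country_match = c(1L, 0L, 1L),
                       z_norm = 1, stringsAsFactors = FALSE)
  expect_error(fit_crossed_lmm(double_dyadic_data(joined)),
               "zero variance")
})

test_that("holm adjustment matches the hand step-down oracle", {
  expect_equal(holm_bonferroni(c(0.01, 0.03, 0.04)), c(0.03, 0.06, 0.06))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_equal(holm_bonferroni(rep(1, 4)), rep(1, 4))
  for (i in 1:25) {
    set.seed(i)
    p <- runif(sample(1:8, 1))
    expect_equal(holm_bonferroni(p), oracle_holm(p), tolerance = 1e-12)
    expect_true(all(holm_bonferroni(p) >= p))
  }
  expect_error(holm_bonferroni(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("BH adjustment matches the hand step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.7), 0.7)
  for (i in 1:25) {
    set.seed(100 + i)
    p <- runif(sample(1:8, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(bh_fdr(c(-0.1)), "\\[0, 1\\]")
})

test_that("region-wise results are region-exchangeable and single-region is uncorrected", {
  chain <- sim_chain(seed = 47, n_subjects = 10, n_videos = 2, n_regions = 3,
                     timepoints_per_video = 40)
  res <- region_wise_analysis(chain$isc, chain$design,
                              contrasts = list(c("HH", "LL")))
  expect_equal(res$region, sort(res$region))
  one <- region_wise_analysis(chain$isc[chain$isc$region == "r002", ],
                              chain$design,
                              contrasts = list(c("HH", "LL")))
  expect_equal(one$p_adjusted, one$p_raw)
  expect_equal(one$estimate, res$estimate[res$region == "r002"],
               tolerance = 1e-12)

  # relabeling regions permutes rows without changing statistics
  relabeled <- chain$isc
  map <- c(r001 = "rB", r002 = "rC", r003 = "rA")
  relabeled$region <- unname(map[relabeled$region])
  res2 <- region_wise_analysis(relabeled, chain$design,
                               contrasts = list(c("HH", "LL")))
  expect_equal(res2$estimate[match(map[res$region], res2$region)],
               res$estimate, tolerance = 1e-12)
})

test_that("region-wise contrast agrees with the independent emmeans oracle", {
  chain <- sim_chain(seed = 53)
  joined <- merge(chain$design,
                  chain$isc[chain$isc$region == "r001",
                            c("subject_a", "subject_b", "video", "z_norm")],
                  by = c("subject_a", "subject_b", "video"))
  fit <- fit_crossed_lmm(double_dyadic_data(joined),
                         model_spec(standardize = FALSE))
  got <- planned_contrast(fit, c("HH", "LL"))

  doubled <- double_dyadic_data(joined)
  m <- lme4::lmer(z_norm ~ sharing_category + age_similarity +
                    gender_match + country_match +
                    (1 | role1) + (1 | role2) + (1 | video) +
                    (1 | role1:video) + (1 | role2:video),
                  data = doubled)
  emm <- emmeans::emmeans(m, "sharing_category", lmer.df = "asymptotic")
  # weights are positional in emmeans' level order (HH, LH, LL)
  ctr <- as.data.frame(emmeans::contrast(
    emm, method = list(hh_ll = c(1, 0, -1))))
  # the oracle is an independent lmer optimization, hence the loose
  # tolerance; emmeans reports the naive doubled-data SE, which the package
  # corrects by sqrt(2) for the doubling redundancy
  expect_equal(got$estimate, ctr$estimate, tolerance = 1e-3)
  expect_equal(got$se, sqrt(2) * ctr$SE, tolerance = 1e-3)
})
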