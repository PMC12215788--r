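test_that("pearson_corr matches direct evaluation and handles edge inputs", {
  expect_equal(pearson_corr(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  x <- c(0.3, 1.2, -0.5, 2.2, 0.1)
  expect_equal(pearson_corr(x, x), 1.0)
  expect_equal(pearson_corr(x, -x), -1.0)
  for (i in 1:20) {
    set.seed(i)
    a <- rnorm(10)
    b <- rnorm(10)
    expect_equal(pearson_corr(a, b), oracle_pearson(a, b), tolerance = 1e-12)
  }
  expect_error(pearson_corr(1:4, 1:5), "lengths differ")
  expect_error(pearson_corr(1:2, 2:3), "length >= 3")
  expect_error(pearson_corr(rep(1, 5), rnorm(5)), "zero-variance")
})

test_that("fisher_z is the odd, strictly increasing atanh with guarded domain", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493061, tolerance = 1e-7)
  expect_equal(fisher_z(0.5), log(3) / 2)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  r <- seq(-0.99, 0.99, by = 0.01)
  expect_equal(fisher_z(r), oracle_fisher_z(r), tolerance = 1e-12)
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_error(fisher_z(1), "clamp")
  expect_error(fisher_z(-1.2), "clamp")
  expect_equal(fisher_z(clamp_correlation(1)), atanh(1 - 1e-7))
})

test_that("record counts follow the dyad combinatorics, including partial data", {
  set.seed(42)
  mk <- function(n) rnorm(n)
  series <- list(
    vA = list(R1 = list(s1 = mk(10), s2 = mk(10), s3 = mk(10), s4 = mk(10)),
              R2 = list(s1 = mk(10), s2 = mk(10), s3 = mk(10), s4 = mk(10))),
    vB = list(R1 = list(s1 = mk(12), s2 = mk(12), s3 = mk(12)),
              R2 = list(s1 = mk(12), s2 = mk(12), s3 = mk(12))))
  isc <- compute_dyadic_isc(build_panel(series))
  expect_equal(nrow(isc), choose(4, 2) * 2 + choose(3, 2) * 2)
  expect_equal(sum(isc$video == "vB"), choose(3, 2) * 2)
  expect_false("s4" %in% c(isc$subject_a[isc$video == "vB"],
                           isc$subject_b[isc$video == "vB"]))

  # 3 subjects, 1 video, 2 regions -> exactly 6 records
  small <- list(v1 = list(R1 = list(a = mk(8), b = mk(8), c = mk(8)),
                          R2 = list(a = mk(8), b = mk(8), c = mk(8))))
  expect_equal(nrow(compute_dyadic_isc(build_panel(small),
                                       normalize = FALSE)), 6)
})

test_that("a region held by only one subject on a shared video is a structural error", {
  set.seed(1)
  series <- list(v1 = list(R1 = list(a = rnorm(8), b = rnorm(8)),
                           R2 = list(a = rnorm(8))))
  expect_error(compute_dyadic_isc(build_panel(series)), "lacks region")
})

test_that("dyadic ISC equals an independent brute-force double loop", {
  set.seed(99)
  mk <- function(n) rnorm(n)
  series <- list(
    v1 = list(R1 = list(a = mk(15), b = mk(15), c = mk(15), d = mk(15)),
              R2 = list(a = mk(15), b = mk(15), c = mk(15), d = mk(15))),
    v2 = list(R1 = list(a = mk(9), b = mk(9), c = mk(9), d = mk(9)),
              R2 = list(a = mk(9), b = mk(9), c = mk(9), d = mk(9))))
  panel <- build_panel(series)
  got <- compute_dyadic_isc(panel, normalize = FALSE)
  want <- oracle_dyadic_isc(panel)
  key <- function(d) paste(d$subject_a, d$subject_b, d$video, d$region)
  want <- want[match(key(got), key(want)), ]
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$z, atanh(want$r), tolerance = 1e-12)
})

test_that("dyads are stored in canonical order exactly once", {
  chain <- sim_chain(seed = 31, n_subjects = 6, n_videos = 2, n_regions = 2,
                     timepoints_per_video = 25)
  isc <- chain$isc
  expect_true(all(isc$subject_a < isc$subject_b))
  expect_equal(anyDuplicated(isc[c("subject_a", "subject_b", "video",
                                   "region")]), 0L)
})

test_that("within-region normalization matches the sample-sd convention", {
  rec <- data.frame(region = c("A", "A"), z = c(1, 3))
  out <- normalize_within_region(rec)
  expect_equal(out$z_norm, c(-1, 1) / sqrt(2), tolerance = 1e-9)

  # idempotence on standardized input and location invariance
  set.seed(5)
  rec <- data.frame(region = rep(c("A", "B"), each = 20),
                    z = rnorm(40))
  once <- normalize_within_region(rec)
  rec2 <- once
  rec2$z <- once$z_norm
  twice <- normalize_within_region(rec2[c("region", "z")])
  expect_equal(twice$z_norm, once$z_norm, tolerance = 1e-9)
  shifted <- rec
  shifted$z <- rec$z + ifelse(rec$region == "A", 10, -3)
  expect_equal(normalize_within_region(shifted)$z_norm, once$z_norm,
               tolerance = 1e-9)

  # per-region mean 0 / sd 1 invariant
  expect_true(all(abs(tapply(once$z_norm, once$region, mean)) < 1e-9))
  expect_true(all(abs(tapply(once$z_norm, once$region, sd) - 1) < 1e-9))

  expect_error(normalize_within_region(
    data.frame(region = c("A", "B", "B"), z = c(1, 1, 2))), "A")
  expect_error(normalize_within_region(
    data.frame(region = c("A", "A"), z = c(2, 2))), "zero spread")
})

test_that("normalized ISC output keeps the per-region standardization invariant", {
  chain <- sim_chain(seed = 13, n_subjects = 8, n_videos = 2, n_regions = 3,
                     timepoints_per_video = 40)
  isc <- chain$isc
  expect_true(all(abs(tapply(isc$z_norm, isc$region, mean)) < 1e-9))
  expect_true(all(abs(tapply(isc$z_norm, isc$region, sd) - 1) < 1e-9))
})
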