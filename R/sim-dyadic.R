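#' Simulate a dyadic outcome with known fixed effects
#'
#' Attaches an outcome column to a dyad design with a known linear predictor
#' (`intercept + beta_HH*[HH] + beta_LH*[LH] + covariate effects`) plus
#' residual noise, for parameter-recovery and degenerate-limit testing of
#' the crossed mixed model.
#'
#' With `exact_zero_re = TRUE` the residuals are projected orthogonal to the
#' span of every random-effect grouping (subject membership, video, and
#' subject-by-video membership indicators), so the generated data carry
#' *exactly* zero in-sample random-effect variance. This instantiates the
#' degenerate limit deterministically: a REML fit must land on the all-zero
#' variance boundary, where the mixed-model fixed effects coincide with OLS.
#' (With merely independent residuals the in-sample group means fluctuate,
#' REML estimates small positive components about half the time, and the
#' GLS fixed effects drift away from OLS at finite n.)
#'
#' @param design A [build_dyad_design()] table.
#' @param beta Named vector of true effects; recognized names are
#'   `intercept`, `HH`, `LH`, `age_similarity`, `gender_match`,
#'   `country_match` (missing names default to 0).
#' @param sd_residual Residual standard deviation.
#' @param seed Integer seed.
#' @param exact_zero_re Project residuals to exactly zero random-effect
#'   contributions (default `FALSE`).
#' @param outcome Name of the outcome column to create (default `z_norm`).
#' @return `design` with the outcome column added.
#' @export
simulate_dyadic_outcome <- function(design, beta = c(intercept = 0, HH = 0.5,
                                                     LH = 0.25),
                                    sd_residual = 0.5, seed = 1L,
                                    exact_zero_re = FALSE,
                                    outcome = "z_norm") {
  full <- c(intercept = 0, HH = 0, LH = 0, age_similarity = 0,
            gender_match = 0, country_match = 0)
  unknown <- setdiff(names(beta), names(full))
  if (length(unknown)) {
    stop("unknown effect name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  full[names(beta)] <- beta
  sd_residual <- check_positive(sd_residual, "sd_residual")
  n <- nrow(design)
  e <- with_seed(derive_seed(seed, "dyadic_outcome"),
                 rnorm(n, sd = sd_residual))
  if (isTRUE(exact_zero_re)) {
    subs <- sort(unique(c(design$subject_a, design$subject_b)))
    M <- vapply(subs, function(s) {
      (design$subject_a == s) + (design$subject_b == s)
    }, numeric(n))
    V <- vapply(sort(unique(design$video)), function(v) {
      as.numeric(design$video == v)
    }, numeric(n))
    SV <- do.call(cbind, lapply(seq_along(subs), function(j) M[, j] * V))
    G <- cbind(M, V, SV)
    e <- e - G %*% qr.coef(qr(G), e)
    e[is.na(e)] <- 0
    e <- as.numeric(e)
  }
  design[[outcome]] <- full[["intercept"]] +
    full[["HH"]] * (design$sharing_category == "HH") +
    full[["LH"]] * (design$sharing_category == "LH") +
    full[["age_similarity"]] * design$age_similarity +
    full[["gender_match"]] * design$gender_match +
    full[["country_match"]] * design$country_match +
    e
  design
}
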