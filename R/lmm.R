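#' Specification of the region-wise crossed mixed model
#'
#' The model regresses within-region normalized ISC on the dyad's sharing
#' category (LL / LH / HH dummies against a reference level) and the
#' demographic-similarity covariates, with random intercepts for each dyad
#' member's role (participant 1, participant 2), the video, and each
#' role-by-video interaction. Because a dyad is symmetric, the data are
#' doubled (each dyadic observation appears once per role ordering) before
#' fitting, and all t-based inference uses degrees of freedom corrected to
#' `N - k`, where `N` is the *undoubled* observation count and `k` the number
#' of fixed-effect coefficients.
#'
#' @param outcome Outcome column name (default `"z_norm"`).
#' @param covariates Fixed-effect covariate columns.
#' @param reference Reference level of the sharing category (default `"LL"`,
#'   so the HH dummy is the headline coefficient).
#' @param standardize If `TRUE`, the outcome and every predictor column
#'   (including 0/1 dummies) are z-scored before fitting; contrasts are then
#'   reported in outcome-SD units.
#' @param reml Use REML (default) rather than ML.
#' @param include_intercept_in_k Whether `k` counts the intercept (default
#'   `TRUE`: `k` is the design-matrix column count).
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(outcome = "z_norm",
                       covariates = c("age_similarity", "gender_match",
                                      "country_match"),
                       reference = "LL",
                       standardize = TRUE,
                       reml = TRUE,
                       include_intercept_in_k = TRUE) {
  if (!reference %in% c("LL", "LH", "HH")) {
    stop("reference must be one of LL, LH, HH", call. = FALSE)
  }
  structure(list(outcome = outcome, covariates = covariates,
                 reference = reference, standardize = standardize,
                 reml = reml,
                 include_intercept_in_k = include_intercept_in_k),
            class = "model_spec")
}

#' Double a dyadic table for fully crossed random effects
#'
#' Each (dyad, video) row appears twice in the output, once per role
#' ordering: `(i, j)` and `(j, i)`. Outcome and dyad-level covariates are
#' identical across the pair; only the `role1` / `role2` columns differ.
#' Rows are sorted canonically so the result is independent of the input's
#' dyad orientation and row order.
#'
#' @param joined data.frame with columns `subject_a`, `subject_b`, `video`
#'   plus outcome/covariates; one row per (dyad, video).
#' @return data.frame of class `doubled_dyadic` with `role1`, `role2`
#'   replacing the subject columns and attribute `n_unique` holding the
#'   undoubled row count.
#' @export
double_dyadic_data <- function(joined) {
  key_cols <- c("subject_a", "subject_b", "video")
  if (!all(key_cols %in% names(joined))) {
    stop("input needs columns subject_a, subject_b, video", call. = FALSE)
  }
  dyad_key <- paste(pmin(joined$subject_a, joined$subject_b),
                    pmax(joined$subject_a, joined$subject_b),
                    joined$video, sep = "\x1f")
  if (anyDuplicated(dyad_key)) {
    stop("input already contains duplicated (dyad, video) rows; ",
         "refusing to double pre-doubled data", call. = FALSE)
  }
  rest <- joined[setdiff(names(joined), key_cols)]
  fwd <- data.frame(role1 = joined$subject_a, role2 = joined$subject_b,
                    video = joined$video, rest, stringsAsFactors = FALSE)
  rev <- data.frame(role1 = joined$subject_b, role2 = joined$subject_a,
                    video = joined$video, rest, stringsAsFactors = FALSE)
  doubled <- rbind(fwd, rev)
  doubled <- doubled[order(doubled$role1, doubled$role2, doubled$video), ,
                     drop = FALSE]
  rownames(doubled) <- NULL
  attr(doubled, "n_unique") <- nrow(joined)
  class(doubled) <- c("doubled_dyadic", class(doubled))
  doubled
}

#' Degrees of freedom corrected for data doubling
#'
#' @param n_unique Number of unique (undoubled) observations.
#' @param k Number of fixed-effect coefficients.
#' @return Integer `n_unique - k` (> 0 required).
#' @export
corrected_df <- function(n_unique, k) {
  n_unique <- check_count(n_unique, "n_unique", min = 1L)
  k <- check_count(k, "k", min = 0L)
  if (n_unique <= k) {
    stop(sprintf("corrected df would be <= 0 (N = %d, k = %d)", n_unique, k),
         call. = FALSE)
  }
  n_unique - k
}

#' Fit the doubled-data crossed random-effects model
#'
#' Fits (by REML, via `lme4::lmer`) the linear mixed model of [model_spec()]
#' on a doubled dyadic table: fixed effects for the sharing-category dummies
#' and covariates, random intercepts for `role1`, `role2`, `video`,
#' `role1:video` and `role2:video`. When `spec$standardize` is `TRUE`, the
#' outcome and all predictor columns are z-scored first (sample sd);
#' coefficients are additionally re-expressed per raw predictor unit so that
#' category contrasts come out in outcome-SD units. Zero-variance predictors
#' (e.g. an all-matching country indicator in a small cohort) are dropped
#' with a warning and excluded from `k`.
#'
#' @param doubled A [double_dyadic_data()] result (or a table with `role1`,
#'   `role2`, `video` columns and an `n_unique` attribute).
#' @param spec A [model_spec()].
#' @param refit_from Optional previous `crossed_lmm_fit` on a table with the
#'   *identical* predictor structure (same rows, groupings and predictor
#'   values; only the outcome may differ). The model-setup stage
#'   (`lme4::lFormula`) is then reused and only the response is replaced
#'   before optimization, which runs from the same default start as a fresh
#'   fit — the estimates are numerically identical to fitting from scratch,
#'   just faster. Used by [region_wise_analysis()], where every region
#'   shares one design.
#' @return Object of class `crossed_lmm_fit`: coefficients, covariance,
#'   variance components, `n_unique`, `k`, `df_corrected`, convergence and
#'   singularity flags, and the underlying `lmerMod`.
#' @export
fit_crossed_lmm <- function(doubled, spec = model_spec(),
                            refit_from = NULL) {
  for (col in c("role1", "role2", "video")) {
    if (!col %in% names(doubled)) {
      stop("doubled table lacks column ", col, call. = FALSE)
    }
  }
  n_unique <- attr(doubled, "n_unique") %||% (nrow(doubled) / 2L)
  outcome <- spec$outcome
  if (!outcome %in% names(doubled)) {
    stop("outcome column '", outcome, "' not found", call. = FALSE)
  }
  y <- doubled[[outcome]]
  if (sd(y) == 0) {
    stop("outcome '", outcome, "' has zero variance; refusing to fit",
         call. = FALSE)
  }

  dat <- data.frame(role1 = factor(doubled$role1),
                    role2 = factor(doubled$role2),
                    video = factor(doubled$video))
  predictors <- list()
  dummy_map <- list()
  if ("sharing_category" %in% names(doubled)) {
    levels_all <- c("LL", "LH", "HH")
    cat <- factor(doubled$sharing_category,
                  levels = c(spec$reference,
                             setdiff(levels_all, spec$reference)))
    for (lev in levels(cat)[-1L]) {
      nm <- paste0("cat_", lev)
      predictors[[nm]] <- as.numeric(cat == lev)
      dummy_map[[lev]] <- nm
    }
  }
  for (cv in spec$covariates) {
    if (!cv %in% names(doubled)) {
      stop("covariate column '", cv, "' not found", call. = FALSE)
    }
    predictors[[cv]] <- as.numeric(doubled[[cv]])
  }

  # drop constant predictors (they carry no information and break scaling)
  keep <- vapply(predictors, function(p) sd(p) > 0, logical(1))
  if (any(!keep)) {
    warning("dropping constant predictor(s): ",
            paste(names(predictors)[!keep], collapse = ", "))
    dummy_map <- dummy_map[unlist(dummy_map) %in% names(predictors)[keep]]
    predictors <- predictors[keep]
  }

  col_sds <- rep(1, length(predictors))
  names(col_sds) <- names(predictors)
  outcome_scale <- list(mean = 0, sd = 1)
  if (isTRUE(spec$standardize)) {
    zs <- zscore(y)
    y <- zs$values
    outcome_scale <- zs[c("mean", "sd")]
    for (nm in names(predictors)) {
      zp <- zscore(predictors[[nm]])
      predictors[[nm]] <- zp$values
      col_sds[[nm]] <- zp$sd
    }
  }
  dat$.y <- y
  for (nm in names(predictors)) dat[[nm]] <- predictors[[nm]]

  rhs <- paste(c(names(predictors), "(1 | role1)", "(1 | role2)",
                 "(1 | video)", "(1 | role1:video)", "(1 | role2:video)"),
               collapse = " + ")
  form <- as.formula(paste(".y ~", rhs))

  reuse <- !is.null(refit_from) &&
    inherits(refit_from, "crossed_lmm_fit") &&
    !is.null(refit_from$lmod) &&
    identical(refit_from$spec_reml, isTRUE(spec$reml)) &&
    identical(refit_from$predictor_frame,
              dat[setdiff(names(dat), ".y")])
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  conv_msgs <- character()
  fit <- withCallingHandlers({
    # modular fit: when the predictor structure is shared (one design,
    # many regions), the model-matrix setup is reused and only the
    # response changes; optimization always runs from the same default
    # start, so reuse is numerically identical to fitting from scratch
    if (reuse) {
      lmod <- refit_from$lmod
      lmod$fr[[1L]] <- dat$.y
      # optimization leaves its converged theta behind in reTrms;
      # restore the pristine start so reuse replays the fresh-fit path
      lmod$reTrms$theta <- c(refit_from$theta_init)
    } else {
      lmod <- lme4::lFormula(form, data = dat, REML = isTRUE(spec$reml),
                             control = ctrl)
    }
    theta_init <- c(lmod$reTrms$theta)
    devfun <- do.call(lme4::mkLmerDevfun,
                      c(lmod[c("fr", "X", "reTrms", "REML")],
                        list(control = ctrl)))
    opt <- lme4::optimizeLmer(devfun, optimizer = ctrl$optimizer,
                              restart_edge = ctrl$restart_edge,
                              boundary.tol = ctrl$boundary.tol,
                              control = ctrl$optCtrl,
                              calc.derivs = FALSE)
    lme4::mkMerMod(environment(devfun), opt, lmod$reTrms, fr = lmod$fr)
  },
  warning = function(w) {
    conv_msgs <<- c(conv_msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  },
  message = function(m) {
    conv_msgs <<- c(conv_msgs, conditionMessage(m))
    invokeRestart("muffleMessage")
  })
  # a boundary (singular) fit is a legitimate outcome, not non-convergence
  problems <- grep("singular", c(conv_msgs,
                                 fit@optinfo$conv$lme4$messages %||%
                                   character()),
                   invert = TRUE, value = TRUE)
  converged <- length(problems) == 0L && (fit@optinfo$conv$opt == 0L)
  singular <- lme4::isSingular(fit)

  beta <- lme4::fixef(fit)
  # Doubling enters every observation twice, so the information matrix of
  # the doubled fit is inflated twofold and naive SEs are sqrt(2) too
  # small; the sampling covariance is corrected by the redundancy factor 2
  # (the companion of the N - k df correction). Null-panel simulations
  # confirm the corrected t-statistics are calibrated.
  vc <- 2 * as.matrix(vcov(fit))
  # re-express slopes per raw predictor unit (outcome stays on fit scale)
  slope_names <- names(predictors)
  d <- c(1, 1 / col_sds[slope_names])  # intercept untouched
  names(d) <- c("(Intercept)", slope_names)
  d <- d[names(beta)]
  beta_raw <- beta * d
  vcov_raw <- vc * tcrossprod(d)

  k <- length(beta) - if (isTRUE(spec$include_intercept_in_k)) 0L else 1L
  vcs <- as.data.frame(lme4::VarCorr(fit))

  structure(list(
    coefficients = beta, coefficients_per_unit = beta_raw,
    vcov_per_unit = vcov_raw, variance_components = vcs,
    dummy_map = dummy_map, reference = spec$reference,
    covariates = intersect(spec$covariates, slope_names),
    outcome = outcome, outcome_scale = outcome_scale,
    standardize = isTRUE(spec$standardize),
    n_unique = as.integer(n_unique), k = as.integer(k),
    df_corrected = corrected_df(n_unique, k),
    converged = converged, singular = singular,
    convergence_messages = conv_msgs, model = fit,
    lmod = lmod, theta_init = theta_init,
    spec_reml = isTRUE(spec$reml),
    predictor_frame = dat[setdiff(names(dat), ".y")]),
    class = "crossed_lmm_fit")
}

#' @export
print.crossed_lmm_fit <- function(x, ...) {
  cat(sprintf(
    "crossed_lmm_fit: N_unique = %d, k = %d, df = %d (%s%s)\n",
    x$n_unique, x$k, x$df_corrected,
    if (x$converged) "converged" else "NOT converged",
    if (x$singular) ", singular" else ""))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Planned contrast of sharing-category levels
#'
#' Difference of estimated marginal means between two sharing-category
#' levels, with covariates held at their means (for a model linear in
#' additive covariates this is the difference of the per-unit dummy
#' coefficients). The standard error comes from the fixed-effect covariance;
#' the two-tailed p-value and the confidence interval use a t distribution
#' on the doubling-corrected `N - k` degrees of freedom.
#'
#' @param fit A [fit_crossed_lmm()] result (converged).
#' @param pair Character vector `c(level_a, level_b)`; the contrast is
#'   `level_a - level_b`.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row data.frame of class `contrast_result`: `contrast`,
#'   `estimate`, `se`, `t`, `df`, `p_raw`, `ci_low`, `ci_high`. Estimates
#'   are in outcome-SD units when the fit was standardized.
#' @export
planned_contrast <- function(fit, pair = c("HH", "LL"), conf_level = 0.95) {
  if (!inherits(fit, "crossed_lmm_fit")) {
    stop("fit must be a crossed_lmm_fit", call. = FALSE)
  }
  if (!fit$converged) {
    stop("model did not converge; inference suppressed", call. = FALSE)
  }
  if (length(pair) != 2L) stop("pair must name two levels", call. = FALSE)
  levels_all <- c(fit$reference, names(fit$dummy_map))
  if (!all(pair %in% levels_all)) {
    stop("unknown level(s): ",
         paste(setdiff(pair, levels_all), collapse = ", "), call. = FALSE)
  }
  w <- setNames(numeric(length(fit$dummy_map)), unlist(fit$dummy_map))
  if (pair[1L] != fit$reference) w[fit$dummy_map[[pair[1L]]]] <- w[fit$dummy_map[[pair[1L]]]] + 1
  if (pair[2L] != fit$reference) w[fit$dummy_map[[pair[2L]]]] <- w[fit$dummy_map[[pair[2L]]]] - 1
  df <- fit$df_corrected
  if (all(w == 0)) {
    est <- 0; se <- 0; tval <- 0; p <- 1
  } else {
    b <- fit$coefficients_per_unit[names(w)]
    v <- fit$vcov_per_unit[names(w), names(w), drop = FALSE]
    est <- sum(w * b)
    se <- sqrt(as.numeric(t(w) %*% v %*% w))
    tval <- est / se
    p <- 2 * pt(-abs(tval), df = df)
  }
  q <- qt(1 - (1 - conf_level) / 2, df = df)
  out <- data.frame(contrast = paste(pair, collapse = "-"),
                    estimate = est, se = se, t = tval, df = df, p_raw = p,
                    ci_low = est - q * se, ci_high = est + q * se,
                    stringsAsFactors = FALSE)
  class(out) <- c("contrast_result", class(out))
  out
}

#' Region-wise doubled-data analysis with multiplicity correction
#'
#' For each region: joins the design table with that region's normalized ISC
#' records on (dyad, video), doubles the joined table, fits the crossed
#' mixed model, and evaluates the requested planned contrasts. Each contrast
#' family is then corrected across regions (Holm-Bonferroni by default).
#' Regions whose model fails to converge are recorded (`converged = FALSE`,
#' statistics `NA`) and excluded from the corrected family.
#'
#' @param isc `isc_records` from [compute_dyadic_isc()].
#' @param design `dyad_design` from [build_dyad_design()].
#' @param spec A [model_spec()].
#' @param contrasts `"all"` (the three pairwise category contrasts) or a list
#'   of level pairs such as `list(c("HH", "LL"))`.
#' @param correction `"holm"`, `"bh"`, or `"none"`.
#' @param alpha Significance threshold applied to adjusted p-values.
#' @return data.frame: `region`, `contrast`, `estimate`, `se`, `t`, `df`,
#'   `p_raw`, `p_adjusted`, `significant`, `converged`; one row per region
#'   and contrast, sorted by region label.
#' @export
region_wise_analysis <- function(isc, design, spec = model_spec(),
                                 contrasts = list(c("HH", "LL")),
                                 correction = c("holm", "bh", "none"),
                                 alpha = 0.05) {
  correction <- match.arg(correction)
  if (identical(contrasts, "all")) {
    contrasts <- list(c("HH", "LL"), c("HH", "LH"), c("LH", "LL"))
  }
  regions <- sort(unique(isc$region))
  if (length(regions) < 1L) stop("no regions in ISC records", call. = FALSE)
  rows <- list()

  # Regions of one panel typically share a single predictor structure; the
  # first fit carries the reusable model setup. Reuse replays the identical
  # optimization from the same start, so results are unchanged.
  template <- NULL
  for (rg in regions) {
    sub <- isc[isc$region == rg,
               c("subject_a", "subject_b", "video", spec$outcome)]
    joined <- merge(design, sub,
                    by = c("subject_a", "subject_b", "video"))
    if (nrow(joined) == 0L) {
      stop("region ", rg, ": no (dyad, video) rows joined between design ",
           "and ISC records", call. = FALSE)
    }
    fit <- fit_crossed_lmm(double_dyadic_data(joined), spec,
                           refit_from = template)
    if (is.null(template)) template <- fit
    for (pair in contrasts) {
      if (fit$converged) {
        cr <- planned_contrast(fit, pair)
        rows[[length(rows) + 1L]] <- data.frame(
          region = rg, cr[c("contrast", "estimate", "se", "t", "df",
                            "p_raw")],
          converged = TRUE, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          region = rg, contrast = paste(pair, collapse = "-"),
          estimate = NA_real_, se = NA_real_, t = NA_real_, df = NA_integer_,
          p_raw = NA_real_, converged = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  res$p_adjusted <- NA_real_
  for (cn in unique(res$contrast)) {
    idx <- which(res$contrast == cn & res$converged)
    if (length(idx)) {
      res$p_adjusted[idx] <- switch(correction,
                                    holm = holm_bonferroni(res$p_raw[idx]),
                                    bh = bh_fdr(res$p_raw[idx]),
                                    none = res$p_raw[idx])
    }
  }
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  res <- res[order(res$region, res$contrast),
             c("region", "contrast", "estimate", "se", "t", "df", "p_raw",
               "p_adjusted", "significant", "converged")]
  rownames(res) <- NULL
  res
}
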