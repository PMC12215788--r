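# Behavioral analyses: perceived similarity -> sharing (crossed random
# intercepts for participant and item) and the four-condition social-context
# experiment (linear model, pairwise planned contrasts under FDR).

#' Mixed model of sharing likelihood on perceived similarity
#'
#' Fits `sharing ~ similarity (+ interest + valence) + (1 | participant) +
#' (1 | article)` by REML. With `scale = "all"` (default) every variable is
#' z-scored before fitting, so the similarity coefficient is a standardized
#' regression coefficient; `"predictors"` z-scores only the predictors
#' (slope per 1-SD similarity in raw outcome units); `"none"` fits raw.
#' Inference on the slope uses residual-style degrees of freedom
#' `n_obs - k`, with `k` the fixed-effect count including the intercept;
#' the df rule is recorded in the returned object.
#'
#' @param table `study2_table` (columns `participant`, `article`, `sharing`,
#'   `similarity`, and for `adjusted` also `interest`, `valence`).
#' @param adjusted Add interest and valence as fixed covariates.
#' @param scale `"all"`, `"predictors"`, or `"none"`.
#' @param conf_level Confidence level for the slope interval.
#' @return Object of class `study2_fit`: the `lmerMod`, coefficient table,
#'   and `slope` (one-row data.frame: estimate, se, t, df, p, CI).
#' @export
fit_study2 <- function(table, adjusted = FALSE,
                       scale = c("all", "predictors", "none"),
                       conf_level = 0.95) {
  scale <- match.arg(scale)
  needed <- c("participant", "article", "sharing", "similarity")
  if (adjusted) needed <- c(needed, "interest", "valence")
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    stop("table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(table$participant)) < 2L ||
      length(unique(table$article)) < 2L) {
    stop("need >= 2 participants and >= 2 articles (random intercepts ",
         "unidentifiable otherwise)", call. = FALSE)
  }
  if (sd(table$similarity) == 0) {
    stop("similarity column is constant", call. = FALSE)
  }
  predictors <- c("similarity", if (adjusted) c("interest", "valence"))
  dat <- data.frame(participant = factor(table$participant),
                    article = factor(table$article))
  y <- as.numeric(table$sharing)
  if (scale == "all") y <- zscore(y)$values
  dat$.y <- y
  for (p in predictors) {
    x <- as.numeric(table[[p]])
    dat[[p]] <- if (scale %in% c("all", "predictors")) zscore(x)$values else x
  }
  X <- cbind(1, as.matrix(dat[predictors]))
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient fixed-effect design (collinear predictors: ",
         paste(predictors, collapse = ", "), ")", call. = FALSE)
  }
  form <- as.formula(paste(".y ~", paste(predictors, collapse = " + "),
                           "+ (1 | participant) + (1 | article)"))
  conv_msgs <- character()
  model <- withCallingHandlers(
    lme4::lmer(form, data = dat,
               control = lme4::lmerControl(calc.derivs = FALSE,
                                           check.conv.singular = "ignore")),
    warning = function(w) {
      conv_msgs <<- c(conv_msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  beta <- lme4::fixef(model)
  vc <- as.matrix(vcov(model))
  k <- length(beta)
  n_obs <- nrow(dat)
  df <- corrected_df(n_obs, k)
  est <- beta[["similarity"]]
  se <- sqrt(vc["similarity", "similarity"])
  tval <- est / se
  q <- qt(1 - (1 - conf_level) / 2, df = df)
  slope <- data.frame(contrast = "similarity", estimate = est, se = se,
                      t = tval, df = df, p_raw = 2 * pt(-abs(tval), df),
                      ci_low = est - q * se, ci_high = est + q * se,
                      stringsAsFactors = FALSE)
  structure(list(model = model, coefficients = beta, vcov = vc,
                 slope = slope, n_obs = n_obs, k = k, df = df,
                 df_rule = "n_obs - k (k includes intercept)",
                 adjusted = adjusted, scale = scale,
                 variance_components = as.data.frame(lme4::VarCorr(model)),
                 converged = length(conv_msgs) == 0L,
                 convergence_messages = conv_msgs),
            class = "study2_fit")
}

#' @export
print.study2_fit <- function(x, ...) {
  cat(sprintf("study2_fit (%s%s): n = %d, df = %d\n",
              x$scale, if (x$adjusted) ", adjusted" else "", x$n_obs, x$df))
  print(x$slope, row.names = FALSE)
  invisible(x)
}

study3_conditions <- c("similar", "dissimilar", "unclear", "mixed")

#' Linear model of sharing likelihood on social context
#'
#' Fits `sharing ~ condition (+ baseline_sharing + interest)` by OLS with
#' the four-level social-context factor (reference: `dissimilar`).
#' `standardize` z-scores the outcome and the numeric covariates (the
#' condition factor is left categorical), so condition contrasts are in
#' outcome-SD units; contrasts are reference-free either way.
#'
#' @param table `study3_table` (columns `participant`, `condition`,
#'   `sharing`, and for `controlled` also `baseline_sharing`, `interest`).
#' @param controlled Add baseline sharing and interest as covariates.
#' @param standardize Z-score outcome and numeric covariates.
#' @return Object of class `study3_fit` wrapping the `lm` fit.
#' @export
fit_study3 <- function(table, controlled = FALSE, standardize = TRUE) {
  needed <- c("participant", "condition", "sharing")
  if (controlled) needed <- c(needed, "baseline_sharing", "interest")
  missing <- setdiff(needed, names(table))
  if (length(missing)) {
    stop("table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(table$condition), study3_conditions)
  if (length(bad)) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  empty <- setdiff(study3_conditions, unique(table$condition))
  if (length(empty)) {
    stop("condition(s) with no participants: ",
         paste(empty, collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(condition = factor(table$condition,
                                       levels = c("dissimilar", "similar",
                                                  "unclear", "mixed")))
  y <- as.numeric(table$sharing)
  if (standardize) y <- zscore(y)$values
  dat$.y <- y
  covariates <- if (controlled) c("baseline_sharing", "interest") else
    character()
  for (cv in covariates) {
    x <- as.numeric(table[[cv]])
    dat[[cv]] <- if (standardize) zscore(x)$values else x
  }
  form <- as.formula(paste(".y ~", paste(c("condition", covariates),
                                         collapse = " + ")))
  model <- lm(form, data = dat)
  structure(list(model = model, coefficients = coef(model),
                 vcov = vcov(model), n_obs = nrow(dat),
                 k = length(coef(model)),
                 df = model$df.residual, controlled = controlled,
                 standardize = standardize),
            class = "study3_fit")
}

#' @export
print.study3_fit <- function(x, ...) {
  cat(sprintf("study3_fit (%s%s): n = %d, residual df = %d\n",
              if (x$standardize) "standardized" else "raw",
              if (x$controlled) ", controlled" else "", x$n_obs, x$df))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Pairwise condition contrasts with FDR correction
#'
#' Differences of estimated marginal condition means (covariates, if any,
#' held at their means) for the requested pairs, with two-tailed t tests on
#' the model's residual degrees of freedom and Benjamini-Hochberg adjustment
#' across exactly the requested family. Without covariates the estimates
#' equal raw group-mean differences.
#'
#' @param fit A [fit_study3()] result.
#' @param which `"primary"` (similar-dissimilar), `"all"` (all six pairwise
#'   contrasts), or a list of condition pairs `c(a, b)` meaning `a - b`.
#' @param conf_level Confidence level.
#' @return data.frame: `contrast`, `estimate`, `se`, `t`, `df`, `p_raw`,
#'   `p_adjusted`, `ci_low`, `ci_high`.
#' @export
study3_contrasts <- function(fit, which = "all", conf_level = 0.95) {
  if (!inherits(fit, "study3_fit")) {
    stop("fit must be a study3_fit", call. = FALSE)
  }
  if (identical(which, "primary")) {
    pairs <- list(c("similar", "dissimilar"))
  } else if (identical(which, "all")) {
    pairs <- list(c("similar", "dissimilar"), c("similar", "unclear"),
                  c("similar", "mixed"), c("mixed", "dissimilar"),
                  c("unclear", "dissimilar"), c("mixed", "unclear"))
  } else {
    pairs <- which
  }
  if (fit$df <= 0) {
    stop("no residual degrees of freedom for inference (df = ", fit$df, ")",
         call. = FALSE)
  }
  beta <- fit$coefficients
  V <- fit$vcov
  dummy_of <- function(lev) {
    if (lev == "dissimilar") return(NULL)
    nm <- paste0("condition", lev)
    if (!nm %in% names(beta)) stop("unknown condition: ", lev,
                                   call. = FALSE)
    nm
  }
  rows <- lapply(pairs, function(pr) {
    if (length(pr) != 2L || !all(pr %in% study3_conditions)) {
      stop("unknown contrast: ", paste(pr, collapse = "-"), call. = FALSE)
    }
    w <- setNames(numeric(length(beta)), names(beta))
    a <- dummy_of(pr[1L]); b <- dummy_of(pr[2L])
    if (!is.null(a)) w[a] <- w[a] + 1
    if (!is.null(b)) w[b] <- w[b] - 1
    est <- sum(w * beta)
    se <- sqrt(as.numeric(t(w) %*% V %*% w))
    tval <- if (se > 0) est / se else 0
    p <- if (se > 0) 2 * pt(-abs(tval), fit$df) else 1
    data.frame(contrast = paste(pr, collapse = "-"), estimate = est,
               se = se, t = tval, df = fit$df, p_raw = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- bh_fdr(res$p_raw)
  q <- qt(1 - (1 - conf_level) / 2, fit$df)
  res$ci_low <- res$estimate - q * res$se
  res$ci_high <- res$estimate + q * res$se
  rownames(res) <- NULL
  res
}
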