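# Behavioral-table generators: a crossed participant x item ratings table
# (perceived similarity -> sharing, with participant and item random
# intercepts) and a balanced four-condition between-subjects experiment.

#' Simulate a participant-by-item similarity/sharing ratings table
#'
#' Each participant rates a set of news items. Sharing likelihood follows
#' `grand_mean + participant intercept + item intercept +
#' slope_similarity * standardized similarity + residual`, with perceived
#' similarity drawn uniformly on 0-100 and standardized by its population
#' moments (mean 50, sd 100/sqrt(12)), so `slope_similarity` is the true
#' effect of a 1-SD similarity increase in outcome units. Interest and
#' valence covariates load on the same standardized similarity plus unit
#' noise, for use in the covariate-adjusted model.
#'
#' @param config A [behavioral_sim_config()].
#' @return data.frame of class `study2_table` with columns `participant`,
#'   `article`, `sharing`, `similarity`, `interest`, `valence`.
#' @export
simulate_study2_table <- function(config) {
  if (!inherits(config, "behavioral_sim_config")) {
    stop("config must be a behavioral_sim_config", call. = FALSE)
  }
  with_seed(derive_seed(config$seed, "study2"), {
    participants <- sprintf("p%03d", seq_len(config$n_participants))
    articles <- sprintf("a%02d", seq_len(config$n_items))
    b_p <- rnorm(config$n_participants, sd = config$sd_participant_intercept)
    b_i <- rnorm(config$n_items, sd = config$sd_item_intercept)
    rows <- lapply(seq_along(participants), function(i) {
      items <- if (is.null(config$items_per_participant) ||
                   config$items_per_participant == config$n_items) {
        seq_len(config$n_items)
      } else {
        sort(sample(config$n_items, config$items_per_participant))
      }
      data.frame(participant = participants[i], article = articles[items],
                 pi = b_p[i], ii = b_i[items], stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    n <- nrow(tab)
    tab$similarity <- runif(n, 0, 100)
    sim_z <- (tab$similarity - 50) / (100 / sqrt(12))
    tab$sharing <- config$grand_mean + tab$pi + tab$ii +
      config$slope_similarity * sim_z + rnorm(n, sd = config$sd_residual)
    il <- config$interest_loading
    vl <- config$valence_loading
    tab$interest <- pmin(100, pmax(0, 50 + 20 * (il * sim_z + rnorm(n))))
    tab$valence <- pmin(100, pmax(0, 50 + 20 * (vl * sim_z + rnorm(n))))
    if (isTRUE(config$discretize)) {
      tab$sharing <- pmin(5L, pmax(1L, as.integer(round(tab$sharing))))
    }
    tab$pi <- NULL
    tab$ii <- NULL
    rownames(tab) <- NULL
    class(tab) <- c("study2_table", class(tab))
    tab
  })
}

#' Simulate a four-condition sharing experiment
#'
#' Participants are allocated in balance (`n_per_condition` each) to the four
#' social-context conditions (`similar`, `dissimilar`, `unclear`, `mixed`).
#' Sharing likelihood is the condition mean plus unit-variance-scaled
#' residual noise; interest and baseline-sharing covariates track the
#' participant's residual sharing propensity with strength
#' `covariate_effect`, for use in the covariate-controlled model.
#'
#' @param config A [behavioral_sim_config()]; `condition_means` must name all
#'   four conditions.
#' @param sd_residual Residual standard deviation of sharing (defaults to the
#'   config's `sd_residual`).
#' @return data.frame of class `study3_table` with columns `participant`,
#'   `condition`, `sharing`, `interest`, `baseline_sharing`.
#' @export
simulate_study3_table <- function(config, sd_residual = NULL) {
  if (!inherits(config, "behavioral_sim_config")) {
    stop("config must be a behavioral_sim_config", call. = FALSE)
  }
  conditions <- c("similar", "dissimilar", "unclear", "mixed")
  missing <- setdiff(conditions, names(config$condition_means))
  if (length(missing)) {
    stop("condition_means missing condition(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sd_residual <- sd_residual %||% config$sd_residual
  with_seed(derive_seed(config$seed, "study3"), {
    n <- config$n_per_condition * 4L
    condition <- sample(rep(conditions, each = config$n_per_condition))
    resid <- rnorm(n, sd = sd_residual)
    sharing <- as.numeric(config$condition_means[condition]) + resid
    g <- config$covariate_effect
    resid_z <- if (sd(resid) > 0) resid / sd(resid) else resid
    tab <- data.frame(
      participant = sprintf("p%03d", seq_len(n)),
      condition = condition,
      sharing = sharing,
      interest = pmin(5, pmax(1, 3 + g * resid_z + rnorm(n, sd = 0.8))),
      baseline_sharing = pmin(5, pmax(1, 3 + g * resid_z +
                                        rnorm(n, sd = 0.8))),
      stringsAsFactors = FALSE)
    if (isTRUE(config$discretize)) {
      tab$sharing <- pmin(5L, pmax(1L, as.integer(round(tab$sharing))))
    }
    class(tab) <- c("study3_table", class(tab))
    tab
  })
}
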