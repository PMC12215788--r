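#' Closed-form population ISC of the generative model
#'
#' Two subjects whose series are `l1*s + e1` and `l2*s + e2`, with a shared
#' unit-variance latent signal `s` and independent noise of standard
#' deviation `noise_sd`, have population Pearson correlation
#' `l1*l2 / sqrt((l1^2 + sd^2) * (l2^2 + sd^2))`.
#'
#' @param coupling_a,coupling_b Coupling strengths of the two subjects.
#' @param noise_sd Noise standard deviation.
#' @return Population correlation.
#' @export
population_isc <- function(coupling_a, coupling_b, noise_sd) {
  coupling_a * coupling_b /
    sqrt((coupling_a^2 + noise_sd^2) * (coupling_b^2 + noise_sd^2))
}

# Latent stimulus signal: white noise passed through a short moving average
# (autocorrelated, BOLD-like), then standardized to unit sample variance.
latent_signal <- function(n, window) {
  x <- rnorm(n + window - 1L)
  if (window > 1L) {
    x <- as.numeric(stats::filter(x, rep(1 / window, window), sides = 1L))
    x <- x[window:(n + window - 1L)]
  } else {
    x <- x[seq_len(n)]
  }
  as.numeric(scale(x))
}

#' Simulate a neural time-series panel with known ground truth
#'
#' Generates a long-format panel of regional time series for a simulated
#' naturalistic-viewing experiment, together with per-subject 1-5 sharing
#' ratings and demographic attributes. Each subject's latent engagement with
#' each video (uniform on \[0, 1\]) is thresholded through fixed quantile
#' cut-points to yield the rating; subjects whose rating reaches the high
#' threshold couple strongly (`coupling_high`) to the shared latent signal in
#' the designated signal regions and weakly (`coupling_low`) everywhere else.
#' All randomness flows from `config$seed` through deterministic sub-streams
#' keyed by subject, video and region labels, so output is reproducible and
#' stable under changes to unrelated dimensions.
#'
#' @param config A [neural_sim_config()].
#' @return List with components `panel` (a `ts_panel` data.frame with columns
#'   `subject`, `video`, `region`, `timepoint`, `value`), `ratings` (columns
#'   `subject`, `video`, `rating`) and `attributes` (columns `subject`,
#'   `age`, `gender`, `country`).
#' @examples
#' sim <- simulate_neural_panel(neural_sim_config(n_subjects = 4,
#'   n_videos = 2, n_regions = 3, timepoints_per_video = 40))
#' head(sim$panel)
#' @export
simulate_neural_panel <- function(config) {
  if (!inherits(config, "neural_sim_config")) {
    stop("config must be a neural_sim_config", call. = FALSE)
  }
  subjects <- sprintf("s%02d", seq_len(config$n_subjects))
  videos <- sprintf("v%02d", seq_len(config$n_videos))
  regions <- config$region_labels
  cuts <- config$rating_rule$cuts
  thr <- config$rating_rule$high_threshold

  # Latent engagement and rating per subject x video
  ratings <- expand.grid(subject = subjects, video = videos,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ratings <- ratings[order(ratings$subject, ratings$video), , drop = FALSE]
  engagement <- vapply(seq_len(nrow(ratings)), function(i) {
    with_seed(derive_seed(config$seed, "engage", ratings$subject[i],
                          ratings$video[i]),
              runif(1))
  }, numeric(1))
  ratings$rating <- findInterval(engagement, cuts) + 1L
  rownames(ratings) <- NULL

  attributes <- data.frame(
    subject = subjects,
    age = vapply(subjects, function(s) {
      with_seed(derive_seed(config$seed, "age", s),
                sample(18:22, 1L, prob = c(0.45, 0.30, 0.15, 0.07, 0.03)))
    }, numeric(1)),
    gender = vapply(subjects, function(s) {
      with_seed(derive_seed(config$seed, "gender", s),
                sample(c("F", "M"), 1L))
    }, character(1)),
    country = vapply(subjects, function(s) {
      with_seed(derive_seed(config$seed, "country", s),
                sample(c("USA", "China", "India", "Korea", "Mexico"), 1L,
                       prob = c(0.80, 0.08, 0.05, 0.04, 0.03)))
    }, character(1)),
    stringsAsFactors = FALSE, row.names = NULL)

  high <- setNames(ratings$rating >= thr,
                   paste(ratings$subject, ratings$video, sep = "\x1f"))
  dropped <- if (!is.null(config$drop_cells)) {
    paste(config$drop_cells$subject, config$drop_cells$video, sep = "\x1f")
  } else {
    character()
  }

  nchunk <- config$n_videos * length(regions)
  chunks <- vector("list", nchunk)
  lab_subject <- vector("list", nchunk)
  lab_video <- vector("list", nchunk)
  lab_region <- vector("list", nchunk)
  lab_time <- vector("list", nchunk)
  ci <- 0L
  for (vi in seq_along(videos)) {
    v <- videos[vi]
    tp <- config$timepoints_per_video[vi]
    present <- subjects[!(paste(subjects, v, sep = "\x1f") %in% dropped)]
    for (r in regions) {
      s <- with_seed(derive_seed(config$seed, "signal", v, r),
                     latent_signal(tp, config$smooth_window))
      in_signal <- r %in% config$signal_regions
      vals <- lapply(present, function(subj) {
        lambda <- if (in_signal && high[[paste(subj, v, sep = "\x1f")]]) {
          config$coupling_high
        } else {
          config$coupling_low
        }
        noise <- with_seed(derive_seed(config$seed, "noise", subj, v, r),
                           rnorm(tp, sd = config$noise_sd))
        lambda * s + noise
      })
      ci <- ci + 1L
      chunks[[ci]] <- unlist(vals, use.names = FALSE)
      lab_subject[[ci]] <- rep(present, each = tp)
      lab_video[[ci]] <- rep.int(v, tp * length(present))
      lab_region[[ci]] <- rep.int(r, tp * length(present))
      lab_time[[ci]] <- rep.int(seq_len(tp), length(present))
    }
  }
  panel <- data.frame(
    subject = unlist(lab_subject, use.names = FALSE),
    video = unlist(lab_video, use.names = FALSE),
    region = unlist(lab_region, use.names = FALSE),
    timepoint = unlist(lab_time, use.names = FALSE),
    value = unlist(chunks, use.names = FALSE),
    stringsAsFactors = FALSE)
  # valid by construction; tag without re-running the structural checks
  class(panel) <- unique(c("ts_panel", class(panel)))
  list(panel = panel, ratings = ratings, attributes = attributes)
}

#' Validate and tag a long-format time-series panel
#'
#' Checks the structural invariants of a panel: required columns, finite
#' values, and equal series lengths across all subjects holding the same
#' video (a subject may lack a video entirely).
#'
#' @param x data.frame with columns `subject`, `video`, `region`,
#'   `timepoint`, `value`.
#' @return `x` with class `ts_panel` prepended.
#' @export
as_ts_panel <- function(x) {
  needed <- c("subject", "video", "region", "timepoint", "value")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    stop("panel is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(x$value) || !all(is.finite(x$value))) {
    stop("panel values must be finite and non-missing", call. = FALSE)
  }
  len <- aggregate(timepoint ~ subject + video + region, data = x,
                   FUN = length)
  bad <- unlist(lapply(split(len$timepoint, len$video),
                       function(l) length(unique(l)) > 1L))
  if (any(bad)) {
    stop("unequal series lengths within video(s): ",
         paste(names(bad)[bad], collapse = ", "), call. = FALSE)
  }
  class(x) <- unique(c("ts_panel", class(x)))
  x
}

#' @export
print.ts_panel <- function(x, ...) {
  cat(sprintf(
    "ts_panel: %d subjects, %d videos, %d regions, %d rows\n",
    length(unique(x$subject)), length(unique(x$video)),
    length(unique(x$region)), nrow(x)))
  print(head(as.data.frame(x)), ...)
  invisible(x)
}
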