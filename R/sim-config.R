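#' Configuration for the synthetic neural panel generator
#'
#' Defines the geometry and generative parameters of a simulated naturalistic
#' viewing experiment: subjects watch a set of videos while a regional time
#' series is recorded per (subject, video, region). Each (video, region) has a
#' shared latent stimulus signal; a subject's series couples to it with
#' strength `coupling_high` when the subject is highly engaged by the video
#' (their sharing rating reaches `rating_rule$high_threshold`) *and* the
#' region belongs to `signal_regions`, and with `coupling_low` otherwise.
#' This makes the headline contrast — larger ISC for \{high, high\} sharing
#' dyads than \{low, low\} dyads — true by construction in the signal regions
#' and absent elsewhere.
#'
#' The population ISC between two subjects with couplings `l1`, `l2` and
#' noise standard deviation `s` is `l1*l2 / sqrt((l1^2 + s^2) * (l2^2 + s^2))`
#' (the latent signal has unit variance).
#'
#' Two presets are provided. `"test"` is a downsized geometry (20 subjects,
#' 4 videos, 10 regions of which 3 carry signal, 150 timepoints) used for fast
#' simulation studies; `"paper"` mirrors the emulated study's published
#' geometry (66 subjects, 14 videos of 114-918 timepoints at a 0.8 s sampling
#' interval, 214 regions).
#'
#' @param n_subjects,n_videos,n_regions Panel geometry.
#' @param timepoints_per_video Integer vector of length `n_videos` (recycled
#'   from length 1); every entry must be at least 3.
#' @param signal_regions Character vector of region labels carrying the
#'   engagement-coupled signal. Defaults to the first 3 regions (or fewer).
#' @param coupling_high,coupling_low Coupling strengths to the latent signal;
#'   `coupling_high >= coupling_low >= 0`.
#' @param noise_sd Standard deviation of the subject-specific noise (> 0).
#' @param rating_rule List with `cuts` (4 increasing cut-points in (0,1)
#'   mapping latent engagement quantiles to the 1-5 rating) and
#'   `high_threshold` (rating at or above which a subject counts as highly
#'   engaged; default 3, the low/high binarization boundary).
#' @param smooth_window Moving-average window (timepoints) applied to the
#'   latent signal to mimic the autocorrelation of slow hemodynamic
#'   responses; 1 disables smoothing.
#' @param region_labels Optional explicit region labels (overrides
#'   `n_regions`).
#' @param drop_cells Optional data.frame (`subject`, `video`) of
#'   subject-by-video cells to drop, emulating partial data.
#' @param seed Integer seed; all randomness derives from it.
#' @param preset `"test"` or `"paper"` baseline geometry, individually
#'   overridable by the other arguments.
#' @return Object of class `neural_sim_config`.
#' @seealso [simulate_neural_panel()]
#' @export
neural_sim_config <- function(preset = c("test", "paper"),
                              n_subjects = NULL,
                              n_videos = NULL,
                              n_regions = NULL,
                              timepoints_per_video = NULL,
                              signal_regions = NULL,
                              coupling_high = 1.0,
                              coupling_low = 0.3,
                              noise_sd = 1.0,
                              rating_rule = NULL,
                              smooth_window = 5L,
                              region_labels = NULL,
                              drop_cells = NULL,
                              seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    n_subjects <- n_subjects %||% 66L
    n_videos <- n_videos %||% 14L
    region_labels <- region_labels %||% region_registry()
    # 14 video durations spanning 91-734 s sampled every 0.8 s
    timepoints_per_video <- timepoints_per_video %||%
      as.integer(round(seq(91, 734, length.out = 14) / 0.8))
  } else {
    n_subjects <- n_subjects %||% 20L
    n_videos <- n_videos %||% 4L
    n_regions <- n_regions %||% 10L
    timepoints_per_video <- timepoints_per_video %||% 150L
  }
  n_subjects <- check_count(n_subjects, "n_subjects", min = 2L)
  n_videos <- check_count(n_videos, "n_videos", min = 1L)
  if (is.null(region_labels)) {
    n_regions <- check_count(n_regions, "n_regions", min = 1L)
    region_labels <- sprintf("r%03d", seq_len(n_regions))
  }
  region_labels <- as.character(region_labels)
  if (anyDuplicated(region_labels)) {
    stop_config("region_labels", "labels must be unique")
  }
  timepoints_per_video <- rep_len(as.integer(timepoints_per_video), n_videos)
  if (any(is.na(timepoints_per_video)) || any(timepoints_per_video < 3L)) {
    stop_config("timepoints_per_video", "every video needs >= 3 timepoints")
  }
  signal_regions <- signal_regions %||%
    region_labels[seq_len(min(3L, length(region_labels)))]
  if (!all(signal_regions %in% region_labels)) {
    stop_config("signal_regions", "must be a subset of the region labels")
  }
  coupling_high <- check_positive(coupling_high, "coupling_high",
                                  strict = FALSE)
  coupling_low <- check_positive(coupling_low, "coupling_low", strict = FALSE)
  if (coupling_high < coupling_low) {
    stop_config("coupling_high", "must satisfy coupling_high >= coupling_low")
  }
  noise_sd <- check_positive(noise_sd, "noise_sd")
  rating_rule <- rating_rule %||%
    list(cuts = c(0.35, 0.65, 0.85, 0.95), high_threshold = 3L)
  if (!is.list(rating_rule) || length(rating_rule$cuts) != 4L ||
      is.unsorted(rating_rule$cuts, strictly = TRUE) ||
      any(rating_rule$cuts <= 0) || any(rating_rule$cuts >= 1)) {
    stop_config("rating_rule", "cuts must be 4 increasing values in (0, 1)")
  }
  rating_rule$high_threshold <-
    check_count(rating_rule$high_threshold %||% 3L,
                "rating_rule$high_threshold", min = 1L)
  smooth_window <- check_count(smooth_window, "smooth_window", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  if (!is.null(drop_cells) &&
      !all(c("subject", "video") %in% names(drop_cells))) {
    stop_config("drop_cells", "needs columns 'subject' and 'video'")
  }
  structure(
    list(n_subjects = n_subjects, n_videos = n_videos,
         region_labels = region_labels,
         n_regions = length(region_labels),
         timepoints_per_video = timepoints_per_video,
         signal_regions = signal_regions,
         coupling_high = coupling_high, coupling_low = coupling_low,
         noise_sd = noise_sd, rating_rule = rating_rule,
         smooth_window = smooth_window, drop_cells = drop_cells,
         seed = seed, preset = preset),
    class = "neural_sim_config")
}

#' @export
print.neural_sim_config <- function(x, ...) {
  cat(sprintf(
    "neural_sim_config ('%s'): %d subjects x %d videos x %d regions\n",
    x$preset, x$n_subjects, x$n_videos, x$n_regions))
  cat(sprintf("  timepoints: %s; signal regions: %d; couplings %.2f/%.2f; noise sd %.2f\n",
              paste(range(x$timepoints_per_video), collapse = "-"),
              length(x$signal_regions), x$coupling_high, x$coupling_low,
              x$noise_sd))
  invisible(x)
}

#' Configuration for the behavioral table generators
#'
#' One config type drives both behavioral simulators.
#' [simulate_study2_table()] uses the crossed-ratings fields: each participant
#' rates items, and sharing likelihood follows a mixed model with participant
#' and item random intercepts plus a slope on standardized perceived
#' similarity. [simulate_study3_table()] uses the experimental fields: a
#' balanced four-condition between-subjects design with condition-specific
#' mean sharing.
#'
#' @param n_participants Number of participants (Study-2 mode).
#' @param n_items Number of items in the pool (Study-2 mode).
#' @param items_per_participant Items rated per participant; `NULL` means all
#'   items (fully crossed).
#' @param grand_mean Intercept of the sharing outcome.
#' @param slope_similarity Effect of a 1-SD increase in perceived similarity
#'   on sharing, in outcome units.
#' @param sd_participant_intercept,sd_item_intercept,sd_residual Standard
#'   deviations of the participant intercepts, item intercepts, and residual
#'   (all >= 0; residual must be > 0).
#' @param interest_loading,valence_loading Loadings of interest/valence on the
#'   standardized similarity (plus unit noise), used for the adjusted model.
#' @param discretize Clip and round sharing to the 1-5 integer scale.
#' @param condition_means Named numeric: mean sharing for conditions
#'   `similar`, `dissimilar`, `unclear`, `mixed` (Study-3 mode).
#' @param n_per_condition Participants per condition (balanced allocation).
#' @param covariate_effect How strongly interest and baseline sharing track
#'   the participant's sharing propensity (Study-3 control covariates).
#' @param seed Integer seed.
#' @return Object of class `behavioral_sim_config`.
#' @export
behavioral_sim_config <- function(n_participants = 100L,
                                  n_items = 29L,
                                  items_per_participant = 5L,
                                  grand_mean = 2.5,
                                  slope_similarity = 0.4,
                                  sd_participant_intercept = 0.6,
                                  sd_item_intercept = 0.3,
                                  sd_residual = 0.8,
                                  interest_loading = 0.5,
                                  valence_loading = 0.3,
                                  discretize = FALSE,
                                  condition_means = c(similar = 3.0,
                                                      dissimilar = 2.4,
                                                      unclear = 2.4,
                                                      mixed = 2.8),
                                  n_per_condition = 75L,
                                  covariate_effect = 0.3,
                                  seed = 1L) {
  n_participants <- check_count(n_participants, "n_participants", min = 2L)
  n_items <- check_count(n_items, "n_items", min = 2L)
  if (!is.null(items_per_participant)) {
    items_per_participant <- check_count(items_per_participant,
                                         "items_per_participant", min = 1L)
    if (items_per_participant > n_items) {
      stop_config("items_per_participant", "cannot exceed n_items")
    }
  }
  for (f in c("sd_participant_intercept", "sd_item_intercept")) {
    check_positive(get(f), f, strict = FALSE)
  }
  sd_residual <- check_positive(sd_residual, "sd_residual")
  allowed <- c("similar", "dissimilar", "unclear", "mixed")
  if (is.null(names(condition_means)) ||
      !all(names(condition_means) %in% allowed)) {
    stop_config("condition_means",
                "names must be among similar, dissimilar, unclear, mixed")
  }
  n_per_condition <- check_count(n_per_condition, "n_per_condition", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(n_participants = n_participants, n_items = n_items,
         items_per_participant = items_per_participant,
         grand_mean = grand_mean, slope_similarity = slope_similarity,
         sd_participant_intercept = sd_participant_intercept,
         sd_item_intercept = sd_item_intercept, sd_residual = sd_residual,
         interest_loading = interest_loading,
         valence_loading = valence_loading, discretize = discretize,
         condition_means = condition_means,
         n_per_condition = n_per_condition,
         covariate_effect = covariate_effect, seed = seed),
    class = "behavioral_sim_config")
}

#' Read a generator configuration from a structured config file
#'
#' Accepts a YAML (or JSON) file whose keys are exactly the
#' [neural_sim_config()] argument names (`n_subjects`, `n_videos`,
#' `n_regions`, `timepoints_per_video`, `signal_regions`, `coupling_high`,
#' `coupling_low`, `noise_sd`, `rating_rule`, `smooth_window`, `drop_cells`,
#' `seed`, `preset`).
#'
#' @param path Config file path (`.yaml`/`.yml` or `.json`).
#' @return A validated `neural_sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  }
  known <- names(formals(neural_sim_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$drop_cells)) {
    cfg$drop_cells <- as.data.frame(cfg$drop_cells,
                                    stringsAsFactors = FALSE)
  }
  do.call(neural_sim_config, cfg)
}
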