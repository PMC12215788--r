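#' Binarize a 1-5 sharing-likelihood rating
#'
#' Ratings of 1 and 2 count as low sharing likelihood; ratings of 3 and above
#' count as high. The threshold is configurable but defaults to this rule.
#'
#' @param rating Integer rating(s) in 1..5.
#' @param high_threshold Smallest rating classified as high (default 3).
#' @return Character vector of `"low"` / `"high"`.
#' @export
binarize_rating <- function(rating, high_threshold = 3L) {
  if (any(is.na(rating)) || any(!rating %in% 1:5)) {
    stop("ratings must be integers in 1..5", call. = FALSE)
  }
  ifelse(rating >= high_threshold, "high", "low")
}

#' Dyad-level sharing category from two binarized ratings
#'
#' Symmetric mapping: both high -> `"HH"`, both low -> `"LL"`, one of each ->
#' `"LH"` regardless of member order.
#'
#' @param a,b Binarized levels (`"low"` / `"high"`), vectorized.
#' @return Character vector in `{"LL", "LH", "HH"}`.
#' @export
dyad_sharing_category <- function(a, b) {
  if (!all(c(a, b) %in% c("low", "high"))) {
    stop("levels must be 'low' or 'high'", call. = FALSE)
  }
  n_high <- (a == "high") + (b == "high")
  c("LL", "LH", "HH")[n_high + 1L]
}

#' Cohort-relative age similarity for dyads
#'
#' `1 - |age_a - age_b| / max_dyad |age_a - age_b|`, where the maximum is
#' taken over the supplied dyads (the retained analysis cohort). The value is
#' 1 exactly when the dyad attains zero age difference, and 0 for the
#' dyad(s) attaining the cohort maximum. If all ages are identical the
#' maximum is 0; every dyad then gets similarity 1, with a warning.
#'
#' @param ages Named numeric vector of ages (names = subject labels).
#' @param dyads data.frame with columns `subject_a`, `subject_b`.
#' @return Numeric vector in \[0, 1\], one value per dyad row.
#' @export
age_similarity <- function(ages, dyads) {
  if (is.null(names(ages)) || anyNA(ages) || any(ages <= 0)) {
    stop("ages must be a named vector of positive values", call. = FALSE)
  }
  missing <- setdiff(unique(c(dyads$subject_a, dyads$subject_b)),
                     names(ages))
  if (length(missing)) {
    stop("no age for subject(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  diffs <- abs(ages[dyads$subject_a] - ages[dyads$subject_b])
  max_diff <- max(diffs)
  if (max_diff == 0) {
    warning("all dyads have identical ages; age similarity set to 1")
    return(rep(1, nrow(dyads)))
  }
  as.numeric(1 - diffs / max_diff)
}

#' Exact-match indicator for a categorical attribute
#'
#' 1 if the two labels are identical, 0 otherwise. Matching is strict string
#' equality; labels differing only in case trigger a warning since that
#' usually signals unnormalized input.
#'
#' @param attr_a,attr_b Labels, vectorized.
#' @return Integer vector of 0/1.
#' @export
match_indicator <- function(attr_a, attr_b) {
  if (anyNA(attr_a) || anyNA(attr_b) || any(!nzchar(attr_a)) ||
      any(!nzchar(attr_b))) {
    stop("attribute labels must be present and non-empty", call. = FALSE)
  }
  exact <- attr_a == attr_b
  case_only <- !exact & (tolower(attr_a) == tolower(attr_b))
  if (any(case_only)) {
    warning("labels differ only in case (e.g. '", attr_a[case_only][1L],
            "' vs '", attr_b[case_only][1L],
            "'); matching is case-sensitive")
  }
  as.integer(exact)
}

#' Build the dyad-by-video design table
#'
#' Transforms participant-level ratings and demographics into dyad-level
#' predictors: the sharing category (LL / LH / HH) from binarized ratings,
#' cohort-relative age similarity, and gender / country match indicators.
#' A row is emitted for each (dyad, video) in which both members rated the
#' video; the table joins to ISC records on (`subject_a`, `subject_b`,
#' `video`).
#'
#' @param ratings data.frame with columns `subject`, `video`, `rating`.
#' @param attrs data.frame with columns `subject`, `age`, `gender`,
#'   `country`; must cover every rated subject.
#' @param dyads Optional data.frame (`subject_a`, `subject_b`) restricting
#'   the dyads; defaults to all pairs of rated subjects.
#' @param high_threshold Binarization threshold (see [binarize_rating()]).
#' @return data.frame of class `dyad_design` with columns `subject_a`,
#'   `subject_b`, `video`, `sharing_category`, `age_similarity`,
#'   `gender_match`, `country_match`.
#' @export
build_dyad_design <- function(ratings, attrs, dyads = NULL,
                              high_threshold = 3L) {
  needed <- c("subject", "video", "rating")
  if (!all(needed %in% names(ratings))) {
    stop("ratings need columns subject, video, rating", call. = FALSE)
  }
  empty <- data.frame(subject_a = character(), subject_b = character(),
                      video = character(), sharing_category = character(),
                      age_similarity = numeric(), gender_match = integer(),
                      country_match = integer(), stringsAsFactors = FALSE)
  class(empty) <- c("dyad_design", class(empty))
  if (nrow(ratings) == 0L) return(empty)
  subjects <- sort(unique(ratings$subject))
  dangling <- setdiff(subjects, attrs$subject)
  if (length(dangling)) {
    stop("subject(s) missing from attributes: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  dyads <- dyads %||% all_dyads(subjects)
  if (nrow(dyads) == 0L) return(empty)

  level <- binarize_rating(ratings$rating, high_threshold)
  key <- function(s, v) paste(s, v, sep = "\x1f")
  lev <- setNames(level, key(ratings$subject, ratings$video))
  videos <- sort(unique(ratings$video))

  grid <- merge(dyads, data.frame(video = videos, stringsAsFactors = FALSE))
  la <- lev[key(grid$subject_a, grid$video)]
  lb <- lev[key(grid$subject_b, grid$video)]
  keep <- !is.na(la) & !is.na(lb)
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid) == 0L) return(empty)
  grid$sharing_category <- dyad_sharing_category(la[keep], lb[keep])

  ages <- setNames(attrs$age, attrs$subject)
  gender <- setNames(attrs$gender, attrs$subject)
  country <- setNames(attrs$country, attrs$subject)
  retained <- unique(grid[c("subject_a", "subject_b")])
  sim <- age_similarity(ages, retained)
  sim_key <- setNames(sim, key(retained$subject_a, retained$subject_b))
  grid$age_similarity <- as.numeric(
    sim_key[key(grid$subject_a, grid$subject_b)])
  grid$gender_match <- match_indicator(gender[grid$subject_a],
                                       gender[grid$subject_b])
  grid$country_match <- match_indicator(country[grid$subject_a],
                                        country[grid$subject_b])
  grid <- grid[order(grid$subject_a, grid$subject_b, grid$video), ,
               drop = FALSE]
  rownames(grid) <- NULL
  class(grid) <- c("dyad_design", class(grid))
  grid
}
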