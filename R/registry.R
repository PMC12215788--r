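#' Region registry: cortical parcels plus subcortical regions
#'
#' Whole-brain coverage is represented as an opaque label registry composed of
#' a cortical parcellation scheme and a set of subcortical regions. The
#' default composition (200 cortical parcels + 14 subcortical regions = 214
#' labels) matches the whole-brain scheme used throughout the neural analyses;
#' region geometry is out of scope, so labels are the only currency.
#'
#' @param n_cortical Number of cortical parcel labels.
#' @param n_subcortical Number of subcortical region labels.
#' @return Character vector of unique region labels, cortical labels first.
#' @examples
#' length(region_registry()) # 214
#' @export
region_registry <- function(n_cortical = 200L, n_subcortical = 14L) {
  n_cortical <- check_count(n_cortical, "n_cortical", min = 0L)
  n_subcortical <- check_count(n_subcortical, "n_subcortical", min = 0L)
  c(sprintf("ctx_%03d", seq_len(n_cortical)),
    sprintf("sub_%02d", seq_len(n_subcortical)))
}

#' Enumerate all unordered dyads of a subject roster
#'
#' A dyad is an unordered pair of distinct subjects; with `n` subjects there
#' are `choose(n, 2)` dyads (2145 for the 66-subject roster of the emulated
#' neuroimaging sample). Members are ordered lexicographically within each
#' dyad so that a dyad has a single canonical representation.
#'
#' @param subjects Character vector of unique subject labels.
#' @return data.frame with columns `subject_a`, `subject_b`
#'   (`subject_a < subject_b`).
#' @examples
#' nrow(all_dyads(sprintf("s%02d", 1:66))) # 2145
#' @export
all_dyads <- function(subjects) {
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects)) {
    stop("subject labels must be unique", call. = FALSE)
  }
  if (length(subjects) < 2L) {
    return(data.frame(subject_a = character(), subject_b = character(),
                      stringsAsFactors = FALSE))
  }
  s <- sort(subjects)
  idx <- utils::combn(length(s), 2L)
  data.frame(subject_a = s[idx[1L, ]], subject_b = s[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Expected number of dyadic ISC records for a simulated design
#'
#' For each video `v` with `n_v` subjects holding it, every region contributes
#' `choose(n_v, 2)` records, so the total is `sum_v choose(n_v, 2) * R`.
#'
#' @param n_subjects_per_video Integer vector, subjects holding each video.
#' @param n_regions Number of regions.
#' @return Expected record count.
#' @export
n_isc_records <- function(n_subjects_per_video, n_regions) {
  sum(choose(n_subjects_per_video, 2L)) * n_regions
}
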