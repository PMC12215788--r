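#' Sample Pearson correlation of two series
#'
#' @param x,y Numeric series of equal length (>= 3), each with nonzero
#'   variance.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) {
    stop("series lengths differ (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  }
  if (length(x) < 3L) stop("series must have length >= 3", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("series contain missing values",
                                 call. = FALSE)
  if (var(x) == 0 || var(y) == 0) {
    stop("undefined correlation: zero-variance input series", call. = FALSE)
  }
  as.numeric(cor(x, y))
}

#' Fisher z-transform of a correlation
#'
#' The variance-stabilizing map `atanh(r)`; odd and strictly increasing.
#' Values with `|r| >= 1` are refused rather than mapped to infinity: clamp
#' explicitly (e.g. `clamp_correlation()`) if noise-free inputs can produce
#' perfect correlations.
#'
#' @param r Correlation(s) with `|r| < 1`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1)) {
    stop("fisher_z requires |r| < 1; clamp perfect correlations explicitly",
         call. = FALSE)
  }
  atanh(r)
}

#' Clamp correlations away from +/-1
#'
#' @param r Correlation(s).
#' @param eps Margin; values are clamped to `[-(1 - eps), 1 - eps]`.
#' @return Clamped correlations.
#' @export
clamp_correlation <- function(r, eps = 1e-7) {
  pmin(1 - eps, pmax(-(1 - eps), r))
}

#' Compute dyadic inter-subject correlations for a panel
#'
#' For every unordered pair of subjects that both hold a video, computes the
#' Pearson correlation of their regional time series — one record per
#' (dyad, video, region) — then Fisher z-transforms the correlations and
#' standardizes the transformed values within each region (see
#' [normalize_within_region()]).
#'
#' @param panel A `ts_panel` (see [as_ts_panel()]).
#' @param clamp If `TRUE`, correlations of magnitude 1 (possible only on
#'   noise-free input) are clamped to `1 - 1e-7` before the z-transform;
#'   if `FALSE` (default) they raise an error.
#' @param normalize Standardize z within region (default `TRUE`; requires
#'   >= 2 records per region).
#' @return data.frame of class `isc_records` with columns `subject_a`,
#'   `subject_b` (lexicographically ordered), `video`, `region`, `r`, `z`
#'   and (if `normalize`) `z_norm`.
#' @export
compute_dyadic_isc <- function(panel, clamp = FALSE, normalize = TRUE) {
  if (!inherits(panel, "ts_panel")) panel <- as_ts_panel(panel)
  videos <- sort(unique(panel$video))
  out <- list()
  for (v in videos) {
    pv <- panel[panel$video == v, , drop = FALSE]
    subjects <- sort(unique(pv$subject))
    regions <- sort(unique(pv$region))
    # every subject on a shared video must hold every region present
    have <- table(pv$subject, pv$region) > 0L
    if (!all(have)) {
      miss <- which(!have, arr.ind = TRUE)
      stop(sprintf(
        "video %s: subject %s lacks region %s held by other subjects",
        v, rownames(have)[miss[1L, 1L]], colnames(have)[miss[1L, 2L]]),
        call. = FALSE)
    }
    if (length(subjects) < 2L) next
    pv <- pv[order(pv$region, pv$subject, pv$timepoint), , drop = FALSE]
    tp <- nrow(pv) / (length(subjects) * length(regions))
    pairs <- utils::combn(length(subjects), 2L)
    for (ri in seq_along(regions)) {
      m <- matrix(pv$value[((ri - 1L) * tp * length(subjects) + 1L):
                             (ri * tp * length(subjects))],
                  nrow = tp, ncol = length(subjects))
      sds <- apply(m, 2L, sd)
      if (any(sds == 0)) {
        stop(sprintf(
          "undefined correlation: zero-variance series (video %s, region %s, subject %s)",
          v, regions[ri], subjects[which(sds == 0)[1L]]), call. = FALSE)
      }
      cm <- cor(m)
      r <- cm[cbind(pairs[1L, ], pairs[2L, ])]
      out[[length(out) + 1L]] <- data.frame(
        subject_a = subjects[pairs[1L, ]],
        subject_b = subjects[pairs[2L, ]],
        video = v, region = regions[ri], r = r,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, out)
  if (is.null(records)) {
    stop("panel contains no video with two or more subjects", call. = FALSE)
  }
  if (clamp) records$r <- clamp_correlation(records$r)
  records$z <- fisher_z(records$r)
  rownames(records) <- NULL
  class(records) <- c("isc_records", class(records))
  if (normalize) records <- normalize_within_region(records)
  records
}

#' Standardize Fisher-z ISC values within region
#'
#' Adds `z_norm = (z - mean_region) / sd_region` per region, using the sample
#' standard deviation (denominator n - 1), pooling records across dyads and
#' videos of the region.
#'
#' @param records data.frame with columns `region` and `z`.
#' @return `records` with a `z_norm` column.
#' @export
normalize_within_region <- function(records) {
  if (!all(c("region", "z") %in% names(records))) {
    stop("records need columns 'region' and 'z'", call. = FALSE)
  }
  counts <- table(records$region)
  if (any(counts < 2L)) {
    stop("region(s) with fewer than 2 records: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  mu <- tapply(records$z, records$region, mean)
  sig <- tapply(records$z, records$region, sd)
  if (any(sig == 0)) {
    stop("region(s) with zero spread in z: ",
         paste(names(sig)[sig == 0], collapse = ", "), call. = FALSE)
  }
  records$z_norm <- (records$z - as.numeric(mu[records$region])) /
    as.numeric(sig[records$region])
  records
}
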