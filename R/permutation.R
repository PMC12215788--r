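#' Permutation test of the sharing-category contrast
#'
#' Nonparametric check of the category contrast: participant-level binarized
#' sharing labels are permuted *within each video* (participants, not dyadic
#' rows, are the exchangeable units; permuting rows would break the dyadic
#' dependence structure), dyad categories are rebuilt from the permuted
#' labels, and the contrast statistic is recomputed per permutation. The
#' p-value is `(1 + #(|stat_perm| >= |stat_obs|)) / (1 + n_permutations)`
#' (two-tailed, add-one).
#'
#' The default statistic is the difference of mean normalized ISC between
#' the two contrasted categories — fast, and any valid statistic yields an
#' exact permutation test. `statistic = "lmm"` instead refits the full
#' doubled-data crossed model per permutation and uses the contrast
#' t-statistic (orders of magnitude slower).
#'
#' @param isc `isc_records` with a `z_norm` column.
#' @param ratings data.frame (`subject`, `video`, `rating`).
#' @param attrs Participant attributes; required for `statistic = "lmm"`.
#' @param n_permutations Number of permutations (>= 100 recommended).
#' @param seed Integer seed for the permutation stream.
#' @param contrast Pair of categories, default `c("HH", "LL")`.
#' @param statistic `"meandiff"` or `"lmm"`.
#' @param regions Regions to test; default all regions in `isc`.
#' @param high_threshold Binarization threshold.
#' @param spec [model_spec()] for the `"lmm"` statistic.
#' @return data.frame: `region`, `stat_obs`, `p_perm`, `n_permutations`.
#' @export
permutation_null <- function(isc, ratings, attrs = NULL,
                             n_permutations = 1000L, seed = 1L,
                             contrast = c("HH", "LL"),
                             statistic = c("meandiff", "lmm"),
                             regions = NULL, high_threshold = 3L,
                             spec = model_spec()) {
  statistic <- match.arg(statistic)
  n_permutations <- check_count(n_permutations, "n_permutations", min = 1L)
  if (n_permutations < 100L) {
    warning("fewer than 100 permutations gives a coarse p-value resolution")
  }
  seed <- check_count(seed, "seed", min = 0L)
  level <- binarize_rating(ratings$rating, high_threshold)
  if (length(unique(level)) < 2L) {
    stop("degenerate label distribution: all binarized ratings are '",
         level[1L], "'", call. = FALSE)
  }
  regions <- regions %||% sort(unique(isc$region))
  if (statistic == "lmm" && is.null(attrs)) {
    stop("attrs required for the 'lmm' statistic", call. = FALSE)
  }

  key <- function(s, v) paste(s, v, sep = "\x1f")
  lab0 <- setNames(level, key(ratings$subject, ratings$video))
  by_video <- split(seq_len(nrow(ratings)), ratings$video)
  row_order <- unlist(by_video, use.names = FALSE)
  row_keys <- key(ratings$subject[row_order], ratings$video[row_order])

  stat_fun <- function(labels, region_sub) {
    la <- labels[key(region_sub$subject_a, region_sub$video)]
    lb <- labels[key(region_sub$subject_b, region_sub$video)]
    keep <- !is.na(la) & !is.na(lb)
    cat <- dyad_sharing_category(la[keep], lb[keep])
    z <- region_sub$z_norm[keep]
    m <- tapply(z, factor(cat, levels = c("LL", "LH", "HH")), mean)
    as.numeric(m[contrast[1L]] - m[contrast[2L]])
  }
  lmm_stat <- function(perm_ratings, region_sub) {
    design <- build_dyad_design(perm_ratings, attrs,
                                high_threshold = high_threshold)
    joined <- merge(design, region_sub,
                    by = c("subject_a", "subject_b", "video"))
    fit <- fit_crossed_lmm(double_dyadic_data(joined), spec)
    if (!fit$converged) return(NA_real_)
    planned_contrast(fit, contrast)$t
  }

  out <- lapply(regions, function(rg) {
    sub <- isc[isc$region == rg,
               c("subject_a", "subject_b", "video", "z_norm")]
    obs <- if (statistic == "meandiff") {
      stat_fun(lab0, sub)
    } else {
      lmm_stat(ratings, sub)
    }
    if (is.na(obs)) {
      stop("region ", rg, ": observed statistic undefined (empty category ",
           "or non-converged fit)", call. = FALSE)
    }
    perm <- with_seed(derive_seed(seed, "perm", rg), {
      vapply(seq_len(n_permutations), function(b) {
        idx <- unlist(lapply(by_video,
                             function(ix) ix[sample.int(length(ix))]),
                      use.names = FALSE)
        if (statistic == "meandiff") {
          labp <- setNames(level[idx], row_keys)
          stat_fun(labp, sub)
        } else {
          pr <- ratings
          pr$rating[row_order] <- ratings$rating[idx]
          lmm_stat(pr, sub)
        }
      }, numeric(1))
    })
    perm <- perm[!is.na(perm)]
    p <- (1 + sum(abs(perm) >= abs(obs))) / (1 + length(perm))
    data.frame(region = rg, stat_obs = obs, p_perm = p,
               n_permutations = length(perm), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
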