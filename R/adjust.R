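#' Holm-Bonferroni step-down adjustment
#'
#' Family-wise error-rate control across a family of tests (here typically
#' across brain regions). Thin, validated wrapper over the standard
#' step-down procedure.
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @return Adjusted p-values, clipped at 1, monotone in the step-down order.
#' @export
holm_bonferroni <- function(p_values) {
  check_pvalues(p_values)
  p.adjust(p_values, method = "holm")
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' False-discovery-rate control across a contrast family (here typically the
#' pairwise condition contrasts of the sharing experiment).
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p_values) {
  check_pvalues(p_values)
  p.adjust(p_values, method = "BH")
}

check_pvalues <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  invisible(p)
}
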