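#' Nominate key harm-reduction target factors
#'
#' The combination rule: a factor is a key target when it is prominent
#' (above-average BC and CC) in the sharing group's network but not in the
#' never-sharing group's network, *and* it is independently associated with
#' needle sharing in the multivariate regression (any non-reference category
#' with adjusted Wald p < `alpha`). In set terms,
#' `key_factors = (above_both_sng \ above_both_nsng) intersect
#' regression_significant`.
#'
#' @param model An `mv_logistic` fit, a data frame of adjusted results with
#'   columns `factor` and `wald_p`, or a character vector of factor names
#'   already judged regression-significant.
#' @param nsng_flags,sng_flags `centrality_flags` for the NSNG and SNG
#'   networks (see [flag_above_average()]); both must be computed on the same
#'   factor universe.
#' @param alpha Significance threshold for the regression criterion.
#' @param prevalence Optional sharing prevalence (fraction) quoted in the
#'   narrative.
#' @return Object of class `key_factor_report`: list with
#'   `regression_significant`, `above_both_nsng`, `above_both_sng`,
#'   `sng_only_prominent`, `key_factors`, and `narrative` (ordered findings).
#' @export
identify_key_factors <- function(model, nsng_flags, sng_flags, alpha = 0.05,
                                 prevalence = NULL) {
  stopifnot(inherits(nsng_flags, "centrality_flags"),
            inherits(sng_flags, "centrality_flags"))
  if (!setequal(nsng_flags$universe, sng_flags$universe)) {
    diff <- c(setdiff(nsng_flags$universe, sng_flags$universe),
              setdiff(sng_flags$universe, nsng_flags$universe))
    stop("flag sets computed on different factor universes; symmetric difference: ",
         paste(diff, collapse = ", "), call. = FALSE)
  }
  reg <- if (is.character(model)) model else significant_factors(model, alpha)
  sng_only <- setdiff(sng_flags$above_both, nsng_flags$above_both)
  key <- intersect(sng_only, reg)
  narrative <- c(
    if (!is.null(prevalence))
      sprintf("Sharing prevalence: %.1f%% of subjects reported needle sharing.",
              100 * prevalence),
    sprintf("Regression: %d factor(s) independently associated with sharing: %s.",
            length(reg), paste(reg, collapse = ", ")),
    sprintf("Network contrast: above-average BC and CC for %d factor(s) in the NSNG and %d in the SNG.",
            length(nsng_flags$above_both), length(sng_flags$above_both)),
    sprintf("Prominent only in the sharing group: %s.",
            if (length(sng_only)) paste(sng_only, collapse = ", ") else "none"),
    sprintf("Key harm-reduction target factor(s): %s.",
            if (length(key)) paste(key, collapse = ", ") else "none"))
  structure(list(regression_significant = reg,
                 above_both_nsng = nsng_flags$above_both,
                 above_both_sng = sng_flags$above_both,
                 sng_only_prominent = sng_only,
                 key_factors = key,
                 narrative = narrative),
            class = "key_factor_report")
}

#' @export
print.key_factor_report <- function(x, ...) {
  cat("Key-factor report\n")
  cat(paste0("  - ", x$narrative, collapse = "\n"), "\n")
  invisible(x)
}
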