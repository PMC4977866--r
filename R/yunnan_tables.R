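#' Published per-category counts for the Yunnan PWID survey
#'
#' The printed summary table of the 2009 Yunnan survey (n = 1 049): per factor
#' category, the total count, the number who shared needles, and the published
#' univariate and multivariate odds ratios with 95% CIs and p-values.
#' These printed counts are the recomputable surface of the study and serve as
#' inputs to the odds-ratio and candidate-selection machinery.
#'
#' @return Data frame with columns `factor`, `category`, `reference` (0/1),
#'   `total`, `shared`, `uni_or`, `uni_lo`, `uni_hi`, `uni_p`, `factor_p`,
#'   `multi_or`, `multi_lo`, `multi_hi`, `multi_p`, `multi_factor_p`.
#' @export
yunnan_table1 <- function() {
  utils::read.csv(system.file("extdata", "yunnan_table1.csv",
                              package = "pwidnet", mustWork = TRUE),
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' Published betweenness/closeness centralities per subgroup
#'
#' Printed normalized betweenness (BC) and closeness (CC) centralities, with
#' ranks, for every factor node in the never-sharing (NSNG) and sharing (SNG)
#' correlation networks. Occupation carries NA for the NSNG: it had no
#' surviving edge there and is not part of that network.
#'
#' @return Data frame with columns `factor`, `bc_nsng`, `bc_rank_nsng`,
#'   `cc_nsng`, `cc_rank_nsng`, `bc_sng`, `bc_rank_sng`, `cc_sng`,
#'   `cc_rank_sng`.
#' @export
yunnan_table3 <- function() {
  utils::read.csv(system.file("extdata", "yunnan_table3.csv",
                              package = "pwidnet", mustWork = TRUE),
                  check.names = FALSE, stringsAsFactors = FALSE)
}

#' Published headline counts of the Yunnan survey
#'
#' Counts reported in the study narrative that are not recoverable from the
#' summary table alone: recruitment flow, the subgroup split, and the number
#' of sharers who shared with a partner known to be HIV-seropositive.
#'
#' @return Named list of integers: `n_recruited`, `n_pwid`, `n_complete`,
#'   `n_sng`, `n_nsng`, `n_hiv_positive`, `n_shared_with_known_hiv_positive`,
#'   and per-subgroup network sizes `nsng_nodes`, `nsng_edges`, `sng_nodes`,
#'   `sng_edges`.
#' @export
yunnan_reported <- function() {
  list(n_recruited = 2048L, n_pwid = 1797L, n_complete = 1049L,
       n_sng = 393L, n_nsng = 656L, n_hiv_positive = 196L,
       n_shared_with_known_hiv_positive = 52L,
       nsng_nodes = 19L, nsng_edges = 38L,
       sng_nodes = 20L, sng_edges = 65L)
}

#' Contingency tables reconstructed from the published counts
#'
#' @param factors Factor names (default: all 20).
#' @return Named list of [contingency_table] objects built via
#'   [contingency_from_counts()].
#' @export
yunnan_contingency_tables <- function(factors = NULL) {
  cb <- yunnan_codebook()
  t1 <- yunnan_table1()
  if (is.null(factors)) factors <- factor_names(cb)
  out <- lapply(factors, function(f) {
    rows <- t1[t1$factor == f, , drop = FALSE]
    spec <- cb$factors[[f]]
    rows <- rows[match(spec$categories, rows$category), , drop = FALSE]
    contingency_from_counts(spec, rows$total, rows$shared)
  })
  names(out) <- factors
  out
}
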