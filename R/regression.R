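Z95 <- 1.959964  # fixed normal quantile for 95% intervals

#' Univariate odds-ratio screening for one factor
#'
#' For each non-reference category k, the odds ratio against the reference is
#' the cross-product ratio (a_k d_ref)/(b_k c_ref) of the 2x2 sub-table, with
#' a Woolf 95% interval exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)) and a
#' Wald p-value from the normal deviate of ln OR / SE. The factor-level
#' omnibus p-value is a likelihood-ratio (G) test of the K-level factor
#' against the intercept-only binomial model, on K - 1 degrees of freedom;
#' for a single categorical predictor this equals the logistic-regression LRT
#' and is computable in closed form from the contingency table.
#'
#' Zero cells make a contrast unestimable: the result row is flagged
#' (`estimable = FALSE`) rather than continuity-corrected.
#'
#' @param table A [contingency_table].
#' @return Data frame of class `or_result`: one row per category with columns
#'   `factor`, `category`, `reference`, `total`, `shared`, `pct_shared`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `wald_p`, `factor_p`, `estimable`.
#'   The reference row carries `odds_ratio = 1` and no CI.
#' @export
univariate_factor_test <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  spec <- attr(table, "factor_spec")
  ref <- which(table$category == spec$reference)
  c_ref <- table$shared[ref]; d_ref <- table$not_shared[ref]
  if (table$total[ref] == 0 || c_ref == 0 || d_ref == 0)
    stop("reference category '", spec$reference,
         "' needs at least one sharer and one non-sharer", call. = FALSE)
  K <- nrow(table)
  res <- data.frame(factor = spec$name, category = table$category,
                    reference = seq_len(K) == ref,
                    total = table$total, shared = table$shared,
                    pct_shared = table$pct_shared,
                    odds_ratio = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, wald_p = NA_real_,
                    factor_p = NA_real_, estimable = TRUE,
                    stringsAsFactors = FALSE)
  res$odds_ratio[ref] <- 1
  for (k in setdiff(seq_len(K), ref)) {
    a <- table$shared[k]; b <- table$not_shared[k]
    if (a == 0 || b == 0) { res$estimable[k] <- FALSE; next }
    or <- (a * d_ref) / (b * c_ref)
    se <- sqrt(1 / a + 1 / b + 1 / c_ref + 1 / d_ref)
    res$odds_ratio[k] <- or
    res$ci_low[k] <- exp(log(or) - Z95 * se)
    res$ci_high[k] <- exp(log(or) + Z95 * se)
    res$wald_p[k] <- 2 * stats::pnorm(-abs(log(or) / se))
  }
  res$factor_p <- lrt_factor_p(table$shared, table$total)
  class(res) <- c("or_result", "data.frame")
  res
}

# Likelihood-ratio (G) test of a K-category binomial split against the pooled
# rate; equals the single-predictor logistic LRT. df = K - 1.
lrt_factor_p <- function(shared, total) {
  keep <- total > 0
  shared <- shared[keep]; total <- total[keep]
  if (length(total) < 2) return(NA_real_)
  O <- cbind(shared, total - shared)
  E <- outer(total, c(sum(shared), sum(total - shared)) / sum(total))
  G <- 2 * sum(ifelse(O > 0, O * log(O / E), 0))
  stats::pchisq(G, df = length(total) - 1, lower.tail = FALSE)
}

#' Run the univariate screen over every factor of a dataset
#'
#' @param data A `survey_dataset`.
#' @return Named list of `or_result` data frames, in codebook order.
#' @export
univariate_screen <- function(data) {
  stopifnot(inherits(data, "survey_dataset"))
  out <- lapply(factor_names(data$codebook), function(f)
    univariate_factor_test(contingency_table(data, f)))
  names(out) <- factor_names(data$codebook)
  out
}

#' Select multivariate candidate factors by omnibus p-value
#'
#' @param results List of `or_result` data frames (one per factor, e.g. from
#'   [univariate_screen()]), or a single combined data frame.
#' @param alpha Significance threshold (strict inequality).
#' @return Character vector of factor names with `factor_p < alpha`, in the
#'   order supplied.
#' @export
select_candidates <- function(results, alpha = 0.05) {
  if (is.data.frame(results)) results <- split(results, results$factor)[unique(results$factor)]
  keep <- vapply(results, function(r) {
    p <- unique(r$factor_p[!is.na(r$factor_p)])
    length(p) == 1 && p < alpha
  }, logical(1))
  unname(vapply(results[keep], function(r) r$factor[1], character(1)))
}

#' Multivariate logistic regression of the sharing outcome
#'
#' Maximum-likelihood logistic fit of the binary outcome on the selected
#' factors with treatment (reference-category) coding; adjusted odds ratios
#' are exp(coefficients) with Wald 95% intervals. All selected factors enter
#' as full indicator sets; there is no stepwise pruning.
#'
#' @param data A `survey_dataset` whose outcome has both classes.
#' @param factors Character vector of factor names to include.
#' @return Object of class `mv_logistic`: list with `included_factors`,
#'   `coefficients` (named log-odds, non-reference categories),
#'   `results` (data frame: `factor`, `category`, `adj_or`, `ci_low`,
#'   `ci_high`, `wald_p`), `converged`, and the underlying `glm` fit.
#' @export
fit_multivariate <- function(data, factors) {
  stopifnot(inherits(data, "survey_dataset"), length(factors) >= 1)
  bad <- setdiff(factors, factor_names(data$codebook))
  if (length(bad)) stop("unknown factor(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  y <- outcome_vector(data)
  if (length(unique(y)) < 2)
    stop("outcome has a single class; cannot fit", call. = FALSE)
  df <- data.frame(.y = y)
  safe <- make.names(factors)  # formula-safe aliases, mapped back afterwards
  for (i in seq_along(factors)) {
    spec <- data$codebook$factors[[factors[i]]]
    v <- base::factor(data$records[[factors[i]]], levels = spec$categories)
    v <- stats::relevel(droplevels(v), ref = spec$reference)
    df[[safe[i]]] <- v
  }
  fit <- suppressWarnings(
    stats::glm(stats::reformulate(safe, response = ".y"), data = df,
               family = stats::binomial()))
  co <- summary(fit)$coefficients
  big <- abs(stats::coef(fit)) > 15
  if (any(big[-1], na.rm = TRUE)) {
    off <- names(which(big[-1]))[1]
    culprit <- factors[vapply(safe, function(s) startsWith(off, s), logical(1))][1]
    stop("perfect separation detected for factor '", culprit, "'", call. = FALSE)
  }
  rows <- do.call(rbind, lapply(seq_along(factors), function(i) {
    spec <- data$codebook$factors[[factors[i]]]
    cats <- setdiff(levels(df[[safe[i]]]), spec$reference)
    terms <- paste0(safe[i], cats)
    est <- co[terms, "Estimate"]; se <- co[terms, "Std. Error"]
    data.frame(factor = factors[i], category = cats,
               coef = est, se = se, adj_or = exp(est),
               ci_low = exp(est - Z95 * se), ci_high = exp(est + Z95 * se),
               wald_p = 2 * stats::pnorm(-abs(est / se)),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  if (!fit$converged)
    warning("logistic fit did not converge; estimates withheld from results")
  structure(list(included_factors = factors,
                 coefficients = stats::setNames(rows$coef,
                                                paste(rows$factor, rows$category, sep = ":")),
                 results = if (fit$converged) rows else rows[0, ],
                 converged = fit$converged, fit = fit),
            class = "mv_logistic")
}

#' @export
print.mv_logistic <- function(x, ...) {
  cat("Multivariate logistic model (", length(x$included_factors),
      " factors, converged: ", x$converged, ")\n", sep = "")
  if (nrow(x$results)) {
    r <- x$results
    cat(sprintf("  %-26s %-20s OR %5.2f (%4.2f-%5.2f) p=%.2g\n",
                r$factor, r$category, r$adj_or, r$ci_low, r$ci_high, r$wald_p),
        sep = "")
  }
  invisible(x)
}

#' Factors with at least one significant adjusted contrast
#'
#' A factor counts as (multivariate-) associated with the outcome when any of
#' its non-reference categories has adjusted Wald p below `alpha`.
#'
#' @param model An `mv_logistic` fit, or a data frame with columns `factor`
#'   and `wald_p` (e.g. printed multivariate results).
#' @param alpha Significance threshold.
#' @return Character vector of factor names.
#' @export
significant_factors <- function(model, alpha = 0.05) {
  res <- if (inherits(model, "mv_logistic")) model$results else model
  stopifnot(all(c("factor", "wald_p") %in% names(res)))
  keep <- !is.na(res$wald_p) & res$wald_p < alpha
  unique(res$factor[keep])
}
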