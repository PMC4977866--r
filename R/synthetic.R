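#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Simulation parameters for a synthetic categorical survey
#'
#' The generator draws each subject's factor categories by thresholding a
#' correlated latent Gaussian vector at the cumulative-marginal quantiles
#' (a Gaussian copula over the ordinal category codes), then draws the binary
#' sharing outcome from a logistic model whose linear predictor is the
#' intercept plus the per-category log-odds increments of the drawn record.
#'
#' @param codebook A [codebook()] describing factors and outcome.
#' @param marginals Named list (one entry per factor) of probability vectors
#'   over that factor's categories, each summing to 1 within 1e-9.
#' @param latent_correlation Symmetric positive-semidefinite matrix with unit
#'   diagonal, one row/column per factor (codebook order). No silent repair is
#'   attempted: a non-PSD matrix is a parameter error.
#' @param outcome_intercept Intercept of the outcome logit.
#' @param outcome_increments Named list (factor -> named numeric vector over
#'   categories) of log-odds increments; reference categories carry 0.
#'   Factors may be omitted (treated as all-zero).
#' @param n_subjects Default number of subjects for [generate_survey()].
#' @param seed Default RNG seed for [generate_survey()].
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(codebook, marginals, latent_correlation,
                       outcome_intercept = 0, outcome_increments = list(),
                       n_subjects = 1000L, seed = 1L) {
  stopifnot(inherits(codebook, "survey_codebook"))
  fn <- factor_names(codebook)
  if (!setequal(names(marginals), fn))
    stop("marginals must be named by the codebook factors", call. = FALSE)
  for (f in fn) {
    p <- marginals[[f]]
    k <- length(codebook$factors[[f]]$categories)
    if (length(p) != k)
      stop("marginal for '", f, "' has length ", length(p), ", expected ", k,
           call. = FALSE)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("marginal for '", f, "' is not a probability vector", call. = FALSE)
  }
  R <- as.matrix(latent_correlation)
  if (nrow(R) != length(fn) || ncol(R) != length(fn))
    stop("latent_correlation must be ", length(fn), " x ", length(fn), call. = FALSE)
  if (max(abs(R - t(R))) > 1e-12 || max(abs(diag(R) - 1)) > 1e-12)
    stop("latent_correlation must be symmetric with unit diagonal", call. = FALSE)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("latent_correlation is not positive semi-definite", call. = FALSE)
  dimnames(R) <- list(fn, fn)
  incr <- lapply(fn, function(f) {
    cats <- codebook$factors[[f]]$categories
    v <- stats::setNames(numeric(length(cats)), cats)
    if (!is.null(outcome_increments[[f]])) {
      g <- outcome_increments[[f]]
      bad <- setdiff(names(g), cats)
      if (length(bad))
        stop("outcome increment for unknown category '", bad[1], "' of '", f,
             "'", call. = FALSE)
      v[names(g)] <- g
    }
    v
  })
  names(incr) <- fn
  structure(list(codebook = codebook, marginals = marginals[fn],
                 latent_correlation = R,
                 outcome_intercept = outcome_intercept,
                 outcome_increments = incr,
                 n_subjects = as.integer(n_subjects), seed = as.integer(seed)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  nz <- names(Filter(function(v) any(v != 0), x$outcome_increments))
  cat(sprintf(paste0("Simulation parameters: %d factors, n_subjects = %d, ",
                     "intercept = %.4f,\n  nonzero outcome effects: %s\n"),
              length(x$marginals), x$n_subjects, x$outcome_intercept,
              if (length(nz)) paste(nz, collapse = ", ") else "none"))
  invisible(x)
}

# Draw n subjects' category indices (1-based, columns = factors) from the
# Gaussian copula defined by R and the marginals.
copula_draw <- function(n, R, marginals) {
  p <- length(marginals)
  # chol() tolerates PSD-with-zero-eigenvalues via pivoting only; nudge the
  # diagonal for exactly singular matrices (e.g. perfectly correlated pairs)
  L <- tryCatch(chol(R), error = function(e) chol(R + diag(1e-10, p)))
  z <- matrix(stats::rnorm(n * p), n, p) %*% L
  u <- stats::pnorm(z)
  codes <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    cuts <- cumsum(marginals[[j]])
    cuts[length(cuts)] <- 1  # guard rounding
    codes[, j] <- findInterval(u[, j], c(0, cuts), rightmost.closed = TRUE,
                               left.open = TRUE)
  }
  codes
}

#' Generate a synthetic survey dataset
#'
#' Deterministic given `seed`: identical seeds yield identical datasets.
#'
#' @param params A [sim_params()] object.
#' @param n Number of subjects (default `params$n_subjects`).
#' @param seed RNG seed (default `params$seed`).
#' @return A [survey_dataset()].
#' @export
generate_survey <- function(params, n = params$n_subjects, seed = params$seed) {
  stopifnot(inherits(params, "sim_params"), n >= 1)
  cb <- params$codebook
  fn <- factor_names(cb)
  with_seed(seed, {
    codes <- copula_draw(n, params$latent_correlation, params$marginals)
    rec <- as.data.frame(lapply(seq_along(fn), function(j) {
      cb$factors[[fn[j]]]$categories[codes[, j]]
    }), stringsAsFactors = FALSE, check.names = FALSE)
    names(rec) <- fn
    eta <- params$outcome_intercept +
      Reduce(`+`, lapply(seq_along(fn), function(j) {
        params$outcome_increments[[fn[j]]][codes[, j]]
      }))
    rec[[cb$outcome_name]] <- as.integer(stats::runif(n) < stats::plogis(eta))
    survey_dataset(rec, cb)
  })
}

#' Default simulation parameters calibrated to the Yunnan survey
#'
#' Marginals equal the published per-category totals divided by 1 049; the
#' outcome log-odds increments equal the log of the published multivariate
#' odds ratios for the six independently associated factors (zero elsewhere);
#' the intercept is calibrated by a one-dimensional root find so the expected
#' sharing prevalence equals 393/1 049. The default latent correlation places
#' r = 0.2 between factors sharing a thematic role and 0 across roles — an
#' explicitly synthetic dependence structure chosen so the network stage has
#' recoverable signal, not an estimate of the real survey's correlations.
#'
#' @param within_role_r Latent correlation between same-role factors (0.2).
#' @param n_calibration Monte-Carlo sample size for the intercept root find.
#' @return A `sim_params` object with `n_subjects = 1049`.
#' @export
default_yunnan_params <- function(within_role_r = 0.2, n_calibration = 100000L) {
  cb <- yunnan_codebook()
  t1 <- yunnan_table1()
  fn <- factor_names(cb)
  n_total <- yunnan_reported()$n_complete
  marginals <- lapply(fn, function(f) {
    rows <- t1[t1$factor == f, , drop = FALSE]
    rows <- rows[match(cb$factors[[f]]$categories, rows$category), ]
    rows$total / n_total
  })
  names(marginals) <- fn
  roles <- vapply(cb$factors, `[[`, character(1), "role")
  R <- outer(roles, roles, `==`) * within_role_r
  diag(R) <- 1
  dimnames(R) <- list(fn, fn)
  mv <- t1[!is.na(t1$multi_or), , drop = FALSE]
  incr <- lapply(split(mv, mv$factor), function(rows)
    stats::setNames(log(rows$multi_or), rows$category))
  # Root-find the intercept against the Monte-Carlo distribution of the
  # summed increments under the copula restricted to the affected factors.
  nz <- names(incr)
  target <- yunnan_reported()$n_sng / n_total
  s <- with_seed(20090101L, {
    codes <- copula_draw(n_calibration, R[nz, nz, drop = FALSE], marginals[nz])
    Reduce(`+`, lapply(seq_along(nz), function(j) {
      v <- stats::setNames(numeric(length(cb$factors[[nz[j]]]$categories)),
                           cb$factors[[nz[j]]]$categories)
      v[names(incr[[nz[j]]])] <- incr[[nz[j]]]
      v[codes[, j]]
    }))
  })
  b0 <- stats::uniroot(function(b) mean(stats::plogis(b + s)) - target,
                       c(-10, 10), tol = 1e-10)$root
  sim_params(cb, marginals, R, outcome_intercept = b0,
             outcome_increments = incr, n_subjects = n_total, seed = 1L)
}

#' Write simulation parameters to a YAML file
#' @param params A `sim_params`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_params <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  fn <- factor_names(params$codebook)
  y <- list(
    outcome = params$codebook$outcome_name,
    n_subjects = params$n_subjects,
    seed = params$seed,
    outcome_intercept = params$outcome_intercept,
    factors = lapply(params$codebook$factors, function(f) list(
      name = f$name, role = f$role, reference = f$reference,
      categories = as.list(f$categories),
      marginal = as.list(as.numeric(params$marginals[[f$name]])),
      log_odds = as.list(as.numeric(params$outcome_increments[[f$name]])))),
    latent_correlation = lapply(seq_along(fn), function(i)
      as.list(as.numeric(params$latent_correlation[i, ]))))
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

#' Read simulation parameters from a YAML file written by [write_sim_params()]
#' @param path Input path.
#' @return A `sim_params`.
#' @export
read_sim_params <- function(path) {
  y <- yaml::read_yaml(path)
  specs <- lapply(y$factors, function(f)
    factor_spec(f$name, unlist(f$categories), f$reference, f$role))
  cb <- codebook(specs, outcome_name = y$outcome)
  marg <- lapply(y$factors, function(f) unlist(f$marginal))
  names(marg) <- factor_names(cb)
  incr <- lapply(y$factors, function(f)
    stats::setNames(unlist(f$log_odds), unlist(f$categories)))
  names(incr) <- factor_names(cb)
  R <- do.call(rbind, lapply(y$latent_correlation, unlist))
  sim_params(cb, marg, R, outcome_intercept = y$outcome_intercept,
             outcome_increments = incr, n_subjects = y$n_subjects,
             seed = y$seed)
}
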