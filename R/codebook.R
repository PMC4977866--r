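#' Construct a factor specification
#'
#' A factor specification describes one categorical survey item: its ordered
#' category labels, the reference category used for odds-ratio contrasts, and
#' its thematic role. Roles drive node colour classes in network exports
#' (sociodemographic, drug use, sexual/infectious-disease factors).
#'
#' @param name Factor name (unique within a codebook).
#' @param categories Character vector of >= 2 distinct ordered category labels.
#' @param reference Reference category; must be one of `categories`.
#' @param role One of `"sociodemographic"`, `"drug_use"`, `"sexual_infectious"`.
#' @return An object of class `factor_spec`.
#' @export
factor_spec <- function(name, categories, reference = categories[1],
                        role = c("sociodemographic", "drug_use", "sexual_infectious")) {
  role <- match.arg(role)
  categories <- trimws(as.character(categories))
  if (length(unique(categories)) < 2L)
    stop("factor '", name, "': needs >= 2 distinct categories", call. = FALSE)
  if (anyDuplicated(categories))
    stop("factor '", name, "': duplicated category labels", call. = FALSE)
  if (!reference %in% categories)
    stop("factor '", name, "': reference '", reference, "' is not a category",
         call. = FALSE)
  structure(list(name = as.character(name), categories = categories,
                 reference = as.character(reference), role = role),
            class = "factor_spec")
}

#' Construct a survey codebook
#'
#' @param factors List of [factor_spec()] objects.
#' @param outcome_name Name of the binary outcome column (ever shared needles).
#' @return An object of class `survey_codebook`.
#' @export
codebook <- function(factors, outcome_name = "Shared needles") {
  stopifnot(length(factors) >= 1L)
  if (!all(vapply(factors, inherits, logical(1), "factor_spec")))
    stop("all elements of 'factors' must be factor_spec objects", call. = FALSE)
  nm <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicated factor names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  if (outcome_name %in% nm)
    stop("outcome name '", outcome_name, "' collides with a factor name",
         call. = FALSE)
  names(factors) <- nm
  structure(list(factors = factors, outcome_name = outcome_name),
            class = "survey_codebook")
}

#' Read a codebook from a YAML file
#'
#' The file holds `outcome:` (the outcome column name) and `factors:`, a list
#' of entries with `name`, `categories`, `reference` and `role`.
#'
#' @param path Path to a YAML codebook.
#' @return A `survey_codebook`.
#' @export
read_codebook <- function(path) {
  if (!file.exists(path)) stop("codebook file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y$factors)) stop("codebook has no 'factors' entry", call. = FALSE)
  specs <- lapply(y$factors, function(f) {
    factor_spec(f$name, unlist(f$categories), f$reference, f$role)
  })
  codebook(specs, outcome_name = if (is.null(y$outcome)) "Shared needles" else y$outcome)
}

#' @export
print.survey_codebook <- function(x, ...) {
  cat(sprintf("Survey codebook: %d factors, outcome '%s'\n",
              length(x$factors), x$outcome_name))
  for (f in x$factors)
    cat(sprintf("  %-28s [%s] %d categories (ref: %s)\n",
                f$name, f$role, length(f$categories), f$reference))
  invisible(x)
}

factor_names <- function(cb) names(cb$factors)

#' Bundled codebook for the Yunnan PWID survey
#'
#' The 20-factor codebook of the 2009 Yunnan cross-sectional survey of people
#' who inject drugs, with categories in printed order.
#'
#' @return A `survey_codebook`.
#' @export
yunnan_codebook <- function() {
  read_codebook(system.file("extdata", "yunnan_codebook.yaml",
                            package = "pwidnet", mustWork = TRUE))
}
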