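#' Construct a survey dataset
#'
#' Validates a subject-by-factor table of category labels plus a binary
#' outcome against a codebook. Records with missing or illegal values are
#' rejected (the design mirrors a complete-questionnaire inclusion criterion;
#' no imputation). Labels are matched case-sensitively after whitespace
#' trimming.
#'
#' @param records Data frame with one column per codebook factor (character
#'   category labels) and one outcome column of 0/1 (or logical).
#' @param cb A [codebook()].
#' @return An object of class `survey_dataset` with elements `codebook` and
#'   `records` (validated data frame, row order preserved).
#' @export
survey_dataset <- function(records, cb) {
  stopifnot(inherits(cb, "survey_codebook"), is.data.frame(records))
  records <- as.data.frame(records, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c(factor_names(cb), cb$outcome_name), names(records))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  records <- records[, c(factor_names(cb), cb$outcome_name), drop = FALSE]
  for (f in cb$factors) {
    v <- trimws(as.character(records[[f$name]]))
    bad <- which(is.na(v) | !(v %in% f$categories))
    if (length(bad))
      stop("validation error: row ", bad[1], ", factor '", f$name,
           "', value '", records[[f$name]][bad[1]], "' is not a legal category",
           call. = FALSE)
    records[[f$name]] <- v
  }
  out <- records[[cb$outcome_name]]
  if (is.logical(out)) out <- as.integer(out)
  out <- suppressWarnings(as.integer(out))
  if (anyNA(out) || !all(out %in% c(0L, 1L)))
    stop("validation error: outcome '", cb$outcome_name,
         "' must be binary 0/1", call. = FALSE)
  records[[cb$outcome_name]] <- out
  structure(list(codebook = cb, records = records), class = "survey_dataset")
}

#' Load a survey dataset from a CSV table and a YAML codebook
#'
#' @param table_path Path to a comma-separated UTF-8 table with a header row.
#' @param codebook_path Path to the YAML codebook.
#' @return A validated `survey_dataset`; row order preserved.
#' @export
load_dataset <- function(table_path, codebook_path) {
  if (!file.exists(table_path)) stop("data file not found: ", table_path, call. = FALSE)
  cb <- read_codebook(codebook_path)
  tab <- utils::read.csv(table_path, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  survey_dataset(tab, cb)
}

#' Write a survey dataset to CSV
#'
#' @param data A `survey_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  stopifnot(inherits(data, "survey_dataset"))
  utils::write.csv(data$records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.survey_dataset <- function(x, ...) {
  n <- nrow(x$records)
  pos <- sum(x$records[[x$codebook$outcome_name]])
  cat(sprintf("Survey dataset: %d subjects, %d factors; outcome '%s' positive in %d (%.1f%%)\n",
              n, length(x$codebook$factors), x$codebook$outcome_name,
              pos, 100 * pos / max(n, 1)))
  invisible(x)
}

#' Number of subjects
#' @param data A `survey_dataset`.
#' @return Integer count of records.
#' @export
n_subjects <- function(data) nrow(data$records)

outcome_vector <- function(data) data$records[[data$codebook$outcome_name]]

#' Split a dataset by the sharing outcome
#'
#' Partitions the subjects into the never-sharing group (NSNG, outcome 0) and
#' the sharing group (SNG, outcome 1).
#'
#' @param data A `survey_dataset`.
#' @return List with elements `NSNG` and `SNG`, both `survey_dataset`s.
#' @export
split_by_outcome <- function(data) {
  stopifnot(inherits(data, "survey_dataset"))
  y <- outcome_vector(data)
  list(NSNG = survey_dataset(data$records[y == 0L, , drop = FALSE], data$codebook),
       SNG  = survey_dataset(data$records[y == 1L, , drop = FALSE], data$codebook))
}

#' Outcome-by-category contingency table for one factor
#'
#' Cross-tabulates one factor's categories against the binary outcome, in
#' codebook category order, with sharing percentages per category.
#'
#' @param data A `survey_dataset`.
#' @param factor Factor name.
#' @return An object of class `contingency_table`: data frame with columns
#'   `category`, `total`, `shared`, `not_shared`, `pct_of_total`,
#'   `pct_shared`, plus attributes `factor_spec` and `n`.
#' @export
contingency_table <- function(data, factor) {
  stopifnot(inherits(data, "survey_dataset"))
  if (!factor %in% factor_names(data$codebook))
    stop("unknown factor: '", factor, "'", call. = FALSE)
  spec <- data$codebook$factors[[factor]]
  v <- base::factor(data$records[[factor]], levels = spec$categories)
  y <- outcome_vector(data)
  total <- as.integer(table(v))
  shared <- as.integer(tapply(y, v, sum, default = 0L))
  n <- n_subjects(data)
  out <- data.frame(category = spec$categories,
                    total = total,
                    shared = shared,
                    not_shared = total - shared,
                    pct_of_total = 100 * total / n,
                    pct_shared = ifelse(total > 0, 100 * shared / total, NA_real_),
                    stringsAsFactors = FALSE)
  structure(out, class = c("contingency_table", "data.frame"),
            factor_spec = spec, n = n)
}

#' Build a contingency table directly from printed counts
#'
#' Convenience constructor used when the subject-level data are replaced by a
#' published count table.
#'
#' @param spec A [factor_spec()].
#' @param total Integer vector of per-category totals (codebook order).
#' @param shared Integer vector of per-category sharer counts.
#' @return A `contingency_table`.
#' @export
contingency_from_counts <- function(spec, total, shared) {
  stopifnot(inherits(spec, "factor_spec"),
            length(total) == length(spec$categories),
            length(shared) == length(total), all(shared <= total),
            all(total >= 0), all(shared >= 0))
  n <- sum(total)
  out <- data.frame(category = spec$categories,
                    total = as.integer(total),
                    shared = as.integer(shared),
                    not_shared = as.integer(total - shared),
                    pct_of_total = 100 * total / n,
                    pct_shared = ifelse(total > 0, 100 * shared / total, NA_real_),
                    stringsAsFactors = FALSE)
  structure(out, class = c("contingency_table", "data.frame"),
            factor_spec = spec, n = n)
}

#' Per-factor category counts and percentages
#'
#' Summary-table analogue of a published "Total n(%)" column: for every factor,
#' category counts and percentages of the full sample, plus sharing counts.
#'
#' @param data A `survey_dataset`.
#' @return Data frame with columns `factor`, `category`, `total`,
#'   `pct_of_total`, `shared`, `pct_shared`.
#' @export
marginal_summary <- function(data) {
  stopifnot(inherits(data, "survey_dataset"))
  do.call(rbind, lapply(factor_names(data$codebook), function(f) {
    ct <- contingency_table(data, f)
    data.frame(factor = f, category = ct$category, total = ct$total,
               pct_of_total = ct$pct_of_total, shared = ct$shared,
               pct_shared = ct$pct_shared, stringsAsFactors = FALSE)
  }))
}
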