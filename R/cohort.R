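# CohortTable container and the study's inclusion/exclusion rules.

#' Construct a cohort table
#'
#' The canonical per-cohort container: an individuals x 13 score matrix (NA =
#' missing), per-individual covariates (sex plus age at collection for each
#' instrument block), a cohort id, and an optional family id used by the
#' one-per-family exclusion.
#'
#' @param values numeric matrix with the 13 canonical columns.
#' @param covariates data.frame with columns `sex`, `age_trait`,
#'   `age_stressor`, `age_depression` (NAs allowed).
#' @param cohort_id character label.
#' @param schema variable schema (see [ndnet_schema()]).
#' @param family_id optional character/integer vector, one entry per row.
#' @return object of class `cohort_table`.
#' @export
cohort_table <- function(values, covariates, cohort_id, schema,
                         family_id = NULL) {
  vars <- schema$name
  if (!identical(colnames(values), vars)) {
    if (!setequal(colnames(values), vars))
      stop("values columns must be the 13 canonical variables")
    values <- values[, vars, drop = FALSE]
  }
  storage.mode(values) <- "double"
  stopifnot(is.data.frame(covariates), nrow(covariates) == nrow(values),
            all(c("sex", "age_trait", "age_stressor", "age_depression")
                %in% names(covariates)))
  if (!is.null(family_id) && length(family_id) != nrow(values))
    stop("family_id must have one entry per row")
  structure(list(values = values, covariates = covariates,
                 cohort_id = cohort_id, schema = schema,
                 family_id = family_id),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %s: %d individuals x %d variables, %.1f%% missing\n",
              x$cohort_id, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' Observed/missing mask of a cohort table
#' @param t a `cohort_table`.
#' @return logical matrix, TRUE = observed.
#' @export
observed_mask <- function(t) !is.na(t$values)

subset_rows <- function(t, keep) {
  cohort_table(t$values[keep, , drop = FALSE],
               t$covariates[keep, , drop = FALSE],
               t$cohort_id, t$schema,
               if (!is.null(t$family_id)) t$family_id[keep])
}

#' Load a cohort table from CSV/TSV
#'
#' Expects one header row and one row per individual; empty cells are missing.
#' Score columns are matched to the schema by name (order-insensitive) and
#' canonicalised; values outside the schema's instrument bounds are rejected.
#' Covariate columns (`sex`, `age_trait`, `age_stressor`, `age_depression`)
#' and `family_id` are optional; absent covariates become NA columns.
#'
#' @param path file path; `.tsv`/`.txt` are read tab-separated.
#' @param schema variable schema.
#' @param cohort_id cohort label; defaults to the file name.
#' @return a `cohort_table`.
#' @export
load_cohort <- function(path, schema, cohort_id = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  vars <- schema$name
  covs <- c("sex", "age_trait", "age_stressor", "age_depression")
  known <- c(vars, covs, "family_id", "id")
  unknown <- setdiff(names(df), known)
  if (length(unknown))
    stop("unknown column(s) ", paste(unknown, collapse = ", "),
         "; expected score columns: ", paste(vars, collapse = ", "))
  missing_vars <- setdiff(vars, names(df))
  if (length(missing_vars))
    stop("missing score column(s): ", paste(missing_vars, collapse = ", "))
  values <- as.matrix(df[, vars, drop = FALSE])
  storage.mode(values) <- "double"
  for (k in seq_along(vars)) {
    bad <- which(!is.na(values[, k]) &
                 (values[, k] < schema$score_min[k] | values[, k] > schema$score_max[k]))
    if (length(bad))
      stop(sprintf("value out of bounds for '%s' at row %d: %g not in [%g, %g]",
                   vars[k], bad[1], values[bad[1], k],
                   schema$score_min[k], schema$score_max[k]))
  }
  covariates <- as.data.frame(
    lapply(stats::setNames(covs, covs),
           function(cv) if (cv %in% names(df)) df[[cv]] else rep(NA_real_, nrow(df)))
  )
  cohort_table(values, covariates,
               cohort_id %||% sub("\\.[^.]+$", "", basename(path)),
               schema,
               family_id = if ("family_id" %in% names(df)) df$family_id)
}

#' Write a cohort table to CSV
#'
#' One header row, one row per individual, empty cell = missing. Round-trips
#' through [load_cohort()].
#'
#' @param t a `cohort_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(t, path) {
  df <- cbind(t$covariates, as.data.frame(t$values))
  if (!is.null(t$family_id)) df <- cbind(family_id = t$family_id, df)
  utils::write.table(df, path, sep = ",", na = "", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Apply the study's inclusion rules
#'
#' Removes individuals with all seven neurodevelopmental trait scores missing;
#' optionally retains exactly one member per family, chosen uniformly at
#' random with the given seed (a documented stand-in for the source cohort's
#' in-house exclusion routines).
#'
#' @param t a `cohort_table`.
#' @param one_per_family keep a single random member per `family_id`?
#' @param seed integer seed for the family selection.
#' @return the filtered `cohort_table`.
#' @export
apply_exclusions <- function(t, one_per_family = FALSE, seed = 1L) {
  traits <- trait_vars()
  keep <- rowSums(!is.na(t$values[, traits, drop = FALSE])) >= 1L
  t <- subset_rows(t, keep)
  if (one_per_family && !is.null(t$family_id)) {
    set.seed(substream_seed(seed, "one_per_family"))
    idx <- seq_len(nrow(t$values))
    pick <- unlist(lapply(split(idx, t$family_id), function(members) {
      if (length(members) == 1L) members else sample(members, 1L)
    }), use.names = FALSE)
    t <- subset_rows(t, sort(pick))
  }
  t
}

#' Completers filter on neurodevelopmental traits
#'
#' Retains rows whose fraction of observed trait scores is at least
#' `min_frac`; at the study's 0.70 cut this keeps individuals with 5+ of the 7
#' traits observed.
#'
#' @param t a `cohort_table`.
#' @param min_frac fraction in (0, 1].
#' @return the filtered `cohort_table`.
#' @export
completers_filter <- function(t, min_frac = 0.70) {
  stopifnot(min_frac > 0, min_frac <= 1)
  traits <- trait_vars()
  frac <- rowSums(!is.na(t$values[, traits, drop = FALSE])) / length(traits)
  subset_rows(t, frac >= min_frac)
}
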