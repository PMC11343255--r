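#' Feature schema for mixed-type phenotype matrices
#'
#' A schema is an ordered table describing each training feature: its name,
#' its distributional type (`continuous`, `binary`, or `categorical`), the
#' number of levels for categorical features, and (optionally) the phenotype
#' category it belongs to.  The mixture model chooses the per-feature
#' likelihood family from the type: Gaussian for continuous, Bernoulli for
#' binary, multinomial for categorical.
#'
#' @param name character vector of unique feature names.
#' @param type character vector in `c("continuous", "binary", "categorical")`.
#' @param n_levels integer vector; required (>= 2) for categorical features,
#'   `NA` otherwise.
#' @param category optional character vector assigning each feature to one of
#'   the seven phenotype categories (see [phenotype_categories()]), or `NA`.
#' @return A `data.frame` of class `feature_schema` with columns
#'   `name`, `type`, `n_levels`, `category`.
#' @export
feature_schema <- function(name, type, n_levels = NA_integer_, category = NA_character_) {
  sch <- data.frame(
    name = as.character(name),
    type = as.character(type),
    n_levels = as.integer(n_levels),
    category = as.character(category),
    stringsAsFactors = FALSE
  )
  validate_schema(sch)
  class(sch) <- c("feature_schema", "data.frame")
  sch
}

validate_schema <- function(sch) {
  stopifnot(is.data.frame(sch), all(c("name", "type") %in% names(sch)))
  if (anyDuplicated(sch$name)) {
    stop("schema error: duplicate feature names: ",
         paste(unique(sch$name[duplicated(sch$name)]), collapse = ", "))
  }
  bad <- setdiff(unique(sch$type), c("continuous", "binary", "categorical"))
  if (length(bad)) {
    stop("schema error: unknown feature type(s): ", paste(bad, collapse = ", "))
  }
  cat_rows <- sch$type == "categorical"
  if (any(cat_rows)) {
    nl <- sch$n_levels[cat_rows]
    if (any(is.na(nl)) || any(nl < 2)) {
      stop("schema error: categorical features need n_levels >= 2")
    }
  }
  invisible(sch)
}

#' The seven phenotype categories
#'
#' Fixed vocabulary used for category affinity profiling: limited
#' social/communication, restricted/repetitive behavior, attention,
#' disruptive behavior, anxiety/mood, developmental delay, and self-injury.
#'
#' @return Character vector of length 7.
#' @export
phenotype_categories <- function() {
  c("limited social/communication", "restricted/repetitive behavior",
    "attention", "disruptive behavior", "anxiety/mood",
    "developmental delay", "self-injury")
}

#' Construct a phenotype cohort container
#'
#' Bundles a per-individual data table with its feature schema.  The data
#' table carries the metadata columns `individual_id`, `family_id`, `role`
#' (`"proband"` or `"sibling"`), `sex` (0/1), `age_years`, and optionally
#' `true_class` (generator ground truth), followed by one column per schema
#' feature.  Categorical features are stored as integer level indices
#' `1..n_levels`.
#'
#' @param data data.frame as described above.
#' @param schema a [feature_schema()].
#' @return Object of class `phenotype_cohort`: a list with elements `data`
#'   and `schema`.
#' @export
phenotype_cohort <- function(data, schema) {
  validate_schema(schema)
  needed <- c("individual_id", "role", "sex", "age_years")
  miss <- setdiff(needed, names(data))
  if (length(miss)) stop("cohort data missing columns: ", paste(miss, collapse = ", "))
  miss_f <- setdiff(schema$name, names(data))
  if (length(miss_f)) {
    stop("schema error: features absent from data: ", paste(miss_f, collapse = ", "))
  }
  structure(list(data = data, schema = schema), class = "phenotype_cohort")
}

#' @export
print.phenotype_cohort <- function(x, ...) {
  n_pro <- sum(x$data$role == "proband")
  n_sib <- sum(x$data$role == "sibling")
  cat(sprintf("phenotype_cohort: %d probands, %d siblings, %d features\n",
              n_pro, n_sib, nrow(x$schema)))
  tt <- table(x$schema$type)
  cat("  feature types:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  invisible(x)
}

# Feature columns in schema order, as a data.frame.
cohort_features <- function(cohort, features = NULL) {
  sch <- cohort$schema
  if (!is.null(features)) {
    miss <- setdiff(features, sch$name)
    if (length(miss)) stop("schema error: unknown feature(s): ", paste(miss, collapse = ", "))
    sch <- sch[match(features, sch$name), , drop = FALSE]
  }
  cohort$data[, sch$name, drop = FALSE]
}

# Numeric feature matrix (categoricals as integer level indices).
cohort_feature_matrix <- function(cohort, features = NULL) {
  as.matrix(as.data.frame(lapply(cohort_features(cohort, features), as.numeric)))
}

# Covariate design matrix (intercept, sex, age) for the class priors.
cohort_covariates <- function(cohort) {
  cbind(intercept = 1, sex = cohort$data$sex, age = cohort$data$age_years)
}

#' Restrict a cohort to a subset of features
#'
#' Used for cross-cohort replication on common features: drops all feature
#' columns not listed, keeping metadata columns and schema order.
#'
#' @param cohort a [phenotype_cohort()].
#' @param features character vector of feature names to keep.
#' @return A [phenotype_cohort()] with the restricted schema.
#' @export
subset_features <- function(cohort, features) {
  miss <- setdiff(features, cohort$schema$name)
  if (length(miss)) stop("schema error: unknown feature(s): ", paste(miss, collapse = ", "))
  sch <- cohort$schema[cohort$schema$name %in% features, , drop = FALSE]
  meta <- setdiff(names(cohort$data), cohort$schema$name)
  dat <- cohort$data[, c(meta, sch$name), drop = FALSE]
  phenotype_cohort(dat, sch)
}

#' Split a cohort into proband and sibling parts
#'
#' @param cohort a [phenotype_cohort()].
#' @return List with elements `probands` and `siblings`, both cohorts.
#' @export
split_roles <- function(cohort) {
  list(
    probands = phenotype_cohort(cohort$data[cohort$data$role == "proband", , drop = FALSE],
                                cohort$schema),
    siblings = phenotype_cohort(cohort$data[cohort$data$role == "sibling", , drop = FALSE],
                                cohort$schema)
  )
}
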