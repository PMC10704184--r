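#' Construct a category scheme
#'
#' A category scheme defines the stratification variables, the ordered
#' category labels of each, the age-bin edges, the label used for missing
#' values, and the target open fraction. The cross-product of the
#' per-variable categories defines the strata within which patients are
#' randomized to the open or sequestered commons.
#'
#' @param variables Named list; one ordered character vector of category
#'   labels per stratification variable, in stratification order. The age
#'   variable's categories must be the age-bin labels plus `missing_label`.
#' @param age_bins Numeric vector of age-bin edges; bin i is the half-open
#'   interval `[edges[i], edges[i+1])`. Bins must be contiguous and
#'   increasing.
#' @param missing_label Category label assigned to blank/absent demographic
#'   values. Must be a category of every demographic variable (the modality
#'   variable excepted: a patient with no modality is a validation error,
#'   not a category).
#' @param open_fraction Target fraction of each stratum assigned to the
#'   open commons; in (0, 1).
#' @param age_variable,modality_variable Names of the age and modality
#'   variables within `variables`.
#' @return An object of class `stratseq_scheme`.
#' @seealso [default_scheme()] for the standard six-variable scheme.
#' @export
category_scheme <- function(variables, age_bins,
                            missing_label = "Not reported",
                            open_fraction = 0.8,
                            age_variable = "age_group",
                            modality_variable = "modality") {
  stopifnot(is.list(variables), length(variables) >= 1,
            !is.null(names(variables)), all(nzchar(names(variables))))
  if (!is.numeric(age_bins) || length(age_bins) < 2 ||
      any(diff(age_bins) <= 0)) {
    stop("`age_bins` must be an increasing numeric vector of bin edges.",
         call. = FALSE)
  }
  if (!(open_fraction > 0 && open_fraction < 1)) {
    stop("`open_fraction` must lie strictly between 0 and 1.", call. = FALSE)
  }
  scheme <- structure(
    list(variables = lapply(variables, as.character),
         age_bins = as.numeric(age_bins),
         missing_label = missing_label,
         open_fraction = open_fraction,
         age_variable = age_variable,
         modality_variable = modality_variable),
    class = "stratseq_scheme")
  validate_scheme(scheme)
  scheme
}

validate_scheme <- function(scheme) {
  vars <- scheme$variables
  for (v in setdiff(names(vars), scheme$modality_variable)) {
    if (!scheme$missing_label %in% vars[[v]]) {
      stop("Variable '", v, "' lacks the missing-value category '",
           scheme$missing_label, "'.", call. = FALSE)
    }
    if (anyDuplicated(vars[[v]])) {
      stop("Variable '", v, "' has duplicated category labels.", call. = FALSE)
    }
  }
  if (scheme$age_variable %in% names(vars)) {
    expected <- c(age_bin_labels(scheme), scheme$missing_label)
    if (!setequal(vars[[scheme$age_variable]], expected)) {
      stop("Age-variable categories must be the age-bin labels plus '",
           scheme$missing_label, "'.", call. = FALSE)
    }
  }
  invisible(scheme)
}

age_bin_labels <- function(scheme) {
  e <- scheme$age_bins
  sprintf("[%g, %g)", e[-length(e)], e[-1])
}

#' The default six-variable category scheme
#'
#' Age group (9 categories: 8 CDC-style bins covering `[0, 140)` plus
#' "Not reported"), race (7, NIH categories), sex at birth (4), ethnicity
#' (3), COVID-19 status (3), and image modality (4: CR, CT, DX, MR) —
#' 9072 strata in total. An optional anonymized clinical-site variable can
#' be prepended for multi-site batches.
#'
#' @param open_fraction Target open-commons fraction (default 0.8).
#' @param site_categories Optional character vector of site labels; when
#'   supplied, `site` becomes the leading stratification variable (with a
#'   "Not reported" category added if absent).
#' @return A `stratseq_scheme`.
#' @examples
#' count_strata(default_scheme()) # 9072
#' @export
default_scheme <- function(open_fraction = 0.8, site_categories = NULL) {
  bins <- c(0, 18, 30, 40, 50, 65, 75, 85, 140)
  missing_label <- "Not reported"
  age_labels <- sprintf("[%g, %g)", bins[-length(bins)], bins[-1])
  variables <- list(
    age_group = c(age_labels, missing_label),
    race = c("American Indian or Alaska Native", "Asian",
             "Black or African American",
             "Native Hawaiian or other Pacific Islander", "White",
             missing_label, "Other"),
    sex_at_birth = c("Female", "Male", "Other", missing_label),
    ethnicity = c("Hispanic or Latino", "Not Hispanic or Latino",
                  missing_label),
    covid_status = c("No", missing_label, "Yes"),
    modality = c("CR", "CT", "DX", "MR"))
  if (!is.null(site_categories)) {
    site <- unique(as.character(site_categories))
    if (!missing_label %in% site) site <- c(site, missing_label)
    variables <- c(list(site = site), variables)
  }
  category_scheme(variables, bins, missing_label, open_fraction)
}

#' Number of strata defined by a scheme
#'
#' The product of the per-variable category counts: the theoretical maximum
#' number of unique variable combinations. Most strata are empty in
#' practice; only occupied strata are ever instantiated.
#'
#' @param scheme A `stratseq_scheme`.
#' @return Integer-valued count.
#' @examples
#' count_strata(default_scheme()) # 9 * 7 * 4 * 3 * 3 * 4 = 9072
#' @export
count_strata <- function(scheme) {
  stopifnot(inherits(scheme, "stratseq_scheme"))
  prod(lengths(scheme$variables))
}

#' Map ages to age-group categories
#'
#' Each age in `[0, 140)` falls in exactly one half-open bin `[lo, hi)`;
#' missing ages map to the scheme's missing label. Ages outside `[0, 140)`
#' are rejected as corrupt metadata rather than silently binned.
#'
#' @param age_years Numeric vector of ages (NA = missing).
#' @param scheme A `stratseq_scheme`.
#' @param patient_id Optional ids used to name offenders in error messages.
#' @return Character vector of age-group labels.
#' @examples
#' categorize_age(c(17, 65, NA), default_scheme())
#' @export
categorize_age <- function(age_years, scheme = default_scheme(),
                           patient_id = NULL) {
  edges <- scheme$age_bins
  bad <- !is.na(age_years) &
    (age_years < edges[1] | age_years >= edges[length(edges)])
  if (any(bad)) {
    who <- if (!is.null(patient_id)) {
      paste0(" (patient ", paste(patient_id[bad], collapse = ", "), ")")
    } else ""
    stop("Age outside [", edges[1], ", ", edges[length(edges)], "): ",
         paste(age_years[bad], collapse = ", "), who, call. = FALSE)
  }
  labels <- age_bin_labels(scheme)
  out <- rep(scheme$missing_label, length(age_years))
  ok <- !is.na(age_years)
  out[ok] <- labels[findInterval(age_years[ok], edges,
                                 rightmost.closed = FALSE)]
  out
}

# Normalize raw categorical values against a variable's vocabulary:
# trim whitespace, match case-insensitively, map blanks to the missing
# label. Unknown non-blank values are errors — silent coercion would
# corrupt the balance bookkeeping.
match_category <- function(values, variable, scheme, patient_id = NULL) {
  categories <- scheme$variables[[variable]]
  out <- rep(NA_character_, length(values))
  blank <- is_blank(values)
  out[blank] <- scheme$missing_label
  idx <- match(tolower(trimws(values[!blank])), tolower(categories))
  if (anyNA(idx)) {
    bad <- unique(values[!blank][is.na(idx)])
    stop("Unrecognized value(s) for '", variable, "': ",
         paste(shQuote(trimws(bad)), collapse = ", "),
         if (!is.null(patient_id)) {
           paste0(" (patient ",
                  paste(unique(patient_id[!blank][is.na(idx)]),
                        collapse = ", "), ")")
         } else "",
         call. = FALSE)
  }
  out[!blank] <- categories[idx]
  out
}

#' Read or write a category scheme as JSON
#'
#' The JSON mirrors the scheme fields (`variables`, `age_bins`,
#' `missing_label`, `open_fraction`); a round trip is lossless.
#'
#' @param path File path.
#' @return `read_scheme()` returns a `stratseq_scheme`; `write_scheme()`
#'   returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  category_scheme(as.list(x$variables), x$age_bins,
                  missing_label = x$missing_label %||% "Not reported",
                  open_fraction = x$open_fraction %||% 0.8,
                  age_variable = x$age_variable %||% "age_group",
                  modality_variable = x$modality_variable %||% "modality")
}

#' @rdname read_scheme
#' @param scheme A `stratseq_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "stratseq_scheme"))
  jsonlite::write_json(unclass(scheme), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.stratseq_scheme <- function(x, ...) {
  cat("<stratseq_scheme> ", length(x$variables), " variables, ",
      count_strata(x), " strata, open fraction ", x$open_fraction, "\n",
      sep = "")
  for (v in names(x$variables)) {
    cat("  ", v, " (", length(x$variables[[v]]), "): ",
        paste(x$variables[[v]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
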