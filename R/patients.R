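#' Read and write patient metadata batches
#'
#' A batch is a tibble with one row per patient and columns `patient_id`,
#' `age`, `race`, `sex_at_birth`, `ethnicity`, `covid_status`, and
#' `modalities` (a `;`-separated list of modality codes). Blank cells are
#' missing values. An optional `site_id` column carries the anonymized
#' clinical site.
#'
#' @param path CSV file path.
#' @return `read_batch()` returns a validated tibble; `write_batch()`
#'   returns `path` invisibly.
#' @export
read_batch <- function(path) {
  batch <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character(),
                            age = readr::col_double()),
    na = c("", "NA"), comment = "#", progress = FALSE)
  validate_batch(batch)
}

#' @rdname read_batch
#' @param batch A patient batch tibble.
#' @export
write_batch <- function(batch, path) {
  readr::write_csv(batch, path, na = "")
  invisible(path)
}

batch_required_cols <- c("patient_id", "age", "race", "sex_at_birth",
                         "ethnicity", "covid_status", "modalities")

#' Validate a patient batch
#'
#' Checks the structural invariants of patient records: required columns
#' present; patient ids non-empty and unique within the batch; at least one
#' modality per patient; ages (where reported) within `[0, 140)`.
#'
#' @param batch A patient batch tibble.
#' @param scheme Scheme used for the age range check.
#' @return The batch, invisibly usable, with `modalities` trimmed.
#' @export
validate_batch <- function(batch, scheme = default_scheme()) {
  missing_cols <- setdiff(batch_required_cols, names(batch))
  if (length(missing_cols) > 0) {
    stop("Batch is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(is_blank(batch$patient_id))) {
    stop("Batch contains blank patient_id values.", call. = FALSE)
  }
  if (anyDuplicated(batch$patient_id)) {
    dup <- unique(batch$patient_id[duplicated(batch$patient_id)])
    stop("Duplicate patient_id within batch: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  mods <- split_modalities(batch$modalities)
  empty <- lengths(mods) == 0
  if (any(empty)) {
    stop("Patient(s) with no modality: ",
         paste(batch$patient_id[empty], collapse = ", "), call. = FALSE)
  }
  categorize_age(batch$age, scheme, patient_id = batch$patient_id)
  batch
}

split_modalities <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(m) unique(trimws(m[nzchar(trimws(m))])))
}

#' Categorize a batch into stratum components
#'
#' Applies the per-field normalization rules (age binning, vocabulary
#' matching, blank-to-missing mapping) and attaches each patient's primary
#' modality, yielding one categorical column per scheme variable plus the
#' canonical stratum key.
#'
#' @param batch A validated patient batch.
#' @param scheme A `stratseq_scheme`.
#' @param primary Named character vector mapping patient_id to primary
#'   modality; resolved from the batch itself when `NULL` (see
#'   [resolve_primary_modality()]).
#' @return Tibble with `patient_id`, one column per scheme variable, and
#'   `stratum` (the canonical key string).
#' @export
normalize_batch <- function(batch, scheme = default_scheme(),
                            primary = NULL) {
  validate_batch(batch, scheme)
  if (is.null(primary)) primary <- resolve_primary_modality(batch)
  out <- tibble::tibble(patient_id = batch$patient_id)
  for (v in names(scheme$variables)) {
    out[[v]] <- if (v == scheme$age_variable) {
      categorize_age(batch$age, scheme, batch$patient_id)
    } else if (v == scheme$modality_variable) {
      match_category(unname(primary[batch$patient_id]), v, scheme,
                     batch$patient_id)
    } else if (v == "site") {
      raw <- if ("site_id" %in% names(batch)) batch$site_id else
        rep(NA_character_, nrow(batch))
      match_category(raw, v, scheme, batch$patient_id)
    } else {
      raw_col <- if (v %in% names(batch)) batch[[v]] else
        stop("Batch lacks column for scheme variable '", v, "'.",
             call. = FALSE)
      match_category(raw_col, v, scheme, batch$patient_id)
    }
  }
  vars <- names(scheme$variables)
  key_cols <- lapply(vars[order(vars)], function(v)
    paste0(v, "=", out[[v]]))
  out$stratum <- do.call(paste, c(key_cols, sep = "|"))
  out
}

#' Normalize a single patient record to a stratum key
#'
#' @param record One-row batch tibble (or a list with the batch fields).
#' @param scheme A `stratseq_scheme`.
#' @param primary_modality The patient's primary modality; must be one of
#'   the record's modalities.
#' @return Named character vector, one component per scheme variable in
#'   scheme order.
#' @export
normalize_record <- function(record, scheme = default_scheme(),
                             primary_modality) {
  record <- tibble::as_tibble(record)
  stopifnot(nrow(record) == 1)
  mods <- split_modalities(record$modalities)[[1]]
  if (!primary_modality %in% mods) {
    stop("primary_modality '", primary_modality,
         "' is not among the record's modalities.", call. = FALSE)
  }
  norm <- normalize_batch(record, scheme,
                          primary = stats::setNames(primary_modality,
                                                    record$patient_id))
  key <- unlist(norm[1, names(scheme$variables)])
  stats::setNames(as.character(key), names(scheme$variables))
}
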