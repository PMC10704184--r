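#' The persistent assignment registry
#'
#' The registry records every patient ever assigned to an arm, so that data
#' from returning patients always land in the same commons across intake
#' batches. Each entry carries provenance (batch label, ISO timestamp).
#' An arm never changes once recorded.
#'
#' @return `new_registry()` returns an empty registry tibble with columns
#'   `patient_id`, `arm`, `batch_label`, `timestamp`.
#' @export
new_registry <- function() {
  tibble::tibble(patient_id = character(), arm = character(),
                 batch_label = character(), timestamp = character())
}

#' @rdname new_registry
#' @param path CSV file path.
#' @export
read_registry <- function(path) {
  if (!file.exists(path)) return(new_registry())
  reg <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  validate_registry(reg)
}

#' @rdname new_registry
#' @param registry A registry tibble.
#' @details `write_registry()` writes atomically (temp file + rename) so a
#'   crashed run never half-records a batch.
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry)
  tmp <- tempfile("registry-", tmpdir = dirname(path), fileext = ".csv")
  readr::write_csv(registry, tmp)
  file.rename(tmp, path)
  invisible(path)
}

validate_registry <- function(registry) {
  needed <- c("patient_id", "arm", "batch_label", "timestamp")
  if (!all(needed %in% names(registry))) {
    stop("Registry is missing column(s): ",
         paste(setdiff(needed, names(registry)), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(registry$patient_id)) {
    stop("Registry contains duplicate patient_id entries.", call. = FALSE)
  }
  if (!all(registry$arm %in% c("open", "sequestered"))) {
    stop("Registry arms must be 'open' or 'sequestered'.", call. = FALSE)
  }
  registry
}

# Arm lookup for a vector of patient ids; NA where unknown.
registry_lookup <- function(registry, patient_id) {
  registry$arm[match(patient_id, registry$patient_id)]
}

# Extend a registry with newly assigned patients. Re-adding an id with the
# same arm is ignored; a conflicting arm is an error (sequestration
# integrity outranks everything else).
registry_add <- function(registry, patient_id, arm, batch_label,
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")) {
  existing <- registry_lookup(registry, patient_id)
  conflict <- !is.na(existing) & existing != arm
  if (any(conflict)) {
    stop("Registry conflict: patient(s) ",
         paste(patient_id[conflict], collapse = ", "),
         " already recorded with a different arm.", call. = FALSE)
  }
  new <- is.na(existing)
  validate_registry(dplyr::bind_rows(
    registry,
    tibble::tibble(patient_id = patient_id[new], arm = arm[new],
                   batch_label = batch_label, timestamp = timestamp)))
}
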