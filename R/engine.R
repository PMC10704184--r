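#' Resolve each patient's primary modality
#'
#' A patient may hold images from several modalities but is stratified only
#' once. The modality prevalence of an intake batch is the number of
#' patients possessing each modality; a patient's primary modality is their
#' possessed modality of highest batch prevalence, with ties broken by
#' lexicographic order of the modality code. Images from less prevalent
#' modalities travel with the primary.
#'
#' @param batch A validated patient batch.
#' @return Named character vector: patient_id -> primary modality code.
#' @examples
#' b <- tibble::tibble(
#'   patient_id = c("a", "b", "c"), age = c(30, 40, 50),
#'   race = "White", sex_at_birth = "Female",
#'   ethnicity = "Not Hispanic or Latino", covid_status = "No",
#'   modalities = c("CT", "CT", "CR;CT"))
#' resolve_primary_modality(b) # patient c -> CT (prevalence 3 vs 1)
#' @export
resolve_primary_modality <- function(batch) {
  mods <- split_modalities(batch$modalities)
  empty <- lengths(mods) == 0
  if (any(empty)) {
    stop("Patient(s) with no modality: ",
         paste(batch$patient_id[empty], collapse = ", "), call. = FALSE)
  }
  prevalence <- table(unlist(mods))
  primary <- vapply(mods, function(m) {
    m[order(-as.numeric(prevalence[m]), m)][1]
  }, character(1))
  stats::setNames(primary, batch$patient_id)
}

#' Randomly split one stratum at the target open fraction
#'
#' For a stratum of size m and open fraction f, the number assigned to the
#' open commons is `floor(f * m)` plus a Bernoulli draw on the fractional
#' part, so the expected open fraction equals f for every stratum size —
#' including the singletons that dominate rare demographic combinations.
#' Members are selected uniformly without replacement. Consumes the current
#' RNG stream; seed beforehand for reproducibility.
#'
#' @param members Vector of patient ids (or any identifiers).
#' @param open_fraction Fraction in (0, 1).
#' @return List with elements `open` and `sequestered`, partitioning
#'   `members`.
#' @export
split_stratum <- function(members, open_fraction = 0.8) {
  m <- length(members)
  stopifnot(m >= 1, open_fraction > 0, open_fraction < 1)
  k <- draw_open_counts(m, open_fraction)
  idx <- sample.int(m, k)
  list(open = members[idx],
       sequestered = if (k == m) members[0] else members[-idx])
}

# Randomized-rounding open counts for a vector of stratum sizes.
# Guards against floating-point drift in f * m before taking the floor.
draw_open_counts <- function(sizes, open_fraction) {
  x <- open_fraction * sizes
  k <- floor(x + 1e-9)
  frac <- pmin(pmax(x - k, 0), 1)
  as.integer(k + stats::rbinom(length(sizes), 1L, frac))
}

# Vectorized within-stratum assignment. `group_sizes` lists stratum sizes
# in canonical-key order and the (implicit) patients are presorted by
# (canonical key, patient_id); within each stratum the k patients with the
# smallest fresh uniforms go open — equivalent to uniform sampling without
# replacement. One rbinom + one runif call per trial keeps multi-thousand-
# trial ensembles cheap, and the canonical ordering makes the draw
# invariant to patient-row order and to scheme-variable permutation.
stratified_open_mask <- function(group_sizes, open_fraction) {
  k <- draw_open_counts(group_sizes, open_fraction)
  n <- sum(group_sizes)
  u <- stats::runif(n)
  gid <- rep.int(seq_along(group_sizes), group_sizes)
  ord <- order(gid, u, method = "radix")
  open <- logical(n)
  open[ord] <- sequence(group_sizes) <= rep.int(k, group_sizes)
  open
}

# Precompute everything about a batch that is constant across trials:
# normalized categories, canonical stratum keys, the presorting
# permutation, stratum sizes, and the patient x subcategory indicator
# matrix (modality columns indicate possession, not primary).
prepare_batch <- function(batch, scheme, primary = NULL) {
  norm <- normalize_batch(batch, scheme, primary = primary)
  ord <- order(norm$stratum, norm$patient_id, method = "radix")
  sorted <- norm[ord, ]
  sizes <- rle(sorted$stratum)
  mods <- split_modalities(batch$modalities)[ord]
  subcat <- subcategory_table(scheme)
  M <- matrix(0, nrow = nrow(sorted), ncol = nrow(subcat))
  for (j in seq_len(nrow(subcat))) {
    v <- subcat$variable[j]
    M[, j] <- if (v == scheme$modality_variable) {
      vapply(mods, function(m) subcat$category[j] %in% m, logical(1))
    } else {
      sorted[[v]] == subcat$category[j]
    }
  }
  subcat$input_count <- as.integer(colSums(M))
  list(normalized = sorted, order = ord, n = nrow(sorted),
       group_keys = sizes$values, group_sizes = sizes$lengths,
       indicator = M, subcategories = subcat)
}

subcategory_table <- function(scheme) {
  tibble::tibble(
    variable = rep(names(scheme$variables), lengths(scheme$variables)),
    category = unlist(scheme$variables, use.names = FALSE))
}

#' Sequester an intake batch
#'
#' The full algorithm: (1) patients already in the registry keep their arm
#' (longitudinal carryover) and bypass splitting; (2) the remaining
#' patients are grouped into strata — unique combinations of one category
#' per scheme variable, with modality represented by the batch-level
#' primary modality — and each stratum is split at the open fraction by
#' randomized rounding; (3) the registry is extended with the new
#' assignments. Identical (batch, registry, scheme, seed) reproduce the
#' identical assignment, regardless of patient-row order.
#'
#' @param batch Patient batch tibble (see [read_batch()]).
#' @param registry Assignment registry (default: empty).
#' @param scheme A `stratseq_scheme`.
#' @param seed Integer master seed.
#' @param batch_label Label recorded in the registry provenance.
#' @param open_fraction Target open fraction; defaults to the scheme's.
#' @return A `stratseq_assignment`: list with `assignments` (tibble of
#'   `patient_id`, `arm`, `stratum`, `source`), the extended `registry`,
#'   `batch_label`, and `seed`.
#' @export
sequester_batch <- function(batch, registry = new_registry(),
                            scheme = default_scheme(), seed = 1L,
                            batch_label = "batch",
                            open_fraction = scheme$open_fraction) {
  validate_batch(batch, scheme)
  validate_registry(registry)
  existing <- registry_lookup(registry, batch$patient_id)
  carried <- !is.na(existing)

  assignments <- tibble::tibble(
    patient_id = batch$patient_id,
    arm = existing,
    stratum = NA_character_,
    source = ifelse(carried, "registry_carryover", "new_split"))

  if (any(!carried)) {
    primary <- resolve_primary_modality(batch) # prevalence over full batch
    prep <- prepare_batch(batch[!carried, , drop = FALSE], scheme,
                          primary = primary[batch$patient_id[!carried]])
    set.seed(strhash(seed, "sequester"))
    open <- stratified_open_mask(prep$group_sizes, open_fraction)
    arm_sorted <- ifelse(open, "open", "sequestered")
    i <- match(batch$patient_id[!carried], prep$normalized$patient_id)
    assignments$arm[!carried] <- arm_sorted[i]
    assignments$stratum[!carried] <- prep$normalized$stratum[i]
    registry <- registry_add(registry,
                             patient_id = batch$patient_id[!carried],
                             arm = assignments$arm[!carried],
                             batch_label = batch_label)
  }

  structure(list(assignments = assignments, registry = registry,
                 batch_label = batch_label, seed = seed,
                 open_fraction = open_fraction),
            class = "stratseq_assignment")
}

#' Naive 80:20 split of a batch
#'
#' The evaluation baseline: the whole batch is treated as a single stratum
#' under the same randomized-rounding count rule, so the two samplers
#' differ only in stratification. No registry interaction.
#'
#' @inheritParams sequester_batch
#' @return A `stratseq_assignment` (strata are `NA`; registry untouched).
#' @export
naive_split <- function(batch, open_fraction = 0.8, seed = 1L) {
  validate_batch(batch)
  ord <- order(batch$patient_id, method = "radix")
  set.seed(strhash(seed, "naive"))
  open <- stratified_open_mask(nrow(batch), open_fraction)
  arm <- character(nrow(batch))
  arm[ord] <- ifelse(open, "open", "sequestered")
  structure(list(
    assignments = tibble::tibble(patient_id = batch$patient_id, arm = arm,
                                 stratum = NA_character_,
                                 source = "new_split"),
    registry = NULL, batch_label = "naive", seed = seed,
    open_fraction = open_fraction),
    class = "stratseq_assignment")
}

#' @export
print.stratseq_assignment <- function(x, ...) {
  tab <- table(x$assignments$arm)
  cat("<stratseq_assignment> batch '", x$batch_label, "', ",
      nrow(x$assignments), " patients: ",
      paste(names(tab), tab, sep = " = ", collapse = ", "),
      " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Write a batch assignment to CSV
#'
#' @param assignment A `stratseq_assignment`.
#' @param path Output CSV path (columns `patient_id, arm, stratum, source`).
#' @export
write_assignment <- function(assignment, path) {
  stopifnot(inherits(assignment, "stratseq_assignment"))
  readr::write_csv(assignment$assignments, path, na = "")
  invisible(path)
}
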