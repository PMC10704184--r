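#' Reference marginal counts for the example 5000-patient cohort
#'
#' Marginal category counts of the example intake batch used throughout the
#' package: each demographic variable's counts sum to 5000, while modality
#' counts are possession counts (a patient may hold several modalities, so
#' they sum to more than 5000).
#'
#' @return Tibble with columns `variable`, `category`, `count`.
#' @export
reference_counts <- function() {
  scheme <- default_scheme()
  nr <- scheme$missing_label
  tibble::tibble(
    variable = rep(c("age_group", "race", "sex_at_birth", "ethnicity",
                     "covid_status", "modality"),
                   c(9L, 7L, 4L, 3L, 3L, 4L)),
    category = c(
      "[0, 18)", "[18, 30)", "[30, 40)", "[40, 50)", "[50, 65)",
      "[65, 75)", "[75, 85)", "[85, 140)", nr,
      "American Indian or Alaska Native", "Asian",
      "Black or African American",
      "Native Hawaiian or other Pacific Islander", "White", nr, "Other",
      "Female", "Male", "Other", nr,
      "Hispanic or Latino", "Not Hispanic or Latino", nr,
      "No", nr, "Yes",
      "CR", "CT", "DX", "MR"),
    count = c(74L, 393L, 529L, 687L, 1434L, 909L, 597L, 284L, 93L,
              17L, 294L, 1386L, 15L, 2568L, 554L, 166L,
              2533L, 2464L, 0L, 3L,
              499L, 4443L, 58L,
              2602L, 1L, 2397L,
              2049L, 910L, 2596L, 27L))
}

#' Specification for a synthetic patient cohort
#'
#' Defines the marginal distributions from which [generate_cohort()] draws:
#' per-variable category probabilities for the demographic variables and
#' per-modality inclusion probabilities (independent Bernoulli per
#' modality, so multi-modality patients arise naturally and the modality
#' probabilities need not sum to 1). Defaults are the reference cohort's
#' counts divided by its size. An optional conditional table lets one
#' demographic variable depend on another, for probing sensitivity to
#' joint structure.
#'
#' @param n_patients Number of patients.
#' @param demographic_probs Named list: variable -> named numeric vector of
#'   category probabilities (each summing to 1).
#' @param modality_probs Named numeric vector of per-modality inclusion
#'   probabilities, each in (0, 1].
#' @param conditional Optional list of specs `list(child=, parent=, table=)`
#'   where `table` is a category-by-category matrix with
#'   `table[i, j] = P(child = colnames[j] | parent = rownames[i])`; rows
#'   named by parent categories, columns by child categories.
#' @param seed Default seed used by [generate_cohort()].
#' @param scheme Scheme supplying variable names and age bins.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_patients = 5000, demographic_probs = NULL,
                        modality_probs = NULL, conditional = NULL,
                        seed = NULL, scheme = default_scheme()) {
  stopifnot(n_patients >= 1)
  counts <- reference_counts()
  demo_vars <- setdiff(names(scheme$variables), scheme$modality_variable)
  if (is.null(demographic_probs)) {
    demographic_probs <- lapply(demo_vars, function(v) {
      cc <- counts[counts$variable == v, ]
      stats::setNames(cc$count / sum(cc$count), cc$category)
    })
    names(demographic_probs) <- demo_vars
  }
  if (is.null(modality_probs)) {
    cc <- counts[counts$variable == scheme$modality_variable, ]
    ref_n <- sum(counts$count[counts$variable == demo_vars[1]])
    modality_probs <- stats::setNames(cc$count / ref_n, cc$category)
  }
  for (v in names(demographic_probs)) {
    p <- demographic_probs[[v]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("Probabilities for '", v, "' must be non-negative and sum to 1.",
           call. = FALSE)
    }
    if (!all(names(p) %in% scheme$variables[[v]])) {
      stop("Unknown categories in probabilities for '", v, "'.",
           call. = FALSE)
    }
  }
  if (any(modality_probs <= 0) || any(modality_probs > 1)) {
    stop("Modality inclusion probabilities must lie in (0, 1].",
         call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 demographic_probs = demographic_probs,
                 modality_probs = modality_probs,
                 conditional = conditional, seed = seed, scheme = scheme),
            class = "cohort_spec")
}

#' Generate a synthetic patient cohort
#'
#' Draws `n_patients` records with demographic fields sampled independently
#' per variable (or via the spec's conditional table where provided), ages
#' uniform within their sampled bin, and modality sets by independent
#' per-modality inclusion, re-drawn until non-empty. Fully reproducible
#' from the seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; overrides `spec$seed`.
#' @param id_prefix Prefix for generated patient ids.
#' @return A patient batch tibble.
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = spec$seed %||% 1L,
                            id_prefix = "SYN") {
  stopifnot(inherits(spec, "cohort_spec"))
  scheme <- spec$scheme
  n <- spec$n_patients
  set.seed(strhash(seed, "generate"))

  draws <- list()
  cond_children <- vapply(spec$conditional %||% list(),
                          function(cd) cd$child, character(1))
  for (v in names(spec$demographic_probs)) {
    if (v %in% cond_children) next
    p <- spec$demographic_probs[[v]]
    draws[[v]] <- sample(names(p), n, replace = TRUE, prob = p)
  }
  for (cd in spec$conditional %||% list()) {
    parent <- draws[[cd$parent]]
    if (is.null(parent)) {
      stop("Conditional parent '", cd$parent, "' must be drawn first.",
           call. = FALSE)
    }
    draws[[cd$child]] <- vapply(parent, function(pc) {
      pr <- cd$table[pc, ]
      sample(colnames(cd$table), 1, prob = pr)
    }, character(1))
  }

  age <- bin_to_age(draws[[scheme$age_variable]], scheme)

  codes <- names(spec$modality_probs)
  poss <- matrix(stats::rbinom(n * length(codes), 1L,
                               rep(spec$modality_probs, each = n)) == 1L,
                 nrow = n, dimnames = list(NULL, codes))
  repeat {
    empty <- which(rowSums(poss) == 0)
    if (length(empty) == 0) break
    poss[empty, ] <- stats::rbinom(length(empty) * length(codes), 1L,
                                   rep(spec$modality_probs,
                                       each = length(empty))) == 1L
  }

  tibble::tibble(
    patient_id = sprintf("%s-%06d", id_prefix, seq_len(n)),
    age = age,
    race = blank_missing(draws$race, scheme),
    sex_at_birth = blank_missing(draws$sex_at_birth, scheme),
    ethnicity = blank_missing(draws$ethnicity, scheme),
    covid_status = blank_missing(draws$covid_status, scheme),
    modalities = apply(poss, 1, function(r) paste(codes[r], collapse = ";")))
}

# Raw batches represent missingness as blank cells, not as the label.
blank_missing <- function(x, scheme) {
  ifelse(x == scheme$missing_label, NA_character_, x)
}

bin_to_age <- function(bin_labels, scheme) {
  labels <- age_bin_labels(scheme)
  lo <- scheme$age_bins[-length(scheme$age_bins)]
  hi <- scheme$age_bins[-1]
  i <- match(bin_labels, labels)
  age <- rep(NA_real_, length(bin_labels))
  ok <- !is.na(i)
  age[ok] <- stats::runif(sum(ok), lo[i[ok]], hi[i[ok]])
  age
}

#' Generate a cohort with exact marginal counts
#'
#' Fills each demographic variable by an independent random permutation of
#' the target category multiset, so every marginal count is reproduced
#' verbatim. Modality possession sets are drawn as uniform subsets of
#' exactly the target size per modality; patients left with an empty
#' modality set are repaired by transferring one modality from a
#' multi-modality donor, which preserves every per-modality count and the
#' at-least-one-modality invariant.
#'
#' @param counts Tibble of `variable`, `category`, `count` targets
#'   (default: [reference_counts()]). Demographic variables must each sum
#'   to the same total n; modality counts must sum to at least n.
#' @param seed Integer seed.
#' @param scheme A `stratseq_scheme`.
#' @param id_prefix Prefix for generated patient ids.
#' @return A patient batch tibble with exact marginals.
#' @export
exact_marginal_cohort <- function(counts = reference_counts(), seed = 1L,
                                  scheme = default_scheme(),
                                  id_prefix = "FIX") {
  demo_vars <- setdiff(names(scheme$variables), scheme$modality_variable)
  totals <- vapply(demo_vars, function(v)
    sum(counts$count[counts$variable == v]), numeric(1))
  if (length(unique(totals)) != 1) {
    stop("Demographic variable counts must all sum to the same total ",
         "(got ", paste(demo_vars, totals, sep = "=", collapse = ", "),
         ").", call. = FALSE)
  }
  n <- as.integer(totals[[1]])
  set.seed(strhash(seed, "exact_marginal"))

  cols <- lapply(demo_vars, function(v) {
    cc <- counts[counts$variable == v, ]
    bad <- cc$count != round(cc$count) | cc$count < 0
    if (any(bad)) stop("Counts for '", v, "' must be non-negative integers.",
                       call. = FALSE)
    sample(rep(cc$category, cc$count))
  })
  names(cols) <- demo_vars

  age <- bin_to_age(cols[[scheme$age_variable]], scheme)

  mc <- counts[counts$variable == scheme$modality_variable, ]
  if (sum(mc$count) < n || any(mc$count > n)) {
    stop("Modality counts must each be <= n and sum to at least n.",
         call. = FALSE)
  }
  poss <- matrix(FALSE, nrow = n, ncol = nrow(mc),
                 dimnames = list(NULL, mc$category))
  for (j in seq_len(nrow(mc))) {
    poss[sample.int(n, mc$count[j]), j] <- TRUE
  }
  rs <- rowSums(poss)
  for (e in which(rs == 0)) {
    donors <- which(rs >= 2)
    if (length(donors) == 0) {
      stop("Cannot repair empty modality sets: no multi-modality donors.",
           call. = FALSE)
    }
    d <- donors[sample.int(length(donors), 1)]
    mo <- which(poss[d, ])
    mo <- mo[sample.int(length(mo), 1)]
    poss[d, mo] <- FALSE
    poss[e, mo] <- TRUE
    rs[d] <- rs[d] - 1L
    rs[e] <- 1L
  }

  tibble::tibble(
    patient_id = sprintf("%s-%06d", id_prefix, seq_len(n)),
    age = age,
    race = blank_missing(cols$race, scheme),
    sex_at_birth = blank_missing(cols$sex_at_birth, scheme),
    ethnicity = blank_missing(cols$ethnicity, scheme),
    covid_status = blank_missing(cols$covid_status, scheme),
    modalities = apply(poss, 1, function(r)
      paste(colnames(poss)[r], collapse = ";")))
}
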