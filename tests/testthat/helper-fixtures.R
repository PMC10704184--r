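# Shared fixtures, built in code at test time.

# One-row-per-patient batch builder with sensible defaults.
make_batch <- function(patient_id, age = 40, race = "White",
                       sex_at_birth = "Female",
                       ethnicity = "Not Hispanic or Latino",
                       covid_status = "No", modalities = "CR") {
  tibble::tibble(patient_id = patient_id, age = age, race = race,
                 sex_at_birth = sex_at_birth, ethnicity = ethnicity,
                 covid_status = covid_status, modalities = modalities)
}

# Small synthetic cohort with the default marginals. Ids embed the seed so
# cohorts drawn with different seeds never share patients.
small_cohort <- function(n = 200, seed = 42) {
  generate_cohort(cohort_spec(n_patients = n), seed = seed,
                  id_prefix = sprintf("S%03d", seed))
}

# The 5000-patient exact-marginal reference cohort, built once per run.
ref_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- exact_marginal_cohort(seed = 101)
    cache
  }
})

# A three-variable toy scheme for arithmetic checks (2 x 3 x 5 categories).
toy_scheme <- function() {
  category_scheme(
    variables = list(
      a = c("a1", "Not reported"),
      b = c("b1", "b2", "Not reported"),
      c = c("c1", "c2", "c3", "c4", "Not reported")),
    age_bins = c(0, 140),
    age_variable = "zz_unused", modality_variable = "zz_unused_m")
}
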