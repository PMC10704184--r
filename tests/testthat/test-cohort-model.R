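test_that("default scheme reproduces the published category structure", {
  scheme <- default_scheme()
  expect_identical(unname(lengths(scheme$variables)),
                   c(9L, 7L, 4L, 3L, 3L, 4L))
  expect_equal(count_strata(scheme), 9072)
  # every demographic variable carries the missing-value category
  for (v in setdiff(names(scheme$variables), "modality")) {
    expect_true("Not reported" %in% scheme$variables[[v]])
  }
  expect_false("Not reported" %in% scheme$variables$modality)
})

test_that("count_strata is the size of the category cross-product", {
  # independent oracle: enumerate the cross-product and count rows
  toy <- toy_scheme()
  enumerated <- nrow(expand.grid(toy$variables))
  expect_equal(count_strata(toy), enumerated)
  expect_equal(count_strata(toy), 30)
  single <- category_scheme(list(modality = c("CR", "CT", "DX", "MR")),
                            age_bins = c(0, 140),
                            age_variable = "zz")
  expect_equal(count_strata(single), 4)
})

test_that("ages map to the published bins with half-open edges", {
  scheme <- default_scheme()
  expect_equal(categorize_age(17, scheme), "[0, 18)")
  expect_equal(categorize_age(65, scheme), "[65, 75)") # lower edge inclusive
  expect_equal(categorize_age(NA_real_, scheme), "Not reported")
  expect_equal(categorize_age(0, scheme), "[0, 18)")
  expect_equal(categorize_age(139.99, scheme), "[85, 140)")
})

test_that("every age in [0, 140) falls in exactly one bin", {
  scheme <- default_scheme()
  grid <- sort(c(seq(0, 139.9, by = 0.7), scheme$age_bins[-9],
                 scheme$age_bins[-9] - 1e-9))
  grid <- grid[grid >= 0 & grid < 140]
  labels <- categorize_age(grid, scheme)
  bins <- age_bin_labels(scheme)
  expect_true(all(labels %in% bins))
  # bin membership agrees with interval arithmetic, bin by bin
  lo <- scheme$age_bins[-9]
  hi <- scheme$age_bins[-1]
  hits <- vapply(grid, function(a) sum(a >= lo & a < hi), numeric(1))
  expect_true(all(hits == 1))
})

test_that("out-of-range ages are rejected naming the patient", {
  expect_error(categorize_age(140, patient_id = "p9"), "p9")
  expect_error(categorize_age(-3), "-3")
  b <- make_batch("p1", age = 141)
  expect_error(validate_batch(b), "p1")
})

test_that("normalization trims, case-folds, and maps blanks to Not reported", {
  r <- make_batch("p1", age = 34, race = "white ", sex_at_birth = "Female",
                  ethnicity = NA, covid_status = "Yes", modalities = "CR")
  key <- normalize_record(r, primary_modality = "CR")
  expect_identical(
    unname(key),
    c("[30, 40)", "White", "Female", "Not reported", "Yes", "CR"))
  all_blank <- make_batch("p2", age = NA, race = NA, sex_at_birth = NA,
                          ethnicity = NA, covid_status = NA,
                          modalities = "DX")
  key2 <- normalize_record(all_blank, primary_modality = "DX")
  expect_identical(unname(key2), c(rep("Not reported", 5), "DX"))
})

test_that("field normalization is idempotent", {
  raw <- make_batch(c("p1", "p2"), age = c(34, NA),
                    race = c(" BLACK or african AMERICAN ", NA),
                    covid_status = c("yes", "no"),
                    modalities = c("CR;DX", "MR"))
  n1 <- normalize_batch(raw)
  # feed normalized categories back through as raw values
  raw2 <- make_batch(c("p1", "p2"), age = c(34, NA), race = n1$race,
                     sex_at_birth = n1$sex_at_birth,
                     ethnicity = n1$ethnicity, covid_status = n1$covid_status,
                     modalities = c("CR;DX", "MR"))
  raw2$ethnicity[n1$ethnicity == "Not reported"] <- NA # blanks stay blank
  n2 <- normalize_batch(raw2)
  expect_identical(n1$stratum, n2$stratum)
})

test_that("unknown vocabulary values are validation errors, not coercions", {
  b <- make_batch("p1", race = "Martian")
  expect_error(normalize_batch(b), "Martian")
  b2 <- make_batch("p1", covid_status = "Positive")
  expect_error(normalize_batch(b2), "Positive")
})

test_that("batch validation names missing columns and duplicate ids", {
  b <- make_batch(c("p1", "p2"))
  expect_error(validate_batch(b[, setdiff(names(b), "ethnicity")]),
               "ethnicity")
  expect_error(validate_batch(make_batch(c("p1", "p1"))), "p1")
  expect_error(validate_batch(make_batch("p1", modalities = "")), "p1")
})

test_that("stratum keys are equal iff all categorized variables are equal", {
  b <- make_batch(c("p1", "p2", "p3"), age = c(30, 35, 30),
                  covid_status = c("Yes", "Yes", "No"))
  n <- normalize_batch(b)
  expect_identical(n$stratum[1], n$stratum[2]) # same bins everywhere
  expect_false(n$stratum[1] == n$stratum[3])   # differs in one component
})

test_that("scheme JSON round-trips losslessly", {
  path <- withr::local_tempfile(fileext = ".json")
  scheme <- default_scheme(open_fraction = 0.75,
                           site_categories = c("site_a", "site_b"))
  write_scheme(scheme, path)
  expect_identical(unclass(read_scheme(path)), unclass(scheme))
})

test_that("the registry round-trips and refuses arm changes", {
  path <- withr::local_tempfile(fileext = ".csv")
  reg <- registry_add(new_registry(), c("p1", "p2"),
                      c("open", "sequestered"), "b1",
                      timestamp = "2026-01-01T00:00:00+0000")
  write_registry(reg, path)
  expect_identical(as.data.frame(read_registry(path)), as.data.frame(reg))
  # re-adding with the same arm is a no-op; flipping is an error
  expect_identical(registry_add(reg, "p1", "open", "b2"), reg)
  expect_error(registry_add(reg, "p1", "sequestered", "b2"), "p1")
})
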