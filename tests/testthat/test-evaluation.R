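test_that("scaled difference from expectation evaluates the published formula", {
  expect_equal(scaled_difference(0.8, 500, 390), 0.025)
  expect_equal(scaled_difference(0.8, 500, 400), 0) # N_open = f N_T exactly
  expect_equal(scaled_difference(0.8, 10, 0), 1) # |8 - 0| / 8
  expect_error(scaled_difference(0.8, 0, 0), "zero input count")
  expect_error(scaled_difference(0.8, 10, 11), "n_open")
})

test_that("scaled difference is symmetric about the expected count", {
  withr::with_seed(2, {
    for (i in 1:50) {
      nt <- sample(5:200, 1)
      f <- stats::runif(1, 0.3, 0.9)
      n_open <- sample(0:nt, 1)
      mirror <- 2 * f * nt - n_open
      if (mirror >= 0 && mirror <= nt) {
        expect_equal(scaled_difference(f, nt, n_open),
                     scaled_difference(f, nt, mirror))
      }
    }
  })
})

test_that("Mann-Whitney exact path enumerates the permutation distribution", {
  res <- mann_whitney_one_tailed(c(1, 2), c(3, 4))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1 / 6) # all C(4,2) = 6 rank assignments
  expect_equal(res$method, "exact enumeration")
  # identical multisets give no evidence for "less"
  same <- mann_whitney_one_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.5)
  expect_warning(deg <- mann_whitney_one_tailed(rep(1, 5), rep(1, 4)),
                 "degenerate")
  expect_equal(deg$p_value, 1)
})

test_that("exact path matches wilcox.test where wilcox.test can be exact", {
  withr::with_seed(5, {
    for (i in 1:20) {
      x <- stats::rnorm(sample(3:10, 1)) # continuous: no ties
      y <- stats::rnorm(sample(3:10, 1))
      ours <- mann_whitney_one_tailed(x, y)
      ref <- stats::wilcox.test(x, y, alternative = "less", exact = TRUE)
      expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
      expect_equal(ours$statistic, unname(ref$statistic))
    }
  })
})

test_that("approximate path agrees with the exact enumeration within 0.01", {
  # oracle comparison at 10 vs 10, the largest size the exact path covers
  withr::with_seed(6, {
    for (i in 1:20) {
      x <- stats::rnorm(10)
      y <- stats::rnorm(10)
      exact <- mann_whitney_one_tailed(x, y, exact = TRUE)$p_value
      approx <- mann_whitney_one_tailed(x, y, exact = FALSE)$p_value
      expect_lt(abs(exact - approx), 0.01)
    }
  })
})

test_that("approximate path matches wilcox.test's tie-corrected normal form", {
  withr::with_seed(8, {
    x <- sample(0:10, 60, replace = TRUE)
    y <- sample(2:12, 55, replace = TRUE)
    ours <- mann_whitney_one_tailed(x, y)
    ref <- stats::wilcox.test(x, y, alternative = "less", exact = FALSE,
                              correct = TRUE)
    expect_equal(ours$method, "normal approximation")
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
  })
})

test_that("Holm flags match hand-computed step-down thresholds", {
  # thresholds alpha/(m - i + 1) over the ascending p-values
  expect_identical(holm_bonferroni(c(0.001, 0.02, 0.04), alpha = 0.05),
                   c(TRUE, TRUE, TRUE))
  expect_identical(holm_bonferroni(c(0.04, 0.04), alpha = 0.05),
                   c(FALSE, FALSE)) # first tested at 0.025, step-down stops
  expect_identical(holm_bonferroni(0.049, alpha = 0.05), TRUE)
})

test_that("Holm flags are monotone in the p-values", {
  withr::with_seed(9, {
    for (i in 1:25) {
      p <- stats::runif(sample(3:12, 1))^2
      flags <- holm_bonferroni(p)
      if (any(flags)) expect_true(all(flags[p < max(p[flags])]))
    }
  })
})

test_that("trial ensembles are reproducible and conserve counts", {
  b <- small_cohort(n = 150, seed = 20)
  e1 <- run_trials(b, sampler = "stratified", n_trials = 25, master_seed = 7)
  e2 <- run_trials(b, sampler = "stratified", n_trials = 25, master_seed = 7)
  expect_identical(e1$open_counts, e2$open_counts)
  # open + sequestered = N_T for every trial and subcategory, by construction;
  # arm sizes partition the batch
  expect_true(all(e1$open_sizes >= 0 & e1$open_sizes <= nrow(b)))
  expect_true(all(t(e1$open_counts) <= e1$subcategories$input_count))
  # demographic subcategory counts sum to the arm size within each trial
  demo <- e1$subcategories$variable == "sex_at_birth"
  expect_equal(unname(rowSums(e1$open_counts[, demo])), e1$open_sizes)
})

test_that("prevalence summary recovers arm shares from the counts", {
  ens <- structure(list(
    sampler = "stratified", n_trials = 1L, open_fraction = 0.8,
    n_patients = 10L, master_seed = 1L,
    subcategories = tibble::tibble(variable = "sex_at_birth",
                                   category = "Female", input_count = 5L),
    open_counts = matrix(4L, 1, 1), open_sizes = 8L),
    class = "trial_ensemble")
  ps <- prevalence_summary(ens)
  expect_equal(ps$open_mean, 50)            # 4 of 8 open patients
  expect_equal(ps$sequestered_mean, 50)     # 1 of 2 sequestered
  expect_equal(ps$open_sd, 0)               # single trial
  ens2 <- ens
  ens2$n_trials <- 3L
  ens2$open_counts <- matrix(4L, 3, 1)      # identical trials
  ens2$open_sizes <- rep(8L, 3)
  ps2 <- prevalence_summary(ens2)
  expect_equal(ps2$open_sd, 0)
  expect_equal(ps2$sequestered_sd, 0)
})

test_that("stratified ensembles preserve input prevalences on average", {
  b <- ref_cohort()
  ens <- run_trials(b, sampler = "stratified", n_trials = 500,
                    master_seed = 23)
  ps <- prevalence_summary(ens)
  common <- ps$input_count >= 50
  mc_se <- ps$open_sd / sqrt(ens$n_trials)
  expect_true(all(abs(ps$open_mean[common] - ps$input_prevalence[common])
                  <= 3 * mc_se[common]))
})

test_that("stratified sampling beats naive randomization where it has power", {
  b <- ref_cohort()
  rep <- compare_samplers(b, n_trials = 500, master_seed = 29)
  expect_equal(attr(rep, "n_comparisons"), 29)
  # power separation: categories that are common but not near-universal
  # (for a category covering most of the batch, the open count is the
  # complement of a small remainder and stratification cannot narrow it)
  powered <- rep$input_count >= 150 & rep$input_count <= 0.8 * 5000
  expect_true(all(rep$p_value[powered] < 0.05))
  # rare categories live in singleton-dominated strata, where stratified
  # assignment degenerates to per-patient Bernoulli draws: no reliable
  # separation, hence never significant after Holm correction
  rare <- rep$category %in% c("American Indian or Alaska Native",
                              "Native Hawaiian or other Pacific Islander")
  expect_true(all(!rep$significant[rare]))
  expect_true(all(rep$p_value[rare] > min(rep$p_value[powered])))
  # untestable subcategory: zero input count
  other_sex <- rep$variable == "sex_at_birth" & rep$category == "Other"
  expect_true(is.na(rep$p_value[other_sex]))
  expect_true(is.na(rep$significant[other_sex]))
})

test_that("a single-category variable shows no sampler difference", {
  b <- small_cohort(n = 250, seed = 33)
  b$sex_at_birth <- "Female" # lone subcategory: identical global count rule
  rep <- compare_samplers(b, n_trials = 120, master_seed = 3)
  j <- rep$variable == "sex_at_birth" & rep$category == "Female"
  expect_gte(rep$p_value[j], 0.05)
})

test_that("p-value formatting floors at the reporting granularity", {
  expect_identical(format_p_value(c(0.003, 0.29, NA)),
                   c("p < 0.01", "p = 0.29", "N/A"))
})

test_that("histogram reports overlay both samplers with shared bins", {
  b <- small_cohort(n = 200, seed = 40)
  s <- run_trials(b, sampler = "stratified", n_trials = 60, master_seed = 2)
  n <- run_trials(b, sampler = "naive", n_trials = 60, master_seed = 2)
  p <- histogram_report(s, n, "sex_at_birth")
  expect_s3_class(p, "ggplot")
  expect_setequal(unique(p$data$sampler), c("stratified", "naive"))
  dir <- withr::local_tempdir()
  paths <- save_histogram_reports(s, n, default_scheme(), dir,
                                  device = "pdf")
  expect_true(length(paths) >= 5)
  expect_true(all(file.exists(paths)))
})
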