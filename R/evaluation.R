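#' Scaled difference from expectation
#'
#' For a subcategory with `N_T` patients in the input batch, the expected
#' open-arm count at open fraction `f` is `f * N_T`; the scaled difference
#' is the relative deviation of the realized count from that expectation:
#' `|f * N_T - N_open| / (f * N_T)`. Zero means a perfectly proportional
#' split; 1 means the subcategory was entirely missed (or doubly
#' over-represented).
#'
#' @param f Open fraction in (0, 1).
#' @param n_total Input count(s) `N_T`; must be >= 1.
#' @param n_open Realized open-arm count(s), in `[0, N_T]`.
#' @return Non-negative numeric vector.
#' @examples
#' scaled_difference(0.8, 500, 390) # 0.025
#' @export
scaled_difference <- function(f, n_total, n_open) {
  stopifnot(f > 0, f < 1)
  if (any(n_total < 1)) {
    stop("scaled_difference is undefined for subcategories with zero ",
         "input count; mark them N/A instead.", call. = FALSE)
  }
  if (any(n_open < 0 | n_open > n_total)) {
    stop("n_open must lie in [0, n_total].", call. = FALSE)
  }
  abs(f * n_total - n_open) / (f * n_total)
}

#' Run repeated independent splits of one batch
#'
#' Applies the chosen sampler to the same input batch for `n_trials`
#' independent trials, each with its own seed derived deterministically
#' from the master seed and the trial index. Registry carryover is
#' disabled: every trial is a fresh split of the full batch. Per trial the
#' ensemble records the open-arm count of every subcategory of every
#' scheme variable (modality counts are possession counts) plus the
#' open-arm size.
#'
#' @param batch Patient batch tibble.
#' @param scheme A `stratseq_scheme`.
#' @param sampler `"stratified"` or `"naive"`.
#' @param n_trials Number of independent trials (>= 1).
#' @param master_seed Integer master seed.
#' @param open_fraction Target open fraction; defaults to the scheme's.
#' @return A `trial_ensemble`: list with `sampler`, `n_trials`,
#'   `open_fraction`, `n_patients`, `master_seed`, `subcategories`
#'   (tibble with `variable`, `category`, `input_count`), `open_counts`
#'   (trials x subcategories matrix), and `open_sizes`.
#' @export
run_trials <- function(batch, scheme = default_scheme(),
                       sampler = c("stratified", "naive"), n_trials = 2000,
                       master_seed = 1L,
                       open_fraction = scheme$open_fraction) {
  sampler <- match.arg(sampler)
  stopifnot(n_trials >= 1)
  prep <- prepare_batch(batch, scheme)
  sizes <- if (sampler == "stratified") prep$group_sizes else prep$n

  open_counts <- matrix(0L, nrow = n_trials, ncol = nrow(prep$subcategories))
  open_sizes <- integer(n_trials)
  for (t in seq_len(n_trials)) {
    set.seed(strhash(master_seed, sampler, t))
    open <- stratified_open_mask(sizes, open_fraction)
    open_counts[t, ] <- as.integer(crossprod(prep$indicator, open))
    open_sizes[t] <- sum(open)
  }
  colnames(open_counts) <- paste(prep$subcategories$variable,
                                 prep$subcategories$category, sep = ":")
  structure(list(sampler = sampler, n_trials = as.integer(n_trials),
                 open_fraction = open_fraction, n_patients = prep$n,
                 master_seed = master_seed,
                 subcategories = prep$subcategories,
                 open_counts = open_counts, open_sizes = open_sizes),
            class = "trial_ensemble")
}

#' @export
print.trial_ensemble <- function(x, ...) {
  cat("<trial_ensemble> ", x$sampler, " sampler, ", x$n_trials,
      " trials on ", x$n_patients, " patients (f = ", x$open_fraction,
      ", master seed ", x$master_seed, ")\n", sep = "")
  invisible(x)
}

#' Per-subcategory prevalence summary over an ensemble
#'
#' Within each trial, a subcategory's prevalence in an arm is its patient
#' count in that arm divided by the arm size (so modality prevalences may
#' sum past 100% across modalities). The summary reports the mean and
#' sample SD across trials, in percent, for both arms, next to the input
#' prevalence.
#'
#' @param ensemble A `trial_ensemble`.
#' @return Tibble with one row per subcategory: `variable`, `category`,
#'   `input_count`, `input_prevalence`, `open_mean`, `open_sd`,
#'   `sequestered_mean`, `sequestered_sd` (all prevalences in percent).
#' @export
prevalence_summary <- function(ensemble) {
  stopifnot(inherits(ensemble, "trial_ensemble"))
  n <- ensemble$n_patients
  open_prev <- 100 * ensemble$open_counts / ensemble$open_sizes
  seq_sizes <- n - ensemble$open_sizes
  seq_counts <- sweep(-ensemble$open_counts, 2,
                      ensemble$subcategories$input_count, `+`)
  seq_prev <- 100 * seq_counts / seq_sizes
  sd0 <- function(m) if (nrow(m) > 1) apply(m, 2, stats::sd) else
    rep(0, ncol(m))
  dplyr::mutate(ensemble$subcategories,
                input_prevalence = 100 * .data$input_count / n,
                open_mean = colMeans(open_prev),
                open_sd = sd0(open_prev),
                sequestered_mean = colMeans(seq_prev),
                sequestered_sd = sd0(seq_prev))
}

#' Scaled-difference samples from an ensemble
#'
#' Evaluates the scaled difference from expectation for every trial and
#' subcategory, on either arm (for the sequestered arm the expectation is
#' `(1 - f) * N_T`). Columns for subcategories with zero input count are
#' `NA` — the statistic is undefined there.
#'
#' @param ensemble A `trial_ensemble`.
#' @param arm `"open"` or `"sequestered"`.
#' @return Numeric matrix, trials x subcategories.
#' @export
scaled_difference_samples <- function(ensemble, arm = c("open", "sequestered")) {
  arm <- match.arg(arm)
  nt <- ensemble$subcategories$input_count
  f <- ensemble$open_fraction
  counts <- ensemble$open_counts
  if (arm == "sequestered") {
    counts <- sweep(-counts, 2, nt, `+`)
    f <- 1 - f
  }
  expected <- f * nt
  out <- abs(sweep(counts, 2, expected, `-`))
  out <- sweep(out, 2, expected, `/`)
  out[, nt == 0] <- NA_real_
  out
}

#' One-tailed Mann-Whitney U test (x stochastically less than y)
#'
#' Rank-sum U with midrank tie handling. The alternative hypothesis is
#' that values in `x` tend to be smaller than values in `y` (small U).
#' When both samples have at most 10 observations the p-value is computed
#' by exact enumeration of the permutation distribution (valid under
#' ties); otherwise a normal approximation with tie-corrected variance and
#' continuity correction is used.
#'
#' @param x,y Numeric samples (e.g., scaled differences under the
#'   stratified and naive samplers).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact path;
#'   `NULL` picks automatically.
#' @return List with `statistic` (U for `x`), `p_value`, and `method`.
#' @examples
#' mann_whitney_one_tailed(c(1, 2), c(3, 4))$p_value # 1/6
#' @export
mann_whitney_one_tailed <- function(x, y, exact = NULL) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  m <- length(x)
  n <- length(y)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1) {
    warning("All values identical across both samples; test is degenerate.",
            call. = FALSE)
    return(list(statistic = m * n / 2, p_value = 1,
                method = "degenerate"))
  }
  r <- rank(pooled) # midranks
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  use_exact <- exact %||% (m <= 10 && n <= 10)

  if (use_exact) {
    combs <- utils::combn(m + n, m)
    u_all <- colSums(matrix(r[combs], nrow = m)) - m * (m + 1) / 2
    p <- mean(u_all <= u_obs)
    method <- "exact enumeration"
  } else {
    nn <- m + n
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- m * n / 12 * (nn + 1 - tie_term)
    if (sigma2 <= 0) {
      warning("Zero variance after tie correction; test is degenerate.",
              call. = FALSE)
      return(list(statistic = u_obs, p_value = 1, method = "degenerate"))
    }
    z <- (u_obs - m * n / 2 + 0.5) / sqrt(sigma2)
    p <- stats::pnorm(z)
    method <- "normal approximation"
  }
  list(statistic = u_obs, p_value = p, method = method)
}

#' Holm-Bonferroni significance flags
#'
#' Standard Holm step-down: with m p-values sorted ascending, the i-th
#' smallest is tested against `alpha / (m - i + 1)` and the procedure
#' stops at the first failure. Equivalently (as implemented here), a
#' hypothesis is rejected when its Holm-adjusted p-value from
#' [stats::p.adjust()] falls below `alpha`. Exclude N/A entries before
#' calling.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param alpha Family-wise significance level.
#' @return Logical vector of flags, in input order.
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "holm") < alpha
}

#' Compare the stratified and naive samplers on one batch
#'
#' Runs both samplers for `n_trials` independent trials on the same batch,
#' computes per-subcategory scaled-difference samples on the chosen arm,
#' and tests — one-tailed Mann-Whitney U — whether stratified sampling
#' yields smaller deviations than naive randomization, with
#' Holm-Bonferroni correction across all testable subcategories.
#' Subcategories with zero input count are untestable and marked N/A.
#'
#' @inheritParams run_trials
#' @param alpha Family-wise significance level.
#' @param arm Arm on which scaled differences are evaluated.
#' @return A `comparison_report` tibble: `variable`, `category`,
#'   `input_count`, `p_value` (NA where untestable), `significant`
#'   (Holm-corrected flag). Attributes carry `n_trials`, `alpha`, `arm`,
#'   `master_seed`, and `n_comparisons`.
#' @export
compare_samplers <- function(batch, scheme = default_scheme(),
                             n_trials = 2000, master_seed = 1L,
                             alpha = 0.05,
                             open_fraction = scheme$open_fraction,
                             arm = c("open", "sequestered")) {
  arm <- match.arg(arm)
  strat <- run_trials(batch, scheme, "stratified", n_trials, master_seed,
                      open_fraction)
  naiv <- run_trials(batch, scheme, "naive", n_trials, master_seed,
                     open_fraction)
  sd_strat <- scaled_difference_samples(strat, arm)
  sd_naive <- scaled_difference_samples(naiv, arm)

  report <- strat$subcategories
  report$p_value <- NA_real_
  testable <- which(report$input_count > 0)
  for (j in testable) {
    report$p_value[j] <- mann_whitney_one_tailed(
      sd_strat[, j], sd_naive[, j])$p_value
  }
  report$significant <- NA
  report$significant[testable] <-
    holm_bonferroni(report$p_value[testable], alpha)

  structure(report, class = c("comparison_report", class(report)),
            n_trials = n_trials, alpha = alpha, arm = arm,
            master_seed = master_seed, n_comparisons = length(testable))
}

#' Format p-values for reporting
#'
#' Prints full-precision p-values floored at 0.01 (`"p < 0.01"`), the
#' granularity conventional in summary tables.
#'
#' @param p Numeric p-values (NA allowed).
#' @return Character vector, `"N/A"` where `p` is NA.
#' @export
format_p_value <- function(p) {
  ifelse(is.na(p), "N/A",
         ifelse(p < 0.01, "p < 0.01", sprintf("p = %.2f", p)))
}
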