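# Report writers: provenance-stamped CSVs and scaled-difference histograms.

#' Write an evaluation table with a provenance header
#'
#' Prepends `#`-comment lines recording the master seed and trial count,
#' then the CSV body. Files written this way re-read with
#' `readr::read_csv(..., comment = "#")`.
#'
#' @param table A tibble (e.g., from [prevalence_summary()] or
#'   [compare_samplers()]).
#' @param path Output path.
#' @param master_seed,n_trials Provenance recorded in the header.
#' @export
write_report_csv <- function(table, path, master_seed = NA, n_trials = NA) {
  header <- sprintf("# master_seed=%s n_trials=%s", master_seed, n_trials)
  writeLines(header, path)
  readr::write_csv(tibble::as_tibble(table), path, na = "", append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' Paired histograms of scaled difference from expectation
#'
#' For one scheme variable, overlays the per-trial scaled-difference
#' distributions of the stratified and naive samplers, one panel per
#' subcategory. A narrower histogram indicates better balance. Bin widths
#' follow Freedman-Diaconis on the pooled samples, shared across the two
#' samplers within a panel so widths are visually comparable.
#'
#' @param stratified,naive `trial_ensemble` objects computed on the same
#'   input batch.
#' @param variable Scheme variable to plot.
#' @param arm Arm on which scaled differences are evaluated.
#' @return A ggplot object (one facet per subcategory).
#' @export
histogram_report <- function(stratified, naive, variable,
                             arm = c("open", "sequestered")) {
  arm <- match.arg(arm)
  stopifnot(inherits(stratified, "trial_ensemble"),
            inherits(naive, "trial_ensemble"),
            stratified$n_patients == naive$n_patients)
  sub <- stratified$subcategories
  keep <- which(sub$variable == variable & sub$input_count > 0)
  if (length(keep) == 0) {
    stop("No testable subcategories for variable '", variable, "'.",
         call. = FALSE)
  }
  sd_s <- scaled_difference_samples(stratified, arm)
  sd_n <- scaled_difference_samples(naive, arm)
  # Bin per subcategory with Freedman-Diaconis on the pooled pair; the two
  # samplers share breaks within a panel so widths are visually comparable.
  df <- dplyr::bind_rows(lapply(keep, function(j) {
    pooled <- c(sd_s[, j], sd_n[, j])
    w <- 2 * stats::IQR(pooled) / length(pooled)^(1 / 3)
    if (w <= 0) w <- max(diff(range(pooled)) / 30, 1e-4)
    breaks <- seq(0, max(pooled) + w, by = w)
    dplyr::bind_rows(lapply(list(stratified = sd_s[, j],
                                 naive = sd_n[, j]), function(v) {
      h <- graphics::hist(v, breaks = breaks, plot = FALSE)
      tibble::tibble(xmin = utils::head(h$breaks, -1),
                     xmax = utils::tail(h$breaks, -1),
                     count = h$counts)
    }), .id = "sampler") |>
      dplyr::mutate(category = sub$category[j])
  }))
  ggplot2::ggplot(df, ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                   ymin = 0, ymax = .data$count,
                                   fill = .data$sampler)) +
    ggplot2::geom_rect(position = "identity", alpha = 0.55) +
    ggplot2::facet_wrap(~category, scales = "free") +
    ggplot2::labs(
      x = "Scaled difference from expectation",
      y = "Trials",
      title = paste0("Scaled difference from expectation: ", variable,
                     " (", arm, " arm)")) +
    ggplot2::theme_minimal()
}

#' Save per-variable histogram reports
#'
#' Writes one figure per scheme variable into `dir`.
#'
#' @inheritParams histogram_report
#' @param scheme The scheme whose variables are plotted.
#' @param dir Output directory (created if absent).
#' @param device Graphics device passed to [ggplot2::ggsave()] (`"pdf"`
#'   needs no system graphics libraries; `"png"`/`"svg"` where available).
#' @return Invisibly, the paths written.
#' @export
save_histogram_reports <- function(stratified, naive, scheme, dir,
                                   arm = "open", device = "pdf") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (v in names(scheme$variables)) {
    p <- tryCatch(histogram_report(stratified, naive, v, arm),
                  error = function(e) NULL)
    if (is.null(p)) next
    path <- file.path(dir, paste0("scaled_difference_", v, ".", device))
    ggplot2::ggsave(path, p, width = 9, height = 6, device = device)
    paths <- c(paths, path)
  }
  invisible(paths)
}
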