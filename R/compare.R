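# Paired-method agreement statistics: Pearson R^2, Bland-Altman limits of
# agreement, signed percent difference.

# Paired tables are (id, A, B, ...): with three or more columns the first is
# the specimen id; with exactly two, both are the measurements.
paired_columns <- function(pairs) {
  if (!is.data.frame(pairs))
    stop_precondition("pairs must be a data frame (id, ecd_a, ecd_b)")
  meas <- if (ncol(pairs) >= 3) pairs[-1] else pairs
  num <- meas[vapply(meas, is.numeric, logical(1))]
  if (ncol(num) < 2)
    stop_precondition("paired table needs two numeric measurement columns")
  list(a = num[[1]], b = num[[2]])
}

#' Read a paired ECD table from CSV
#'
#' Expects columns id, method-A ECD, method-B ECD (by position; extra
#' columns are kept). ECD values must be positive and at least two rows are
#' required.
#'
#' @param path CSV file path.
#' @return Data frame of the paired measurements.
#' @export
read_paired_ecd <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  tab <- read.csv(path)
  cols <- paired_columns(tab)
  if (length(cols$a) < 2) stop_precondition("paired table needs n >= 2 rows")
  if (any(cols$a <= 0) || any(cols$b <= 0))
    stop_precondition("ECD values must be > 0")
  tab
}

#' Squared Pearson correlation of paired measurements
#'
#' @param pairs data frame whose first two numeric columns are the paired
#'   measurements (method A, method B); n >= 3 with nonzero variance in both.
#' @return R^2, the square of the sample Pearson correlation coefficient.
#' @export
pearson_r2 <- function(pairs) {
  cols <- paired_columns(pairs)
  if (length(cols$a) < 3) stop_precondition("pearson_r2 requires n >= 3 pairs")
  if (sd(cols$a) == 0 || sd(cols$b) == 0)
    stop_precondition("pearson_r2 requires nonzero variance in both columns")
  stats::cor(cols$a, cols$b)^2
}

#' Bland-Altman agreement of paired measurements
#'
#' Mean difference (B - A) and half-width of the 95% limits of agreement,
#' `1.96 * sd` of the differences (sample sd, n - 1 denominator). The
#' per-pair plot data (mean vs difference) are returned alongside.
#'
#' @param pairs data frame whose first two numeric columns are the paired
#'   measurements; n >= 2.
#' @return List with `mean_difference`, `loa_half_width`, and `data`
#'   (data frame of per-pair `mean` and `difference`).
#' @export
bland_altman <- function(pairs) {
  cols <- paired_columns(pairs)
  if (length(cols$a) < 2) stop_precondition("bland_altman requires n >= 2 pairs")
  d <- cols$b - cols$a
  list(mean_difference = mean(d),
       loa_half_width = 1.96 * sd(d),
       data = data.frame(mean = (cols$a + cols$b) / 2, difference = d))
}

#' Signed percent difference relative to the reference method
#'
#' `100 * (b - a) / a`; the first (reference) method is the denominator.
#'
#' @param a reference measurements (> 0).
#' @param b comparison measurements.
#' @return Signed percent differences (vectorized).
#' @export
percent_difference <- function(a, b) {
  if (any(a <= 0)) stop_precondition("reference values must be > 0")
  100 * (b - a) / a
}

#' Summarize paired-method agreement
#'
#' Aggregates the agreement statistics for a paired ECD table: n, mean
#' difference and Bland-Altman limits of agreement, Pearson R^2 (flagged
#' undefined when either column has zero variance), and the mean signed
#' percent difference relative to the first (reference) column.
#'
#' @param pairs data frame whose first two numeric columns are the paired
#'   measurements (reference method first).
#' @return An object of class `agreement_report`: `n`, `mean_difference`,
#'   `loa_half_width`, `r_squared` (NA when undefined), `r_squared_defined`,
#'   `mean_percent_difference`, `bland_altman_data`.
#' @export
summarize_agreement <- function(pairs) {
  cols <- paired_columns(pairs)
  ba <- bland_altman(pairs)
  r2_ok <- length(cols$a) >= 3 && sd(cols$a) > 0 && sd(cols$b) > 0
  structure(list(n = length(cols$a),
                 mean_difference = ba$mean_difference,
                 loa_half_width = ba$loa_half_width,
                 r_squared = if (r2_ok) pearson_r2(pairs) else NA_real_,
                 r_squared_defined = r2_ok,
                 mean_percent_difference = mean(percent_difference(cols$a, cols$b)),
                 bland_altman_data = ba$data),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("<agreement_report> n = %d\n",
                     "  mean difference (B - A): %.1f\n",
                     "  95%% limits of agreement: +/- %.1f\n",
                     "  Pearson R^2: %s\n",
                     "  mean percent difference: %.1f%%\n"),
              x$n, x$mean_difference, x$loa_half_width,
              if (x$r_squared_defined) sprintf("%.2f", x$r_squared) else "undefined",
              x$mean_percent_difference))
  invisible(x)
}

#' Bland-Altman scatter of an agreement report
#'
#' Plots per-pair differences against per-pair means with the mean
#' difference and 95% limits of agreement as horizontal lines.
#'
#' @param report an [summarize_agreement()] result.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, the plot data.
#' @importFrom graphics abline plot
#' @export
plot_bland_altman <- function(report, ...) {
  d <- report$bland_altman_data
  plot(d$mean, d$difference, xlab = "Mean of methods",
       ylab = "Difference (B - A)", ...)
  abline(h = report$mean_difference, lty = 1)
  abline(h = report$mean_difference + c(-1, 1) * report$loa_half_width, lty = 2)
  invisible(d)
}

#' Paired ECD measurements of ten donor corneas (bundled example)
#'
#' Endothelial cell density of ten donor corneas measured by two methods on
#' the same central corneal region: semi-automated specular microscopy
#' (`sm_ecd`, a technician selects 50-100 cells) and fully automated counting
#' on flattened volumetric optical coherence microscopy (`gdocm_ecd`). The
#' `percent_difference` column is the signed percent difference as reported
#' alongside the measurements, for cross-checking.
#'
#' @return Data frame with columns `cornea`, `sm_ecd`, `gdocm_ecd`,
#'   `percent_difference`.
#' @export
ecd_method_pairs <- function() {
  read.csv(system.file("extdata", "sm_gdocm_ecd_pairs.csv",
                       package = "ecdquant"))
}

#' Donor tissue timeline of the ten example corneas (bundled example)
#'
#' Donor age and handling intervals for the ten corneas of
#' [ecd_method_pairs()]: hours from death to cooling, death to preservation,
#' preservation to specular-microscopy imaging, and from specular-microscopy
#' to volumetric imaging.
#'
#' @return Data frame with columns `cornea`, `age`, `death_to_cooling_h`,
#'   `death_to_preservation_h`, `preservation_to_sm_h`, `sm_to_gdocm_h`.
#' @export
donor_tissue_times <- function() {
  read.csv(system.file("extdata", "donor_tissue_times.csv",
                       package = "ecdquant"))
}
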