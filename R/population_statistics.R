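#' @title Population statistics
#' @description Bias-corrected moment statistics for polyp-leaf-count
#'   distributions, per-count dispersion of rachis length, and the
#'   trawl-vs-ROV distribution comparison.
#' @name population_statistics
NULL

#' Bias-corrected moment summary of a count sample
#'
#' Computes the descriptive statistics used for comparing leaf-count
#' distributions:
#' * `mean`;
#' * `sd_corrected` -- the bias-corrected standard deviation
#'   (denominator `m - 1`);
#' * `sd_uncorrected` -- the population-form standard deviation
#'   (denominator `m`);
#' * `skewness` -- bias-corrected sample skewness
#'   `G1 = sqrt(m(m-1))/(m-2) * (1/m) * sum(((x - mean)/sd_uncorrected)^3)`;
#' * `kurtosis` -- bias-corrected kurtosis in the *non-excess* convention
#'   (a normal sample tends to 3), equal to the bias-corrected excess
#'   kurtosis plus 3.
#'
#' With `m` of 2 or 3 only the mean and standard deviations are defined;
#' skewness and kurtosis are reported as `NA`, as they are for constant
#' samples (`sd_uncorrected == 0`), never as infinities.
#'
#' @param counts numeric vector, `m >= 2`.
#' @return Object of class `moment_summary` with fields `m`, `mean`,
#'   `sd_corrected`, `sd_uncorrected`, `skewness`, `kurtosis`.
#' @export
moment_summary <- function(counts) {
  m <- length(counts)
  if (m < 2) {
    stop("moment_summary needs at least 2 values", call. = FALSE)
  }
  mu <- mean(counts)
  ss <- sum((counts - mu)^2)
  sd_unc <- sqrt(ss / m)
  sd_cor <- sqrt(ss / (m - 1))
  skew <- NA_real_
  kurt <- NA_real_
  if (m >= 4 && sd_unc > 0) {
    z <- (counts - mu) / sd_unc
    skew <- sqrt(m * (m - 1)) / (m - 2) * mean(z^3)
    kurt <- (m - 1) / ((m - 2) * (m - 3)) *
      ((m + 1) * mean(z^4) - 3 * (m - 1)) + 3
  }
  structure(
    list(m = m, mean = mu, sd_corrected = sd_cor, sd_uncorrected = sd_unc,
         skewness = skew, kurtosis = kurt),
    class = "moment_summary"
  )
}

#' @export
print.moment_summary <- function(x, ...) {
  cat(sprintf(
    "Moment summary (m = %d): mean %.3f, sd %.3f (uncorrected %.3f), skewness %.3f, kurtosis %.3f\n",
    x$m, x$mean, x$sd_corrected, x$sd_uncorrected, x$skewness, x$kurtosis
  ))
  invisible(x)
}

#' Absolute relative difference against a reference
#'
#' `|x - reference| / |reference|`; `NA` with a warning when the reference
#' is zero.
#'
#' @param x value to compare.
#' @param reference reference value (denominator).
#' @return Non-negative fraction, or `NA`.
#' @export
relative_difference <- function(x, reference) {
  if (length(reference) != 1 || length(x) != 1) {
    stop("relative_difference compares two scalars", call. = FALSE)
  }
  if (is.na(reference) || reference == 0) {
    warning("reference value is zero or NA; relative difference undefined",
            call. = FALSE)
    return(NA_real_)
  }
  abs(x - reference) / abs(reference)
}

#' Rachis-length dispersion by leaf count
#'
#' Groups colonies by their max-side leaf count (counts below `min_count`
#' excluded: small colonies are too few to show length variation at the
#' same count) and reports, per count, the number of colonies and the mean
#' and bias-corrected standard deviation of rachis length.
#'
#' @param colonies validated colony data frame.
#' @param min_count smallest leaf count included (default 15).
#' @return Data frame with columns `leaf_count`, `m`, `mean_rachis`,
#'   `sd_rachis` (`NA` for single-colony groups), sorted by count;
#'   zero rows if nothing qualifies.
#' @export
dispersion_by_count <- function(colonies, min_count = 15) {
  stopifnot(min_count >= 0)
  n <- leaf_count_for_size(colonies)
  lr <- rachis_length(colonies)
  keep <- n >= min_count
  n <- n[keep]
  lr <- lr[keep]
  if (length(n) == 0) {
    return(data.frame(leaf_count = integer(0), m = integer(0),
                      mean_rachis = numeric(0), sd_rachis = numeric(0)))
  }
  counts <- sort(unique(n))
  rows <- lapply(counts, function(k) {
    v <- lr[n == k]
    data.frame(
      leaf_count = k, m = length(v), mean_rachis = mean(v),
      sd_rachis = if (length(v) > 1) stats::sd(v) else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare two leaf-count distributions
#'
#' Summarises both samples with [moment_summary()] and reports the
#' absolute relative differences of the means and skewnesses, with sample
#' `b` as the reference (in the trawl-vs-ROV comparison, the ROV set), plus
#' shared-bin integer histograms.
#'
#' @param a,b numeric count vectors, each admitting a moment summary.
#' @return Object of class `distribution_comparison`: `summary_a`,
#'   `summary_b`, `relative_mean_diff`, `relative_skewness_diff`, and a
#'   `histogram` data frame (`leaf_count`, `freq_a`, `freq_b`) over the
#'   shared integer range.
#' @export
compare_distributions <- function(a, b) {
  sa <- moment_summary(a)
  sb <- moment_summary(b)
  bins <- seq(floor(min(a, b)), ceiling(max(a, b)))
  hist_of <- function(x) {
    as.integer(table(factor(round(x), levels = bins)))
  }
  structure(
    list(
      summary_a = sa,
      summary_b = sb,
      relative_mean_diff = relative_difference(sa$mean, sb$mean),
      relative_skewness_diff = relative_difference(sa$skewness, sb$skewness),
      histogram = data.frame(
        leaf_count = bins, freq_a = hist_of(a), freq_b = hist_of(b)
      )
    ),
    class = "distribution_comparison"
  )
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat("Distribution comparison (b is the reference set):\n")
  cat(sprintf("  mean: %.3f vs %.3f  (relative difference %.1f%%)\n",
              x$summary_a$mean, x$summary_b$mean,
              100 * x$relative_mean_diff))
  cat(sprintf("  skewness: %.3f vs %.3f  (relative difference %.1f%%)\n",
              x$summary_a$skewness, x$summary_b$skewness,
              100 * x$relative_skewness_diff))
  invisible(x)
}
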