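#' Canonical methylation standard series
#'
#' Expected percent methylation of the five-point mixture series used for
#' assay validation: 100% unmethylated DNA, 1:3, 2:2 and 3:1
#' methylated:unmethylated mixes, and 100% methylated DNA.
#'
#' @return `c(0, 25, 50, 75, 100)`.
#' @export
build_standard_series <- function() c(0, 25, 50, 75, 100)

#' Linearity of an assay against the standard series
#'
#' Ordinary least squares of observed on expected percent methylation;
#' r-squared is the squared Pearson correlation of the fit.
#'
#' @param expected Numeric vector of known input percents.
#' @param observed Numeric vector of assay readings, same length.
#' @return `linearity_result`: list with `slope`, `intercept`, `r_squared`,
#'   `n_points` and logical `constant_observed`.
#' @export
assess_linearity <- function(expected, observed) {
  keep <- stats::complete.cases(expected, observed)
  expected <- expected[keep]; observed <- observed[keep]
  if (length(expected) != length(observed) || length(expected) < 2)
    stop("need >= 2 paired points", call. = FALSE)
  if (stats::sd(expected) == 0)
    stop("expected values are constant; slope undefined", call. = FALSE)
  constant_observed <- stats::sd(observed) == 0
  if (constant_observed) {
    warning("observed values are constant; r_squared set to 0")
    out <- list(slope = 0, intercept = observed[1], r_squared = 0,
                n_points = length(expected), constant_observed = TRUE)
  } else {
    fit <- stats::lm(observed ~ expected)
    out <- list(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]),
                r_squared = stats::cor(expected, observed)^2,
                n_points = length(expected), constant_observed = FALSE)
  }
  structure(out, class = "linearity_result")
}

#' @export
print.linearity_result <- function(x, ...) {
  cat(sprintf("Standards linearity: slope %.3f, intercept %.2f%%, r^2 %.3f (n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Replicate agreement (regression + Bland-Altman)
#'
#' Concordance of two technical replicates: OLS r-squared and slope of
#' replicate 2 on replicate 1, plus classic Bland-Altman agreement — bias is
#' the mean of (rep1 - rep2) and the limits of agreement are
#' bias +/- 1.96 x sample SD of the differences. Incomplete pairs are dropped
#' (pairwise deletion).
#'
#' @param rep1,rep2 Numeric vectors of paired readings (>= 3 complete pairs).
#' @return `agreement_result`: list with `r_squared`, `slope`, `bias`,
#'   `loa_low`, `loa_high`, `n_pairs`.
#' @export
replicate_agreement <- function(rep1, rep2) {
  if (length(rep1) != length(rep2))
    stop("replicate vectors must have equal length", call. = FALSE)
  keep <- stats::complete.cases(rep1, rep2)
  rep1 <- rep1[keep]; rep2 <- rep2[keep]
  if (length(rep1) < 3) stop("need >= 3 complete pairs", call. = FALSE)
  d <- rep1 - rep2
  bias <- mean(d)
  sd_d <- stats::sd(d)
  slope <- if (stats::sd(rep1) == 0) NA_real_ else
    unname(stats::coef(stats::lm(rep2 ~ rep1))[2])
  r2 <- if (stats::sd(rep1) == 0 || stats::sd(rep2) == 0) {
    if (sd_d == 0) 1 else 0
  } else stats::cor(rep1, rep2)^2
  structure(list(r_squared = r2, slope = slope, bias = bias,
                 loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
                 n_pairs = length(rep1)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "Replicate agreement: r^2 %.3f, bias %.2f%% (LoA %.2f to %.2f, n = %d)\n",
    x$r_squared, x$bias, x$loa_low, x$loa_high, x$n_pairs))
  invisible(x)
}

#' Input-titration sensitivity with allelic-dropout detection
#'
#' Assesses the smallest template mass at which 50% standards still report
#' within the DMR window. A replicate is called an allelic dropout when its
#' mean reading collapses toward a rail: at or beyond 20 percentage points
#' outside the window on either side (threshold configurable; the failure
#' mode is mono-allelic amplification pulling a 50% locus toward 0 or 100).
#'
#' @param dataset A `meth_dataset` of 50% standards whose samples carry
#'   `template_mass_ng` (typically `filter_group(ds, "standard")`).
#' @param window A [derive_dmr_window()] result.
#' @param dropout_margin Distance in percent beyond the window bounds that
#'   flags dropout (default 20).
#' @return `sensitivity_result`: data frame `per_mass` (mass, mean_reading,
#'   within_window, dropout) plus `min_reliable_mass_ng` (NA when no mass
#'   qualifies).
#' @export
titration_sensitivity <- function(dataset, window, dropout_margin = 20) {
  stopifnot(inherits(dataset, "meth_dataset"), inherits(window, "dmr_window"))
  m <- assay_sample_means(dataset)
  m <- m[!is.na(m$template_mass_ng), , drop = FALSE]
  if (nrow(m) == 0) stop("no standard samples with template_mass_ng", call. = FALSE)
  lo_rail <- window$lower - dropout_margin
  hi_rail <- window$upper + dropout_margin
  masses <- sort(unique(m$template_mass_ng))
  per_mass <- do.call(rbind, lapply(masses, function(mass) {
    reps <- m$mean[m$template_mass_ng == mass]
    data.frame(template_mass_ng = mass,
               mean_reading = mean(reps, na.rm = TRUE),
               within_window = {
                 mu <- mean(reps, na.rm = TRUE)
                 mu >= window$lower && mu <= window$upper
               },
               dropout = any(reps <= lo_rail | reps >= hi_rail, na.rm = TRUE))
  }))
  ok <- per_mass$within_window & !per_mass$dropout
  structure(list(per_mass = per_mass,
                 min_reliable_mass_ng = if (any(ok))
                   min(per_mass$template_mass_ng[ok]) else NA_real_),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Titration sensitivity\n")
  print(x$per_mass, row.names = FALSE)
  cat("min reliable template mass:",
      if (is.na(x$min_reliable_mass_ng)) "none" else
        paste0(x$min_reliable_mass_ng, " ng"), "\n")
  invisible(x)
}
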