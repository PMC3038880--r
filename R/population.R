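#' Population reference interval
#'
#' The default is a normal reference range, mean +/- z_(1+level)/2 x sample
#' SD, truncated to [0, 100]: individuals (not means) are being flagged, so
#' this is a tolerance band for single observations, not a confidence
#' interval of the mean. A distribution-free percentile alternative is
#' available.
#'
#' @param values Numeric vector (>= 3 non-missing).
#' @param level Coverage level in (0, 1), e.g. 0.95 or 0.99.
#' @param method `"parametric"` (default) or `"percentile"` (empirical
#'   quantiles).
#' @return Numeric `c(low, high)`.
#' @export
reference_interval <- function(values, level = 0.95,
                               method = c("parametric", "percentile")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (length(values) < 3) stop("need >= 3 values", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  if (method == "parametric") {
    z <- stats::qnorm((1 + level) / 2)
    out <- mean(values) + c(-1, 1) * z * stats::sd(values)
  } else {
    out <- unname(stats::quantile(values, c((1 - level) / 2, (1 + level) / 2)))
  }
  c(low = max(0, out[1]), high = min(100, out[2]))
}

#' Flag population outliers per DMR
#'
#' Computes per-assay reference intervals at each level from the cohort's
#' per-individual mean methylation and flags every individual outside them.
#' Intervals include the tested individual by default (no leave-one-out).
#'
#' @param dataset A `meth_dataset` (e.g. a blood cohort: one sample per
#'   individual).
#' @param levels Numeric vector of coverage levels (default `c(0.95, 0.99)`).
#' @param method Passed to [reference_interval()].
#' @param leave_one_out When TRUE, each individual is tested against the
#'   interval computed from the remaining individuals.
#' @return `outlier_report`: list with `intervals` (assay, level, low, high),
#'   `flags` (assay, sample, value, level_exceeded = highest violated level),
#'   and `counts` (per sample x level flag counts). Assays with fewer than 3
#'   individuals are skipped with a warning.
#' @export
flag_population_outliers <- function(dataset, levels = c(0.95, 0.99),
                                     method = c("parametric", "percentile"),
                                     leave_one_out = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "meth_dataset"))
  levels <- sort(levels)
  m <- assay_sample_means(dataset)
  m <- m[!is.na(m$mean), , drop = FALSE]
  intervals <- list(); flags <- list()
  for (a in unique(m$assay)) {
    v <- m[m$assay == a, , drop = FALSE]
    if (nrow(v) < 3) {
      warning("assay '", a, "' skipped: fewer than 3 individuals")
      next
    }
    for (lv in levels) {
      ri <- reference_interval(v$mean, lv, method)
      intervals[[length(intervals) + 1L]] <-
        data.frame(assay = a, level = lv, low = ri[["low"]], high = ri[["high"]])
    }
    for (i in seq_len(nrow(v))) {
      exceeded <- NA_real_
      for (lv in levels) {
        ri <- if (leave_one_out)
          reference_interval(v$mean[-i], lv, method)
        else reference_interval(v$mean, lv, method)
        if (v$mean[i] < ri[["low"]] || v$mean[i] > ri[["high"]])
          exceeded <- lv
      }
      if (!is.na(exceeded))
        flags[[length(flags) + 1L]] <-
          data.frame(assay = a, sample = v$sample[i], value = v$mean[i],
                     level_exceeded = exceeded)
    }
  }
  intervals <- if (length(intervals)) do.call(rbind, intervals) else
    data.frame(assay = character(), level = numeric(), low = numeric(),
               high = numeric())
  flags <- if (length(flags)) do.call(rbind, flags) else
    data.frame(assay = character(), sample = character(), value = numeric(),
               level_exceeded = numeric())
  all_samples <- unique(m$sample)
  counts <- do.call(rbind, lapply(levels, function(lv) {
    n <- sapply(all_samples, function(s)
      sum(flags$sample == s & flags$level_exceeded >= lv))
    data.frame(sample = all_samples, level = lv, n_flags = as.integer(n))
  }))
  structure(list(intervals = intervals, flags = flags, counts = counts,
                 levels = levels),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("Population outlier report: ", length(unique(x$intervals$assay)),
      " assays, levels ", paste(x$levels, collapse = "/"), "\n", sep = "")
  for (lv in x$levels)
    cat(sprintf("  level %.2f: %d flag(s) across %d assay(s)\n", lv,
                sum(x$flags$level_exceeded >= lv),
                length(unique(x$flags$assay[x$flags$level_exceeded >= lv]))))
  invisible(x)
}

#' Per-individual outlier burden and consistency test
#'
#' Asks whether any individual is systematically aberrant across DMRs:
#' per-individual flag counts plus a two-way ANOVA without replication on
#' per-assay z-scores (individual + assay), reporting the individual-effect
#' p-value. An all-identical cohort degenerates to F = 0, p = 1.
#'
#' @param dataset A `meth_dataset` (>= 2 individuals, >= 2 assays; at most
#'   20% missing cells).
#' @param report An [flag_population_outliers()] result for the same dataset.
#' @return `burden_result`: list with `counts` (per sample, at the lowest
#'   level), `anova_p`, `statistic` (F) and `max_count_sample`.
#' @export
individual_burden <- function(dataset, report) {
  stopifnot(inherits(dataset, "meth_dataset"), inherits(report, "outlier_report"))
  m <- assay_sample_means(dataset)
  assays <- unique(m$assay); samples <- unique(m$sample)
  if (length(assays) < 2) stop("need >= 2 assays", call. = FALSE)
  if (length(samples) < 2) stop("need >= 2 individuals", call. = FALSE)
  n_missing <- sum(is.na(m$mean)) +
    (length(assays) * length(samples) - nrow(m))
  if (n_missing / (length(assays) * length(samples)) > 0.2)
    stop("more than 20% missing cells: unbalanced design unsupported",
         call. = FALSE)
  m <- m[!is.na(m$mean), , drop = FALSE]
  # per-assay z-scores so assays are on a common scale
  z <- unlist(lapply(split(m$mean, m$assay), function(v) {
    s <- stats::sd(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  ord <- order(m$assay)
  dat <- data.frame(z = z, individual = factor(m$sample[ord]),
                    assay = factor(m$assay[ord]))
  if (stats::var(dat$z) == 0) {
    f <- 0; p <- 1
  } else {
    s <- summary(stats::aov(z ~ individual + assay, data = dat))[[1]]
    i <- which(trimws(rownames(s)) == "individual")
    f <- s[["F value"]][i]; p <- s[["Pr(>F)"]][i]
  }
  lv <- min(report$levels)
  counts <- report$counts[report$counts$level == lv, , drop = FALSE]
  max_sample <- if (nrow(counts) && max(counts$n_flags) > 0)
    counts$sample[which.max(counts$n_flags)] else NA_character_
  structure(list(counts = counts, anova_p = p, statistic = f,
                 max_count_sample = max_sample),
            class = "burden_result")
}

#' @export
print.burden_result <- function(x, ...) {
  cat(sprintf(
    "Individual burden: individual-effect F = %.3g, p = %.3g; max flags: %s\n",
    x$statistic, x$anova_p,
    if (is.na(x$max_count_sample)) "none" else x$max_count_sample))
  invisible(x)
}

#' Correlation of methylation between DMRs in the same cis cluster
#'
#' For every pair of assays sharing a `cluster_id`, the r-squared of
#' per-individual mean methylation — tests whether loss or gain at one DMR
#' propagates to its neighbours in cis.
#'
#' @param dataset A `meth_dataset` with >= 3 individuals.
#' @param catalog An `assay_catalog` (or any data frame with `name` and
#'   `cluster_id` columns) supplying the cluster assignments.
#' @return `cluster_correlation`: data frame (`cluster`, `assay1`, `assay2`,
#'   `r_squared`, `n`) with attribute `max_r_squared` (NA when no clustered
#'   pairs exist, reported with a message).
#' @export
cis_cluster_correlation <- function(dataset, catalog) {
  stopifnot(inherits(dataset, "meth_dataset"),
            all(c("name", "cluster_id") %in% names(catalog)))
  m <- assay_sample_means(dataset)
  wide <- stats::reshape(m[c("assay", "sample", "mean")], idvar = "sample",
                         timevar = "assay", direction = "wide")
  rows <- list()
  clusters <- unique(catalog$cluster_id[!is.na(catalog$cluster_id)])
  for (cl in clusters) {
    members <- intersect(catalog$name[!is.na(catalog$cluster_id) &
                                        catalog$cluster_id == cl],
                         unique(m$assay))
    if (length(members) < 2) next
    for (i in seq_len(length(members) - 1)) for (j in seq(i + 1, length(members))) {
      x <- wide[[paste0("mean.", members[i])]]
      y <- wide[[paste0("mean.", members[j])]]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3) next
      r2 <- if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) NA_real_ else
        stats::cor(x[ok], y[ok])^2
      rows[[length(rows) + 1L]] <-
        data.frame(cluster = cl, assay1 = members[i], assay2 = members[j],
                   r_squared = r2, n = sum(ok))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    message("no clustered assay pairs in dataset")
    data.frame(cluster = character(), assay1 = character(),
               assay2 = character(), r_squared = numeric(), n = integer())
  }
  attr(out, "max_r_squared") <- if (nrow(out) && any(!is.na(out$r_squared)))
    max(out$r_squared, na.rm = TRUE) else NA_real_
  class(out) <- c("cluster_correlation", "data.frame")
  out
}

#' @export
print.cluster_correlation <- function(x, ...) {
  cat("Cis-cluster correlation: ", nrow(x), " same-cluster pair(s), max r^2 = ",
      format(attr(x, "max_r_squared"), digits = 3), "\n", sep = "")
  NextMethod()
}

#' Demethylation treatment response
#'
#' Percent reduction of methylation after treatment with a demethylating
#' agent (e.g. 5-azacytidine): 100 x (control - treated) / control per assay
#' and dose. A methylation gain reports as a negative reduction; a zero
#' control leaves the reduction undefined (NA, flagged), never 0. When
#' `treated` carries an `experiment` column, reductions are averaged across
#' experiments and their range reported.
#'
#' @param control Named numeric vector of per-assay control means (percent).
#' @param treated Data frame with columns `assay`, `dose_label`, `mean` and
#'   optional `experiment`.
#' @return `reduction_result`: data frame (`assay`, `dose_label`,
#'   `control_mean`, `treated_mean`, `percent_reduction`, `range_low`,
#'   `range_high`, `undefined`).
#' @export
treatment_reduction <- function(control, treated) {
  stopifnot(is.numeric(control), !is.null(names(control)),
            all(c("assay", "dose_label", "mean") %in% names(treated)))
  if (any(control < 0 | control > 100, na.rm = TRUE))
    stop("control means outside [0,100]", call. = FALSE)
  missing <- setdiff(unique(treated$assay), names(control))
  if (length(missing) > 0)
    stop("treated assay(s) without control: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"experiment" %in% names(treated)) treated$experiment <- 1L
  red <- treated
  red$control_mean <- control[red$assay]
  red$reduction <- ifelse(red$control_mean == 0, NA_real_,
                          100 * (red$control_mean - red$mean) / red$control_mean)
  agg <- stats::aggregate(cbind(mean, reduction) ~ assay + dose_label,
                          data = red, FUN = mean, na.rm = TRUE,
                          na.action = stats::na.pass)
  rng <- stats::aggregate(reduction ~ assay + dose_label, data = red,
                          FUN = function(v) if (all(is.na(v)))
                            c(NA_real_, NA_real_) else range(v, na.rm = TRUE),
                          na.action = stats::na.pass)
  out <- data.frame(assay = agg$assay, dose_label = agg$dose_label,
                    control_mean = unname(control[agg$assay]),
                    treated_mean = agg$mean,
                    percent_reduction = ifelse(is.nan(agg$reduction), NA_real_,
                                               agg$reduction),
                    range_low = rng$reduction[, 1],
                    range_high = rng$reduction[, 2])
  out$undefined <- out$control_mean == 0
  out$percent_reduction[out$undefined] <- NA_real_
  out <- out[order(out$assay, out$dose_label), ]
  rownames(out) <- NULL
  class(out) <- c("reduction_result", "data.frame")
  out
}

#' @export
print.reduction_result <- function(x, ...) {
  ok <- !x$undefined & !is.na(x$percent_reduction)
  cat("Treatment response: ", length(unique(x$assay)), " assays; mean reduction ",
      if (any(ok)) sprintf("%.1f%%", mean(x$percent_reduction[ok])) else "NA",
      "\n", sep = "")
  NextMethod()
}
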