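#' Derive the DMR calling window from 50% standards
#'
#' The operating definition of "differentially methylated": a reading within
#' k sample standard deviations of the mean of known-DMR 50% standards. With
#' the published standards (mean 50.38%, SD 9.7667%) and the default
#' k = 1.5 this gives the 35.73%-65.03% window.
#'
#' @param standard_readings Numeric vector (>= 2) of percent readings of
#'   50%-methylated standards across known DMR assays.
#' @param k Spread multiplier (default 1.5).
#' @return `dmr_window`: list with `center`, `spread` (sample SD), `k`,
#'   `lower`, `upper`. Bounds are kept at full precision; `print` rounds to
#'   2 decimals.
#' @examples
#' derive_dmr_window(c(40, 50, 60), k = 1)  # window (40, 60)
#' @export
derive_dmr_window <- function(standard_readings, k = 1.5) {
  standard_readings <- standard_readings[!is.na(standard_readings)]
  if (length(standard_readings) < 2)
    stop("need >= 2 standard readings", call. = FALSE)
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  center <- mean(standard_readings)
  spread <- stats::sd(standard_readings)
  structure(list(center = center, spread = spread, k = k,
                 lower = center - k * spread, upper = center + k * spread),
            class = "dmr_window")
}

#' Construct a fixed DMR window from explicit bounds
#'
#' @param lower,upper Window bounds in percent (`lower < upper`).
#' @return A `dmr_window` with center at the midpoint.
#' @export
fixed_dmr_window <- function(lower, upper) {
  if (!(lower < upper)) stop("need lower < upper", call. = FALSE)
  structure(list(center = (lower + upper) / 2,
                 spread = (upper - lower) / 2, k = 1,
                 lower = lower, upper = upper),
            class = "dmr_window")
}

#' @export
print.dmr_window <- function(x, ...) {
  cat(sprintf("DMR window: %.2f%%-%.2f%% (center %.2f%%, spread %.4f, k = %g)\n",
              x$lower, x$upper, x$center, x$spread, x$k))
  invisible(x)
}

#' Classify methylation values against a DMR window
#'
#' Values below the window are hypomethylated, above it hypermethylated, and
#' inside it (bounds inclusive) consistent with differential methylation.
#'
#' @param value Numeric vector of percents in [0, 100] (NA allowed).
#' @param window A `dmr_window`.
#' @return Ordered factor with levels
#'   `hypomethylated < differential < hypermethylated`.
#' @export
classify_value <- function(value, window) {
  stopifnot(inherits(window, "dmr_window"))
  if (any(value < 0 | value > 100, na.rm = TRUE))
    stop("value outside [0,100]", call. = FALSE)
  out <- ifelse(is.na(value), NA_character_,
                ifelse(value < window$lower, "hypomethylated",
                       ifelse(value > window$upper, "hypermethylated",
                              "differential")))
  factor(out, levels = c("hypomethylated", "differential", "hypermethylated"),
         ordered = TRUE)
}

#' Classify a tissue-panel dataset
#'
#' Collapses each assay x tissue cell to its mean (individuals averaged
#' before tissues, each individual's per-CpG readings averaged first) and
#' classifies the cell against the window. An assay is `ever_differential`
#' when at least one tissue falls inside the window.
#'
#' @param dataset A `meth_dataset` whose samples carry `tissue` metadata.
#' @param window A `dmr_window`.
#' @return `classification_table`: data frame (`assay`, `tissue`, `mean`,
#'   `category`) with an `ever_differential` attribute (named logical per
#'   assay) also exposed by [ever_differential()].
#' @export
classify_dataset <- function(dataset, window) {
  stopifnot(inherits(dataset, "meth_dataset"), inherits(window, "dmr_window"))
  m <- assay_sample_means(dataset)
  if (all(is.na(m$tissue))) stop("samples carry no tissue metadata", call. = FALSE)
  empty <- tapply(m$mean, m$assay, function(v) all(is.na(v)))
  if (any(empty)) {
    warning("assay(s) with no values excluded: ",
            paste(names(empty)[empty], collapse = ", "))
    m <- m[!(m$assay %in% names(empty)[empty]), , drop = FALSE]
  }
  cell <- stats::aggregate(mean ~ assay + tissue, data = m, FUN = mean,
                           na.rm = TRUE)
  cell$category <- classify_value(cell$mean, window)
  cell <- cell[order(cell$assay, cell$tissue), ]
  rownames(cell) <- NULL
  ever <- tapply(cell$category == "differential", cell$assay, any)
  attr(cell, "ever_differential") <- ever
  class(cell) <- c("classification_table", "data.frame")
  cell
}

#' Per-assay ever-differential flags of a classification table
#'
#' @param classification A [classify_dataset()] result.
#' @return Named logical vector: TRUE when the assay reads inside the window
#'   in at least one tissue.
#' @export
ever_differential <- function(classification) {
  attr(classification, "ever_differential")
}

#' @export
print.classification_table <- function(x, ...) {
  ever <- ever_differential(x)
  cat("DMR classification: ", length(ever), " assays x ",
      length(unique(x$tissue)), " tissues; ", sum(!ever),
      " assay(s) never differential\n", sep = "")
  NextMethod()
}

#' Intra-CpG standard deviation
#'
#' Sample standard deviation of per-CpG readings within one assay run — the
#' within-region variability statistic that separates maternally from
#' paternally methylated DMRs.
#'
#' @param values Numeric vector of per-CpG percents.
#' @return Sample SD, or NA when fewer than 2 CpGs are non-missing.
#' @export
intra_cpg_sd <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) return(NA_real_)
  stats::sd(values)
}

#' Per assay x sample intra-CpG variability records
#'
#' @param dataset A `meth_dataset`.
#' @param catalog Optional `assay_catalog`; when given, `parental_mark` is
#'   joined on by assay name.
#' @return Data frame (`assay`, `sample`, `tissue`, `intra_cpg_sd`, and
#'   `parental_mark` when a catalog is supplied).
#' @export
intra_cpg_variability <- function(dataset, catalog = NULL) {
  stopifnot(inherits(dataset, "meth_dataset"))
  agg <- stats::aggregate(percent ~ assay + sample, data = dataset$values,
                          FUN = intra_cpg_sd, na.action = stats::na.pass)
  names(agg)[names(agg) == "percent"] <- "intra_cpg_sd"
  out <- merge(agg, dataset$samples[c("sample", "tissue")], by = "sample",
               sort = FALSE)
  if (!is.null(catalog)) {
    stopifnot(inherits(catalog, "assay_catalog"))
    out <- merge(out, catalog[c("name", "parental_mark")],
                 by.x = "assay", by.y = "name", all.x = TRUE, sort = FALSE)
  }
  out[order(out$assay, out$sample), c("assay", "sample", "tissue",
                                      "intra_cpg_sd",
                                      intersect("parental_mark", names(out)))]
}
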