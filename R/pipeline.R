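#' Configuration for an end-to-end analysis run
#'
#' @param catalog Path to an assay catalog CSV.
#' @param methylation Optional path to a long-format methylation table
#'   holding the tissue panel (and any other groups).
#' @param standards Optional path to a long-format table of 50% standards
#'   (group `standard`); required when `window = "from_standards"`.
#' @param intervals Optional named list of BED paths (e.g. `ctcf`,
#'   `cpg_islands`), loaded and echoed into the bundle.
#' @param out_dir Output directory for the report bundle (created).
#' @param window `"from_standards"` or a numeric `c(lower, upper)` fixed
#'   window.
#' @param k Window spread multiplier when derived from standards.
#' @param exclude Assay names excluded from catalog-level association tests.
#' @param levels Outlier reference-interval levels.
#' @param seed Integer seed echoed into the summary.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(catalog, methylation = NULL, standards = NULL,
                       intervals = NULL, out_dir,
                       window = "from_standards", k = 1.5,
                       exclude = character(), levels = c(0.95, 0.99),
                       seed = 1) {
  for (p in c(catalog, methylation, standards, unlist(intervals)))
    if (!file.exists(p)) stop("config validation: path not found: ", p,
                              call. = FALSE)
  if (is.numeric(window)) {
    if (length(window) != 2 || !(window[1] < window[2]))
      stop("config validation: fixed window needs lower < upper", call. = FALSE)
  } else if (!identical(window, "from_standards")) {
    stop("config validation: window must be 'from_standards' or c(lower, upper)",
         call. = FALSE)
  } else if (is.null(standards)) {
    stop("config validation: window 'from_standards' needs a standards table",
         call. = FALSE)
  }
  structure(list(catalog = catalog, methylation = methylation,
                 standards = standards, intervals = intervals,
                 out_dir = out_dir, window = window, k = k, exclude = exclude,
                 levels = levels, seed = as.integer(seed)),
            class = "run_config")
}

write_report_csv <- function(df, out_dir, name) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round(v, 2))
  utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Sequences the analyses end to end: catalog summary, DMR-window derivation
#' (or fixed bounds), tissue-panel classification, genomic-feature
#' associations, population outlier detection with per-individual burden,
#' and cis-cluster correlation. Each stage writes a CSV to the output
#' directory (percentages rounded to 2 decimals), a structured log line is
#' kept per stage, and a machine-readable JSON summary retains full
#' precision. Any stage error aborts the run, removes partial outputs and
#' names the failing stage.
#'
#' @param config A [run_config()].
#' @return The summary list, invisibly. Side effects: the report bundle in
#'   `config$out_dir` (`*.csv`, `summary.json`, `run.log`).
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  created <- character()
  log_lines <- character()
  log_stage <- function(stage, detail)
    log_lines <<- c(log_lines, sprintf("[%s] %s: %s",
                                       format(Sys.time(), "%H:%M:%S"),
                                       stage, detail))
  emit <- function(df, name) {
    write_report_csv(df, config$out_dir, name)
    created <<- c(created, file.path(config$out_dir, name))
  }
  stage <- "init"
  summary <- list(seed = config$seed)
  result <- tryCatch({
    stage <- "catalog"
    catalog <- load_assay_catalog(config$catalog)
    cat_sum <- summarize_catalog(catalog, exclude = config$exclude)
    summary$catalog <- list(n = nrow(catalog),
                            counts = lapply(cat_sum[c("timing", "parental_mark",
                                                      "ctcf_class", "cpg_island")],
                                            as.list))
    emit(catalog, "catalog.csv")
    log_stage(stage, sprintf("%d assays in, %d after exclusion", nrow(catalog),
                             cat_sum$n))

    stage <- "window"
    if (is.numeric(config$window)) {
      window <- fixed_dmr_window(config$window[1], config$window[2])
    } else {
      std <- read_methylation_table(config$standards)
      m <- assay_sample_means(std)
      # the window comes from the 50% standards (the "known DMR" templates);
      # other mixture points calibrate linearity, not the window
      is50 <- !is.na(m$dose_label) & m$dose_label == "mix_50"
      readings <- if (any(is50)) m$mean[is50] else m$mean
      window <- derive_dmr_window(readings, k = config$k)
    }
    summary$window <- list(lower = window$lower, upper = window$upper,
                           center = window$center, spread = window$spread,
                           k = window$k)
    log_stage(stage, sprintf("window %.2f-%.2f", window$lower, window$upper))

    stage <- "classification"
    dataset <- NULL
    if (!is.null(config$methylation)) {
      dataset <- read_methylation_table(config$methylation)
      panel <- tryCatch(filter_group(dataset, "tissue_panel"),
                        error = function(e) dataset)
      if (nrow(panel$values) > 0) {
        cls <- classify_dataset(panel, window)
        ever <- ever_differential(cls)
        emit(data.frame(cls, check.names = FALSE), "classification.csv")
        summary$classification <- list(
          n_assays = length(ever),
          category_counts = as.list(table(cls$category)),
          never_differential = names(ever)[!ever])
        log_stage(stage, sprintf("%d assay x tissue cells", nrow(cls)))
      } else log_stage(stage, "skipped: no tissue_panel samples")
    } else log_stage(stage, "skipped: no methylation table")

    stage <- "features"
    feats <- list()
    for (f in c("ctcf", "cpg_island", "position", "density")) {
      r <- tryCatch(feature_association(catalog, f, exclude = config$exclude),
                    error = function(e) NULL, warning = function(w)
                      suppressWarnings(feature_association(catalog, f,
                                                           exclude = config$exclude)))
      if (is.null(r)) next
      feats[[f]] <- if (inherits(r, "density_association"))
        list(r_squared = r$r_squared, slope = r$slope, n = r$n)
      else list(statistic = r$statistic, p_value = r$p_value, n = r$n)
    }
    summary$feature_associations <- feats
    emit(data.frame(feature = names(feats),
                    value = vapply(feats, function(x)
                      if (!is.null(x$r_squared)) x$r_squared else x$p_value,
                      numeric(1)),
                    measure = vapply(feats, function(x)
                      if (!is.null(x$r_squared)) "r_squared" else "p_value",
                      character(1))),
         "feature_associations.csv")
    log_stage(stage, paste(names(feats), collapse = ", "))

    stage <- "outliers"
    if (!is.null(dataset)) {
      blood <- tryCatch(filter_group(dataset, "blood"), error = function(e) NULL)
      if (!is.null(blood) && nrow(blood$values) > 0) {
        report <- flag_population_outliers(blood, levels = config$levels)
        emit(report$flags, "outlier_flags.csv")
        emit(report$intervals, "outlier_intervals.csv")
        burden <- tryCatch(individual_burden(blood, report),
                           error = function(e) NULL)
        summary$outliers <- list(
          n_flags = stats::setNames(
            lapply(config$levels, function(lv)
              sum(report$flags$level_exceeded >= lv)),
            paste0("level_", config$levels)),
          burden_anova_p = if (!is.null(burden)) burden$anova_p else NA)
        cis <- cis_cluster_correlation(blood, catalog)
        if (nrow(cis) > 0) emit(data.frame(cis), "cis_cluster.csv")
        summary$cis_max_r_squared <- attr(cis, "max_r_squared")
        log_stage(stage, sprintf("%d flag rows", nrow(report$flags)))
      } else log_stage(stage, "skipped: no blood samples")
    } else log_stage(stage, "skipped: no methylation table")

    stage <- "report"
    writeLines(log_lines, file.path(config$out_dir, "run.log"))
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summary
  }, error = function(e) {
    unlink(created)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
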