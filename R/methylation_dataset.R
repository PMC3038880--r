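SAMPLE_META_COLUMNS <- c("sample", "individual", "tissue", "group", "replicate",
                         "template_mass_ng", "dose_label")

#' Construct a per-CpG methylation dataset
#'
#' The central data container: long-format per-CpG pyrosequencing
#' percentages (assay x sample x CpG index) plus per-sample metadata.
#' Values are percent methylation in [0, 100]; individual CpG readings may be
#' missing (real pyrosequencing runs drop single dispensations) and are
#' excluded pairwise from downstream statistics.
#'
#' @param values Data frame with columns `assay`, `sample`, `cpg_index`
#'   (contiguous from 1 within each assay) and `percent` (in [0, 100] or NA).
#' @param samples Optional per-sample metadata data frame with a `sample`
#'   column and any of `individual`, `tissue`, `group`, `replicate`,
#'   `template_mass_ng`, `dose_label`. Missing metadata columns are filled
#'   with NA.
#' @return An object of class `meth_dataset`: a list with elements `values`
#'   and `samples`.
#' @export
methylation_dataset <- function(values, samples = NULL) {
  req <- c("assay", "sample", "cpg_index", "percent")
  missing_cols <- setdiff(req, names(values))
  if (length(missing_cols) > 0)
    stop("values is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  values <- values[req]
  values$assay <- as.character(values$assay)
  values$sample <- as.character(values$sample)
  values$cpg_index <- as.integer(values$cpg_index)
  values$percent <- as.numeric(values$percent)

  bad <- !is.na(values$percent) & (values$percent < 0 | values$percent > 100)
  if (any(bad))
    stop(sprintf("methylation percent out of [0,100]: %s (assay %s, sample %s)",
                 values$percent[bad][1L], values$assay[bad][1L],
                 values$sample[bad][1L]), call. = FALSE)
  key <- paste(values$assay, values$sample, values$cpg_index, sep = "\r")
  if (anyDuplicated(key)) {
    d <- values[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate (assay, sample, cpg_index) key: (%s, %s, %d)",
                 d$assay, d$sample, d$cpg_index), call. = FALSE)
  }
  # CpG indices must be contiguous from 1 within each assay
  for (a in unique(values$assay)) {
    idx <- sort(unique(values$cpg_index[values$assay == a]))
    if (!identical(idx, seq_len(max(idx))))
      stop("assay '", a, "': cpg_index not contiguous from 1", call. = FALSE)
  }

  if (is.null(samples)) {
    samples <- data.frame(sample = unique(values$sample), stringsAsFactors = FALSE)
  }
  if (!"sample" %in% names(samples))
    stop("samples metadata needs a 'sample' column", call. = FALSE)
  samples$sample <- as.character(samples$sample)
  if (anyDuplicated(samples$sample))
    stop("duplicate sample in metadata: ",
         samples$sample[duplicated(samples$sample)][1L], call. = FALSE)
  for (col in setdiff(SAMPLE_META_COLUMNS, names(samples))) samples[[col]] <- NA
  samples <- samples[SAMPLE_META_COLUMNS]
  orphan <- setdiff(values$sample, samples$sample)
  if (length(orphan) > 0)
    stop("sample(s) in values without metadata: ",
         paste(orphan, collapse = ", "), call. = FALSE)

  structure(list(values = values, samples = samples), class = "meth_dataset")
}

#' @export
print.meth_dataset <- function(x, ...) {
  cat("Per-CpG methylation dataset: ", length(unique(x$values$assay)),
      " assays x ", nrow(x$samples), " samples, ", nrow(x$values),
      " readings (", sum(is.na(x$values$percent)), " missing)\n", sep = "")
  invisible(x)
}

#' Read a long-format methylation table
#'
#' Reads a CSV (or TSV, by file extension) long-format table with required
#' columns `assay`, `sample`, `cpg_index`, `percent` and any of the optional
#' per-sample metadata columns (`individual`, `tissue`, `group`, `replicate`,
#' `template_mass_ng`, `dose_label`), which must be constant within a sample.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file.
#' @return A [methylation_dataset()].
#' @export
read_methylation_table <- function(path) {
  if (!file.exists(path)) stop("methylation table not found: ", path, call. = FALSE)
  tab <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE))
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  else
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(SAMPLE_META_COLUMNS, names(tab))
  meta_cols <- union("sample", meta_cols)
  samples <- unique(tab[meta_cols])
  if (anyDuplicated(samples$sample))
    stop("inconsistent per-sample metadata for sample: ",
         samples$sample[duplicated(samples$sample)][1L], call. = FALSE)
  methylation_dataset(tab, samples)
}

#' Write a methylation dataset to a long-format table
#'
#' Inverse of [read_methylation_table()]: merges sample metadata back onto the
#' per-CpG values and writes one CSV/TSV row per reading.
#'
#' @param dataset A `meth_dataset`.
#' @param path Output path; `.tsv`/`.txt` writes tab-separated, otherwise CSV.
#' @return `path`, invisibly.
#' @export
write_methylation_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "meth_dataset"))
  tab <- merge(dataset$values, dataset$samples, by = "sample", sort = FALSE)
  tab <- tab[c("assay", "sample", "cpg_index", "percent",
               setdiff(SAMPLE_META_COLUMNS, "sample"))]
  tab <- tab[order(tab$assay, tab$sample, tab$cpg_index), ]
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE))
    utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  else
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per assay x sample mean methylation
#'
#' Collapses the per-CpG readings to one mean percent per (assay, sample),
#' with missing CpGs excluded pairwise.
#'
#' @param dataset A `meth_dataset`.
#' @return Data frame with columns `assay`, `sample`, `mean` and the sample
#'   metadata joined on.
#' @export
assay_sample_means <- function(dataset) {
  stopifnot(inherits(dataset, "meth_dataset"))
  agg <- stats::aggregate(percent ~ assay + sample, data = dataset$values,
                          FUN = mean, na.rm = TRUE, na.action = stats::na.pass)
  names(agg)[names(agg) == "percent"] <- "mean"
  agg$mean[is.nan(agg$mean)] <- NA_real_
  merge(agg, dataset$samples, by = "sample", sort = FALSE)
}

#' Restrict a dataset to one sample group
#'
#' @param dataset A `meth_dataset`.
#' @param group Group label to keep (e.g. `"standard"`, `"blood"`).
#' @return A `meth_dataset` with only the matching samples.
#' @export
filter_group <- function(dataset, group) {
  stopifnot(inherits(dataset, "meth_dataset"))
  keep <- dataset$samples$sample[!is.na(dataset$samples$group) &
                                   dataset$samples$group == group]
  methylation_dataset(
    dataset$values[dataset$values$sample %in% keep, , drop = FALSE],
    dataset$samples[dataset$samples$sample %in% keep, , drop = FALSE]
  )
}
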