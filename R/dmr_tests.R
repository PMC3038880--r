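meth_test <- function(statistic, p_value, test_name, n, ...) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 test_name = test_name, n = n, ...),
            class = "meth_test")
}

#' @export
print.meth_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g (n = %d)\n",
              x$test_name, x$statistic, x$p_value, x$n))
  invisible(x)
}

# Matched-pair t-test that tolerates degenerate (zero-variance) differences:
# identical vectors give statistic 0 / p 1; a constant nonzero shift gives
# +/-Inf / p 0 instead of stats::t.test()'s "data are essentially constant".
paired_t <- function(x, y) {
  d <- x - y
  d <- d[!is.na(d)]
  if (length(d) < 2) stop("need >= 2 complete pairs", call. = FALSE)
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(statistic = 0, p.value = 1, n = length(d)))
    return(list(statistic = sign(mean(d)) * Inf, p.value = 0, n = length(d)))
  }
  tt <- stats::t.test(d)
  list(statistic = unname(tt$statistic), p.value = tt$p.value, n = length(d))
}

welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 values per group", call. = FALSE)
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(statistic = 0, p.value = 1, n = length(x) + length(y)))
    return(list(statistic = sign(mean(x) - mean(y)) * Inf, p.value = 0,
                n = length(x) + length(y)))
  }
  tt <- stats::t.test(x, y)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       n = length(x) + length(y))
}

#' Compare intra-CpG variability between parental classes
#'
#' Tests whether paternally methylated DMRs show greater within-region
#' (intra-CpG) variability than maternally methylated DMRs. With
#' `pairing = "by_sample"` each sample contributes one (mean maternal SD,
#' mean paternal SD) pair and a matched-pair t-test is used; otherwise the
#' per-record SDs enter an unpaired Welch t-test.
#'
#' @param records Data frame from [intra_cpg_variability()] with columns
#'   `sample`, `parental_mark`, `intra_cpg_sd`.
#' @param pairing `"by_sample"` (default) or `"unpaired"`.
#' @return A `meth_test` (statistic, p_value, test_name, n).
#' @export
compare_parental_variability <- function(records,
                                         pairing = c("by_sample", "unpaired")) {
  pairing <- match.arg(pairing)
  stopifnot(all(c("sample", "parental_mark", "intra_cpg_sd") %in% names(records)))
  records <- records[records$parental_mark %in% c("maternal", "paternal") &
                       !is.na(records$intra_cpg_sd), , drop = FALSE]
  for (cls in c("maternal", "paternal"))
    if (!any(records$parental_mark == cls))
      stop("no ", cls, " records", call. = FALSE)
  if (pairing == "by_sample") {
    per <- stats::aggregate(intra_cpg_sd ~ sample + parental_mark,
                            data = records, FUN = mean)
    wide <- merge(per[per$parental_mark == "maternal", c("sample", "intra_cpg_sd")],
                  per[per$parental_mark == "paternal", c("sample", "intra_cpg_sd")],
                  by = "sample", suffixes = c("_mat", "_pat"))
    if (nrow(wide) < 2)
      stop("need >= 2 samples with both parental classes", call. = FALSE)
    r <- paired_t(wide$intra_cpg_sd_mat, wide$intra_cpg_sd_pat)
    meth_test(r$statistic, r$p.value,
              "matched-pair t-test (maternal vs paternal intra-CpG SD)", r$n)
  } else {
    r <- welch_t(records$intra_cpg_sd[records$parental_mark == "maternal"],
                 records$intra_cpg_sd[records$parental_mark == "paternal"])
    meth_test(r$statistic, r$p.value,
              "Welch t-test (maternal vs paternal intra-CpG SD)", r$n)
  }
}

#' Test deviation of one tissue from the somatic average
#'
#' For each assay, pairs the focal tissue's mean methylation with the mean of
#' all other tissues, then runs a matched-pair t-test across assays. The
#' canonical use is testis versus the somatic tissues: sperm cells erase
#' maternal imprints, so maternal germ-line DMRs collapse there.
#'
#' @param dataset A `meth_dataset` with tissue metadata.
#' @param focal_tissue Tissue label to contrast.
#' @param assay_subset Optional character vector of assays to include
#'   (>= 2 required).
#' @return A `meth_test`.
#' @export
tissue_deviation_test <- function(dataset, focal_tissue, assay_subset = NULL) {
  stopifnot(inherits(dataset, "meth_dataset"))
  m <- assay_sample_means(dataset)
  if (!focal_tissue %in% m$tissue)
    stop("focal tissue '", focal_tissue, "' absent", call. = FALSE)
  if (!is.null(assay_subset)) m <- m[m$assay %in% assay_subset, , drop = FALSE]
  cell <- stats::aggregate(mean ~ assay + tissue, data = m, FUN = mean,
                           na.rm = TRUE)
  if (length(unique(cell$tissue)) < 2) stop("need >= 2 tissues", call. = FALSE)
  assays <- unique(cell$assay)
  if (length(assays) < 2) stop("need >= 2 assays", call. = FALSE)
  focal <- sapply(assays, function(a)
    cell$mean[cell$assay == a & cell$tissue == focal_tissue][1])
  others <- sapply(assays, function(a)
    mean(cell$mean[cell$assay == a & cell$tissue != focal_tissue]))
  r <- paired_t(focal, others)
  meth_test(r$statistic, r$p.value,
            sprintf("matched-pair t-test (%s vs other tissues)", focal_tissue),
            r$n)
}

#' CpG density around a point
#'
#' Counts CpG dinucleotides whose first base lies within `flank` bp on each
#' side of `midpoint` (a half-open window of 2 x flank bases) and reports
#' sites per 100 bp. With the default 250 bp flank the density is count / 5,
#' matching the 0.2-granularity of the packaged catalog. CpGs are counted on
#' the top strand only; CG is its own reverse complement, so this equals
#' both-strand site counting.
#'
#' @param sequence DNA string.
#' @param midpoint 1-based position within `sequence` (e.g. the amplicon
#'   midpoint).
#' @param flank Half-window in bp (default 250).
#' @return CpG sites per 100 bp.
#' @export
cpg_density <- function(sequence, midpoint, flank = 250) {
  n <- nchar(sequence)
  lo <- midpoint - flank
  hi <- midpoint + flank - 1L  # first base of a counted CG lies in [lo, hi]
  if (lo < 1 || hi > n)
    stop("window [", lo, ", ", hi, "] exceeds sequence of length ", n,
         call. = FALSE)
  p <- cpg_positions(sequence)
  sum(p >= lo & p <= hi) / (2 * flank / 100)
}

#' Association of average somatic methylation with a genomic feature
#'
#' Tests whether average somatic methylation across the catalog relates to a
#' genomic feature: CTCF occupancy (two-sample t-test, variable and
#' constitutive pooled as "binding"; the three-level breakdown is attached),
#' CpG-island status (two-sample t-test), genomic position (one-way ANOVA
#' over location categories, groups with n < 2 dropped with a warning), or
#' CpG density (OLS r-squared of methylation on density).
#'
#' @param catalog An `assay_catalog`.
#' @param feature One of `"ctcf"`, `"cpg_island"`, `"position"`, `"density"`.
#' @param exclude Assay names to remove first (e.g. the five never-DMR
#'   assays); the DMR-set membership is deliberately a parameter, not a
#'   constant.
#' @return For `"density"` a `density_association` (slope, intercept,
#'   r_squared, n); otherwise a `meth_test`.
#' @export
feature_association <- function(catalog,
                                feature = c("ctcf", "cpg_island", "position",
                                            "density"),
                                exclude = character()) {
  feature <- match.arg(feature)
  stopifnot(inherits(catalog, "assay_catalog"))
  missing <- setdiff(exclude, catalog$name)
  if (length(missing) > 0)
    stop("exclusion name(s) not in catalog: ", paste(missing, collapse = ", "),
         call. = FALSE)
  cc <- catalog[!(catalog$name %in% exclude), , drop = FALSE]
  y <- cc$avg_somatic_methylation

  if (feature == "density") {
    if (stats::sd(cc$cpg_density) == 0)
      stop("constant predictor: cpg_density has no variation", call. = FALSE)
    fit <- stats::lm(y ~ cpg_density, data = cc)
    return(structure(list(slope = unname(stats::coef(fit)[2]),
                          intercept = unname(stats::coef(fit)[1]),
                          r_squared = stats::cor(cc$cpg_density, y)^2,
                          n = nrow(cc), feature = "density"),
                     class = "density_association"))
  }
  if (feature == "ctcf") {
    binding <- cc$ctcf_class %in% c("constitutive", "variable")
    r <- welch_t(y[binding], y[!binding])
    out <- meth_test(r$statistic, r$p.value,
                     "Welch t-test (CTCF binding vs none)", r$n)
    out$group_means <- tapply(y, cc$ctcf_class, mean)
    return(out)
  }
  if (feature == "cpg_island") {
    r <- welch_t(y[cc$cpg_island], y[!cc$cpg_island])
    return(meth_test(r$statistic, r$p.value,
                     "Welch t-test (CpG island vs not)", r$n))
  }
  # position: one-way ANOVA over location categories
  grp <- droplevels(cc$location_category)
  small <- names(which(table(grp) < 2))
  if (length(small) > 0) {
    warning("location group(s) with n < 2 dropped: ",
            paste(small, collapse = ", "))
    keep <- !(grp %in% small)
    grp <- droplevels(grp[keep]); y <- y[keep]
  }
  if (nlevels(grp) < 2) stop("need >= 2 location groups", call. = FALSE)
  if (stats::sd(y) == 0)
    return(meth_test(0, 1, "one-way ANOVA (location category)", length(y)))
  fit <- stats::aov(y ~ grp)
  s <- summary(fit)[[1]]
  meth_test(s[["F value"]][1], s[["Pr(>F)"]][1],
            "one-way ANOVA (location category)", length(y))
}

#' @export
print.density_association <- function(x, ...) {
  cat(sprintf(
    "CpG density association: r^2 %.3f (slope %.3f %%/CpG-per-100bp, n = %d)\n",
    x$r_squared, x$slope, x$n))
  invisible(x)
}
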