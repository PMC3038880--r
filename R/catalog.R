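PARENTAL_LEVELS <- c("maternal", "paternal", "none", "unknown")
TIMING_LEVELS   <- c("germline", "germline_qualified", "somatic", "none", "unknown")
CTCF_LEVELS     <- c("none", "constitutive", "variable")
LOCATION_LEVELS <- c("promoter", "isoform_promoter", "embedded_gene_promoter",
                     "antisense_promoter", "five_prime_upstream", "intergenic",
                     "gene_body_exonic", "gene_body_intronic")

CATALOG_COLUMNS <- c("name", "chromosome", "position", "parental_mark", "timing",
                     "avg_somatic_methylation", "location_category", "cpg_island",
                     "ctcf_class", "cpg_density", "cluster_id")

#' Path to the packaged assay catalog
#'
#' Location of the transcribed 49-assay imprinted-DMR catalog shipped with the
#' package (see `inst/extdata/README.md` for provenance notes).
#'
#' @return File path to the packaged CSV catalog.
#' @export
packaged_catalog_path <- function() {
  system.file("extdata", "table1_assays.csv", package = "imprintpsq", mustWork = TRUE)
}

norm_enum <- function(x, map, levels, column, row) {
  x <- trimws(as.character(x))
  key <- tolower(x)
  out <- ifelse(key %in% names(map), unname(map[key]), key)
  bad <- !(out %in% levels)
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf("catalog row %d, column '%s': unrecognised value '%s'",
                 row[i], column, x[i]), call. = FALSE)
  }
  factor(out, levels = levels)
}

#' Load an assay catalog
#'
#' Reads a CSV assay catalog (one row per pyrosequencing assay) and normalises
#' it to canonical form: '#'-suffixed germ-line entries become
#' `timing = "germline_qualified"`, CTCF codes map `Y` to `constitutive`,
#' `YV` to `variable` and `N` to `none`, and `Yes`/`No` island flags become
#' logical. Already-canonical values are accepted unchanged.
#'
#' @param path Path to a catalog CSV with the columns
#'   `name,chromosome,position,parental_mark,timing,avg_somatic_methylation,`
#'   `location_category,cpg_island,ctcf_class,cpg_density,cluster_id`.
#' @return A data frame of class `assay_catalog` with canonical columns;
#'   `cluster_id` is `NA` for singleton assays.
#' @examples
#' cat49 <- load_assay_catalog(packaged_catalog_path())
#' nrow(cat49)
#' @export
load_assay_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(CATALOG_COLUMNS, names(raw))
  if (length(missing_cols) > 0)
    stop("catalog is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0) {
    out <- empty_catalog()
    return(out)
  }
  rowno <- seq_len(nrow(raw))

  name <- trimws(raw$name)
  if (anyDuplicated(name))
    stop("duplicate assay name in catalog: ",
         paste(unique(name[duplicated(name)]), collapse = ", "), call. = FALSE)
  if (any(name == ""))
    stop(sprintf("catalog row %d, column 'name': empty", which(name == "")[1L]),
         call. = FALSE)

  num_col <- function(x, column, lo = -Inf, hi = Inf) {
    v <- suppressWarnings(as.numeric(x))
    bad <- is.na(v) | v < lo | v > hi
    if (any(bad))
      stop(sprintf("catalog row %d, column '%s': invalid value '%s'",
                   rowno[bad][1L], column, x[bad][1L]), call. = FALSE)
    v
  }

  position <- num_col(raw$position, "position", lo = 1)
  avg <- num_col(raw$avg_somatic_methylation, "avg_somatic_methylation", 0, 100)
  density <- num_col(raw$cpg_density, "cpg_density", lo = 0)
  # printed densities are multiples of 0.2 (count over a 500 bp window / 5)
  off_grid <- abs(density / 0.2 - round(density / 0.2)) > 1e-8
  if (any(off_grid))
    stop(sprintf("catalog row %d, column 'cpg_density': %s is not a multiple of 0.2",
                 rowno[off_grid][1L], raw$cpg_density[off_grid][1L]), call. = FALSE)

  timing_raw <- trimws(raw$timing)
  qualified <- grepl("#$", timing_raw)
  timing_base <- sub("#$", "", timing_raw)
  timing <- norm_enum(timing_base,
                      c("germ-line" = "germline", "germ line" = "germline",
                        "germline_qualified" = "germline_qualified"),
                      TIMING_LEVELS, "timing", rowno)
  timing[qualified & timing == "germline"] <- "germline_qualified"

  parental <- norm_enum(raw$parental_mark, c(), PARENTAL_LEVELS, "parental_mark", rowno)
  ctcf <- norm_enum(raw$ctcf_class,
                    c("y" = "constitutive", "yv" = "variable", "n" = "none"),
                    CTCF_LEVELS, "ctcf_class", rowno)
  location <- norm_enum(raw$location_category, c(), LOCATION_LEVELS,
                        "location_category", rowno)

  island_raw <- tolower(trimws(raw$cpg_island))
  island <- island_raw %in% c("yes", "y", "true", "1")
  bad_island <- !(island_raw %in% c("yes", "y", "true", "1", "no", "n", "false", "0"))
  if (any(bad_island))
    stop(sprintf("catalog row %d, column 'cpg_island': invalid value '%s'",
                 rowno[bad_island][1L], raw$cpg_island[bad_island][1L]), call. = FALSE)

  cluster <- trimws(raw$cluster_id)
  cluster[cluster == ""] <- NA_character_

  out <- data.frame(
    name = name,
    chromosome = trimws(raw$chromosome),
    position = as.integer(position),
    parental_mark = parental,
    timing = timing,
    avg_somatic_methylation = avg,
    location_category = location,
    cpg_island = island,
    ctcf_class = ctcf,
    cpg_density = density,
    cluster_id = cluster,
    stringsAsFactors = FALSE
  )
  class(out) <- c("assay_catalog", "data.frame")
  out
}

empty_catalog <- function() {
  out <- data.frame(
    name = character(), chromosome = character(), position = integer(),
    parental_mark = factor(character(), levels = PARENTAL_LEVELS),
    timing = factor(character(), levels = TIMING_LEVELS),
    avg_somatic_methylation = numeric(),
    location_category = factor(character(), levels = LOCATION_LEVELS),
    cpg_island = logical(),
    ctcf_class = factor(character(), levels = CTCF_LEVELS),
    cpg_density = numeric(), cluster_id = character(),
    stringsAsFactors = FALSE
  )
  class(out) <- c("assay_catalog", "data.frame")
  out
}

#' Summarise an assay catalog
#'
#' Counts assays by germ-line/somatic timing, parent-of-origin mark, CTCF
#' occupancy class and CpG-island status, optionally after removing a named
#' exclusion set (e.g. the assays that never report differential methylation
#' in any tissue).
#'
#' @param catalog An `assay_catalog` from [load_assay_catalog()].
#' @param exclude Character vector of assay names to remove before counting.
#'   Every name must be present in the catalog.
#' @return A `catalog_summary`: a list of named integer count tables
#'   (`timing`, `parental_mark`, `ctcf_class`, `cpg_island`) plus `n`, the
#'   catalog size after exclusion.
#' @examples
#' cat49 <- load_assay_catalog(packaged_catalog_path())
#' summarize_catalog(cat49)$timing[["germline"]]
#' @export
summarize_catalog <- function(catalog, exclude = character()) {
  stopifnot(inherits(catalog, "assay_catalog"))
  missing <- setdiff(exclude, catalog$name)
  if (length(missing) > 0)
    stop("exclusion name(s) not in catalog: ", paste(missing, collapse = ", "),
         call. = FALSE)
  keep <- !(catalog$name %in% exclude)
  cc <- catalog[keep, , drop = FALSE]
  count_of <- function(x) {
    tab <- table(x)
    stats::setNames(as.integer(tab), names(tab))
  }
  out <- list(
    n = nrow(cc),
    timing = count_of(cc$timing),
    parental_mark = count_of(cc$parental_mark),
    ctcf_class = count_of(cc$ctcf_class),
    cpg_island = count_of(factor(cc$cpg_island, levels = c("FALSE", "TRUE")))
  )
  class(out) <- "catalog_summary"
  out
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("Assay catalog summary (", x$n, " assays)\n", sep = "")
  for (field in c("timing", "parental_mark", "ctcf_class", "cpg_island")) {
    cat("  ", field, ": ",
        paste(sprintf("%s=%d", names(x[[field]]), x[[field]]), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.assay_catalog <- function(x, ...) {
  cat("Imprinted-DMR assay catalog: ", nrow(x), " assays on ",
      length(unique(x$chromosome)), " chromosomes\n", sep = "")
  NextMethod()
}
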