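#' Read a BED3/BED4 interval file
#'
#' Parses a minimal BED file (chromosome, start, end and optional name
#' column). Coordinates are kept exactly as in the file: 0-based start,
#' exclusive end. Records are retained in file order; sorting is never
#' required for overlap queries.
#'
#' @param path Path to a BED3+ file; extra columns beyond the fourth are
#'   ignored. Lines starting with `track` or `#` are skipped.
#' @return A data frame of class `interval_set` with columns `chromosome`,
#'   `start`, `end`, `label` (NA when absent).
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("interval file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  out <- data.frame(chromosome = character(), start = integer(), end = integer(),
                    label = character(), stringsAsFactors = FALSE)
  rows <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("line %d: expected at least 3 tab-separated fields", i),
           call. = FALSE)
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      stop(sprintf("line %d: non-numeric coordinates", i), call. = FALSE)
    if (start < 0)
      stop(sprintf("line %d: negative start coordinate", i), call. = FALSE)
    if (start >= end)
      stop(sprintf("line %d: start (%d) >= end (%d)", i, start, end),
           call. = FALSE)
    j <- j + 1L
    rows[[j]] <- data.frame(chromosome = f[1], start = start, end = end,
                            label = if (length(f) >= 4) f[4] else NA_character_,
                            stringsAsFactors = FALSE)
  }
  if (j > 0) out <- do.call(rbind, rows[seq_len(j)])
  class(out) <- c("interval_set", "data.frame")
  out
}

#' @export
print.interval_set <- function(x, ...) {
  cat("Interval set: ", nrow(x), " records on ",
      length(unique(x$chromosome)), " chromosomes\n", sep = "")
  NextMethod()
}

#' Convert 1-based point positions to 0-based half-open intervals
#'
#' Catalog positions are 1-based (as printed); all interval arithmetic is
#' 0-based half-open (BED). The conversion is explicit so printed coordinates
#' are never silently shifted.
#'
#' @param position Integer vector of 1-based positions.
#' @param flank Symmetric flank in bp added to each side (default 0: a
#'   single-base interval).
#' @return Data frame with `start` (0-based) and `end` (exclusive).
#' @export
position_to_interval <- function(position, flank = 0) {
  stopifnot(all(position >= 1), flank >= 0)
  data.frame(start = pmax(0L, as.integer(position) - 1L - as.integer(flank)),
             end = as.integer(position) + as.integer(flank))
}

#' Overlap query between two interval sets
#'
#' Finds all pairs of overlapping records (same chromosome, half-open
#' overlap) between `query` and `subject` using IRanges.
#'
#' @param query,subject `interval_set` data frames (or anything with
#'   `chromosome`, `start`, `end` columns in 0-based half-open coordinates).
#' @return Data frame with columns `query_idx`, `subject_idx` (row indices
#'   into the inputs).
#' @export
overlap_intervals <- function(query, subject) {
  out <- data.frame(query_idx = integer(), subject_idx = integer())
  if (nrow(query) == 0 || nrow(subject) == 0) return(out)
  for (chr in intersect(unique(query$chromosome), unique(subject$chromosome))) {
    qi <- which(query$chromosome == chr)
    si <- which(subject$chromosome == chr)
    # half-open [start, end) maps to closed IRanges [start+1, end]
    qr <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
    sr <- IRanges::IRanges(start = subject$start[si] + 1L, end = subject$end[si])
    hits <- IRanges::findOverlaps(qr, sr)
    if (length(hits) > 0)
      out <- rbind(out, data.frame(query_idx = qi[S4Vectors::queryHits(hits)],
                                   subject_idx = si[S4Vectors::subjectHits(hits)]))
  }
  out[order(out$query_idx, out$subject_idx), , drop = FALSE]
}
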