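#' Universal biotinylated second-round tag
#'
#' The common biotinylated reverse-primer tag used for second-round
#' amplification; biotin itself is metadata, not sequence.
#' @format A length-1 character string.
#' @export
PSQ_UNIVERSAL_TAG <- "CGCCAGGGTTTTCCCAGTCACGAC"

seq_chars <- function(sequence) strsplit(toupper(sequence), "", fixed = TRUE)[[1]]

#' In-silico bisulfite conversion
#'
#' Converts a genomic top-strand sequence as sodium bisulfite would: every
#' cytosine outside a CpG context is deaminated and read as T; a cytosine in
#' CpG context is read as C when the template is fully methylated and T when
#' unmethylated. Length and all non-C bases are preserved.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param state `"methylated"` (CpG cytosines protected) or
#'   `"unmethylated"` (all cytosines converted).
#' @return The converted DNA string.
#' @examples
#' bisulfite_convert("ACGTCGAC", "unmethylated")  # "ATGTTGAT"
#' bisulfite_convert("ACGTCGAC", "methylated")    # "ACGTCGAT"
#' @export
bisulfite_convert <- function(sequence, state = c("methylated", "unmethylated")) {
  state <- match.arg(state)
  ch <- seq_chars(sequence)
  bad <- !(ch %in% c("A", "C", "G", "T", "N"))
  if (any(bad))
    stop(sprintf("invalid character '%s' at position %d", ch[bad][1L],
                 which(bad)[1L]), call. = FALSE)
  n <- length(ch)
  if (n == 0) return("")
  is_c <- ch == "C"
  in_cpg <- is_c & c(ch[-1] == "G", FALSE)
  convert <- if (state == "methylated") is_c & !in_cpg else is_c
  ch[convert] <- "T"
  paste(ch, collapse = "")
}

#' Wallace-rule primer melting temperature
#'
#' Tm = 2(A+T) + 4(G+C) degrees C. This deliberately simple convention makes
#' the 56 degree design constraint reproducible; it is a design window, not a
#' thermodynamic prediction.
#'
#' @param primer DNA string, length >= 8, no ambiguity codes.
#' @return Melting temperature in degrees C.
#' @export
primer_melting_temperature <- function(primer) {
  ch <- seq_chars(primer)
  if (length(ch) < 8) stop("primer shorter than 8 nt", call. = FALSE)
  bad <- !(ch %in% c("A", "C", "G", "T"))
  if (any(bad))
    stop("ambiguity code or invalid base '", ch[bad][1L], "' in primer",
         call. = FALSE)
  2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
}

#' Primer design constraints
#'
#' @param target_tm Target melting temperature in degrees C (default 56).
#' @param tm_tolerance Allowed deviation from `target_tm` (default 2).
#' @param primer_length_range Min/max primer length in nt (default 18-30; the
#'   source protocol states no bounds, these are configurable defaults).
#' @param max_cpg_in_primer Maximum CpG dinucleotides allowed under a primer
#'   footprint (default 0: primers must be methylation-insensitive).
#' @param flank_search_window bp searched on each side of the target span
#'   (default 150).
#' @param forbid_snp_overlap Reject primers overlapping annotated SNPs
#'   (default TRUE).
#' @param max_amplicon Maximum amplicon length in bp (default 350).
#' @param target_cpg_range Allowed number of CpGs read by the assay
#'   (default 3-9).
#' @return A list of class `design_constraints`.
#' @export
design_constraints <- function(target_tm = 56, tm_tolerance = 2,
                               primer_length_range = c(18, 30),
                               max_cpg_in_primer = 0,
                               flank_search_window = 150,
                               forbid_snp_overlap = TRUE,
                               max_amplicon = 350,
                               target_cpg_range = c(3, 9)) {
  stopifnot(target_tm > 0, tm_tolerance >= 0,
            length(primer_length_range) == 2,
            primer_length_range[1] <= primer_length_range[2],
            primer_length_range[1] >= 8,
            max_cpg_in_primer >= 0, flank_search_window > 0, max_amplicon > 0)
  structure(list(target_tm = target_tm, tm_tolerance = tm_tolerance,
                 primer_length_range = as.integer(primer_length_range),
                 max_cpg_in_primer = max_cpg_in_primer,
                 flank_search_window = as.integer(flank_search_window),
                 forbid_snp_overlap = isTRUE(forbid_snp_overlap),
                 max_amplicon = as.integer(max_amplicon),
                 target_cpg_range = as.integer(target_cpg_range)),
            class = "design_constraints")
}

#' Prepend the universal second-round tag to a reverse primer
#'
#' @param reverse_primer Gene-specific reverse primer sequence.
#' @return Tagged primer: [PSQ_UNIVERSAL_TAG] followed by the input.
#' @export
tag_second_round_primer <- function(reverse_primer) {
  if (!is.character(reverse_primer) || length(reverse_primer) != 1 ||
      is.na(reverse_primer) || nchar(reverse_primer) == 0)
    stop("empty reverse primer", call. = FALSE)
  if (startsWith(toupper(reverse_primer), PSQ_UNIVERSAL_TAG))
    stop("already tagged", call. = FALSE)
  paste0(PSQ_UNIVERSAL_TAG, toupper(reverse_primer))
}

cpg_positions <- function(sequence) {
  ch <- seq_chars(sequence)
  if (length(ch) < 2) return(integer())
  which(ch[-length(ch)] == "C" & ch[-1] == "G")
}

revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Design a bisulfite pyrosequencing assay for a target span
#'
#' Exhaustively searches the bisulfite-converted top strand for a
#' deterministic primer pair flanking `target_span`: both primers must sit on
#' CpG-free genomic footprints (methylation-insensitive), hit the target Tm
#' window under the Wallace rule, avoid annotated SNPs, and bracket 3-9
#' target CpGs. The reverse primer is designed against the reverse complement
#' of the converted strand. Ties break to the shortest amplicon, then the
#' leftmost pair, so identical inputs always give identical designs.
#'
#' @param region Genomic (pre-conversion) top-strand DNA string.
#' @param region_offset 1-based genomic coordinate of the first base of
#'   `region` (used only for SNP bookkeeping; default 1).
#' @param target_span Integer pair `(start, end)`, 1-based inclusive
#'   positions within `region`, containing the CpGs to read.
#' @param snps Integer vector of 1-based genomic SNP positions.
#' @param constraints A [design_constraints()] object.
#' @return An object of class `assay_design` with elements `forward_primer`,
#'   `reverse_primer`, `tagged_reverse_primer`, `amplicon_span` (1-based on
#'   the region), `sequence_to_analyze` (converted sequence between the
#'   primers, methylated-template form with CpG cytosines retained) and
#'   `target_cpg_offsets` (1-based offsets of target CpGs within
#'   `sequence_to_analyze`).
#' @export
design_assay <- function(region, region_offset = 1, target_span,
                         snps = integer(), constraints = design_constraints()) {
  stopifnot(inherits(constraints, "design_constraints"),
            length(target_span) == 2)
  region <- toupper(region)
  n <- nchar(region)
  ts <- as.integer(target_span)
  if (ts[1] < 1 || ts[2] > n || ts[1] > ts[2])
    stop("target_span outside region", call. = FALSE)

  n_target_cpg <- sum(cpg_positions(region) >= ts[1] &
                        cpg_positions(region) <= ts[2])
  rng <- constraints$target_cpg_range
  if (n_target_cpg < rng[1] || n_target_cpg > rng[2])
    stop(sprintf("no design: target span contains %d CpGs, outside [%d,%d]",
                 n_target_cpg, rng[1], rng[2]), call. = FALSE)

  converted <- bisulfite_convert(region, "methylated")
  snps_local <- as.integer(snps) - as.integer(region_offset) + 1L
  snps_local <- snps_local[snps_local >= 1 & snps_local <= n]
  reject <- c(cpg_in_primer = 0L, tm = 0L, snp_overlap = 0L)

  candidate_windows <- function(lo, hi) {
    # all (start, len) windows fully inside [lo, hi]
    out <- list()
    for (len in seq(constraints$primer_length_range[1],
                    constraints$primer_length_range[2])) {
      starts <- seq.int(lo, hi - len + 1L)
      starts <- starts[starts >= lo & (starts + len - 1L) <= hi]
      for (s in starts) out[[length(out) + 1L]] <- c(s, len)
    }
    out
  }
  window_ok <- function(s, len) {
    e <- s + len - 1L
    genomic <- substr(region, s, e)
    # CpG under the footprint, including one split across the 3' edge
    n_cpg <- length(cpg_positions(substr(region, s, min(n, e + 1L))))
    if (n_cpg > constraints$max_cpg_in_primer) {
      reject["cpg_in_primer"] <<- reject["cpg_in_primer"] + 1L
      return(FALSE)
    }
    if (constraints$forbid_snp_overlap &&
        any(snps_local >= s & snps_local <= e)) {
      reject["snp_overlap"] <<- reject["snp_overlap"] + 1L
      return(FALSE)
    }
    tm <- primer_melting_temperature(substr(converted, s, e))
    if (abs(tm - constraints$target_tm) > constraints$tm_tolerance) {
      reject["tm"] <<- reject["tm"] + 1L
      return(FALSE)
    }
    TRUE
  }

  fwd_lo <- max(1L, ts[1] - constraints$flank_search_window)
  fwd <- Filter(function(w) window_ok(w[1], w[2]),
                candidate_windows(fwd_lo, ts[1] - 1L))
  rev_hi <- min(n, ts[2] + constraints$flank_search_window)
  rev <- Filter(function(w) window_ok(w[1], w[2]),
                candidate_windows(ts[2] + 1L, rev_hi))

  if (length(fwd) == 0 || length(rev) == 0)
    stop("no design: no feasible ",
         if (length(fwd) == 0) "forward" else "reverse",
         " primer (rejected: ",
         paste(sprintf("%s=%d", names(reject), reject), collapse = ", "), ")",
         call. = FALSE)

  best <- NULL
  for (f in fwd) for (r in rev) {
    amp <- (r[1] + r[2] - 1L) - f[1] + 1L
    if (amp > constraints$max_amplicon) next
    cand <- c(f[1], f[2], r[1], r[2], amp)
    if (is.null(best) || amp < best[5] ||
        (amp == best[5] && (f[1] < best[1] ||
                            (f[1] == best[1] && r[1] < best[3]))))
      best <- cand
  }
  if (is.null(best))
    stop("no design: every feasible pair exceeds max amplicon length ",
         constraints$max_amplicon, call. = FALSE)

  f_start <- best[1]; f_end <- best[1] + best[2] - 1L
  r_start <- best[3]; r_end <- best[3] + best[4] - 1L
  forward_primer <- substr(converted, f_start, f_end)
  reverse_primer <- revcomp(substr(converted, r_start, r_end))
  seq_to_analyze <- substr(converted, f_end + 1L, r_start - 1L)
  offsets <- cpg_positions(region)
  offsets <- offsets[offsets >= ts[1] & offsets <= ts[2]] - f_end

  structure(list(
    forward_primer = forward_primer,
    reverse_primer = reverse_primer,
    tagged_reverse_primer = tag_second_round_primer(reverse_primer),
    amplicon_span = c(f_start, r_end),
    sequence_to_analyze = seq_to_analyze,
    target_cpg_offsets = as.integer(offsets)
  ), class = "assay_design")
}

#' @export
print.assay_design <- function(x, ...) {
  cat("Bisulfite PSQ assay design\n",
      "  forward:  5'-", x$forward_primer, "-3' (Tm ",
      primer_melting_temperature(x$forward_primer), " C)\n",
      "  reverse:  5'-", x$reverse_primer, "-3' (Tm ",
      primer_melting_temperature(x$reverse_primer), " C)\n",
      "  amplicon: ", x$amplicon_span[1], "-", x$amplicon_span[2], " (",
      diff(x$amplicon_span) + 1L, " bp), ", length(x$target_cpg_offsets),
      " target CpGs\n", sep = "")
  invisible(x)
}

#' Read a single region from a FASTA file
#'
#' @param path FASTA file path.
#' @param which Record index or name (default: first record).
#' @return Upper-case DNA string.
#' @export
read_region_fasta <- function(path, which = 1) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("no sequences in ", path, call. = FALSE)
  toupper(as.character(seqs[[which]]))
}
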