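# Independent brute-force oracles, deliberately naive: each recomputes a
# quantity from first principles so the implementation is checked against a
# different code path.

bf_bland_altman <- function(r1, r2) {
  d <- r1 - r2
  m <- sum(d) / length(d)
  v <- sum((d - m)^2) / (length(d) - 1)
  list(bias = m, loa_low = m - 1.96 * sqrt(v), loa_high = m + 1.96 * sqrt(v))
}

bf_cpg_density <- function(sequence, midpoint, flank = 250) {
  ch <- strsplit(sequence, "")[[1]]
  count <- 0
  for (p in seq(midpoint - flank, midpoint + flank - 1)) {
    if (p >= 1 && p + 1 <= length(ch) && ch[p] == "C" && ch[p + 1] == "G")
      count <- count + 1
  }
  count / (2 * flank / 100)
}

bf_overlaps <- function(query, subject) {
  hits <- NULL
  for (i in seq_len(nrow(query))) for (j in seq_len(nrow(subject))) {
    if (query$chromosome[i] == subject$chromosome[j] &&
        query$start[i] < subject$end[j] && subject$start[j] < query$end[i])
      hits <- rbind(hits, data.frame(query_idx = i, subject_idx = j))
  }
  if (is.null(hits))
    return(data.frame(query_idx = integer(), subject_idx = integer()))
  hits[order(hits$query_idx, hits$subject_idx), ]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

count_cg <- function(s) {
  ch <- strsplit(s, "")[[1]]
  if (length(ch) < 2) return(0L)
  sum(ch[-length(ch)] == "C" & ch[-1] == "G")
}

# exhaustive constraint check of a returned design against its inputs
check_design <- function(design, region, target_span, snps,
                         constraints = design_constraints()) {
  f_len <- nchar(design$forward_primer)
  f_start <- design$amplicon_span[1]
  f_span <- f_start:(f_start + f_len - 1)
  r_len <- nchar(design$reverse_primer)
  r_end <- design$amplicon_span[2]
  r_span <- (r_end - r_len + 1):r_end
  ok <- TRUE
  fail <- function(msg) { ok <<- FALSE; message("design check failed: ", msg) }
  for (span in list(f_span, r_span)) {
    foot <- substr(region, min(span), max(span) + 1)
    if (count_cg(substr(foot, 1, length(span) + 1)) > constraints$max_cpg_in_primer)
      fail("CpG under primer footprint")
    if (constraints$forbid_snp_overlap && any(snps %in% span))
      fail("SNP under primer")
  }
  for (p in list(design$forward_primer, design$reverse_primer)) {
    tm <- primer_melting_temperature(p)
    if (abs(tm - constraints$target_tm) > constraints$tm_tolerance)
      fail(sprintf("Tm %g outside window", tm))
    if (grepl("CG", p, fixed = TRUE) && constraints$max_cpg_in_primer == 0)
      fail("CG dinucleotide in primer sequence")
  }
  if (max(f_span) >= target_span[1]) fail("forward primer enters target span")
  if (min(r_span) <= target_span[2]) fail("reverse primer enters target span")
  if (r_end - f_start + 1 > constraints$max_amplicon) fail("amplicon too long")
  n_cpg <- length(design$target_cpg_offsets)
  if (n_cpg < constraints$target_cpg_range[1] ||
      n_cpg > constraints$target_cpg_range[2]) fail("target CpG count")
  ok
}

# tiny hand-built dataset: one assay, three samples across two tissues
tiny_panel <- function() {
  values <- expand.grid(assay = c("A", "B"), sample = c("s1", "s2", "s3"),
                        cpg_index = 1:3, stringsAsFactors = FALSE)
  values$percent <- 50
  samples <- data.frame(sample = c("s1", "s2", "s3"),
                        individual = c("i1", "i2", "i3"),
                        tissue = c("brain", "brain", "liver"),
                        group = "tissue_panel", stringsAsFactors = FALSE)
  methylation_dataset(values, samples)
}

never_dmr_assays <- function() c("UBE3A", "BLCAP", "CDKN1C", "TCEB3C", "RTL")
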