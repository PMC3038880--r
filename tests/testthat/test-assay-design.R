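test_that("bisulfite conversion follows the CpG-context rule", {
  expect_equal(bisulfite_convert("ACGTCGAC", "unmethylated"), "ATGTTGAT")
  expect_equal(bisulfite_convert("ACGTCGAC", "methylated"), "ACGTCGAT")
  expect_equal(bisulfite_convert("TTAA", "methylated"), "TTAA")
  expect_equal(bisulfite_convert("TTAA", "unmethylated"), "TTAA")
  expect_error(bisulfite_convert("ACXT"), "position 3")
})

test_that("methylated and unmethylated conversions differ exactly at CpGs", {
  set.seed(7)
  for (rep in 1:25) {
    s <- random_dna(sample(10:200, 1))
    m <- strsplit(bisulfite_convert(s, "methylated"), "")[[1]]
    u <- strsplit(bisulfite_convert(s, "unmethylated"), "")[[1]]
    expect_equal(sum(m != u), count_cg(s))
    ch <- strsplit(s, "")[[1]]
    expect_equal(which(m != u),
                 which(ch == "C" & c(ch[-1] == "G", FALSE)))
  }
})

test_that("Wallace-rule Tm matches hand counts", {
  expect_equal(primer_melting_temperature(
    paste0(strrep("AT", 6), strrep("GC", 4))), 56)  # 12 A/T + 8 G/C
  expect_equal(primer_melting_temperature("ATATATATATATAT"), 28)
  expect_equal(primer_melting_temperature("GGGGCCCC"), 32)
  expect_error(primer_melting_temperature("ATATATN"), "shorter")
  expect_error(primer_melting_temperature("ATATATNGGG"), "ambiguity")
})

test_that("universal tag concatenation guards its inputs", {
  expect_equal(tag_second_round_primer("AACCTT"),
               "CGCCAGGGTTTTCCCAGTCACGACAACCTT")
  expect_error(tag_second_round_primer(""), "empty")
  expect_error(tag_second_round_primer(
    paste0(PSQ_UNIVERSAL_TAG, "AAA")), "already tagged")
})

test_that("design search finds a valid, deterministic design", {
  reg <- generate_design_region(island_length = 100, island_cpg_count = 5,
                                seed = 12)
  span <- reg$truth$island_span
  d <- design_assay(reg$sequence, target_span = span)
  expect_s3_class(d, "assay_design")
  expect_length(d$target_cpg_offsets, 5)
  expect_true(check_design(d, reg$sequence, span, integer()))
  expect_true(startsWith(d$tagged_reverse_primer, PSQ_UNIVERSAL_TAG))
  expect_true(endsWith(d$tagged_reverse_primer, d$reverse_primer))

  # determinism: identical inputs, identical design
  d2 <- design_assay(reg$sequence, target_span = span)
  expect_identical(d, d2)
})

test_that("constraints exclude designs and errors name the reason", {
  reg <- generate_design_region(island_length = 100, island_cpg_count = 5,
                                seed = 12)
  span <- reg$truth$island_span
  # SNPs blanketing the whole upstream search window kill every forward site
  snps <- seq(max(1, span[1] - 150), span[1] - 1)
  expect_error(design_assay(reg$sequence, target_span = span, snps = snps),
               "no design.*forward.*snp")

  # target with too few CpGs violates the 3-9 rule
  reg2 <- generate_design_region(island_length = 60, island_cpg_count = 2,
                                 seed = 3)
  expect_error(design_assay(reg2$sequence,
                            target_span = reg2$truth$island_span),
               "no design.*2 CpGs")
})

test_that("random returned designs pass the brute-force constraint checker", {
  for (seed in c(4, 21, 33)) {
    reg <- generate_design_region(island_length = 150, island_cpg_count = 7,
                                  seed = seed)
    span <- reg$truth$island_span
    d <- design_assay(reg$sequence, target_span = span)
    expect_true(check_design(d, reg$sequence, span, integer()))
  }
})
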