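test_that("window derivation is mean +/- k x sample SD", {
  w <- derive_dmr_window(c(40, 50, 60), k = 1)
  expect_equal(w$center, 50)
  expect_equal(w$spread, 10)
  expect_equal(c(w$lower, w$upper), c(40, 60))

  w <- derive_dmr_window(c(50, 50, 50), k = 1.5)
  expect_equal(c(w$lower, w$upper), c(50, 50))

  # standards with the published center and spread give the printed bounds
  s <- 14.65 / 1.5
  w <- derive_dmr_window(50.38 + s * c(-1, 0, 1), k = 1.5)
  expect_equal(round(w$lower, 2), 35.73)
  expect_equal(round(w$upper, 2), 65.03)

  expect_error(derive_dmr_window(50), ">= 2")
  expect_error(derive_dmr_window(c(40, 60), k = 0), "k must be")
})

test_that("windows are monotone in k", {
  set.seed(3)
  readings <- rnorm(20, 50, 8)
  ks <- c(0.5, 1, 1.5, 2, 3)
  for (i in seq_len(length(ks) - 1)) {
    w1 <- derive_dmr_window(readings, ks[i])
    w2 <- derive_dmr_window(readings, ks[i + 1])
    expect_gte(w1$lower, w2$lower)
    expect_lte(w1$upper, w2$upper)
  }
})

test_that("classification is exhaustive, exclusive and matches printed values", {
  w <- fixed_dmr_window(35.73, 65.03)
  expect_equal(as.character(classify_value(45.23, w)), "differential")
  expect_equal(as.character(classify_value(12.07, w)), "hypomethylated")
  expect_equal(as.character(classify_value(88.27, w)), "hypermethylated")
  # bounds are inclusive
  expect_equal(as.character(classify_value(c(35.73, 65.03), w)),
               c("differential", "differential"))

  grid <- seq(0, 100, by = 0.25)
  cats <- classify_value(grid, w)
  expect_false(any(is.na(cats)))
  expect_true(all((grid < w$lower) == (cats == "hypomethylated")))
  expect_true(all((grid > w$upper) == (cats == "hypermethylated")))
  expect_error(classify_value(101, w), "outside")
})

test_that("dataset classification flags ever-differential assays", {
  w <- fixed_dmr_window(35, 65)
  vals <- expand.grid(assay = c("A", "B"), sample = paste0("s", 1:4),
                      cpg_index = 1:3, stringsAsFactors = FALSE)
  vals$percent <- ifelse(vals$assay == "A", 50, 90)
  # B dips to 50 in brain only: the brain-specific DMR pattern
  samples <- data.frame(sample = paste0("s", 1:4),
                        tissue = c("brain", "liver", "heart", "kidney"))
  vals$percent[vals$assay == "B" & vals$sample == "s1"] <- 50
  cls <- classify_dataset(methylation_dataset(vals, samples), w)
  ever <- ever_differential(cls)
  expect_true(ever[["A"]])
  expect_true(ever[["B"]])
  expect_equal(as.character(cls$category[cls$assay == "B" &
                                           cls$tissue != "brain"]),
               rep("hypermethylated", 3))

  vals$percent[vals$assay == "B"] <- 90
  cls <- classify_dataset(methylation_dataset(vals, samples), w)
  expect_false(ever_differential(cls)[["B"]])
})

test_that("classification recovers synthetic truth at low noise", {
  cfg <- synthetic_config(n_individuals = 3, measurement_sd = 2, seed = 17)
  cfg$assays$intra_cpg_sd <- 0  # isolate measurement noise
  out <- generate_tissue_panel(cfg)
  cls <- classify_dataset(out$dataset, out$truth$window)
  got <- cls$category
  want <- mapply(function(a, t) out$truth$category[a, t],
                 cls$assay, cls$tissue)
  expect_equal(as.character(got), unname(want))
})

test_that("intra-CpG SD is the sample SD over CpGs", {
  expect_equal(intra_cpg_sd(c(50, 50, 50)), 0)
  expect_equal(intra_cpg_sd(c(40, 50, 60)), 10)
  expect_equal(intra_cpg_sd(c(48, 52)), sqrt(8))
  expect_true(is.na(intra_cpg_sd(c(50, NA))))
})
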