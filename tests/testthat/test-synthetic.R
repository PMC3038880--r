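test_that("generators are deterministic and respect zero noise", {
  cfg <- synthetic_config(n_individuals = 2, measurement_sd = 0, seed = 5)
  cfg$assays$intra_cpg_sd <- 0
  out <- generate_tissue_panel(cfg)
  merged <- merge(out$dataset$values, out$dataset$samples, by = "sample")
  want <- mapply(function(a, t) out$truth$true_means[a, t],
                 merged$assay, merged$tissue)
  expect_equal(merged$percent, unname(want))

  out2 <- generate_tissue_panel(cfg)
  expect_identical(out$dataset, out2$dataset)

  out3 <- generate_tissue_panel(synthetic_config(n_individuals = 2,
                                                 measurement_sd = 0, seed = 6))
  expect_false(identical(out$dataset$values$percent,
                         out3$dataset$values$percent))
})

test_that("somatic-tissue germ-line means stay within a 3-sigma band", {
  cfg <- synthetic_config(n_individuals = 3, measurement_sd = 2, seed = 21)
  cfg$assays$intra_cpg_sd <- 2  # the stated germ-line world: true 50, sd 2
  out <- generate_tissue_panel(cfg)
  m <- assay_sample_means(out$dataset)
  gl <- cfg$assays$name[cfg$assays$timing == "germline"]
  somatic <- m[m$assay %in% gl & m$tissue != "testis", ]
  cell <- aggregate(mean ~ assay + tissue, somatic, mean)
  expect_true(all(cell$mean > 44 & cell$mean < 56))
})

test_that("emitted means converge to truth as 1/sqrt(n)", {
  err <- sapply(c(10, 100, 1000), function(n) {
    cfg <- synthetic_config(n_individuals = n, measurement_sd = 5, seed = 33)
    cfg$assays <- cfg$assays[cfg$assays$name == "mg1", ]
    cfg$assays$intra_cpg_sd <- 0
    cfg$true_profiles <- cfg$true_profiles["mg1", , drop = FALSE]
    bc <- generate_blood_cohort(cfg)
    abs(mean(bc$dataset$values$percent) - bc$truth$true_means[["mg1"]])
  })
  expect_lt(err[3], err[1])
  expect_lt(err[3], 1)
})

test_that("blood cohorts separate parental intra-CpG dispersion", {
  hits <- 0; n_seeds <- 40
  for (s in 1:n_seeds) {
    cfg <- synthetic_config(n_individuals = 10,
                            assays = blood_panel_assays(2, 5), seed = 600 + s)
    bc <- generate_blood_cohort(cfg)
    rec <- intra_cpg_variability(bc$dataset)
    rec$parental_mark <- cfg$assays$parental_mark[match(rec$assay,
                                                        cfg$assays$name)]
    per <- aggregate(intra_cpg_sd ~ parental_mark, rec, mean)
    if (per$intra_cpg_sd[per$parental_mark == "paternal"] >
        per$intra_cpg_sd[per$parental_mark == "maternal"]) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.99)

  cfg0 <- synthetic_config(n_individuals = 3, measurement_sd = 0, seed = 2)
  cfg0$assays$intra_cpg_sd <- 0
  bc0 <- generate_blood_cohort(cfg0)
  rec0 <- intra_cpg_variability(bc0$dataset)
  expect_true(all(rec0$intra_cpg_sd == 0))
})

test_that("spiked outliers are recorded in the truth and visible in data", {
  spike <- data.frame(assay = "mg1", individual = "ind003", shift = 18)
  cfg <- synthetic_config(n_individuals = 10, measurement_sd = 1, seed = 44)
  bc <- generate_blood_cohort(cfg, spike = spike)
  expect_equal(nrow(bc$truth$spikes), 1)
  m <- assay_sample_means(bc$dataset)
  spiked <- m$mean[m$assay == "mg1" & m$sample == "ind003"]
  rest <- m$mean[m$assay == "mg1" & m$sample != "ind003"]
  expect_gt(spiked, max(rest) + 10)
})

test_that("standards carry the mixture ladder and dropout model", {
  std0 <- generate_standards(noise_sd = 0, reps = 2, seed = 1)
  m <- assay_sample_means(std0$dataset)
  mix <- m[!is.na(m$dose_label), ]
  expect_equal(mix$mean, as.numeric(sub("mix_", "", mix$dose_label)))

  # dropout probability 1 at 1 ng makes every 1 ng replicate a dropout
  std1 <- generate_standards(noise_sd = 0, reps = 5, masses_ng = c(5, 1),
                             dropout_model = function(m) as.numeric(m <= 1),
                             seed = 2)
  expect_equal(sum(std1$truth$dropouts$template_mass_ng == 1), 5)
  expect_equal(sum(std1$truth$dropouts$template_mass_ng == 5), 0)
  m1 <- assay_sample_means(std1$dataset)
  one_ng <- m1[!is.na(m1$template_mass_ng) & m1$template_mass_ng == 1, ]
  expect_true(all(one_ng$mean <= 20 | one_ng$mean >= 80))

  expect_error(generate_standards(masses_ng = c(5, -1)), "mass")
})

test_that("design regions hit the requested island density exactly", {
  reg <- generate_design_region(island_length = 500, island_cpg_count = 29,
                                seed = 9)
  expect_equal(cpg_density(reg$sequence, reg$truth$midpoint), 5.8)
  span <- reg$truth$island_span
  inner <- substr(reg$sequence, span[1], span[2])
  expect_equal(count_cg(inner), 29)
  # flanks are CpG-free
  expect_equal(count_cg(reg$sequence), 29)

  reg2 <- generate_design_region(island_length = 500, island_cpg_count = 29,
                                 seed = 9)
  expect_identical(reg$sequence, reg2$sequence)
})
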