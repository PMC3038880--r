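test_that("reference intervals follow the normal reference range", {
  expect_equal(unname(reference_interval(c(50, 50, 50))), c(50, 50))

  v <- c(45, 50, 55)  # mean 50, sample SD 5
  ri <- reference_interval(v, 0.95)
  expect_equal(unname(ri), 50 + c(-1, 1) * qnorm(0.975) * 5)
  expect_equal(unname(round(ri, 1)), c(40.2, 59.8))

  ri99 <- reference_interval(v, 0.99)
  expect_lt(ri99[["low"]], ri[["low"]])
  expect_gt(ri99[["high"]], ri[["high"]])

  # truncation to the percent scale
  expect_equal(unname(reference_interval(c(1, 2, 3), 0.99)[1]), 0)
  expect_error(reference_interval(c(50, 50)), ">= 3")

  q <- reference_interval(0:100, 0.9, method = "percentile")
  expect_equal(unname(q), unname(quantile(0:100, c(0.05, 0.95))))
})

test_that("95% reference interval covers ~95% of a Gaussian cohort", {
  set.seed(23)
  x <- rnorm(1e4, 50, 5)
  ri <- reference_interval(x, 0.95)
  coverage <- mean(x >= ri[["low"]] & x <= ri[["high"]])
  expect_true(abs(coverage - 0.95) <= 0.02)
})

test_that("outlier flagging is exact under construction and nested in level", {
  n <- 50; sd <- 3
  set.seed(31)
  vals <- expand.grid(assay = c("A", "B"), sample = sprintf("i%02d", 1:n),
                      cpg_index = 1:3, stringsAsFactors = FALSE)
  vals$percent <- 50
  ds0 <- methylation_dataset(vals)
  rep0 <- flag_population_outliers(ds0)
  expect_equal(nrow(rep0$flags), 0)

  # spike one individual to mean + 6 SD at one assay; the rest of the cohort
  # sits on a tight deterministic grid so only the spike can flag
  base <- 50 + sd * seq(-1.5, 1.5, length.out = n)
  vals$percent <- base[match(vals$sample, sprintf("i%02d", 1:n))]
  spike_val <- mean(base) + 6 * sd(base)
  vals$percent[vals$assay == "A" & vals$sample == "i07"] <- spike_val
  vals$percent <- pmin(100, vals$percent)
  ds <- methylation_dataset(vals)
  rep1 <- flag_population_outliers(ds)
  hit <- rep1$flags[rep1$flags$level_exceeded >= 0.99, ]
  expect_equal(unique(hit$assay), "A")
  expect_equal(unique(hit$sample), "i07")

  # flags at 0.99 are a subset of flags at 0.95
  key <- function(f) paste(f$assay, f$sample)
  expect_true(all(key(rep1$flags[rep1$flags$level_exceeded >= 0.99, ]) %in%
                    key(rep1$flags)))

  # assays with <3 individuals are skipped with a warning
  small <- methylation_dataset(data.frame(assay = "C", sample = c("i1", "i2"),
                                          cpg_index = 1, percent = 50))
  expect_warning(flag_population_outliers(small), "fewer than 3")
})

test_that("individual burden ANOVA finds a consistently shifted individual", {
  n <- 30
  set.seed(13)
  vals <- expand.grid(assay = paste0("a", 1:6), sample = sprintf("i%02d", 1:n),
                      cpg_index = 1:3, stringsAsFactors = FALSE)
  vals$percent <- 50
  ds0 <- methylation_dataset(vals)
  rep0 <- flag_population_outliers(ds0)
  b0 <- individual_burden(ds0, rep0)
  expect_equal(b0$statistic, 0)
  expect_equal(b0$anova_p, 1)

  vals$percent <- rnorm(nrow(vals), 50, 3)
  vals$percent[vals$sample == "i05"] <- vals$percent[vals$sample == "i05"] + 10
  vals$percent <- pmin(100, pmax(0, vals$percent))
  ds <- methylation_dataset(vals)
  repx <- flag_population_outliers(ds)
  b <- individual_burden(ds, repx)
  expect_lt(b$anova_p, 0.001)
  expect_equal(b$max_count_sample, "i05")

  one <- methylation_dataset(vals[vals$assay == "a1", ])
  expect_error(individual_burden(one, repx), ">= 2 assays")
})

test_that("burden ANOVA p-values are uniform under the null", {
  n <- 20
  ps <- numeric(60)
  for (s in seq_along(ps)) {
    set.seed(1000 + s)
    vals <- expand.grid(assay = paste0("a", 1:5),
                        sample = sprintf("i%02d", 1:n),
                        cpg_index = 1, stringsAsFactors = FALSE)
    vals$percent <- pmin(100, pmax(0, rnorm(nrow(vals), 50, 3)))
    ds <- methylation_dataset(vals)
    ps[s] <- individual_burden(ds, flag_population_outliers(ds))$anova_p
  }
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("cis-cluster correlation reports same-cluster pairs and the max", {
  catalog <- load_assay_catalog(packaged_catalog_path())
  n <- 20
  set.seed(3)
  base <- rnorm(n, 50, 5)
  vals <- expand.grid(assay = c("KvDMR", "KCNQ1DN", "ZAC"),
                      sample = sprintf("i%02d", 1:n),
                      cpg_index = 1:3, stringsAsFactors = FALSE)
  vals$percent <- pmin(100, pmax(0, base[match(vals$sample,
                                               sprintf("i%02d", 1:n))]))
  ds <- methylation_dataset(vals)
  cc <- cis_cluster_correlation(ds, catalog)
  # KvDMR and KCNQ1DN share a cluster and here are identical: r^2 = 1
  expect_equal(nrow(cc), 1)
  expect_equal(cc$r_squared, 1)
  expect_equal(attr(cc, "max_r_squared"), 1)

  # assays without shared clusters give an empty result with a notice
  solo <- ds
  solo$values <- solo$values[solo$values$assay %in% c("KvDMR", "ZAC"), ]
  expect_message(cc0 <- cis_cluster_correlation(
    methylation_dataset(solo$values), catalog), "no clustered")
  expect_equal(nrow(cc0), 0)
})

test_that("independent loci in a cluster show near-zero max r^2", {
  catalog <- load_assay_catalog(packaged_catalog_path())
  hits <- 0; n_seeds <- 50
  for (s in 1:n_seeds) {
    set.seed(s)
    vals <- expand.grid(assay = c("KvDMR", "KCNQ1DN"),
                        sample = sprintf("i%02d", 1:50),
                        cpg_index = 1, stringsAsFactors = FALSE)
    vals$percent <- pmin(100, pmax(0, rnorm(nrow(vals), 50, 5)))
    cc <- cis_cluster_correlation(methylation_dataset(vals), catalog)
    if (attr(cc, "max_r_squared") < 0.2) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("treatment reduction applies the sign and zero-control rules", {
  control <- c(a = 50, b = 40, c = 50, d = 0)
  treated <- data.frame(assay = c("a", "b", "c", "d"), dose_label = "#1",
                        mean = c(25, 40, 60, 10))
  r <- treatment_reduction(control, treated)
  expect_equal(r$percent_reduction[r$assay == "a"], 50)
  expect_equal(r$percent_reduction[r$assay == "b"], 0)
  expect_equal(r$percent_reduction[r$assay == "c"], -20)
  expect_true(is.na(r$percent_reduction[r$assay == "d"]))
  expect_true(r$undefined[r$assay == "d"])

  # invariant under common positive rescaling
  r2 <- treatment_reduction(control[1:3] * 0.5,
                            transform(treated[1:3, ], mean = mean * 0.5))
  expect_equal(r2$percent_reduction, r$percent_reduction[1:3])

  # replicate experiments give a range (the error bars)
  t2 <- data.frame(assay = "a", dose_label = "#1", mean = c(20, 30),
                   experiment = 1:2)
  r3 <- treatment_reduction(control, t2)
  expect_equal(r3$percent_reduction, 50)
  expect_equal(c(r3$range_low, r3$range_high), c(40, 60))

  expect_error(treatment_reduction(c(a = 50),
                                   data.frame(assay = "zz", dose_label = "#1",
                                              mean = 10)),
               "without control")
})
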