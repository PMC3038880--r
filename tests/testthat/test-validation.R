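test_that("the canonical standard series is the five-mix ladder", {
  expect_equal(build_standard_series(), c(0, 25, 50, 75, 100))
})

test_that("linearity regression matches closed-form OLS", {
  r <- assess_linearity(c(0, 25, 50, 75, 100), c(0, 25, 50, 75, 100))
  expect_equal(r$slope, 1)
  expect_equal(r$intercept, 0)
  expect_equal(r$r_squared, 1)

  r <- assess_linearity(c(0, 50, 100), c(10, 50, 90))
  expect_equal(r$slope, 0.8)
  expect_equal(r$intercept, 10)
  expect_equal(r$r_squared, 1)

  expect_warning(r <- assess_linearity(c(0, 50, 100), c(50, 50, 50)),
                 "constant")
  expect_equal(r$r_squared, 0)
  expect_true(r$constant_observed)

  expect_error(assess_linearity(c(50, 50, 50), c(0, 50, 100)), "constant")
  expect_error(assess_linearity(1, 1), ">= 2")
})

test_that("linearity recovers generating parameters on noisy standards", {
  set.seed(5)
  expected <- rep(build_standard_series(), each = 5)
  for (rep in 1:5) {
    a <- runif(1, 0.8, 1.1); b <- runif(1, -3, 3)
    observed <- a * expected + b + rnorm(length(expected), 0, 1)
    fit <- assess_linearity(expected, observed)
    se_slope <- 1 / sqrt(sum((expected - mean(expected))^2))
    expect_lt(abs(fit$slope - a), 3 * se_slope + 1e-9)
  }
})

test_that("replicate agreement reproduces Bland-Altman by hand", {
  r <- replicate_agreement(c(40, 50, 60), c(40, 50, 60))
  expect_equal(r$bias, 0)
  expect_equal(r$r_squared, 1)

  r <- replicate_agreement(c(50, 60, 70), c(48, 58, 68))
  expect_equal(r$bias, 2)
  expect_equal(r$loa_low, 2)
  expect_equal(r$loa_high, 2)

  r <- replicate_agreement(c(40, 50, 60, 70), c(42, 49, 63, 68))
  want <- bf_bland_altman(c(40, 50, 60, 70), c(42, 49, 63, 68))
  expect_equal(r$bias, want$bias)
  expect_equal(r$loa_low, want$loa_low)
  expect_equal(r$loa_high, want$loa_high)

  expect_error(replicate_agreement(c(1, 2), c(1, 2)), ">= 3")
  expect_error(replicate_agreement(c(1, NA, 3, NA), c(1, 2, 3, 4)), ">= 3")
})

test_that("agreement bias is antisymmetric under argument swap", {
  set.seed(11)
  for (rep in 1:10) {
    r1 <- runif(8, 20, 80); r2 <- r1 + rnorm(8, 1, 2)
    a <- replicate_agreement(r1, r2)
    b <- replicate_agreement(r2, r1)
    expect_equal(a$bias, -b$bias)
    expect_equal(a$loa_high, -b$loa_low)
  }
})

test_that("bias stays within 3 sigma/sqrt(n) on Gaussian replicates", {
  sigma <- 2; n <- 40
  hits <- 0
  for (seed in 1:50) {
    set.seed(seed)
    r1 <- 50 + rnorm(n, 0, sigma)
    r2 <- 50 + rnorm(n, 0, sigma)
    a <- replicate_agreement(r1, r2)
    if (abs(a$bias) < 3 * sigma * sqrt(2) / sqrt(n)) hits <- hits + 1
  }
  expect_gte(hits / 50, 0.95)
})

test_that("titration sensitivity applies the window and dropout rules", {
  w <- fixed_dmr_window(35.73, 65.03)
  mk <- function(mass, reading) {
    data.frame(assay = "std", sample = paste0("m", mass), cpg_index = 1:3,
               percent = reading, stringsAsFactors = FALSE)
  }
  vals <- rbind(mk(10, 50.1), mk(5, 49.5), mk(2.5, 51.0), mk(1, 12.0))
  samples <- data.frame(sample = paste0("m", c(10, 5, 2.5, 1)),
                        group = "standard",
                        template_mass_ng = c(10, 5, 2.5, 1))
  sens <- titration_sensitivity(methylation_dataset(vals, samples), w)
  expect_equal(sens$min_reliable_mass_ng, 2.5)
  expect_true(sens$per_mass$dropout[sens$per_mass$template_mass_ng == 1])
  expect_false(any(sens$per_mass$dropout[sens$per_mass$template_mass_ng > 1]))

  # all masses read 50: the smallest mass is reliable
  vals <- rbind(mk(10, 50), mk(1, 50))
  samples <- samples[samples$template_mass_ng %in% c(10, 1), ]
  sens <- titration_sensitivity(methylation_dataset(vals, samples), w)
  expect_equal(sens$min_reliable_mass_ng, 1)

  empty <- methylation_dataset(mk(10, 50),
                               data.frame(sample = "m10", group = "standard"))
  expect_error(titration_sensitivity(empty, w), "no standard samples")
})
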