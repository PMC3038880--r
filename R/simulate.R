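DEFAULT_TISSUES <- c("brain", "breast", "colon", "heart", "kidney", "liver",
                     "placenta", "testis")

default_assay_table <- function() {
  # A representative panel mirroring the catalog's composition: germ-line
  # DMRs sit near 50% in every somatic tissue, maternal somatic DMRs are
  # tissue-specific, paternal somatic DMRs are uniformly near 50%, and
  # paternally methylated regions carry larger intra-CpG dispersion.
  data.frame(
    name = c("mg1", "mg2", "mg3", "mg4", "mg5", "mg6",
             "pg1", "pg2", "pg3", "ms1", "ms2", "ps1"),
    parental_mark = c(rep("maternal", 6), rep("paternal", 3),
                      "maternal", "maternal", "paternal"),
    timing = c(rep("germline", 9), "somatic", "somatic", "somatic"),
    intra_cpg_sd = c(rep(2, 6), rep(5, 3), 2, 2, 5),
    n_cpgs = c(5, 4, 6, 3, 7, 5, 4, 5, 3, 6, 5, 4),
    cluster_id = c("cl1", "cl1", NA, NA, "cl2", NA, "cl2", NA, NA,
                   NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' The 23-assay blood-cohort panel
#'
#' Composition of the cohort panel used for inter-individual variation
#' studies: 23 DMR assays (15 maternally, 8 paternally methylated; a mix of
#' germ-line and somatic), with the documented default intra-CpG dispersions
#' (maternal 2%, paternal 5%) and cis-cluster assignments.
#'
#' @param maternal_sd,paternal_sd Intra-CpG SDs per parental class
#'   (defaults 2 and 5).
#' @return Assay table suitable for [synthetic_config()].
#' @export
blood_panel_assays <- function(maternal_sd = 2, paternal_sd = 5) {
  mk <- c(rep("maternal", 15), rep("paternal", 8))
  data.frame(
    name = c(sprintf("mat%02d", 1:15), sprintf("pat%02d", 1:8)),
    parental_mark = mk,
    timing = c(rep("germline", 10), rep("somatic", 5),
               rep("germline", 4), rep("somatic", 4)),
    intra_cpg_sd = ifelse(mk == "maternal", maternal_sd, paternal_sd),
    n_cpgs = rep(c(5, 4, 6, 3, 7, 5, 4, 8, 5, 6, 4, 5, 9, 3, 5, 4, 6, 5, 4,
                   7, 5, 3, 6), length.out = 23),
    cluster_id = c("clA", "clA", "clA", "clB", "clB", rep(NA, 10),
                   "clC", "clC", "clC", rep(NA, 5)),
    stringsAsFactors = FALSE
  )
}

default_true_profiles <- function(assays, tissues) {
  profiles <- matrix(50, nrow = nrow(assays), ncol = length(tissues),
                     dimnames = list(assays$name, tissues))
  # germ-line marks in testis: sperm erases maternal imprints (near 0) and
  # carries paternal ones (near 100)
  if ("testis" %in% tissues) {
    profiles[assays$timing == "germline" & assays$parental_mark == "maternal",
             "testis"] <- 5
    profiles[assays$timing == "germline" & assays$parental_mark == "paternal",
             "testis"] <- 95
  }
  # maternal somatic DMRs: differential in a couple of tissues, hypo/hyper
  # elsewhere (the GNAS 1A / MEST isoform pattern)
  ms <- which(assays$timing == "somatic" & assays$parental_mark == "maternal")
  somatic_tissues <- setdiff(tissues, "testis")
  for (k in seq_along(ms)) {
    base <- if (k %% 2 == 1) 20 else 80
    profiles[ms[k], ] <- base
    on_tissues <- somatic_tissues[(seq_along(somatic_tissues) - 1) %%
                                    length(somatic_tissues) < 2]
    profiles[ms[k], on_tissues[seq_len(min(2, length(on_tissues)))]] <- 50
  }
  profiles
}

#' Configuration for the synthetic-data generators
#'
#' The defaults describe the world the analysis assumes: eight adult tissues
#' (including testis with its germ-line imprint erasure), three pooled
#' individuals per tissue, germ-line DMRs near 50% everywhere, maternal
#' somatic DMRs tissue-specific, paternal assays with ~2.5x the maternal
#' intra-CpG dispersion, and technical (measurement) noise of SD 2% — the
#' order of magnitude implied by a replicate bias of 1.60%.
#'
#' @param n_individuals Individuals per tissue (default 3, pooled-tissue
#'   panel) or cohort size for blood.
#' @param tissues Character vector of tissue labels.
#' @param assays Data frame (`name`, `parental_mark`, `timing`,
#'   `intra_cpg_sd`, `n_cpgs` in 3-9, `cluster_id`).
#' @param true_profiles Numeric matrix assay x tissue of true mean percents;
#'   default built from the assay classes.
#' @param measurement_sd Technical noise SD in percent (default 2).
#' @param dropout_model Function mass_ng -> dropout probability (default:
#'   0.1 at <= 1 ng, 0 above — dropout was seen only at the lowest input).
#' @param treatment_effect Named numeric: fraction of methylation lost per
#'   assay under treatment (NULL to skip).
#' @param seed Integer seed; every generator is deterministic given it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_individuals = 3, tissues = DEFAULT_TISSUES,
                             assays = default_assay_table(),
                             true_profiles = NULL, measurement_sd = 2,
                             dropout_model = function(mass_ng)
                               ifelse(mass_ng <= 1, 0.1, 0),
                             treatment_effect = NULL, seed = 1) {
  stopifnot(n_individuals >= 1, length(tissues) >= 1,
            all(c("name", "parental_mark", "timing", "intra_cpg_sd",
                  "n_cpgs") %in% names(assays)),
            measurement_sd >= 0, is.function(dropout_model))
  if (anyDuplicated(assays$name)) stop("duplicate assay names", call. = FALSE)
  if (any(assays$n_cpgs < 3 | assays$n_cpgs > 9))
    stop("n_cpgs must be in [3,9]", call. = FALSE)
  if (any(assays$intra_cpg_sd < 0)) stop("intra_cpg_sd must be >= 0", call. = FALSE)
  if (is.null(true_profiles))
    true_profiles <- default_true_profiles(assays, tissues)
  stopifnot(identical(rownames(true_profiles), assays$name),
            all(tissues %in% colnames(true_profiles)))
  if (any(true_profiles < 0 | true_profiles > 100))
    stop("true profiles must be in [0,100]", call. = FALSE)
  p <- dropout_model(c(0.5, 1, 2.5, 10))
  if (any(p < 0 | p > 1)) stop("dropout_model must return probabilities", call. = FALSE)
  if (!is.null(treatment_effect) &&
      (is.null(names(treatment_effect)) ||
       any(treatment_effect < 0 | treatment_effect > 1)))
    stop("treatment_effect must be a named vector of fractions in [0,1]",
         call. = FALSE)
  structure(list(n_individuals = as.integer(n_individuals), tissues = tissues,
                 assays = assays, true_profiles = true_profiles,
                 measurement_sd = measurement_sd, dropout_model = dropout_model,
                 treatment_effect = treatment_effect, seed = as.integer(seed)),
            class = "synthetic_config")
}

# fixed per-(assay, CpG) offsets: systematic dispensation bias that makes
# intra-CpG SD a stable per-assay property
draw_cpg_offsets <- function(assays) {
  offsets <- lapply(seq_len(nrow(assays)), function(i)
    stats::rnorm(assays$n_cpgs[i], 0, assays$intra_cpg_sd[i]))
  names(offsets) <- assays$name
  offsets
}

#' Simulate a multi-tissue methylation panel with ground truth
#'
#' Emits per assay x tissue x individual x CpG readings:
#' `clip(true_profile[assay, tissue] + cpg_offset + noise, 0, 100)` with
#' per-CpG offsets drawn once per assay (Normal, `intra_cpg_sd`) and
#' independent technical noise (Normal, `measurement_sd`).
#'
#' @param config A [synthetic_config()].
#' @return List with `dataset` (a `meth_dataset`, group `tissue_panel`) and
#'   `truth` (`synthetic_truth`: true assay x tissue means, the per-CpG
#'   offsets, and the category of each true mean under the standard
#'   35.73-65.03 window).
#' @export
generate_tissue_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  offsets <- draw_cpg_offsets(config$assays)
  grid <- expand.grid(individual = seq_len(config$n_individuals),
                      tissue = config$tissues, stringsAsFactors = FALSE)
  samples <- data.frame(sample = sprintf("%s_%02d", grid$tissue, grid$individual),
                        individual = sprintf("ind%02d", grid$individual),
                        tissue = grid$tissue, group = "tissue_panel",
                        replicate = 1L, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(config$assays)), function(i) {
    a <- config$assays$name[i]
    nc <- config$assays$n_cpgs[i]
    n <- nc * nrow(samples)
    true <- rep(config$true_profiles[a, samples$tissue], each = nc)
    vals <- clip01(true + rep(offsets[[a]], times = nrow(samples)) +
                     stats::rnorm(n, 0, config$measurement_sd))
    data.frame(assay = a, sample = rep(samples$sample, each = nc),
               cpg_index = rep(seq_len(nc), times = nrow(samples)),
               percent = vals, stringsAsFactors = FALSE)
  })
  dataset <- methylation_dataset(do.call(rbind, rows), samples)
  window <- fixed_dmr_window(35.73, 65.03)
  true_means <- config$true_profiles[config$assays$name, config$tissues,
                                     drop = FALSE]
  truth <- structure(list(
    true_means = true_means,
    category = apply(true_means, c(1, 2), function(v)
      as.character(classify_value(v, window))),
    cpg_offsets = offsets, window = window, seed = config$seed),
    class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}

#' Simulate a blood cohort with parental-class variability and spiked outliers
#'
#' One blood sample per individual. Paternal assays carry the larger
#' intra-CpG dispersion set in the config (default 5% vs maternal 2%, at
#' least the documented 2x contrast). Optional spiked individuals shift the
#' whole assay reading by a stated amount and are recorded in the truth.
#'
#' @param config A [synthetic_config()] (`n_individuals` is the cohort size;
#'   a single `blood` tissue is used and each assay's somatic true level is
#'   its first-tissue profile value).
#' @param spike Optional data frame (`assay`, `individual`, `shift`) of
#'   ground-truth outlier events, e.g. +6 SD at one DMR.
#' @return List with `dataset` (group `blood`) and `truth` (true means,
#'   per-CpG offsets, spikes).
#' @export
generate_blood_cohort <- function(config, spike = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(spike))
    stopifnot(all(c("assay", "individual", "shift") %in% names(spike)))
  set.seed(config$seed)
  offsets <- draw_cpg_offsets(config$assays)
  base <- stats::setNames(
    config$true_profiles[, setdiff(config$tissues, "testis")[1]],
    rownames(config$true_profiles))
  sids <- sprintf("ind%03d", seq_len(config$n_individuals))
  samples <- data.frame(sample = sids, individual = sids, tissue = "blood",
                        group = "blood", replicate = 1L,
                        stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(config$assays)), function(i) {
    a <- config$assays$name[i]
    nc <- config$assays$n_cpgs[i]
    shift <- numeric(length(sids))
    if (!is.null(spike)) {
      hit <- spike[spike$assay == a, , drop = FALSE]
      shift[match(hit$individual, sids)] <- hit$shift
    }
    vals <- clip01(rep(base[a] + shift, each = nc) +
                     rep(offsets[[a]], times = length(sids)) +
                     stats::rnorm(nc * length(sids), 0, config$measurement_sd))
    data.frame(assay = a, sample = rep(sids, each = nc),
               cpg_index = rep(seq_len(nc), times = length(sids)),
               percent = vals, stringsAsFactors = FALSE)
  })
  dataset <- methylation_dataset(do.call(rbind, rows), samples)
  truth <- structure(list(true_means = base, cpg_offsets = offsets,
                          spikes = spike, seed = config$seed),
                     class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}

#' Simulate the validation standards
#'
#' Emits the five-point 0/25/50/75/100 mixture series with Gaussian noise
#' (`reps` replicates each) plus 50% standards at each template mass, where a
#' replicate drops out with probability `dropout_model(mass)`; a dropout
#' replaces the reading with a draw near 0 or 100 (whole-allele loss, equal
#' probability per rail) and is recorded in the truth.
#'
#' @param noise_sd Technical noise SD in percent (default 1).
#' @param reps Replicates per mixture and per mass (default 3).
#' @param masses_ng Template masses for the titration (default
#'   `c(10, 5, 2.5, 1)`).
#' @param dropout_model Function mass -> dropout probability (default as in
#'   [synthetic_config()]).
#' @param n_cpgs CpGs per simulated assay (default 5).
#' @param seed Integer seed.
#' @return List with `dataset` (group `standard`; mixture samples carry
#'   `dose_label = "mix_<expected>"`, titration samples carry
#'   `template_mass_ng`) and `truth` (expected percents per sample, dropout
#'   events).
#' @export
generate_standards <- function(noise_sd = 1, reps = 3,
                               masses_ng = c(10, 5, 2.5, 1),
                               dropout_model = function(mass_ng)
                                 ifelse(mass_ng <= 1, 0.1, 0),
                               n_cpgs = 5, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (any(masses_ng <= 0)) stop("negative or zero template mass", call. = FALSE)
  set.seed(seed)
  rows <- list(); samples <- list(); expected <- list(); dropouts <- list()
  emit <- function(sid, true, mass = NA_real_, dose = NA_character_) {
    dropped <- FALSE
    level <- true
    if (!is.na(mass) && stats::runif(1) < dropout_model(mass)) {
      dropped <- TRUE
      level <- if (stats::runif(1) < 0.5) 2 else 98  # whole-allele loss
    }
    vals <- clip01(level + stats::rnorm(n_cpgs, 0, noise_sd))
    rows[[length(rows) + 1L]] <<- data.frame(
      assay = "std", sample = sid, cpg_index = seq_len(n_cpgs),
      percent = vals, stringsAsFactors = FALSE)
    samples[[sid]] <<- data.frame(sample = sid, individual = NA_character_,
                                  tissue = NA_character_, group = "standard",
                                  replicate = as.integer(sub(".*_r", "", sid)),
                                  template_mass_ng = mass, dose_label = dose,
                                  stringsAsFactors = FALSE)
    expected[[sid]] <<- true
    if (dropped) dropouts[[length(dropouts) + 1L]] <<-
        data.frame(sample = sid, template_mass_ng = mass, rail = level)
  }
  for (mix in build_standard_series()) for (r in seq_len(reps))
    emit(sprintf("mix%03d_r%d", mix, r), mix, dose = paste0("mix_", mix))
  for (mass in masses_ng) for (r in seq_len(reps))
    emit(sprintf("mass%s_r%d", gsub("[.]", "p", format(mass)), r), 50,
         mass = mass)
  dataset <- methylation_dataset(do.call(rbind, rows), do.call(rbind, samples))
  truth <- structure(list(
    expected = unlist(expected),
    dropouts = if (length(dropouts)) do.call(rbind, dropouts) else
      data.frame(sample = character(), template_mass_ng = numeric(),
                 rail = numeric()),
    noise_sd = noise_sd, seed = seed), class = "synthetic_truth")
  list(dataset = dataset, truth = truth)
}

#' Generate a region fixture for assay design
#'
#' Builds a deterministic random sequence with an embedded CpG island of
#' exactly the requested CpG count flanked by CpG-free, G-controlled flanks
#' that each admit at least one primer at the Wallace-rule target Tm
#' (verified by exhaustive scan before returning).
#'
#' @param island_length Island length in bp (default 500).
#' @param island_cpg_count Number of CpG sites in the island (default 29;
#'   with the 500 bp window this gives density 5.8).
#' @param snp_positions 1-based positions (within the emitted sequence) to
#'   report as SNPs; no sequence change is made, they are annotation.
#' @param flank_length Flank length each side (default 150).
#' @param target_tm,primer_length Primer site parameters (defaults 56 C,
#'   20 nt: 8 G + 12 A/T under the Wallace rule).
#' @param seed Integer seed.
#' @return List with `sequence`, `snps`, and `truth` (island span, CpG
#'   count, midpoint, designed primer-site spans).
#' @export
generate_design_region <- function(island_length = 500, island_cpg_count = 29,
                                   snp_positions = integer(),
                                   flank_length = 150, target_tm = 56,
                                   primer_length = 20, seed = 1) {
  stopifnot(island_length >= 2 * island_cpg_count, island_cpg_count >= 0,
            flank_length >= primer_length)
  n_gc <- (target_tm - 2 * primer_length) / 2
  if (n_gc < 0 || n_gc > primer_length || n_gc != round(n_gc))
    stop("target_tm unreachable at this primer length under the Wallace rule",
         call. = FALSE)
  set.seed(seed)

  primer_site <- function() {
    # CpG-free by construction: G plus A/T only
    paste(sample(c(rep("G", n_gc), sample(c("A", "T"), primer_length - n_gc,
                                          replace = TRUE))), collapse = "")
  }
  filler <- function(len) {
    if (len <= 0) return("")
    # A/T/C only: no G, hence no CpG and no competing high-Tm windows
    paste(sample(c("A", "T", "C"), len, replace = TRUE,
                 prob = c(0.4, 0.4, 0.2)), collapse = "")
  }
  island <- function() {
    if (island_cpg_count == 0) return(filler(island_length))
    spacer_total <- island_length - 2 * island_cpg_count
    cuts <- sort(stats::runif(island_cpg_count))
    lens <- diff(c(0, cuts)) / max(cuts) * spacer_total
    lens <- floor(lens)
    lens[1] <- lens[1] + (spacer_total - sum(lens))
    paste0(paste0(vapply(lens, function(l)
      paste0(paste(sample(c("A", "T"), max(0, l), replace = TRUE),
                   collapse = ""), "CG"), character(1)), collapse = ""))
  }

  for (attempt in 1:20) {
    left_site <- primer_site(); right_site <- primer_site()
    pad <- flank_length - primer_length
    left <- paste0(filler(floor(pad / 2)), left_site, filler(ceiling(pad / 2)))
    right <- paste0(filler(ceiling(pad / 2)), right_site, filler(floor(pad / 2)))
    isl <- island()
    seqn <- paste0(left, isl, right)
    # exhaustive verification of the stated properties
    island_span <- c(flank_length + 1L, flank_length + island_length)
    p <- cpg_positions(seqn)
    cpg_ok <- sum(p >= island_span[1] & p <= island_span[2]) ==
      island_cpg_count &&
      !any(p < island_span[1] | p > island_span[2])
    tm_site <- function(site) primer_melting_temperature(
      bisulfite_convert(site, "unmethylated"))
    if (cpg_ok && tm_site(left_site) == target_tm &&
        tm_site(right_site) == target_tm)
      return(list(
        sequence = seqn, snps = as.integer(snp_positions),
        truth = list(island_span = island_span,
                     island_cpg_count = island_cpg_count,
                     midpoint = island_span[1] + island_length %/% 2,
                     left_site_span = c(floor(pad / 2) + 1L,
                                        floor(pad / 2) + primer_length),
                     right_site_span = flank_length + island_length +
                       ceiling(pad / 2) + c(1L, primer_length),
                     seed = seed)))
  }
  stop("infeasible design-region specification after 20 attempts", call. = FALSE)
}
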