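test_that("variant fixtures carry truth labels and honour the exclusion dial", {
  ref <- simulate_reference(n_chrom = 2L, chrom_length = 300000L, seed = 12L)
  sim <- simulate_tumor_normal_variants(ref, n_variants = 2000L,
                                        exclusion_fraction = 0.10, seed = 12L)
  expect_identical(nrow(sim$calls), 2000L)
  expect_equal(mean(sim$calls$in_exclusion), 0.10, tolerance = 0.01)
  # AF ~ Beta(5,5) leaves essentially everything above the 10% AF cut, so
  # the designable truth count is ~1,800 of 2,000
  designable <- with(sim$calls, !in_exclusion & tumor_af > 0.10)
  expect_gt(sum(designable), 1750L)
  expect_lt(sum(designable), 1850L)
  # reference bases in the calls match the reference itself
  idx <- sample.int(2000L, 25L)
  for (i in idx)
    expect_identical(sim$calls$ref[i],
                     ref_base_at(ref, sim$calls$chrom[i], sim$calls$pos[i]))
  # loci are spaced so one cfDNA fragment spans at most one target
  for (ctg in unique(sim$calls$chrom)) {
    p <- sort(sim$calls$pos[sim$calls$chrom == ctg])
    expect_gte(min(diff(p)), 200L)
  }

  # everything excluded -> nothing designable downstream
  sim_all <- simulate_tumor_normal_variants(ref, n_variants = 100L,
                                            exclusion_fraction = 1, seed = 3L)
  model <- exact_error_model()
  kept <- filter_candidate_variants(sim_all$calls, sim_all$exclusion_granges,
                                    ref)
  expect_identical(nrow(kept), 0L)
  expect_error(rank_and_select_targets(kept, model), "no designable")

  # same seed, same fixture
  sim2 <- simulate_tumor_normal_variants(ref, n_variants = 2000L,
                                         exclusion_fraction = 0.10, seed = 12L)
  expect_identical(sim$calls, sim2$calls)
  expect_identical(sim$exclusions, sim2$exclusions)
  expect_error(simulate_tumor_normal_variants(ref, 10, af_shape1 = -1),
               "Beta")
})

test_that("background cohorts behave binomially and reject bad rates", {
  cohort <- simulate_background_cohort(n_samples = 200L,
                                       molecules_per_sample = 1e6, seed = 2L)
  expect_identical(nrow(cohort), 200L * 12L)
  model <- estimate_substitution_error_model(cohort)
  rates <- raw_class_rates()
  for (cl in c("C>T", "A>C")) {
    se <- sqrt(rates[cl] / (200 * 1e6))
    expect_lt(abs(model$rates[cl] - rates[cl]), 3 * se)
  }
  bad <- raw_class_rates(); bad["C>T"] <- 0
  expect_error(simulate_background_cohort(10L, bad), "rates")
  expect_error(simulate_background_cohort(0L), "n_samples")
  expect_identical(cohort,
                   simulate_background_cohort(n_samples = 200L,
                                              molecules_per_sample = 1e6,
                                              seed = 2L))
})

test_that("plasma simulation conserves per-target truth and spikes correctly", {
  ref <- tiny_reference(seed = 41L, chrom_length = 60000L)
  targets <- make_targets("chr1", seq(1000L, by = 400L, length.out = 50L),
                          "N", "N", error_rate = 1e-6)
  targets$ref <- vapply(targets$pos, function(p) ref_base_at(ref, "chr1", p),
                        character(1))
  targets$alt <- vapply(targets$pos, function(p) alt_base_at(ref, "chr1", p),
                        character(1))
  panel <- make_panel(targets)

  truth <- simulation_truth(tumor_fraction = 0.05,
                            mean_molecules_per_target = 10,
                            seq_error_rate = 0, q_low_frac = 0,
                            min_reads_per_strand = 2L, seed = 13L)
  s <- simulate_plasma_sample(panel, truth, ref)
  expect_identical(sum(s$truth_table$n_molecules),
                   length(unique(sub("_r[0-9]+$", "", s$pairs$read_id))))
  # truth conservation at read level: with zero sequencing error, the alt
  # molecules in the truth table are exactly the fragments carrying alt
  for (i in c(1L, 25L, 50L)) {
    t_i <- targets[i, ]
    span <- s$pairs$start < t_i$pos & s$pairs$end >= t_i$pos
    frag <- s$pairs[span, ]
    base <- substr(frag$bases, t_i$pos - frag$start, t_i$pos - frag$start)
    mol <- unique(sub("_r[0-9]+$", "", frag$read_id[base == t_i$alt]))
    expect_identical(length(mol), s$truth_table$n_alt_molecules[i])
  }
  # f = 1 makes every molecule tumor-derived
  truth1 <- simulation_truth(tumor_fraction = 1,
                             mean_molecules_per_target = 5,
                             seq_error_rate = 0, seed = 14L)
  s1 <- simulate_plasma_sample(panel, truth1, ref)
  expect_identical(s1$truth_table$n_tumor_molecules,
                   s1$truth_table$n_molecules)
})

test_that("consensus recovers simulated molecules exactly in the clean regime", {
  ref <- tiny_reference(seed = 42L, chrom_length = 60000L)
  sim <- simulate_tumor_normal_variants(ref, n_variants = 40L,
                                        exclusion_fraction = 0, seed = 15L)
  model <- exact_error_model(raw_class_rates())
  panel <- make_panel(rank_and_select_targets(
    filter_candidate_variants(sim$calls, NULL, ref), model, 30L))
  truth <- simulation_truth(tumor_fraction = 0.01,
                            mean_molecules_per_target = 10,
                            seq_error_rate = 0, q_low_frac = 0,
                            min_reads_per_strand = 2L,
                            distinct_fragments = TRUE, seed = 16L)
  s <- simulate_plasma_sample(panel, truth, ref)
  out <- call_consensus_molecules(s$pairs, ref)
  # guaranteed duplex families, no sequencing error, and collision-free
  # fragment placement: every simulated molecule survives consensus
  expect_identical(out$qc$n_molecules, sum(s$truth_table$n_molecules))
  obs <- count_target_molecules(out$molecules, panel)
  expect_identical(obs$alt_molecules, s$truth_table$n_alt_molecules)
  expect_identical(obs$total_molecules, s$truth_table$n_molecules)
})

test_that("simulated SAM output is byte-identical under a fixed seed", {
  ref <- tiny_reference(seed = 43L, chrom_length = 30000L)
  targets <- make_targets("chr1", c(2000L, 5000L, 9000L), "N", "N")
  targets$ref <- vapply(targets$pos, function(p) ref_base_at(ref, "chr1", p),
                        character(1))
  targets$alt <- vapply(targets$pos, function(p) alt_base_at(ref, "chr1", p),
                        character(1))
  panel <- make_panel(targets)
  truth <- simulation_truth(tumor_fraction = 0.01,
                            mean_molecules_per_target = 15, seed = 20L)
  f1 <- tempfile(fileext = ".sam"); f2 <- tempfile(fileext = ".sam")
  write_sam(simulate_plasma_sample(panel, truth, ref)$pairs, f1, ref)
  write_sam(simulate_plasma_sample(panel, truth, ref)$pairs, f2, ref)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("fast-path observations have the spiked mean and ppm is unbiased", {
  targets <- make_targets("chr1", seq(1000L, by = 400L, length.out = 100L),
                          "A", "G", error_rate = 1e-7)
  panel <- make_panel(targets)
  # f = 1000 ppm over M ~ 1e5: k averages ~100 across replicates
  set.seed(22)
  ks <- vapply(1:60, function(i) {
    obs <- simulate_target_observations(panel, 1000e-6,
                                        mean_molecules_per_target = 1000)
    aggregate_panel_signal(obs)$k
  }, numeric(1))
  expect_lt(abs(mean(ks) - 100), 3 * sqrt(100 / 60))

  # two seeds give statistically indistinguishable ppm distributions
  ppm_for_seed <- function(seed) {
    set.seed(seed)
    vapply(1:50, function(i) {
      obs <- simulate_target_observations(panel, 500e-6,
                                          mean_molecules_per_target = 1000)
      detect_ctdna(obs)$ppm
    }, numeric(1))
  }
  ks_test <- suppressWarnings(stats::ks.test(ppm_for_seed(1), ppm_for_seed(2)))
  expect_gt(ks_test$p.value, 0.01)
})

test_that("the end-to-end pipeline reports detection against known truth", {
  ref <- tiny_reference(seed = 44L, chrom_length = 80000L)
  sim <- simulate_tumor_normal_variants(ref, n_variants = 120L,
                                        exclusion_fraction = 0.1, seed = 17L)
  model <- exact_error_model(duplex_class_rates())
  panel <- design_panel(sim$calls, sim$exclusion_granges, ref, model,
                        panel_cap = 100L, seed = 1L)
  truth <- simulation_truth(tumor_fraction = 0.005,
                            mean_molecules_per_target = 25, seed = 18L)
  e2e <- run_end_to_end(panel, truth, ref, plasma_volume_ml = 2)
  expect_s3_class(e2e$result, "sample_detection_result")
  expect_true(e2e$result$detected)   # 5,000 ppm at M ~ 2,000 is unmissable
  expect_identical(e2e$true_ppm, 5000)
  expect_equal(e2e$result$tumor_molecules_per_ml, e2e$result$k / 2)
  expect_lte(e2e$qc$n_molecules, e2e$qc$n_groups_after_split)
})
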