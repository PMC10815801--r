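test_that("all generators are reproducible given their seed", {
  cfg_sel <- selex_sim_config(n_rounds = 2, reads_per_round = 200,
                              background_diversity = 50, seed = 6)
  expect_identical(gen_selex_rounds(cfg_sel), gen_selex_rounds(cfg_sel))

  cfg_bind <- binding_sim_config(binding_params(100, 150), noise_sd = 5,
                                 seed = 6)
  expect_identical(gen_binding_curve(cfg_bind), gen_binding_curve(cfg_bind))

  cfg_coh <- cohort_sim_config(seed = 6)
  expect_identical(gen_recognition_cohort(cfg_coh),
                   gen_recognition_cohort(cfg_coh))

  expect_identical(gen_proteomic_tables("P1", 3, 4, 2, seed = 6),
                   gen_proteomic_tables("P1", 3, 4, 2, seed = 6))

  cfg_traj <- trajectory_sim_config(n_frames = 10, n_replicates = 1,
                                    n_atoms = 10, seed = 6)
  expect_identical(gen_trajectory(cfg_traj), gen_trajectory(cfg_traj))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_binding_curve(binding_sim_config(binding_params(10, 10),
                                                 noise_sd = 1, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("planted SELEX enrichment doubles in expectation", {
  ratios <- vapply(1:100, function(s) {
    cfg <- selex_sim_config(n_rounds = 2, reads_per_round = 1000,
                            background_diversity = 200,
                            planted_sequences = list(
                              list(sequence = strrep("G", 30), factor = 2)),
                            planted_initial_frac = 0.02, seed = s)
    tr <- gen_selex_rounds(cfg)$truth
    tr$count[tr$round == "R2"] / max(tr$count[tr$round == "R1"], 1)
  }, 0)
  expect_gt(mean(ratios), 1.7)
  expect_lt(mean(ratios), 2.3)
})

test_that("background-only pools stay near-uniform", {
  cfg <- selex_sim_config(n_rounds = 1, reads_per_round = 5000,
                          background_diversity = 100, seed = 3)
  sim <- gen_selex_rounds(cfg)
  expect_equal(nrow(sim$truth), 0L)
  tab <- count_frequencies(lapply(sim$rounds, `[[`, "sequence"))
  expect_lt(max(tab$freqs), 5 / 100)   # no sequence far above 1/diversity
})

test_that("degenerate and invalid SELEX configs are handled", {
  cfg0 <- selex_sim_config(n_rounds = 2, reads_per_round = 0, seed = 1)
  sim0 <- gen_selex_rounds(cfg0)
  expect_equal(vapply(sim0$rounds, length, 0L), c(R1 = 0L, R2 = 0L))
  expect_true(all(sim0$truth$count == 0))

  expect_error(selex_sim_config(planted_sequences = list(
    list(sequence = "AAA", factor = 0))), "> 0")
  expect_error(selex_sim_config(planted_sequences = list(
    list(sequence = strrep("A", 40), factor = 2))), "longer")
})

test_that("read layout embeds planted regions between the flanks", {
  cfg <- selex_sim_config(n_rounds = 1, reads_per_round = 100,
                          background_diversity = 10,
                          planted_sequences = list(
                            list(sequence = strrep("T", 30), factor = 5)),
                          planted_initial_frac = 0.5, seed = 8)
  sim <- gen_selex_rounds(cfg)
  planted_full <- unique(sim$truth$sequence)
  expect_equal(nchar(planted_full), 76L)
  expect_equal(substr(planted_full, 1, nchar(cfg$flank5)), cfg$flank5)
  expect_true(grepl(strrep("T", 30), planted_full, fixed = TRUE))
  expect_true(all(nchar(sim$rounds$R1$sequence) == 76L))
})

test_that("quality degradation lowers tail qualities", {
  cfg <- selex_sim_config(n_rounds = 1, reads_per_round = 200,
                          background_diversity = 20,
                          quality_mean = 38, quality_sd = 1,
                          degrade_rate = 1.2, degrade_start = 40, seed = 4)
  sim <- gen_selex_rounds(cfg)
  qm <- do.call(rbind, sim$rounds$R1$quality)
  head_mean <- mean(qm[, 1:40])
  tail_mean <- mean(qm[, 70:76])
  expect_gt(head_mean - tail_mean, 10)
  expect_true(all(qm >= 2 & qm <= 41))
})

test_that("noiseless binding curves hit the model exactly", {
  p <- binding_params(100, 100)
  sim <- gen_binding_curve(binding_sim_config(p, noise_sd = 0,
                                              replicates = 1, seed = 1))
  d <- sim$data
  expect_equal(d$response[d$dose_nM == 100 & is.na(d$control_type)], 50)
  expect_equal(d$response[d$control_type %in% "no_aptamer"], 0)
  expect_error(binding_sim_config(p, noise_sd = -1), "nonnegative")
  expect_error(binding_sim_config(p, doses = c(50, 25)), "increasing")
})

test_that("noiseless curves round-trip through fit_kd to the truth", {
  p <- binding_params(Bmax = 90, Kd = 140, NS = 0.03, Background = 6)
  sim <- gen_binding_curve(binding_sim_config(p, noise_sd = 0, seed = 5))
  f <- fit_kd(sim$data)
  for (nm in c("Bmax", "Kd", "NS", "Background"))
    expect_lt(abs(coef(f)[[nm]] - p[[nm]]) / max(p[[nm]], 1), 1e-6)
})

test_that("cohort generator honors extreme recognition rates", {
  perfect <- gen_recognition_cohort(cohort_sim_config(
    true_positive_rate = c(A = 1), false_positive_rate = c(A = 0),
    seed = 2))
  cc <- build_contingency(perfect$cohort, "A")
  expect_equal(cc[["FN"]], 0L)
  expect_equal(cc[["FP"]], 0L)
  expect_equal(cc[["TP"]], 90L)

  silent <- gen_recognition_cohort(cohort_sim_config(
    true_positive_rate = c(A = 0), false_positive_rate = c(A = 0),
    seed = 2))
  expect_true(all(silent$cohort$A == 0))
})

test_that("cohort empirical rates stay within 3 binomial SDs", {
  cfg <- cohort_sim_config(n_adjacent = 1000, n_primary = 500,
                           n_metastatic = 500,
                           true_positive_rate = c(A = 0.5),
                           false_positive_rate = c(A = 0.1), seed = 13)
  sim <- gen_recognition_cohort(cfg)
  cc <- build_contingency(sim$cohort, "A")
  n_tumor <- cc[["TP"]] + cc[["FN"]]
  tpr_hat <- cc[["TP"]] / n_tumor
  expect_lt(abs(tpr_hat - 0.5), 3 * sqrt(0.5 * 0.5 / n_tumor))
  fpr_hat <- cc[["FP"]] / (cc[["FP"]] + cc[["TN"]])
  expect_lt(abs(fpr_hat - 0.1), 3 * sqrt(0.1 * 0.9 / 1000))
})

test_that("cohort ground truth matches recomputed contingencies", {
  sim <- gen_recognition_cohort(cohort_sim_config(
    true_positive_rate = c(A = 0.4, B = 0.7),
    false_positive_rate = c(A = 0.05, B = 0.2), seed = 19))
  for (a in c("A", "B")) {
    cc <- build_contingency(sim$cohort, a)
    expect_equal(unclass(cc)[names(sim$truth[[a]])], sim$truth[[a]],
                 label = a)
  }
})

test_that("cohort config validates proportions and rates", {
  expect_error(cohort_sim_config(subtype_proportions = c(luminal = 0.5,
                                                         HER2 = 0.4)),
               "sum to 1")
  expect_error(cohort_sim_config(true_positive_rate = c(A = 1.2),
                                 false_positive_rate = c(A = 0)),
               "\\[0, 1\\]")
  expect_error(cohort_sim_config(true_positive_rate = c(A = 0.5),
                                 false_positive_rate = c(B = 0.1)),
               "same aptamers")
})

test_that("proteomic fixtures are recovered exactly by the cascade", {
  for (s in 1:10) {
    gp <- gen_proteomic_tables(planted_ids, n_membrane_decoys = 15,
                               n_nonmembrane_decoys = 30,
                               n_foldfail_decoys = 20, seed = 50 + s)
    casc <- run_cascade(gp$records, default_phenotype())
    expect_setequal(casc$shortlist, gp$truth)
  }
})

test_that("proteomic generator edge cases", {
  expect_error(gen_proteomic_tables(c("A", "A")), "duplicate")
  empty <- gen_proteomic_tables(character(), 0, 0, 0, seed = 1)
  expect_equal(nrow(empty$records), 0L)
  one <- gen_proteomic_tables("ONLY", 0, 0, 1, seed = 2)
  casc <- run_cascade(one$records, default_phenotype())
  expect_equal(casc$shortlist, "ONLY")
})

test_that("trajectory generator plants recoverable structure", {
  sim1 <- gen_trajectory(trajectory_sim_config(n_frames = 20,
                                               n_replicates = 1,
                                               n_atoms = 10,
                                               n_clusters = 1, seed = 3))
  expect_equal(length(gromos_cluster(sim1$traj, 2.5)$sizes), 1L)
  expect_false(sim1$truth$overlap_warning)

  big_jitter <- gen_trajectory(trajectory_sim_config(
    n_frames = 10, n_replicates = 1, n_atoms = 10, n_clusters = 2,
    jitter_sd = 3, seed = 3))
  expect_true(big_jitter$truth$overlap_warning)

  occ <- gen_trajectory(trajectory_sim_config(
    n_frames = 100, n_replicates = 2, n_atoms = 12, n_clusters = 1,
    planted_hbonds = list(list(occupancy = 0.5)), seed = 21))
  res <- hbond_occupancy(occ$traj, occ$truth$hbond_specs)
  expect_equal(res$table$occupancy_pct, 50)
  expect_equal(res$frames[[1]], occ$truth$hbond_frames[[1]])

  expect_error(trajectory_sim_config(planted_hbonds = list(
    list(occupancy = 1.5))), "\\[0, 1\\]")
  expect_error(trajectory_sim_config(n_atoms = 4, planted_hbonds = list(
    list(occupancy = 0.5))), "too small")
})

test_that("selex FASTQ sidecars round-trip through read_fastq", {
  cfg <- selex_sim_config(n_rounds = 2, reads_per_round = 50,
                          background_diversity = 20, seed = 9)
  sim <- gen_selex_rounds(cfg)
  dir <- tempfile()
  paths <- write_selex_fastq(sim, dir)
  expect_length(paths, 2)
  back <- read_fastq(paths[["R1"]])
  expect_equal(back$sequence, sim$rounds$R1$sequence)
  expect_equal(back$quality, sim$rounds$R1$quality)
})
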