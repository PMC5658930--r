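test_that("config validation enforces the response-probability ordering", {
  expect_s3_class(sim_config(seed = 3), "ctr_sim_config")
  expect_error(sim_config(response_prob = c(ER = 0.9, MR = 0.5, SR = 0.2)),
               class = "ctr_config_error")
  expect_error(sim_config(noise_cv = -0.1), class = "ctr_config_error")
  expect_error(sim_config(n_reference = 1), class = "ctr_config_error")
  expect_error(sim_config(drugs = data.frame(drug = "Avastin",
                                             mean_pci = 0.5, sd_pci = 0.2)),
               class = "ctr_config_error")
})

test_that("identical seed and config give bit-identical outputs", {
  cfg <- sim_config(seed = 123)
  a <- simulate_assay(cfg)
  b <- simulate_assay(cfg)
  expect_identical(a$measurements, b$measurements)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg))
  # different seeds give different draws but compatible panel statistics
  c2 <- simulate_assay(sim_config(seed = 124))
  expect_false(identical(a$measurements$cpm_treated,
                         c2$measurements$cpm_treated))
  expect_equal(a$panels$drug, c2$panels$drug)
})

test_that("the noiseless pipeline recovers true inhibition exactly", {
  cfg <- sim_config(seed = 9, noise_cv = 0)
  sim <- simulate_assay(cfg)
  merged <- merge(sim$pci, sim$truth, by = c("sample_id", "drug"))
  in_range <- merged$true_inhibition <=
    cfg$cpm_neg_mean / (cfg$cpm_neg_mean - cfg$cpm_pos_mean)
  expect_true(all(in_range))
  expect_equal(merged$pci, merged$true_inhibition, tolerance = 1e-12)
})

test_that("large reference panels concentrate on the true mean", {
  cfg <- sim_config(seed = 31, n_reference = 10000, noise_cv = 0,
                    drugs = data.frame(drug = "Carboplatin",
                                       mean_pci = 0.5, sd_pci = 0.2))
  panels <- simulate_assay(cfg)$panels
  expect_lt(abs(panels$mean_pci - 0.5), 3 * 0.2 / sqrt(10000))
  expect_lt(abs(panels$sd_pci - 0.2), 0.01)
})

test_that("deterministic response limits propagate through tabulation", {
  cfg <- sim_config(seed = 17,
                    n_patients = c(mono = 100, mono_plus_avastin = 0,
                                   combination = 100),
                    response_prob = c(ER = 0, MR = 0, SR = 1))
  tab <- tabulate_cohort(simulate_cohort(cfg), "all")
  sr <- which(as.character(tab$class) == "SR")
  er <- which(as.character(tab$class) == "ER")
  expect_equal(tab$responders[sr], tab$n[sr])
  expect_equal(tab$responders[er], 0L)
})

test_that("exchangeable response probabilities give AUC near one half", {
  cfg <- sim_config(seed = 71,
                    n_patients = c(mono = 0, mono_plus_avastin = 0,
                                   combination = 5000),
                    response_prob = c(ER = 0.4, MR = 0.4, SR = 0.4))
  tab <- tabulate_cohort(simulate_cohort(cfg), "all")
  auc <- ordinal_auc(tab)
  se <- sqrt(delong_ci(tab)$variance)
  expect_lt(abs(auc - 0.5), 4 * se)
})

test_that("empirical AUC matches the closed-form oracle from the config", {
  cfg <- sim_config(seed = 53,
                    n_patients = c(mono = 0, mono_plus_avastin = 0,
                                   combination = 5000),
                    response_prob = c(ER = 0, MR = 0.64, SR = 0.95))
  cohort <- simulate_cohort(cfg)
  tab <- tabulate_cohort(cohort, "all")
  # oracle: expected AUC given the realised class mix and the true
  # class-conditional response probabilities
  ord <- order(tab$class)
  oracle <- expected_auc(cfg$response_prob[as.character(tab$class[ord])],
                         tab$n[ord])
  se <- sqrt(delong_ci(tab)$variance)
  expect_lt(abs(ordinal_auc(tab) - oracle), 4 * se)
})

test_that("expected AUC increases with the response-probability contrast", {
  q <- c(0.16, 0.34, 0.5)
  aucs <- vapply(seq(0.05, 0.45, by = 0.1), function(d) {
    expected_auc(c(0.5 - d, 0.5, 0.5 + d), q)
  }, 1.0)
  expect_true(all(diff(aucs) > 0))
  expect_equal(expected_auc(c(0.4, 0.4, 0.4), q), 0.5)
})

test_that("yaml configs round-trip through read_sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "seed: 11",
    "n_reference: 30",
    "noise_cv: 0.05",
    "drugs:",
    "  - {drug: Carboplatin, mean_pci: 0.55, sd_pci: 0.18}",
    "  - {drug: Paclitaxel, mean_pci: 0.45, sd_pci: 0.22}",
    "n_patients: {mono: 5, mono_plus_avastin: 0, combination: 20}",
    "response_prob: {ER: 0.1, MR: 0.5, SR: 0.9}"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$seed, 11L)
  expect_equal(cfg$drugs$mean_pci, c(0.55, 0.45))
  expect_equal(unname(cfg$response_prob), c(0.1, 0.5, 0.9))
  writeLines("bogus_key: 1", path)
  expect_error(read_sim_config(path), class = "ctr_config_error")
})

test_that("parameter recovery reports near-nominal coverage", {
  cfg <- sim_config(seed = 2024,
                    n_patients = c(mono = 40, mono_plus_avastin = 0,
                                   combination = 80),
                    response_prob = c(ER = 0.1, MR = 0.45, SR = 0.8))
  rep_tbl <- parameter_recovery_report(cfg, n_reps = 150)
  expect_equal(rep_tbl$quantity, c("p_ER", "p_MR", "p_SR", "auc"))
  # exact intervals are conservative
  expect_true(all(rep_tbl$coverage[1:3] >= 0.95))
  # proportions are estimated without material bias at this size
  expect_true(all(abs(rep_tbl$bias[1:3]) < 0.1))
  # DeLong coverage within Monte-Carlo slack of nominal
  mc_se <- sqrt(0.95 * 0.05 / rep_tbl$n_used[4])
  expect_gt(rep_tbl$coverage[4], 0.95 - 4 * mc_se - 0.02)
  expect_error(parameter_recovery_report(cfg, n_reps = 10),
               class = "ctr_config_error")
})
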