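test_that("simulation is deterministic under a fixed seed", {
  cfg <- cohort_config(n_tumor = 12, n_blood = 12, n_resident_species = 45,
                       n_contaminant_species = 20, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(amx_values(a$tumor), amx_values(b$tumor))
  expect_identical(amx_values(a$blood), amx_values(b$blood))
  expect_identical(a$metadata, b$metadata)
  # integer-valued counts
  expect_true(all(amx_values(a$tumor) == round(amx_values(a$tumor))))
})

test_that("zero contaminant prevalence leaves blood with residents only", {
  cfg <- cohort_config(n_tumor = 20, n_blood = 20, n_resident_species = 45,
                       n_contaminant_species = 10,
                       contaminant_prevalence = 0,
                       resident_blood_prevalence = 0.3,
                       resident_tissue_prevalence = 0.6, seed = 3)
  sim <- simulate_cohort(cfg)
  blood <- amx_values(sim$blood)
  con <- sim$truth$contaminant_species
  expect_true(all(blood[, con] == 0))
  expect_gt(sum(blood[, sim$truth$resident_species]), 0)
})

test_that("expected_prevalence returns configured probabilities and matches simulation", {
  cfg <- cohort_config(seed = 21)
  expect_equal(expected_prevalence(cfg, "resident", "tumor"), 0.4)
  expect_equal(expected_prevalence(cfg, "resident", "blood"), 0.02)
  expect_equal(expected_prevalence(cfg, "contaminant", "blood"), 0.3)
  wes <- cohort_config(mode = "wes_like", seed = 21)
  expect_equal(expected_prevalence(wes, "resident", "tumor"), 0.2)

  # observed prevalence over a large cohort within 3 binomial SEs
  big <- cohort_config(n_tumor = 1000, n_blood = 1000,
                       n_resident_species = 45, n_contaminant_species = 20,
                       msi_abundance_multiplier = 1, msi_richness_boost = 0,
                       covariate_effects = NULL, seed = 77)
  sim <- simulate_cohort(big)
  for (mat in c("tumor", "blood")) {
    prev <- compute_prevalence(sim[[mat]])
    for (cls in c("resident", "contaminant")) {
      ids <- sim$truth[[paste0(cls, "_species")]]
      p0 <- expected_prevalence(big, cls, mat)
      obs <- mean(prev$present[prev$species_id %in% ids] / 1000)
      se <- sqrt(p0 * (1 - p0) / (1000 * length(ids)))
      expect_lt(abs(obs - p0), max(3 * se, 1e-6))
    }
  }
})

test_that("with MSI effects disabled the MSI/MSS abundance difference is null", {
  # two-sided Wilcoxon p should look uniform over replicate seeds
  ps <- vapply(1:12, function(s) {
    cfg <- cohort_config(n_tumor = 40, n_blood = 5,
                         n_resident_species = 45, n_contaminant_species = 5,
                         msi_abundance_multiplier = 1, msi_richness_boost = 0,
                         covariate_effects = NULL, msi_fraction = 0.5,
                         ebv_fraction = 0.05, cin_fraction = 0.2, seed = 400 + s)
    sim <- simulate_cohort(cfg)
    tot <- rowSums(amx_values(sim$tumor))
    stats::wilcox.test(tot ~ sim$metadata$msi_status, exact = FALSE)$p.value
  }, numeric(1))
  expect_gt(min(ps), 0.001)
  expect_gt(mean(ps > 0.1), 0.5)
})

test_that("metadata is consistent with the latent subtype", {
  cfg <- cohort_config(n_tumor = 300, n_blood = 5, n_resident_species = 45,
                       n_contaminant_species = 5, seed = 12)
  sim <- simulate_cohort(cfg)
  md <- sim$metadata
  sub <- sim$truth$subtype[md$sample_id]
  expect_true(all(md$scv_per_mb[md$msi_status == "MSI"] >= 20))
  expect_true(all(md$scv_per_mb[md$msi_status == "MSS"] < 20))
  expect_identical(unname(sub == "MSI"),
                   unname(md$msi_status == "MSI"))
  expect_true(all(md$ebv_per_human_cell[sub == "EBV"] >= 1e-3))
  expect_true(all(md$ebv_per_human_cell[sub != "EBV"] < 1e-3))
  expect_true(all(md$ploidy[sub == "CIN"] > 2.5))
  expect_true(all(md$ploidy[sub != "CIN"] <= 2.5))
})

test_that("wes_like mode hides genome-wide metadata and reduces detection", {
  wes <- simulate_cohort(cohort_config(mode = "wes_like", cohort = "B",
                                       n_tumor = 60, n_blood = 10,
                                       n_resident_species = 45,
                                       n_contaminant_species = 20, seed = 5))
  expect_true(all(is.na(wes$metadata$human_reads)))
  expect_true(all(is.na(wes$metadata$ploidy)))
  expect_true(all(is.na(wes$metadata$purity)))
  wgs <- simulate_cohort(cohort_config(mode = "wgs_like", n_tumor = 60,
                                       n_blood = 10,
                                       n_resident_species = 45,
                                       n_contaminant_species = 20, seed = 5))
  expect_lt(mean(amx_values(wes$tumor) > 0), mean(amx_values(wgs$tumor) > 0))
})

test_that("degenerate configurations are rejected", {
  expect_error(cohort_config(n_resident_species = 0), "n_resident_species")
  expect_error(cohort_config(resident_tissue_prevalence = 0.01,
                             resident_blood_prevalence = 0.02),
               "must exceed")
  expect_error(cohort_config(contaminant_prevalence = 1.3), "probabilities")
})
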