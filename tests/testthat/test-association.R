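test_that("two groups use Wilcoxon, more use Kruskal-Wallis", {
  res2 <- compare_outcome_by_group(c(1, 2, 3, 10, 11, 12),
                                   rep(c("x", "y"), each = 3))
  expect_equal(res2$test, "wilcoxon")
  expect_equal(res2$p_value, 0.1, tolerance = 1e-12)  # exact 3v3 extreme

  res3 <- compare_outcome_by_group(rnorm(30),
                                   rep(c("x", "y", "z"), each = 10))
  expect_equal(res3$test, "kruskal_wallis")

  expect_error(compare_outcome_by_group(1:4, rep("x", 4)), "2 groups")
  # missing labels are excluded before dispatch
  res_na <- compare_outcome_by_group(c(1, 2, 3, 4, 5, 6, 7, 8),
                                     c("x", "x", "x", "y", "y", "y", NA, NA))
  expect_equal(res_na$test, "wilcoxon")
  expect_equal(sum(unlist(res_na$group_ns[[1]])), 6)
})

test_that("wilcoxon p-values are calibrated under label exchange", {
  set.seed(33)
  ps <- replicate(200, {
    v <- rnorm(24)
    g <- sample(rep(c("a", "b"), 12))
    compare_outcome_by_group(v, g)$p_value
  })
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.10)
  # rank-test p-values are discrete, so KS ties are expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("spearman correlation handles monotone, reversed, tied and constant input", {
  x <- 1:10
  expect_equal(spearman_correlation(x, x^3)$statistic, 1)
  expect_equal(spearman_correlation(x, -x)$statistic, -1)

  set.seed(8)
  for (i in 1:10) {
    a <- sample(1:6, 30, TRUE)  # heavy ties
    b <- rnorm(30)
    got <- spearman_correlation(a, b)$statistic
    # direct midrank formula oracle
    expect_equal(got, stats::cor(rank(a), rank(b)), tolerance = 1e-12)
  }
  const <- spearman_correlation(rep(1, 5), rnorm(5))
  expect_true(const$degenerate)
  expect_true(is.na(const$statistic))
  expect_error(spearman_correlation(1:2, 1:2), "at least 3")
})

test_that("DA covariates are the PERMANOVA-significant terms in order", {
  pm <- tibble::tibble(
    term = c("sex", "age", "msi_status", "pT", "Residual"),
    df = c(1, 1, 1, 1, 60),
    sum_of_squares = 1, R2 = 0.2,
    F = c(1, 1, 2, 1, NA),
    p_perm = c(0.3, 0.7, 0.036, 0.02, NA)
  )
  class(pm) <- c("gc_permanova", class(pm))
  expect_equal(select_da_covariates(pm), c("msi_status", "pT"))
  expect_equal(select_da_covariates(pm, alpha = 0.01), character(0))
  pm$p_perm <- c(0.3, 0.7, 0.5, 0.6, NA)
  expect_equal(select_da_covariates(pm), character(0))
})

test_that("stage covariates binarise to the pre-specified contrasts", {
  md <- tibble::tibble(
    sample_id = paste0("s", 1:5),
    pT = factor(c("1", "2", "3", "4", NA), levels = c("1", "2", "3", "4")),
    pN = factor(c("0", "1", "3", NA, "0"), levels = c("0", "1", "2", "3")),
    msi_status = factor(c("MSI", "MSS", "MSS", "MSI", NA),
                        levels = c("MSI", "MSS"))
  )
  b <- binarize_stage(md)
  expect_equal(as.character(b$pT), c("pT1/2", "pT1/2", "pT3/4", "pT3/4", NA))
  expect_equal(as.character(b$pN), c("pN0", "pN+", "pN+", NA, "pN0"))
  expect_equal(levels(b$msi_status), c("MSS", "MSI"))  # MSS is reference
})

test_that("differential abundance filters by prevalence and recovers planted effects", {
  eff <- tibble::tibble(covariate = "msi_status",
                        species = sprintf("res_%03d", 1:10),
                        log2fc = rep(c(2, -2), each = 5))
  cfg <- cohort_config(n_tumor = 100, n_blood = 5,
                       n_resident_species = 60, n_contaminant_species = 5,
                       msi_abundance_multiplier = 1, msi_richness_boost = 0,
                       covariate_effects = eff, seed = 19)
  sim <- simulate_cohort(cfg)
  md <- binarize_stage(sim$metadata)
  da <- differential_abundance(sim$tumor_score, md, "msi_status")

  # prevalence filter: only taxa present in >= 10% of samples are fitted
  rel <- amx_values(sim$tumor_score) /
    rowSums(amx_values(sim$tumor_score))
  prev <- colMeans(rel > 0)
  expect_setequal(unique(da$taxon), names(prev)[prev >= 0.10])

  planted_sig <- da[da$taxon %in% eff$species & da$significant, ]
  expect_gt(nrow(planted_sig), 0)
  truth_sign <- sign(eff$log2fc[match(planted_sig$taxon, eff$species)])
  expect_true(all(sign(planted_sig$coefficient) == truth_sign))
  expect_identical(planted_sig$direction,
                   ifelse(planted_sig$coefficient > 0,
                          "enriched_in_comparison", "enriched_in_reference"))
})

test_that("DA coefficients are invariant to a global log-abundance shift", {
  cfg <- cohort_config(n_tumor = 60, n_blood = 5, n_resident_species = 45,
                       n_contaminant_species = 5,
                       msi_abundance_multiplier = 1, msi_richness_boost = 0,
                       covariate_effects = NULL, seed = 23)
  sim <- simulate_cohort(cfg)
  md <- binarize_stage(sim$metadata)
  da1 <- differential_abundance(sim$tumor_score, md, "msi_status")
  # scaling every count by a constant leaves TSS proportions unchanged,
  # so covariate coefficients are identical
  scaled <- abundance_matrix(amx_values(sim$tumor_score) * 8,
                             semantics = "score", material = "tumor")
  da2 <- differential_abundance(scaled, md, "msi_status")
  expect_equal(da1$coefficient, da2$coefficient, tolerance = 1e-12)
})

test_that("constant covariates are dropped with a warning; empty results handled", {
  cfg <- cohort_config(n_tumor = 30, n_blood = 5, n_resident_species = 45,
                       n_contaminant_species = 5, seed = 29)
  sim <- simulate_cohort(cfg)
  md <- binarize_stage(sim$metadata)
  md$const <- factor("x", levels = c("x", "y"))
  expect_warning(
    da <- differential_abundance(sim$tumor_score, md,
                                 c("msi_status", "const")),
    "constant covariate")
  expect_false("const" %in% da$covariate)
  expect_error(differential_abundance(sim$tumor_score, md, character()),
               "at least one")

  expect_equal(nrow(effect_plot_table(empty_da_result())), 0)
})

test_that("effect tables keep significant taxa sorted by effect magnitude", {
  da <- empty_da_result()
  da <- dplyr::bind_rows(da, tibble::tibble(
    taxon = c("a", "b", "c", "d"), covariate = "msi_status",
    term_level = "msi_statusMSI",
    coefficient = c(0.5, -2, 1.2, 3), standard_error = 0.1,
    p_value = 0.01, q_value = c(0.01, 0.01, 0.5, 0.01),
    significant = c(TRUE, TRUE, FALSE, TRUE),
    direction = c("enriched_in_comparison", "enriched_in_reference",
                  "enriched_in_comparison", "enriched_in_comparison")
  ))
  tab <- effect_plot_table(da)
  expect_equal(tab$taxon, c("d", "b", "a"))
  expect_setequal(unique(tab$direction),
                  c("enriched_in_comparison", "enriched_in_reference"))
})

test_that("group_associations sweeps covariates with per-comparison complete cases", {
  cfg <- cohort_config(n_tumor = 50, n_blood = 5, n_resident_species = 45,
                       n_contaminant_species = 5, seed = 41)
  sim <- simulate_cohort(cfg)
  tbl <- sim$metadata |>
    dplyr::left_join(alpha_diversity(sim$tumor_score), by = "sample_id")
  res <- group_associations(tbl, outcomes = "shannon",
                            covariates = c("msi_status", "histology", "age"))
  expect_equal(res$test[res$variable == "msi_status"], "wilcoxon")
  expect_equal(res$test[res$variable == "histology"], "kruskal_wallis")
  expect_equal(res$test[res$variable == "age"], "spearman")
})
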