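test_that("prevalence uses the at-least-two-unambiguous-reads rule", {
  m <- matrix(c(0, 1, 2, 5), ncol = 1,
              dimnames = list(paste0("s", 1:4), "spA"))
  prev <- compute_prevalence(toy_amx(m), min_reads = 2)
  expect_equal(prev$present, 2L)
  expect_equal(prev$total, 4L)

  zeros <- matrix(0, 4, 1, dimnames = list(paste0("s", 1:4), "spA"))
  expect_equal(compute_prevalence(toy_amx(zeros))$present, 0L)

  m1 <- matrix(c(0, 1), ncol = 1, dimnames = list(c("s1", "s2"), "spA"))
  expect_equal(compute_prevalence(toy_amx(m1), min_reads = 1)$present, 1L)

  expect_error(compute_prevalence(toy_amx(m, semantics = "score")),
               "unambiguous-read semantics")
})

test_that("fisher_one_sided is the exact hypergeometric tail", {
  expect_equal(fisher_one_sided(2, 0, 0, 2), 1 / 6, tolerance = 1e-14)
  expect_equal(fisher_one_sided(0, 7, 0, 9), 1)
  # spot-check a grid against brute-force enumeration and fisher.test
  set.seed(2)
  for (i in 1:25) {
    tp <- sample(0:8, 1); ta <- sample(0:8, 1)
    bp <- sample(0:8, 1); ba <- sample(0:8, 1)
    if (tp + ta + bp + ba == 0) next
    p <- fisher_one_sided(tp, ta, bp, ba)
    expect_equal(p, fisher_oracle(tp, ta, bp, ba), tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(c(tp, ta, bp, ba), 2, byrow = TRUE),
                             alternative = "greater")
    expect_equal(p, ft$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_one_sided(-1, 1, 1, 1), "nonnegative")
})

test_that("q-values: BH fallback, Storey bound, order preservation", {
  expect_equal(estimate_qvalues(rep(1, 5)), rep(1, 5))
  expect_lte(estimate_qvalues(0.03), 0.03)  # single p: q = p * pi0 <= p

  p <- c(0.01, 0.02, 0.9)
  expect_equal(estimate_qvalues(p, pi0 = 1),
               c(0.03, 0.03, 0.9))  # hand BH: min(3*.01/1, 3*.02/2), 0.9

  set.seed(9)
  for (i in 1:10) {
    pv <- runif(sample(c(5, 50, 500), 1))^2
    q <- estimate_qvalues(pv)
    expect_true(all(q >= 0 & q <= 1))
    # order-preserving
    expect_true(all(diff(q[order(pv)]) >= -1e-12))
    # permutation invariance
    perm <- sample(length(pv))
    expect_equal(estimate_qvalues(pv[perm]), q[perm])
    # never below the BH value scaled by pi0
    bh <- p.adjust(pv, "BH")
    expect_true(all(q <= bh + 1e-12))
  }
  expect_error(estimate_qvalues(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("include-list routes: statistical, blood cap, curated band, manual", {
  mk <- function(species, q, blood_frac, n = 100) {
    tibble::tibble(
      species_id = species,
      tissue_present = 50L, tissue_total = n,
      blood_present = as.integer(round(blood_frac * n)), blood_total = n,
      fisher_p = q, q_value = q, blood_prev_frac = blood_frac,
      classification = "exclude"
    )
  }
  res_a <- mk(c("s1", "s2", "s3", "s4"),
              q = c(0.01, 0.001, 0.5, 0.9),
              blood_frac = c(0, 0.25, 0.0, 0.0))
  res_b <- mk(c("s1", "s2", "s3", "s4"),
              q = c(0.5, 0.01, 0.2, 0.9),
              blood_frac = c(0, 0.1, 0.0, 0.0))

  incl <- build_include_list(res_a, res_b, curated_species = "s3",
                             manual_additions = "EBV")
  expect_setequal(incl$species_id, c("s1", "s3", "EBV"))
  expect_equal(incl$provenance[incl$species_id == "s1"], "statistical")
  # s2: q significant in both but blood prevalence 25% in cohort A
  expect_false("s2" %in% incl$species_id)
  # s3: cohort-B q in [0.05, 0.4) and on the curated list
  expect_equal(incl$provenance[incl$species_id == "s3"], "curated")
  expect_equal(incl$provenance[incl$species_id == "EBV"], "manual")

  # curated species outside the band warns and is not included
  expect_warning(
    incl2 <- build_include_list(res_a, res_b, curated_species = "s4"),
    "outside the q band")
  expect_false("s4" %in% incl2$species_id)

  # monotonicity: manual additions never remove other species
  incl3 <- build_include_list(res_a, res_b, curated_species = "s3",
                              manual_additions = c("EBV", "extra"))
  expect_true(all(incl$species_id %in% incl3$species_id))
})

test_that("species absent from one cohort satisfy the blood cap there", {
  mk <- function(species, q, blood_frac) {
    tibble::tibble(species_id = species, tissue_present = 40L,
                   tissue_total = 80L, blood_present = 0L, blood_total = 80L,
                   fisher_p = q, q_value = q, blood_prev_frac = blood_frac,
                   classification = "exclude")
  }
  res_a <- mk("only_in_a", 0.001, 0.0)
  res_b <- mk("only_in_b", 0.001, 0.0)
  incl <- build_include_list(res_a, res_b)
  expect_setequal(incl$species_id, c("only_in_a", "only_in_b"))
})

test_that("apply_include_list filters columns, flags empties, reports retention", {
  m <- matrix(c(4, 0, 6,
                0, 0, 10), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  amx <- toy_amx(m, semantics = "score")

  filt <- apply_include_list(amx, c("a", "b"))
  expect_equal(amx_taxa(filt), c("a", "b"))
  expect_equal(attr(filt, "empty_samples"), "s2")
  expect_equal(attr(filt, "retained_fraction"), 4 / 20)

  all_in <- apply_include_list(amx, c("a", "b", "c"))
  expect_equal(amx_values(all_in), amx_values(amx))
  expect_equal(attr(all_in, "retained_fraction"), 1)

  none <- apply_include_list(amx, character())
  expect_equal(ncol(amx_values(none)), 0)
  expect_setequal(attr(none, "empty_samples"), c("s1", "s2"))
})

test_that("decontamination report partitions the species universe", {
  sim_a <- simulate_cohort(cohort_config(n_tumor = 30, n_blood = 30,
                                         n_resident_species = 45,
                                         n_contaminant_species = 30,
                                         seed = 61))
  sim_b <- simulate_cohort(cohort_config(n_tumor = 30, n_blood = 30,
                                         n_resident_species = 45,
                                         n_contaminant_species = 30,
                                         cohort = "B", mode = "wes_like",
                                         seed = 62))
  res_a <- prevalence_tests(sim_a$tumor, sim_a$blood)
  res_b <- prevalence_tests(sim_b$tumor, sim_b$blood)
  incl <- build_include_list(res_a, res_b, manual_additions = "EBV")
  filt <- list(A = apply_include_list(sim_a$tumor_score, incl))
  rep <- decontamination_report(list(A = res_a, B = res_b), incl,
                                filtered = filt)
  expect_equal(rep$n_included + rep$n_excluded,
               rep$n_species_universe + 1)  # EBV is outside the universe
  expect_equal(rep$provenance_counts$manual, 1)
  expect_true(rep$retained_fraction$A > 0 &&
                rep$retained_fraction$A <= 1)
  # borderline awaiting curation = band species not curated/included
  band <- unique(c(res_a$species_id[res_a$classification == "borderline"],
                   res_b$species_id[res_b$classification == "borderline"]))
  expect_setequal(rep$borderline_awaiting_curation,
                  setdiff(band, incl$species_id))
})

test_that("species list files read one id per line, ignoring comments", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# curated", "sp1", "", "  sp2  "), path)
  expect_equal(read_species_list(path), c("sp1", "sp2"))
  expect_equal(read_species_list(NULL), character())
})
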