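#' Pipeline run configuration
#'
#' Collects every tunable threshold of the analysis in one nested list:
#' simulation settings for the two cohorts (cohort A is WGS-like, cohort
#' B WES-like), decontamination thresholds, normalization constants,
#' subtype thresholds, diversity/PERMANOVA settings and
#' differential-abundance filters. The master `seed` drives every
#' stochastic stage; per-stage seeds are derived as
#' `seed * 131 + stage_counter` (kept below 2^31) so a stage rerun in
#' isolation reproduces its in-pipeline result.
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Master integer seed.
#' @param cohort_a,cohort_b [cohort_config()] objects (defaults: WGS-like
#'   A, WES-like B, seeds derived from `seed`).
#' @param q_sig,blood_prev_cap,curation_band,min_reads Decontamination
#'   thresholds.
#' @param curated_species,manual_additions Character vectors (or paths
#'   readable by [read_species_list()]).
#' @param base_genome_bp Human genome size for normalization.
#' @param subtype_thresholds List with `ebv`, `scv`, `ploidy`.
#' @param completeness_threshold,permanova_terms,n_permutations
#'   Beta-diversity settings; `permanova_terms` is the pre-defined
#'   candidate order.
#' @param da_min_prevalence,da_q_threshold,da_alpha Differential
#'   abundance filters (`da_alpha` gates covariates on PERMANOVA p).
#' @return A list of class `gc_run_config`.
#' @export
run_config <- function(out_dir = tempfile("gastromicro_run_"),
                       seed = 1L,
                       cohort_a = NULL, cohort_b = NULL,
                       q_sig = 0.05, blood_prev_cap = 0.20,
                       curation_band = c(0.05, 0.4), min_reads = 2,
                       curated_species = character(),
                       manual_additions = character(),
                       base_genome_bp = 3.1e9,
                       subtype_thresholds = list(ebv = 1e-3, scv = 20,
                                                 ploidy = 2.5),
                       completeness_threshold = 0.85,
                       permanova_terms = c("geography", "age", "sex",
                                           "histology", "msi_status",
                                           "pT", "pN"),
                       n_permutations = 999,
                       da_min_prevalence = 0.10, da_q_threshold = 0.25,
                       da_alpha = 0.05) {
  seed <- as.integer(seed)
  if (is.null(cohort_a)) {
    cohort_a <- cohort_config(mode = "wgs_like", cohort = "A",
                              seed = stage_seed(seed, 1))
  }
  if (is.null(cohort_b)) {
    cohort_b <- cohort_config(mode = "wes_like", cohort = "B",
                              seed = stage_seed(seed, 2))
  }
  cfg <- list(
    out_dir = out_dir, seed = seed,
    cohort_a = cohort_a, cohort_b = cohort_b,
    q_sig = q_sig, blood_prev_cap = blood_prev_cap,
    curation_band = curation_band, min_reads = min_reads,
    curated_species = curated_species,
    manual_additions = manual_additions,
    base_genome_bp = base_genome_bp,
    subtype_thresholds = subtype_thresholds,
    completeness_threshold = completeness_threshold,
    permanova_terms = permanova_terms,
    n_permutations = n_permutations,
    da_min_prevalence = da_min_prevalence,
    da_q_threshold = da_q_threshold,
    da_alpha = da_alpha
  )
  class(cfg) <- "gc_run_config"
  cfg
}

stage_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 131 + counter) %% .Machine$integer.max)
}

#' Validate a run configuration
#'
#' Checks every threshold against its documented domain. Never throws:
#' returns a character vector of problems, empty when the configuration
#' is valid.
#'
#' @param config A [run_config()] list.
#' @return Character vector of problem descriptions (possibly empty).
#' @export
validate_config <- function(config) {
  problems <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  in01 <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
    x >= 0 && x <= 1
  chk(in01(config$q_sig), sprintf("q_sig = %s not in [0, 1]",
                                  format(config$q_sig)))
  chk(in01(config$blood_prev_cap),
      sprintf("blood_prev_cap = %s not in [0, 1]",
              format(config$blood_prev_cap)))
  band <- config$curation_band
  chk(length(band) == 2 && in01(band[1]) && in01(band[2]) &&
        band[1] < band[2],
      sprintf("curation_band = [%s, %s) must satisfy 0 <= low < high <= 1",
              format(band[1]), format(band[2])))
  chk(is.numeric(config$min_reads) && config$min_reads >= 1,
      "min_reads must be >= 1")
  chk(is.numeric(config$base_genome_bp) && config$base_genome_bp > 0,
      "base_genome_bp must be positive")
  th <- config$subtype_thresholds
  chk(is.numeric(th$ebv) && th$ebv > 0, "subtype ebv threshold must be > 0")
  chk(is.numeric(th$scv) && th$scv > 0, "subtype scv threshold must be > 0")
  chk(is.numeric(th$ploidy) && th$ploidy > 0,
      "subtype ploidy threshold must be > 0")
  chk(in01(config$completeness_threshold),
      "completeness_threshold must be in [0, 1]")
  chk(is.numeric(config$n_permutations) && config$n_permutations >= 1,
      "n_permutations must be >= 1")
  chk(in01(config$da_min_prevalence), "da_min_prevalence must be in [0, 1]")
  chk(in01(config$da_q_threshold), "da_q_threshold must be in [0, 1]")
  chk(in01(config$da_alpha), "da_alpha must be in [0, 1]")
  chk(is.numeric(config$seed) && length(config$seed) == 1 &&
        !is.na(config$seed), "seed is mandatory")
  for (co in c("cohort_a", "cohort_b")) {
    ok <- tryCatch({validate_sim_config(config[[co]]); TRUE},
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) problems <- c(problems, paste0(co, ": ", ok))
  }
  problems
}

#' Run the full analysis pipeline
#'
#' Executes the stages in their methodological order: simulate the two
#' cohorts, decontaminate (prevalence tests, include-list, matrix
#' filtering), normalise abundance (microbes per human cell for cohort
#' A, read sums for cohort B), call molecular subtypes, compute alpha
#' diversity and group comparisons, run sequential PERMANOVA per cohort,
#' and fit differential abundance restricted to PERMANOVA-significant
#' covariates (skipped, with a log line, when none is significant).
#' Every artifact is written under `config$out_dir` as TSV + JSON; a
#' JSON run manifest records the configuration, per-stage wall-clock,
#' warnings, and an md5 checksum per output file.
#'
#' @param config A [run_config()] object.
#' @param quiet Suppress progress messages (default FALSE).
#' @return The manifest, invisibly, as a list; the full results are in
#'   the `results` attribute.
#' @export
run_all <- function(config, quiet = FALSE) {
  problems <- validate_config(config)
  if (length(problems)) {
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  manifest <- list(config = config_snapshot(config), stages = list(),
                   warnings = character())
  results <- list()
  t_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- withCallingHandlers(expr, warning = function(w) {
      manifest$warnings <<- c(manifest$warnings,
                              paste0(name, ": ", conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  say("stage 1/7: simulating cohorts")
  sims <- t_stage("simulate", list(
    A = simulate_cohort(config$cohort_a),
    B = simulate_cohort(config$cohort_b)
  ))
  readr::write_tsv(dplyr::bind_rows(sims$A$metadata, sims$B$metadata),
                   file.path(config$out_dir, "metadata.tsv"))
  jsonlite::write_json(
    list(A = sims$A$truth[c("resident_species", "contaminant_species")],
         B = sims$B$truth[c("resident_species", "contaminant_species")]),
    file.path(config$out_dir, "ground_truth.json"), auto_unbox = FALSE)

  say("stage 2/7: decontamination")
  decon <- t_stage("decontam", {
    res_a <- prevalence_tests(sims$A$tumor, sims$A$blood,
                              min_reads = config$min_reads,
                              q_sig = config$q_sig,
                              curation_band = config$curation_band)
    res_b <- prevalence_tests(sims$B$tumor, sims$B$blood,
                              min_reads = config$min_reads,
                              q_sig = config$q_sig,
                              curation_band = config$curation_band)
    incl <- build_include_list(res_a, res_b, q_sig = config$q_sig,
                               blood_prev_cap = config$blood_prev_cap,
                               curation_band = config$curation_band,
                               curated_species = config$curated_species,
                               manual_additions = config$manual_additions)
    filt <- list(A = apply_include_list(sims$A$tumor_score, incl),
                 B = apply_include_list(sims$B$tumor_score, incl))
    report <- decontamination_report(list(A = res_a, B = res_b), incl,
                                     filtered = filt,
                                     curated_species = config$curated_species)
    list(results = list(A = res_a, B = res_b), include_list = incl,
         filtered = filt, report = report)
  })
  write_report(decon$results$A, file.path(config$out_dir, "prevalence_A"))
  write_report(decon$results$B, file.path(config$out_dir, "prevalence_B"))
  write_report(tibble::as_tibble(decon$include_list),
               file.path(config$out_dir, "include_list"))
  jsonlite::write_json(unclass(decon$report),
                       file.path(config$out_dir, "decontam_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  say("stage 3/7: abundance normalization")
  abund <- t_stage("normalize", list(
    A = abundance_summary(decon$filtered$A, sims$A$metadata,
                          mode = "per_human_cell",
                          taxonomy = sims$A$taxonomy,
                          base_genome_bp = config$base_genome_bp),
    B = abundance_summary(decon$filtered$B, sims$B$metadata,
                          mode = "read_sum")
  ))
  write_report(dplyr::bind_rows(abund$A, abund$B),
               file.path(config$out_dir, "abundance_summary"))

  say("stage 4/7: molecular subtyping")
  subtypes <- t_stage("subtype", {
    call_molecular_subtypes(sims$A$metadata,
                            thresholds = config$subtype_thresholds,
                            use_measured_msi = FALSE)
  })
  write_report(tibble::as_tibble(subtypes),
               file.path(config$out_dir, "subtype_calls"))

  say("stage 5/7: alpha diversity and group comparisons")
  alpha <- t_stage("alpha_diversity", {
    purrr::imap(decon$filtered, function(f, nm) {
      sims[[nm]]$metadata |>
        dplyr::left_join(alpha_diversity(f), by = "sample_id") |>
        dplyr::left_join(abund[[nm]][, c("sample_id", "total_abundance")],
                         by = "sample_id")
    })
  })
  group_tests <- t_stage("group_tests", {
    purrr::imap_dfr(alpha, function(tbl, nm) {
      dplyr::mutate(group_associations(
        tbl, outcomes = c("total_abundance", "shannon"),
        covariates = c("msi_status", "sex", "location", "geography",
                       "histology", "pT", "pN", "age")),
        cohort = nm, .before = 1)
    })
  })
  write_report(dplyr::select(group_tests, -"group_ns"),
               file.path(config$out_dir, "group_tests"))

  say("stage 6/7: beta diversity / PERMANOVA")
  permanovas <- t_stage("permanova", {
    purrr::imap(decon$filtered, function(f, nm) {
      md <- binarize_stage(sims[[nm]]$metadata)
      terms <- completeness_filter(md, config$permanova_terms,
                                   config$completeness_threshold)
      terms <- terms[vapply(terms, function(tm) {
        length(unique(stats::na.omit(md[[tm]]))) >= 2
      }, logical(1))]
      kept <- drop_empty_samples(f, md, terms)
      permanova_sequential(bray_curtis(kept$matrix), kept$metadata, terms,
                           n_permutations = config$n_permutations,
                           seed = stage_seed(config$seed, 6))
    })
  })
  for (nm in names(permanovas)) {
    write_report(tibble::as_tibble(permanovas[[nm]]),
                 file.path(config$out_dir, paste0("permanova_", nm)))
  }

  say("stage 7/7: differential abundance")
  da <- t_stage("differential_abundance", {
    purrr::imap(permanovas, function(pm, nm) {
      covs <- select_da_covariates(pm, alpha = config$da_alpha)
      if (length(covs) == 0) {
        say("  cohort ", nm,
            ": no PERMANOVA-significant covariates; DA skipped")
        return(empty_da_result())
      }
      differential_abundance(decon$filtered[[nm]],
                             binarize_stage(sims[[nm]]$metadata), covs,
                             min_prevalence = config$da_min_prevalence,
                             q_threshold = config$da_q_threshold)
    })
  })
  write_report(dplyr::bind_rows(purrr::imap(da, function(d, nm) {
    dplyr::mutate(tibble::as_tibble(d), cohort = nm, .before = 1)
  })), file.path(config$out_dir, "differential_abundance"))

  files <- sort(list.files(config$out_dir, recursive = TRUE,
                           full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  manifest$checksums <- as.list(tools::md5sum(
    file.path(config$out_dir, files)))
  names(manifest$checksums) <- files
  manifest$versions <- list(
    gastromicro = as.character(utils::packageVersion("gastromicro")),
    R = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  results <- list(sims = sims, decontam = decon, abundance = abund,
                  subtypes = subtypes, alpha = alpha,
                  group_tests = group_tests, permanova = permanovas,
                  da = da)
  out <- structure(manifest, results = results)
  invisible(out)
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$cohort_a <- unclass(snap$cohort_a)
  snap$cohort_b <- unclass(snap$cohort_b)
  for (co in c("cohort_a", "cohort_b")) {
    if (!is.null(snap[[co]]$covariate_effects)) {
      snap[[co]]$covariate_effects <-
        as.data.frame(snap[[co]]$covariate_effects)
    }
  }
  snap
}
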