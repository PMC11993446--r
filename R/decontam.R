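#' Per-species prevalence under the two-read rule
#'
#' A species is "present" in a sample when it has at least `min_reads`
#' unambiguously mapped reads. Prevalence is the number of samples that
#' meet the rule. The matrix must carry unambiguous-read semantics:
#' score-weighted values would inflate presence and are rejected.
#'
#' @param x A `gc_abundance` matrix with `unambiguous_reads` semantics.
#' @param min_reads Presence threshold in reads (default 2).
#' @return A tibble with columns `species_id`, `present`, `total`.
#' @export
compute_prevalence <- function(x, min_reads = 2) {
  if (!identical(amx_semantics(x), "unambiguous_reads")) {
    stop("prevalence requires unambiguous-read semantics, got '",
         amx_semantics(x), "'", call. = FALSE)
  }
  if (min_reads < 1) stop("min_reads must be >= 1", call. = FALSE)
  m <- amx_values(x)
  tibble::tibble(
    species_id = colnames(m),
    present = as.integer(colSums(m >= min_reads)),
    total = nrow(m)
  )
}

#' One-sided Fisher exact test for tissue-enriched prevalence
#'
#' Exact hypergeometric upper-tail probability that tissue prevalence is
#' at least as extreme as observed, under the null of equal prevalence
#' with all margins fixed — the alternative is "prevalence greater in
#' tissue than in blood". Vectorised over its arguments. Degenerate
#' tables with a zero margin return 1.
#'
#' @param tissue_present,tissue_absent,blood_present,blood_absent
#'   Nonnegative integer cell counts of the 2x2 table(s).
#' @return P-value(s) in \[0, 1\].
#' @export
fisher_one_sided <- function(tissue_present, tissue_absent,
                             blood_present, blood_absent) {
  counts <- cbind(tissue_present, tissue_absent, blood_present, blood_absent)
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(counts != round(counts))) {
    stop("counts must be integers", call. = FALSE)
  }
  # P(X >= tissue_present), X ~ Hypergeom(drawn = tissue margin,
  # successes = total present)
  stats::phyper(tissue_present - 1,
                m = tissue_present + blood_present,
                n = tissue_absent + blood_absent,
                k = tissue_present + tissue_absent,
                lower.tail = FALSE)
}

#' Storey q-values with a BH fallback for small test families
#'
#' Estimates the proportion of true nulls pi0 with Storey's smoother
#' (natural cubic spline through pi0(lambda) over lambda = 0.05, ...,
#' 0.95, evaluated at the largest lambda) and returns
#' `q_i = pi0 * m * p_(i) / i` with the usual step-up monotonisation.
#' With fewer than `min_tests_for_pi0` p-values the smoother is too
#' unstable, so pi0 is fixed at 1 and the result is exactly the
#' Benjamini-Hochberg adjustment.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param pi0 Optional fixed pi0 in (0, 1\]; `NULL` estimates it.
#' @param min_tests_for_pi0 Minimum family size for the smoother
#'   (default 100).
#' @return Q-values in the input order.
#' @export
estimate_qvalues <- function(p, pi0 = NULL, min_tests_for_pi0 = 100) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  if (is.null(pi0)) {
    pi0 <- if (m < min_tests_for_pi0) 1 else estimate_pi0_smoother(p)
  }
  if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]", call. = FALSE)
  o <- order(p)
  q_sorted <- pi0 * ((m / seq_len(m)) * p[o])
  q_sorted <- pmin(1, rev(cummin(rev(q_sorted))))
  q_sorted[order(o)]
}

estimate_pi0_smoother <- function(p, lambda = seq(0.05, 0.95, 0.05)) {
  m <- length(p)
  pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(max(pi0, 1 / m), 1)
}

#' Blood-versus-tissue prevalence tests for one cohort
#'
#' Runs [compute_prevalence()] on the tumor and blood matrices, the
#' one-sided Fisher test per species, and q-value estimation across the
#' cohort's species family, then classifies each species as
#' `statistical_include` (q below `q_sig`), `borderline` (q inside
#' `curation_band`, the manual-curation window) or `exclude`.
#'
#' @param tumor,blood `gc_abundance` matrices with unambiguous-read
#'   semantics.
#' @param min_reads Presence rule threshold (default 2 reads).
#' @param q_sig Inclusion significance threshold on q (default 0.05).
#' @param curation_band Half-open interval `[low, high)` of q-values
#'   eligible for literature curation (default `c(0.05, 0.4)`).
#' @param pi0 Passed to [estimate_qvalues()].
#' @return A tibble with one row per species: prevalence counts, blood
#'   prevalence fraction, `fisher_p`, `q_value`, `classification`.
#' @export
prevalence_tests <- function(tumor, blood, min_reads = 2, q_sig = 0.05,
                             curation_band = c(0.05, 0.4), pi0 = NULL) {
  if (!identical(amx_material(tumor), "tumor") ||
      !identical(amx_material(blood), "blood")) {
    stop("expected a tumor matrix and a blood matrix", call. = FALSE)
  }
  pt <- compute_prevalence(tumor, min_reads)
  pb <- compute_prevalence(blood, min_reads)
  species <- union(pt$species_id, pb$species_id)
  res <- tibble::tibble(
    species_id = species,
    tissue_present = int_lookup(pt, species, "present"),
    tissue_total = int_lookup(pt, species, "total", default = nrow(tumor)),
    blood_present = int_lookup(pb, species, "present"),
    blood_total = int_lookup(pb, species, "total", default = nrow(blood))
  )
  res$fisher_p <- fisher_one_sided(res$tissue_present,
                                   res$tissue_total - res$tissue_present,
                                   res$blood_present,
                                   res$blood_total - res$blood_present)
  res$q_value <- estimate_qvalues(res$fisher_p, pi0 = pi0)
  res$blood_prev_frac <- res$blood_present / res$blood_total
  res$classification <- dplyr::case_when(
    res$q_value < q_sig ~ "statistical_include",
    res$q_value >= curation_band[1] & res$q_value < curation_band[2] ~
      "borderline",
    TRUE ~ "exclude"
  )
  res
}

int_lookup <- function(tbl, keys, col, default = 0L) {
  i <- match(keys, tbl$species_id)
  out <- tbl[[col]][i]
  out[is.na(i)] <- default
  as.integer(out)
}

#' Build the species include-list from two cohorts
#'
#' Merges the two cohorts' prevalence-test results into the final
#' include-list. A species enters with provenance `statistical` when its
#' q-value is below `q_sig` in either cohort and its blood prevalence
#' fraction is below `blood_prev_cap` in both cohorts (a species never
#' observed in a cohort counts as prevalence 0 there, so the cap is met
#' trivially). A species whose cohort-B q-value falls in the curation
#' band enters with provenance `curated` if and only if it appears on the
#' user-supplied curated list (digestive/respiratory-tract inhabitants
#' from literature review). Manual additions (e.g. Epstein-Barr virus)
#' always enter with provenance `manual`. Everything else is excluded.
#'
#' @param results_a,results_b Tibbles from [prevalence_tests()] for
#'   cohorts A and B.
#' @param q_sig Statistical-inclusion threshold (default 0.05).
#' @param blood_prev_cap Maximum tolerated blood prevalence fraction
#'   (default 0.20, exclusive).
#' @param curation_band Half-open q interval eligible for curation.
#' @param curated_species Character vector of curated species ids.
#' @param manual_additions Character vector of species ids always
#'   included.
#' @return A tibble of class `gc_include_list` with columns `species_id`,
#'   `provenance` (`statistical`, `curated`, `manual`).
#' @export
build_include_list <- function(results_a, results_b, q_sig = 0.05,
                               blood_prev_cap = 0.20,
                               curation_band = c(0.05, 0.4),
                               curated_species = character(),
                               manual_additions = character()) {
  species <- union(results_a$species_id, results_b$species_id)
  qa <- num_lookup(results_a, species, "q_value", default = NA_real_)
  qb <- num_lookup(results_b, species, "q_value", default = NA_real_)
  bfa <- num_lookup(results_a, species, "blood_prev_frac", default = 0)
  bfb <- num_lookup(results_b, species, "blood_prev_frac", default = 0)

  sig_either <- (!is.na(qa) & qa < q_sig) | (!is.na(qb) & qb < q_sig)
  cap_both <- bfa < blood_prev_cap & bfb < blood_prev_cap
  statistical <- sig_either & cap_both

  in_band_b <- !is.na(qb) & qb >= curation_band[1] & qb < curation_band[2]
  curated <- in_band_b & species %in% curated_species & !statistical

  off_band <- setdiff(curated_species, species[in_band_b])
  off_band <- setdiff(off_band, species[statistical])
  if (length(off_band)) {
    warning("curated species outside the q band were not included: ",
            paste(off_band, collapse = ", "), call. = FALSE)
  }

  manual <- species %in% manual_additions & !statistical & !curated
  extra_manual <- setdiff(manual_additions, species)

  out <- tibble::tibble(
    species_id = c(species[statistical], species[curated], species[manual],
                   extra_manual),
    provenance = c(rep("statistical", sum(statistical)),
                   rep("curated", sum(curated)),
                   rep("manual", sum(manual) + length(extra_manual)))
  )
  out <- dplyr::arrange(out, .data$species_id)
  class(out) <- c("gc_include_list", class(out))
  out
}

num_lookup <- function(tbl, keys, col, default) {
  i <- match(keys, tbl$species_id)
  out <- tbl[[col]][i]
  out[is.na(i)] <- default
  out
}

#' Filter a matrix to the include-list
#'
#' Restricts the taxon columns of an abundance matrix to the species on
#' the include-list. Samples whose filtered row sums to zero are kept but
#' flagged in the `empty_samples` attribute (they are removed only where
#' an analysis requires it, e.g. before PERMANOVA). The attribute
#' `retained_fraction` records `sum(filtered) / sum(original)`, the share
#' of the original microbial signal the include-list retains.
#'
#' @param x A species-level `gc_abundance` matrix.
#' @param include_list A `gc_include_list` (or character vector of
#'   species ids).
#' @return A filtered `gc_abundance` with `empty_samples` and
#'   `retained_fraction` attributes.
#' @export
apply_include_list <- function(x, include_list) {
  keep_ids <- if (is.data.frame(include_list)) include_list$species_id
  else as.character(include_list)
  m <- amx_values(x)
  keep <- intersect(colnames(m), keep_ids)
  fm <- m[, keep, drop = FALSE]
  out <- abundance_matrix(fm, semantics = amx_semantics(x),
                          material = amx_material(x))
  total <- sum(m)
  attr(out, "retained_fraction") <- if (total > 0) sum(fm) / total else NA_real_
  attr(out, "empty_samples") <- rownames(m)[rowSums(fm) == 0]
  out
}

#' Summarise a decontamination run
#'
#' Counts species per classification and provenance, reports the
#' per-cohort retained signal fraction when the score matrices are
#' supplied, and lists borderline species still awaiting curation.
#'
#' @param results Named list of [prevalence_tests()] tibbles (e.g.
#'   `list(A = ..., B = ...)`).
#' @param include_list The [build_include_list()] result.
#' @param filtered Optional named list (same names as `results`) of
#'   matrices returned by [apply_include_list()], used for the retained
#'   fractions.
#' @param curated_species Curated list used, to compute the outstanding
#'   borderline set.
#' @return A list of class `gc_decontam_report`.
#' @export
decontamination_report <- function(results, include_list, filtered = NULL,
                                   curated_species = character()) {
  universe <- unique(unlist(lapply(results, `[[`, "species_id")))
  included <- include_list$species_id
  class_counts <- lapply(results, function(r) table(r$classification))
  borderline <- unique(unlist(lapply(results, function(r) {
    r$species_id[r$classification == "borderline"]
  })))
  awaiting <- setdiff(borderline, union(curated_species, included))
  report <- list(
    n_species_universe = length(universe),
    n_included = length(intersect(included, universe)) +
      length(setdiff(included, universe)),
    n_excluded = length(setdiff(universe, included)),
    provenance_counts = as.list(table(include_list$provenance)),
    classification_counts = lapply(class_counts, as.list),
    retained_fraction = if (!is.null(filtered)) {
      lapply(filtered, function(f) attr(f, "retained_fraction", exact = TRUE))
    },
    borderline_awaiting_curation = awaiting
  )
  class(report) <- "gc_decontam_report"
  report
}

#' @export
print.gc_decontam_report <- function(x, ...) {
  cat("Decontamination report\n")
  cat(sprintf("  species universe: %d; included: %d; excluded: %d\n",
              x$n_species_universe, x$n_included, x$n_excluded))
  cat("  provenance:",
      paste(names(x$provenance_counts), unlist(x$provenance_counts),
            sep = "=", collapse = ", "), "\n")
  if (!is.null(x$retained_fraction)) {
    cat("  retained signal:",
        paste(names(x$retained_fraction),
              sprintf("%.1f%%", 100 * unlist(x$retained_fraction)),
              sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("  borderline species awaiting curation: %d\n",
              length(x$borderline_awaiting_curation)))
  invisible(x)
}

#' Read a plain-text species list (one species id per line)
#'
#' @param path File path; blank lines and `#` comments are ignored.
#' @return Character vector of species ids.
#' @export
read_species_list <- function(path) {
  if (is.null(path) || !nzchar(path)) return(character())
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
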