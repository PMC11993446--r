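#' Compare an outcome across the groups of a categorical variable
#'
#' Dispatches on the number of groups with data: Wilcoxon rank-sum for
#' two groups, Kruskal-Wallis for more. Two-sided throughout; the
#' Wilcoxon test is exact when the combined sample size is at most 20
#' and there are no ties, otherwise the normal approximation with
#' continuity correction is used; ties are handled by midranks with the
#' tie-corrected variance. Missing outcome values and missing labels are
#' excluded.
#'
#' @param values Numeric outcome vector.
#' @param groups Group labels (factor or character), same length.
#' @param variable,outcome Optional names recorded in the result.
#' @return A one-row tibble: `variable`, `outcome`, `test`, `statistic`,
#'   `p_value`, `group_ns` (list column of per-group counts).
#' @export
compare_outcome_by_group <- function(values, groups, variable = NA_character_,
                                     outcome = NA_character_) {
  ok <- !is.na(values) & !is.na(groups)
  v <- values[ok]
  g <- droplevels(factor(groups[ok]))
  ns <- table(g)
  if (length(ns) < 2 || any(ns < 2)) {
    stop("need at least 2 groups with at least 2 observations each",
         call. = FALSE)
  }
  if (nlevels(g) == 2) {
    x <- v[g == levels(g)[1]]
    y <- v[g == levels(g)[2]]
    exact <- (length(v) <= 20) && !anyDuplicated(v)
    ht <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
    test <- "wilcoxon"
  } else {
    ht <- stats::kruskal.test(v, g)
    test <- "kruskal_wallis"
  }
  tibble::tibble(
    variable = variable, outcome = outcome, test = test,
    statistic = unname(ht$statistic), p_value = ht$p.value,
    group_ns = list(as.list(ns))
  )
}

#' Spearman rank correlation between a continuous covariate and an
#' outcome
#'
#' Midrank ties; p-value from the large-sample approximation. A constant
#' vector has no rank ordering, so the correlation is undefined and
#' flagged.
#'
#' @param x,y Paired numeric vectors; pairs with missing values are
#'   dropped (at least 3 complete pairs required).
#' @param variable,outcome Optional names recorded in the result.
#' @return A one-row tibble with `test = "spearman"`, `statistic` (rho)
#'   and `p_value` (`NA` with `degenerate = TRUE` for constant input).
#' @export
spearman_correlation <- function(x, y, variable = NA_character_,
                                 outcome = NA_character_) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  degenerate <- length(unique(x)) < 2 || length(unique(y)) < 2
  if (degenerate) {
    rho <- NA_real_; p <- NA_real_
  } else {
    ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    rho <- unname(ht$estimate); p <- ht$p.value
  }
  tibble::tibble(
    variable = variable, outcome = outcome, test = "spearman",
    statistic = rho, p_value = p, group_ns = list(list(n = length(x))),
    degenerate = degenerate
  )
}

#' Group comparisons of abundance and diversity across covariates
#'
#' Runs [compare_outcome_by_group()] (categorical covariates) or
#' [spearman_correlation()] (continuous covariates) for each outcome in
#' `outcomes` against each covariate, complete-case per comparison.
#'
#' @param data Tibble holding outcomes and covariates per sample.
#' @param outcomes Character vector of outcome columns (e.g.
#'   `total_abundance`, `shannon`).
#' @param covariates Character vector of covariate columns.
#' @return A tibble with one row per (covariate, outcome) comparison.
#' @export
group_associations <- function(data, outcomes, covariates) {
  grid <- tidyr::expand_grid(variable = covariates, outcome = outcomes)
  purrr::pmap_dfr(grid, function(variable, outcome) {
    v <- data[[variable]]
    y <- data[[outcome]]
    res <- tryCatch({
      if (is.numeric(v)) spearman_correlation(v, y, variable, outcome)
      else compare_outcome_by_group(y, v, variable, outcome)
    }, error = function(e) NULL)
    res
  })
}

#' Select differential-abundance covariates from a PERMANOVA result
#'
#' Differential abundance is only fitted for covariates whose
#' beta-diversity association is supported: terms with permutation p
#' below `alpha`, in their model order.
#'
#' @param permanova A `gc_permanova` result.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of selected terms (possibly empty).
#' @export
select_da_covariates <- function(permanova, alpha = 0.05) {
  terms <- permanova$term[permanova$term != "Residual"]
  p <- permanova$p_perm[permanova$term != "Residual"]
  terms[!is.na(p) & p < alpha]
}

#' Pre-specified binarisations of staged covariates
#'
#' The sequential models and differential abundance use two-level
#' versions of the staging variables: pT1/pT2 versus pT3/pT4, pN0 versus
#' node-positive, MSI versus MSS. Other covariates pass through.
#'
#' @param metadata Metadata tibble.
#' @return The tibble with `pT` collapsed to `{pT1/2, pT3/4}` and `pN`
#'   to `{pN0, pN+}` (factors; reference level first).
#' @export
binarize_stage <- function(metadata) {
  md <- metadata
  if ("pT" %in% names(md)) {
    md$pT <- factor(ifelse(is.na(md$pT), NA_character_,
                           ifelse(md$pT %in% c("1", "2"), "pT1/2", "pT3/4")),
                    levels = c("pT1/2", "pT3/4"))
  }
  if ("pN" %in% names(md)) {
    md$pN <- factor(ifelse(is.na(md$pN), NA_character_,
                           ifelse(md$pN == "0", "pN0", "pN+")),
                    levels = c("pN0", "pN+"))
  }
  if ("msi_status" %in% names(md)) {
    md$msi_status <- factor(as.character(md$msi_status),
                            levels = c("MSS", "MSI"))
  }
  md
}
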