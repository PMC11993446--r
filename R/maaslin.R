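#' Multivariable differential abundance (MaAsLin2-style)
#'
#' Per-taxon multivariable linear models on log-transformed total-sum
#' scaled abundance, at the tool's default configuration: counts are
#' divided by the sample total (TSS); taxa present in fewer than
#' `min_prevalence` of samples are dropped before fitting; each retained
#' taxon's relative abundance is log2-transformed after adding a
#' pseudocount of half its smallest nonzero relative abundance; a linear
#' model with all covariates jointly is fitted per taxon; each
#' covariate's coefficient gets a two-sided t-test p-value and
#' Benjamini-Hochberg q-values across taxa within the covariate;
#' significance is declared at `q < q_threshold`.
#'
#' Staged covariates should be binarised first (see [binarize_stage()]);
#' the coefficient then measures the log2 shift at the comparison level
#' relative to the reference level.
#'
#' @param x A decontaminated `gc_abundance` matrix (species or genus
#'   level, score semantics).
#' @param metadata Metadata tibble covering the samples.
#' @param covariates Character vector of metadata columns to model
#'   jointly (from [select_da_covariates()]).
#' @param min_prevalence Minimum fraction of samples with the taxon
#'   present (default 0.10).
#' @param q_threshold Significance threshold on q (default 0.25).
#' @return A tibble of class `gc_da`: `taxon`, `covariate`, `term_level`,
#'   `coefficient`, `standard_error`, `p_value`, `q_value`,
#'   `significant`, `direction`.
#' @export
differential_abundance <- function(x, metadata, covariates,
                                   min_prevalence = 0.10,
                                   q_threshold = 0.25) {
  if (length(covariates) == 0) {
    stop("no covariates supplied; differential abundance requires at ",
         "least one PERMANOVA-significant covariate", call. = FALSE)
  }
  m <- amx_values(x)
  meta <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]

  # complete cases on the modelled covariates, then drop zero-total samples
  keep <- rep(TRUE, nrow(m))
  for (cv in covariates) {
    if (!cv %in% names(meta)) stop("covariate not in metadata: ", cv,
                                   call. = FALSE)
    keep <- keep & !is.na(meta[[cv]])
  }
  totals <- rowSums(m)
  keep <- keep & totals > 0
  m <- m[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  if (nrow(m) < length(covariates) + 3) {
    stop("too few complete samples for the model", call. = FALSE)
  }

  # drop covariates that became constant after filtering
  usable <- vapply(covariates, function(cv) {
    length(unique(droplevels(as.factor(meta[[cv]])))) >= 2 ||
      (is.numeric(meta[[cv]]) && length(unique(meta[[cv]])) >= 2)
  }, logical(1))
  if (any(!usable)) {
    warning("dropping constant covariate(s): ",
            paste(covariates[!usable], collapse = ", "), call. = FALSE)
    covariates <- covariates[usable]
    if (length(covariates) == 0) stop("no usable covariates", call. = FALSE)
  }

  rel <- m / rowSums(m)
  prevalence <- colMeans(rel > 0)
  taxa <- colnames(rel)[prevalence >= min_prevalence]
  if (length(taxa) == 0) {
    return(empty_da_result())
  }

  mf <- droplevels(as.data.frame(meta[, covariates, drop = FALSE]))
  form <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
  X <- stats::model.matrix(form, data = mf)
  assign <- attr(X, "assign")
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    stop("model matrix is rank deficient; covariates are collinear",
         call. = FALSE)
  }
  xtx_inv_diag <- diag(chol2inv(qr.R(qr_x)))
  rdf <- nrow(X) - ncol(X)
  covariate_cols <- which(assign > 0)

  fits <- purrr::map_dfr(taxa, function(tx) {
    v <- rel[, tx]
    pseudo <- min(v[v > 0]) / 2
    y <- log2(v + pseudo)
    coefs <- qr.coef(qr_x, y)
    rss <- sum(qr.resid(qr_x, y)^2)
    se <- sqrt(xtx_inv_diag * rss / rdf)
    tibble::tibble(
      taxon = tx,
      covariate = covariates[assign[covariate_cols]],
      term_level = colnames(X)[covariate_cols],
      coefficient = unname(coefs[covariate_cols]),
      standard_error = se[covariate_cols],
      p_value = 2 * stats::pt(abs(coefs[covariate_cols] / se[covariate_cols]),
                              rdf, lower.tail = FALSE)
    )
  })

  out <- fits |>
    dplyr::group_by(.data$covariate, .data$term_level) |>
    dplyr::mutate(q_value = stats::p.adjust(.data$p_value, method = "BH")) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      significant = .data$q_value < q_threshold,
      direction = ifelse(.data$coefficient > 0, "enriched_in_comparison",
                         "enriched_in_reference")
    )
  class(out) <- c("gc_da", class(out))
  out
}

empty_da_result <- function() {
  out <- tibble::tibble(
    taxon = character(), covariate = character(), term_level = character(),
    coefficient = numeric(), standard_error = numeric(),
    p_value = numeric(), q_value = numeric(), significant = logical(),
    direction = character()
  )
  class(out) <- c("gc_da", class(out))
  out
}

#' Significant-effect table for plotting
#'
#' Per-covariate table of significant taxa, sorted by decreasing absolute
#' coefficient, with direction labels following the usual figure
#' convention (taxa enriched at the comparison level versus the
#' reference level).
#'
#' @param da A `gc_da` result from [differential_abundance()].
#' @return A tibble with the significant rows, ordered within covariate
#'   by `abs(coefficient)` descending.
#' @export
effect_plot_table <- function(da) {
  da |>
    dplyr::filter(.data$significant) |>
    dplyr::arrange(.data$covariate, dplyr::desc(abs(.data$coefficient)))
}
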