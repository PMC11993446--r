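#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sequential PERMANOVA result
#'
#' One row per model term (the residual row is kept, with `NA` statistic
#' and p-value), in broom column conventions.
#'
#' @param x A `gc_permanova` object.
#' @param ... Unused.
#' @return A tibble with `term`, `df`, `sum_of_squares`, `R2`,
#'   `statistic`, `p.value`.
#' @export
tidy.gc_permanova <- function(x, ...) {
  tibble::tibble(
    term = x$term, df = x$df, sum_of_squares = x$sum_of_squares,
    R2 = x$R2, statistic = x$F, p.value = x$p_perm
  )
}

#' @rdname tidy.gc_permanova
#' @return `glance` returns a one-row tibble with `n_samples`,
#'   `n_permutations`, `seed`, `n_terms` and the residual R-squared.
#' @export
glance.gc_permanova <- function(x, ...) {
  tibble::tibble(
    n_samples = attr(x, "n_samples"),
    n_permutations = attr(x, "n_permutations"),
    seed = attr(x, "seed"),
    n_terms = sum(x$term != "Residual"),
    residual_R2 = x$R2[x$term == "Residual"]
  )
}

#' Tidy a differential-abundance result
#'
#' @param x A `gc_da` object.
#' @param ... Unused.
#' @return A tibble in broom conventions: `term` (taxon), `covariate`,
#'   `estimate`, `std.error`, `p.value`, `q.value`, `direction`.
#' @export
tidy.gc_da <- function(x, ...) {
  tibble::tibble(
    term = x$taxon, covariate = x$covariate, estimate = x$coefficient,
    std.error = x$standard_error, p.value = x$p_value,
    q.value = x$q_value, direction = x$direction
  )
}

#' @rdname tidy.gc_da
#' @export
glance.gc_da <- function(x, ...) {
  tibble::tibble(
    n_taxa = length(unique(x$taxon)),
    n_covariates = length(unique(x$covariate)),
    n_significant = sum(x$significant)
  )
}
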