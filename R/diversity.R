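#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` over taxa with positive abundance, where
#' `p_i` are within-sample proportions (natural log). An all-zero sample
#' has no composition; its index is defined as 0 and flagged.
#'
#' @param x Nonnegative numeric abundance vector.
#' @return Scalar H; attribute `empty` is TRUE for an all-zero vector.
#' @export
shannon_index <- function(x) {
  if (any(x < 0)) stop("abundances must be nonnegative", call. = FALSE)
  total <- sum(x)
  if (total == 0) return(structure(0, empty = TRUE))
  p <- x[x > 0] / total
  structure(-sum(p * log(p)), empty = FALSE)
}

#' Per-sample alpha diversity
#'
#' @param x A `gc_abundance` matrix.
#' @return A tibble with `sample_id`, `shannon`, `richness` (taxa with
#'   positive abundance) and `empty`.
#' @export
alpha_diversity <- function(x) {
  m <- amx_values(x)
  tibble::tibble(
    sample_id = rownames(m),
    shannon = apply(m, 1, function(v) as.numeric(shannon_index(v))),
    richness = as.integer(rowSums(m > 0)),
    empty = rowSums(m) == 0
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(u, v) = sum|u_i - v_i| / sum(u_i + v_i)` for every sample pair. A
#' pair of all-zero samples has an undefined dissimilarity; it is set to
#' 0 and the affected samples are flagged in the `empty_samples`
#' attribute.
#'
#' @param x A `gc_abundance` matrix with at least two samples.
#' @return A list of class `gc_dist`: `sample_ids` and `d`, a symmetric
#'   matrix with zero diagonal and entries in \[0, 1\].
#' @export
bray_curtis <- function(x) {
  m <- amx_values(x)
  if (nrow(m) < 2) stop("need at least two samples", call. = FALSE)
  num <- as.matrix(stats::dist(m, method = "manhattan"))
  rs <- rowSums(m)
  den <- outer(rs, rs, "+")
  d <- num / den
  d[den == 0] <- 0
  diag(d) <- 0
  structure(list(sample_ids = rownames(m), d = d,
                 empty_samples = rownames(m)[rs == 0]),
            class = "gc_dist")
}

#' @export
print.gc_dist <- function(x, ...) {
  cat(sprintf("# Bray-Curtis dissimilarity over %d samples\n",
              length(x$sample_ids)))
  invisible(x)
}

#' Filter candidate PERMANOVA terms by completeness
#'
#' Retains, in their pre-defined order, the candidate covariates whose
#' non-missing fraction strictly exceeds `threshold` (a term at exactly
#' the threshold is dropped). The conventional candidate order for this
#' analysis is geography, age, sex, histology, MSI status, pT, pN.
#'
#' @param metadata Metadata tibble.
#' @param candidate_terms Character vector of metadata columns, in the
#'   order the sequential model should use.
#' @param threshold Completeness threshold (default 0.85, strict).
#' @return The retained terms, order preserved.
#' @export
completeness_filter <- function(metadata, candidate_terms, threshold = 0.85) {
  keep <- vapply(candidate_terms, function(term) {
    if (!term %in% names(metadata)) return(FALSE)
    mean(!is.na(metadata[[term]])) > threshold
  }, logical(1))
  candidate_terms[keep]
}

#' Remove empty and incomplete samples before PERMANOVA
#'
#' Drops samples whose decontaminated abundance row sums to zero, and
#' samples missing any of the retained model terms (complete-case), then
#' subsets the metadata to match.
#'
#' @param x A `gc_abundance` matrix.
#' @param metadata Metadata tibble covering the matrix samples.
#' @param terms Character vector of retained model terms (may be empty).
#' @return A list with filtered `matrix` and `metadata`.
#' @export
drop_empty_samples <- function(x, metadata, terms = character()) {
  m <- amx_values(x)
  meta <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]
  keep <- rowSums(m) > 0
  for (term in terms) keep <- keep & !is.na(meta[[term]])
  if (sum(keep) < 3) {
    stop("fewer than 3 samples remain after removing empty/incomplete ",
         "samples", call. = FALSE)
  }
  out_m <- abundance_matrix(m[keep, , drop = FALSE],
                            semantics = amx_semantics(x),
                            material = amx_material(x))
  list(matrix = out_m, metadata = meta[keep, , drop = FALSE])
}
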