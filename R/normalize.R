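#' Effective human genome size under ploidy and purity
#'
#' A tumor sample is a mixture of tumor cells (fraction `purity`, each
#' carrying `ploidy/2` haploid-genome equivalents relative to a diploid
#' cell) and normal diploid cells. The human DNA content per "cell" is
#' therefore `base_genome_bp * (purity * ploidy / 2 + (1 - purity))`.
#' At ploidy 2, or with no tumor content, this reduces to the base genome.
#'
#' @param base_genome_bp Haploid-pair human genome size in bp (default
#'   3.1e9).
#' @param ploidy Tumor DNA ploidy (> 0).
#' @param purity Tumor cell fraction in \[0, 1\].
#' @return Effective genome size in bp.
#' @export
effective_human_genome_size <- function(base_genome_bp = 3.1e9, ploidy = 2,
                                        purity = 0) {
  if (any(base_genome_bp <= 0)) stop("base genome size must be positive",
                                     call. = FALSE)
  if (any(ploidy <= 0, na.rm = TRUE)) stop("ploidy must be positive",
                                           call. = FALSE)
  if (any(purity < 0 | purity > 1, na.rm = TRUE)) {
    stop("purity must lie in [0, 1]", call. = FALSE)
  }
  base_genome_bp * (purity * ploidy / 2 + (1 - purity))
}

#' Microbes per human cell
#'
#' The whole-genome abundance measure: genome-equivalents of microbes per
#' human cell,
#' `sum_s(reads_s / genome_size_s) / (human_reads / human_genome_bp)`,
#' with the human genome size already adjusted for ploidy and purity
#' (see [effective_human_genome_size()]).
#'
#' @param microbial_reads Named numeric vector of per-species reads (or
#'   score mass).
#' @param genome_sizes Named numeric vector of per-species genome sizes
#'   (bp); must cover every species in `microbial_reads`.
#' @param human_reads Human read count (> 0).
#' @param effective_human_genome_bp Effective human genome size in bp.
#' @return A nonnegative scalar.
#' @export
microbes_per_human_cell <- function(microbial_reads, genome_sizes,
                                    human_reads, effective_human_genome_bp) {
  if (human_reads <= 0) stop("human_reads must be positive", call. = FALSE)
  if (length(microbial_reads) == 0) return(0)
  sp <- names(microbial_reads)
  if (is.null(sp)) stop("microbial_reads must be named by species",
                        call. = FALSE)
  missing <- setdiff(sp, names(genome_sizes))
  if (length(missing)) {
    stop("species missing genome size: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  gs <- genome_sizes[sp]
  sum(microbial_reads / gs) / (human_reads / effective_human_genome_bp)
}

#' Sum of microbial reads for one sample
#'
#' The exome-cohort abundance measure: the plain sum of microbial
#' abundance over included taxa, with no human-genome adjustment (exome
#' human reads over-represent exons and are not usable as a genome-wide
#' denominator).
#'
#' @param reads Numeric vector of per-taxon abundance.
#' @return A nonnegative scalar.
#' @export
total_read_sum <- function(reads) {
  if (length(reads) == 0) return(0)
  sum(reads)
}

#' Epstein-Barr virus load in virions per human cell
#'
#' The microbes-per-human-cell formula restricted to the EBV taxon.
#'
#' @param ebv_reads EBV read count (or score mass).
#' @param ebv_genome_bp EBV genome size in bp (default 1.718e5).
#' @param human_reads,effective_human_genome_bp As in
#'   [microbes_per_human_cell()].
#' @return Virions per human cell.
#' @export
ebv_load <- function(ebv_reads, ebv_genome_bp = 1.718e5, human_reads,
                     effective_human_genome_bp) {
  microbes_per_human_cell(c(EBV = ebv_reads), c(EBV = ebv_genome_bp),
                          human_reads, effective_human_genome_bp)
}

#' Per-sample abundance summaries for a cohort
#'
#' Computes each sample's total microbial abundance under the cohort's
#' measurement mode: `per_human_cell` (whole-genome cohorts; requires
#' `human_reads`, `ploidy`, `purity` metadata and per-species genome
#' sizes) or `read_sum` (exome cohorts).
#'
#' @param x A decontaminated score-semantics `gc_abundance` matrix.
#' @param metadata Metadata tibble with `sample_id` and, for
#'   `per_human_cell`, `human_reads`, `ploidy`, `purity`.
#' @param mode `"per_human_cell"` or `"read_sum"`.
#' @param taxonomy Taxonomy tibble (needed for `per_human_cell`).
#' @param base_genome_bp Base human genome size (default 3.1e9).
#' @return A tibble with `sample_id`, `mode`, `total_abundance`, and (for
#'   `per_human_cell`) `effective_human_genome_bp`.
#' @export
abundance_summary <- function(x, metadata,
                              mode = c("per_human_cell", "read_sum"),
                              taxonomy = NULL, base_genome_bp = 3.1e9) {
  mode <- match.arg(mode)
  m <- amx_values(x)
  if (mode == "read_sum") {
    return(tibble::tibble(
      sample_id = rownames(m), mode = mode,
      total_abundance = as.numeric(rowSums(m))
    ))
  }
  if (is.null(taxonomy)) {
    stop("per_human_cell mode needs a taxonomy with genome sizes",
         call. = FALSE)
  }
  gs <- stats::setNames(taxonomy$genome_size_bp, taxonomy$taxon_id)
  meta <- metadata[match(rownames(m), metadata$sample_id), , drop = FALSE]
  eff <- effective_human_genome_size(base_genome_bp, meta$ploidy, meta$purity)
  mpc <- vapply(seq_len(nrow(m)), function(i) {
    if (is.na(meta$human_reads[i]) || is.na(eff[i])) return(NA_real_)
    microbes_per_human_cell(m[i, ], gs, meta$human_reads[i], eff[i])
  }, numeric(1))
  tibble::tibble(
    sample_id = rownames(m), mode = mode, total_abundance = mpc,
    effective_human_genome_bp = eff
  )
}
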