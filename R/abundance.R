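#' Construct an abundance matrix
#'
#' An abundance matrix is a tibble with one row per sample: a `sample_id`
#' character column followed by one nonnegative numeric column per taxon.
#' Two attributes record how the values must be interpreted: `semantics`
#' distinguishes PathSeq "score" values (score-weighted read mass, used for
#' all abundance and diversity analyses) from unambiguously mapped read
#' counts (required by the prevalence-based decontamination), and
#' `material` records whether the samples are tumor tissue or matched
#' blood.
#'
#' @param data A data frame with a `sample_id` column and numeric taxon
#'   columns, or a numeric matrix with sample row names and taxon column
#'   names.
#' @param semantics Either `"score"` or `"unambiguous_reads"`. Set exactly
#'   once, at load time.
#' @param material Either `"tumor"` or `"blood"`.
#' @return A tibble of class `gc_abundance` with `semantics` and
#'   `material` attributes.
#' @export
abundance_matrix <- function(data,
                             semantics = c("score", "unambiguous_reads"),
                             material = c("tumor", "blood")) {
  semantics <- match.arg(semantics)
  material <- match.arg(material)
  if (is.matrix(data)) {
    if (is.null(rownames(data))) {
      stop("matrix input must carry sample ids as row names", call. = FALSE)
    }
    data <- tibble::as_tibble(data, rownames = "sample_id")
  }
  data <- tibble::as_tibble(data)
  if (!"sample_id" %in% names(data)) {
    stop("abundance data must have a 'sample_id' column", call. = FALSE)
  }
  data <- dplyr::relocate(data, "sample_id")
  data$sample_id <- as.character(data$sample_id)
  if (anyDuplicated(data$sample_id)) {
    dup <- unique(data$sample_id[duplicated(data$sample_id)])
    stop("duplicate sample_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  taxa <- setdiff(names(data), "sample_id")
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon columns", call. = FALSE)
  }
  for (tx in taxa) {
    v <- data[[tx]]
    if (!is.numeric(v)) {
      stop("taxon column '", tx, "' is not numeric", call. = FALSE)
    }
    if (anyNA(v) || any(v < 0)) {
      stop("taxon column '", tx, "' has missing or negative abundance",
           call. = FALSE)
    }
  }
  structure(
    data,
    semantics = semantics,
    material = material,
    class = c("gc_abundance", class(tibble::tibble()))
  )
}

#' @export
print.gc_abundance <- function(x, ...) {
  cat(sprintf("# Abundance matrix: %d samples x %d taxa [%s, %s]\n",
              nrow(x), ncol(x) - 1L, amx_semantics(x), amx_material(x)))
  NextMethod()
}

#' Abundance matrix accessors
#'
#' Small helpers used throughout the pipeline: sample ids, taxon ids, the
#' numeric value matrix (samples x taxa, with dimnames), and the two
#' interpretation flags.
#'
#' @param x A `gc_abundance` object.
#' @return A character vector, numeric matrix, or single string.
#' @export
amx_samples <- function(x) x$sample_id

#' @rdname amx_samples
#' @export
amx_taxa <- function(x) setdiff(names(x), "sample_id")

#' @rdname amx_samples
#' @export
amx_values <- function(x) {
  taxa <- amx_taxa(x)
  m <- as.matrix(x[, taxa, drop = FALSE])
  rownames(m) <- x$sample_id
  storage.mode(m) <- "double"
  m
}

#' @rdname amx_samples
#' @export
amx_semantics <- function(x) attr(x, "semantics", exact = TRUE)

#' @rdname amx_samples
#' @export
amx_material <- function(x) attr(x, "material", exact = TRUE)

#' Write / read an abundance matrix as TSV
#'
#' Matrices are written with sample rows and taxon columns. Integer-valued
#' (read-count) matrices round-trip bit exactly; real-valued score matrices
#' round-trip to at least 12 significant digits.
#'
#' @param x A `gc_abundance` object.
#' @param path File path.
#' @return `write_abundance` returns `x` invisibly; `read_abundance`
#'   returns a `gc_abundance`.
#' @export
write_abundance <- function(x, path) {
  df <- tibble::as_tibble(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  readr::write_tsv(df, path)
  invisible(x)
}

#' @rdname write_abundance
#' @param semantics,material Interpretation flags, as in
#'   [abundance_matrix()].
#' @export
read_abundance <- function(path, semantics = c("score", "unambiguous_reads"),
                           material = c("tumor", "blood")) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample_id = readr::col_character(),
                          .default = readr::col_double()
                        ))
  abundance_matrix(df, semantics = semantics, material = material)
}
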