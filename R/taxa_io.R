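#' Read a PathSeq-style taxon table
#'
#' Reads one sample's tab-separated taxon table in the shape of GATK
#' PathSeq score output and returns the species/genus-rank taxonomy records
#' together with a per-taxon abundance vector. Rows at other ranks
#' (superkingdom, family, ...) are dropped. The abundance column is chosen
#' by `semantics`: the PathSeq "score" (score-weighted read mass) or the
#' unambiguously mapped read count.
#'
#' The column dialect is configurable because PathSeq headers vary between
#' runs; `col_map` maps the logical fields to the file's column names. The
#' default mirrors PathSeq score-file headers.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param semantics `"score"` or `"unambiguous_reads"`.
#' @param col_map Named character vector mapping logical fields
#'   (`taxon_id`, `name`, `rank`, `lineage`, `genome_size_bp`, `score`,
#'   `unambiguous_reads`) to file column names. `lineage` is optional.
#' @return A list with `taxonomy` (a tibble with columns `taxon_id`,
#'   `name`, `rank`, `genus_name`, `genome_size_bp`) and `abundance`
#'   (a named numeric vector keyed by `taxon_id`).
#' @export
read_pathseq_table <- function(path,
                               semantics = c("score", "unambiguous_reads"),
                               col_map = pathseq_col_map()) {
  semantics <- match.arg(semantics)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  required <- c("taxon_id", "name", "rank", "genome_size_bp", "score",
                "unambiguous_reads")
  for (field in required) {
    col <- col_map[[field]]
    if (is.null(col) || !col %in% names(df)) {
      stop("format error: required column '", col_map[[field]] %||% field,
           "' (", field, ") missing from ", path, call. = FALSE)
    }
  }
  has_lineage <- !is.null(col_map[["lineage"]]) &&
    col_map[["lineage"]] %in% names(df)

  rank <- tolower(df[[col_map[["rank"]]]])
  keep <- rank %in% c("species", "genus")
  df <- df[keep, , drop = FALSE]
  rank <- rank[keep]

  abcol <- if (semantics == "score") col_map[["score"]] else
    col_map[["unambiguous_reads"]]
  abundance <- suppressWarnings(as.numeric(df[[abcol]]))
  if (anyNA(abundance)) {
    stop("validation error: non-numeric abundance in column '", abcol,
         "', row(s) ", paste(which(is.na(abundance)), collapse = ", "),
         call. = FALSE)
  }
  if (any(abundance < 0)) {
    stop("validation error: negative abundance in row(s) ",
         paste(which(abundance < 0), collapse = ", "), call. = FALSE)
  }
  genome <- suppressWarnings(as.numeric(df[[col_map[["genome_size_bp"]]]]))
  if (anyNA(genome) || any(genome <= 0)) {
    stop("validation error: genome size must be a positive number",
         call. = FALSE)
  }

  name <- df[[col_map[["name"]]]]
  genus_name <- character(nrow(df))
  genus_name[rank == "genus"] <- name[rank == "genus"]
  if (any(rank == "species")) {
    sp <- which(rank == "species")
    if (has_lineage) {
      # PathSeq lineage is pipe-separated root..taxon; the parent genus is
      # the second-to-last element.
      parts <- strsplit(df[[col_map[["lineage"]]]][sp], "|", fixed = TRUE)
      genus_name[sp] <- vapply(parts, function(p) {
        if (length(p) >= 2) p[length(p) - 1L] else NA_character_
      }, character(1))
    }
    # fall back to the binomial's first word
    miss <- sp[is.na(genus_name[sp]) | genus_name[sp] == ""]
    genus_name[miss] <- vapply(strsplit(name[miss], "\\s+"), `[`, character(1), 1L)
  }

  taxonomy <- tibble::tibble(
    taxon_id = as.character(df[[col_map[["taxon_id"]]]]),
    name = name,
    rank = rank,
    genus_name = genus_name,
    genome_size_bp = genome
  )
  list(taxonomy = taxonomy,
       abundance = stats::setNames(abundance, taxonomy$taxon_id))
}

#' @rdname read_pathseq_table
#' @export
pathseq_col_map <- function() {
  c(taxon_id = "tax_id", name = "name", rank = "type", lineage = "taxonomy",
    genome_size_bp = "reference_length", score = "score",
    unambiguous_reads = "unambiguous")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble per-sample abundance maps into one matrix
#'
#' Takes the per-sample abundance vectors returned by
#' [read_pathseq_table()] and builds a samples-by-taxa abundance matrix
#' over the union of taxa; a taxon absent from a sample gets 0.
#'
#' @param maps A named list of named numeric vectors, one per sample; list
#'   names are sample ids.
#' @param material,semantics Interpretation flags, as in
#'   [abundance_matrix()].
#' @return A `gc_abundance` tibble.
#' @export
assemble_matrix <- function(maps, material = c("tumor", "blood"),
                            semantics = c("score", "unambiguous_reads")) {
  material <- match.arg(material)
  semantics <- match.arg(semantics)
  if (length(maps) < 1) stop("need at least one sample", call. = FALSE)
  ids <- names(maps)
  if (is.null(ids) || any(ids == "")) {
    stop("maps must be a named list of samples", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  taxa <- unique(unlist(lapply(maps, names), use.names = FALSE))
  m <- matrix(0, nrow = length(ids), ncol = length(taxa),
              dimnames = list(ids, taxa))
  for (s in ids) {
    v <- maps[[s]]
    if (length(v)) m[s, names(v)] <- unname(v)
  }
  abundance_matrix(m, semantics = semantics, material = material)
}

#' Aggregate a species-level matrix to genus level
#'
#' Genus abundance is the sum of the abundances of its member species, so
#' genus tables stay consistent with the decontaminated species table.
#' Column totals are conserved.
#'
#' @param x A species-level `gc_abundance` matrix.
#' @param taxonomy Taxonomy tibble as returned by [read_pathseq_table()],
#'   giving each species' parent `genus_name`.
#' @return A genus-level `gc_abundance` matrix (columns named by genus).
#' @export
aggregate_to_genus <- function(x, taxonomy) {
  taxa <- amx_taxa(x)
  tax <- taxonomy[match(taxa, taxonomy$taxon_id), , drop = FALSE]
  if (any(is.na(tax$taxon_id))) {
    stop("taxa missing from taxonomy: ",
         paste(taxa[is.na(tax$taxon_id)], collapse = ", "), call. = FALSE)
  }
  if (any(tax$rank != "species")) {
    stop("aggregate_to_genus expects a species-rank matrix", call. = FALSE)
  }
  orphan <- taxa[is.na(tax$genus_name) | tax$genus_name == ""]
  if (length(orphan)) {
    stop("species with unknown genus: ", paste(orphan, collapse = ", "),
         call. = FALSE)
  }
  m <- amx_values(x)
  g <- t(rowsum(t(m), group = tax$genus_name))
  abundance_matrix(g, semantics = amx_semantics(x),
                   material = amx_material(x))
}

gc_enum_levels <- list(
  cohort = c("A", "B"),
  sex = c("female", "male"),
  location = c("cardia", "non_cardia"),
  geography = c("asia", "not_asia"),
  pT = c("1", "2", "3", "4"),
  pN = c("0", "1", "2", "3"),
  histology = c("diffuse", "intestinal", "mixed", "mucinous"),
  msi_status = c("MSI", "MSS")
)

#' Read a sample metadata table
#'
#' Reads the tab-separated per-sample clinical/molecular covariate table.
#' Enumerated columns are validated against their allowed levels; blank
#' cells become explicit `NA` (missingness is never coded as a sentinel
#' value). Numeric covariates are range-checked.
#'
#' Expected columns (all optional except `sample_id`): `cohort` (A/B),
#' `age`, `sex` (female/male), `location` (cardia/non_cardia), `geography`
#' (asia/not_asia), `pT` (1-4), `pN` (0-3), `histology`
#' (diffuse/intestinal/mixed/mucinous), `msi_status` (MSI/MSS),
#' `scv_per_mb`, `ebv_per_human_cell`, `ploidy`, `purity`, `human_reads`.
#'
#' @param path Path to a TSV file with a header row.
#' @return A tibble with validated covariates.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA"),
                        col_types = readr::cols(.default = readr::col_character()))
  if (!"sample_id" %in% names(df)) {
    stop("metadata must have a 'sample_id' column", call. = FALSE)
  }
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param metadata A data frame of raw metadata to validate and coerce.
#' @export
validate_metadata <- function(metadata) {
  df <- tibble::as_tibble(metadata)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  for (col in intersect(names(gc_enum_levels), names(df))) {
    v <- as.character(df[[col]])
    levels <- gc_enum_levels[[col]]
    bad <- which(!is.na(v) & !v %in% levels)
    if (length(bad)) {
      stop("validation error: column '", col, "', row ", bad[1],
           ": value '", v[bad[1]], "' not one of {",
           paste(levels, collapse = ", "), "}", call. = FALSE)
    }
    df[[col]] <- factor(v, levels = levels)
  }
  num_cols <- c(age = 0, scv_per_mb = 0, ebv_per_human_cell = 0,
                ploidy = 1e-9, human_reads = 1)
  for (col in intersect(names(num_cols), names(df))) {
    v <- suppressWarnings(as.numeric(as.character(df[[col]])))
    bad <- which(!is.na(df[[col]]) & (is.na(v) | v < num_cols[[col]]))
    if (length(bad)) {
      stop("validation error: column '", col, "', row ", bad[1],
           ": value out of range", call. = FALSE)
    }
    df[[col]] <- v
  }
  if ("purity" %in% names(df)) {
    v <- suppressWarnings(as.numeric(as.character(df$purity)))
    bad <- which(!is.na(df$purity) & (is.na(v) | v < 0 | v > 1))
    if (length(bad)) {
      stop("validation error: column 'purity', row ", bad[1],
           ": must be in [0, 1]", call. = FALSE)
    }
    df$purity <- v
  }
  df
}

#' Write a tibble report as TSV and JSON side by side
#'
#' Every pipeline report is emitted in both formats: TSV for spreadsheet
#' use, JSON for machine consumption.
#'
#' @param x A data frame.
#' @param path_base File path without extension; `.tsv` and `.json` are
#'   appended.
#' @return `x`, invisibly.
#' @export
write_report <- function(x, path_base) {
  readr::write_tsv(tibble::as_tibble(x), paste0(path_base, ".tsv"))
  jsonlite::write_json(x, paste0(path_base, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(x)
}
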