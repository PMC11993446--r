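#' Harmonise raw microsatellite-instability labels
#'
#' Collapses the three-level assay labels to the two-level analysis
#' labels: MSI-high stays MSI; MSI-low is grouped with microsatellite
#' stable.
#'
#' @param raw_label Character vector with values in
#'   `{MSI-H, MSI-L, MSS}`.
#' @return Factor with levels `MSI`, `MSS`.
#' @export
harmonize_msi_labels <- function(raw_label) {
  out <- dplyr::case_when(
    raw_label == "MSI-H" ~ "MSI",
    raw_label %in% c("MSI-L", "MSS") ~ "MSS",
    TRUE ~ NA_character_
  )
  bad <- which(!is.na(raw_label) & is.na(out))
  if (length(bad)) {
    stop("unknown MSI label: ", paste(unique(raw_label[bad]), collapse = ", "),
         call. = FALSE)
  }
  factor(out, levels = c("MSI", "MSS"))
}

#' Infer MSI status from mutation burden
#'
#' Samples with at least `threshold` somatic coding variants per megabase
#' are inferred MSI (the boundary is inclusive); below the threshold,
#' MSS. Missing burden yields a missing call.
#'
#' @param scv_per_mb Somatic coding variants per Mb (nonnegative).
#' @param threshold Burden threshold (default 20 mut/Mb).
#' @return Factor with levels `MSI`, `MSS` (NA where burden is missing).
#' @export
infer_msi <- function(scv_per_mb, threshold = 20) {
  if (any(scv_per_mb < 0, na.rm = TRUE)) {
    stop("scv_per_mb must be nonnegative", call. = FALSE)
  }
  factor(ifelse(is.na(scv_per_mb), NA_character_,
                ifelse(scv_per_mb >= threshold, "MSI", "MSS")),
         levels = c("MSI", "MSS"))
}

#' Infer TCGA molecular subtype
#'
#' Bass-style decision hierarchy on three thresholds: EBV load at least
#' `ebv` virions per human cell classifies EBV; otherwise a mutation
#' burden at least `scv` mut/Mb classifies MSI; otherwise ploidy strictly
#' above `ploidy` classifies chromosomal instability (CIN); the remainder
#' is genomically stable (GS). EBV and SCV boundaries are inclusive; the
#' ploidy boundary is exclusive (ploidy exactly 2.5 is GS).
#'
#' @param ebv_per_human_cell EBV load (virions per human cell).
#' @param scv_per_mb Somatic coding variants per Mb.
#' @param ploidy Tumor DNA ploidy.
#' @param thresholds Named list or vector with `ebv` (default 1e-3),
#'   `scv` (default 20) and `ploidy` (default 2.5).
#' @return Character vector with values in `{EBV, MSI, CIN, GS}`; `NA`
#'   where a required input is missing (attribute `missing_field` names
#'   the first missing input per sample).
#' @export
infer_tcga_subtype <- function(ebv_per_human_cell, scv_per_mb, ploidy,
                               thresholds = list(ebv = 1e-3, scv = 20,
                                                 ploidy = 2.5)) {
  n <- max(length(ebv_per_human_cell), length(scv_per_mb), length(ploidy))
  ebv <- rep_len(ebv_per_human_cell, n)
  scv <- rep_len(scv_per_mb, n)
  pl <- rep_len(ploidy, n)
  missing_field <- dplyr::case_when(
    is.na(ebv) ~ "ebv_per_human_cell",
    is.na(scv) ~ "scv_per_mb",
    is.na(pl) ~ "ploidy",
    TRUE ~ NA_character_
  )
  out <- dplyr::case_when(
    !is.na(missing_field) ~ NA_character_,
    ebv >= thresholds$ebv ~ "EBV",
    scv >= thresholds$scv ~ "MSI",
    pl > thresholds$ploidy ~ "CIN",
    TRUE ~ "GS"
  )
  structure(out, missing_field = missing_field)
}

#' Molecular calls for a cohort
#'
#' Applies [infer_msi()] and [infer_tcga_subtype()] to a metadata table.
#' When a measured `msi_status` is present it is used as-is (`inferred =
#' FALSE`); otherwise the call is inferred from mutation burden.
#'
#' @param metadata Metadata tibble with `sample_id`, `scv_per_mb`,
#'   `ebv_per_human_cell`, `ploidy` and optionally `msi_status`.
#' @param thresholds As in [infer_tcga_subtype()].
#' @param use_measured_msi Prefer a measured `msi_status` column when
#'   present (default TRUE).
#' @return A tibble of class `gc_subtype_calls`: `sample_id`, `msi_call`,
#'   `subtype_call`, the inputs used, `inferred`, `missing_field`.
#' @export
call_molecular_subtypes <- function(metadata,
                                    thresholds = list(ebv = 1e-3, scv = 20,
                                                      ploidy = 2.5),
                                    use_measured_msi = TRUE) {
  md <- metadata
  inferred_msi <- infer_msi(md$scv_per_mb, thresholds$scv)
  measured <- use_measured_msi && "msi_status" %in% names(md)
  msi_call <- if (measured) {
    factor(ifelse(is.na(md$msi_status), as.character(inferred_msi),
                  as.character(md$msi_status)), levels = c("MSI", "MSS"))
  } else inferred_msi
  sub <- infer_tcga_subtype(md$ebv_per_human_cell, md$scv_per_mb, md$ploidy,
                            thresholds)
  out <- tibble::tibble(
    sample_id = md$sample_id,
    msi_call = msi_call,
    subtype_call = as.character(sub),
    scv_per_mb = md$scv_per_mb,
    ebv_per_human_cell = md$ebv_per_human_cell,
    ploidy = md$ploidy,
    inferred = if (measured) is.na(md$msi_status) else TRUE,
    missing_field = attr(sub, "missing_field", exact = TRUE)
  )
  class(out) <- c("gc_subtype_calls", class(out))
  out
}
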