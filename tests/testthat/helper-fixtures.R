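# Shared fixture builders: everything is generated in code at test time.

# A tiny PathSeq-style score file with configurable rows.
write_pathseq_fixture <- function(path, rows = NULL) {
  if (is.null(rows)) {
    rows <- data.frame(
      tax_id = c("562", "561", "2"),
      taxonomy = c("root|Bacteria|Escherichia|Escherichia coli",
                   "root|Bacteria|Escherichia",
                   "root|Bacteria"),
      type = c("species", "genus", "superkingdom"),
      name = c("Escherichia coli", "Escherichia", "Bacteria"),
      reference_length = c(4641652, 4641652, 1),
      score = c(120.5, 130.25, 500),
      unambiguous = c(100, 110, 400),
      stringsAsFactors = FALSE
    )
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# Small abundance matrix from an explicit value matrix.
toy_amx <- function(values, semantics = "unambiguous_reads",
                    material = "tumor") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("sp%02d", seq_len(ncol(values)))
  }
  abundance_matrix(values, semantics = semantics, material = material)
}

# Brute-force one-sided Fisher p by enumerating all 2x2 tables with the
# observed margins (independent of phyper).
fisher_oracle <- function(tp, ta, bp, ba) {
  tt <- tp + ta; bt <- bp + ba; k <- tp + bp
  xs <- max(0, k - bt):min(k, tt)
  probs <- choose(tt, xs) * choose(bt, k - xs) / choose(tt + bt, k)
  sum(probs[xs >= tp])
}

# Small metadata table for association/diversity tests.
toy_metadata <- function(n, seed = 1) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  withr_seed(tibble::tibble(
    sample_id = sprintf("s%02d", seq_len(n)),
    group = factor(sample(c("a", "b"), n, TRUE)),
    age = rnorm(n, 65, 9)
  ))
}
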