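# Shared fixtures and independent oracles. Fixtures are built in code; the
# oracles are deliberately naive (pairwise counting, direct interval checks)
# so they stay independent of the implementation they verify.

make_em <- function(values, dataset_id = "fix", species = "human",
                    probes = NULL, samples = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- probes %||% sprintf("p%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- samples %||% sprintf("s%d", seq_len(ncol(values)))
  }
  expression_matrix(values, dataset_id, species)
}

make_ann <- function(probe_id, gene_symbol, accession = NULL,
                     is_control = FALSE) {
  if (is.null(accession)) accession <- sprintf("NM_%06d", seq_along(probe_id))
  ann <- data.frame(probe_id = probe_id,
                    gene_symbol = normalize_symbol(gene_symbol),
                    transcript_accession = accession,
                    is_control = rep_len(is_control, length(probe_id)),
                    stringsAsFactors = FALSE)
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

# Binned dataset built directly from percentiles (mean_log2 follows the
# percentile so ranks stay consistent); for comparison-stage tests that do
# not need the normalization pipeline.
make_binned <- function(symbols, percentiles, dataset_id = "fix",
                        species = "human", curated = TRUE,
                        dropped = character(0), cutoffs = c(10, 50, 90)) {
  genes <- data.frame(
    gene_symbol = normalize_symbol(symbols),
    mean_log2 = 4 + percentiles / 10,
    percentile = percentiles,
    bin = assign_bins(percentiles, cutoffs),
    n_probes = 1L,
    has_curated_accession = rep_len(curated, length(symbols)),
    stringsAsFactors = FALSE
  )
  binned_dataset(dataset_id, species, genes, dropped, cutoffs)
}

# Brute-force pairwise-count percentile oracle.
oracle_percentile <- function(x) {
  vapply(x, function(v) 100 * sum(x < v) / length(x), numeric(1))
}

# Direct interval-check bin oracle.
oracle_bin <- function(p) {
  vapply(p, function(pi) {
    if (pi >= 90) "H" else if (pi >= 50) "M" else if (pi >= 10) "L" else "VL"
  }, character(1))
}

# Sorted non-missing column values all equal across samples?
identical_column_multisets <- function(X, tol = 1e-9) {
  sorted <- apply(X, 2, function(x) sort(x[!is.na(x)]))
  if (is.list(sorted)) return(FALSE)  # unequal lengths
  all(apply(sorted, 1, function(r) max(r) - min(r)) <= tol)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

quiet_bin <- function(...) suppressWarnings(bin_dataset(...))
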