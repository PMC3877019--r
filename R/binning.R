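# Percentile ranking, four-category binning, duplicate-probe collapsing and
# the binned_dataset container. This is the core of the rank-based
# cross-species comparison: within each dataset only ranks matter, which
# makes datasets from different platforms and species comparable despite
# probe-affinity differences.

#' Percentile ranks from strict-lower counts
#'
#' `percentile(g) = 100 * (# values strictly below g) / N`. Ties share a
#' percentile; values lie in `[0, 100)`. With N distinct values the lowest
#' gets 0 and the highest `100 * (N - 1) / N`, so exactly 10% of a tie-free
#' dataset sits at or above the 90th percentile.
#'
#' @param x numeric vector of (finite) per-gene mean expression values,
#'   optionally named.
#' @param warn_small warn when fewer than this many values are ranked
#'   (default 100); set to 0 to silence.
#' @return numeric vector of percentiles in `[0, 100)`, names preserved.
#' @export
percentile_rank <- function(x, warn_small = 100L) {
  if (length(x) == 0L) stop("cannot rank an empty vector")
  if (any(!is.finite(x))) stop("percentile_rank requires finite values")
  if (length(x) < warn_small) {
    warning("ranking only ", length(x), " values; percentiles are coarse",
            call. = FALSE)
  }
  # rank(ties = "min") - 1 equals the strict-lower count
  100 * (rank(x, ties.method = "min") - 1) / length(x)
}

#' Assign expression bins from percentiles
#'
#' Half-open intervals closed at the lower edge: `H` for `p >= 90`, `M` for
#' `50 <= p < 90`, `L` for `10 <= p < 50`, `VL` for `p < 10` (default
#' cut-offs). Together with the strict-lower-count percentile definition, a
#' gene exactly at the 90th percentile is in the top 10% and therefore `H`.
#'
#' @param p numeric vector of percentiles in `[0, 100)`.
#' @param cutoffs increasing vector of three cut-offs in (0, 100), default
#'   `c(10, 50, 90)`.
#' @return ordered factor with levels `VL < L < M < H`, names preserved.
#' @export
assign_bins <- function(p, cutoffs = c(10, 50, 90)) {
  check_cutoffs(cutoffs)
  if (any(p < 0 | p >= 100, na.rm = TRUE)) {
    stop("percentiles must lie in [0, 100)")
  }
  idx <- findInterval(p, cutoffs) + 1L  # 1..4
  out <- bin_factor(BIN_LEVELS[idx])
  names(out) <- names(p)
  out
}

check_cutoffs <- function(cutoffs) {
  if (length(cutoffs) != 3L || any(!is.finite(cutoffs)) ||
      any(diff(cutoffs) <= 0) || cutoffs[1L] <= 0 || cutoffs[3L] >= 100) {
    stop("cutoffs must be three strictly increasing values in (0, 100)")
  }
  invisible(cutoffs)
}

#' Collapse probe-level means to gene level with a consistency filter
#'
#' Control probes and probes without a gene symbol are excluded first.
#' Provisional probe-level bins are computed over all retained probe means;
#' a gene whose probes' provisional bins span more than one adjacent category
#' (e.g. `H` together with `L`) has inconsistent hybridization signals and is
#' moved to the dropped set. Otherwise the gene mean is the mean of its
#' probes' means. A gene carries a curated accession if at least one of its
#' probes has an `NM_` RefSeq accession.
#'
#' @param means named numeric vector of per-probe means (names are probe ids).
#' @param ann a `probe_annotation` data frame covering every probe in `means`.
#' @param cutoffs bin cut-offs for the provisional bins (default 10/50/90).
#' @return list with `genes` (data frame: `gene_symbol`, `mean_log2`,
#'   `n_probes`, `has_curated_accession`) and `dropped_inconsistent`
#'   (sorted character vector of gene symbols).
#' @export
collapse_probes <- function(means, ann, cutoffs = c(10, 50, 90)) {
  stopifnot(is.numeric(means), !is.null(names(means)))
  missing <- setdiff(names(means), ann$probe_id)
  if (length(missing) > 0L) {
    stop("probe(s) missing from annotation: ",
         paste(utils::head(missing, 5L), collapse = ", "),
         if (length(missing) > 5L) ", ...")
  }
  info <- ann[match(names(means), ann$probe_id), , drop = FALSE]
  keep <- !info$is_control & nzchar(info$gene_symbol)
  means <- means[keep]
  info <- info[keep, , drop = FALSE]
  if (length(means) == 0L) stop("no annotated non-control probes to collapse")

  prov_bin_idx <- as.integer(assign_bins(
    percentile_rank(means, warn_small = 0L), cutoffs))
  curated <- is_curated_accession(info$transcript_accession)

  sym <- info$gene_symbol
  gene_mean <- tapply(means, sym, mean)
  gene_span <- tapply(prov_bin_idx, sym, function(b) max(b) - min(b))
  gene_n <- tapply(means, sym, length)
  gene_cur <- tapply(curated, sym, any)

  inconsistent <- gene_span > 1L
  genes <- data.frame(
    gene_symbol = names(gene_mean)[!inconsistent],
    mean_log2 = unname(gene_mean[!inconsistent]),
    n_probes = as.integer(unname(gene_n[!inconsistent])),
    has_curated_accession = unname(gene_cur[!inconsistent]),
    stringsAsFactors = FALSE
  )
  genes <- genes[order(genes$gene_symbol), , drop = FALSE]
  rownames(genes) <- NULL
  list(genes = genes,
       dropped_inconsistent = sort(names(gene_mean)[inconsistent]))
}

empty_gene_table <- function() {
  data.frame(gene_symbol = character(0L), mean_log2 = numeric(0L),
              percentile = numeric(0L), bin = bin_factor(character(0L)),
              n_probes = integer(0L), has_curated_accession = logical(0L),
              stringsAsFactors = FALSE)
}

#' Construct a binned dataset
#'
#' Validates the container invariants: unique gene symbols, bins consistent
#' with percentiles under the stored cut-offs, and no symbol both retained
#' and dropped as inconsistent.
#'
#' @param dataset_id,species labels.
#' @param genes data frame with columns `gene_symbol`, `mean_log2`,
#'   `percentile`, `bin`, `n_probes`, `has_curated_accession`.
#' @param dropped_inconsistent character vector of gene symbols removed by
#'   the duplicate-consistency filter.
#' @param cutoffs the bin cut-offs the dataset was binned with.
#' @param stats optional named list of pipeline statistics (probe counts etc.).
#' @return object of class `binned_dataset`.
#' @export
binned_dataset <- function(dataset_id, species, genes, dropped_inconsistent,
                           cutoffs = c(10, 50, 90), stats = NULL) {
  check_cutoffs(cutoffs)
  need <- c("gene_symbol", "mean_log2", "percentile", "bin", "n_probes",
            "has_curated_accession")
  if (!all(need %in% colnames(genes))) {
    stop("genes table must have columns ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(genes$gene_symbol)) stop("duplicate gene symbols")
  genes$bin <- bin_factor(genes$bin)
  expected <- assign_bins(genes$percentile, cutoffs)
  if (!identical(as.character(expected), as.character(genes$bin))) {
    stop("bins inconsistent with percentiles under cutoffs ",
         paste(cutoffs, collapse = "/"))
  }
  overlap <- intersect(genes$gene_symbol, dropped_inconsistent)
  if (length(overlap) > 0L) {
    stop("symbol(s) both retained and dropped: ",
         paste(overlap, collapse = ", "))
  }
  structure(
    list(dataset_id = as.character(dataset_id),
         species = as.character(species),
         genes = genes,
         dropped_inconsistent = sort(as.character(dropped_inconsistent)),
         cutoffs = as.numeric(cutoffs),
         stats = stats),
    class = "binned_dataset"
  )
}

#' @export
print.binned_dataset <- function(x, ...) {
  cat(sprintf("<binned_dataset> %s (%s): %d genes, %d dropped inconsistent\n",
              x$dataset_id, x$species, nrow(x$genes),
              length(x$dropped_inconsistent)))
  print(bin_counts(x))
  invisible(x)
}

#' Bin counts of a binned dataset
#' @param binned a `binned_dataset`.
#' @return named integer vector of gene counts per bin (VL, L, M, H).
#' @export
bin_counts <- function(binned) {
  stopifnot(inherits(binned, "binned_dataset"))
  table(binned$genes$bin)
}

#' Run the full within-dataset pipeline: normalize, average, collapse, bin
#'
#' Applies [quantile_normalize()], [average_replicates()],
#' [collapse_probes()], then recomputes [percentile_rank()] and
#' [assign_bins()] on the collapsed gene-level means. Ranking happens on
#' replicate-averaged, gene-collapsed means so the result is deterministic
#' and independent of probe order.
#'
#' The `stats` element of the result records both probe-level and gene-level
#' counts (total probes, retained annotated probes, probe-level high-bin
#' count, gene counts per bin, dropped genes), since probe- and gene-level
#' high counts can differ substantially on real arrays.
#'
#' @param m an [expression_matrix()].
#' @param ann a `probe_annotation` table covering the matrix's probes.
#' @param cutoffs bin cut-offs, default `c(10, 50, 90)`.
#' @return a `binned_dataset`.
#' @export
bin_dataset <- function(m, ann, cutoffs = c(10, 50, 90)) {
  check_cutoffs(cutoffs)
  norm <- quantile_normalize(m)
  means <- average_replicates(norm)
  collapsed <- collapse_probes(means, ann, cutoffs)

  g <- collapsed$genes
  if (nrow(g) == 0L) stop("no genes left after collapsing")
  pct <- percentile_rank(stats::setNames(g$mean_log2, g$gene_symbol))
  bins <- assign_bins(pct, cutoffs)
  genes <- data.frame(
    gene_symbol = g$gene_symbol,
    mean_log2 = g$mean_log2,
    percentile = unname(pct),
    bin = unname(bins),
    n_probes = g$n_probes,
    has_curated_accession = g$has_curated_accession,
    stringsAsFactors = FALSE
  )

  # probe-level provisional high count, for side-by-side reporting
  info <- ann[match(names(means), ann$probe_id), , drop = FALSE]
  retained <- !info$is_control & nzchar(info$gene_symbol)
  probe_bins <- assign_bins(
    percentile_rank(means[retained], warn_small = 0L), cutoffs)

  stats <- list(
    n_probes_input = nrow(m$values),
    n_probes_retained = sum(retained),
    n_probe_high = sum(probe_bins == "H"),
    n_genes = nrow(genes),
    n_gene_high = sum(genes$bin == "H"),
    n_dropped_inconsistent = length(collapsed$dropped_inconsistent)
  )
  binned_dataset(m$dataset_id, m$species, genes,
                 collapsed$dropped_inconsistent, cutoffs, stats)
}
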