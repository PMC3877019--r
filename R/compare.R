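# Cross-dataset operations: ortholog matching by gene symbol, extreme-bin
# selection, species-specific gene calling, high-bin concordance and
# gene-set bin profiles.

#' Match orthologs between two binned datasets by gene symbol
#'
#' One row per symbol present (after uppercasing) in both datasets; symbols
#' found in only one dataset or present in either dataset's
#' dropped-inconsistent set are excluded. Symbol-identity matching is the
#' deliberate ortholog rule here: human and mouse nomenclature for
#' one-to-one orthologs differs essentially by case.
#'
#' @param a,b `binned_dataset` objects, typically from different species.
#' @return a data frame of class `ortholog_pairs` with columns
#'   `gene_symbol`, `bin_a`, `bin_b`, `percentile_a`, `percentile_b`,
#'   `curated_a`, `curated_b`, sorted by symbol. Dataset ids and species are
#'   attached as attributes `dataset_a`, `dataset_b`, `species_a`,
#'   `species_b`.
#' @export
match_orthologs <- function(a, b) {
  stopifnot(inherits(a, "binned_dataset"), inherits(b, "binned_dataset"))
  syms <- intersect(a$genes$gene_symbol, b$genes$gene_symbol)
  syms <- setdiff(syms, union(a$dropped_inconsistent, b$dropped_inconsistent))
  syms <- sort(syms)
  ia <- match(syms, a$genes$gene_symbol)
  ib <- match(syms, b$genes$gene_symbol)
  pairs <- data.frame(
    gene_symbol = syms,
    bin_a = a$genes$bin[ia],
    bin_b = b$genes$bin[ib],
    percentile_a = a$genes$percentile[ia],
    percentile_b = b$genes$percentile[ib],
    curated_a = a$genes$has_curated_accession[ia],
    curated_b = b$genes$has_curated_accession[ib],
    stringsAsFactors = FALSE
  )
  attr(pairs, "dataset_a") <- a$dataset_id
  attr(pairs, "dataset_b") <- b$dataset_id
  attr(pairs, "species_a") <- a$species
  attr(pairs, "species_b") <- b$species
  class(pairs) <- c("ortholog_pairs", "data.frame")
  pairs
}

#' Select ortholog pairs with a given bin combination
#'
#' @param pairs an `ortholog_pairs` data frame from [match_orthologs()].
#' @param bin_a,bin_b requested bins (one of `"VL"`, `"L"`, `"M"`, `"H"`).
#' @return the subset of `pairs` with exactly this bin combination, sorted
#'   by gene symbol.
#' @export
select_cross_bins <- function(pairs, bin_a, bin_b) {
  bin_a <- match.arg(bin_a, BIN_LEVELS)
  bin_b <- match.arg(bin_b, BIN_LEVELS)
  out <- pairs[pairs$bin_a == bin_a & pairs$bin_b == bin_b, , drop = FALSE]
  out <- out[order(out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call species-specific genes from ortholog pairs
#'
#' A gene is specific to `specific_species` when it is in the high bin (`H`)
#' of that species' dataset and the very low bin (`VL`) of the other
#' species' dataset, carries a curated (`NM_`) accession in both species,
#' and survived the duplicate-consistency filter in both (inconsistent
#' genes never enter the pair list).
#'
#' @param pairs an `ortholog_pairs` data frame from [match_orthologs()].
#' @param specific_species species label; must match one of the two source
#'   datasets' species.
#' @return data frame with columns `gene_symbol`, `specific_species`,
#'   `other_species`, `bin_specific` (always `"H"`), `bin_other` (always
#'   `"VL"`), `percentile_specific`, `percentile_other`, in deterministic
#'   symbol order.
#' @export
call_specific_genes <- function(pairs, specific_species) {
  sa <- attr(pairs, "species_a")
  sb <- attr(pairs, "species_b")
  if (identical(specific_species, sa)) {
    sel <- select_cross_bins(pairs, "H", "VL")
    other <- sb
  } else if (identical(specific_species, sb)) {
    sel <- select_cross_bins(pairs, "VL", "H")
    other <- sa
  } else {
    stop("species '", specific_species, "' matches neither dataset (",
         sa, ", ", sb, ")")
  }
  sel <- sel[sel$curated_a & sel$curated_b, , drop = FALSE]
  out <- data.frame(
    gene_symbol = sel$gene_symbol,
    specific_species = rep_len(specific_species, nrow(sel)),
    other_species = rep_len(other, nrow(sel)),
    bin_specific = rep_len("H", nrow(sel)),
    bin_other = rep_len("VL", nrow(sel)),
    percentile_specific = if (identical(specific_species, sa)) sel$percentile_a else sel$percentile_b,
    percentile_other = if (identical(specific_species, sa)) sel$percentile_b else sel$percentile_a,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' High-bin concordance of two same-species datasets
#'
#' Counts how many of the query dataset's high-bin genes are also in the
#' reference dataset's high bin. The percentage is taken over the query's
#' high set and rounded to the nearest integer.
#'
#' @param ref,query `binned_dataset` objects of the same species.
#' @return one-row data frame with columns `ref_dataset`, `query_dataset`,
#'   `n_query_high`, `n_overlap`, `pct_overlap`.
#' @export
concordance <- function(ref, query) {
  stopifnot(inherits(ref, "binned_dataset"), inherits(query, "binned_dataset"))
  if (!identical(ref$species, query$species)) {
    stop("species mismatch: ref is ", ref$species, ", query is ",
         query$species)
  }
  qh <- query$genes$gene_symbol[query$genes$bin == "H"]
  if (length(qh) == 0L) stop("query dataset ", query$dataset_id,
                             " has an empty high bin")
  rh <- ref$genes$gene_symbol[ref$genes$bin == "H"]
  n_overlap <- length(intersect(qh, rh))
  data.frame(
    ref_dataset = ref$dataset_id,
    query_dataset = query$dataset_id,
    n_query_high = length(qh),
    n_overlap = n_overlap,
    pct_overlap = round(100 * n_overlap / length(qh)),
    stringsAsFactors = FALSE
  )
}

#' Bin profile of a gene set across datasets
#'
#' For every gene in the set and every dataset, reports the gene's bin
#' (`"-"` where the gene is absent from that dataset), a per-dataset
#' histogram over the four bins, and the genes whose bins in the two
#' `flag_pair` datasets differ by two or more ordered categories
#' (`VL < L < M < H`). A one-category difference is within the expected
#' cross-platform wobble; two or more marks a candidate expression shift.
#'
#' @param set character vector of gene symbols (uppercased internally), or a
#'   single-element named list as returned by [read_gene_sets()].
#' @param datasets list of `binned_dataset` objects with unique dataset ids.
#' @param flag_pair character vector of two dataset ids to compare for
#'   flagged shifts.
#' @param set_name name of the set (defaults to the list name or "gene_set").
#' @return object of class `gene_set_profile`: list with `set_name`,
#'   `per_gene` (data frame, one bin column per dataset), `histogram`
#'   (4 x n-datasets matrix), `shifts` (data frame with `gene_symbol`,
#'   `bin_1`, `bin_2`, `shift`) and `flagged_shifts` (subset with
#'   `shift >= 2`).
#' @export
gene_set_profile <- function(set, datasets, flag_pair, set_name = NULL) {
  if (is.list(set) && !is.data.frame(set)) {
    if (is.null(set_name)) set_name <- names(set)[1L] %||% "gene_set"
    set <- set[[1L]]
  }
  if (is.null(set_name)) set_name <- "gene_set"
  symbols <- sort(unique(normalize_symbol(set)))
  if (length(symbols) == 0L) stop("empty gene set")
  ids <- vapply(datasets, function(d) d$dataset_id, character(1L))
  if (anyDuplicated(ids)) stop("duplicate dataset ids")
  names(datasets) <- ids
  missing_ids <- setdiff(flag_pair, ids)
  if (length(flag_pair) != 2L || length(missing_ids) > 0L) {
    stop("flag_pair must name two datasets in the list; unknown: ",
         paste(missing_ids, collapse = ", "))
  }

  per_gene <- data.frame(gene_symbol = symbols, stringsAsFactors = FALSE)
  for (id in ids) {
    g <- datasets[[id]]$genes
    bin <- as.character(g$bin[match(symbols, g$gene_symbol)])
    bin[is.na(bin)] <- "-"
    per_gene[[id]] <- bin
  }

  histogram <- vapply(ids, function(id) {
    present <- per_gene[[id]][per_gene[[id]] != "-"]
    as.integer(table(bin_factor(present)))
  }, integer(4L))
  rownames(histogram) <- BIN_LEVELS

  b1 <- per_gene[[flag_pair[1L]]]
  b2 <- per_gene[[flag_pair[2L]]]
  both <- b1 != "-" & b2 != "-"
  shifts <- data.frame(
    gene_symbol = symbols[both],
    bin_1 = b1[both],
    bin_2 = b2[both],
    shift = abs(bin_index(b1[both]) - bin_index(b2[both])),
    stringsAsFactors = FALSE
  )
  structure(
    list(set_name = set_name,
         datasets = ids,
         flag_pair = flag_pair,
         per_gene = per_gene,
         histogram = histogram,
         shifts = shifts,
         flagged_shifts = shifts[shifts$shift >= 2L, , drop = FALSE]),
    class = "gene_set_profile"
  )
}

#' @export
print.gene_set_profile <- function(x, ...) {
  cat(sprintf("<gene_set_profile> %s: %d genes x %d datasets; %d flagged shift(s)\n",
              x$set_name, nrow(x$per_gene), length(x$datasets),
              nrow(x$flagged_shifts)))
  print(x$histogram)
  invisible(x)
}
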