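# The probes x samples container used throughout the pipeline. A thin S3
# wrapper around a numeric matrix with dimnames, plus dataset/species labels.

#' Construct an expression matrix
#'
#' Wraps a log2 intensity matrix (probes in rows, samples in columns) together
#' with a dataset identifier and species label, and validates the container
#' invariants: unique probe and sample ids, at least one sample, all entries
#' finite or `NA`.
#'
#' @param values numeric matrix of log2 intensities with rownames (probe ids)
#'   and colnames (sample ids). Missing values are `NA`.
#' @param dataset_id character scalar identifying the dataset.
#' @param species character scalar, e.g. `"human"` or `"mouse"`.
#' @return an object of class `expression_matrix`: a list with elements
#'   `dataset_id`, `species` and `values`.
#' @examples
#' m <- matrix(rnorm(6, 8), nrow = 3,
#'             dimnames = list(paste0("p", 1:3), c("s1", "s2")))
#' em <- expression_matrix(m, "demo", "human")
#' dim(em$values)
#' @export
expression_matrix <- function(values, dataset_id, species) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must carry probe ids as rownames and sample ids as colnames")
  }
  if (ncol(values) < 1L) stop("expression matrix needs at least one sample")
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate probe id(s): ", paste(dup, collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  }
  if (any(is.infinite(values))) stop("expression values must be finite or NA")
  all_missing <- rowSums(!is.na(values)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " probe(s) have no observed value in any sample",
            call. = FALSE)
  }
  structure(
    list(dataset_id = as.character(dataset_id),
         species = as.character(species),
         values = values),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %s (%s): %d probes x %d samples\n",
              x$dataset_id, x$species, nrow(x$values), ncol(x$values)))
  cat(sprintf("  missing entries: %d\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)
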