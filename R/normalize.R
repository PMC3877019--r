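# Between-array quantile normalization and replicate averaging.

#' Quantile normalize an expression matrix between arrays
#'
#' Forces every sample onto a common reference distribution: the mean of the
#' samples' empirical quantile functions. On a complete matrix each sample's
#' sorted value vector equals the column-wise mean of the input samples'
#' sorted vectors, so after normalization all samples share an identical
#' multiset of values. Within-sample rank order is preserved; tied input
#' values receive the mean of their target quantile values. Missing entries
#' are excluded from the quantile computation and stay missing; samples with
#' unequal numbers of observed values are aligned by linear interpolation of
#' the quantile functions.
#'
#' @param m an [expression_matrix()].
#' @return an [expression_matrix()] of the same shape, normalized.
#' @examples
#' m <- expression_matrix(
#'   matrix(c(1, 2, 3, 2, 4, 6), ncol = 2,
#'          dimnames = list(paste0("p", 1:3), c("s1", "s2"))),
#'   "demo", "human")
#' quantile_normalize(m)$values  # both columns become (1.5, 3, 4.5)
#' @export
quantile_normalize <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  X <- m$values
  n <- nrow(X)
  n_obs <- colSums(!is.na(X))
  if (any(n_obs == 0L)) {
    stop("sample(s) entirely missing: ",
         paste(colnames(X)[n_obs == 0L], collapse = ", "))
  }
  if (ncol(X) == 1L) return(m)

  grid <- (seq_len(n) - 0.5) / n
  Q <- vapply(seq_len(ncol(X)), function(j) {
    x <- sort(X[, j], na.last = NA)
    if (length(x) == n) {
      x
    } else {
      stats::approx((seq_along(x) - 0.5) / length(x), x,
                    xout = grid, rule = 2)$y
    }
  }, numeric(n))
  ref <- rowMeans(Q)

  out <- X
  for (j in seq_len(ncol(X))) {
    idx <- which(!is.na(X[, j]))
    x <- X[idx, j]
    nj <- length(x)
    target <- if (nj == n) {
      ref
    } else {
      stats::approx(grid, ref, xout = (seq_len(nj) - 0.5) / nj, rule = 2)$y
    }
    res <- numeric(nj)
    res[order(x)] <- target
    # tied inputs share the mean of their target quantile values
    res <- stats::ave(res, match(x, x), FUN = mean)
    out[idx, j] <- res
  }
  expression_matrix(out, m$dataset_id, m$species)
}

#' Average replicate arrays into one value per probe
#'
#' Arithmetic mean over non-missing samples for each probe. Probes with no
#' observed value in any sample are dropped with a warning.
#'
#' @param m an [expression_matrix()], typically quantile normalized.
#' @return named numeric vector of per-probe mean log2 values.
#' @export
average_replicates <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  n_obs <- rowSums(!is.na(m$values))
  if (any(n_obs == 0L)) {
    warning("dropping ", sum(n_obs == 0L),
            " probe(s) with no observed value in any sample", call. = FALSE)
  }
  keep <- n_obs > 0L
  rowMeans(m$values[keep, , drop = FALSE], na.rm = TRUE)
}
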