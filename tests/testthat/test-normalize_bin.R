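# Normalization, replicate averaging, probe collapsing, percentile ranking
# and bin assignment.

test_that("quantile normalization matches the hand oracle and fixed points", {
  m <- make_em(matrix(c(1, 2, 3, 2, 4, 6), ncol = 2))
  out <- quantile_normalize(m)$values
  expect_equal(unname(out[, 1]), c(1.5, 3, 4.5))
  expect_equal(unname(out[, 2]), c(1.5, 3, 4.5))

  # two identical columns: already normalized
  m2 <- make_em(matrix(c(5, 1, 3, 5, 1, 3), ncol = 2))
  expect_equal(quantile_normalize(m2)$values, m2$values)

  # single sample: mean of one sorted vector is itself
  m3 <- make_em(matrix(c(9, 2, 7), ncol = 1))
  expect_identical(quantile_normalize(m3)$values, m3$values)
})

test_that("quantile normalization equalizes value multisets and keeps ranks", {
  set.seed(11)
  X <- matrix(rnorm(500 * 5, 8, 2), ncol = 5,
              dimnames = list(sprintf("p%03d", 1:500), sprintf("s%d", 1:5)))
  X <- sweep(sweep(X, 2, runif(5, 0.7, 1.3), "*"), 2, runif(5, -1, 1), "+")
  out <- quantile_normalize(make_em(X))$values
  expect_true(identical_column_multisets(out))
  for (j in 1:5) {
    expect_identical(order(out[, j]), order(X[, j]))
    expect_equal(cor(out[, j], X[, j], method = "spearman"), 1)
  }
})

test_that("quantile normalization agrees with limma on complete matrices", {
  skip_if_not_installed("limma")
  set.seed(3)
  X <- matrix(rnorm(200 * 4, 8, 2), ncol = 4,
              dimnames = list(sprintf("p%03d", 1:200), sprintf("s%d", 1:4)))
  ours <- quantile_normalize(make_em(X))$values
  ref <- limma::normalizeQuantiles(X)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("missing entries are excluded and stay missing; ties share targets", {
  X <- matrix(c(1, 2, 3, 4,
                2, NA, 6, 8), ncol = 2)
  out <- quantile_normalize(make_em(X))$values
  expect_true(is.na(out[2, 2]))
  expect_identical(unname(is.na(out)), is.na(X))
  expect_identical(order(out[!is.na(X[, 2]), 2]),
                   order(X[!is.na(X[, 2]), 2]))

  # tied inputs in one sample get identical outputs
  Xt <- matrix(c(1, 1, 5, 2, 3, 4), ncol = 2)
  outt <- quantile_normalize(make_em(Xt))$values
  expect_equal(outt[1, 1], outt[2, 1])
  # and equal the mean of the two lowest reference quantiles
  ref <- rowMeans(cbind(sort(Xt[, 1]), sort(Xt[, 2])))
  expect_equal(unname(outt[1, 1]), mean(ref[1:2]))

  all_na <- matrix(c(1, 2, NA, NA), ncol = 2,
                   dimnames = list(c("p1", "p2"), c("good", "bad")))
  em <- suppressWarnings(make_em(all_na))
  expect_error(quantile_normalize(em), "bad")
})

test_that("replicate averaging takes non-missing means and drops empty probes", {
  X <- matrix(c(4, 4, 5, 6, NA, 7), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  mu <- average_replicates(make_em(X))
  expect_equal(mu, c(a = 5, b = 4, c = 6))

  X2 <- matrix(c(4, NA, 6, NA), ncol = 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  em <- suppressWarnings(make_em(X2))
  expect_warning(mu2 <- average_replicates(em), "dropping")
  expect_identical(names(mu2), "a")

  X3 <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  expect_equal(average_replicates(make_em(X3)), X3[, 1])
})

test_that("percentile ranks use strict-lower counts with shared ties", {
  expect_equal(percentile_rank(1:10, warn_small = 0),
               seq(0, 90, by = 10))
  expect_equal(percentile_rank(c(1, 1, 2), warn_small = 0),
               c(0, 0, 200 / 3))
  p <- percentile_rank(rnorm(100))
  expect_identical(sum(p >= 90), 10L)
  expect_error(percentile_rank(numeric(0)), "empty")
  expect_warning(percentile_rank(rnorm(50)), "coarse")
})

test_that("percentile ranks agree with the pairwise-count oracle", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    x <- if (i %% 2 == 0) round(rnorm(n, 8, 2), 1) else rnorm(n, 8, 2)
    expect_equal(percentile_rank(x, warn_small = 0), oracle_percentile(x))
  }
})

test_that("bin assignment follows the half-open boundary convention", {
  expect_identical(as.character(assign_bins(c(95, 50, 9.9, 90, 10, 49.999, 0))),
                   c("H", "M", "VL", "H", "L", "L", "VL"))
  expect_error(assign_bins(c(50, 100)), "\\[0, 100\\)")
  expect_error(assign_bins(c(-1)), "\\[0, 100\\)")
  # custom cut-offs
  expect_identical(as.character(assign_bins(c(96, 94), cutoffs = c(5, 50, 95))),
                   c("H", "M"))
})

test_that("tie-free bins split exactly 10/40/40/10 percent", {
  set.seed(5)
  x <- sample(rnorm(1000))
  bins <- assign_bins(percentile_rank(x))
  expect_identical(as.integer(table(bins)), c(100L, 400L, 400L, 100L))
})

test_that("probe collapsing keeps adjacent-bin duplicates and drops spans > 1", {
  set.seed(9)
  n <- 200
  base <- sort(rnorm(n, 8, 2))
  probes <- sprintf("p%03d", seq_len(n + 4))
  syms <- c(sprintf("G%03d", seq_len(n)), "GADJ", "GADJ", "GFAR", "GFAR")
  # GADJ: two probes around the 90th percentile boundary (H and M, adjacent)
  # GFAR: one probe near the top, one near the bottom (span >= 2)
  means <- c(base, base[n - 2] + 0.01, base[n - 25], base[n - 2] + 0.02, base[3])
  names(means) <- probes
  ann <- make_ann(probes, syms)
  out <- collapse_probes(means, ann)
  expect_identical(out$dropped_inconsistent, "GFAR")
  expect_true("GADJ" %in% out$genes$gene_symbol)
  gadj <- out$genes[out$genes$gene_symbol == "GADJ", ]
  expect_equal(gadj$mean_log2, mean(c(base[n - 2] + 0.01, base[n - 25])))
  expect_identical(gadj$n_probes, 2L)
  # single-probe genes keep their mean
  g1 <- out$genes[out$genes$gene_symbol == "G001", ]
  expect_equal(g1$mean_log2, base[1])
  expect_identical(g1$n_probes, 1L)
})

test_that("collapsing excludes controls, empty symbols, and flags curation", {
  means <- c(p1 = 5, p2 = 6, p3 = 7, p4 = 8, p5 = 9)
  ann <- make_ann(paste0("p", 1:5),
                  c("GA", "GA", "GB", "", "GC"),
                  accession = c("XR_000001", "NM_000002", "XR_000003", "",
                                "NM_000005"),
                  is_control = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  out <- collapse_probes(means, ann)
  expect_setequal(out$genes$gene_symbol, c("GA", "GB", "GC"))
  cur <- setNames(out$genes$has_curated_accession, out$genes$gene_symbol)
  expect_true(cur[["GA"]])   # one NM_ probe suffices
  expect_false(cur[["GB"]])
  expect_true(cur[["GC"]])

  expect_error(collapse_probes(c(zz = 1, p1 = 2), ann), "zz")
})

test_that("collapsing is invariant under probe-order permutation", {
  set.seed(21)
  n <- 150
  means <- rnorm(n + 10, 8, 2)
  names(means) <- sprintf("p%03d", seq_along(means))
  syms <- c(sprintf("G%03d", seq_len(n)), rep(sprintf("G%03d", 1:5), 2))
  ann <- make_ann(names(means), syms)
  ref <- collapse_probes(means, ann)
  perm <- sample(seq_along(means))
  out <- collapse_probes(means[perm], ann[perm, ])
  expect_identical(out$genes, ref$genes)
  expect_identical(out$dropped_inconsistent, ref$dropped_inconsistent)
})

test_that("full binning pipeline composes the stages", {
  cfg <- synthetic_config(seed = 77, n_genes = 1000, noise_sd = 0.1,
                          n_specific_a = 2, n_specific_b = 2)
  gen <- generate_synthetic(cfg)
  b <- bin_dataset(gen$expr$human, gen$ann$human)
  counts <- as.integer(bin_counts(b))
  n <- nrow(b$genes)
  # high bin close to 10% of genes (ties and planting move it by a few)
  expect_lt(abs(counts[4] - 0.1 * n), 0.01 * n + 5)
  expect_identical(sum(counts), n)
  # planted inconsistent duplicates end up dropped, not binned
  expect_true(all(gen$truth$inconsistent_genes %in% b$dropped_inconsistent))
  expect_false(any(gen$truth$inconsistent_genes %in% b$genes$gene_symbol))
})

test_that("re-binning a dataset's own gene means reproduces identical bins", {
  cfg <- synthetic_config(seed = 12, n_genes = 300, noise_sd = 0.2)
  gen <- generate_synthetic(cfg)
  b <- bin_dataset(gen$expr$mouse, gen$ann$mouse)
  # rebuild a degenerate 1-sample matrix of the collapsed gene means
  vals <- matrix(b$genes$mean_log2, ncol = 1,
                 dimnames = list(b$genes$gene_symbol, "mean"))
  ann2 <- make_ann(b$genes$gene_symbol, b$genes$gene_symbol)
  b2 <- bin_dataset(make_em(vals, dataset_id = "re", species = "mouse"), ann2)
  expect_identical(as.character(b2$genes$bin), as.character(b$genes$bin))
  expect_equal(b2$genes$percentile, b$genes$percentile)
})

test_that("raising one gene's mean never lowers its bin", {
  set.seed(31)
  x <- rnorm(120, 8, 2)
  names(x) <- sprintf("G%03d", seq_along(x))
  target <- "G060"
  bins <- integer(0)
  for (delta in c(0, 0.5, 2, 4, 8)) {
    y <- x
    y[target] <- x[target] + delta
    b <- assign_bins(percentile_rank(y, warn_small = 0))
    bins <- c(bins, as.integer(b[target]))
  }
  expect_true(all(diff(bins) >= 0))
})
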