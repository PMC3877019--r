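# Fully synthetic two-species expression data with planted ground truth:
# species-specific genes in opposite extreme bins, bin-shifted gene pairs,
# duplicate probes (consistent and inconsistent), curated and non-curated
# accessions, replicate arrays with per-array affine distortion and i.i.d.
# log2 noise. Everything is reproducible from the config seed.

#' Build a synthetic-data configuration
#'
#' Defaults mirror the study design the generator emulates: 7 replicate
#' arrays for species A (human) and 3 for species B (mouse), 3 planted
#' B-specific genes and none for A (the asymmetric outcome), per-array
#' affine distortion that quantile normalization must undo, and moderate
#' log2 intensity noise.
#'
#' @param seed integer RNG seed; every random draw flows through it.
#' @param n_genes number of genes (orthologs shared by both species).
#' @param n_samples_a,n_samples_b replicate array counts (defaults 7 and 3).
#' @param species_a,species_b species labels (defaults "human", "mouse").
#' @param n_specific_a,n_specific_b planted species-specific genes: high bin
#'   in that species, very low in the other.
#' @param n_decoy_noncurated planted B-specific-like genes annotated with a
#'   non-curated (`XR_`) accession; the curated filter must exclude them.
#' @param n_decoy_inconsistent planted B-specific-like genes given an
#'   inconsistent duplicate probe (bins two categories apart); the
#'   consistency filter must drop them.
#' @param n_shifted_pairs genes displaced by exactly `shift_distance` bins
#'   between the species.
#' @param shift_distance bin distance of the shifted genes (default 2).
#' @param frac_duplicate_probes fraction of genes carrying a second probe.
#' @param frac_inconsistent_duplicates fraction of duplicated background
#'   genes whose duplicate is displaced to a non-adjacent bin.
#' @param frac_noncurated fraction of background genes annotated with
#'   non-curated accessions.
#' @param n_control_probes control spots (no gene symbol) per array.
#' @param noise_sd sd of i.i.d. per-probe-per-sample noise, log2 units.
#' @param array_distortion apply per-array affine distortion (scale drawn
#'   from `array_scale`, offset from `array_offset`). The random draws are
#'   made regardless of the flag so that toggling it leaves all other
#'   numbers unchanged.
#' @param array_scale,array_offset distortion ranges.
#' @param specific_margin_bins intensity margin of planted specific genes,
#'   in local bin widths beyond the 90th/10th percentile cut-off values.
#' @param dup_jitter_sd sd of the jitter of consistent duplicate probes.
#' @param baseline_mean,baseline_sd normal distribution of baseline gene
#'   means on the log2 scale.
#' @param cutoffs bin cut-offs used for placement (default 10/50/90).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 1000L,
                             n_samples_a = 7L,
                             n_samples_b = 3L,
                             species_a = "human",
                             species_b = "mouse",
                             n_specific_a = 0L,
                             n_specific_b = 3L,
                             n_decoy_noncurated = 0L,
                             n_decoy_inconsistent = 0L,
                             n_shifted_pairs = 5L,
                             shift_distance = 2L,
                             frac_duplicate_probes = 0.10,
                             frac_inconsistent_duplicates = 0.05,
                             frac_noncurated = 0.10,
                             n_control_probes = 5L,
                             noise_sd = 0.25,
                             array_distortion = TRUE,
                             array_scale = c(0.8, 1.2),
                             array_offset = c(-1, 1),
                             specific_margin_bins = 2,
                             dup_jitter_sd = 0.05,
                             baseline_mean = 8,
                             baseline_sd = 2,
                             cutoffs = c(10, 50, 90)) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_samples_a = as.integer(n_samples_a),
              n_samples_b = as.integer(n_samples_b),
              species_a = species_a, species_b = species_b,
              n_specific_a = as.integer(n_specific_a),
              n_specific_b = as.integer(n_specific_b),
              n_decoy_noncurated = as.integer(n_decoy_noncurated),
              n_decoy_inconsistent = as.integer(n_decoy_inconsistent),
              n_shifted_pairs = as.integer(n_shifted_pairs),
              shift_distance = as.integer(shift_distance),
              frac_duplicate_probes = frac_duplicate_probes,
              frac_inconsistent_duplicates = frac_inconsistent_duplicates,
              frac_noncurated = frac_noncurated,
              n_control_probes = as.integer(n_control_probes),
              noise_sd = noise_sd,
              array_distortion = isTRUE(array_distortion),
              array_scale = array_scale, array_offset = array_offset,
              specific_margin_bins = specific_margin_bins,
              dup_jitter_sd = dup_jitter_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              cutoffs = cutoffs)
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  counts <- c(cfg$n_genes, cfg$n_samples_a, cfg$n_samples_b, cfg$n_specific_a,
              cfg$n_specific_b, cfg$n_decoy_noncurated,
              cfg$n_decoy_inconsistent, cfg$n_shifted_pairs,
              cfg$n_control_probes)
  if (any(counts < 0L)) stop("counts must be non-negative")
  if (cfg$n_samples_a < 1L || cfg$n_samples_b < 1L) {
    stop("each species needs at least one sample")
  }
  fr <- c(cfg$frac_duplicate_probes, cfg$frac_inconsistent_duplicates,
          cfg$frac_noncurated)
  if (any(fr < 0 | fr > 1)) stop("proportions must lie in [0, 1]")
  if (!(cfg$shift_distance %in% 1:3)) stop("shift_distance must be 1, 2 or 3")
  check_cutoffs(cfg$cutoffs)

  n_planted <- cfg$n_specific_a + cfg$n_specific_b + cfg$n_decoy_noncurated +
    cfg$n_decoy_inconsistent + cfg$n_shifted_pairs
  decile <- floor(cfg$n_genes * (100 - cfg$cutoffs[3L]) / 100)
  high_a <- cfg$n_specific_a
  high_b <- cfg$n_specific_b + cfg$n_decoy_noncurated + cfg$n_decoy_inconsistent
  if (n_planted > cfg$n_genes || high_a > decile || high_b > decile) {
    stop("over-committed planting: planted categories exceed decile capacity")
  }
  invisible(cfg)
}

# background-quantile helper used for placements
placement_bin <- function(value, bg, cutoffs) {
  p <- 100 * mean(bg < value)
  findInterval(p, cutoffs) + 1L
}

#' Generate a synthetic two-species dataset with known truth
#'
#' Baseline gene means are drawn once and shared between the species
#' (orthologs), then planted categories displace selected genes: specific
#' genes go well inside the top decile of one species and the bottom decile
#' of the other (margin `specific_margin_bins` local bin widths beyond the
#' cut-off value), shifted genes move by exactly `shift_distance` bins,
#' inconsistent duplicates get a probe two bins away. Each array applies an
#' affine distortion (undone by quantile normalization) and adds i.i.d.
#' noise.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_dataset` with elements `expr` (list of
#'   two [expression_matrix()] objects named by species), `ann` (matching
#'   `probe_annotation` tables), `truth` (planted ground truth) and
#'   `config`.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_synthetic_config(config)
  cfg <- config
  withr::with_seed(cfg$seed, {
    n <- cfg$n_genes
    width <- max(4L, nchar(as.character(n)))
    symbols <- sprintf("GENE%0*d", width, seq_len(n))
    mu <- stats::rnorm(n, cfg$baseline_mean, cfg$baseline_sd)

    k <- c(sa = cfg$n_specific_a, sb = cfg$n_specific_b,
           dn = cfg$n_decoy_noncurated, di = cfg$n_decoy_inconsistent,
           sh = cfg$n_shifted_pairs)
    planted <- sample(n, sum(k))
    ends <- cumsum(k)
    take <- function(nm) {
      if (k[[nm]] == 0L) return(integer(0L))
      planted[(ends[[nm]] - k[[nm]] + 1L):ends[[nm]]]
    }
    idx_sa <- take("sa"); idx_sb <- take("sb"); idx_dn <- take("dn")
    idx_di <- take("di"); idx_sh <- take("sh")
    background <- setdiff(seq_len(n), planted)
    bg <- mu[background]

    qf <- function(p) stats::quantile(bg, p, names = FALSE)
    cut_p <- cfg$cutoffs / 100
    w_hi <- qf(cut_p[3L]) - qf(cut_p[3L] - 0.10)
    w_lo <- qf(cut_p[1L] + 0.10) - qf(cut_p[1L])
    high_vals <- function(m) {
      qf(cut_p[3L]) + cfg$specific_margin_bins * w_hi +
        stats::runif(m, 0, 0.25 * w_hi)
    }
    low_vals <- function(m) {
      qf(cut_p[1L]) - cfg$specific_margin_bins * w_lo -
        stats::runif(m, 0, 0.25 * w_lo)
    }

    mu_a <- mu
    mu_b <- mu
    mu_a[idx_sa] <- high_vals(k[["sa"]]); mu_b[idx_sa] <- low_vals(k[["sa"]])
    mu_b[idx_sb] <- high_vals(k[["sb"]]); mu_a[idx_sb] <- low_vals(k[["sb"]])
    mu_b[idx_dn] <- high_vals(k[["dn"]]); mu_a[idx_dn] <- low_vals(k[["dn"]])
    mu_b[idx_di] <- high_vals(k[["di"]]); mu_a[idx_di] <- low_vals(k[["di"]])

    # bin mid-point percentiles for placements inside a target bin
    mids <- c(cut_p[1L] / 2,
              (cut_p[1L] + cut_p[2L]) / 2,
              (cut_p[2L] + cut_p[3L]) / 2,
              (cut_p[3L] + 1) / 2)
    shifted_bins <- data.frame(gene_symbol = character(0L),
                               bin_a = character(0L), bin_b = character(0L),
                               stringsAsFactors = FALSE)
    d <- cfg$shift_distance
    for (i in idx_sh) {
      feasible <- which(vapply(1:4, function(b) {
        (b + d <= 4L) || (b - d >= 1L)
      }, logical(1L)))
      ba <- sample(feasible, 1L)
      dirs <- c(if (ba + d <= 4L) 1L, if (ba - d >= 1L) -1L)
      bb <- ba + d * if (length(dirs) > 1L) sample(dirs, 1L) else dirs
      mu_a[i] <- qf(mids[ba]) + stats::rnorm(1L, 0, 0.05)
      mu_b[i] <- qf(mids[bb]) + stats::rnorm(1L, 0, 0.05)
      shifted_bins <- rbind(shifted_bins, data.frame(
        gene_symbol = symbols[i], bin_a = BIN_LEVELS[ba],
        bin_b = BIN_LEVELS[bb], stringsAsFactors = FALSE))
    }

    # duplicate probes: background genes only, plus forced inconsistent decoys
    n_dup <- round(cfg$frac_duplicate_probes * n)
    dup_idx <- if (n_dup > 0L) sample(background, min(n_dup, length(background)))
               else integer(0L)
    n_inc <- round(cfg$frac_inconsistent_duplicates * length(dup_idx))
    inc_idx <- utils::head(dup_idx, n_inc)
    cons_idx <- setdiff(dup_idx, inc_idx)

    # non-curated accessions: background genes (outside the inconsistent
    # set, keeping truth categories disjoint) plus the XR_ decoys
    noncur_pool <- setdiff(background, inc_idx)
    n_noncur <- min(round(cfg$frac_noncurated * n), length(noncur_pool))
    noncur_idx <- if (n_noncur > 0L) sample(noncur_pool, n_noncur) else integer(0L)

    curated_of <- function(i) !(i %in% c(noncur_idx, idx_dn))
    accession_for <- function(i, offset) {
      ifelse(vapply(i, curated_of, logical(1L)),
             sprintf("NM_%06d", i + offset),
             sprintf("XR_%06d", i + offset))
    }

    displaced_value <- function(i, mu_s) {
      b <- placement_bin(mu_s[i], bg, cfg$cutoffs)
      target <- if (b + 2L <= 4L && b - 2L >= 1L) {
        b + 2L * sample(c(-1L, 1L), 1L)
      } else if (b + 2L <= 4L) b + 2L else b - 2L
      qf(mids[target]) + stats::rnorm(1L, 0, 0.05)
    }

    build_species <- function(species, mu_s, n_samples, acc_offset) {
      gene_idx <- c(seq_len(n), cons_idx, inc_idx, idx_di)
      probe_role <- c(rep("main", n), rep("cons", length(cons_idx)),
                      rep("inc", length(inc_idx) + length(idx_di)))
      probe_mu <- mu_s[gene_idx]
      jcons <- which(probe_role == "cons")
      probe_mu[jcons] <- probe_mu[jcons] +
        stats::rnorm(length(jcons), 0, cfg$dup_jitter_sd)
      jinc <- which(probe_role == "inc")
      for (j in jinc) probe_mu[j] <- displaced_value(gene_idx[j], mu_s)

      n_probes <- length(gene_idx) + cfg$n_control_probes
      probe_ids <- sprintf("%s_P%06d", toupper(substr(species, 1L, 1L)),
                           seq_len(n_probes))
      ctrl_mu <- stats::rnorm(cfg$n_control_probes, cfg$baseline_mean,
                              cfg$baseline_sd)
      all_mu <- c(probe_mu, ctrl_mu)

      ann <- data.frame(
        probe_id = probe_ids,
        gene_symbol = c(symbols[gene_idx], rep("", cfg$n_control_probes)),
        transcript_accession = c(accession_for(gene_idx, acc_offset),
                                 rep("", cfg$n_control_probes)),
        is_control = c(rep(FALSE, length(gene_idx)),
                       rep(TRUE, cfg$n_control_probes)),
        stringsAsFactors = FALSE
      )
      class(ann) <- c("probe_annotation", "data.frame")

      scales <- stats::runif(n_samples, cfg$array_scale[1L], cfg$array_scale[2L])
      offsets <- stats::runif(n_samples, cfg$array_offset[1L], cfg$array_offset[2L])
      noise <- matrix(stats::rnorm(n_probes * n_samples, 0, cfg$noise_sd),
                      nrow = n_probes)
      V <- matrix(all_mu, nrow = n_probes, ncol = n_samples) + noise
      if (cfg$array_distortion) {
        V <- sweep(sweep(V, 2L, scales, "*"), 2L, offsets, "+")
      }
      dimnames(V) <- list(probe_ids,
                          sprintf("%s_s%d", species, seq_len(n_samples)))
      list(expr = expression_matrix(V, paste0("syn_", species), species),
           ann = ann)
    }

    a <- build_species(cfg$species_a, mu_a, cfg$n_samples_a, 0L)
    b <- build_species(cfg$species_b, mu_b, cfg$n_samples_b, 500000L)

    truth <- list(
      specific_genes = stats::setNames(
        list(sort(symbols[idx_sa]), sort(symbols[idx_sb])),
        c(cfg$species_a, cfg$species_b)),
      shifted_genes = shifted_bins[order(shifted_bins$gene_symbol), ,
                                   drop = FALSE],
      inconsistent_genes = sort(symbols[c(inc_idx, idx_di)]),
      noncurated_genes = sort(symbols[c(noncur_idx, idx_dn)]),
      decoy_noncurated = sort(symbols[idx_dn]),
      decoy_inconsistent = sort(symbols[idx_di])
    )
    rownames(truth$shifted_genes) <- NULL

    structure(
      list(expr = stats::setNames(list(a$expr, b$expr),
                                  c(cfg$species_a, cfg$species_b)),
           ann = stats::setNames(list(a$ann, b$ann),
                                 c(cfg$species_a, cfg$species_b)),
           truth = truth,
           config = cfg),
      class = "synthetic_dataset"
    )
  })
}

#' Write a synthetic dataset to a directory
#'
#' Emits the standard pipeline text formats: one expression TSV and one
#' annotation TSV per species, plus `truth.json` and `config.json`.
#'
#' @param x a `synthetic_dataset` from [generate_synthetic()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_synthetic <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0L)
  for (sp in names(x$expr)) {
    pe <- file.path(dir, paste0("expr_", sp, ".tsv"))
    pa <- file.path(dir, paste0("annotation_", sp, ".tsv"))
    write_expression_tsv(x$expr[[sp]], pe)
    write_annotation(x$ann[[sp]], pa)
    paths <- c(paths, stats::setNames(c(pe, pa),
                                      paste0(c("expr_", "annotation_"), sp)))
  }
  pt <- file.path(dir, "truth.json")
  jsonlite::write_json(x$truth, pt, auto_unbox = FALSE, digits = NA,
                       dataframe = "columns")
  pc <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(x$config), pc, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, truth = pt, config = pc)
  invisible(paths)
}

#' Precision and recall of specificity calls against planted truth
#'
#' Both are 1 by convention when their denominator is zero (no calls made
#' and nothing planted is a perfect vacuous outcome).
#'
#' @param calls data frame from [call_specific_genes()] (or a character
#'   vector of called gene symbols).
#' @param truth the `truth` element of a `synthetic_dataset`.
#' @param species which species' planted specific genes to score against.
#' @return named numeric vector with elements `precision`, `recall`, `tp`,
#'   `fp`, `fn`.
#' @export
evaluate_recovery <- function(calls, truth, species) {
  called <- if (is.data.frame(calls)) calls$gene_symbol else as.character(calls)
  called <- unique(normalize_symbol(called))
  if (!species %in% names(truth$specific_genes)) {
    stop("species '", species, "' not present in truth")
  }
  planted <- truth$specific_genes[[species]]
  tp <- length(intersect(called, planted))
  fp <- length(setdiff(called, planted))
  fn <- length(setdiff(planted, called))
  precision <- if (tp + fp == 0L) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 1 else tp / (tp + fn)
  c(precision = precision, recall = recall, tp = tp, fp = fp, fn = fn)
}
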