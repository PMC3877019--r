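# Config-driven orchestration of the pipeline stages. A single JSON config
# lists the datasets (path, format, species, annotation), the bin cut-offs,
# the per-species reference datasets, gene-set files and the output
# directory. Every output table carries a provenance header (tool version,
# config hash, cut-offs); analysis stages are seed-free, so config bytes
# determine output bytes.

#' Load and validate a pipeline configuration
#'
#' @param x path to a JSON config file, or an equivalent named list.
#'   Relative dataset paths are resolved against the config file's
#'   directory.
#'
#' Recognized fields: `datasets` (list of entries with `dataset_id`,
#' `species`, `path`, `annotation`, optional `format` = `"tsv"` (default) or
#' `"series_matrix"`, optional `log2_transform` for linear-scale deposits),
#' `cutoffs` (default `c(10, 50, 90)`), `references` (named list species ->
#' dataset_id), `gene_sets` (paths), `out_dir`, `missing_token` (default
#' `"NA"`), `seed`.
#'
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  base_dir <- "."
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config file not found: ", x)
    base_dir <- dirname(normalizePath(x))
    x <- jsonlite::read_json(x, simplifyVector = FALSE)
  }
  stopifnot(is.list(x))
  cfg <- x
  cfg$cutoffs <- as.numeric(unlist(cfg$cutoffs %||% c(10, 50, 90)))
  check_cutoffs(cfg$cutoffs)
  cfg$missing_token <- cfg$missing_token %||% "NA"
  cfg$out_dir <- cfg$out_dir %||% "."
  cfg$seed <- cfg$seed %||% 1L
  cfg$references <- lapply(cfg$references %||% list(), function(v) as.character(v))
  cfg$gene_sets <- as.character(unlist(cfg$gene_sets %||% character(0L)))

  resolve <- function(p) {
    if (length(p) == 0L) return(character(0L))
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base_dir, p))
  }
  problems <- character(0L)
  if (length(cfg$datasets %||% list()) == 0L) {
    problems <- c(problems, "config lists no datasets")
  }
  ids <- character(0L)
  cfg$datasets <- lapply(cfg$datasets, function(e) {
    for (field in c("dataset_id", "species", "path", "annotation")) {
      if (is.null(e[[field]])) {
        problems <<- c(problems, paste0("dataset entry missing '", field, "'"))
      }
    }
    e$format <- e$format %||% "tsv"
    if (!e$format %in% c("tsv", "series_matrix")) {
      problems <<- c(problems, paste0("unknown format '", e$format, "' for ",
                                      e$dataset_id %||% "?"))
    }
    e$log2_transform <- isTRUE(e$log2_transform)
    if (!is.null(e$path)) {
      e$path <- resolve(e$path)
      if (!file.exists(e$path)) {
        problems <<- c(problems, paste0("missing expression file: ", e$path))
      }
    }
    if (!is.null(e$annotation)) {
      e$annotation <- resolve(e$annotation)
      if (!file.exists(e$annotation)) {
        problems <<- c(problems, paste0("missing annotation file: ", e$annotation))
      }
    }
    ids <<- c(ids, e$dataset_id %||% NA_character_)
    e
  })
  if (anyDuplicated(stats::na.omit(ids))) {
    problems <- c(problems, paste0("duplicate dataset ids: ",
                                   paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  for (sp in names(cfg$references)) {
    if (!cfg$references[[sp]] %in% ids) {
      problems <- c(problems, paste0("reference dataset '", cfg$references[[sp]],
                                     "' (", sp, ") not among dataset ids"))
    }
  }
  cfg$gene_sets <- resolve(cfg$gene_sets)
  missing_sets <- cfg$gene_sets[!file.exists(cfg$gene_sets)]
  if (length(missing_sets) > 0L) {
    problems <- c(problems, paste0("missing gene-set file: ", missing_sets))
  }
  if (length(problems) > 0L) {
    stop("invalid pipeline config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  names(cfg$datasets) <- ids
  structure(cfg, class = "pipeline_config")
}

dataset_entry <- function(config, dataset_id) {
  e <- config$datasets[[dataset_id]]
  if (is.null(e)) stop("unknown dataset id: ", dataset_id)
  e
}

load_dataset <- function(config, dataset_id) {
  e <- dataset_entry(config, dataset_id)
  m <- switch(e$format,
    tsv = {
      m0 <- read_expression_tsv(e$path, e$dataset_id, e$species,
                                missing_token = config$missing_token)
      if (e$log2_transform) {
        v <- m0$values
        nonpos <- !is.na(v) & v <= 0
        if (any(nonpos)) v[nonpos] <- NA_real_
        m0 <- expression_matrix(log2(v), m0$dataset_id, m0$species)
      }
      m0
    },
    series_matrix = read_series_matrix(e$path, dataset_id = e$dataset_id,
                                       species = e$species,
                                       log2_transform = e$log2_transform)
  )
  ann <- read_annotation(e$annotation)
  list(expr = m, ann = ann)
}

provenance_lines <- function(config) {
  c(sprintf("tool=orthobin %s", pkg_version()),
    sprintf("config_hash=%s", config_hash(unclass(config))),
    sprintf("bin_cutoffs=%s", paste(config$cutoffs, collapse = ",")),
    "normalization=quantile (between arrays, on the provided log2 matrix; stands in for two-color A-value quantile normalization)")
}

write_table_with_header <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header_lines), con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df) > 0L) {
    rows <- apply(df, 1L, function(r) paste(trimws(as.character(r)), collapse = "\t"))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Bin one configured dataset and write its table
#'
#' Loads the dataset, runs the full within-dataset pipeline
#' ([bin_dataset()]), logs probe/gene/bin counts via [message()], and writes
#' `<out_dir>/<dataset_id>_binned.tsv` with a provenance header.
#'
#' @param config a [pipeline_config()] (or path/list coercible to one).
#' @param dataset_id which dataset to bin.
#' @param write write the binned table (default `TRUE`).
#' @return the `binned_dataset`, invisibly when `write = TRUE`.
#' @export
run_bin <- function(config, dataset_id, write = TRUE) {
  config <- as_pipeline_config(config)
  d <- load_dataset(config, dataset_id)
  binned <- bin_dataset(d$expr, d$ann, config$cutoffs)
  s <- binned$stats
  message(sprintf(
    "[bin] %s: %d probes in, %d annotated, probe-level H=%d; %d genes (H=%d), %d dropped inconsistent; bins VL/L/M/H = %s",
    dataset_id, s$n_probes_input, s$n_probes_retained, s$n_probe_high,
    s$n_genes, s$n_gene_high, s$n_dropped_inconsistent,
    paste(as.integer(bin_counts(binned)), collapse = "/")))
  if (write) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(config$out_dir, paste0(dataset_id, "_binned.tsv"))
    write_binned_table(binned, path, provenance = provenance_lines(config))
    message("[bin] wrote ", path)
    return(invisible(binned))
  }
  binned
}

as_pipeline_config <- function(config) {
  if (inherits(config, "pipeline_config")) config else pipeline_config(config)
}

#' Compare two species' datasets: specificity calls and cross-bin counts
#'
#' Bins both datasets, matches orthologs, writes one specificity-call TSV
#' per direction plus the full 4x4 cross-bin count matrix.
#'
#' @param config a [pipeline_config()].
#' @param id_a,id_b dataset ids of two different species.
#' @param write write output tables (default `TRUE`).
#' @return list with `pairs`, `calls` (named by species), `crossbin`
#'   (4x4 matrix, rows = bins in `id_a`, columns = bins in `id_b`).
#' @export
run_compare <- function(config, id_a, id_b, write = TRUE) {
  config <- as_pipeline_config(config)
  ba <- run_bin(config, id_a, write = FALSE)
  bb <- run_bin(config, id_b, write = FALSE)
  if (identical(ba$species, bb$species)) {
    stop("specificity is defined across species; both datasets are ",
         ba$species)
  }
  pairs <- match_orthologs(ba, bb)
  if (nrow(pairs) == 0L) {
    stop("empty ortholog intersection between ", id_a, " (",
         nrow(ba$genes), " genes) and ", id_b, " (", nrow(bb$genes),
         " genes); check that both annotations use comparable gene symbols")
  }
  crossbin <- table(bin_a = pairs$bin_a, bin_b = pairs$bin_b)
  calls <- stats::setNames(
    list(call_specific_genes(pairs, ba$species),
         call_specific_genes(pairs, bb$species)),
    c(ba$species, bb$species))
  message(sprintf("[compare] %s vs %s: %d ortholog pairs; %s-specific=%d, %s-specific=%d",
                  id_a, id_b, nrow(pairs), ba$species, nrow(calls[[1L]]),
                  bb$species, nrow(calls[[2L]])))
  if (write) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- provenance_lines(config)
    for (sp in names(calls)) {
      path <- file.path(config$out_dir,
                        sprintf("calls_%s_vs_%s_%s_specific.tsv", id_a, id_b, sp))
      write_table_with_header(calls[[sp]], path, hdr)
    }
    cb <- as.data.frame.matrix(crossbin)
    cb <- cbind(data.frame(bin_a = rownames(cb), stringsAsFactors = FALSE), cb)
    write_table_with_header(
      cb, file.path(config$out_dir, sprintf("crossbin_%s_vs_%s.tsv", id_a, id_b)),
      hdr)
  }
  list(pairs = pairs, calls = calls, crossbin = crossbin)
}

#' High-bin concordance rows for all same-species dataset pairs
#'
#' For each species with a designated reference dataset, emits one row per
#' other same-species dataset (the query): size of the query's high bin,
#' overlap with the reference's high bin, and the rounded percentage.
#'
#' @param config a [pipeline_config()] with a `references` entry.
#' @param write write `concordance.tsv` (default `TRUE`).
#' @return data frame of concordance rows (possibly empty).
#' @export
run_concordance <- function(config, write = TRUE) {
  config <- as_pipeline_config(config)
  if (length(config$references) == 0L) stop("config designates no reference datasets")
  binned <- lapply(names(config$datasets), function(id) run_bin(config, id, write = FALSE))
  names(binned) <- names(config$datasets)
  rows <- list()
  for (sp in names(config$references)) {
    ref_id <- config$references[[sp]]
    ref <- binned[[ref_id]]
    queries <- Filter(function(b) identical(b$species, sp) &&
                        !identical(b$dataset_id, ref_id), binned)
    if (length(queries) == 0L) {
      warning("no same-species query dataset for reference ", ref_id,
              " (", sp, "); row skipped", call. = FALSE)
      next
    }
    for (q in queries) rows[[length(rows) + 1L]] <- concordance(ref, q)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(ref_dataset = character(0L), query_dataset = character(0L),
               n_query_high = integer(0L), n_overlap = integer(0L),
               pct_overlap = numeric(0L))
  if (write) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table_with_header(out, file.path(config$out_dir, "concordance.tsv"),
                            provenance_lines(config))
  }
  out
}

#' Bin profiles of the configured gene sets across all datasets
#'
#' Flags shifts between the two reference datasets (one per species).
#'
#' @param config a [pipeline_config()] with `gene_sets` and two `references`.
#' @param write write one profile TSV per set (default `TRUE`).
#' @return named list of [gene_set_profile()] objects.
#' @export
run_profile <- function(config, write = TRUE) {
  config <- as_pipeline_config(config)
  if (length(config$gene_sets) == 0L) stop("config lists no gene sets")
  if (length(config$references) != 2L) {
    stop("gene-set profiling needs exactly two reference datasets (one per species)")
  }
  binned <- lapply(names(config$datasets), function(id) run_bin(config, id, write = FALSE))
  flag_pair <- unname(unlist(config$references))
  sets <- do.call(c, lapply(config$gene_sets, read_gene_sets))
  profiles <- lapply(names(sets), function(nm) {
    gene_set_profile(sets[[nm]], binned, flag_pair, set_name = nm)
  })
  names(profiles) <- names(sets)
  if (write) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- provenance_lines(config)
    for (nm in names(profiles)) {
      p <- profiles[[nm]]
      per_gene <- p$per_gene
      flagged <- per_gene$gene_symbol %in% p$flagged_shifts$gene_symbol
      per_gene$flagged_shift <- flagged
      write_table_with_header(
        per_gene,
        file.path(config$out_dir, sprintf("profile_%s.tsv", nm)),
        c(hdr, sprintf("gene_set=%s", nm),
          sprintf("flag_pair=%s", paste(flag_pair, collapse = ","))))
    }
  }
  profiles
}
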