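# Text-format readers and writers: expression TSV, GEO series-matrix dialect,
# probe annotation tables, gene-set lists and binned-gene tables. All formats
# are tab-delimited UTF-8 with a header row; binned tables carry '#' comment
# headers for provenance and round-trip exactly.

format_error <- function(...) {
  stop(structure(class = c("orthobin_format_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Read an expression matrix from TSV
#'
#' First column holds probe ids, remaining columns one sample each; a header
#' row is required. Cells equal to `missing_token` become `NA`; any other
#' non-numeric cell is a format error reported with its row and column.
#'
#' @param path path to the TSV file.
#' @param dataset_id,species labels stored on the returned object.
#' @param missing_token string encoding a missing value (default `"NA"`).
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, dataset_id, species, missing_token = "NA") {
  if (!file.exists(path)) format_error("file not found: ", path)
  if (length(readLines(path, n = 2L, warn = FALSE)) < 2L) {
    format_error("empty expression table: ", path)
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "")
  if (nrow(tab) == 0L || ncol(tab) < 2L) {
    format_error("empty or sample-less expression table: ", path)
  }
  probe_ids <- trimws(tab[[1L]])
  if (anyDuplicated(probe_ids)) {
    dup <- unique(probe_ids[duplicated(probe_ids)])
    format_error("duplicate probe id(s) in ", path, ": ",
                 paste(dup, collapse = ", "))
  }
  sample_ids <- colnames(tab)[-1L]
  vals <- matrix(NA_real_, nrow = nrow(tab), ncol = length(sample_ids),
                 dimnames = list(probe_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    cell <- trimws(tab[[j + 1L]])
    is_missing <- cell == missing_token | cell == ""
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) & !is_missing)
    if (length(bad) > 0L) {
      format_error(sprintf(
        "non-numeric value '%s' at row %d, column '%s' of %s",
        cell[bad[1L]], bad[1L], sample_ids[j], path))
    }
    num[is_missing] <- NA_real_
    vals[, j] <- num
  }
  expression_matrix(vals, dataset_id, species)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_tsv()]; `NA` entries are written as
#' `missing_token`.
#'
#' @param m an [expression_matrix()].
#' @param path output path.
#' @param missing_token string used for missing values.
#' @export
write_expression_tsv <- function(m, path, missing_token = "NA") {
  stopifnot(inherits(m, "expression_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("probe_id", colnames(m$values)), collapse = "\t"), con)
  body <- apply(m$values, 1L, function(row) {
    txt <- fmt_num(row)
    txt[is.na(row)] <- missing_token
    paste(txt, collapse = "\t")
  })
  writeLines(paste(rownames(m$values), body, sep = "\t"), con)
  invisible(path)
}

#' Read a GEO series-matrix text file
#'
#' Parses the series-matrix dialect: metadata lines prefixed `!`, a data table
#' delimited by `!series_matrix_table_begin` / `!series_matrix_table_end` with
#' an `ID_REF` first column and quoted sample accessions as column headers.
#' Values are taken as provided and assumed to be log2 scale; set
#' `log2_transform = TRUE` for linear-scale deposits.
#'
#' @param path path to the series-matrix file.
#' @param dataset_id dataset label; defaults to the `!Series_geo_accession`
#'   metadata value when present, else the file name.
#' @param species species label stored on the result (GEO metadata is not
#'   parsed for it).
#' @param log2_transform if `TRUE`, entries are log2-transformed on read
#'   (non-positive values become `NA` with a warning).
#' @return an [expression_matrix()]; series metadata key/value pairs are
#'   attached as the `"metadata"` attribute (a named list).
#' @export
read_series_matrix <- function(path, dataset_id = NULL, species = "unknown",
                               log2_transform = FALSE) {
  if (!file.exists(path)) format_error("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  begin <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
  end <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    format_error("missing or malformed series-matrix table delimiters in ", path)
  }

  meta_lines <- grep("^!", lines[seq_len(begin - 1L)], value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    parts <- strsplit(sub("^!", "", ln), "\t", fixed = TRUE)[[1L]]
    key <- parts[1L]
    val <- gsub('^"|"$', "", parts[-1L])
    if (length(val) > 0L) meta[[key]] <- c(meta[[key]], val)
  }

  tbl <- lines[(begin + 1L):(end - 1L)]
  cells <- strsplit(tbl, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    format_error("ragged series-matrix table rows in ", path,
                 " (widths ", paste(unique(widths), collapse = "/"), ")")
  }
  header <- gsub('^"|"$', "", cells[[1L]])
  if (!identical(toupper(header[1L]), "ID_REF")) {
    format_error("series-matrix table must start with an ID_REF column")
  }
  sample_ids <- header[-1L]
  rows <- cells[-1L]
  probe_ids <- gsub('^"|"$', "", vapply(rows, `[`, character(1L), 1L))
  if (anyDuplicated(probe_ids)) {
    dup <- unique(probe_ids[duplicated(probe_ids)])
    format_error("duplicate probe id(s) in series-matrix table: ",
                 paste(dup, collapse = ", "))
  }
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(sample_ids),
                 dimnames = list(probe_ids, sample_ids))
  for (i in seq_along(rows)) {
    cell <- rows[[i]][-1L]
    cell[cell %in% c("null", "NULL", "", "NA")] <- NA_character_
    vals[i, ] <- suppressWarnings(as.numeric(cell))
  }
  if (log2_transform) {
    nonpos <- !is.na(vals) & vals <= 0
    if (any(nonpos)) {
      warning(sum(nonpos), " non-positive value(s) set to NA before log2",
              call. = FALSE)
      vals[nonpos] <- NA_real_
    }
    vals <- log2(vals)
  }
  if (is.null(dataset_id)) {
    dataset_id <- meta[["Series_geo_accession"]][1L] %||% basename(path)
  }
  m <- expression_matrix(vals, dataset_id, species)
  attr(m, "metadata") <- meta
  attr(m, "log2_transformed_on_read") <- log2_transform
  m
}

#' Read a probe annotation table
#'
#' TSV with columns `probe_id`, `gene_symbol`, `transcript_accession` and an
#' optional `is_control`. Gene symbols are uppercased and whitespace-stripped;
#' a non-empty accession that does not match the RefSeq-style pattern
#' `[A-Z]{2}_[0-9]+` triggers a warning and is treated as empty.
#'
#' @param path path to the annotation TSV.
#' @return a `probe_annotation` data frame with the four columns above.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) format_error("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  need <- c("probe_id", "gene_symbol", "transcript_accession")
  if (!all(need %in% colnames(tab))) {
    format_error("annotation table must have columns ",
                 paste(need, collapse = ", "))
  }
  ann <- data.frame(
    probe_id = trimws(tab$probe_id),
    gene_symbol = normalize_symbol(tab$gene_symbol),
    transcript_accession = trimws(tab$transcript_accession),
    stringsAsFactors = FALSE
  )
  ann$gene_symbol[is.na(ann$gene_symbol)] <- ""
  ann$transcript_accession[is.na(ann$transcript_accession)] <- ""
  ann$is_control <- if ("is_control" %in% colnames(tab)) {
    trimws(tab$is_control) %in% c("TRUE", "true", "1", "T")
  } else {
    rep(FALSE, nrow(ann))
  }
  if (anyDuplicated(ann$probe_id)) {
    dup <- unique(ann$probe_id[duplicated(ann$probe_id)])
    format_error("duplicate probe id(s) in annotation ", path, ": ",
                 paste(dup, collapse = ", "))
  }
  bad <- ann$transcript_accession != "" &
    !grepl(ACCESSION_PATTERN, ann$transcript_accession)
  if (any(bad)) {
    warning(sum(bad), " malformed accession(s) treated as empty (e.g. '",
            ann$transcript_accession[which(bad)[1L]], "')", call. = FALSE)
    ann$transcript_accession[bad] <- ""
  }
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Write a probe annotation table
#' @param ann a `probe_annotation` data frame.
#' @param path output path.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets
#'
#' Accepts either one symbol per line (a single set named after the file) or
#' two tab-separated columns `set_name<TAB>symbol` (multiple sets). Symbols
#' are uppercased; duplicates within a set are collapsed.
#'
#' @param path path to the gene-set file.
#' @return a named list of character vectors of gene symbols.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) format_error("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L) format_error("empty gene-set file: ", path)
  if (any(grepl("\t", lines, fixed = TRUE))) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L)) {
      format_error("gene-set file mixes one- and two-column lines: ", path)
    }
    nm <- vapply(parts, `[`, character(1L), 1L)
    sym <- normalize_symbol(vapply(parts, `[`, character(1L), 2L))
    sets <- lapply(split(sym, nm), unique)
  } else {
    nm <- sub("\\.[^.]*$", "", basename(path))
    sets <- stats::setNames(list(unique(normalize_symbol(lines))), nm)
  }
  sets
}

#' Write a binned dataset to TSV
#'
#' Serializes a [bin_dataset()] result: `#`-prefixed header lines carry the
#' dataset id, species, bin cut-offs, the dropped-inconsistent symbol list and
#' any extra provenance lines, followed by a table with columns `gene_symbol`,
#' `mean_log2`, `percentile`, `bin`, `n_probes`, `has_curated_accession`.
#' Numeric columns are written at full precision so that
#' [read_binned_table()] reproduces the dataset exactly.
#'
#' @param binned a `binned_dataset`.
#' @param path output path.
#' @param provenance optional character vector of extra header lines (written
#'   as `# <line>`).
#' @export
write_binned_table <- function(binned, path, provenance = NULL) {
  stopifnot(inherits(binned, "binned_dataset"))
  con <- tryCatch(file(path, "w"), condition = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(c(
    sprintf("# orthobin_binned_table v1"),
    sprintf("# dataset_id=%s", binned$dataset_id),
    sprintf("# species=%s", binned$species),
    sprintf("# cutoffs=%s", paste(fmt_num(binned$cutoffs), collapse = ",")),
    sprintf("# dropped_inconsistent=%s",
            paste(binned$dropped_inconsistent, collapse = ",")),
    if (length(provenance)) paste0("# ", provenance)
  ), con)
  g <- binned$genes
  writeLines(paste(c("gene_symbol", "mean_log2", "percentile", "bin",
                     "n_probes", "has_curated_accession"), collapse = "\t"), con)
  if (nrow(g) > 0L) {
    writeLines(paste(g$gene_symbol, fmt_num(g$mean_log2), fmt_num(g$percentile),
                     as.character(g$bin), g$n_probes,
                     g$has_curated_accession, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a binned dataset written by [write_binned_table()]
#'
#' @param path path to the binned table TSV.
#' @return a `binned_dataset`.
#' @export
read_binned_table <- function(path) {
  if (!file.exists(path)) format_error("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(ln) == 0L) return(NULL)
    sub(paste0("^# ", key, "="), "", ln[1L])
  }
  dataset_id <- get_field("dataset_id") %||%
    format_error("missing dataset_id header in ", path)
  species <- get_field("species") %||% "unknown"
  cutoffs <- as.numeric(strsplit(get_field("cutoffs") %||% "10,50,90", ",")[[1L]])
  dropped <- get_field("dropped_inconsistent") %||% ""
  dropped <- if (nzchar(dropped)) strsplit(dropped, ",", fixed = TRUE)[[1L]] else character(0L)

  if (length(body) < 1L) format_error("missing table header in ", path)
  cols <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  rows <- body[-1L]
  rows <- rows[nzchar(rows)]
  if (length(rows) > 0L) {
    cells <- strsplit(rows, "\t", fixed = TRUE)
    if (any(lengths(cells) != length(cols))) {
      format_error("ragged rows in binned table ", path)
    }
    df <- as.data.frame(do.call(rbind, cells), stringsAsFactors = FALSE)
    colnames(df) <- cols
    genes <- data.frame(
      gene_symbol = df$gene_symbol,
      mean_log2 = as.numeric(df$mean_log2),
      percentile = as.numeric(df$percentile),
      bin = bin_factor(df$bin),
      n_probes = as.integer(df$n_probes),
      has_curated_accession = df$has_curated_accession == "TRUE",
      stringsAsFactors = FALSE
    )
  } else {
    genes <- empty_gene_table()
  }
  binned_dataset(dataset_id, species, genes, dropped, cutoffs)
}
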