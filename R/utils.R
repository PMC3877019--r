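# Shared helpers: symbol normalization, accession patterns, bin levels,
# deterministic number formatting for text round-trips.

#' Expression bin levels, lowest to highest
#'
#' The four within-dataset expression categories: very low (`VL`, below the
#' 10th percentile), low (`L`, 10th-50th), moderate (`M`, 50th-90th) and
#' high (`H`, at or above the 90th percentile).
#' @export
BIN_LEVELS <- c("VL", "L", "M", "H")

# RefSeq-style accession: two uppercase letters, underscore, digits.
ACCESSION_PATTERN <- "^[A-Z]{2}_[0-9]+$"

#' Normalize gene symbols for cross-species matching
#'
#' Uppercases and strips surrounding whitespace so that human "ACE" and
#' mouse "Ace" compare equal. Idempotent.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalize_symbol <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Test for a curated (NM_) RefSeq accession
#'
#' @param x character vector of transcript accessions.
#' @return logical vector, `TRUE` where the accession is a curated mRNA
#'   (`NM_` prefix).
#' @export
is_curated_accession <- function(x) {
  !is.na(x) & grepl("^NM_[0-9]+$", x)
}

# Ordered factor over the four bins.
bin_factor <- function(x) {
  f <- factor(as.character(x), levels = BIN_LEVELS, ordered = TRUE)
  if (anyNA(f) && !all(is.na(x) == is.na(f))) {
    bad <- unique(setdiff(as.character(x), BIN_LEVELS))
    stop("invalid bin label(s): ", paste(bad, collapse = ", "))
  }
  f
}

# Integer rank of a bin in the total order VL < L < M < H.
bin_index <- function(x) as.integer(bin_factor(x))

# Full-precision decimal text that survives write/read round-trips exactly.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# Stable md5 of an R object via its canonical JSON serialization; used for
# provenance headers in output tables.
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null"), f)
  unname(tools::md5sum(f))
}

pkg_version <- function() {
  as.character(utils::packageVersion("orthobin"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
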