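#' Search-hit tables
#'
#' One row of a structure-search result is a "hit": the target identifier,
#' query and aligned lengths, rmsd of the superposed match, and (dialect
#' permitting) sequence identity and taxonomic lineage. Hits are carried as a
#' data frame with the columns documented in [search_hits()].
#'
#' @name search-tables
NULL

SEARCH_HIT_COLS <- c("query_id", "target_id", "query_length", "aligned_length",
                     "rmsd", "identity", "taxon_name", "tax_lineage", "kingdom",
                     "coverage", "coverage_flag")

#' Assemble a search-hit table
#'
#' @param query_id,target_id character identifiers.
#' @param query_length,aligned_length residue counts.
#' @param rmsd superposition rmsd in Angstrom.
#' @param identity optional sequence identity fraction in \[0,1\] (`NA` where
#'   the dialect does not report it).
#' @param taxon_name,tax_lineage optional taxon annotations; lineage is a
#'   semicolon-separated rank string.
#' @return data frame with one row per hit; `coverage` is
#'   `aligned_length / query_length` and `coverage_flag` marks values > 1.
#' @export
search_hits <- function(query_id, target_id, query_length, aligned_length,
                        rmsd, identity = NA_real_, taxon_name = NA_character_,
                        tax_lineage = NA_character_) {
  n <- length(target_id)
  df <- data.frame(
    query_id = rep_len(as.character(query_id), n),
    target_id = as.character(target_id),
    query_length = as.numeric(query_length),
    aligned_length = as.numeric(aligned_length),
    rmsd = as.numeric(rmsd),
    identity = rep_len(as.numeric(identity), n),
    taxon_name = rep_len(as.character(taxon_name), n),
    tax_lineage = rep_len(as.character(tax_lineage), n),
    stringsAsFactors = FALSE)
  if (any(df$rmsd < 0, na.rm = TRUE)) stop("rmsd must be >= 0")
  df$kingdom <- infer_kingdom(df$tax_lineage)
  df$coverage <- df$aligned_length / df$query_length
  df$coverage_flag <- !is.na(df$coverage) & df$coverage > 1
  df
}

empty_search_hits <- function() {
  search_hits(character(), character(), numeric(), numeric(), numeric())
}

#' Map a taxonomic lineage string to a kingdom label
#'
#' Scans the semicolon-separated ranks in order and returns the first match
#' against a fixed five-kingdom vocabulary (bacteria, fungi, metazoa, plantae,
#' protozoa); anything unmatched falls back to `"unknown"`. The mapping is
#' total by construction.
#'
#' @param lineage character vector of lineage strings.
#' @return character vector of kingdom labels.
#' @export
infer_kingdom <- function(lineage) {
  vocab <- list(
    bacteria = c("bacteria", "eubacteria"),
    fungi    = c("fungi"),
    metazoa  = c("metazoa"),
    plantae  = c("viridiplantae", "plantae", "streptophyta", "chlorophyta"),
    protozoa = c("protozoa", "amoebozoa", "apicomplexa", "euglenozoa",
                 "ciliophora", "parabasalia", "percolozoa", "discoba"))
  vapply(lineage, function(x) {
    if (is.na(x) || !nzchar(x)) return("unknown")
    ranks <- tolower(trimws(strsplit(x, ";", fixed = TRUE)[[1L]]))
    for (r in ranks) {
      for (k in names(vocab)) if (r %in% vocab[[k]]) return(k)
    }
    "unknown"
  }, character(1), USE.NAMES = FALSE)
}

#' Parse a Foldseek-style tabular result
#'
#' Expects exactly six tab-separated fields per row, in the order
#' `target, qlen, alnlen, rmsd, taxname, taxlineage`. Kingdoms are derived
#' from the lineage; rows with unparseable numeric fields are rejected with
#' their row index.
#'
#' @param path file path.
#' @param query_id identifier to record as the query.
#' @return search-hit data frame (zero rows for an empty file).
#' @export
parse_foldseek_table <- function(path, query_id = "query") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_search_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L)) {
    bad <- which(nf != 6L)[1L]
    stop(sprintf(
      "dialect error at row %d: expected 6 tab-separated fields, found %d",
      bad, nf[bad]))
  }
  m <- do.call(rbind, parts)
  num <- function(col, name) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      stop(sprintf("parse error at row %d: non-numeric %s '%s'",
                   which(is.na(v))[1L], name, m[which(is.na(v))[1L], col]))
    }
    v
  }
  search_hits(query_id = query_id, target_id = m[, 1L],
              query_length = num(2L, "qlen"), aligned_length = num(3L, "alnlen"),
              rmsd = num(4L, "rmsd"), taxon_name = m[, 5L],
              tax_lineage = m[, 6L])
}

#' Write hits in the Foldseek six-column dialect
#' @param hits search-hit data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_foldseek_table <- function(hits, path) {
  out <- data.frame(
    target = hits$target_id,
    qlen = hits$query_length,
    alnlen = hits$aligned_length,
    rmsd = hits$rmsd,
    taxname = ifelse(is.na(hits$taxon_name), "", hits$taxon_name),
    taxlineage = ifelse(is.na(hits$tax_lineage), "", hits$tax_lineage))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Parse a DALI-style summary table
#'
#' Skips blank lines and lines whose first field starts with `#`, `Job:` or
#' `Query:`. Data rows are whitespace-separated with field 1 the hit id,
#' field 2 the Z-score, field 3 the rmsd and field 4 the aligned length;
#' optional fields 5 and 6 are target length and percent identity. The query
#' length is not present in this dialect and must be supplied by the caller.
#'
#' @param path file path.
#' @param query_length residue length of the query structure.
#' @param query_id identifier to record as the query.
#' @return search-hit data frame (empty for a header-only file).
#' @export
parse_dali_table <- function(path, query_length, query_id = "query") {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(is.numeric(query_length), query_length > 0)
  lines <- readLines(path, warn = FALSE)
  keep <- vapply(lines, function(ln) {
    f1 <- sub("^\\s*", "", ln)
    nzchar(trimws(ln)) && !startsWith(f1, "#") &&
      !startsWith(f1, "Job:") && !startsWith(f1, "Query:")
  }, logical(1), USE.NAMES = FALSE)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_search_hits())
  parts <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(parts)
  if (any(nf < 4L)) {
    stop(sprintf("dialect error at row %d: expected >= 4 whitespace fields",
                 which(nf < 4L)[1L]))
  }
  get <- function(p, i) if (length(p) >= i) p[[i]] else NA_character_
  num <- function(i, name, required = TRUE) {
    raw <- vapply(parts, get, character(1), i)
    v <- suppressWarnings(as.numeric(raw))
    if (required && anyNA(v)) {
      stop(sprintf("parse error at row %d: non-numeric %s '%s'",
                   which(is.na(v))[1L], name, raw[which(is.na(v))[1L]]))
    }
    v
  }
  ident <- num(6L, "identity", required = FALSE) / 100
  search_hits(query_id = query_id,
              target_id = vapply(parts, `[[`, character(1), 1L),
              query_length = query_length,
              aligned_length = num(4L, "aligned length"),
              rmsd = num(3L, "rmsd"),
              identity = ident)
}
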