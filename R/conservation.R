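#' Remove gap-rich alignment columns
#'
#' Retains columns whose gap fraction is strictly below `max_gap_fraction`
#' (default 10%), the usual pre-filter before per-column conservation
#' statistics so that entropy is not confounded with alignment coverage.
#'
#' @param msa character alignment matrix.
#' @param max_gap_fraction columns with gap fraction `>=` this are dropped.
#' @return list with `msa` (filtered alignment, possibly zero columns, with a
#'   warning when everything is removed) and `index_map` (original column
#'   index of each retained column).
#' @export
filter_columns <- function(msa, max_gap_fraction = 0.10) {
  check_msa(msa)
  if (ncol(msa) == 0L) stop("msa has no columns")
  gf <- colMeans(msa == "-")
  keep <- which(gf < max_gap_fraction)
  if (length(keep) == 0L) warning("all columns removed by the gap filter")
  list(msa = msa[, keep, drop = FALSE], index_map = keep)
}

#' Shannon entropy of one alignment column
#'
#' `H = -sum_a p_a log2(p_a)` over the amino-acid frequencies among non-gap
#' symbols; gaps carry no probability mass. Reported in bits, so an invariant
#' column scores 0 and a uniform 20-state column scores `log2(20)`.
#'
#' @param column character vector of residues and `-` gaps.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(column) {
  res <- column[column != "-"]
  if (length(res) == 0L) stop("undefined entropy: all-gap column")
  p <- table(res) / length(res)
  -sum(p * log2(p))
}

#' Per-column conservation profile
#'
#' One record per column, in column order: gap fraction, number of non-gap
#' residues, Shannon entropy in bits, the column index in the profiled
#' alignment and (when `index_map` is given, e.g. from [filter_columns()])
#' the original column index before filtering.
#'
#' @param msa character alignment matrix.
#' @param index_map optional original indices of the columns of `msa`.
#' @return data frame: column_index, original_column_index, gap_fraction,
#'   n_effective, entropy.
#' @export
entropy_profile <- function(msa, index_map = NULL) {
  check_msa(msa)
  nc <- ncol(msa)
  if (is.null(index_map)) index_map <- seq_len(nc)
  stopifnot(length(index_map) == nc)
  ent <- vapply(seq_len(nc), function(j) {
    tryCatch(shannon_entropy(msa[, j]),
             error = function(e) stop("column ", index_map[j], ": ",
                                      conditionMessage(e)))
  }, numeric(1))
  data.frame(column_index = seq_len(nc),
             original_column_index = as.integer(index_map),
             gap_fraction = colMeans(msa == "-"),
             n_effective = colSums(msa != "-"),
             entropy = ent)
}

#' Select low-entropy (core candidate) positions
#'
#' Either all columns with entropy at or below a numeric threshold, or the
#' `k` columns with the smallest entropy (ties broken deterministically by
#' lower original column index). Indices are returned on the original
#' (pre-filter) column numbering.
#'
#' @param profile output of [entropy_profile()].
#' @param mode `"bottom_k"` or `"threshold"`.
#' @param value `k` for bottom-k, the entropy cutoff for threshold mode.
#' @return sorted integer vector of original column indices.
#' @export
low_entropy_positions <- function(profile, mode = c("bottom_k", "threshold"),
                                  value) {
  mode <- match.arg(mode)
  if (nrow(profile) == 0L) stop("empty profile")
  if (mode == "threshold") {
    return(sort(profile$original_column_index[profile$entropy <= value]))
  }
  k <- as.integer(value)
  if (k > nrow(profile)) stop("k exceeds the number of columns")
  ord <- order(profile$entropy, profile$original_column_index)
  sort(profile$original_column_index[ord[seq_len(k)]])
}

#' Extract a sub-alignment at selected columns
#'
#' @param msa character alignment matrix.
#' @param positions column indices into `msa` (returned columns are in
#'   ascending index order; row labels preserved).
#' @return alignment matrix of the selected columns; zero-width input is
#'   allowed and flagged with a warning.
#' @export
extract_subalignment <- function(msa, positions) {
  check_msa(msa)
  positions <- sort(unique(as.integer(positions)))
  if (any(positions < 1L) || any(positions > ncol(msa))) {
    stop("position out of range 1..", ncol(msa))
  }
  if (length(positions) == 0L) warning("empty position set: zero-width alignment")
  msa[, positions, drop = FALSE]
}

#' Write a conservation profile as a tab-separated table
#' @param profile output of [entropy_profile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_entropy_profile <- function(profile, path) {
  utils::write.table(
    profile[, c("original_column_index", "gap_fraction", "n_effective",
                "entropy")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
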