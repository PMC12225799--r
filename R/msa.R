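#' Build an alignment matrix from gapped sequence strings
#'
#' Alignments are represented as character matrices: one row per taxon (row
#' names are the taxon labels), one column per alignment column, each cell a
#' single residue code or the gap symbol `-`.
#'
#' @param seqs named character vector of equal-length gapped sequences.
#' @return character matrix with row names.
#' @export
msa_from_strings <- function(seqs) {
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    stop("all sequences must be labeled")
  }
  if (anyDuplicated(names(seqs))) stop("duplicate sequence labels")
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L) {
    stop("ragged alignment: sequence lengths differ (",
         paste(range(widths), collapse = "-"), ")")
  }
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

#' Collapse an alignment matrix back to gapped strings
#' @param msa character matrix as produced by [msa_from_strings()].
#' @return named character vector.
#' @export
msa_to_strings <- function(msa) {
  stats::setNames(apply(msa, 1L, paste0, collapse = ""), rownames(msa))
}

check_msa <- function(msa) {
  if (!is.matrix(msa) || !is.character(msa)) stop("msa must be a character matrix")
  if (is.null(rownames(msa)) || anyDuplicated(rownames(msa))) {
    stop("msa rows must carry unique taxon labels")
  }
  invisible(msa)
}

#' Read an aligned FASTA file
#'
#' Thin wrapper over `Biostrings::readAAStringSet` that enforces the
#' alignment contract: equal row lengths and unique labels.
#'
#' @param path FASTA file path.
#' @return character alignment matrix.
#' @export
read_fasta_msa <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no sequences in ", path)
  labels <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(labels)) stop("duplicate labels in ", path)
  widths <- Biostrings::width(set)
  if (length(unique(widths)) > 1L) {
    stop("ragged alignment in ", path, ": widths ",
         paste(sort(unique(widths)), collapse = ", "))
  }
  msa_from_strings(stats::setNames(as.character(set), labels))
}

#' Write an alignment matrix as aligned FASTA
#' @param msa character alignment matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_msa <- function(msa, path) {
  check_msa(msa)
  seqs <- msa_to_strings(msa)
  set <- Biostrings::AAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
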