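#' Construct a Calpha structure record
#'
#' A `structure_record` is the unit of superposition: one chain reduced to its
#' Calpha trace, with residue numbers carried verbatim from the source so that
#' records with deleted residues can still be paired by number.
#'
#' @param id character identifier for the chain/protein.
#' @param resno integer residue numbers (as in the source file), one per
#'   residue, strictly ordered as encountered.
#' @param aa one-letter amino-acid codes, same length as `resno`.
#' @param xyz numeric matrix with one row per residue and columns x, y, z in
#'   Angstrom.
#' @return object of class `structure_record`.
#' @export
structure_record <- function(id, resno, aa, xyz) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  n <- nrow(xyz)
  resno <- as.integer(resno)
  aa <- as.character(aa)
  if (length(resno) != n || length(aa) != n) {
    stop("resno, aa and xyz must describe the same number of residues")
  }
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  colnames(xyz) <- c("x", "y", "z")
  structure(list(id = as.character(id), resno = resno, aa = aa, xyz = xyz),
            class = "structure_record")
}

#' @export
length.structure_record <- function(x) nrow(x$xyz)

#' @export
print.structure_record <- function(x, ...) {
  cat(sprintf("<structure_record '%s': %d Calpha residues>\n", x$id, length(x)))
  invisible(x)
}

#' Read a Calpha trace from a PDB-format file
#'
#' Parses ATOM records only (HETATM is skipped), keeps Calpha atoms with a
#' blank or 'A' alternate-location indicator, and returns the first chain
#' encountered unless `chain` names one explicitly. Residue numbers are taken
#' verbatim from the record.
#'
#' @param path path to a PDB-format file.
#' @param chain optional single chain identifier; default: first chain seen.
#' @param id identifier for the returned record; default: file base name.
#' @return a [structure_record()].
#' @export
read_structure <- function(path, chain = NULL, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "ATOM\t")
  if (!any(is_atom)) stop("no ATOM records in ", path)
  idx <- which(is_atom)
  fields <- lapply(idx, function(i) {
    ln <- lines[[i]]
    if (nchar(ln) < 54L) {
      stop(sprintf("parse error at line %d: ATOM record shorter than 54 columns", i))
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz))) {
      stop(sprintf("parse error at line %d: malformed coordinate field", i))
    }
    list(atom = trimws(substr(ln, 13, 16)),
         alt = substr(ln, 17, 17),
         res3 = trimws(substr(ln, 18, 20)),
         chain = substr(ln, 22, 22),
         resno = suppressWarnings(as.integer(trimws(substr(ln, 23, 26)))),
         xyz = xyz,
         line = i)
  })
  keep <- vapply(fields, function(f) {
    f$atom == "CA" && f$alt %in% c(" ", "A") && !is.na(f$resno)
  }, logical(1))
  fields <- fields[keep]
  if (length(fields) == 0L) stop("no Calpha ATOM records in ", path)
  chains <- vapply(fields, `[[`, character(1), "chain")
  use_chain <- if (is.null(chain)) chains[[1L]] else as.character(chain)
  fields <- fields[chains == use_chain]
  if (length(fields) == 0L) stop("no Calpha records for chain '", use_chain, "' in ", path)
  structure_record(
    id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id,
    resno = vapply(fields, `[[`, integer(1), "resno"),
    aa = aa_to_one(vapply(fields, `[[`, character(1), "res3")),
    xyz = do.call(rbind, lapply(fields, `[[`, "xyz")))
}

#' Write a Calpha trace as PDB-format ATOM records
#'
#' @param x a [structure_record()].
#' @param path output file path.
#' @param chain chain identifier to emit (single character), default "A".
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path, chain = "A") {
  stopifnot(inherits(x, "structure_record"))
  n <- length(x)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), aa_to_three(x$aa), substr(chain, 1, 1), x$resno,
    x$xyz[, 1], x$xyz[, 2], x$xyz[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# Restrict two records to their shared residue numbers, returning paired
# coordinate matrices (used for rmsd between family members that may have
# different residues deleted).
pair_by_resno <- function(a, b) {
  shared <- intersect(a$resno, b$resno)
  list(a = a$xyz[match(shared, a$resno), , drop = FALSE],
       b = b$xyz[match(shared, b$resno), , drop = FALSE],
       resno = shared)
}
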