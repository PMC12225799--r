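#' Domain architecture of a protein
#'
#' An ordered list of named domain intervals along one chain; the unit of
#' novelty classification. Intervals are 1-based inclusive, must not overlap,
#' and are stored sorted by start position so the signature reflects sequence
#' order regardless of input order.
#'
#' @param protein_id identifier.
#' @param names domain names (non-empty strings).
#' @param start,end 1-based inclusive interval bounds.
#' @return object of class `domain_architecture`.
#' @export
domain_architecture <- function(protein_id, names, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  names <- as.character(names)
  if (any(!nzchar(names))) stop("domain names must be non-empty")
  if (length(names) != length(start) || length(start) != length(end)) {
    stop("names, start and end must have equal length")
  }
  if (any(start > end)) stop("interval start must be <= end")
  o <- order(start)
  start <- start[o]; end <- end[o]; names <- names[o]
  if (length(start) > 1L && any(start[-1L] <= end[-length(end)])) {
    stop("domain intervals must not overlap")
  }
  structure(list(protein_id = as.character(protein_id),
                 domains = data.frame(name = names, start = start, end = end,
                                      stringsAsFactors = FALSE)),
            class = "domain_architecture")
}

#' @export
print.domain_architecture <- function(x, ...) {
  cat(sprintf("<architecture '%s': %s>\n", x$protein_id,
              paste(sprintf("%s(%d-%d)", x$domains$name, x$domains$start,
                            x$domains$end), collapse = " + ")))
  invisible(x)
}

#' Architecture signature: ordered domain-name tuple
#'
#' The equality key for "distinct domain architecture": domain names in
#' sequence order, positions discarded.
#'
#' @param arch a [domain_architecture()].
#' @return character vector of domain names.
#' @export
architecture_signature <- function(arch) {
  stopifnot(inherits(arch, "domain_architecture"))
  arch$domains$name
}

#' Reference catalog of solved structures and their architectures
#'
#' Each entry pairs the architecture of a deposited structure with the
#' architecture of the corresponding full-length protein, so that the
#' category-2 test ("the extra domain is known, but its full-length protein
#' lacks the trefoil") can be evaluated.
#'
#' @param entries named list; each element a list with elements
#'   `architecture` and `full_length_architecture`, both
#'   [domain_architecture()] objects (`full_length_architecture` defaults to
#'   `architecture` when absent).
#' @return object of class `architecture_catalog`.
#' @export
architecture_catalog <- function(entries = list()) {
  if (length(entries) > 0L && is.null(names(entries))) {
    stop("catalog entries must be named by structure id")
  }
  entries <- lapply(entries, function(e) {
    stopifnot(inherits(e$architecture, "domain_architecture"))
    if (is.null(e$full_length_architecture)) {
      e$full_length_architecture <- e$architecture
    }
    stopifnot(inherits(e$full_length_architecture, "domain_architecture"))
    e
  })
  structure(list(entries = entries), class = "architecture_catalog")
}

catalog_signatures <- function(catalog) {
  vapply(catalog$entries, function(e) {
    paste(architecture_signature(e$architecture), collapse = "|")
  }, character(1))
}

#' Classify a trefoil-containing protein into a novelty category
#'
#' Categories for a trefoil protein with at least one extra domain:
#' category 1 — the extra domain appears in no catalog structure (its
#' structure is not experimentally determined); category 2 — the extra
#' domain is in the catalog, but no catalog protein containing it carries the
#' trefoil even in its full-length architecture; category 3 — some catalog
#' entry holds both the extra domain and the trefoil. A protein whose whole
#' signature already exists in the catalog, or that carries no extra domain,
#' is `"known"`. Proteins with several extra domains take the minimum
#' category over the extras (the most novel wins); the per-domain verdicts
#' are reported alongside.
#'
#' @param arch a [domain_architecture()]; must contain `trefoil_name`.
#' @param trefoil_name the name under which the trefoil domain is annotated.
#' @param catalog an [architecture_catalog()].
#' @return list with `category` (`"1"`, `"2"`, `"3"` or `"known"`) and
#'   `per_domain` (data frame: domain, category).
#' @export
classify_category <- function(arch, trefoil_name, catalog) {
  stopifnot(inherits(arch, "domain_architecture"),
            inherits(catalog, "architecture_catalog"))
  sig <- architecture_signature(arch)
  if (!(trefoil_name %in% sig)) {
    stop("precondition violated: architecture of '", arch$protein_id,
         "' lacks the trefoil domain '", trefoil_name, "'")
  }
  if (paste(sig, collapse = "|") %in% catalog_signatures(catalog)) {
    return(list(category = "known",
                per_domain = data.frame(domain = character(0),
                                        category = character(0))))
  }
  extras <- setdiff(unique(sig), trefoil_name)
  if (length(extras) == 0L) {
    return(list(category = "known",
                per_domain = data.frame(domain = character(0),
                                        category = character(0))))
  }
  per <- vapply(extras, function(d) {
    holders <- Filter(function(e) d %in% architecture_signature(e$architecture),
                      catalog$entries)
    if (length(holders) == 0L) return("1")
    with_tref <- vapply(holders, function(e) {
      trefoil_name %in% architecture_signature(e$architecture) ||
        trefoil_name %in% architecture_signature(e$full_length_architecture)
    }, logical(1))
    if (any(with_tref)) "3" else "2"
  }, character(1))
  list(category = as.character(min(as.integer(per))),
       per_domain = data.frame(domain = extras, category = unname(per)))
}

#' Find trefoil proteins with architectures absent from the catalog
#'
#' Returns every trefoil-containing protein whose signature matches no
#' catalog signature, with its novelty category, in deterministic order
#' (by signature, then protein id). Proteins without the trefoil domain are
#' ignored.
#'
#' @param archs list of [domain_architecture()] objects.
#' @param catalog an [architecture_catalog()].
#' @param trefoil_name trefoil domain name.
#' @return data frame: protein_id, signature (|-joined), category.
#' @export
find_novel_architectures <- function(archs, catalog, trefoil_name = "trefoil") {
  known_sigs <- catalog_signatures(catalog)
  rows <- lapply(archs, function(a) {
    sig <- architecture_signature(a)
    if (!(trefoil_name %in% sig)) return(NULL)
    key <- paste(sig, collapse = "|")
    if (key %in% known_sigs) return(NULL)
    data.frame(protein_id = a$protein_id, signature = key,
               category = classify_category(a, trefoil_name, catalog)$category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(protein_id = character(0), signature = character(0),
                      category = character(0)))
  }
  out[order(out$signature, out$protein_id), , drop = FALSE]
}

#' Read domain annotations from a tab-separated table
#'
#' Expected columns: `protein_id`, `domain_name`, `start`, `end`, optionally
#' `full_length` (0/1). Without the flag column the result is a named list of
#' architectures; with it, an [architecture_catalog()] where flagged rows
#' form each entry's full-length architecture.
#'
#' @param path file path.
#' @return named list of [domain_architecture()] or an
#'   [architecture_catalog()].
#' @export
read_architecture_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("protein_id", "domain_name", "start", "end")
  if (!all(need %in% names(df))) {
    stop("architecture table must have columns ", paste(need, collapse = ", "))
  }
  build <- function(sub, id) {
    domain_architecture(id, sub$domain_name, sub$start, sub$end)
  }
  if (!"full_length" %in% names(df)) {
    archs <- lapply(split(df, df$protein_id), function(sub) {
      build(sub, sub$protein_id[[1L]])
    })
    return(archs)
  }
  entries <- lapply(split(df, df$protein_id), function(sub) {
    core <- sub[sub$full_length == 0, , drop = FALSE]
    full <- sub[sub$full_length == 1, , drop = FALSE]
    id <- sub$protein_id[[1L]]
    list(architecture = build(core, id),
         full_length_architecture = if (nrow(full) > 0L) {
           build(full, paste0(id, "_fl"))
         } else build(core, id))
  })
  architecture_catalog(entries)
}

#' Write domain annotations as a tab-separated table
#' @param archs named list of [domain_architecture()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_architecture_table <- function(archs, path) {
  rows <- lapply(archs, function(a) {
    data.frame(protein_id = a$protein_id, domain_name = a$domains$name,
               start = a$domains$start, end = a$domains$end)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
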