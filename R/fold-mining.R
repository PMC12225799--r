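#' Filtering presets for structure-search hits
#'
#' The two survey iterations use fixed thresholds: the first (PDB-wide, to
#' suppress false positives) keeps hits with rmsd strictly below 2 A and
#' query coverage of at least 80%; the second (AlphaFold-database, relaxed
#' after the first round proved too stringent) keeps rmsd strictly below 3 A
#' and coverage of at least 30%. Rmsd is compared strictly, coverage
#' inclusively, matching the operational filter commands the thresholds come
#' from.
#'
#' @param name `"iteration1"`, `"iteration2"` or `"custom"`.
#' @param rmsd_max,coverage_min thresholds; required for `"custom"`, fixed
#'   for the named presets.
#' @return object of class `filter_preset`.
#' @export
filter_preset <- function(name = c("iteration1", "iteration2", "custom"),
                          rmsd_max = NULL, coverage_min = NULL) {
  name <- match.arg(name)
  if (name == "iteration1") {
    rmsd_max <- 2.0; coverage_min <- 0.80
  } else if (name == "iteration2") {
    rmsd_max <- 3.0; coverage_min <- 0.30
  } else if (is.null(rmsd_max) || is.null(coverage_min)) {
    stop("custom preset requires rmsd_max and coverage_min")
  }
  stopifnot(rmsd_max > 0, coverage_min > 0, coverage_min <= 1)
  structure(list(name = name, rmsd_max = rmsd_max, coverage_min = coverage_min),
            class = "filter_preset")
}

#' Filter a search-hit table against a preset
#'
#' Keeps a hit iff `rmsd < rmsd_max` and
#' `aligned_length / query_length >= coverage_min`. Rows with a
#' non-positive query length are a data error: they are rejected and counted
#' separately rather than aborting the run.
#'
#' @param hits search-hit data frame (see [search_hits()]).
#' @param preset a [filter_preset()] or a preset name.
#' @return list with `kept` and `rejected` hit tables and a `report` list
#'   (`n_input`, `n_kept`, `n_rejected`, and a `reasons` count vector over
#'   rmsd / coverage / rmsd+coverage / bad_query_length).
#' @export
filter_hits <- function(hits, preset) {
  if (is.character(preset)) preset <- filter_preset(preset)
  stopifnot(inherits(preset, "filter_preset"))
  n <- nrow(hits)
  bad_q <- !is.finite(hits$query_length) | hits$query_length <= 0
  coverage <- ifelse(bad_q, NA_real_, hits$aligned_length / hits$query_length)
  ok_rmsd <- hits$rmsd < preset$rmsd_max
  ok_cov <- !is.na(coverage) & coverage >= preset$coverage_min
  keep <- !bad_q & ok_rmsd & ok_cov
  reason <- rep(NA_character_, n)
  reason[bad_q] <- "bad_query_length"
  reason[!bad_q & !ok_rmsd & ok_cov] <- "rmsd"
  reason[!bad_q & ok_rmsd & !ok_cov] <- "coverage"
  reason[!bad_q & !ok_rmsd & !ok_cov] <- "rmsd+coverage"
  list(kept = hits[keep, , drop = FALSE],
       rejected = hits[!keep, , drop = FALSE],
       report = list(
         n_input = n, n_kept = sum(keep), n_rejected = sum(!keep),
         preset = preset$name,
         reasons = table(factor(reason[!keep],
                                levels = c("rmsd", "coverage", "rmsd+coverage",
                                           "bad_query_length")))))
}

#' Kingdom-diversity summary of a hit table
#'
#' For each coverage bin (default: coverage >= 80% and >= 30%), counts the
#' hits in the bin and reports, among hits from kingdoms other than the
#' query's, the percentage contributed by each of the five kingdoms.
#' Hits with an unknown kingdom are counted separately and excluded from the
#' percentages.
#'
#' @param hits search-hit data frame.
#' @param query_kingdom the query's own kingdom (excluded from percentages).
#' @param coverage_bins numeric vector of minimum-coverage thresholds.
#' @return data frame with one row per bin: `bin_min_coverage`, `n_hits`,
#'   `n_other_kingdom`, `n_unknown`, and `pct_<kingdom>` columns summing to
#'   100 (up to rounding) whenever any non-query-kingdom hits exist.
#' @export
kingdom_summary <- function(hits, query_kingdom,
                            coverage_bins = c(0.80, 0.30)) {
  kingdoms <- c("bacteria", "fungi", "metazoa", "plantae", "protozoa")
  rows <- lapply(coverage_bins, function(cmin) {
    sel <- hits[!is.na(hits$coverage) & hits$coverage >= cmin, , drop = FALSE]
    other <- sel[sel$kingdom != query_kingdom & sel$kingdom != "unknown", ,
                 drop = FALSE]
    pct <- if (nrow(other) == 0L) {
      stats::setNames(rep(0, length(kingdoms)), kingdoms)
    } else {
      100 * table(factor(other$kingdom, levels = kingdoms)) / nrow(other)
    }
    out <- data.frame(bin_min_coverage = cmin, n_hits = nrow(sel),
                      n_other_kingdom = nrow(other),
                      n_unknown = sum(sel$kingdom == "unknown"))
    for (k in kingdoms) out[[paste0("pct_", k)]] <- as.numeric(pct[[k]])
    out
  })
  do.call(rbind, rows)
}

#' Render a kingdom summary with "None" for empty cells
#' @param summary output of [kingdom_summary()].
#' @return character matrix suitable for printing.
#' @export
format_kingdom_summary <- function(summary) {
  pct_cols <- grep("^pct_", names(summary), value = TRUE)
  out <- as.matrix(format(summary, digits = 3))
  for (cc in pct_cols) {
    out[, cc] <- ifelse(summary[[cc]] == 0, "None",
                        sprintf("%.1f%%", summary[[cc]]))
  }
  out
}

#' Rmsd-versus-identity profile of a hit set
#'
#' Computes the Spearman rank correlation between pairwise rmsd and sequence
#' identity (the inverse coupling expected when predicted structures degrade
#' smoothly with divergence) and detects "steps": contiguous identity bands
#' whose occupancy exceeds a density threshold, the signature of discrete
#' taxonomic layers in the hit set.
#'
#' @param pairs data frame with numeric columns `rmsd` and `identity`
#'   (identity as a fraction in \[0,1\]).
#' @param band_width identity band width (default 0.05, i.e. 5 percentage
#'   points).
#' @param density_threshold minimum count for a band to be a step; default
#'   twice the mean occupancy of an even spread.
#' @return list with `scatter` (the input rows), `spearman_rho` (`NA` and
#'   `rho_defined = FALSE` with fewer than 3 pairs or zero variance) and
#'   `step_segments` (data frame: identity_lo, identity_hi, n).
#' @export
rmsd_identity_profile <- function(pairs, band_width = 0.05,
                                  density_threshold = NULL) {
  stopifnot(all(c("rmsd", "identity") %in% names(pairs)))
  n <- nrow(pairs)
  rho <- NA_real_; defined <- FALSE
  if (n >= 3L && stats::sd(pairs$rmsd) > 0 && stats::sd(pairs$identity) > 0) {
    rho <- stats::cor(pairs$rmsd, pairs$identity, method = "spearman")
    defined <- is.finite(rho)
  }
  breaks <- seq(0, 1, by = band_width)
  if (max(pairs$identity, -Inf) > 1) breaks <- c(breaks, max(pairs$identity))
  counts <- if (n > 0) {
    table(cut(pairs$identity, breaks, include.lowest = TRUE, right = FALSE))
  } else table(factor(levels = levels(cut(numeric(0), breaks))))
  if (is.null(density_threshold)) {
    density_threshold <- max(2, 2 * n / length(counts))
  }
  steps <- which(as.integer(counts) >= density_threshold)
  step_segments <- data.frame(identity_lo = breaks[steps],
                              identity_hi = breaks[steps + 1L],
                              n = as.integer(counts)[steps])
  list(scatter = pairs, spearman_rho = rho, rho_defined = defined,
       step_segments = step_segments)
}

#' Pairwise rmsd and identity table for a structure family
#'
#' Builds the input of [rmsd_identity_profile()] from a family of Calpha
#' records and their alignment: for every sampled pair of members, the
#' Kabsch rmsd over shared residue numbers and the sequence identity
#' (1 minus p-distance) from the alignment.
#'
#' @param structures named list of [structure_record()]s.
#' @param msa character alignment matrix whose rows cover the structure ids.
#' @param step take every `step`-th pair (pair subsampling for large
#'   families; default 1 = all pairs).
#' @return data frame: id_a, id_b, rmsd, identity.
#' @export
rmsd_identity_pairs <- function(structures, msa, step = 1L) {
  ids <- vapply(structures, `[[`, character(1), "id")
  stopifnot(all(ids %in% rownames(msa)), length(ids) >= 2L)
  d <- p_distance(msa[ids, , drop = FALSE])
  pairs <- t(utils::combn(length(ids), 2L))
  pairs <- pairs[seq(1L, nrow(pairs), by = step), , drop = FALSE]
  rmsd <- apply(pairs, 1L, function(ij) {
    p <- pair_by_resno(structures[[ij[1L]]], structures[[ij[2L]]])
    suppressWarnings(kabsch(p$a, p$b))$rmsd
  })
  data.frame(id_a = ids[pairs[, 1L]], id_b = ids[pairs[, 2L]],
             rmsd = rmsd, identity = 1 - d[pairs])
}

#' Select one representative hit per distinct domain architecture
#'
#' Groups hits by architecture signature and keeps, per signature, the hit
#' with the lowest rmsd (ties broken by lexicographically smallest target
#' id). Hits without an architecture entry are skipped and listed.
#'
#' @param hits search-hit data frame.
#' @param architectures named list of [domain_architecture()] keyed by
#'   target id.
#' @return list with `ids` (representative target ids, ordered by signature)
#'   and `missing` (target ids lacking an architecture entry).
#' @export
select_representatives <- function(hits, architectures) {
  have <- hits$target_id %in% names(architectures)
  missing <- unique(hits$target_id[!have])
  hits <- hits[have, , drop = FALSE]
  if (nrow(hits) == 0L) return(list(ids = character(0), missing = missing))
  sig <- vapply(hits$target_id, function(id) {
    paste(architecture_signature(architectures[[id]]), collapse = "|")
  }, character(1))
  reps <- vapply(split(seq_len(nrow(hits)), sig), function(ix) {
    sub <- hits[ix, , drop = FALSE]
    sub$target_id[order(sub$rmsd, sub$target_id)][1L]
  }, character(1))
  list(ids = unname(reps[order(names(reps))]), missing = missing)
}
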