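#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end demo run. The defaults mirror the
#' survey's operating points: 2 A / 80% coverage for the first filtering
#' iteration, 3 A / 30% for the second, a 10% column gap filter, bottom-9
#' low-entropy candidates with a 7-position core, and k = 4 clade cuts for
#' the purity comparison.
#'
#' @param seed mandatory integer seed for every stochastic stage.
#' @param out_dir output directory (created if missing).
#' @param n_taxa,n_columns family size and alignment width.
#' @param core_signal planted-core wiring, see [simulation_config()].
#' @param n_search_hits rows per synthetic search table.
#' @param reference_id reference structure id for the star alignment.
#' @param msa_coverage_floor exclusion floor for the star alignment.
#' @param max_gap_fraction column gap filter threshold.
#' @param bottom_k,core_k low-entropy candidate count and core size.
#' @param purity_k number of groups for the clade-purity cut.
#' @param n_msa_structures number of family members carried into the
#'   structure-based alignment stage (the stage is quadratic in chain length
#'   per member; the remaining members still flow through the sequence-level
#'   stages).
#' @param stages character vector of stage names to run (default: all).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, out_dir,
                            n_taxa = 64L, n_columns = 150L,
                            core_signal = "function",
                            n_search_hits = 500L,
                            reference_id = "template",
                            msa_coverage_floor = 0.5,
                            max_gap_fraction = 0.10,
                            bottom_k = 9L, core_k = 7L, purity_k = 4L,
                            n_msa_structures = 16L,
                            stages = c("simulate", "search", "filter",
                                       "represent", "classify", "align",
                                       "entropy", "tree", "purity")) {
  if (missing(seed)) stop("seed is mandatory")
  if (missing(out_dir)) stop("out_dir is required")
  stopifnot(bottom_k >= core_k, purity_k >= 2L)
  if ("align" %in% stages && (is.null(reference_id) || !nzchar(reference_id))) {
    stop("validation error: the align stage requires a reference_id")
  }
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_taxa = as.integer(n_taxa), n_columns = as.integer(n_columns),
                 core_signal = core_signal,
                 n_search_hits = as.integer(n_search_hits),
                 reference_id = reference_id,
                 msa_coverage_floor = msa_coverage_floor,
                 max_gap_fraction = max_gap_fraction,
                 bottom_k = as.integer(bottom_k), core_k = as.integer(core_k),
                 purity_k = as.integer(purity_k),
                 n_msa_structures = as.integer(n_msa_structures),
                 stages = stages),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat keys matching the arguments of [pipeline_config()]; `seed` is
#' mandatory in the file or as an override.
#'
#' @param path YAML file path.
#' @param ... overrides passed to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

log_stage <- function(log_path, stage, ...) {
  entry <- c(list(stage = stage), list(...))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      file = log_path, append = TRUE, sep = "")
  message(sprintf("[%s] %s", stage,
                  paste(names(entry[-1L]), unlist(lapply(entry[-1L], paste,
                                                         collapse = ",")),
                        sep = "=", collapse = " ")))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Executes, in order: family simulation; synthetic search tables; both
#' filtering iterations; representative selection; architecture
#' classification; reference-based structural alignment; column gap
#' filtering and entropy profiling; core-position extraction; neighbor-
#' joining trees on the full filtered and core-only alignments; and the
#' function-versus-kingdom clade-purity comparison. Every stage writes its
#' artifact under `config$out_dir` plus one JSON log line; a rerun with the
#' same config and seed is bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of per-stage reports.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.jsonl")
  if (file.exists(log_path)) file.remove(log_path)
  on <- function(s) s %in% config$stages
  report <- list()
  fail <- function(stage, e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }

  # simulate -----------------------------------------------------------
  family <- NULL
  if (on("simulate")) {
    tryCatch({
      cfg <- simulation_config(seed = config$seed, n_taxa = config$n_taxa,
                               n_columns = config$n_columns,
                               core_signal = config$core_signal)
      template <- make_template_structure(config$n_columns,
                                          derive_seed(config$seed, 1L))
      family <- evolve_family(template, cfg)
      family$template <- template
      write_structure(template, file.path(config$out_dir, "template.pdb"))
      sdir <- file.path(config$out_dir, "structures")
      dir.create(sdir, showWarnings = FALSE)
      for (s in family$structures) {
        write_structure(s, file.path(sdir, paste0(s$id, ".pdb")))
      }
      write_fasta_msa(family$msa, file.path(config$out_dir, "family_msa.fasta"))
      write_newick(family$truth$true_tree,
                   file.path(config$out_dir, "true_tree.nwk"))
      utils::write.table(
        data.frame(taxon = names(family$truth$function_label),
                   func = unname(family$truth$function_label),
                   kingdom = unname(family$truth$kingdom_label)),
        file.path(config$out_dir, "labels.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      report$simulate <- list(n_taxa = config$n_taxa,
                              core = family$truth$core_positions)
      log_stage(log_path, "simulate", n_taxa = config$n_taxa,
                n_columns = config$n_columns,
                core_positions = family$truth$core_positions)
    }, error = function(e) fail("simulate", e))
  }

  # search + filter ----------------------------------------------------
  if (on("search")) {
    tryCatch({
      for (preset in c("iteration1", "iteration2")) {
        st <- make_search_table(config$n_search_hits, preset,
                                derive_seed(config$seed, match(preset, c(
                                  "iteration1", "iteration2"))))
        tab_path <- file.path(config$out_dir, paste0("search_", preset, ".tsv"))
        write_foldseek_table(st$hits, tab_path)
        write_truth_sidecar(st$truth, st$hits,
                            file.path(config$out_dir,
                                      paste0("search_", preset, "_truth.tsv")))
        log_stage(log_path, "search", preset = preset, n_hits = nrow(st$hits))
        if (on("filter")) {
          hits <- parse_foldseek_table(tab_path, query_id = "synthetic_query")
          fl <- filter_hits(hits, preset)
          write_foldseek_table(fl$kept,
                               file.path(config$out_dir,
                                         paste0("filtered_", preset, ".tsv")))
          agree <- mean(seq_len(nrow(hits)) %in%
                          match(fl$kept$target_id, hits$target_id) ==
                          st$truth$pass_label)
          report[[paste0("filter_", preset)]] <- c(fl$report,
                                                   truth_agreement = agree)
          log_stage(log_path, "filter", preset = preset,
                    n_input = fl$report$n_input, n_kept = fl$report$n_kept,
                    n_rejected = fl$report$n_rejected,
                    truth_agreement = agree)
        }
      }
    }, error = function(e) fail("search/filter", e))
  }

  # representatives + classification -----------------------------------
  if (on("represent") || on("classify")) {
    tryCatch({
      fx <- make_architecture_fixtures(derive_seed(config$seed, 5L))
      if (on("classify")) {
        novel <- find_novel_architectures(fx$architectures, fx$catalog)
        utils::write.table(novel,
                           file.path(config$out_dir, "novel_architectures.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        report$classify <- novel
        log_stage(log_path, "classify", n_input = length(fx$architectures),
                  n_novel = nrow(novel))
      }
      if (on("represent")) {
        ids <- names(fx$architectures)
        rep_hits <- search_hits(query_id = "q", target_id = ids,
                                query_length = 150,
                                aligned_length = 140,
                                rmsd = seq(0.5, by = 0.1,
                                           length.out = length(ids)))
        reps <- select_representatives(rep_hits, fx$architectures)
        writeLines(reps$ids,
                   file.path(config$out_dir, "representatives.txt"))
        report$represent <- reps
        log_stage(log_path, "represent", n_input = length(ids),
                  n_representatives = length(reps$ids))
      }
    }, error = function(e) fail("represent/classify", e))
  }

  # structural alignment ------------------------------------------------
  struct_msa <- NULL
  if (on("align")) {
    tryCatch({
      if (is.null(family)) stop("align stage requires the simulate stage")
      subset <- family$structures[seq_len(min(config$n_msa_structures,
                                              length(family$structures)))]
      sm <- reference_msa(c(list(family$template), unname(subset)),
                          reference_id = config$reference_id,
                          coverage_floor = config$msa_coverage_floor)
      struct_msa <- sm$msa
      write_fasta_msa(struct_msa,
                      file.path(config$out_dir, "structure_msa.fasta"))
      utils::write.table(sm$report,
                         file.path(config$out_dir, "structure_msa_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$align <- sm$report
      log_stage(log_path, "align", n_structures = length(subset) + 1L,
                n_included = sum(sm$report$included),
                width = ncol(struct_msa))
    }, error = function(e) fail("align", e))
  }

  # conservation ---------------------------------------------------------
  core_sel <- NULL; filtered <- NULL
  if (on("entropy")) {
    tryCatch({
      if (is.null(family)) stop("entropy stage requires the simulate stage")
      filtered <- filter_columns(family$msa, config$max_gap_fraction)
      prof <- entropy_profile(filtered$msa, filtered$index_map)
      write_entropy_profile(prof,
                            file.path(config$out_dir, "entropy_profile.tsv"))
      cand <- low_entropy_positions(prof, "bottom_k", config$bottom_k)
      prof_cand <- prof[prof$original_column_index %in% cand, , drop = FALSE]
      core_sel <- low_entropy_positions(prof_cand, "bottom_k", config$core_k)
      writeLines(as.character(core_sel),
                 file.path(config$out_dir, "core_positions.txt"))
      report$entropy <- list(n_columns_kept = nrow(prof),
                             candidates = cand, core = core_sel)
      log_stage(log_path, "entropy", n_input_columns = ncol(family$msa),
                n_kept_columns = nrow(prof),
                n_candidates = length(cand), n_core = length(core_sel))
    }, error = function(e) fail("entropy", e))
  }

  # trees + purity -------------------------------------------------------
  if (on("tree")) {
    tryCatch({
      if (is.null(filtered)) stop("tree stage requires the entropy stage")
      full_tree <- neighbor_joining(p_distance(filtered$msa))
      core_msa <- extract_subalignment(family$msa, core_sel)
      core_tree <- neighbor_joining(p_distance(core_msa))
      write_newick(full_tree, file.path(config$out_dir, "tree_full.nwk"))
      write_newick(core_tree, file.path(config$out_dir, "tree_core.nwk"))
      log_stage(log_path, "tree", full_width = ncol(filtered$msa),
                core_width = ncol(core_msa))
      if (on("purity")) {
        pur <- data.frame(
          tree = rep(c("core", "full"), each = 2L),
          label_set = rep(c("function", "kingdom"), 2L),
          k = config$purity_k,
          purity = c(
            clade_purity(core_tree, family$truth$function_label, config$purity_k),
            clade_purity(core_tree, family$truth$kingdom_label, config$purity_k),
            clade_purity(full_tree, family$truth$function_label, config$purity_k),
            clade_purity(full_tree, family$truth$kingdom_label, config$purity_k)))
        utils::write.table(pur, file.path(config$out_dir, "purity.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        report$purity <- pur
        log_stage(log_path, "purity", k = config$purity_k,
                  core_function = pur$purity[1L], core_kingdom = pur$purity[2L],
                  full_function = pur$purity[3L], full_kingdom = pur$purity[4L])
      }
    }, error = function(e) fail("tree/purity", e))
  }

  invisible(report)
}
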