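#' Simulation configuration for synthetic trefoil families
#'
#' The generator emulates the study conditions of a fold-expansion survey:
#' 64 trefoil-like domains of ~150 residues diverging jointly in sequence and
#' coordinates, with a small planted set of invariant "core" columns and
#' taxon labels for function and kingdom.
#'
#' Two wirings of the planted core are supported. In `core_signal =
#' "invariant"` (the default) the core columns carry one residue type across
#' the whole family, giving exactly zero Shannon entropy. In `core_signal =
#' "function"` each function group carries its own signature residue at every
#' core column, so core columns track function while the remaining columns
#' track the (kingdom-structured) tree — the convergent-evolution scenario.
#'
#' @param seed mandatory integer seed; fully determines all output.
#' @param n_taxa number of family members (default 64).
#' @param n_columns alignment width and template length (default 150).
#' @param core_positions integer set of planted core columns in
#'   `1..n_columns`; default: 7 positions drawn deterministically from `seed`.
#' @param n_function_groups number of function labels, also the number of
#'   deep kingdom clades (default 4).
#' @param substitution_rate expected substitution events per site per unit
#'   branch length (default 1).
#' @param structure_noise_scale Angstrom scale of the Brownian Calpha noise:
#'   coordinate variance accumulated per unit of expected per-site sequence
#'   divergence along a branch is `structure_noise_scale^2` (default 1.5).
#' @param gap_rate per-cell gap probability outside core columns (default 0.05).
#' @param mean_branch_length mean of the i.i.d. exponential branch lengths of
#'   the random tree (default 0.1 substitutions/site).
#' @param core_signal `"invariant"` or `"function"`; see Details.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed,
                              n_taxa = 64L,
                              n_columns = 150L,
                              core_positions = NULL,
                              n_function_groups = 4L,
                              substitution_rate = 1,
                              structure_noise_scale = 1.5,
                              gap_rate = 0.05,
                              mean_branch_length = 0.1,
                              core_signal = c("invariant", "function")) {
  if (missing(seed)) stop("seed is mandatory")
  core_signal <- match.arg(core_signal)
  stopifnot(n_taxa >= 4L, n_columns >= 8L, n_function_groups >= 2L,
            substitution_rate >= 0, structure_noise_scale >= 0,
            gap_rate >= 0, gap_rate < 1, mean_branch_length > 0)
  if (is.null(core_positions)) {
    core_positions <- with_seed(derive_seed(seed, 77L),
                                sort(sample.int(n_columns, 7L)))
  }
  core_positions <- sort(unique(as.integer(core_positions)))
  if (any(core_positions < 1L) || any(core_positions > n_columns)) {
    stop("core_positions must lie in 1..n_columns")
  }
  structure(list(seed = as.integer(seed), n_taxa = as.integer(n_taxa),
                 n_columns = as.integer(n_columns),
                 core_positions = core_positions,
                 n_function_groups = as.integer(n_function_groups),
                 substitution_rate = substitution_rate,
                 structure_noise_scale = structure_noise_scale,
                 gap_rate = gap_rate,
                 mean_branch_length = mean_branch_length,
                 core_signal = core_signal),
            class = "simulation_config")
}

#' Build a pseudo-threefold-symmetric template Calpha trace
#'
#' The template stands in for a trefoil representative: three lobes of
#' `n_residues/3` residues, each a helical arc around its own axis, the three
#' axes placed 120 degrees apart so the lobes are near-copies of one another
#' (internal pseudo-symmetry) and the trace is self-avoiding by construction.
#' A small seeded per-lobe jitter (0.15 A per coordinate) breaks the exact
#' symmetry. Consecutive Calpha atoms are ~3.8 A apart.
#'
#' @param n_residues total residue count; must be >= 9 and divisible by 3.
#' @param seed integer seed (also draws the template amino-acid sequence).
#' @return a [structure_record()] with residues numbered 1..n.
#' @export
make_template_structure <- function(n_residues, seed) {
  n_residues <- as.integer(n_residues)
  if (is.na(n_residues) || n_residues < 9L || n_residues %% 3L != 0L) {
    stop("invalid parameter: n_residues must be >= 9 and divisible by 3")
  }
  m <- n_residues %/% 3L
  with_seed(seed, {
    # one lobe: a serpentine bundle of radial strands stacked in z inside a
    # 120-degree wedge, echoing the beta-beta-beta-loop-beta lobe of the
    # fold: compact (aspect ratio near 1, so short fragments pin the global
    # frame) and irregular (strand lengths vary, so local geometry is
    # position dependent rather than helically self-similar)
    # strands come in out-and-back pairs of equal length so every pair
    # returns to the inner radius; a leftover tail becomes one outward strand
    strand_lens <- integer(0)
    remaining <- m
    while (remaining >= 12L) {
      p <- sample(6:10, 1L)
      if (2L * p > remaining) p <- remaining %/% 2L
      strand_lens <- c(strand_lens, p, p)
      remaining <- remaining - 2L * p
    }
    if (remaining > 0L) strand_lens <- c(strand_lens, remaining)
    t_global <- 0L
    pts <- matrix(NA_real_, m, 3L)
    row <- 1L
    r_here <- 6
    for (k in seq_along(strand_lens)) {
      len <- strand_lens[k]
      dir <- if (k %% 2L == 1L) 1 else -1
      radii <- r_here + dir * 3.8 * (seq_len(len) - 1L)
      for (ri in radii) {
        t_global <- t_global + 1L
        phi <- 0.06 * sin(1.3 * t_global)
        pts[row, ] <- c(ri * cos(phi), ri * sin(phi),
                        (k - 1L) * 4.2 + 0.4 * cos(0.9 * t_global))
        row <- row + 1L
      }
      r_here <- radii[len]
    }
    lobes <- lapply(0:2, function(k) {
      phi <- 2 * pi * k / 3
      rot <- matrix(c(cos(phi), -sin(phi), 0,
                      sin(phi),  cos(phi), 0,
                      0, 0, 1), 3, 3, byrow = TRUE)
      pts %*% t(rot) + matrix(stats::rnorm(3L * m, sd = 0.15), m, 3L)
    })
    structure_record(id = "template",
                     resno = seq_len(n_residues),
                     aa = sample(AA20, n_residues, replace = TRUE),
                     xyz = do.call(rbind, lobes))
  })
}

#' Self-avoiding random-walk Calpha trace
#'
#' Control structure with no internal symmetry and no relation to the
#' template family; used to exercise the aligner on unrelated chains.
#'
#' @param n_residues chain length.
#' @param seed integer seed.
#' @param step Calpha-Calpha step length in Angstrom.
#' @param min_dist minimum allowed distance between non-consecutive atoms.
#' @return a [structure_record()].
#' @export
make_random_structure <- function(n_residues, seed, step = 3.8, min_dist = 3.2) {
  n_residues <- as.integer(n_residues)
  stopifnot(n_residues >= 2L)
  with_seed(seed, {
    xyz <- matrix(0, n_residues, 3L)
    for (i in 2:n_residues) {
      repeat {
        dir <- stats::rnorm(3L)
        cand <- xyz[i - 1L, ] + step * dir / sqrt(sum(dir^2))
        prev <- xyz[seq_len(max(i - 2L, 1L)), , drop = FALSE]
        if (i == 2L || min(sqrt(rowSums(sweep(prev, 2L, cand)^2))) >= min_dist) {
          xyz[i, ] <- cand
          break
        }
      }
    }
    structure_record(id = sprintf("walk%d", seed),
                     resno = seq_len(n_residues),
                     aa = sample(AA20, n_residues, replace = TRUE),
                     xyz = xyz)
  })
}

# Partition the tips of a rooted tree into k deep clades by repeatedly
# splitting the largest current clade at its root node.
deep_clades <- function(tree, k) {
  n <- ape::Ntip(tree)
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  tips_under <- function(node) {
    if (node <= n) return(node)
    unlist(lapply(children[[as.character(node)]], tips_under))
  }
  groups <- lapply(children[[as.character(n + 1L)]], tips_under)
  nodes <- children[[as.character(n + 1L)]]
  while (length(groups) < k) {
    sizes <- lengths(groups)
    splittable <- which(nodes > n & sizes == max(sizes[nodes > n]))
    if (length(splittable) == 0L) break
    i <- splittable[[1L]]
    kids <- children[[as.character(nodes[[i]])]]
    groups <- c(groups[-i], lapply(kids, tips_under))
    nodes <- c(nodes[-i], kids)
  }
  membership <- integer(n)
  for (g in seq_along(groups)) membership[groups[[g]]] <- g
  membership
}

#' Evolve a synthetic trefoil family down a random tree
#'
#' Simulates sequences along a random-topology tree with i.i.d. exponential
#' branch lengths under a uniform 20-state replacement process (a site on a
#' branch of length t substitutes with probability `1 - exp(-rate * t)` to a
#' uniformly drawn residue). Planted core columns are held invariant
#' (globally, or per function group — see [simulation_config()]). Coordinates
#' evolve as Brownian motion along the same tree: each branch adds isotropic
#' Gaussian Calpha increments whose variance is `structure_noise_scale^2`
#' times the branch's expected per-site divergence, so a taxon's deviation
#' from the template grows with its sequence divergence and pairwise rmsd is
#' inversely coupled to sequence identity. Gaps are planted i.i.d. per cell
#' outside core columns;
#' gapped residues are removed from the taxon's structure, so residue
#' numbering records which template positions survive.
#'
#' Kingdom labels follow the `n_function_groups` deepest clades of the true
#' tree (background divergence is kingdom-structured); function labels are
#' assigned round-robin along the tip order, orthogonal to the tree.
#'
#' @param template a [structure_record()] of length `config$n_columns`.
#' @param config a [simulation_config()].
#' @return list with `structures` (named list of [structure_record()]s),
#'   `msa` (character alignment matrix) and `truth` (class `ground_truth`:
#'   `true_tree`, `function_label`, `kingdom_label`, `core_positions`,
#'   `divergence`, `config`).
#' @export
evolve_family <- function(template, config) {
  stopifnot(inherits(template, "structure_record"),
            inherits(config, "simulation_config"))
  L <- config$n_columns
  if (length(template) != L) {
    stop("template length must equal config$n_columns")
  }
  n <- config$n_taxa
  core <- config$core_positions
  free <- setdiff(seq_len(L), core)
  kingdom_names <- c("bacteria", "fungi", "metazoa", "plantae", "protozoa")
  with_seed(config$seed, {
    tree <- ape::rtree(n, br = function(k) stats::rexp(k, rate = 1 / config$mean_branch_length))
    tree$tip.label <- sprintf("t%02d", seq_len(n))
    taxa <- tree$tip.label

    func_label <- stats::setNames(
      paste0("F", rep_len(seq_len(config$n_function_groups), n)), taxa)
    king_label <- stats::setNames(
      kingdom_names[rep_len(seq_len(config$n_function_groups),
                            config$n_function_groups)][deep_clades(tree, config$n_function_groups)],
      taxa)

    root_seq <- template$aa
    nnode <- tree$Nnode
    seqs <- matrix(NA_character_, n + nnode, L)
    seqs[n + 1L, ] <- root_seq
    coords <- vector("list", n + nnode)
    coords[[n + 1L]] <- template$xyz
    # cladewise edge order guarantees parents are filled before children
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      p <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
      t_br <- ord$edge.length[e]
      s <- seqs[p, ]
      p_sub <- 1 - exp(-config$substitution_rate * t_br)
      if (length(free) > 0L && config$substitution_rate > 0) {
        hit <- free[stats::runif(length(free)) < p_sub]
        if (length(hit) > 0L) s[hit] <- sample(AA20, length(hit), replace = TRUE)
      }
      seqs[ch, ] <- s
      # Brownian coordinate evolution: variance accumulates with the branch's
      # expected per-site divergence (19/20 of substitution draws change the
      # residue under the uniform replacement model)
      br_sd <- config$structure_noise_scale * sqrt(p_sub * 19 / 20)
      coords[[ch]] <- coords[[p]] +
        matrix(stats::rnorm(3L * L, sd = br_sd), L, 3L)
    }
    tip_seqs <- seqs[seq_len(n), , drop = FALSE]
    rownames(tip_seqs) <- taxa

    if (config$core_signal == "function") {
      # one signature residue per function group per core column, all groups
      # distinct within a column
      sig <- vapply(core, function(j) sample(AA20, config$n_function_groups),
                    character(config$n_function_groups))
      sig <- matrix(sig, nrow = config$n_function_groups)
      gi <- as.integer(sub("^F", "", func_label))
      for (ci in seq_along(core)) tip_seqs[, core[ci]] <- sig[gi, ci]
    } else {
      for (j in core) tip_seqs[, j] <- root_seq[j]
    }

    divergence <- rowMeans(tip_seqs != matrix(root_seq, n, L, byrow = TRUE))

    gap_mask <- matrix(FALSE, n, L)
    if (config$gap_rate > 0 && length(free) > 0L) {
      gap_mask[, free] <- matrix(stats::runif(n * length(free)) < config$gap_rate,
                                 n, length(free))
    }

    msa <- tip_seqs
    msa[gap_mask] <- "-"

    structures <- lapply(seq_len(n), function(i) {
      keep <- !gap_mask[i, ]
      structure_record(id = taxa[i],
                       resno = which(keep),
                       aa = tip_seqs[i, keep],
                       xyz = coords[[i]][keep, , drop = FALSE])
    })
    names(structures) <- taxa

    truth <- structure(list(true_tree = tree,
                            function_label = func_label,
                            kingdom_label = king_label,
                            core_positions = core,
                            divergence = stats::setNames(divergence, taxa),
                            config = config),
                       class = "ground_truth")
    list(structures = structures, msa = msa, truth = truth)
  })
}

#' Generate a synthetic structure-search table with known pass/fail labels
#'
#' Draws hits whose rmsd and coverage straddle the thresholds of the chosen
#' filtering preset and records, for each row, the exact pass/fail label the
#' filter should assign (`rmsd < rmsd_max` and `coverage >= coverage_min`,
#' computed here independently of the filtering code). The first rows are
#' deterministic boundary probes: coverage exactly at the threshold with rmsd
#' just under (pass), rmsd exactly at the threshold (fail), coverage one
#' residue short (fail), and a clear pass. Lineage strings are drawn from a
#' fixed five-kingdom vocabulary.
#'
#' @param n_hits number of rows (0 gives an empty table).
#' @param preset `"iteration1"` (2 A, 80%) or `"iteration2"` (3 A, 30%).
#' @param seed integer seed.
#' @return list with `hits` (search-hit data frame) and `truth` (list:
#'   logical `pass_label`, the `preset` used).
#' @export
make_search_table <- function(n_hits, preset, seed) {
  fp <- filter_preset(preset)   # validates the preset name
  n_hits <- as.integer(n_hits)
  stopifnot(n_hits >= 0L)
  lineages <- c(
    bacteria = "cellular organisms;Bacteria;Pseudomonadota",
    fungi    = "cellular organisms;Eukaryota;Fungi;Ascomycota",
    metazoa  = "cellular organisms;Eukaryota;Metazoa;Chordata",
    plantae  = "cellular organisms;Eukaryota;Viridiplantae;Streptophyta",
    protozoa = "cellular organisms;Eukaryota;Amoebozoa")
  if (n_hits == 0L) {
    return(list(hits = empty_search_hits(),
                truth = list(pass_label = logical(0), preset = fp)))
  }
  with_seed(seed, {
    qlen <- sample(100:300, n_hits, replace = TRUE)
    cov <- stats::runif(n_hits, max(0.02, fp$coverage_min - 0.25),
                        min(1, fp$coverage_min + 0.25))
    alnlen <- pmax(1, round(qlen * cov))
    rmsd <- pmax(0.05, stats::runif(n_hits, fp$rmsd_max - 1.5, fp$rmsd_max + 1.5))
    if (n_hits >= 4L) {
      qlen[1:4] <- 100L
      alnlen[1:4] <- round(c(fp$coverage_min * 100, fp$coverage_min * 100,
                             fp$coverage_min * 100 - 1, 95))
      rmsd[1:4] <- c(fp$rmsd_max - 0.01, fp$rmsd_max, 0.5, fp$rmsd_max / 2)
    }
    kingdom <- sample(names(lineages), n_hits, replace = TRUE)
    hits <- search_hits(
      query_id = "synthetic_query",
      target_id = sprintf("AF-%05d", seq_len(n_hits)),
      query_length = qlen, aligned_length = alnlen, rmsd = rmsd,
      taxon_name = paste0(kingdom, " sp."),
      tax_lineage = unname(lineages[kingdom]))
    pass <- rmsd < fp$rmsd_max & (alnlen / qlen) >= fp$coverage_min
    list(hits = hits, truth = list(pass_label = pass, preset = fp))
  })
}

#' Write the ground-truth pass labels as a tab-separated sidecar
#' @param truth the `truth` element of [make_search_table()].
#' @param hits the matching hit table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(truth, hits, path) {
  utils::write.table(
    data.frame(target = hits$target_id, pass = as.integer(truth$pass_label)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Domain-architecture fixtures covering the three novelty categories
#'
#' Emits a small set of trefoil-containing proteins together with the
#' reference catalog rows that force each classification: a protein whose
#' extra domain is absent from the catalog (category 1), one whose extra
#' domain is known but whose catalog proteins lack the trefoil even at full
#' length (category 2, the chitinase-style pattern), one whose extra domain
#' already co-occurs with a trefoil in a catalog entry (category 3), plus
#' single-domain and known-architecture controls and a multi-extra-domain
#' case where the most novel domain wins.
#'
#' @param seed integer seed (shuffles interval placement only; the expected
#'   categories are fixed by construction).
#' @return list with `architectures` (named list of [domain_architecture()]),
#'   `catalog` (an [architecture_catalog()]) and `expected` (named character
#'   vector of categories).
#' @export
make_architecture_fixtures <- function(seed = 1L) {
  with_seed(seed, {
    off <- function() sample(0:20, 1L)
    arch <- function(id, names) {
      n <- length(names)
      starts <- cumsum(c(1L + off(), rep(0L, n - 1L))) +
        c(0L, cumsum(rep(160L, n - 1L)))
      domain_architecture(id, names, starts, starts + 150L)
    }
    architectures <- list(
      cat1_like  = arch("cat1_like",  c("trefoil", "orphanase")),
      cat2_like  = arch("cat2_like",  c("trefoil", "chitinase")),
      cat3_like  = arch("cat3_like",  c("trefoil", "agglutinin")),
      known_solo = arch("known_solo", "trefoil"),
      known_pair = arch("known_pair", c("trefoil", "agglutinin", "lectin_x")),
      mixed_12   = arch("mixed_12",   c("trefoil", "orphanase", "chitinase")))
    # known_pair shares its full signature with the pdb_both catalog entry;
    # cat3_like's extra domain co-occurs with a trefoil there without
    # matching the whole signature
    catalog <- architecture_catalog(list(
      pdb_chit = list(
        architecture = arch("pdb_chit", "chitinase"),
        full_length_architecture = arch("pdb_chit_fl", c("chitinase", "fn3"))),
      pdb_both = list(
        architecture = arch("pdb_both", c("trefoil", "agglutinin", "lectin_x")),
        full_length_architecture = arch("pdb_both_fl",
                                        c("trefoil", "agglutinin", "lectin_x"))),
      pdb_tref = list(
        architecture = arch("pdb_tref", "trefoil"),
        full_length_architecture = arch("pdb_tref_fl", "trefoil"))))
    expected <- c(cat1_like = "1", cat2_like = "2", cat3_like = "3",
                  known_solo = "known", known_pair = "known", mixed_12 = "1")
    list(architectures = architectures, catalog = catalog, expected = expected)
  })
}
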