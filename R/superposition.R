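#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the root-mean-square
#' deviation between paired Calpha coordinate sets, via the SVD of the
#' cross-covariance matrix. Reflections are excluded (the determinant of the
#' rotation is forced to +1) because protein backbones are chiral.
#'
#' @param points_a,points_b paired n x 3 coordinate matrices (rows correspond).
#' @return object of class `superposition` with elements `rotation` (3 x 3,
#'   applied as `x %*% t(rotation)`), `translation` (length-3), `rmsd`
#'   (Angstrom), `correspondence` (n x 2 index matrix) and `degenerate`
#'   (TRUE when the input is near-collinear, in which case the rotation about
#'   the degenerate axis is arbitrary but the rmsd is still optimal).
#' @export
kabsch <- function(points_a, points_b) {
  a <- as.matrix(points_a); b <- as.matrix(points_b)
  storage.mode(a) <- storage.mode(b) <- "double"
  if (!all(dim(a) == dim(b)) || ncol(a) != 3L) {
    stop("point sets must be paired n x 3 matrices")
  }
  n <- nrow(a)
  if (n < 3L) stop("underdetermined: need at least 3 paired points")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("coordinates must be finite")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2L, ca); b0 <- sweep(b, 2L, cb)
  h <- crossprod(a0, b0)            # sum over points of a_i b_i^T
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  resid <- a0 %*% t(rot) - b0
  rmsd <- sqrt(mean(rowSums(resid^2)))
  # collinearity: second singular value of either centered set ~ 0
  degen <- {
    sa <- svd(a0, nu = 0, nv = 0)$d
    sb <- svd(b0, nu = 0, nv = 0)$d
    sa[2L] < 1e-8 * max(sa[1L], 1) || sb[2L] < 1e-8 * max(sb[1L], 1)
  }
  if (degen) warning("near-collinear point set: rotation is not unique")
  structure(list(rotation = rot,
                 translation = as.numeric(cb - rot %*% ca),
                 rmsd = rmsd,
                 correspondence = cbind(query = seq_len(n), target = seq_len(n)),
                 degenerate = degen),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition: %d pairs, rmsd %.3f A%s>\n",
              nrow(x$correspondence), x$rmsd,
              if (isFALSE(x$converged %||% TRUE)) ", not converged" else ""))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Apply a superposition to an n x 3 coordinate matrix.
transform_coords <- function(xyz, sup) {
  sweep(xyz %*% t(sup$rotation), 2L, -sup$translation)
}

#' Sequence-independent pairwise structure alignment
#'
#' Toy stand-in for a full structural-homolog search engine: the
#' correspondence is seeded from the best-superposing pair of contiguous
#' backbone fragments, then refined by alternating (i) Kabsch superposition on
#' the current correspondence and (ii) extraction of a new monotone
#' correspondence by dynamic programming on the inter-structure Calpha
#' distance matrix with per-pair score `dist_cutoff - d_ij` (negative cells
#' cannot be matched; no gap penalty). Iteration stops when the
#' correspondence stabilizes or `max_iter` is reached, in which case the best
#' correspondence seen so far is returned with `converged = FALSE`.
#'
#' @param a,b [structure_record()] objects, both of length >= 10.
#' @param max_iter maximum refinement iterations.
#' @param dist_cutoff Angstrom; residue pairs farther apart than this are
#'   unmatchable. Default 5 A, the conventional fold-level contact scale.
#' @param frag_len,frag_stride fragment length and stride of the seeding scan.
#' @return a `superposition` whose `correspondence` holds the matched
#'   (query index, target index) pairs, plus `aligned_length`,
#'   `coverage_query`, `coverage_target`, `n_iter` and `converged`.
#' @export
align_structures <- function(a, b, max_iter = 20L, dist_cutoff = 5,
                             frag_len = 12L, frag_stride = 3L) {
  stopifnot(inherits(a, "structure_record"), inherits(b, "structure_record"))
  na <- length(a); nb <- length(b)
  if (na < 10L || nb < 10L) stop("structures must have length >= 10")
  L <- min(frag_len, na, nb)
  # seed candidates: the best-superposing contiguous fragment pairs; keep the
  # best few distinct diagonal offsets, because internally pseudo-symmetric
  # chains (three similar lobes) offer near-tied seeds in a shifted register
  # and only refinement can arbitrate between them
  seeds <- list()
  for (i in seq(1L, na - L + 1L, by = frag_stride)) {
    fa <- a$xyz[i:(i + L - 1L), , drop = FALSE]
    for (j in seq(1L, nb - L + 1L, by = frag_stride)) {
      fb <- b$xyz[j:(j + L - 1L), , drop = FALSE]
      r <- suppressWarnings(kabsch(fa, fb))$rmsd
      off <- as.character(i - j)                # one seed per register offset
      if (is.null(seeds[[off]]) || r < seeds[[off]]$rmsd) {
        seeds[[off]] <- list(rmsd = r, i = i, j = j)
      }
    }
  }
  seeds <- seeds[order(vapply(seeds, `[[`, numeric(1), "rmsd"))]
  seeds <- seeds[seq_len(min(12L, length(seeds)))]
  # one DP pass per register band: the resulting match count separates the
  # true register from shifted ones far more reliably than fragment rmsd,
  # which is nearly blind to small register shifts on locally regular chains
  one_pass <- function(corr) {
    sup <- suppressWarnings(kabsch(a$xyz[corr[, 1L], , drop = FALSE],
                                   b$xyz[corr[, 2L], , drop = FALSE]))
    axyz <- transform_coords(a$xyz, sup)
    dmat <- sqrt(pmax(outer(rowSums(axyz^2), rowSums(b$xyz^2), `+`) -
                        2 * axyz %*% t(b$xyz), 0))
    dp_correspondence(dist_cutoff - dmat)
  }
  cand <- lapply(seeds, function(s) {
    one_pass(cbind(query = s$i:(s$i + L - 1L),
                   target = s$j:(s$j + L - 1L)))
  })
  cand <- cand[order(-vapply(cand, nrow, integer(1)))]
  cand <- cand[vapply(cand, nrow, integer(1)) >= 3L]
  cand <- cand[seq_len(min(3L, length(cand)))]
  if (length(cand) == 0L) {
    s <- seeds[[which.min(vapply(seeds, `[[`, numeric(1), "rmsd"))]]
    cand <- list(cbind(query = s$i:(s$i + L - 1L),
                       target = s$j:(s$j + L - 1L)))
  }

  refine <- function(corr) {
    best_state <- NULL
    converged <- FALSE
    n_iter <- 0L
    for (iter in seq_len(max_iter)) {
      n_iter <- iter
      new_corr <- one_pass(corr)
      if (nrow(new_corr) < 3L) break
      state_rmsd <- suppressWarnings(
        kabsch(a$xyz[new_corr[, 1L], , drop = FALSE],
               b$xyz[new_corr[, 2L], , drop = FALSE]))$rmsd
      if (is.null(best_state) || nrow(new_corr) > nrow(best_state$corr) ||
          (nrow(new_corr) == nrow(best_state$corr) &&
             state_rmsd < best_state$rmsd)) {
        best_state <- list(corr = new_corr, rmsd = state_rmsd)
      }
      if (nrow(new_corr) == nrow(corr) && all(new_corr == corr)) {
        converged <- TRUE
        break
      }
      corr <- new_corr
    }
    if (is.null(best_state)) best_state <- list(corr = corr, rmsd = Inf)
    c(best_state, converged = converged, n_iter = n_iter)
  }

  runs <- lapply(cand, refine)
  score <- vapply(runs, function(r) nrow(r$corr) - r$rmsd / 1e6, numeric(1))
  best_run <- runs[[which.max(score)]]
  corr <- best_run$corr
  converged <- best_run$converged
  n_iter <- best_run$n_iter
  sup <- suppressWarnings(kabsch(a$xyz[corr[, 1L], , drop = FALSE],
                                 b$xyz[corr[, 2L], , drop = FALSE]))
  sup$correspondence <- corr
  sup$aligned_length <- nrow(corr)
  sup$coverage_query <- nrow(corr) / na
  sup$coverage_target <- nrow(corr) / nb
  sup$converged <- converged
  sup$n_iter <- n_iter
  sup
}

# Monotone correspondence by dynamic programming on a score matrix; cells with
# score <= 0 are ineligible for matching, there is no gap penalty, and
# traceback prefers match over vertical over horizontal moves.
dp_correspondence <- function(s) {
  n <- nrow(s); m <- ncol(s)
  M <- matrix(0, n + 1L, m + 1L)
  P <- matrix(0L, n + 1L, m + 1L)    # 1 diag, 2 up, 3 left
  for (i in seq_len(n)) {
    si <- s[i, ]
    for (j in seq_len(m)) {
      up <- M[i, j + 1L]; left <- M[i + 1L, j]
      bestv <- up; bestp <- 2L
      if (left > bestv) { bestv <- left; bestp <- 3L }
      if (si[j] > 0) {
        dg <- M[i, j] + si[j]
        if (dg >= bestv) { bestv <- dg; bestp <- 1L }
      }
      M[i + 1L, j + 1L] <- bestv
      P[i + 1L, j + 1L] <- bestp
    }
  }
  qi <- integer(0); ti <- integer(0)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    p <- P[i + 1L, j + 1L]
    if (p == 1L) {
      qi <- c(i, qi); ti <- c(j, ti)
      i <- i - 1L; j <- j - 1L
    } else if (p == 2L) i <- i - 1L else j <- j - 1L
  }
  cbind(query = qi, target = ti)
}

#' Reference-based (star) structural multiple alignment
#'
#' Aligns every structure pairwise to a designated reference and stacks the
#' matches: one alignment column per reference residue, gaps where a target
#' has no residue matched to that reference position. Target residues not
#' matched to any reference residue are dropped and counted in the report.
#' Structures whose alignment covers less than `coverage_floor` of the
#' reference are excluded (also reported).
#'
#' @param structures list of [structure_record()]s (the reference may be among
#'   them or passed separately via `reference`).
#' @param reference_id id of the reference structure.
#' @param reference optional [structure_record()] used as reference when it is
#'   not an element of `structures`.
#' @param coverage_floor minimum fraction of reference residues that must be
#'   matched for a structure to be included (default 0.5).
#' @param ... passed to [align_structures()].
#' @return list with `msa` (character alignment matrix, width = reference
#'   length, rows in input order) and `report` (data frame: id, coverage,
#'   n_dropped, included).
#' @export
reference_msa <- function(structures, reference_id, reference = NULL,
                          coverage_floor = 0.5, ...) {
  ids <- vapply(structures, `[[`, character(1), "id")
  if (is.null(reference)) {
    ix <- match(reference_id, ids)
    if (is.na(ix)) stop("reference '", reference_id, "' not among structures")
    reference <- structures[[ix]]
  }
  nref <- length(reference)
  rows <- list()
  rep_rows <- list()
  for (s in structures) {
    if (identical(s$id, reference$id)) {
      row <- reference$aa
      cov <- 1; dropped <- 0L; included <- TRUE
    } else {
      aln <- align_structures(reference, s, ...)
      cov <- aln$aligned_length / nref
      dropped <- length(s) - aln$aligned_length
      included <- cov >= coverage_floor
      row <- rep("-", nref)
      if (included) row[aln$correspondence[, 1L]] <- s$aa[aln$correspondence[, 2L]]
    }
    rep_rows[[s$id]] <- data.frame(id = s$id, coverage = cov,
                                   n_dropped = dropped, included = included)
    if (included) rows[[s$id]] <- row
  }
  msa <- do.call(rbind, rows)
  rownames(msa) <- names(rows)
  list(msa = msa, report = do.call(rbind, c(rep_rows, list(make.row.names = FALSE))))
}
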