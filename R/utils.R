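#' @keywords internal
"_PACKAGE"

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number generator seeded to `seed`,
#' restoring the previous RNG state afterwards. All stochastic operations in
#' the package route through this helper so identical seeds give bit-identical
#' output without disturbing the caller's RNG stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a sub-seed from a base seed and an index, kept inside 32-bit range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 1009 + as.double(i) * 7919) %% 2147483647)
}

# The 20 canonical amino acids, one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

AA_THREE <- c(
  A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
  H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
  P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
  W = "TRP", Y = "TYR", X = "UNK")

AA_ONE <- stats::setNames(names(AA_THREE), AA_THREE)

aa_to_three <- function(aa) {
  out <- AA_THREE[aa]
  out[is.na(out)] <- "UNK"
  unname(out)
}

aa_to_one <- function(res3) {
  out <- AA_ONE[toupper(res3)]
  out[is.na(out)] <- "X"
  unname(out)
}
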