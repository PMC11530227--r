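# Scoring constants shared by the search engine, the profile builder and the
# fixture generators.

#' Protein alphabet used throughout the package
#'
#' The 20 standard amino acids plus `X` (ambiguous/masked residue) and `*`
#' (translation stop).  `*` never occurs in query residues handed to the
#' search engine; internally its score column doubles as the hard mask used
#' by repeated-domain re-alignment.
#' @keywords internal
AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                 "P","S","T","W","Y","V","X","*")

DNA_ALPHABET <- c("A","C","G","T","N")

#' BLOSUM62 substitution matrix (half-bit units)
#'
#' Standard NCBI BLOSUM62 restricted to the package alphabet.
#' @keywords internal
BLOSUM62_MAT <- local({
  v <- c(
     4,  -1,  -2,  -2,   0,  -1,  -1,   0,  -2,  -1,  -1,  -1,  -1,  -2,  -1,   1,   0,  -3,  -2,   0,  -1,  -4,
    -1,   5,   0,  -2,  -3,   1,   0,  -2,   0,  -3,  -2,   2,  -1,  -3,  -2,  -1,  -1,  -3,  -2,  -3,  -1,  -4,
    -2,   0,   6,   1,  -3,   0,   0,   0,   1,  -3,  -3,   0,  -2,  -3,  -2,   1,   0,  -4,  -2,  -3,  -1,  -4,
    -2,  -2,   1,   6,  -3,   0,   2,  -1,  -1,  -3,  -4,  -1,  -3,  -3,  -1,   0,  -1,  -4,  -3,  -3,  -1,  -4,
     0,  -3,  -3,  -3,   9,  -3,  -4,  -3,  -3,  -1,  -1,  -3,  -1,  -2,  -3,  -1,  -1,  -2,  -2,  -1,  -1,  -4,
    -1,   1,   0,   0,  -3,   5,   2,  -2,   0,  -3,  -2,   1,   0,  -3,  -1,   0,  -1,  -2,  -1,  -2,  -1,  -4,
    -1,   0,   0,   2,  -4,   2,   5,  -2,   0,  -3,  -3,   1,  -2,  -3,  -1,   0,  -1,  -3,  -2,  -2,  -1,  -4,
     0,  -2,   0,  -1,  -3,  -2,  -2,   6,  -2,  -4,  -4,  -2,  -3,  -3,  -2,   0,  -2,  -2,  -3,  -3,  -1,  -4,
    -2,   0,   1,  -1,  -3,   0,   0,  -2,   8,  -3,  -3,  -1,  -2,  -1,  -2,  -1,  -2,  -2,   2,  -3,  -1,  -4,
    -1,  -3,  -3,  -3,  -1,  -3,  -3,  -4,  -3,   4,   2,  -3,   1,   0,  -3,  -2,  -1,  -3,  -1,   3,  -1,  -4,
    -1,  -2,  -3,  -4,  -1,  -2,  -3,  -4,  -3,   2,   4,  -2,   2,   0,  -3,  -2,  -1,  -2,  -1,   1,  -1,  -4,
    -1,   2,   0,  -1,  -3,   1,   1,  -2,  -1,  -3,  -2,   5,  -1,  -3,  -1,   0,  -1,  -3,  -2,  -2,  -1,  -4,
    -1,  -1,  -2,  -3,  -1,   0,  -2,  -3,  -2,   1,   2,  -1,   5,   0,  -2,  -1,  -1,  -1,  -1,   1,  -1,  -4,
    -2,  -3,  -3,  -3,  -2,  -3,  -3,  -3,  -1,   0,   0,  -3,   0,   6,  -4,  -2,  -2,   1,   3,  -1,  -1,  -4,
    -1,  -2,  -2,  -1,  -3,  -1,  -1,  -2,  -2,  -3,  -3,  -1,  -2,  -4,   7,  -1,  -1,  -4,  -3,  -2,  -1,  -4,
     1,  -1,   1,   0,  -1,   0,   0,   0,  -1,  -2,  -2,   0,  -1,  -2,  -1,   4,   1,  -3,  -2,  -2,  -1,  -4,
     0,  -1,   0,  -1,  -1,  -1,  -1,  -2,  -2,  -1,  -1,  -1,  -1,  -2,  -1,   1,   5,  -2,  -2,   0,  -1,  -4,
    -3,  -3,  -4,  -4,  -2,  -2,  -3,  -2,  -2,  -3,  -2,  -3,  -1,   1,  -4,  -3,  -2,  11,   2,  -3,  -1,  -4,
    -2,  -2,  -2,  -3,  -2,  -1,  -2,  -3,   2,  -1,  -1,  -2,  -1,   3,  -3,  -2,  -2,   2,   7,  -1,  -1,  -4,
     0,  -3,  -3,  -3,  -1,  -2,  -2,  -3,  -3,   3,   1,  -2,   1,  -1,  -2,  -2,   0,  -3,  -1,   4,  -1,  -4,
    -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -1,  -4,
    -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,  -4,   1)
  m <- matrix(v, nrow = 22, byrow = TRUE,
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  m
})

#' Background amino-acid frequencies (BLOSUM62 marginals)
#'
#' Used as the null model for E-value calibration, the pseudocount prior for
#' PSSM construction, and the residue composition of synthetic fixtures.
#' @keywords internal
AA_BACKGROUND <- local({
  p <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
         Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
         L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
         S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)
  p / sum(p)
})

# Gumbel parameters for gapped local alignment with BLOSUM62, gap open 11 /
# extend 1 (the published values used by BLAST for this scoring system).
KA_LAMBDA_BLOSUM62_11_1 <- 0.267
KA_K_BLOSUM62_11_1 <- 0.041

#' BLOSUM62-conditional substitution probabilities
#'
#' Row b gives P(a | b): the probability that residue b is aligned to residue
#' a under the BLOSUM62 target distribution.  Reconstructed from the half-bit
#' score matrix s_ab = 2 log2(q_ab / (p_a p_b)) and the marginal frequencies,
#' then renormalised.  Drives biologically plausible point mutations in the
#' fixture generators and the pseudocount mixing of the profile builder.
#' @keywords internal
AA_CONDITIONAL <- local({
  p <- AA_BACKGROUND
  s <- BLOSUM62_MAT[1:20, 1:20]
  q <- outer(p, p) * 2^(s / 2)
  q <- q / sum(q)
  cond <- sweep(q, 1, rowSums(q), "/")   # rows: original residue b -> P(a|b)
  cond
})

# residues -> 0-based indices into AA_ALPHABET (for the C++ aligner)
aa_index0 <- function(residues) {
  idx <- match(strsplit(residues, "", fixed = TRUE)[[1]], AA_ALPHABET)
  if (anyNA(idx)) {
    stop("illegal protein residue '",
         strsplit(residues, "")[[1]][which(is.na(idx))[1]], "'")
  }
  idx - 1L
}

# score of aligning each query residue (columns) at each target residue (rows)
target_colscore <- function(t_idx0, submat = BLOSUM62_MAT) {
  submat[t_idx0 + 1L, , drop = FALSE]
}
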