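# R surface over the C++ affine-gap local aligner.

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gap costs: a gap of length k costs
#' `gap_open + k * gap_extend`.  Percent identity is matching residues over
#' alignment columns (gap columns included).
#'
#' @param q,t protein sequence strings.
#' @param gap_open,gap_extend positive gap penalties (defaults 11 and 1).
#' @param submat substitution matrix over [AA_ALPHABET] (default BLOSUM62).
#' @return `NULL` when no alignment scores above zero, otherwise a list with
#'   `score`, 0-based half-open `q_start`, `q_end`, `t_start`, `t_end`,
#'   `pct_identity`, and the column counts `n_cols`, `n_match`,
#'   `n_mismatch`, `n_gapopen`.
#' @export
align_local <- function(q, t, gap_open = 11, gap_extend = 1,
                        submat = BLOSUM62_MAT) {
  stopifnot(nchar(q) > 0, nchar(t) > 0, gap_open >= gap_extend,
            gap_extend >= 1)
  qi <- aa_index0(q)
  ti <- aa_index0(t)
  res <- .align_local_cpp(qi, target_colscore(ti, submat), ti,
                          gap_open, gap_extend)
  if (!isTRUE(res$hit)) return(NULL)
  res$pct_identity <- 100 * res$n_match / res$n_cols
  res
}

#' Optimal local alignment of a protein sequence against a profile
#'
#' The query is aligned to the profile's match columns; the gain of placing
#' residue a at column i is `pssm[i, a]`.  Identity is computed against the
#' profile consensus.  Masked query residues (`*`) can never align.
#'
#' @param q protein sequence string (may contain `X`; `X` scores 0 at every
#'   column).
#' @param profile a `protein_profile` object from [build_profile()].
#' @param gap_open,gap_extend positive gap penalties.
#' @return as [align_local()]; `t_start`/`t_end` index profile columns.
#' @export
align_profile <- function(q, profile, gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(profile, "protein_profile"), nchar(q) > 0)
  qi <- aa_index0(q)
  ci <- aa_index0(profile$consensus)
  res <- .align_local_cpp(qi, profile$colscore, ci, gap_open, gap_extend)
  if (!isTRUE(res$hit)) return(NULL)
  res$pct_identity <- 100 * res$n_match / res$n_cols
  res
}

#' Bit score and E-value for a sequence-database hit
#'
#' Karlin-Altschul statistics: `bit = (lambda * raw - ln K) / ln 2`,
#' `E = m * n * 2^-bit` with m the query length and n the total residue
#' count of the searched database.
#'
#' @param raw_score raw alignment score.
#' @param query_len query length in residues.
#' @param db_size_letters summed target lengths of the searched database.
#' @param lambda,K Gumbel parameters of the scoring system (defaults:
#'   published gapped BLOSUM62 11/1 values).
#' @return list with `bit_score` and `e_value`.
#' @export
evalue_sequence <- function(raw_score, query_len, db_size_letters,
                            lambda = KA_LAMBDA_BLOSUM62_11_1,
                            K = KA_K_BLOSUM62_11_1) {
  if (query_len <= 0 || db_size_letters <= 0) {
    stop("query and database sizes must be positive", call. = FALSE)
  }
  stopifnot(lambda > 0, K > 0)
  bit <- (lambda * raw_score - log(K)) / log(2)
  list(bit_score = bit,
       e_value = query_len * db_size_letters * 2^(-bit))
}

# E-value of a profile hit from the profile's calibrated Gumbel parameters
evalue_profile <- function(raw_score, query_len, profile) {
  stopifnot(profile$gumbel_lambda > 0, profile$gumbel_K > 0)
  e <- profile$gumbel_K * profile$length * query_len *
    exp(-profile$gumbel_lambda * raw_score)
  bit <- (profile$gumbel_lambda * raw_score - log(profile$gumbel_K)) / log(2)
  list(bit_score = bit, e_value = e)
}
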