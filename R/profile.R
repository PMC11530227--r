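# Position-specific scoring matrices built from multiple sequence alignments,
# with empirical E-value calibration.

#' Build a profile (PSSM) from a multiple sequence alignment
#'
#' Match columns are the alignment columns with at most 50% gaps.  Observed
#' residue frequencies in each match column are mixed with a
#' BLOSUM62-conditional pseudocount, `f' = (n f + alpha g) / (n + alpha)`,
#' where `g[a] = sum_b f[b] P(a|b)` under the BLOSUM62 target distribution
#' and n is the number of residues observed in the column.  Scores are
#' half-bit log-odds against the background: `2 log2(f'[a] / p[a])`.  The
#' consensus residue of a column is the residue with the maximal score.
#'
#' @param msa a `seq_set` (or data frame) of aligned protein sequences, all
#'   the same length; gaps `-` or `.`, `X` treated as unobserved.
#' @param id profile identifier.
#' @param pseudocount_alpha pseudocount weight alpha (default 1).
#' @param background length-20 background frequency vector (default BLOSUM62
#'   marginals).
#' @return a `protein_profile`: list with `id`, `length` (match columns),
#'   `pssm` (length x 20 half-bit matrix), `consensus`, and Gumbel slots
#'   `gumbel_lambda`/`gumbel_K` (`NA` until [calibrate_profile()]).
#' @export
build_profile <- function(msa, id, pseudocount_alpha = 1,
                          background = AA_BACKGROUND) {
  rows <- toupper(msa$residues)
  if (length(rows) < 2) stop("profile MSA needs at least 2 rows",
                             call. = FALSE)
  if (length(unique(nchar(rows))) != 1) {
    stop("ragged MSA for profile '", id, "': rows differ in length",
         call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(chartr(".", "-", rows), "", fixed = TRUE))
  gap_frac <- colMeans(chars == "-")
  match_cols <- which(gap_frac <= 0.5)
  if (!length(match_cols)) stop("profile '", id, "' has no match columns",
                                call. = FALSE)
  aa20 <- AA_ALPHABET[1:20]
  L <- length(match_cols)
  pssm <- matrix(0, L, 20, dimnames = list(NULL, aa20))
  consensus <- character(L)
  for (k in seq_len(L)) {
    col <- chars[, match_cols[k]]
    col <- col[col %in% aa20]
    n <- length(col)
    f <- tabulate(match(col, aa20), nbins = 20) / max(n, 1)
    g <- as.numeric(f %*% AA_CONDITIONAL)        # conditional pseudocount
    fprime <- (n * f + pseudocount_alpha * g) / (n + pseudocount_alpha)
    # guard true zeros (alpha = 0 and unobserved residue)
    sc <- ifelse(fprime > 0, 2 * log2(fprime / background), -20)
    pssm[k, ] <- sc
    consensus[k] <- aa20[which.max(sc)]
  }
  p <- list(id = id, length = L, pssm = pssm,
            consensus = paste(consensus, collapse = ""),
            match_cols = match_cols,
            gumbel_lambda = NA_real_, gumbel_K = NA_real_)
  p$colscore <- profile_colscore(pssm)
  class(p) <- "protein_profile"
  p
}

# extend an L x 20 pssm to the 22-letter alphabet: X neutral (0), * hard mask
profile_colscore <- function(pssm) {
  cbind(pssm, X = 0, "*" = -1000)
}

#' @export
print.protein_profile <- function(x, ...) {
  cat(sprintf("profile '%s': %d match columns, consensus %s%s\n", x$id,
              x$length, substr(x$consensus, 1, 40),
              if (x$length > 40) "..." else ""))
  if (is.finite(x$gumbel_lambda)) {
    cat(sprintf("  calibrated: lambda = %.4f, K = %.4g\n",
                x$gumbel_lambda, x$gumbel_K))
  } else cat("  not calibrated\n")
  invisible(x)
}

#' Calibrate a profile's score statistics against a random null
#'
#' Scores `n_shuffles` random sequences (drawn i.i.d. from the background
#' composition, length `shuffle_len`) with the profile aligner and fits a
#' Gumbel distribution to the null scores by the method of moments:
#' `lambda = pi / (sd * sqrt(6))`, `mu = mean - gamma / lambda`, and
#' `K = exp(lambda * mu) / (L * shuffle_len)` so that
#' `E = K * L * m * exp(-lambda * S)` for a query of length m.
#'
#' @param profile a `protein_profile`.
#' @param n_shuffles number of null sequences (>= 100).
#' @param shuffle_len length of each null sequence.
#' @param seed integer seed; calibration is deterministic given the seed.
#' @param gap_open,gap_extend gap penalties used for the null alignments
#'   (must match the search parameters).
#' @return the profile with `gumbel_lambda` and `gumbel_K` filled in.
#' @export
calibrate_profile <- function(profile, n_shuffles = 200, shuffle_len = 150,
                              seed = 42, gap_open = 11, gap_extend = 1) {
  stopifnot(n_shuffles >= 100, shuffle_len >= 10)
  scores <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      s <- random_protein(shuffle_len)
      r <- align_profile(s, profile, gap_open, gap_extend)
      if (is.null(r)) 0 else r$score
    }, numeric(1))
  })
  fit <- fit_gumbel_moments(scores)
  if (!is.finite(fit$lambda)) {
    stop("calibration failed for profile '", profile$id,
         "': zero variance in null scores", call. = FALSE)
  }
  profile$gumbel_lambda <- fit$lambda
  profile$gumbel_K <- exp(fit$lambda * fit$mu) /
    (profile$length * shuffle_len)
  profile$calibration <- list(n_shuffles = n_shuffles,
                              shuffle_len = shuffle_len, seed = seed)
  profile
}

# method-of-moments Gumbel fit; Euler-Mascheroni constant
fit_gumbel_moments <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(list(lambda = NA_real_, mu = NA_real_))
  lambda <- pi / (s * sqrt(6))
  mu <- mean(x) - 0.5772156649015329 / lambda
  list(lambda = lambda, mu = mu)
}

# random protein from the background composition (uses current RNG stream)
random_protein <- function(len, background = AA_BACKGROUND) {
  paste(sample(names(background), len, replace = TRUE, prob = background),
        collapse = "")
}

# run code with a temporary RNG state; never perturbs the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
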