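# The homology search engine: k-mer prefilter + gapped local alignment for
# sequence databases, PSSM scans with masked re-alignment for profile
# databases, and E-value filtering.

#' Search parameters
#'
#' @param kmer_len prefilter k-mer length (must equal the database index's).
#' @param min_diag_kmers minimum shared k-mers on a common diagonal band for
#'   a target to become an alignment candidate.
#' @param band_halfwidth half-width of the diagonal band (diagonals within
#'   `+/- band_halfwidth` of a common centre count together).
#' @param gap_open,gap_extend affine gap penalties (gap of length k costs
#'   `gap_open + k * gap_extend`).
#' @param max_evalue E-value acceptance threshold (default 1e-5).
#' @param max_domain_hits maximum masked re-alignment rounds per
#'   (query, profile) pair.
#' @return a `search_params` list.
#' @export
search_params <- function(kmer_len = 5, min_diag_kmers = 2,
                          band_halfwidth = 4, gap_open = 11, gap_extend = 1,
                          max_evalue = 1e-5, max_domain_hits = 10) {
  stopifnot(gap_open >= gap_extend, gap_extend >= 1, max_evalue > 0,
            kmer_len >= 3, min_diag_kmers >= 1)
  structure(list(kmer_len = kmer_len, min_diag_kmers = min_diag_kmers,
                 band_halfwidth = band_halfwidth, gap_open = gap_open,
                 gap_extend = gap_extend, max_evalue = max_evalue,
                 max_domain_hits = max_domain_hits),
            class = "search_params")
}

empty_hits <- function() {
  data.frame(query_id = character(), target_id = character(),
             db_name = character(), db_role = character(),
             q_start = integer(), q_end = integer(),
             t_start = integer(), t_end = integer(),
             raw_score = numeric(), bit_score = numeric(),
             e_value = numeric(), pct_identity = numeric(),
             n_cols = integer(), n_match = integer(),
             n_mismatch = integer(), n_gapopen = integer(),
             stringsAsFactors = FALSE)
}

#' k-mer prefilter against a sequence database
#'
#' A target is a candidate when it shares at least `min_diag_kmers` query
#' k-mers whose diagonals (`t_pos - q_pos`) fall in a common band of
#' half-width `band_halfwidth`.  Candidates are returned by decreasing
#' shared-k-mer count, ties by target id.
#'
#' @param residues query protein string.
#' @param db a `sequence_db`.
#' @param params a `search_params` (its `kmer_len` must match the index).
#' @return data frame with `target_id` and `n_shared` (the best in-band
#'   k-mer count).
#' @export
prefilter <- function(residues, db, params = search_params()) {
  if (params$kmer_len != db$kmer_len) {
    stop("prefilter kmer_len (", params$kmer_len,
         ") does not match the database index (", db$kmer_len, ")",
         call. = FALSE)
  }
  qk <- enumerate_kmers(residues, db$kmer_len)
  hits <- db$index[qk$kmer]
  keep <- !vapply(hits, is.null, logical(1))
  if (!any(keep)) {
    return(data.frame(target_id = character(), n_shared = integer(),
                      stringsAsFactors = FALSE))
  }
  qpos <- rep(qk$pos[keep], vapply(hits[keep], nrow, 1L))
  tab <- do.call(rbind, hits[keep])
  diag <- tab$pos - qpos
  counts <- vapply(split(diag, tab$target), max_band_count,
                   integer(1), w = 2L * params$band_halfwidth)
  counts <- counts[counts >= params$min_diag_kmers]
  if (!length(counts)) {
    return(data.frame(target_id = character(), n_shared = integer(),
                      stringsAsFactors = FALSE))
  }
  ids <- db$entries$id[as.integer(names(counts))]
  ord <- order(-counts, ids)
  data.frame(target_id = ids[ord], n_shared = as.integer(counts[ord]),
             stringsAsFactors = FALSE)
}

# most diagonals within any window of width w (inclusive): max k-mer matches
# whose diagonals differ pairwise by <= w
max_band_count <- function(diags, w) {
  d <- sort(diags)
  n <- length(d)
  j <- 1L
  best <- 1L
  for (i in seq_len(n)) {
    while (d[i] - d[j] > w) j <- j + 1L
    best <- max(best, i - j + 1L)
  }
  best
}

#' Search queries against a sequence database
#'
#' For each query: prefilter, gapped local alignment against every
#' candidate, Karlin-Altschul E-value; hits with `e_value < max_evalue` are
#' returned.  The search space of the E-value is query length times the
#' summed length of this database's targets (each database is filtered
#' independently).
#'
#' @param queries a protein `seq_set`.
#' @param db a `sequence_db`.
#' @param params a `search_params`.
#' @return a hit table (one row per retained hit) ordered by
#'   (`query_id`, `e_value`, `-bit_score`, `target_id`); intervals are
#'   0-based half-open.
#' @export
search_sequence_db <- function(queries, db, params = search_params()) {
  out <- list()
  for (i in seq_len(nrow(queries))) {
    qid <- queries$id[i]
    qres <- queries$residues[i]
    if (nchar(qres) < db$kmer_len) next
    cand <- prefilter(qres, db, params)
    for (tid in cand$target_id) {
      tres <- db$entries$residues[match(tid, db$entries$id)]
      aln <- align_local(qres, tres, params$gap_open, params$gap_extend)
      if (is.null(aln)) next
      ev <- evalue_sequence(aln$score, nchar(qres), db$db_size_letters)
      if (ev$e_value >= params$max_evalue) next
      out[[length(out) + 1L]] <- data.frame(
        query_id = qid, target_id = tid, db_name = db$name,
        db_role = "sequence",
        q_start = aln$q_start, q_end = aln$q_end,
        t_start = aln$t_start, t_end = aln$t_end,
        raw_score = aln$score, bit_score = ev$bit_score,
        e_value = ev$e_value, pct_identity = aln$pct_identity,
        n_cols = aln$n_cols, n_match = aln$n_match,
        n_mismatch = aln$n_mismatch, n_gapopen = aln$n_gapopen,
        stringsAsFactors = FALSE)
    }
  }
  sort_hits(do.call(rbind, out) %||% empty_hits())
}

#' Search queries against a profile database
#'
#' Every (query, profile) pair is aligned (no prefilter: profile databases
#' are small).  Multiple non-identical hits per pair are found by masked
#' re-alignment: the aligned query span is replaced by the hard mask and the
#' query re-aligned, up to `max_domain_hits` rounds, stopping when the
#' E-value fails the threshold.
#'
#' @param queries a protein `seq_set`.
#' @param pdb a `profile_db` with calibrated profiles.
#' @param params a `search_params`.
#' @return a hit table as [search_sequence_db()]; `pct_identity` is identity
#'   to the profile consensus.
#' @export
search_profile_db <- function(queries, pdb, params = search_params()) {
  out <- list()
  for (i in seq_len(nrow(queries))) {
    qid <- queries$id[i]
    for (pid in names(pdb$profiles)) {
      prof <- pdb$profiles[[pid]]
      if (!is.finite(prof$gumbel_lambda)) {
        stop("profile '", pid, "' is not calibrated", call. = FALSE)
      }
      qres <- queries$residues[i]
      for (round in seq_len(params$max_domain_hits)) {
        aln <- align_profile(qres, prof, params$gap_open, params$gap_extend)
        if (is.null(aln)) break
        ev <- evalue_profile(aln$score, nchar(queries$residues[i]), prof)
        if (ev$e_value >= params$max_evalue) break
        out[[length(out) + 1L]] <- data.frame(
          query_id = qid, target_id = pid, db_name = pdb$name,
          db_role = "profile",
          q_start = aln$q_start, q_end = aln$q_end,
          t_start = aln$t_start, t_end = aln$t_end,
          raw_score = aln$score, bit_score = ev$bit_score,
          e_value = ev$e_value, pct_identity = aln$pct_identity,
          n_cols = aln$n_cols, n_match = aln$n_match,
          n_mismatch = aln$n_mismatch, n_gapopen = aln$n_gapopen,
          stringsAsFactors = FALSE)
        # mask the matched span and look for further domain instances
        qres <- mask_span(qres, aln$q_start, aln$q_end)
      }
    }
  }
  sort_hits(do.call(rbind, out) %||% empty_hits())
}

mask_span <- function(residues, start0, end0) {
  paste0(substr(residues, 1, start0),
         strrep("*", end0 - start0),
         substr(residues, end0 + 1, nchar(residues)))
}

# deterministic global hit order
sort_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits <- hits[order(hits$query_id, hits$db_name, hits$e_value,
                     -hits$bit_score, hits$target_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write hits in BLAST tabular (M8) format
#'
#' 12 columns: qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore, with 1-based inclusive coordinates.
#' @param hits a hit table.
#' @param path output path.
#' @export
write_m8 <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                   hits$query_id, hits$target_id, hits$pct_identity,
                   hits$n_cols, hits$n_mismatch, hits$n_gapopen,
                   hits$q_start + 1L, hits$q_end, hits$t_start + 1L,
                   hits$t_end, format_evalue(hits$e_value), hits$bit_score)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BLAST tabular (M8) file
#'
#' Companion reader for [write_m8()]; coordinates stay 1-based inclusive as
#' in the file.
#' @param path path to an M8 file.
#' @return data frame with the 12 canonical columns.
#' @export
read_m8 <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (file.size(path) == 0) {
    df <- as.data.frame(setNames(rep(list(character(0)), 12), cols))
    return(df)
  }
  df <- read.delim(path, header = FALSE, col.names = cols,
                   stringsAsFactors = FALSE)
  df
}

format_evalue <- function(e) sprintf("%.3g", e)
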