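# Linear-time greedy redundancy clustering in the spirit of linclust: group
# sequences by shared selected k-mers, verify candidate members against the
# group centre by gapped alignment, never all-vs-all.

#' Clustering parameters
#'
#' @param min_seq_id minimum member-representative identity (fraction).
#' @param min_cov minimum bidirectional coverage: the verifying alignment
#'   must span at least this fraction of both sequences.
#' @param kmer_len k-mer length for minimum-hash selection.
#' @param kmers_per_seq number of selected k-mers per sequence.
#' @param seed seed of the k-mer hash.
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(min_seq_id = 0.9, min_cov = 0.8, kmer_len = 10,
                           kmers_per_seq = 20, seed = 42) {
  stopifnot(min_seq_id > 0, min_seq_id <= 1, min_cov > 0, min_cov <= 1,
            kmer_len >= 4, kmers_per_seq >= 1)
  structure(list(min_seq_id = min_seq_id, min_cov = min_cov,
                 kmer_len = kmer_len, kmers_per_seq = kmers_per_seq,
                 seed = seed),
            class = "cluster_params")
}

#' Select minimum-hash k-mers of a sequence
#'
#' Returns the `m` k-mers with the smallest seeded hash values (all k-mers
#' when fewer exist), deterministically for a fixed seed.  Ties are broken
#' by sequence position, so duplicated k-mers can appear at several
#' positions.
#'
#' @param residues protein string.
#' @param k k-mer length.
#' @param m number of k-mers to select.
#' @param seed hash seed.
#' @return data frame with `kmer`, `pos` (0-based), `hash`.
#' @export
select_kmers <- function(residues, k, m, seed) {
  km <- enumerate_kmers(residues, k)
  if (!nrow(km)) {
    km$hash <- numeric(0)
    return(km)
  }
  km$hash <- kmer_hash(km$kmer, seed)
  km <- km[order(km$hash, km$pos), , drop = FALSE]
  head(km, m)
}

# Seeded polynomial hash over residue codes, exact in doubles: the base is
# kept below 2^21 so every intermediate stays below 2^53.  Modulus is the
# Mersenne prime 2^31 - 1.
kmer_hash <- function(kmers, seed) {
  p <- 2147483647
  b <- (abs(seed) * 2654435761 + 104729) %% 2097152
  if (b < 256) b <- b + 256
  k <- nchar(kmers[1])
  mat <- matrix(match(unlist(strsplit(kmers, "", fixed = TRUE)),
                      AA_ALPHABET), nrow = k)
  h <- rep(0, length(kmers))
  inc <- (seed %% p) + 1
  for (r in seq_len(k)) {
    h <- (h * b + mat[r, ] * 104729 + inc) %% p
  }
  h
}

#' Cluster redundant protein sequences
#'
#' Sequences are processed from longest to shortest (ties by id).  Each
#' sequence is compared only against the representatives that share one of
#' its selected k-mers; the first representative it verifies against (local
#' alignment with identity >= `min_seq_id` and coverage >= `min_cov` of
#' both sequences) absorbs it, otherwise it founds its own cluster.  The
#' number of verification alignments is bounded by
#' `n * kmers_per_seq`, never quadratic.
#'
#' @param queries a protein `seq_set` with unique ids.
#' @param params a `cluster_params`.
#' @return a `cluster_set`: list with `clusters` (named list
#'   representative id -> member ids, representative included), `params`,
#'   and `n_verifications` (alignment counter).
#' @export
cluster_sequences <- function(queries, params = cluster_params()) {
  if (anyDuplicated(queries$id)) stop("duplicate query ids", call. = FALSE)
  n <- nrow(queries)
  cs <- list(clusters = list(), params = params, n_verifications = 0L)
  class(cs) <- "cluster_set"
  if (n == 0) return(cs)

  ord <- order(-nchar(queries$residues), queries$id)
  assignment <- setNames(rep(NA_character_, n), queries$id)
  # k-mer -> id of the first (longest) representative that carried it
  kmer_owner <- new.env(parent = emptyenv())
  n_ver <- 0L

  for (i in ord) {
    id <- queries$id[i]
    res <- queries$residues[i]
    sel <- select_kmers(res, params$kmer_len, params$kmers_per_seq,
                        params$seed)
    # candidate representatives: owners of this sequence's selected k-mers
    cand <- unique(unlist(lapply(sel$kmer, function(km) {
      if (exists(km, envir = kmer_owner, inherits = FALSE))
        get(km, envir = kmer_owner) else NULL
    })))
    assigned <- FALSE
    for (rep_id in cand) {
      rep_res <- queries$residues[match(rep_id, queries$id)]
      n_ver <- n_ver + 1L
      if (verify_pair(res, rep_res, params)) {
        assignment[id] <- rep_id
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      assignment[id] <- id
      for (km in sel$kmer) {
        if (!exists(km, envir = kmer_owner, inherits = FALSE)) {
          assign(km, id, envir = kmer_owner)
        }
      }
    }
  }

  reps <- unique(assignment[queries$id[ord]])
  cs$clusters <- lapply(setNames(reps, reps), function(r) {
    members <- names(assignment)[assignment == r]
    # stable member order: input order
    intersect(queries$id, members)
  })
  cs$n_verifications <- n_ver
  cs
}

# does `a` belong to representative `b`? identity and bidirectional coverage
verify_pair <- function(a, b, params) {
  aln <- align_local(a, b)
  if (is.null(aln)) return(FALSE)
  identity <- aln$n_match / aln$n_cols
  cov_a <- (aln$q_end - aln$q_start) / nchar(a)
  cov_b <- (aln$t_end - aln$t_start) / nchar(b)
  identity >= params$min_seq_id && cov_a >= params$min_cov &&
    cov_b >= params$min_cov
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("cluster_set: %d cluster(s) over %d sequence(s), largest %d\n",
              length(sizes), sum(sizes), if (length(sizes)) max(sizes) else 0))
  invisible(x)
}

#' Representative sequences of a clustering
#'
#' @param cs a `cluster_set`.
#' @param queries the `seq_set` that was clustered.
#' @return a `seq_set` with one record per cluster, in input order of the
#'   representatives.
#' @export
representatives <- function(cs, queries) {
  reps <- names(cs$clusters)
  idx <- match(reps, queries$id)
  if (anyNA(idx)) {
    stop("cluster set is inconsistent with the query set (unknown id '",
         reps[which(is.na(idx))[1]], "')", call. = FALSE)
  }
  out <- queries[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alphabet") <- attr(queries, "alphabet")
  class(out) <- c("seq_set", "data.frame")
  out
}

#' Write a cluster table
#'
#' Two tab-separated columns, `representative_id` and `member_id`, one row
#' per member.
#' @param cs a `cluster_set`.
#' @param path output path.
#' @export
write_cluster_tsv <- function(cs, path) {
  rep_col <- rep(names(cs$clusters), lengths(cs$clusters))
  mem_col <- unlist(cs$clusters, use.names = FALSE)
  writeLines(c("representative_id\tmember_id",
               if (length(rep_col)) paste(rep_col, mem_col, sep = "\t")),
             path)
  invisible(path)
}

#' Read a cluster table written by [write_cluster_tsv()]
#' @param path path to the TSV.
#' @return a named list representative id -> member ids.
#' @export
read_cluster_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character")
  split(df$member_id, factor(df$representative_id,
                             levels = unique(df$representative_id)))
}

# trivial clustering: every sequence its own representative
identity_clusters <- function(queries) {
  cs <- list(clusters = lapply(setNames(queries$id, queries$id), identity),
             params = NULL, n_verifications = 0L)
  class(cs) <- "cluster_set"
  cs
}
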