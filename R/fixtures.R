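# Synthetic reference databases and query sets with planted ground truth.
# All generators are deterministic for a fixed seed and emit exactly the
# formats the pipeline consumes.  Point mutations are drawn from
# BLOSUM62-conditional substitution probabilities (excluding the original
# residue), so a copy "at identity x" matches its source at exactly
# round((1 - x) * L) substituted positions.

# uniform integer draw from an inclusive range, safe for degenerate ranges
sample_range <- function(range, n) {
  range[1] + sample.int(range[2] - range[1] + 1L, n, replace = TRUE) - 1L
}

# mutate a protein at exactly round((1 - identity) * L) positions
mutate_protein <- function(residues, identity) {
  stopifnot(identity > 0, identity <= 1)
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  n_mut <- round((1 - identity) * length(ch))
  if (n_mut == 0) return(residues)
  pos <- sample(length(ch), n_mut)
  aa20 <- AA_ALPHABET[1:20]
  for (p in pos) {
    from <- ch[p]
    probs <- AA_CONDITIONAL[from, ]
    probs[from] <- 0
    ch[p] <- sample(aa20, 1, prob = probs)
  }
  paste(ch, collapse = "")
}

random_go_terms <- function(n_max = 3) {
  n <- sample(0:n_max, 1)
  if (n == 0) return("")
  paste(sprintf("GO:%07d", sample(1e6, n)), collapse = "|")
}

#' Generate a synthetic sequence database fixture
#'
#' Random proteins from the background composition with synthetic
#' annotation metadata (description, 0-3 GO ids, orthogroup label).
#'
#' @param n_targets number of targets.
#' @param len_range integer range of target lengths.
#' @param seed seed; output files are byte-identical for a fixed seed.
#' @param dir output directory (created).
#' @return list with `fasta` and `metadata` paths.
#' @export
make_sequence_db_fixture <- function(n_targets, len_range = c(150, 400),
                                     seed = 1,
                                     dir = tempfile("seqdb_fixture")) {
  stopifnot(n_targets >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(derive_seed(seed, "sequence-db-fixture"), {
    lens <- sample_range(len_range, n_targets)
    ids <- sprintf("T%04d", seq_len(n_targets))
    seqs <- vapply(lens, random_protein, character(1))
    meta <- data.frame(
      target_id = ids,
      description = sprintf("synthetic protein %d", seq_len(n_targets)),
      go_terms = vapply(seq_len(n_targets), function(i) random_go_terms(),
                        character(1)),
      orthogroup = sprintf("OG%04d", sample(500, n_targets, replace = TRUE)),
      domain_name = "", stringsAsFactors = FALSE)
    fasta <- file.path(dir, "targets.fasta")
    write_fasta(seq_set(ids, meta$description, seqs), fasta)
    meta_path <- file.path(dir, "metadata.tsv")
    write_metadata_tsv(meta, meta_path)
    list(fasta = fasta, metadata = meta_path)
  })
}

#' Generate a synthetic profile database fixture
#'
#' Each profile is one MSA: a random master sequence plus mutated copies at
#' the requested within-MSA identity (gapless).
#'
#' @param n_profiles number of profiles.
#' @param n_seqs_per_msa rows per MSA (master included).
#' @param len_range integer range of master lengths.
#' @param within_msa_identity identity of each copy to the master,
#'   in (0.5, 1].
#' @param seed seed.
#' @param dir output directory (created); MSAs under `<dir>/msa`.
#' @return list with `msa_dir`, `metadata`, and `masters` (named vector of
#'   master sequences, the planted consensus truth).
#' @export
make_profile_db_fixture <- function(n_profiles, n_seqs_per_msa = 10,
                                    len_range = c(60, 120),
                                    within_msa_identity = 0.9, seed = 1,
                                    dir = tempfile("profdb_fixture")) {
  stopifnot(within_msa_identity > 0.5, within_msa_identity <= 1)
  msa_dir <- file.path(dir, "msa")
  dir.create(msa_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(derive_seed(seed, "profile-db-fixture"), {
    ids <- sprintf("PF%04d", seq_len(n_profiles))
    masters <- character(n_profiles)
    for (i in seq_len(n_profiles)) {
      len <- sample_range(len_range, 1)
      master <- random_protein(len)
      masters[i] <- master
      rows <- c(master,
                vapply(seq_len(n_seqs_per_msa - 1), function(j) {
                  mutate_protein(master, within_msa_identity)
                }, character(1)))
      msa <- seq_set(sprintf("%s_row%d", ids[i], seq_along(rows)), "", rows)
      write_fasta(msa, file.path(msa_dir, paste0(ids[i], ".fasta")))
    }
    names(masters) <- ids
    meta <- data.frame(
      target_id = ids,
      description = sprintf("synthetic domain family %d",
                            seq_len(n_profiles)),
      go_terms = vapply(seq_len(n_profiles), function(i) random_go_terms(),
                        character(1)),
      orthogroup = "",
      domain_name = sprintf("DOM_%04d", seq_len(n_profiles)),
      stringsAsFactors = FALSE)
    meta_path <- file.path(dir, "metadata.tsv")
    write_metadata_tsv(meta, meta_path)
    list(msa_dir = msa_dir, metadata = meta_path, masters = masters)
  })
}

#' Generate a query fixture with planted ground truth
#'
#' Non-decoy queries are point-mutated copies of random sequence-database
#' targets (at `homolog_identity`); when `n_domains_per_query > 0`, mutated
#' profile masters (at `domain_identity`) joined by random linkers are
#' appended, and their query intervals recorded.  Decoy queries are pure
#' background with no planted signal.
#'
#' @param seq_db_fasta FASTA of the sequence database the homologs are
#'   drawn from.
#' @param profile_masters named vector of profile master sequences (from
#'   [make_profile_db_fixture()]); may be `NULL`.
#' @param n_queries total query count.
#' @param homolog_identity identity of each query to its source target.
#' @param domain_identity identity of planted domain segments to the
#'   profile master.
#' @param n_domains_per_query planted domain segments per non-decoy query.
#' @param decoy_fraction fraction of queries that are pure background.
#' @param linker_len length of the random linkers around domain segments.
#' @param seed seed.
#' @param dir output directory.
#' @return list with `fasta`, `truth_json`, and `truth` (per query: source
#'   target or `NA`, planted domain intervals as 1-based inclusive
#'   `[start, end]`, decoy flag).
#' @export
make_query_fixture <- function(seq_db_fasta, profile_masters = NULL,
                               n_queries = 40, homolog_identity = 0.7,
                               domain_identity = 0.8,
                               n_domains_per_query = 1,
                               decoy_fraction = 0.1, linker_len = 15,
                               seed = 1, dir = tempfile("query_fixture")) {
  stopifnot(homolog_identity > 0, homolog_identity <= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  targets <- read_fasta(seq_db_fasta, "protein")
  with_seed(derive_seed(seed, "query-fixture"), {
    n_decoy <- round(decoy_fraction * n_queries)
    decoy <- seq_len(n_queries) > (n_queries - n_decoy)
    truth <- vector("list", n_queries)
    ids <- sprintf("Q%04d", seq_len(n_queries))
    seqs <- character(n_queries)
    for (i in seq_len(n_queries)) {
      if (decoy[i]) {
        seqs[i] <- random_protein(sample_range(c(150, 350), 1))
        truth[[i]] <- list(query_id = ids[i], source_target = NA_character_,
                           domains = list(), decoy = TRUE)
        next
      }
      src <- sample(nrow(targets), 1)
      body <- mutate_protein(targets$residues[src], homolog_identity)
      domains <- list()
      if (!is.null(profile_masters) && n_domains_per_query > 0) {
        picks <- sample(names(profile_masters), n_domains_per_query,
                        replace = FALSE)
        for (pid in picks) {
          seg <- mutate_protein(profile_masters[[pid]], domain_identity)
          linker <- random_protein(linker_len)
          start <- nchar(body) + nchar(linker) + 1L
          body <- paste0(body, linker, seg)
          domains[[length(domains) + 1L]] <-
            list(profile_id = pid, q_start = start,
                 q_end = start + nchar(seg) - 1L)
        }
      }
      seqs[i] <- body
      truth[[i]] <- list(query_id = ids[i],
                         source_target = targets$id[src],
                         domains = domains, decoy = FALSE)
    }
    fasta <- file.path(dir, "queries.fasta")
    write_fasta(seq_set(ids, "", seqs), fasta)
    truth_json <- file.path(dir, "truth.json")
    jsonlite::write_json(truth, truth_json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    list(fasta = fasta, truth_json = truth_json, truth = truth)
  })
}

#' Generate a redundant query fixture for clustering tests
#'
#' Each base query is replicated with point mutations at `copy_identity`;
#' the intended cluster grouping is returned as truth.
#'
#' @param base_queries a protein `seq_set` of base sequences.
#' @param copies_per_query copies per base (base included in the group).
#' @param copy_identity identity of each copy to its base.
#' @param seed seed.
#' @param dir output directory.
#' @return list with `fasta` and `groups` (named list base id -> member
#'   ids, base's own id included).
#' @export
make_redundant_fixture <- function(base_queries, copies_per_query = 4,
                                   copy_identity = 0.9, seed = 1,
                                   dir = tempfile("redundant_fixture")) {
  stopifnot(copy_identity > 0, copy_identity <= 1, copies_per_query >= 1)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(derive_seed(seed, "redundant-fixture"), {
    ids <- character(0); seqs <- character(0)
    groups <- list()
    for (i in seq_len(nrow(base_queries))) {
      base_id <- base_queries$id[i]
      g <- base_id
      ids <- c(ids, base_id)
      seqs <- c(seqs, base_queries$residues[i])
      for (k in seq_len(copies_per_query - 1)) {
        cid <- sprintf("%s_copy%d", base_id, k)
        ids <- c(ids, cid)
        seqs <- c(seqs, mutate_protein(base_queries$residues[i],
                                       copy_identity))
        g <- c(g, cid)
      }
      groups[[base_id]] <- g
    }
    fasta <- file.path(dir, "redundant.fasta")
    write_fasta(seq_set(ids, "", seqs), fasta)
    list(fasta = fasta, groups = groups)
  })
}
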