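# Independent oracles used across the suite.  These deliberately share no
# code with the package internals: the alignment oracle is a plain-R
# wavefront DP, clustering truth comes from Biostrings::pairwiseAlignment,
# and the tiling oracle re-simulates the greedy policy from its definition.

# ---- alignment oracle -----------------------------------------------------

# score-only affine-gap local DP; colscore[i, a] = gain of query residue
# index a (1-based) at target column i; gap of length k costs open+k*extend
oracle_local_score <- function(qidx1, colscore, open = 11, extend = 1) {
  m <- length(qidx1)
  n <- nrow(colscore)
  NEG <- -1e30
  gi <- open + extend
  Hprev <- numeric(m + 1)
  Fprev <- rep(NEG, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    H <- numeric(m + 1)
    E <- rep(NEG, m + 1)
    F <- rep(NEG, m + 1)
    for (j in seq_len(m)) {
      E[j + 1] <- max(H[j] - gi, E[j] - extend)
      F[j + 1] <- max(Hprev[j + 1] - gi, Fprev[j + 1] - extend)
      h <- max(0, Hprev[j] + colscore[i, qidx1[j]], E[j + 1], F[j + 1])
      H[j + 1] <- h
      if (h > best) best <- h
    }
    Hprev <- H
    Fprev <- F
  }
  best
}

aa_idx1 <- function(s) match(strsplit(s, "", fixed = TRUE)[[1]],
                             protannot:::AA_ALPHABET)

oracle_seq_score <- function(q, t, open = 11, extend = 1) {
  sub <- protannot:::BLOSUM62_MAT
  oracle_local_score(aa_idx1(q), sub[aa_idx1(t), , drop = FALSE],
                     open, extend)
}

oracle_profile_score <- function(q, profile, open = 11, extend = 1) {
  oracle_local_score(aa_idx1(q), profile$colscore, open, extend)
}

# Biostrings-based local alignment (independent library implementation)
biostrings_local <- function(q, t, open = 11, extend = 1) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  Biostrings::pairwiseAlignment(q, t, type = "local",
                                substitutionMatrix = env$BLOSUM62,
                                gapOpening = open, gapExtension = extend)
}

# ---- prefilter oracle -----------------------------------------------------

# brute-force diagonal k-mer counting straight from the definition
oracle_prefilter <- function(query, targets, k, min_diag_kmers,
                             band_halfwidth) {
  qk <- substring(query, 1:(nchar(query) - k + 1),
                  k:nchar(query))
  counts <- integer(0)
  for (tid in names(targets)) {
    t <- targets[[tid]]
    if (nchar(t) < k) next
    tk <- substring(t, 1:(nchar(t) - k + 1), k:nchar(t))
    diags <- integer(0)
    for (qp in seq_along(qk)) {
      tp <- which(tk == qk[qp])
      diags <- c(diags, (tp - 1L) - (qp - 1L))
    }
    if (!length(diags)) next
    best <- 0L
    for (centre in sort(unique(diags))) {
      best <- max(best, sum(abs(diags - centre) <= band_halfwidth))
    }
    if (best >= min_diag_kmers) counts[tid] <- best
  }
  if (!length(counts)) {
    return(data.frame(target_id = character(), n_shared = integer(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(-counts, names(counts))
  data.frame(target_id = names(counts)[ord],
             n_shared = as.integer(counts[ord]), stringsAsFactors = FALSE)
}

# ---- clustering oracle ----------------------------------------------------

# all-vs-all identity/coverage graph -> connected components
oracle_cluster_groups <- function(queries, min_seq_id, min_cov) {
  n <- nrow(queries)
  adj <- diag(TRUE, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      aln <- biostrings_local(queries$residues[i], queries$residues[j])
      if (Biostrings::score(aln) <= 0) next
      w <- Biostrings::nchar(aln)   # alignment length incl gaps
      idy <- Biostrings::nmatch(aln) / w
      cov_i <- Biostrings::width(Biostrings::pattern(aln)) /
        nchar(queries$residues[i])
      cov_j <- Biostrings::width(Biostrings::subject(aln)) /
        nchar(queries$residues[j])
      if (idy >= min_seq_id && cov_i >= min_cov && cov_j >= min_cov) {
        adj[i, j] <- adj[j, i] <- TRUE
      }
    }
  }
  comp <- rep(0L, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (comp[v]) next
      comp[v] <- cur
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  unname(split(queries$id, comp))
}

# ---- tiling oracle --------------------------------------------------------

# literal re-simulation of the greedy policy (independent code path)
oracle_tiling_ids <- function(hits, max_overlap = 0) {
  ord <- order(hits$e_value, -hits$bit_score, hits$q_start, hits$target_id)
  acc <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (a in acc) {
      ov <- min(hits$q_end[i], hits$q_end[a]) -
        max(hits$q_start[i], hits$q_start[a])
      if (ov > max_overlap) { ok <- FALSE; break }
    }
    if (ok) acc <- c(acc, i)
  }
  sort(acc)
}

# ---- misc generators ------------------------------------------------------

random_seq_set <- function(n, len_range = c(30, 120), id_prefix = "s") {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  protannot:::seq_set(sprintf("%s%03d", id_prefix, seq_len(n)),
                      ifelse(seq_len(n) %% 2 == 0,
                             sprintf("random record %d", seq_len(n)), ""),
                      vapply(lens, protannot:::random_protein,
                             character(1)))
}

random_hit_table <- function(n, query_len = 200) {
  starts <- sample(0:(query_len - 30), n, replace = TRUE)
  widths <- sample(10:60, n, replace = TRUE)
  data.frame(
    query_id = "q1", target_id = sprintf("P%02d", sample(99, n)),
    db_name = "profdb", db_role = "profile",
    q_start = starts, q_end = pmin(starts + widths, query_len),
    t_start = 0L, t_end = widths,
    raw_score = round(runif(n, 20, 90)),
    bit_score = round(runif(n, 20, 90), 1),
    e_value = 10^runif(n, -30, -6),
    pct_identity = round(runif(n, 30, 100), 1),
    n_cols = widths, n_match = widths, n_mismatch = 0L, n_gapopen = 0L,
    stringsAsFactors = FALSE)
}

# standard genetic code entered independently (codon -> amino acid)
STD_CODON_TABLE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

# independent six-frame translation built on the table above
oracle_translate_frame <- function(dna, frame) {
  revcomp <- function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]),
                                   collapse = ""))
  }
  s <- if (frame > 0) dna else revcomp(dna)
  off <- abs(frame) - 1
  s <- substr(s, off + 1, nchar(s))
  n_codons <- nchar(s) %/% 3
  if (n_codons == 0) return("")
  codons <- substring(s, seq(1, by = 3, length.out = n_codons),
                      seq(3, by = 3, length.out = n_codons))
  aa <- ifelse(grepl("N", codons), "X", unname(STD_CODON_TABLE[codons]))
  paste(aa, collapse = "")
}
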