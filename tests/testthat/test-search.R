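test_that("self-alignment scores the BLOSUM62 diagonal and 100% identity", {
  a <- align_local("MKVLYA", "MKVLYA")
  expect_equal(a$score, 29)   # M5 K5 V4 L4 Y7 A4
  expect_equal(a$pct_identity, 100)
  expect_equal(c(a$q_start, a$q_end), c(0L, 6L))
})

test_that("alignment with no positive pair score reports no hit", {
  expect_null(align_local("AAAA", "CCCC"))
  expect_null(align_profile(strrep("X", 30),
                            local({
                              msa <- protannot:::seq_set(c("a", "b"), "",
                                                         c("MKVL", "MKVL"))
                              build_profile(msa, "p1")
                            })))
})

test_that("aligner agrees exactly with an independent R DP and Biostrings", {
  set.seed(404)
  for (i in 1:40) {
    q <- protannot:::random_protein(sample(20:120, 1))
    t <- protannot:::random_protein(sample(20:120, 1))
    a <- align_local(q, t)
    got <- if (is.null(a)) 0 else a$score
    expect_equal(got, oracle_seq_score(q, t))
  }
  # cross-check against the library implementation on positive-score pairs
  for (i in 1:15) {
    src <- protannot:::random_protein(80)
    mut <- protannot:::with_seed(500 + i,
                                 protannot:::mutate_protein(src, 0.7))
    a <- align_local(mut, src)
    expect_equal(a$score,
                 Biostrings::score(biostrings_local(mut, src)))
  }
})

test_that("profile alignment equals the PSSM DP oracle", {
  set.seed(405)
  msa_master <- protannot:::random_protein(60)
  msa <- protannot:::seq_set(
    sprintf("r%d", 1:6), "",
    c(msa_master,
      vapply(1:5, function(i) protannot:::mutate_protein(msa_master, 0.85),
             character(1))))
  prof <- build_profile(msa, "pf1")
  for (i in 1:40) {
    q <- protannot:::random_protein(sample(20:100, 1))
    a <- align_profile(q, prof)
    got <- if (is.null(a)) 0 else a$score
    expect_equal(got, oracle_profile_score(q, prof), tolerance = 1e-9)
  }
  # consensus aligns over all match columns with per-column maxima
  a <- align_profile(prof$consensus, prof)
  expect_equal(c(a$t_start, a$t_end), c(0L, prof$length))
  expect_equal(a$score, sum(apply(prof$pssm, 1, max)), tolerance = 1e-9)
  expect_equal(a$pct_identity, 100)
})

test_that("Karlin-Altschul bit scores and E-values follow the closed form", {
  # bit score zero <=> E equals the search space m*n
  s0 <- log(0.041) / 0.267
  ev <- evalue_sequence(s0, 300, 1e5)
  expect_equal(ev$bit_score, 0, tolerance = 1e-12)
  expect_equal(ev$e_value, 300 * 1e5)

  # one extra bit halves E
  e1 <- evalue_sequence(100, 250, 5e4)
  e2 <- evalue_sequence(100 + 1 / 0.267 * log(2), 250, 5e4)
  expect_equal(e2$e_value, e1$e_value / 2, tolerance = 1e-9)

  # hand-computed example
  ev <- evalue_sequence(100, 300, 1e5, lambda = 0.267, K = 0.041)
  bit_hand <- (0.267 * 100 - log(0.041)) / log(2)
  expect_equal(ev$bit_score, bit_hand)
  expect_equal(ev$e_value, 300 * 1e5 * 2^(-bit_hand))

  expect_error(evalue_sequence(50, 0, 100), "positive")
})

test_that("prefilter matches brute-force diagonal k-mer counting", {
  set.seed(406)
  fx <- make_sequence_db_fixture(30, c(80, 160), seed = 21)
  db <- build_sequence_db(fx$fasta, fx$metadata, "db")
  targets <- setNames(db$entries$residues, db$entries$id)
  params <- search_params()

  # identical query: its source is a candidate with the maximal count
  q_self <- db$entries$residues[7]
  got <- prefilter(q_self, db, params)
  expect_equal(got$target_id[1], db$entries$id[7])

  # query sharing no k-mer with the database
  expect_equal(nrow(prefilter(strrep("W", 40), db, params)), 0L)

  for (i in 1:8) {
    q <- if (i <= 4) protannot:::random_protein(100)
         else protannot:::with_seed(600 + i,
                protannot:::mutate_protein(targets[[sample(30, 1)]], 0.75))
    want <- oracle_prefilter(q, as.list(targets), params$kmer_len,
                             params$min_diag_kmers, params$band_halfwidth)
    got <- prefilter(q, db, params)
    expect_equal(got$target_id, want$target_id)
    expect_equal(got$n_shared, want$n_shared)
  }
})

test_that("sequence search recovers planted homologs and ranks self-hits first", {
  fx <- make_sequence_db_fixture(25, c(120, 250), seed = 22)
  db <- build_sequence_db(fx$fasta, fx$metadata, "db")
  qfx <- make_query_fixture(fx$fasta, NULL, n_queries = 15,
                            homolog_identity = 0.7,
                            n_domains_per_query = 0, decoy_fraction = 0,
                            seed = 22)
  queries <- read_fasta(qfx$fasta, "protein")
  hits <- search_sequence_db(queries, db)
  expect_true(all(hits$e_value < 1e-5))
  for (t in qfx$truth) {
    qh <- hits[hits$query_id == t$query_id, ]
    expect_gt(nrow(qh), 0)
    top <- qh[order(-qh$bit_score), ][1, ]
    expect_equal(top$target_id, t$source_target)
  }

  # a query identical to a target ranks that target first by bit score
  self_q <- protannot:::seq_set("selfq", "", db$entries$residues[3])
  sh <- search_sequence_db(self_q, db)
  expect_equal(sh$target_id[order(-sh$bit_score)][1], db$entries$id[3])
})

test_that("tightening max_evalue yields a subset of hits", {
  fx <- make_sequence_db_fixture(20, c(100, 200), seed = 23)
  db <- build_sequence_db(fx$fasta, fx$metadata, "db")
  qfx <- make_query_fixture(fx$fasta, NULL, n_queries = 10,
                            homolog_identity = 0.6,
                            n_domains_per_query = 0, decoy_fraction = 0.2,
                            seed = 23)
  queries <- read_fasta(qfx$fasta, "protein")
  loose <- search_sequence_db(queries, db, search_params(max_evalue = 1e-3))
  tight <- search_sequence_db(queries, db, search_params(max_evalue = 1e-8))
  key <- function(h) paste(h$query_id, h$target_id, h$q_start)
  expect_true(all(key(tight) %in% key(loose)))
  expect_true(all(tight$e_value < 1e-8))
})

test_that("random queries almost never hit the database at E < 1e-5", {
  set.seed(407)
  fx <- make_sequence_db_fixture(40, c(150, 300), seed = 24)
  db <- build_sequence_db(fx$fasta, fx$metadata, "db")
  decoys <- protannot:::seq_set(
    sprintf("d%03d", 1:50), "",
    vapply(sample(150:300, 50, replace = TRUE),
           protannot:::random_protein, character(1)))
  hits <- search_sequence_db(decoys, db)
  expect_lte(length(unique(hits$query_id)), 1)   # >= 98% hit-free
})

test_that("profile search finds multiple domains at the right positions", {
  pfx <- make_profile_db_fixture(4, 8, c(50, 80), 0.9, seed = 25)
  pdb <- load_profile_db(pfx$msa_dir, pfx$metadata, "pdb", seed = 25)

  # two different consensi concatenated -> one hit per profile, in place
  c1 <- pdb$profiles[[1]]$consensus
  c2 <- pdb$profiles[[2]]$consensus
  q <- protannot:::seq_set("q2dom", "", paste0(c1, c2))
  hits <- search_profile_db(q, pdb)
  h1 <- hits[hits$target_id == names(pdb$profiles)[1], ]
  h2 <- hits[hits$target_id == names(pdb$profiles)[2], ]
  expect_equal(nrow(h1), 1)
  expect_equal(nrow(h2), 1)
  expect_equal(c(h1$q_start, h1$q_end), c(0L, nchar(c1)))
  expect_equal(c(h2$q_start, h2$q_end), c(nchar(c1), nchar(c1) + nchar(c2)))

  # tandem repeat of one consensus -> two disjoint hits to the same profile
  qq <- protannot:::seq_set("qtandem", "", paste0(c1, c1))
  th <- search_profile_db(qq, pdb)
  th <- th[th$target_id == names(pdb$profiles)[1], ]
  expect_equal(nrow(th), 2)
  expect_lte(min(th$q_end), max(th$q_start))   # disjoint intervals

  # an all-X query has no hits
  xq <- protannot:::seq_set("qx", "", strrep("X", 120))
  expect_equal(nrow(search_profile_db(xq, pdb)), 0L)
})

test_that("M8 output round-trips with 1-based inclusive coordinates", {
  fx <- make_sequence_db_fixture(10, c(100, 150), seed = 26)
  db <- build_sequence_db(fx$fasta, fx$metadata, "db")
  q <- protannot:::seq_set("q1", "", db$entries$residues[5])
  hits <- search_sequence_db(q, db)
  f <- withr::local_tempfile(fileext = ".m8")
  write_m8(hits, f)
  back <- read_m8(f)
  expect_equal(nrow(back), nrow(hits))
  expect_equal(back$qstart, hits$q_start + 1L)
  expect_equal(back$qend, hits$q_end)        # half-open end == inclusive end
  expect_equal(back$sstart, hits$t_start + 1L)
  expect_equal(back$qseqid, hits$query_id)
  # full-length self hit spans 1..len in the file
  self_row <- back[back$sseqid == db$entries$id[5], ]
  expect_equal(self_row$qstart, 1L)
  expect_equal(self_row$qend, nchar(db$entries$residues[5]))
})
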