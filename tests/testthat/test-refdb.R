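write_tmp_fasta <- function(ids, seqs, desc = "") {
  f <- tempfile(fileext = ".fasta")
  write_fasta(protannot:::seq_set(ids, desc, seqs), f)
  f
}

write_tmp_meta <- function(df) {
  f <- tempfile(fileext = ".tsv")
  protannot:::write_metadata_tsv(df, f)
  f
}

meta_row <- function(id, desc = "", go = "", og = "", dom = "") {
  data.frame(target_id = id, description = desc, go_terms = go,
             orthogroup = og, domain_name = dom, stringsAsFactors = FALSE)
}

test_that("sequence databases join metadata and index k-mers", {
  fa <- write_tmp_fasta(c("P1", "P2", "P3"),
                        c("MKVLMKVL", "ACDEFGHIKL", "WYVACDEF"))
  meta <- rbind(meta_row("P1", "kinase", "GO:0008150|GO:0003674", "OG1"),
                meta_row("P2", "phosphatase", "GO:0001234", "OG2"),
                meta_row("P3", "unknown", "", "OG3"))
  db <- build_sequence_db(fa, write_tmp_meta(meta), "testdb", kmer_len = 4)
  expect_equal(nrow(db$entries), 3)
  expect_equal(db$metadata["P1", "description"], "kinase")
  expect_equal(strsplit(db$metadata["P1", "go_terms"], "|", fixed = TRUE)[[1]],
               c("GO:0008150", "GO:0003674"))
  # repeated k-mer of a repeated sequence appears at both positions
  mkvl <- db$index[["MKVL"]]
  expect_equal(nrow(mkvl[mkvl$target == 1, ]), 2)
  expect_equal(mkvl$pos[mkvl$target == 1], c(0L, 4L))
  expect_equal(db$db_size_letters, 8L + 10L + 8L)
})

test_that("metadata mismatches warn and malformed GO ids fail", {
  fa <- write_tmp_fasta(c("P1", "P2"), c("MKVLAYTRPW", "ACDEFGHIKL"))
  # FASTA id absent from metadata -> warning, empty annotations
  m1 <- write_tmp_meta(meta_row("P1", "only one"))
  expect_warning(db <- build_sequence_db(fa, m1, "db"), "without metadata")
  expect_equal(db$metadata["P2", "description"], "")
  # metadata id absent from FASTA -> warning, kept
  m2 <- write_tmp_meta(rbind(meta_row("P1"), meta_row("P2"),
                             meta_row("P9", "orphan")))
  expect_warning(build_sequence_db(fa, m2, "db"), "without a matching")
  # malformed GO id -> format error
  m3 <- write_tmp_meta(meta_row("P1", go = "GO:123"))
  expect_error(read_metadata_tsv(m3), "malformed GO")
})

test_that("PSSM construction follows the pseudocount formula", {
  # degenerate identical MSA, vanishing pseudocount
  msa <- protannot:::seq_set(c("a", "b"), "", c("MK", "MK"))
  p <- build_profile(msa, "p0", pseudocount_alpha = 1e-9)
  expect_equal(p$consensus, "MK")
  expect_equal(p$length, 2)
  expect_equal(unname(apply(p$pssm, 1, which.max)),
               match(c("M", "K"), protannot:::AA_ALPHABET[1:20]))

  # hand-computed column: A,A,A,C with alpha = 0 and uniform background
  msa4 <- protannot:::seq_set(sprintf("r%d", 1:4), "",
                              c("A", "A", "A", "C"))
  p4 <- build_profile(msa4, "p4", pseudocount_alpha = 0,
                      background = rep(0.05, 20))
  expect_equal(unname(p4$pssm[1, "A"]), 2 * log2(0.75 / 0.05))
  expect_equal(unname(p4$pssm[1, "C"]), 2 * log2(0.25 / 0.05))

  # a column over 50% gaps is not a match state
  msa_g <- protannot:::seq_set(sprintf("r%d", 1:5), "",
                               c("M-K", "M-K", "M-K", "MAK", "MAK"))
  pg <- build_profile(msa_g, "pg")
  expect_equal(pg$length, 2)
  expect_equal(pg$consensus, "MK")

  # consensus residue always carries the column's maximal score
  set.seed(408)
  master <- protannot:::random_protein(40)
  msa_r <- protannot:::seq_set(sprintf("r%d", 1:8), "",
                               c(master, vapply(1:7, function(i)
                                 protannot:::mutate_protein(master, 0.8),
                                 character(1))))
  pr <- build_profile(msa_r, "pr")
  cons <- strsplit(pr$consensus, "")[[1]]
  for (i in seq_len(pr$length)) {
    expect_equal(unname(pr$pssm[i, cons[i]]), max(pr$pssm[i, ]))
  }

  # error cases
  expect_error(build_profile(protannot:::seq_set("a", "", "MK"), "p"),
               "at least 2")
  expect_error(build_profile(protannot:::seq_set(c("a", "b"), "",
                                                 c("MK", "MKV")), "p"),
               "ragged")
})

test_that("Gumbel calibration is deterministic and moment fitting is sound", {
  set.seed(409)
  master <- protannot:::random_protein(50)
  msa <- protannot:::seq_set(sprintf("r%d", 1:6), "",
                             c(master, vapply(1:5, function(i)
                               protannot:::mutate_protein(master, 0.85),
                               character(1))))
  prof <- build_profile(msa, "pcal")
  c1 <- calibrate_profile(prof, n_shuffles = 120, shuffle_len = 80,
                          seed = 77)
  c2 <- calibrate_profile(prof, n_shuffles = 120, shuffle_len = 80,
                          seed = 77)
  expect_identical(c1$gumbel_lambda, c2$gumbel_lambda)
  expect_identical(c1$gumbel_K, c2$gumbel_K)
  expect_gt(c1$gumbel_lambda, 0)
  expect_gt(c1$gumbel_K, 0)

  # the moment estimator recovers a known Gumbel's lambda = 1/beta
  x <- protannot:::with_seed(410, 10 - 2 * log(-log(runif(5000))))
  fit <- protannot:::fit_gumbel_moments(x)
  expect_equal(fit$lambda, 1 / 2, tolerance = 0.1)
  expect_equal(fit$mu, 10, tolerance = 0.05)

  # scale equivariance: doubling all scores roughly halves lambda
  prof2 <- prof
  prof2$pssm <- prof$pssm * 2
  prof2$colscore <- protannot:::profile_colscore(prof2$pssm)
  # gap costs scale with the scores so the optimal paths are unchanged
  c2x <- calibrate_profile(prof2, n_shuffles = 120, shuffle_len = 80,
                           seed = 77, gap_open = 22, gap_extend = 2)
  expect_equal(c2x$gumbel_lambda, c1$gumbel_lambda / 2, tolerance = 0.01)
})

test_that("profile databases load from MSA dirs with Stockholm accessions", {
  dir <- tempfile("msadir")
  dir.create(dir)
  set.seed(411)
  for (i in 1:3) {
    master <- protannot:::random_protein(40)
    rows <- c(master, vapply(1:4, function(j)
      protannot:::mutate_protein(master, 0.9), character(1)))
    write_fasta(protannot:::seq_set(sprintf("fam%d_r%d", i, 1:5), "", rows),
                file.path(dir, sprintf("fam%d.fasta", i)))
  }
  # one Stockholm file carrying an accession
  sto <- c("# STOCKHOLM 1.0", "#=GF AC PF99999.12",
           "seq1   MKVLAYTRPW", "seq2   MKVLAYTRPW", "seq3   MKVAAYTRPW",
           "//")
  writeLines(sto, file.path(dir, "fam4.sto"))
  meta <- do.call(rbind, c(
    lapply(1:3, function(i) meta_row(sprintf("fam%d", i),
                                     dom = sprintf("DOM%d", i))),
    list(meta_row("PF99999", dom = "DOM4"))))
  suppressWarnings(
    pdb <- load_profile_db(dir, write_tmp_meta(meta), "pdb",
                           n_shuffles = 100, shuffle_len = 60, seed = 5))
  expect_equal(length(pdb$profiles), 4)
  expect_true("PF99999" %in% names(pdb$profiles))
  expect_equal(pdb$metadata["fam2", "domain_name"], "DOM2")

  # missing metadata row warns and yields empty annotations
  meta_short <- meta[1:3, ]
  expect_warning(
    pdb2 <- load_profile_db(dir, write_tmp_meta(meta_short), "pdb",
                            n_shuffles = 100, shuffle_len = 60, seed = 5),
    "without metadata")
  expect_equal(pdb2$metadata["PF99999", "description"], "")

  expect_error(load_profile_db(tempfile("nodir"), write_tmp_meta(meta),
                               "pdb"), "not found")
})

test_that("compiled databases round-trip and rebuild deterministically", {
  sfx <- make_sequence_db_fixture(8, c(80, 120), seed = 41)
  d1 <- tempfile("cdb1")
  expect_equal(suppressMessages(
    cmd_createdb(sfx$fasta, sfx$metadata, "sequence", d1)), 0L)
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$role, "sequence")
  db <- load_compiled_db(d1)
  expect_s3_class(db, "sequence_db")
  expect_equal(nrow(db$entries), 8)

  # rebuilding with the same inputs gives byte-identical checksums
  d2 <- tempfile("cdb2")
  suppressMessages(cmd_createdb(sfx$fasta, sfx$metadata, "sequence", d2))
  man2 <- jsonlite::read_json(file.path(d2, "manifest.json"))
  expect_identical(man$md5, man2$md5)

  # profile role
  pfx <- make_profile_db_fixture(3, 6, c(40, 60), 0.9, seed = 41)
  d3 <- tempfile("cdb3")
  expect_equal(suppressMessages(
    cmd_createdb(pfx$msa_dir, pfx$metadata, "profile", d3,
                 n_shuffles = 100, shuffle_len = 60)), 0L)
  pdb <- load_compiled_db(d3)
  expect_s3_class(pdb, "profile_db")
  expect_equal(length(pdb$profiles), 3)
  expect_true(all(vapply(pdb$profiles, function(p) p$gumbel_lambda,
                         numeric(1)) > 0))
})
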