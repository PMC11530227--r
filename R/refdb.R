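# Annotation target databases: one protein sequence database with a k-mer
# index, and profile databases built from directories of MSAs.  Each carries
# per-target annotation metadata (description, GO terms, orthogroup, domain).

empty_meta_row <- function(target_id) {
  data.frame(target_id = target_id, description = "", go_terms = "",
             orthogroup = "", domain_name = "", stringsAsFactors = FALSE)
}

#' Read an annotation metadata table
#'
#' Tab-separated with a header; required column `target_id`, optional
#' `description`, `go_terms` (pipe-separated `GO:NNNNNNN` ids),
#' `orthogroup`, `domain_name`.  Missing optional columns are filled empty.
#' @param path path to the TSV.
#' @return data frame with the five canonical columns.
#' @export
read_metadata_tsv <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path,
                               call. = FALSE)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!("target_id" %in% names(df))) {
    stop("metadata ", path, " lacks a 'target_id' column", call. = FALSE)
  }
  for (col in c("description", "go_terms", "orthogroup", "domain_name")) {
    if (!(col %in% names(df))) df[[col]] <- ""
  }
  df <- df[, c("target_id", "description", "go_terms", "orthogroup",
               "domain_name")]
  df[is.na(df)] <- ""
  go <- setdiff(unlist(strsplit(df$go_terms, "|", fixed = TRUE)), "")
  bad <- go[!grepl("^GO:[0-9]{7}$", go)]
  if (length(bad)) {
    stop("malformed GO identifier '", bad[1], "' in ", path, call. = FALSE)
  }
  if (anyDuplicated(df$target_id)) {
    stop("duplicate target_id in metadata ", path, call. = FALSE)
  }
  df
}

write_metadata_tsv <- function(meta, path) {
  write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# join metadata onto a set of ids; absent rows become empty (with a warning)
join_metadata <- function(ids, meta, what = "target") {
  missing <- setdiff(ids, meta$target_id)
  if (length(missing)) {
    warning(length(missing), " ", what,
            "(s) without metadata (empty annotations assigned), e.g. '",
            missing[1], "'", call. = FALSE)
    meta <- rbind(meta, do.call(rbind, lapply(missing, empty_meta_row)))
  }
  extra <- setdiff(meta$target_id, ids)
  if (length(extra)) {
    warning(length(extra), " metadata row(s) without a matching ", what,
            ", e.g. '", extra[1], "' (kept)", call. = FALSE)
  }
  rownames(meta) <- meta$target_id
  meta
}

# all k-mers of a sequence as a data.frame(kmer, pos) with 0-based positions
enumerate_kmers <- function(residues, k) {
  n <- nchar(residues) - k + 1L
  if (n < 1) {
    return(data.frame(kmer = character(), pos = integer(),
                      stringsAsFactors = FALSE))
  }
  data.frame(kmer = substring(residues, 1:n, k:(n + k - 1L)),
             pos = 0:(n - 1L), stringsAsFactors = FALSE)
}

#' Build a sequence database with a k-mer index
#'
#' @param fasta_path protein FASTA of targets.
#' @param metadata_path annotation metadata TSV ([read_metadata_tsv()]).
#' @param name database name (appears in output `db_name` columns).
#' @param kmer_len k-mer length of the prefilter index (default 5).
#' @return a `sequence_db`: targets, metadata joined by id, the inverted
#'   k-mer index, and `db_size_letters` (summed target lengths) used for
#'   E-values.
#' @export
build_sequence_db <- function(fasta_path, metadata_path, name,
                              kmer_len = 5) {
  entries <- read_fasta(fasta_path, "protein")
  meta <- read_metadata_tsv(metadata_path)
  meta <- join_metadata(entries$id, meta)
  km <- lapply(seq_len(nrow(entries)), function(i) {
    d <- enumerate_kmers(entries$residues[i], kmer_len)
    if (nrow(d)) d$target <- i
    d
  })
  km <- do.call(rbind, km[vapply(km, nrow, 1L) > 0])
  index <- if (is.null(km)) list() else {
    km <- km[order(km$kmer, km$target, km$pos), ]
    split(km[, c("target", "pos")], km$kmer)
  }
  db <- list(name = name, role = "sequence", entries = entries,
             metadata = meta, kmer_len = kmer_len, index = index,
             db_size_letters = sum(nchar(entries$residues)))
  class(db) <- "sequence_db"
  db
}

#' @export
print.sequence_db <- function(x, ...) {
  cat(sprintf("sequence_db '%s': %d targets, %d residues, %d-mer index\n",
              x$name, nrow(x$entries), x$db_size_letters, x$kmer_len))
  invisible(x)
}

# ---- MSA reading (aligned FASTA or Stockholm) -----------------------------

read_msa_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonempty <- lines[nzchar(trimws(lines))]
  if (!length(nonempty)) stop("empty MSA file: ", path, call. = FALSE)
  if (startsWith(nonempty[1], "# STOCKHOLM")) read_stockholm(lines, path)
  else {
    msa <- read_fasta_alignment(path)
    list(msa = msa, accession = NA_character_)
  }
}

# aligned FASTA: like read_fasta but gap characters allowed
read_fasta_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path, format = "fasta")
  if (!length(ss)) stop("empty MSA file: ", path, call. = FALSE)
  id <- sub("\\s.*$", "", names(ss))
  df <- seq_set(id, "", toupper(as.character(ss)), "protein")
  ok <- grepl(paste0("^[", paste(AA_ALPHABET[1:21], collapse = ""), ".\\-]+$"),
              df$residues)
  if (!all(ok)) {
    stop("illegal residue in MSA row '", df$id[which(!ok)[1]], "' of ", path,
         call. = FALSE)
  }
  df
}

read_stockholm <- function(lines, path) {
  acc <- NA_character_
  seqs <- list()
  for (ln in lines) {
    if (startsWith(ln, "#=GF AC")) {
      acc <- sub("\\..*$", "", trimws(sub("^#=GF AC", "", ln)))
    } else if (!startsWith(ln, "#") && !startsWith(ln, "//") &&
               nzchar(trimws(ln))) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(parts) >= 2) {
        seqs[[parts[1]]] <- paste0(seqs[[parts[1]]] %||% "",
                                   toupper(parts[2]))
      }
    }
  }
  if (!length(seqs)) stop("no sequences in Stockholm file ", path,
                          call. = FALSE)
  msa <- seq_set(names(seqs), "", unlist(seqs, use.names = FALSE), "protein")
  list(msa = msa, accession = acc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load and calibrate a profile database from a directory of MSAs
#'
#' One profile per MSA file (aligned FASTA or Stockholm).  Profile ids are
#' the file stems, or the Stockholm `#=GF AC` accession when present.  Each
#' profile's calibration seed is derived deterministically from `seed` and
#' the profile id, so the database is reproducible regardless of file order.
#'
#' @param dir_path directory of MSA files.
#' @param metadata_path annotation metadata TSV.
#' @param name database name.
#' @param pseudocount_alpha,n_shuffles,shuffle_len,seed profile construction
#'   and calibration parameters ([build_profile()], [calibrate_profile()]).
#' @return a `profile_db`: named list of calibrated profiles plus metadata.
#' @export
load_profile_db <- function(dir_path, metadata_path, name,
                            pseudocount_alpha = 1, n_shuffles = 200,
                            shuffle_len = 150, seed = 42) {
  if (!dir.exists(dir_path)) stop("profile directory not found: ", dir_path,
                                  call. = FALSE)
  files <- sort(list.files(dir_path, full.names = TRUE,
                           pattern = "\\.(fa|fasta|afa|aln|sto|stk)$"))
  if (!length(files)) stop("no MSA files in ", dir_path, call. = FALSE)
  meta <- read_metadata_tsv(metadata_path)
  profiles <- list()
  for (f in files) {
    parsed <- tryCatch(read_msa_file(f), error = function(e) {
      stop("failed to read MSA '", basename(f), "': ",
           conditionMessage(e), call. = FALSE)
    })
    id <- if (!is.na(parsed$accession)) parsed$accession
          else sub("\\.[^.]*$", "", basename(f))
    prof <- build_profile(parsed$msa, id, pseudocount_alpha)
    prof <- calibrate_profile(prof, n_shuffles, shuffle_len,
                              seed = derive_seed(seed, id))
    if (id %in% names(profiles)) {
      stop("duplicate profile id '", id, "' in ", dir_path, call. = FALSE)
    }
    profiles[[id]] <- prof
  }
  meta <- join_metadata(names(profiles), meta, what = "profile")
  pdb <- list(name = name, role = "profile", profiles = profiles,
              metadata = meta)
  class(pdb) <- "profile_db"
  pdb
}

#' @export
print.profile_db <- function(x, ...) {
  cat(sprintf("profile_db '%s': %d profiles (%s)\n", x$name,
              length(x$profiles),
              paste(head(names(x$profiles), 5), collapse = ", ")))
  invisible(x)
}

# deterministic 31-bit seed from a base seed and a string label
derive_seed <- function(seed, label) {
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  as.integer(h)
}

# ---- compiled on-disk databases -------------------------------------------

#' Compile a database directory for later annotation runs
#'
#' Sequence role: copies the FASTA and metadata next to a JSON manifest.
#' Profile role: copies the MSA directory and metadata; profiles are rebuilt
#' and recalibrated deterministically on load from the recorded seed.
#'
#' @param input_path FASTA (sequence role) or MSA directory (profile role).
#' @param metadata_path metadata TSV.
#' @param role `"sequence"` or `"profile"`.
#' @param out_dir output directory (created).
#' @param name database name (default: basename of `out_dir`).
#' @param kmer_len,seed,n_shuffles,shuffle_len,pseudocount_alpha build
#'   parameters recorded in the manifest.
#' @return `out_dir`, invisibly.
#' @export
compile_db <- function(input_path, metadata_path,
                       role = c("sequence", "profile"), out_dir,
                       name = basename(out_dir), kmer_len = 5, seed = 42,
                       n_shuffles = 200, shuffle_len = 150,
                       pseudocount_alpha = 1) {
  role <- match.arg(role)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- read_metadata_tsv(metadata_path)    # validates
  write_metadata_tsv(meta, file.path(out_dir, "metadata.tsv"))
  if (role == "sequence") {
    seqs <- read_fasta(input_path, "protein") # validates
    write_fasta(seqs, file.path(out_dir, "targets.fasta"))
    payload <- "targets.fasta"
  } else {
    msa_out <- file.path(out_dir, "msa")
    dir.create(msa_out, showWarnings = FALSE)
    files <- sort(list.files(input_path, full.names = TRUE,
                             pattern = "\\.(fa|fasta|afa|aln|sto|stk)$"))
    if (!length(files)) stop("no MSA files in ", input_path, call. = FALSE)
    for (f in files) {
      read_msa_file(f)                        # validates
      file.copy(f, file.path(msa_out, basename(f)), overwrite = TRUE)
    }
    payload <- "msa"
  }
  payload_files <- if (role == "sequence") payload
                   else file.path("msa", sort(list.files(file.path(out_dir, "msa"))))
  checks <- tools::md5sum(file.path(out_dir, c(payload_files, "metadata.tsv")))
  names(checks) <- c(payload_files, "metadata.tsv")
  manifest <- list(
    format = "protannot-db", version = 1L, name = name, role = role,
    payload = payload,
    params = list(kmer_len = kmer_len, seed = seed, n_shuffles = n_shuffles,
                  shuffle_len = shuffle_len,
                  pseudocount_alpha = pseudocount_alpha),
    md5 = as.list(checks))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Load a compiled database directory
#'
#' @param db_dir a directory produced by [compile_db()].
#' @return a `sequence_db` or `profile_db` according to the manifest role.
#' @export
load_compiled_db <- function(db_dir) {
  mf <- file.path(db_dir, "manifest.json")
  if (!file.exists(mf)) {
    stop("'", db_dir, "' is not a compiled database (no manifest.json); ",
         "build one with compile_db()/createdb", call. = FALSE)
  }
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(man$format, "protannot-db")) {
    stop("unrecognised database manifest in ", db_dir, call. = FALSE)
  }
  p <- man$params
  meta_path <- file.path(db_dir, "metadata.tsv")
  if (man$role == "sequence") {
    build_sequence_db(file.path(db_dir, man$payload), meta_path,
                      name = man$name, kmer_len = p$kmer_len)
  } else {
    load_profile_db(file.path(db_dir, man$payload), meta_path,
                    name = man$name, pseudocount_alpha = p$pseudocount_alpha,
                    n_shuffles = p$n_shuffles, shuffle_len = p$shuffle_len,
                    seed = p$seed)
  }
}
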