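# Sequence input/output and translation.
#
# Sequence sets are plain data frames with columns id, description, residues
# and an "alphabet" attribute ("protein" or "dna").  Internal coordinates are
# 0-based half-open; anything written for users is 1-based inclusive.

seq_set <- function(id = character(), description = character(),
                    residues = character(), alphabet = "protein") {
  df <- data.frame(id = as.character(id),
                   description = as.character(description),
                   residues = as.character(residues),
                   stringsAsFactors = FALSE)
  attr(df, "alphabet") <- alphabet
  class(df) <- c("seq_set", "data.frame")
  df
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set of %d %s sequence(s)\n", nrow(x), attr(x, "alphabet")))
  if (nrow(x)) {
    shown <- head(x, 6)
    for (i in seq_len(nrow(shown))) {
      r <- shown$residues[i]
      cat(sprintf("  %s  [%d] %s%s\n", shown$id[i], nchar(r),
                  substr(r, 1, 40), if (nchar(r) > 40) "..." else ""))
    }
    if (nrow(x) > 6) cat(sprintf("  ... and %d more\n", nrow(x) - 6))
  }
  invisible(x)
}

validate_residues <- function(df, alphabet) {
  legal <- if (alphabet == "dna") DNA_ALPHABET else AA_ALPHABET
  for (i in seq_len(nrow(df))) {
    ch <- strsplit(df$residues[i], "", fixed = TRUE)[[1]]
    bad <- which(!(ch %in% legal))
    if (length(bad)) {
      stop(sprintf("illegal %s residue '%s' in record '%s' at position %d",
                   alphabet, ch[bad[1]], df$id[i], bad[1]), call. = FALSE)
    }
    if (!length(ch)) {
      stop(sprintf("record '%s' has empty sequence", df$id[i]), call. = FALSE)
    }
  }
  invisible(df)
}

#' Read a FASTA file
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines).
#' @param alphabet `"protein"` or `"dna"`; residues are validated against the
#'   declared alphabet and uppercased.
#' @return a `seq_set` data frame with columns `id`, `description`,
#'   `residues`, one row per record in file order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ss <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                 error = function(e) stop("not a valid FASTA file: ", path,
                                          " (", conditionMessage(e), ")",
                                          call. = FALSE))
  if (length(ss) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(ss)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id '", id[duplicated(id)][1], "' in ", path,
         call. = FALSE)
  }
  if (any(id == "")) stop("empty sequence id in ", path, call. = FALSE)
  df <- seq_set(id, description, toupper(as.character(ss)), alphabet)
  validate_residues(df, alphabet)
  df
}

#' Write a FASTA file
#'
#' Round-trips through [read_fasta()]: ids, descriptions and residues are
#' preserved exactly.
#' @param records a `seq_set` data frame.
#' @param path output path.
#' @export
write_fasta <- function(records, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path,
                                           call. = FALSE))
  on.exit(close(con))
  if (nrow(records)) {
    hdr <- ifelse(nchar(records$description) > 0,
                  paste(records$id, records$description),
                  records$id)
    writeLines(paste0(">", hdr, "\n", records$residues, collapse = "\n"),
               con)
  }
  invisible(path)
}

#' Read a FASTQ file
#'
#' Strict 4-line-per-record FASTQ.  Qualities are validated (same length as
#' the sequence) and then discarded; the pipeline only needs the residues.
#' @param path path to an uncompressed FASTQ file.
#' @return a `seq_set` with alphabet `"dna"`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  while (length(lines) && lines[length(lines)] == "")
    lines <- lines[-length(lines)]
  if (!length(lines)) stop("empty FASTQ file: ", path, call. = FALSE)
  if (length(lines) %% 4 != 0) {
    stop("truncated FASTQ record in ", path, " (", length(lines),
         " lines, not a multiple of 4)", call. = FALSE)
  }
  n <- length(lines) / 4
  hdr <- lines[seq(1, by = 4, length.out = n)]
  seqs <- toupper(lines[seq(2, by = 4, length.out = n)])
  plus <- lines[seq(3, by = 4, length.out = n)]
  qual <- lines[seq(4, by = 4, length.out = n)]
  if (any(!startsWith(hdr, "@")) || any(!startsWith(plus, "+"))) {
    stop("malformed FASTQ record in ", path, call. = FALSE)
  }
  if (any(nchar(seqs) != nchar(qual))) {
    i <- which(nchar(seqs) != nchar(qual))[1]
    stop(sprintf("FASTQ record '%s': sequence and quality lengths differ",
                 sub("^@", "", sub("\\s.*$", "", hdr[i]))), call. = FALSE)
  }
  id <- sub("\\s.*$", "", substring(hdr, 2))
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  df <- seq_set(id, desc, seqs, "dna")
  validate_residues(df, "dna")
  df
}

#' Six-frame translation
#'
#' Translates a DNA sequence in all six frames under the standard genetic
#' code.  Frames `-k` are frames `+k` of the reverse complement.  Trailing
#' partial codons are dropped, stop codons render `*`, and codons containing
#' `N` render `X`.
#' @param residues a DNA sequence string.
#' @return named character vector of 6 protein strings
#'   (`"+1","+2","+3","-1","-2","-3"`).
#' @export
six_frame_translate <- function(residues) {
  fwd <- Biostrings::DNAString(residues)
  rev <- Biostrings::reverseComplement(fwd)
  tr1 <- function(s, off) {
    len <- (length(s) - off) %/% 3 * 3
    if (len < 3) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(s, start = off + 1, width = len),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
  }
  out <- c(tr1(fwd, 0), tr1(fwd, 1), tr1(fwd, 2),
           tr1(rev, 0), tr1(rev, 1), tr1(rev, 2))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

#' Extract open reading frames from a DNA record
#'
#' ORFs are maximal stop-free stretches in any of the six frame translations
#' (stop-to-stop, not ATG-initiated), of length at least `min_len_aa`.
#'
#' @param id,residues id and DNA residues of the input record.
#' @param min_len_aa minimum ORF length in amino acids (default 30).
#' @return data frame with columns `orf_id`, `parent_id`, `frame`,
#'   `start_nt` (0-based offset of the ORF on the forward strand),
#'   `length_aa`, `residues`.  `orf_id` is `"<parent>_f<frame>_<k>"`.
#' @export
extract_orfs <- function(id, residues, min_len_aa = 30) {
  stopifnot(min_len_aa >= 1)
  L <- nchar(residues)
  frames <- six_frame_translate(residues)
  out <- list()
  for (fr in names(frames)) {
    aa <- frames[[fr]]
    if (!nchar(aa)) next
    # maximal stop-free runs
    runs <- gregexpr("[^*]+", aa)[[1]]
    if (runs[1] == -1) next
    lens <- attr(runs, "match.length")
    keep <- lens >= min_len_aa
    if (!any(keep)) next
    starts_aa <- (runs - 1L)[keep]   # 0-based aa offset within frame
    lens <- lens[keep]
    fnum <- as.integer(fr)
    off <- abs(fnum) - 1L
    for (k in seq_along(starts_aa)) {
      nt0_in_frame <- off + 3L * starts_aa[k]
      start_nt <- if (fnum > 0) nt0_in_frame
                  else L - nt0_in_frame - 3L * lens[k]
      out[[length(out) + 1L]] <- data.frame(
        orf_id = sprintf("%s_f%s_%d", id, fr, k),
        parent_id = id, frame = fr, start_nt = start_nt,
        length_aa = lens[k],
        residues = substr(aa, starts_aa[k] + 1L, starts_aa[k] + lens[k]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(orf_id = character(), parent_id = character(),
                      frame = character(), start_nt = integer(),
                      length_aa = integer(), residues = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# ORFs of a whole seq_set, as a protein seq_set ready for search
orf_query_set <- function(records, min_len_aa = 30) {
  orfs <- lapply(seq_len(nrow(records)), function(i) {
    extract_orfs(records$id[i], records$residues[i], min_len_aa)
  })
  orfs <- do.call(rbind, orfs)
  if (is.null(orfs) || !nrow(orfs)) return(seq_set())
  seq_set(orfs$orf_id, paste0("parent=", orfs$parent_id), orfs$residues,
          "protein")
}

# interleave two paired-end read sets into one query set
interleave_pairs <- function(r1, r2) {
  n1 <- nrow(r1); n2 <- nrow(r2); k <- min(n1, n2)
  ord <- as.vector(rbind(seq_len(k), n1 + seq_len(k)))
  if (n1 > k) ord <- c(ord, (k + 1L):n1)
  if (n2 > k) ord <- c(ord, n1 + (k + 1L):n2)
  both <- rbind(r1, r2)[ord, , drop = FALSE]
  attr(both, "alphabet") <- "dna"
  class(both) <- c("seq_set", "data.frame")
  rownames(both) <- NULL
  both
}
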