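# Hit-retention policies and annotation transfer: best hit per sequence
# database, non-overlapping tiling per profile database, propagation of
# representative annotations to cluster members, merged TSV output and the
# annotation-rate summary.

#' Best hit of one query in a sequence database
#'
#' Minimal E-value; ties broken by maximal bit score, then lexicographically
#' smallest target id.
#' @param hits a non-empty hit table for one query and one sequence-role
#'   database.
#' @return the selected row.
#' @export
best_hit <- function(hits) {
  stopifnot(nrow(hits) >= 1)
  ord <- order(hits$e_value, -hits$bit_score, hits$target_id)
  hits[ord[1], , drop = FALSE]
}

#' Greedy non-overlapping tiling of profile hits on a query
#'
#' Hits are considered by (E-value ascending, bit score descending, query
#' start ascending, target id); a hit is accepted iff its query interval
#' overlaps every already-accepted hit by at most `max_overlap` residues.
#' The result is maximal (no rejected hit could still be added) and is
#' returned sorted by query start.
#'
#' @param hits a hit table for one query and one profile database.
#' @param max_overlap maximum tolerated overlap in residues (default 0:
#'   strictly non-overlapping).
#' @return the retained subset of `hits`, sorted by `q_start`.
#' @export
tile_nonoverlapping <- function(hits, max_overlap = 0) {
  if (nrow(hits) <= 1) return(hits)
  ord <- order(hits$e_value, -hits$bit_score, hits$q_start, hits$target_id)
  sel <- integer(0)
  for (i in ord) {
    ov <- overlap_len(hits$q_start[i], hits$q_end[i],
                      hits$q_start[sel], hits$q_end[sel])
    if (all(ov <= max_overlap)) sel <- c(sel, i)
  }
  out <- hits[sel[order(hits$q_start[sel])], , drop = FALSE]
  rownames(out) <- NULL
  out
}

# pairwise overlap length of [s, e) with vectors of [s2, e2)
overlap_len <- function(s, e, s2, e2) {
  if (!length(s2)) return(integer(0))
  pmax(0L, pmin(e, e2) - pmax(s, s2))
}

#' Apply retention policies and transfer annotations
#'
#' Sequence-role databases keep the single best hit per query; profile-role
#' databases keep a non-overlapping tiling per query.  Target metadata is
#' joined by id.  When a clustering is supplied, every representative's
#' records are copied to its cluster members (with `inherited` naming the
#' representative).  Output coordinates are 1-based inclusive.
#'
#' @param hits a hit table covering any number of databases
#'   (concatenated search results).
#' @param dbs list of the searched `sequence_db`/`profile_db` objects.
#' @param query_ids all query ids, in input order (drives output order).
#' @param cluster_set optional `cluster_set` for propagation.
#' @param max_overlap tiling tolerance ([tile_nonoverlapping()]).
#' @param propagate copy representative records to members (default TRUE).
#' @return an annotation table: `query_id`, `db_name`, `target_id`,
#'   `q_start`, `q_end` (1-based inclusive), `e_value`, `pct_identity`,
#'   `bit_score`, `description`, `go_terms`, `orthogroup`, `domain_name`,
#'   `inherited`.
#' @export
assemble_annotations <- function(hits, dbs, query_ids, cluster_set = NULL,
                                 max_overlap = 0, propagate = TRUE) {
  meta_all <- list()
  for (db in dbs) meta_all[[db$name]] <- db$metadata
  kept <- list()
  if (nrow(hits)) {
    for (grp in split(hits, list(hits$query_id, hits$db_name), drop = TRUE)) {
      role <- grp$db_role[1]
      kept[[length(kept) + 1L]] <-
        if (role == "sequence") best_hit(grp)
        else tile_nonoverlapping(grp, max_overlap)
    }
  }
  kept <- do.call(rbind, kept) %||% empty_hits()
  recs <- data.frame(
    query_id = kept$query_id, db_name = kept$db_name,
    target_id = kept$target_id,
    q_start = kept$q_start + 1L, q_end = kept$q_end,  # 1-based inclusive
    e_value = kept$e_value, pct_identity = kept$pct_identity,
    bit_score = kept$bit_score, stringsAsFactors = FALSE)
  ann <- lapply(seq_len(nrow(recs)), function(i) {
    meta <- meta_all[[recs$db_name[i]]]
    j <- match(recs$target_id[i], meta$target_id)
    if (is.na(j)) {
      warning("hit to unknown target '", recs$target_id[i],
              "' in database '", recs$db_name[i],
              "' (empty annotations)", call. = FALSE)
      empty_meta_row(recs$target_id[i])[, -1]
    } else meta[j, c("description", "go_terms", "orthogroup",
                     "domain_name")]
  })
  ann <- do.call(rbind, ann)
  recs <- if (nrow(recs)) cbind(recs, ann, inherited = "")
          else cbind(recs, empty_meta_row("x")[0, -1], inherited = character(0))
  rownames(recs) <- NULL

  if (!is.null(cluster_set) && propagate && nrow(recs)) {
    copies <- list()
    for (rep_id in names(cluster_set$clusters)) {
      members <- setdiff(cluster_set$clusters[[rep_id]], rep_id)
      if (!length(members)) next
      rep_recs <- recs[recs$query_id == rep_id, , drop = FALSE]
      if (!nrow(rep_recs)) next
      for (m in members) {
        cp <- rep_recs
        cp$query_id <- m
        cp$inherited <- rep_id
        copies[[length(copies) + 1L]] <- cp
      }
    }
    recs <- do.call(rbind, c(list(recs), copies))
  }

  # deterministic global order: query input order, then db, then q_start
  recs <- recs[order(match(recs$query_id, query_ids), recs$db_name,
                     recs$q_start, recs$target_id), , drop = FALSE]
  rownames(recs) <- NULL
  recs
}

#' Summarise an annotation run
#'
#' A query counts as annotated when it owns at least one record with
#' `pct_identity >= 100 * identity_threshold` in any database (the
#' 50%-identity, any-database rule).
#'
#' @param records an annotation table from [assemble_annotations()].
#' @param all_query_ids every query id that entered the pipeline.
#' @param identity_threshold fraction in `[0, 1]` (default 0.5).
#' @return an `annotation_summary`: `n_queries`, `n_annotated`,
#'   `annotation_rate`, `per_db_counts`, `identity_threshold`.
#' @export
summarize_annotations <- function(records, all_query_ids,
                                  identity_threshold = 0.5) {
  stopifnot(identity_threshold >= 0, identity_threshold <= 1)
  if (!length(all_query_ids)) {
    warning("empty query set: annotation rate reported as 0",
            call. = FALSE)
  }
  ok <- records$pct_identity >= 100 * identity_threshold
  annotated <- unique(records$query_id[ok])
  annotated <- intersect(all_query_ids, annotated)
  per_db <- vapply(split(records$query_id[ok], records$db_name[ok]),
                   function(q) length(unique(q)), integer(1))
  out <- list(n_queries = length(all_query_ids),
              n_annotated = length(annotated),
              annotation_rate = if (length(all_query_ids))
                length(annotated) / length(all_query_ids) else 0,
              per_db_counts = as.list(per_db),
              identity_threshold = identity_threshold)
  class(out) <- "annotation_summary"
  out
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat(sprintf("%d / %d queries annotated (rate %.3f, identity >= %.0f%%)\n",
              x$n_annotated, x$n_queries, x$annotation_rate,
              100 * x$identity_threshold))
  for (db in names(x$per_db_counts)) {
    cat(sprintf("  %s: %d annotated quer%s\n", db, x$per_db_counts[[db]],
                if (x$per_db_counts[[db]] == 1) "y" else "ies"))
  }
  invisible(x)
}

ANNOTATION_COLS <- c("query_id", "db_name", "target_id", "q_start", "q_end",
                     "e_value", "pct_identity", "bit_score", "description",
                     "go_terms", "orthogroup", "domain_name", "inherited")

#' Write the merged annotation table
#'
#' Header plus one row per record; 13 tab-separated columns; E-values
#' formatted `%.3g`, identities and bit scores with one decimal.
#' @param records an annotation table.
#' @param path output path.
#' @export
write_annotation_tsv <- function(records, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write to ", path,
                                           call. = FALSE))
  on.exit(close(con))
  writeLines(paste(ANNOTATION_COLS, collapse = "\t"), con)
  if (nrow(records)) {
    lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%.1f\t%.1f\t%s\t%s\t%s\t%s\t%s",
                     records$query_id, records$db_name, records$target_id,
                     records$q_start, records$q_end,
                     format_evalue(records$e_value), records$pct_identity,
                     records$bit_score, records$description,
                     records$go_terms, records$orthogroup,
                     records$domain_name, records$inherited)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read an annotation table written by [write_annotation_tsv()]
#' @param path path to the TSV.
#' @return annotation table data frame.
#' @export
read_annotation_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = character(0))
  if (!identical(names(df), ANNOTATION_COLS)) {
    stop("'", path, "' is not an annotation table", call. = FALSE)
  }
  for (col in c("q_start", "q_end")) df[[col]] <- as.integer(df[[col]])
  for (col in c("e_value", "pct_identity", "bit_score")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Write the summary sidecar JSON
#' @param summary an `annotation_summary`.
#' @param path output path.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
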