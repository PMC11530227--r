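# The annotation pipeline shared by every command: optional clustering,
# search of every database, retention policies, transfer, outputs.

#' Run the annotation pipeline on an in-memory query set
#'
#' Steps: optional redundancy clustering (annotating representatives only),
#' search of every database, E-value filtering (inside the search), best-hit
#' and tiling retention, annotation transfer with optional propagation to
#' cluster members, and the annotation-rate summary.
#'
#' @param queries a protein `seq_set`.
#' @param dbs list of `sequence_db` / `profile_db` objects.
#' @param params a `search_params`.
#' @param run_clust cluster before searching (default TRUE).
#' @param clust_params a `cluster_params`.
#' @param propagate copy representative annotations to cluster members.
#' @param max_overlap tiling overlap tolerance in residues.
#' @param identity_threshold summary identity threshold (fraction).
#' @param outdir when non-NULL, writes `annotation.tsv`, `summary.json`,
#'   `clusters.tsv` (when clustering ran), per-database `<db>.m8` dumps
#'   when `write_m8 = TRUE`, and `unannotated.txt`.
#' @param write_m8 also dump raw retained hits per database in BLAST
#'   tabular format.
#' @param log a function taking a message string (default `message`).
#' @return list with `records`, `summary`, `cluster_set` (or NULL), `hits`
#'   (the filtered search hits before retention).
#' @export
run_annotation <- function(queries, dbs, params = search_params(),
                           run_clust = TRUE,
                           clust_params = cluster_params(),
                           propagate = TRUE, max_overlap = 0,
                           identity_threshold = 0.5, outdir = NULL,
                           write_m8 = FALSE, log = message) {
  stopifnot(nrow(queries) > 0, length(dbs) >= 1)
  names(dbs) <- vapply(dbs, function(d) d$name, character(1))
  log(sprintf("input: %d quer%s", nrow(queries),
              if (nrow(queries) == 1) "y" else "ies"))

  cs <- NULL
  reps <- queries
  if (run_clust) {
    cs <- cluster_sequences(queries, clust_params)
    reps <- representatives(cs, queries)
    log(sprintf("clustering: %d cluster(s), %d verification alignment(s)",
                length(cs$clusters), cs$n_verifications))
  } else {
    log("clustering: disabled (--no-run-clust)")
  }

  hits <- list()
  for (db in dbs) {
    h <- if (db$role == "sequence") search_sequence_db(reps, db, params)
         else search_profile_db(reps, db, params)
    log(sprintf("search %s [%s]: %d hit(s) at E < %g", db$name, db$role,
                nrow(h), params$max_evalue))
    hits[[db$name]] <- h
  }
  all_hits <- do.call(rbind, unname(hits)) %||% empty_hits()

  records <- assemble_annotations(all_hits, dbs, queries$id,
                                  cluster_set = cs,
                                  max_overlap = max_overlap,
                                  propagate = propagate)
  log(sprintf("retention + transfer: %d annotation record(s)",
              nrow(records)))
  summary <- summarize_annotations(records, queries$id, identity_threshold)
  log(sprintf("annotated: %d / %d queries (rate %.3f)",
              summary$n_annotated, summary$n_queries,
              summary$annotation_rate))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_annotation_tsv(records, file.path(outdir, "annotation.tsv"))
    write_summary_json(summary, file.path(outdir, "summary.json"))
    if (!is.null(cs)) write_cluster_tsv(cs, file.path(outdir, "clusters.tsv"))
    if (write_m8) {
      for (db_name in names(hits)) {
        write_m8(hits[[db_name]], file.path(outdir, paste0(db_name, ".m8")))
      }
    }
    unann <- setdiff(queries$id, unique(records$query_id))
    writeLines(unann, file.path(outdir, "unannotated.txt"))
  }

  list(records = records, summary = summary, cluster_set = cs,
       hits = all_hits)
}
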