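## Corpus input/output: tab-separated tables with header rows; JSON-lines
## accepted for documents (list-valued fields need structure). In TSV
## documents, list fields (mesh_terms, authors, doc_types) are
## semicolon-delimited.

DOC_LIST_COLS <- c("mesh_terms", "authors", "doc_types")

#' Read a document table
#'
#' Accepts JSON-lines (one object per line; `.jsonl`/`.ndjson`, list-valued
#' fields as JSON arrays, metrics either flat or under a `metrics` object) or
#' TSV with a header row (list fields semicolon-delimited).
#'
#' @param path file path.
#' @return data.table of documents with list columns for `mesh_terms`,
#'   `authors`, `doc_types`.
#' @export
read_documents <- function(path) {
  if (!file.exists(path)) stop_litmap("file not found: ", path)
  if (grepl("\\.(jsonl|ndjson)$", path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) {
      docs <- data.table(doc_id = character(0), year = integer(0),
                         journal = character(0))
      for (lc in DOC_LIST_COLS) docs[[lc]] <- list()
      return(docs[])
    }
    recs <- lapply(seq_along(lines), function(k) {
      obj <- tryCatch(jsonlite::fromJSON(lines[k], simplifyVector = TRUE),
                      error = function(e)
                        stop_litmap("malformed line ", k, " in ", path, ": ",
                                    conditionMessage(e)))
      if (!is.null(obj$metrics)) {
        obj <- c(obj[setdiff(names(obj), "metrics")], obj$metrics)
      }
      obj
    })
    all_names <- unique(unlist(lapply(recs, names)))
    cols <- lapply(all_names, function(nm) {
      vals <- lapply(recs, function(r) r[[nm]])
      if (nm %in% DOC_LIST_COLS) {
        lapply(vals, function(v) if (is.null(v)) character(0) else as.character(v))
      } else {
        unlist(lapply(vals, function(v) if (is.null(v)) NA else v))
      }
    })
    docs <- setDT(setNames(cols, all_names))
  } else {
    docs <- fread(path, sep = "\t", header = TRUE, colClasses = list(
      character = intersect(c("doc_id", "title", "abstract", "journal",
                              "tagged_title", "tagged_abstract"),
                            names(fread(path, sep = "\t", nrows = 0)))))
    for (lc in intersect(DOC_LIST_COLS, names(docs)))
      docs[[lc]] <- split_list_field(docs[[lc]])
  }
  if (!"doc_id" %in% names(docs)) docs[, doc_id := character(0)]
  docs[, doc_id := as.character(doc_id)]
  if (anyDuplicated(docs$doc_id))
    stop_litmap("duplicate doc_id in ", path, ": ",
                paste(head(unique(docs$doc_id[duplicated(docs$doc_id)]), 3),
                      collapse = ", "))
  for (lc in setdiff(DOC_LIST_COLS, names(docs)))
    docs[[lc]] <- rep(list(character(0)), nrow(docs))
  docs[]
}

#' Read and filter a complete corpus
#'
#' Loads documents, citation edges and raw similarity records, drops
#' documents from excluded journals, and drops edges/records that reference
#' dropped or unknown documents. Counts of everything dropped are reported.
#'
#' @param doc_path documents file (JSONL or TSV).
#' @param citation_path TSV with columns `citing_id`, `cited_id`.
#' @param sa_path TSV with columns `id_a`, `id_b`, `score`.
#' @param excluded_journals character vector (or path to a file with one
#'   journal name per line); matching is exact-string.
#' @return list `documents`, `citations`, `similarity`, `log` (drop counts).
#' @export
read_corpus <- function(doc_path, citation_path, sa_path,
                        excluded_journals = character(0)) {
  if (length(excluded_journals) == 1L && file.exists(excluded_journals))
    excluded_journals <- readLines(excluded_journals, warn = FALSE)
  docs <- read_documents(doc_path)
  n0 <- nrow(docs)
  docs <- docs[!journal %in% excluded_journals]
  n_dropped_docs <- n0 - nrow(docs)
  keep <- docs$doc_id

  cit <- fread(citation_path, sep = "\t", header = TRUE)
  if (!all(c("citing_id", "cited_id") %in% names(cit)))
    stop_litmap("malformed citation file (need citing_id, cited_id): ",
                citation_path)
  cit[, `:=`(citing_id = as.character(citing_id),
             cited_id = as.character(cited_id))]
  nc0 <- nrow(cit)
  n_self <- cit[citing_id == cited_id, .N]
  if (n_self > 0L) warning(sprintf("dropping %d self-citation(s)", n_self))
  cit <- cit[citing_id != cited_id]
  cit <- cit[citing_id %in% keep & cited_id %in% keep]
  n_dropped_cit <- nc0 - nrow(cit)
  if (n_dropped_cit > n_self)
    warning(sprintf("dropped %d citation edge(s) referencing excluded/unknown documents",
                    n_dropped_cit - n_self))

  sa <- fread(sa_path, sep = "\t", header = TRUE)
  if (!all(c("id_a", "id_b", "score") %in% names(sa)))
    stop_litmap("malformed similarity file (need id_a, id_b, score): ", sa_path)
  sa[, `:=`(id_a = as.character(id_a), id_b = as.character(id_b))]
  if (any(is.na(sa$score)) || any(sa$score < 0))
    stop_litmap("similarity scores must be non-negative in ", sa_path)
  ns0 <- nrow(sa)
  sa <- sa[id_a %in% keep & id_b %in% keep & id_a != id_b]
  n_dropped_sa <- ns0 - nrow(sa)
  if (n_dropped_sa > 0L)
    warning(sprintf("dropped %d similarity record(s) referencing excluded/unknown documents",
                    n_dropped_sa))
  ## unordered-pair dedup
  pk <- pair_key(sa$id_a, sa$id_b)
  sa <- cbind(pk, score = sa$score)[, .(score = max(score)), by = .(i, j)][
    , .(id_a = i, id_b = j, score)]

  list(documents = docs, citations = cit, similarity = sa,
       log = list(docs_in = n0, docs_dropped = n_dropped_docs,
                  citations_dropped = n_dropped_cit,
                  similarity_dropped = ns0 - nrow(sa)))
}

#' Write the workbook-style output tables
#'
#' Writes each characterization sheet (see [characterize_clusters()]) and the
#' document-to-cluster assignment as TSV files with header rows.
#'
#' @param profiles named list of data.tables (sheets).
#' @param assignment cluster assignment table.
#' @param out_dir output directory (created if missing).
#' @return invisible character vector of written paths.
#' @export
write_tables <- function(profiles, assignment, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_litmap("cannot create output directory: ", out_dir)
  }
  paths <- character(0)
  for (nm in names(profiles)) {
    tab <- profiles[[nm]]
    if (is.null(tab)) next
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    fwrite(tab, p, sep = "\t", quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(assignment)) {
    p <- file.path(out_dir, "assignment.tsv")
    asn <- as.data.table(assignment)
    out <- asn[, .(doc_id, PM5, PM4, PM3, removed = as.integer(removed))]
    fwrite(out, p, sep = "\t", quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write / read the relatedness edge list
#'
#' TSV with columns `i`, `j`, `r_dc`, `r_sa`, `r_hyb`, `sa_imputed` (0/1).
#'
#' @param edges RelatednessEdge table.
#' @param path file path.
#' @return `read_edges` returns the data.table; `write_edges` the path,
#'   invisibly.
#' @export
write_edges <- function(edges, path) {
  e <- as.data.table(edges)[, .(i, j, r_dc, r_sa, r_hyb,
                                sa_imputed = as.integer(sa_imputed))]
  fwrite(e, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  e <- fread(path, sep = "\t", header = TRUE,
             colClasses = list(character = c("i", "j")))
  e[, sa_imputed := as.logical(sa_imputed)]
  e[]
}

#' Write documents to JSON-lines
#'
#' The inverse of [read_documents()] for the JSONL dialect.
#'
#' @param documents document table.
#' @param path output path (`.jsonl`).
#' @return the path, invisibly.
#' @export
write_documents <- function(documents, path) {
  docs <- as.data.table(documents)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_len(nrow(docs))) {
    rec <- as.list(docs[k])
    rec <- lapply(rec, function(v) if (is.list(v)) v[[1]] else v)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"),
               con)
  }
  invisible(path)
}
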