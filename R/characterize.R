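## Cluster characterization: phrases, central papers, indicators, overlays.

#' Parse a "word/TAG" encoded token string
#'
#' Tagged text is stored as space-separated `word/TAG` tokens (Penn-style
#' tags). Returns a data.frame of `text`, `pos` suitable for
#' [match_noun_phrases()].
#'
#' @param x a single encoded string.
#' @return data.frame with columns `text`, `pos`.
#' @export
parse_tagged <- function(x) {
  if (is.na(x) || !nzchar(x))
    return(data.frame(text = character(0), pos = character(0)))
  toks <- strsplit(x, " ", fixed = TRUE)[[1]]
  m <- regmatches(toks, regexpr("/[^/]*$", toks))
  pos <- sub("^/", "", m)
  text <- sub("/[^/]*$", "", toks)
  data.frame(text = text, pos = pos)
}

#' Minimal rule-based part-of-speech tagger
#'
#' A deliberately small fallback for untagged text: closed-class words get
#' DT/IN/CC, words ending in -ing get VBG, common adjectival suffixes get JJ,
#' everything else NN. Phrase-grammar behaviour is tagger-independent; tests
#' and the synthetic generator feed pre-tagged tokens.
#'
#' @param text a character string.
#' @return data.frame `text`, `pos`.
#' @export
tag_text <- function(text) {
  toks <- strsplit(tolower(gsub("[^[:alnum:] -]", " ", text)), "[ ]+")[[1]]
  toks <- toks[nzchar(toks)]
  det <- c("the", "a", "an", "this", "that", "these", "those")
  prep <- c("of", "in", "on", "for", "with", "by", "to", "from", "at", "as")
  conj <- c("and", "or", "but")
  pos <- ifelse(toks %in% det, "DT",
         ifelse(toks %in% prep, "IN",
         ifelse(toks %in% conj, "CC",
         ifelse(grepl("ing$", toks) & nchar(toks) > 4, "VBG",
         ifelse(grepl("(al|ic|ous|ive|ary|able)$", toks) & nchar(toks) > 4,
                "JJ", "NN")))))
  data.frame(text = toks, pos = pos)
}

#' Extract noun phrases from tagged tokens
#'
#' Matches the chunk grammar `(JJ.*|VBG)* (NN.*)+ (VBG)?`: a run of zero or
#' more adjectives or gerunds, one or more nouns, and at most one trailing
#' gerund. Matching is greedy and left-to-right with maximal, non-overlapping
#' chunks; phrases are lowercased.
#'
#' @param tokens data.frame with columns `text`, `pos`, or a `word/TAG`
#'   encoded string (see [parse_tagged()]).
#' @return character vector of phrases (possibly empty).
#' @examples
#' match_noun_phrases(data.frame(text = c("novel", "scoring", "function"),
#'                               pos = c("JJ", "VBG", "NN")))
#' @export
match_noun_phrases <- function(tokens) {
  if (is.character(tokens) && length(tokens) == 1L) tokens <- parse_tagged(tokens)
  pos <- tokens$pos
  txt <- tolower(tokens$text)
  n <- length(pos)
  is_adj <- grepl("^JJ", pos) | pos == "VBG"
  is_noun <- grepl("^NN", pos)
  phrases <- character(0)
  p <- 1L
  while (p <= n) {
    q <- p
    while (q <= n && is_adj[q]) q <- q + 1L       # adjective/gerund prefix
    r <- q
    while (r <= n && is_noun[r]) r <- r + 1L      # noun run
    if (r > q) {                                  # >= 1 noun: match
      if (r <= n && pos[r] == "VBG") r <- r + 1L  # optional trailing gerund
      phrases <- c(phrases, paste(txt[p:(r - 1L)], collapse = " "))
      p <- r
    } else {
      p <- p + 1L
    }
  }
  phrases
}

## All phrases of one document: title and abstract are chunked separately so
## no phrase spans the title/abstract boundary.
doc_phrases <- function(tagged_title, tagged_abstract) {
  c(match_noun_phrases(tagged_title %||% ""),
    match_noun_phrases(tagged_abstract %||% ""))
}

#' Bootstrapped phrase counts for one cluster
#'
#' Phrase occurrences are counted in `n_samples` random subsamples (without
#' replacement) of `ceiling(np * sample_frac)` documents each and summed over
#' samples. Bootstrapping separates the scores of genuinely prevalent phrases
#' from incidental ones.
#'
#' @param phrase_list list (one element per document) of character vectors of
#'   phrase occurrences.
#' @param n_samples number of bootstrap samples (default 20).
#' @param sample_frac fraction of documents per sample (default 1/3).
#' @param seed integer seed; deterministic given the seed.
#' @return named integer vector: phrase -> summed count.
#' @export
bootstrap_phrase_counts <- function(phrase_list, n_samples = 20L,
                                    sample_frac = 1 / 3, seed = 1L) {
  np <- length(phrase_list)
  if (np < 1L) stop_litmap("cluster has no documents in the window")
  m <- max(1L, ceiling(np * sample_frac))
  set.seed(seed)
  acc <- new.env(hash = TRUE, parent = emptyenv())
  for (s in seq_len(n_samples)) {
    idx <- sample.int(np, m, replace = FALSE)
    ph <- unlist(phrase_list[idx], use.names = FALSE)
    if (length(ph) == 0L) next
    tab <- table(ph)
    for (k in names(tab)) {
      acc[[k]] <- (acc[[k]] %||% 0L) + as.integer(tab[[k]])
    }
  }
  keys <- ls(acc)
  setNames(vapply(keys, function(k) acc[[k]], integer(1)), keys)
}

#' Transform a bootstrapped count to a per-paper phrase score
#'
#' `sc = count / (20 * np / 3)`: an estimate of the number of occurrences of
#' the phrase per paper in the cluster, under 20 one-third subsamples.
#'
#' @param count summed bootstrap count (vectorized).
#' @param np number of papers in the cluster window.
#' @return numeric score(s).
#' @export
phrase_score <- function(count, np) {
  if (np < 1) stop_litmap("`np` must be >= 1")
  count / (20 * np / 3)
}

#' Idiosyncrasy score of a phrase within a cluster
#'
#' `idio = 10 * log(1 + sc/nptot) * sc/sctot`, where `sc` is the cluster's
#' phrase score, `sctot` the sum of that phrase's scores over all clusters,
#' and `nptot` the total number of papers in all clusters in which the phrase
#' appears. Phrases diluted across many clusters score near zero; phrases
#' concentrated in one cluster keep their weight.
#'
#' @param sc,sctot,nptot score, corpus-wide score total, corpus-wide paper
#'   total (vectorized).
#' @param base logarithm base (default natural).
#' @return numeric idio score(s).
#' @export
idio_score <- function(sc, sctot, nptot, base = exp(1)) {
  if (any(sctot <= 0)) stop_litmap("`sctot` must be positive")
  if (any(nptot < 1)) stop_litmap("`nptot` must be >= 1")
  10 * log(1 + sc / nptot, base = base) * sc / sctot
}

#' Phrase and idio-phrase tables for all clusters
#'
#' Runs the bootstrap scoring per cluster, then computes corpus-wide `sctot`
#' and `nptot` aggregates and idio scores. Documents outside the
#' characterization window are ignored.
#'
#' @param documents document table with `doc_id`, `year`, `tagged_title`,
#'   `tagged_abstract` columns.
#' @param assignment cluster assignment (`doc_id`, `PM5`, `removed`).
#' @param window integer vector of years to include (NULL = all).
#' @param n_samples,sample_frac bootstrap parameters.
#' @param seed integer seed (per-cluster seeds are derived from it).
#' @param top_k rows per cluster in the ranked tables (default 10).
#' @param idio_log_base base of the idio logarithm.
#' @return list with `phrase` and `idio` ranked data.tables
#'   (`PM5`, `rank`, `descriptor`, `score`) and `scores` (full table).
#' @export
cluster_phrases <- function(documents, assignment, window = NULL,
                            n_samples = 20L, sample_frac = 1 / 3, seed = 1L,
                            top_k = 10L, idio_log_base = exp(1)) {
  docs <- as.data.table(documents)
  asn <- as.data.table(assignment)
  if ("removed" %in% names(asn)) asn <- asn[removed == FALSE]
  d <- docs[asn[, .(doc_id, PM5)], on = "doc_id", nomatch = NULL]
  if (!is.null(window)) d <- d[year %in% window]

  clusters <- sort(unique(d$PM5))
  per_cluster <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    dd <- d[PM5 == cl]
    if (nrow(dd) == 0L) next
    plist <- Map(doc_phrases, dd$tagged_title, dd$tagged_abstract)
    cnt <- bootstrap_phrase_counts(plist, n_samples, sample_frac,
                                   seed = seed + cl)
    if (length(cnt) == 0L) next
    ## which phrases appear in this cluster at all (for nptot accounting)
    per_cluster[[ci]] <- data.table(PM5 = cl, phrase = names(cnt),
                                    count = as.integer(cnt), np = nrow(dd))
  }
  sc_tab <- rbindlist(per_cluster)
  if (nrow(sc_tab) == 0L) {
    empty <- data.table(PM5 = integer(0), rank = integer(0),
                        descriptor = character(0), score = numeric(0))
    return(list(phrase = empty, idio = copy(empty), scores = sc_tab))
  }
  sc_tab[, sc := phrase_score(count, np[1L]), by = PM5]
  ## corpus-wide aggregates: sum of scores, and total papers of the clusters
  ## in which the phrase appears
  agg <- sc_tab[, .(sctot = sum(sc), nptot = sum(np)), by = phrase]
  sc_tab <- agg[sc_tab, on = "phrase"]
  sc_tab[, idio := idio_score(sc, sctot, nptot, base = idio_log_base)]

  rank_table <- function(tab, col) {
    t2 <- copy(tab)
    setorderv(t2, c("PM5", col, "phrase"), order = c(1L, -1L, 1L))
    t2[, rank := seq_len(.N), by = PM5]
    t2 <- t2[rank <= top_k,
             .(PM5, rank, descriptor = phrase, score = get(col))]
    t2[]
  }
  list(phrase = rank_table(sc_tab, "sc"),
       idio = rank_table(sc_tab, "idio"),
       scores = sc_tab[])
}

#' Central papers of each cluster
#'
#' A document's centrality is the sum of its hybrid relatedness to the other
#' members of its cluster; the reported score is normalized to the cluster
#' maximum. The core list excludes reviews; the review list holds only
#' reviews. Ties break by document id.
#'
#' @param documents document table (`doc_id`, `doc_types`, optional `cites`
#'   metric column used for the `ncited` output field).
#' @param assignment cluster assignment.
#' @param edges hybrid relatedness table.
#' @param window optional year window.
#' @param n_core,n_reviews list lengths (defaults 10 and 5).
#' @return list of data.tables `core` and `review` with columns
#'   `PM5`, `rank`, `score`, `type`, `source`, `ncited`.
#' @export
central_papers <- function(documents, assignment, edges, window = NULL,
                           n_core = 10L, n_reviews = 5L) {
  docs <- as.data.table(documents)
  asn <- as.data.table(assignment)
  if ("removed" %in% names(asn)) asn <- asn[removed == FALSE]
  d <- docs[asn[, .(doc_id, PM5)], on = "doc_id", nomatch = NULL]
  if (!is.null(window)) d <- d[year %in% window]
  map <- setNames(d$PM5, d$doc_id)

  e <- as.data.table(edges)[, .(i, j, r_hyb)]
  e[, `:=`(cm = map[i], cn = map[j])]
  e <- e[!is.na(cm) & cm == cn]
  cent <- rbind(e[, .(doc_id = i, r_hyb)], e[, .(doc_id = j, r_hyb)])[
    , .(centrality = sum(r_hyb)), by = doc_id]
  d <- cent[d, on = "doc_id"]
  d[is.na(centrality), centrality := 0]
  d[, score := if (max(centrality) > 0) centrality / max(centrality) else 0,
    by = PM5]
  d[, is_review := vapply(doc_types, function(t) "review" %in% tolower(t),
                          logical(1))]
  has_cites <- "cites" %in% names(d)

  take <- function(tab, k) {
    setorder(tab, PM5, -score, doc_id)
    tab[, rank := seq_len(.N), by = PM5]
    tab <- tab[rank <= k]
    tab[, .(PM5, rank, score,
            type = vapply(doc_types, paste, character(1), collapse = ";"),
            source = paste0(doc_id, ", ", title, ", ", journal, ", ", year),
            ncited = if (has_cites) cites else NA_real_)]
  }
  list(core = take(d[is_review == FALSE], n_core),
       review = take(d[is_review == TRUE], n_reviews))
}

#' Top descriptor lists per cluster
#'
#' Counts of documents carrying each descriptor (MeSH heading, journal,
#' category or author) within the window; ties break alphabetically. For
#' authors the mean cites-per-paper within the cluster is also reported.
#'
#' @param documents document table.
#' @param assignment cluster assignment.
#' @param key one of "mesh", "journal", "category", "author".
#' @param k rows per cluster (default 10).
#' @param window optional year window.
#' @return data.table `PM5`, `rank`, `descriptor`, `score` (count), and for
#'   authors additionally `cpp`.
#' @export
top_descriptors <- function(documents, assignment,
                            key = c("mesh", "journal", "category", "author"),
                            k = 10L, window = NULL) {
  key <- match.arg(key)
  docs <- as.data.table(documents)
  asn <- as.data.table(assignment)
  if ("removed" %in% names(asn)) asn <- asn[removed == FALSE]
  d <- docs[asn[, .(doc_id, PM5)], on = "doc_id", nomatch = NULL]
  if (!is.null(window)) d <- d[year %in% window]
  if (nrow(d) == 0L)
    return(data.table(PM5 = integer(0), rank = integer(0),
                      descriptor = character(0), score = numeric(0)))

  col <- switch(key, mesh = "mesh_terms", journal = "journal",
                category = "categories", author = "authors")
  if (!"cites" %in% names(d)) d[, cites := NA_real_]
  if (key == "journal") {
    long <- d[, .(PM5, doc_id, cites, descriptor = journal)]
  } else {
    long <- d[, .(descriptor = {
      v <- unique(unlist(get(col), use.names = FALSE))
      if (length(v) == 0L) NA_character_ else v
    }), by = .(PM5, doc_id, cites)]
  }
  long <- long[!is.na(descriptor) & nzchar(descriptor)]
  cnt <- long[, .(score = as.numeric(uniqueN(doc_id)),
                  cpp = mean(cites[!duplicated(doc_id)])), by = .(PM5, descriptor)]
  setorder(cnt, PM5, -score, descriptor)
  cnt[, rank := seq_len(.N), by = PM5]
  cnt <- cnt[rank <= k]
  if (key == "author") cnt[, .(PM5, rank, score, cpp, descriptor)]
  else cnt[, .(PM5, rank, descriptor, score)]
}

#' Portfolio indicators for each cluster
#'
#' Means of per-document metric columns over window documents, fractions of
#' 0/1 flags and document types, author-community counts, mean paper age,
#' vitality (inverse mean reference age, with a one-year floor on reference
#' age), and the annualized three-year growth rate
#' `((n_last + 1)/(n_first + 1))^(1/3) - 1` (counts +1-smoothed so empty
#' years stay finite).
#'
#' @param documents document table.
#' @param assignment cluster assignment.
#' @param citations citation table (for reference ages).
#' @param window year window for windowed indicators.
#' @param ref_year reference "now" year (default max corpus year).
#' @param growth_span years spanned by the growth rate (default 3).
#' @return data.table of one row per retained cluster with indicator columns.
#' @export
cluster_metrics <- function(documents, assignment, citations = NULL,
                            window = NULL, ref_year = NULL, growth_span = 3L) {
  docs <- as.data.table(documents)
  asn <- as.data.table(assignment)
  if ("removed" %in% names(asn)) asn <- asn[removed == FALSE]
  d_all <- docs[asn[, .(doc_id, PM5)], on = "doc_id", nomatch = NULL]
  if (is.null(ref_year)) ref_year <- max(d_all$year)
  d <- if (is.null(window)) copy(d_all) else d_all[year %in% window]

  mean_col <- function(tab, col)
    if (col %in% names(tab)) tab[, .(v = mean(get(col), na.rm = TRUE)), by = PM5]
    else data.table(PM5 = unique(tab$PM5), v = NA_real_)

  out <- d_all[, .(nptot = .N), by = PM5]
  nw <- d[, .(np_window = .N), by = PM5]
  out <- nw[out, on = "PM5"]
  out[is.na(np_window), np_window := 0L]

  add <- function(col_in, col_out, tab = d) {
    m <- mean_col(tab, col_in)
    out[m, on = "PM5", (col_out) := i.v]
  }
  add("cites", "cpp"); add("rcr", "rcr"); add("snip", "snip"); add("apt", "apt")
  add("industry_flag", "ind_fr"); add("patent_cites", "nprpp")
  add("clinical_flag", "clin_fr"); add("research_level", "rlev")
  add("funding_types", "fundpp"); add("grants", "grantpp"); add("funding", "starpp")
  add("method_flag", "meth_fr", d_all); add("discovery_flag", "disc_fr", d_all)

  type_frac <- function(tt)
    d[, .(v = mean(vapply(doc_types, function(x) tt %in% tolower(x), logical(1)))),
      by = PM5]
  out[type_frac("review"), on = "PM5", rev_fr := i.v]
  out[type_frac("clinical-trial"), on = "PM5", trl_fr := i.v]

  ## authorship: authors with >= 2 / >= 5 window papers in the cluster
  out[, `:=`(nauth2 = 0L, nauth5 = 0L)]
  au <- d[, .(author = unlist(authors, use.names = FALSE)), by = .(PM5, doc_id)]
  if (nrow(au) > 0L) {
    ac <- au[, .(npap = uniqueN(doc_id)), by = .(PM5, author)]
    a2 <- ac[, .(v = sum(npap >= 2)), by = PM5]
    a5 <- ac[, .(v = sum(npap >= 5)), by = PM5]
    out[a2, on = "PM5", nauth2 := as.integer(i.v)]
    out[a5, on = "PM5", nauth5 := as.integer(i.v)]
  }

  ## age and vitality
  agev <- d[, .(v = ref_year - mean(year)), by = PM5]
  out[agev, on = "PM5", age := i.v]
  if (!is.null(citations) && nrow(citations) > 0L) {
    cit <- as.data.table(citations)[, .(citing_id = as.character(citing_id),
                                        cited_id = as.character(cited_id))]
    yr <- setNames(docs$year, docs$doc_id)
    cit[, `:=`(cy = yr[citing_id], ty = yr[cited_id])]
    cit <- cit[!is.na(cy) & !is.na(ty)]
    cit[, ref_age := pmax(cy - ty, 1)]
    cit <- cit[d[, .(doc_id, PM5)], on = c(citing_id = "doc_id"), nomatch = NULL]
    vit <- cit[, .(v = 1 / mean(ref_age)), by = PM5]
    out[vit, on = "PM5", vitality := i.v]
  } else out[, vitality := NA_real_]

  ## annualized growth over the trailing span
  y0 <- ref_year - growth_span
  gcnt <- d_all[, .(n_first = sum(year == y0), n_last = sum(year == ref_year)),
                by = PM5]
  gcnt[, growth := ((n_last + 1) / (n_first + 1))^(1 / growth_span) - 1]
  out[gcnt, on = "PM5", growth := i.growth]
  setorder(out, PM5)
  out[]
}

#' Percentile ranks across clusters
#'
#' `100 * midrank / n` over non-missing values; ties share their midrank, the
#' maximum maps to 100, missing values stay missing.
#'
#' @param values numeric vector (one value per cluster).
#' @return numeric vector of percentiles in (0, 100].
#' @examples
#' percentile_ranks(c(1, 2, 3, 4))  # 25 50 75 100
#' @export
percentile_ranks <- function(values) {
  out <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  if (!any(ok)) return(out)
  out[ok] <- 100 * rank(values[ok], ties.method = "average") / sum(ok)
  out
}

#' Project an external document subset onto the cluster model
#'
#' Per cluster, the count and concentration of subset documents; the passing
#' set holds clusters meeting both a minimum count and a minimum fraction
#' (e.g. "at least 25 documents and at least 10% concentration").
#'
#' @param subset_ids character vector of document ids (ids outside the corpus
#'   are ignored, with a count reported).
#' @param assignment cluster assignment.
#' @param min_count,min_fraction thresholds for the passing set.
#' @param level cluster column.
#' @return list with `table` (`cluster`, `subset_count`, `subset_fraction`),
#'   `passing` (integer cluster ids) and `n_unknown`.
#' @export
overlay <- function(subset_ids, assignment, min_count = 25L,
                    min_fraction = 0.10, level = "PM5") {
  asn <- as.data.table(assignment)
  if ("removed" %in% names(asn)) asn <- asn[removed == FALSE]
  subset_ids <- unique(as.character(subset_ids))
  n_unknown <- sum(!subset_ids %in% asn$doc_id)
  if (n_unknown > 0L)
    message(sprintf("overlay: %d subset id(s) not in the corpus", n_unknown))
  tab <- asn[, .(size = .N, subset_count = sum(doc_id %in% subset_ids)),
             by = .(cluster = get(level))]
  tab[, subset_fraction := subset_count / size]
  setorder(tab, cluster)
  passing <- tab[subset_count >= min_count & subset_fraction >= min_fraction,
                 cluster]
  list(table = tab[, .(cluster, subset_count, subset_fraction)],
       passing = passing, n_unknown = n_unknown)
}

#' Full cluster characterization
#'
#' Drives every descriptor and indicator computation and assembles the output
#' sheets: CLUST (positions, indicators, percentiles), COUNT (annual counts),
#' PHRASE/IDIO/MESH/JNL/AUTH (ranked descriptors), CORE/REVIEW (central
#' papers) and QUERY (overlays).
#'
#' @param documents document table.
#' @param assignment cluster assignment with `removed` flags.
#' @param edges hybrid relatedness edges.
#' @param citations citation table.
#' @param layout optional layout table from [map_layout()].
#' @param fields optional field table from [assign_field()].
#' @param window year window for windowed statistics (default: last 5 years
#'   of the corpus span).
#' @param overlays named list of document-id vectors to overlay.
#' @param seed integer seed for the phrase bootstrap.
#' @param n_samples,sample_frac,idio_log_base phrase-scoring parameters.
#' @param top_k descriptors per cluster (default 10; central reviews use 5).
#' @return named list of data.tables, one per output sheet.
#' @export
characterize_clusters <- function(documents, assignment, edges, citations,
                                  layout = NULL, fields = NULL,
                                  window = NULL, overlays = list(),
                                  seed = 1L, n_samples = 20L,
                                  sample_frac = 1 / 3,
                                  idio_log_base = exp(1), top_k = 10L) {
  docs <- as.data.table(documents)
  asn <- as.data.table(assignment)
  if (is.null(window)) {
    ymax <- max(docs$year)
    window <- (ymax - 4L):ymax
  }
  live <- asn[removed == FALSE]

  ph <- cluster_phrases(docs, asn, window = window, n_samples = n_samples,
                        sample_frac = sample_frac, seed = seed,
                        top_k = top_k, idio_log_base = idio_log_base)
  cp <- central_papers(docs, asn, edges, window = window,
                       n_core = top_k, n_reviews = 5L)
  met <- cluster_metrics(docs, asn, citations, window = window)

  ## percentile columns
  pc <- function(col) percentile_ranks(met[[col]])
  clust <- copy(met)
  for (cols in list(c("cpp", "cpp_pctl"), c("rcr", "rcr_pctl"),
                    c("snip", "snip_pctl"), c("apt", "apt_pctl"),
                    c("ind_fr", "ind_pctl"), c("nprpp", "npr_pctl"),
                    c("clin_fr", "clin_pctl"), c("fundpp", "nf_pctl"),
                    c("grantpp", "ng_pctl"), c("starpp", "star_pctl"),
                    c("meth_fr", "meth_pctl"), c("disc_fr", "disc_pctl"),
                    c("rev_fr", "rev_pctl"), c("trl_fr", "trl_pctl"))) {
    if (cols[1] %in% names(clust)) clust[, (cols[2]) := pc(cols[1])]
  }
  nest <- unique(live[, .(PM5, PM4, PM3)])
  clust <- nest[clust, on = "PM5"]
  if (!is.null(layout))
    clust <- merge(clust, as.data.table(layout)[, .(PM5 = cluster, X, Y)],
                   by = "PM5", all.x = TRUE)
  if (!is.null(fields))
    clust <- merge(clust, as.data.table(fields)[, .(PM5 = cluster, field)],
                   by = "PM5", all.x = TRUE)
  setorder(clust, PM5)

  cnt <- docs[live[, .(doc_id, PM5)], on = "doc_id", nomatch = NULL][
    , .(n = .N), by = .(PM5, year)]
  count_sheet <- dcast(cnt, PM5 ~ year, value.var = "n", fill = 0L)

  query <- NULL
  if (length(overlays) > 0L) {
    query <- data.table(PM5 = sort(unique(live$PM5)))
    for (nm in names(overlays)) {
      ov <- overlay(overlays[[nm]], asn, min_count = 0L, min_fraction = 0)
      query <- merge(query,
                     ov$table[, .(PM5 = cluster, subset_count, subset_fraction)],
                     by = "PM5", all.x = TRUE)
      setnames(query, c("subset_count", "subset_fraction"),
               c(paste0("n_", nm), paste0("fr_", nm)))
    }
  }

  list(
    CLUST = clust,
    COUNT = count_sheet,
    PHRASE = ph$phrase,
    IDIO = ph$idio,
    MESH = top_descriptors(docs, asn, "mesh", k = top_k, window = window),
    JNL = top_descriptors(docs, asn, "journal", k = top_k, window = window),
    AUTH = top_descriptors(docs, asn, "author", k = top_k, window = window),
    CORE = cp$core,
    REVIEW = cp$review,
    QUERY = query
  )
}
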