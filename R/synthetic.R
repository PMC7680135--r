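## Synthetic corpora with planted topic structure.
##
## Emulates the statistical structure the pipeline assumes: citations
## concentrated within topics and directed toward the past, per-document
## top-k text-similarity partners that are predominantly same-topic, topic-
## specific vocabulary in titles/abstracts (emitted pre-tagged), topic author
## pools, document types and per-document metrics.

#' Configuration for the synthetic corpus generator
#'
#' Defaults describe the standard validation corpus: 20 topics of 100
#' documents over a 10-year span, a 0.9 probability that a reference stays
#' within its topic, and text-similarity partners drawn mostly within topic
#' with clearly larger score magnitudes (`sa_within_scale` vs
#' `sa_cross_scale`).
#'
#' @param n_topics number of planted topics.
#' @param docs_per_topic documents per topic.
#' @param years inclusive publication-year range.
#' @param refs_per_doc mean of the per-document reference-count distribution
#'   (Poisson).
#' @param p_within probability a reference targets the same topic.
#' @param sa_top_k similarity partners retained per document downstream.
#' @param sa_partners_within,sa_partners_cross similarity partners drawn per
#'   document within/across topic.
#' @param sa_within_scale,sa_cross_scale exponential score scales (within
#'   must exceed cross).
#' @param vocab_shared_n,shared_adj_n,vocab_per_topic sizes of the shared
#'   noun, shared adjective and per-topic noun vocabularies.
#' @param authors_per_topic author-pool size per topic.
#' @param review_fraction,trial_fraction document-type probabilities.
#' @param title_len,abstract_len token counts of generated texts.
#' @param seed integer root seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_topics = 20L, docs_per_topic = 100L,
                             years = 2010:2019, refs_per_doc = 8,
                             p_within = 0.9, sa_top_k = 20L,
                             sa_partners_within = 20L, sa_partners_cross = 5L,
                             sa_within_scale = 30, sa_cross_scale = 3,
                             vocab_shared_n = 40L, shared_adj_n = 15L,
                             vocab_per_topic = 6L, authors_per_topic = 40L,
                             review_fraction = 0.10, trial_fraction = 0.05,
                             title_len = 8L, abstract_len = 40L,
                             seed = 1L) {
  stopifnot(p_within > 0, p_within <= 1, sa_within_scale > sa_cross_scale,
            n_topics >= 1, docs_per_topic >= 2)
  if (refs_per_doc >= n_topics * docs_per_topic)
    stop_litmap("`refs_per_doc` must be below the corpus size")
  structure(as.list(environment()), class = "synthetic_config")
}

## sample() without the scalar trap: always index-based
safe_sample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

## deterministic pseudo-word factories (valid NN/JJ tokens for the grammar)
make_words <- function(prefixes, n, suffix = "") {
  paste0(rep(prefixes, length.out = n), rep(seq_len(ceiling(n / length(prefixes))),
                                            each = length(prefixes))[seq_len(n)],
         suffix)
}

#' Generate a synthetic corpus with planted topics
#'
#' @param config a [synthetic_config()].
#' @return list with `documents` (data.table incl. `tagged_title`,
#'   `tagged_abstract` and metric columns), `citations`, `similarity`,
#'   `truth` (data.table `doc_id`, `topic`; attribute `vocab` maps topic ->
#'   planted nouns).
#' @export
generate_corpus <- function(config = synthetic_config()) {
  cf <- config
  set.seed(cf$seed)
  K <- cf$n_topics; m <- cf$docs_per_topic
  n <- K * m
  ids <- sprintf("d%05d", seq_len(n))
  topic <- rep(seq_len(K), each = m)

  ## vocabulary: shared nouns/adjectives/stopwords + topic-specific nouns
  shared_nouns <- make_words(c("cell", "protein", "model", "analysis", "assay",
                               "pathway", "cohort", "sample", "tissue", "gene"),
                             cf$vocab_shared_n)
  shared_adjs <- make_words(c("clinic", "molecul", "structur", "function",
                              "statistic"), cf$shared_adj_n, suffix = "al")
  stopw <- c("the", "a", "of", "in", "for", "with")
  stop_tag <- c("DT", "DT", "IN", "IN", "IN", "IN")
  topic_vocab <- lapply(seq_len(K), function(t)
    make_words(c("marker", "receptor", "variant", "syndrome", "inhibitor",
                 "genotype"), cf$vocab_per_topic, suffix = paste0("t", t)))

  years <- sample(cf$years, n, replace = TRUE)
  journals <- paste0("journal_", ((topic - 1L) %% max(2L, ceiling(K / 2))) + 1L)
  author_pool <- lapply(seq_len(K), function(t)
    paste0("author_", t, "_", seq_len(cf$authors_per_topic)))

  ## tagged text: mixture of stopwords, shared adjectives/nouns, topic nouns
  gen_text <- function(t, len) {
    kind <- sample(c("stop", "adj", "noun", "topic"), len, replace = TRUE,
                   prob = c(0.25, 0.15, 0.30, 0.30))
    w <- character(len); tag <- character(len)
    ns <- sum(kind == "stop")
    if (ns) { k <- sample.int(length(stopw), ns, replace = TRUE)
              w[kind == "stop"] <- stopw[k]; tag[kind == "stop"] <- stop_tag[k] }
    na <- sum(kind == "adj")
    if (na) { w[kind == "adj"] <- sample(shared_adjs, na, replace = TRUE)
              tag[kind == "adj"] <- "JJ" }
    nn <- sum(kind == "noun")
    if (nn) { w[kind == "noun"] <- sample(shared_nouns, nn, replace = TRUE)
              tag[kind == "noun"] <- "NN" }
    nt <- sum(kind == "topic")
    if (nt) { w[kind == "topic"] <- sample(topic_vocab[[t]], nt, replace = TRUE)
              tag[kind == "topic"] <- "NN" }
    list(text = paste(w, collapse = " "),
         tagged = paste(paste0(w, "/", tag), collapse = " "))
  }
  titles <- lapply(topic, gen_text, len = cf$title_len)
  abstracts <- lapply(topic, gen_text, len = cf$abstract_len)

  is_review <- runif(n) < cf$review_fraction
  is_trial <- !is_review & runif(n) < cf$trial_fraction
  doc_types <- Map(function(r, tr) {
    c("article", if (r) "review", if (tr) "clinical-trial")
  }, is_review, is_trial)

  authors <- lapply(seq_len(n), function(ix) {
    na <- sample(1:4, 1L)
    sample(author_pool[[topic[ix]]], na)
  })
  mesh <- lapply(seq_len(n), function(ix)
    unique(c(sample(topic_vocab[[topic[ix]]], 2L),
             sample(shared_nouns, 2L))))

  ## topic-tilted per-document metrics
  topic_mu <- rgamma(K, shape = 4, rate = 0.5)  # per-topic mean cites
  docs <- data.table(
    doc_id = ids, year = years, journal = journals,
    title = vapply(titles, `[[`, character(1), "text"),
    abstract = vapply(abstracts, `[[`, character(1), "text"),
    tagged_title = vapply(titles, `[[`, character(1), "tagged"),
    tagged_abstract = vapply(abstracts, `[[`, character(1), "tagged"),
    mesh_terms = mesh, authors = authors, doc_types = doc_types,
    cites = rnbinom(n, mu = topic_mu[topic], size = 2),
    rcr = rlnorm(n, meanlog = 0, sdlog = 0.5),
    snip = rlnorm(n, meanlog = 0.2, sdlog = 0.4),
    apt = runif(n),
    research_level = sample(1:4, n, replace = TRUE),
    funding = rexp(n, rate = 2),
    grants = rpois(n, 1.2),
    funding_types = rpois(n, 1.0),
    industry_flag = rbinom(n, 1, 0.10),
    clinical_flag = rbinom(n, 1, 0.25),
    method_flag = rbinom(n, 1, 0.05),
    discovery_flag = rbinom(n, 1, 0.03),
    patent_cites = rexp(n, rate = 4)
  )

  ## citations: within-topic w.p. p_within, only toward earlier-or-equal years
  by_topic_year <- split(seq_len(n), topic)
  cit_list <- vector("list", n)
  nrefs <- rpois(n, cf$refs_per_doc)
  for (ix in seq_len(n)) {
    nr <- nrefs[ix]
    if (nr == 0L) next
    same <- runif(nr) < cf$p_within
    cands_in <- by_topic_year[[topic[ix]]]
    cands_in <- cands_in[years[cands_in] <= years[ix] & cands_in != ix]
    cands_out <- which(topic != topic[ix] & years <= years[ix])
    tgt <- integer(0)
    n_in <- sum(same); n_out <- nr - n_in
    if (n_in > 0L && length(cands_in) > 0L)
      tgt <- c(tgt, safe_sample(cands_in, min(n_in, length(cands_in))))
    if (n_out > 0L && length(cands_out) > 0L)
      tgt <- c(tgt, safe_sample(cands_out, min(n_out, length(cands_out))))
    if (length(tgt))
      cit_list[[ix]] <- data.table(citing_id = ids[ix], cited_id = ids[unique(tgt)])
  }
  citations <- rbindlist(cit_list)

  ## similarity: within-topic partners with large scores, cross with small
  sim_list <- vector("list", n)
  for (ix in seq_len(n)) {
    cands_in <- setdiff(by_topic_year[[topic[ix]]], ix)
    k_in <- min(cf$sa_partners_within, length(cands_in))
    p_in <- safe_sample(cands_in, k_in)
    cands_out <- which(topic != topic[ix])
    k_out <- min(cf$sa_partners_cross, length(cands_out))
    p_out <- if (k_out > 0L) safe_sample(cands_out, k_out) else integer(0)
    sim_list[[ix]] <- data.table(
      id_a = ids[ix],
      id_b = ids[c(p_in, p_out)],
      score = c(rexp(k_in, 1 / cf$sa_within_scale),
                rexp(k_out, 1 / cf$sa_cross_scale)))
  }
  similarity <- rbindlist(sim_list)
  ## enforce unordered-pair uniqueness (keep the larger draw)
  pk <- pair_key(similarity$id_a, similarity$id_b)
  similarity <- cbind(pk, score = similarity$score)[
    , .(score = max(score)), by = .(i, j)][, .(id_a = i, id_b = j, score)]

  truth <- data.table(doc_id = ids, topic = topic)
  setattr(truth, "vocab", topic_vocab)
  list(documents = docs, citations = citations, similarity = similarity,
       truth = truth, config = cf)
}

#' Score recovery of the planted partition
#'
#' Adjusted Rand index and normalized mutual information between a computed
#' cluster assignment and the planted topics.
#'
#' @param assignment data.table `doc_id` + cluster column, or a named vector.
#' @param truth data.table `doc_id`, `topic`.
#' @param level cluster column when `assignment` is a table (default "PM5").
#' @return list with `ari`, `nmi`, `n_clusters`.
#' @export
evaluate_recovery <- function(assignment, truth, level = "PM5") {
  tr <- as.data.table(truth)
  if (is.data.frame(assignment)) {
    asn <- as.data.table(assignment)
    lab <- setNames(asn[[level]], asn$doc_id)
  } else lab <- assignment
  common <- intersect(names(lab), tr$doc_id)
  if (length(common) == 0L) stop_litmap("assignment and truth share no documents")
  a <- lab[common]
  b <- setNames(tr$topic, tr$doc_id)[common]
  list(ari = adjusted_rand_index(a, b),
       nmi = normalized_mutual_information(a, b),
       n_clusters = length(unique(a)))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement; 1 for identical partitions,
#' about 0 for independent ones.
#'
#' @param a,b equal-length label vectors.
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  nc2 <- choose2(sum(tab))
  expected <- sum_a * sum_b / nc2
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (mx - expected)
}

#' Normalized mutual information between two labelings
#'
#' Mutual information divided by the arithmetic mean of the two label
#' entropies (0 when either partition is trivial).
#'
#' @param a,b equal-length label vectors.
#' @return numeric NMI in [0, 1].
#' @export
normalized_mutual_information <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij); pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  denom <- (h(pi_) + h(pj_)) / 2
  if (denom == 0) return(0)
  mi / denom
}
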