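tok <- function(...) {
  x <- c(...)
  data.frame(text = x[c(TRUE, FALSE)], pos = x[c(FALSE, TRUE)])
}

test_that("match_noun_phrases implements the chunk grammar", {
  cases <- list(
    list(tok("novel", "JJ", "scoring", "VBG", "function", "NN"),
         "novel scoring function"),
    list(tok("the", "DT", "cell", "NN"), "cell"),
    list(tok("running", "VBG"), character(0)),            # >= 1 noun required
    list(tok("gene", "NN", "expression", "NN", "profiling", "VBG"),
         "gene expression profiling"),                    # trailing gerund
    list(tok("deep", "JJ", "neural", "JJ", "networks", "NNS"),
         "deep neural networks"),                         # JJ.* prefix, NNS
    list(tok("a", "DT", "big", "JJ", "dog", "NN", "and", "CC", "cat", "NN"),
         c("big dog", "cat")),                            # non-overlapping
    list(tok("Cell", "NN"), "cell")                       # lowercased
  )
  for (cs in cases) expect_equal(match_noun_phrases(cs[[1]]), cs[[2]])

  ## encoded word/TAG strings parse to the same result
  expect_equal(match_noun_phrases("novel/JJ scoring/VBG function/NN"),
               "novel scoring function")
  expect_equal(parse_tagged("")$text, character(0))
})

test_that("bootstrap counts follow the sampling arithmetic", {
  ## phrase occurring once in every document: summed count = n_samples * m
  plist <- rep(list("common phrase"), 9L)
  cnt <- bootstrap_phrase_counts(plist, n_samples = 20L, sample_frac = 1 / 3,
                                 seed = 1L)
  expect_equal(unname(cnt[["common phrase"]]), 20L * 3L)
  ## absent phrase absent from the map
  expect_false("missing" %in% names(cnt))
  ## determinism
  cnt2 <- bootstrap_phrase_counts(plist, 20L, 1 / 3, seed = 1L)
  expect_identical(cnt, cnt2)
})

test_that("bootstrap expectation matches the inclusion probability", {
  ## np = 3, samples of 1 doc, phrase in exactly 1 doc once: each sample
  ## includes it with probability 1/3, so E[summed count] = 20/3
  plist <- list("rare", character(0), character(0))
  obs <- vapply(1:200, function(s) {
    cnt <- bootstrap_phrase_counts(plist, n_samples = 20L, sample_frac = 1 / 3,
                                   seed = s)
    if ("rare" %in% names(cnt)) as.numeric(cnt[["rare"]]) else 0
  }, numeric(1))
  expect_lt(abs(mean(obs) - 20 / 3), 1)
})

test_that("phrase_score and idio_score evaluate their formulas", {
  expect_equal(phrase_score(40, 6), 1.0)
  expect_equal(phrase_score(0, 6), 0)
  expect_equal(phrase_score(10, 3), 0.5)
  expect_error(phrase_score(1, 0), "np")

  ## phrase unique to one cluster: sc == sctot
  expect_equal(idio_score(2, 2, 50), 10 * log(1 + 2 / 50))
  expect_equal(idio_score(1, 1, 100), 10 * log(1.01), tolerance = 1e-10)
  expect_equal(round(idio_score(1, 1, 100), 4), 0.0995)
  ## dilution limit
  expect_lt(idio_score(1, 1e6, 100), 1e-5)
  ## configurable log base
  expect_equal(idio_score(1, 1, 100, base = 10), 10 * log10(1.01))
  expect_error(idio_score(1, 0, 100), "sctot")
})

test_that("idio is strictly decreasing in sctot; sc scales linearly in count", {
  sctot <- seq(1, 10, by = 0.5)
  v <- idio_score(1, sctot, 100)
  expect_true(all(diff(v) < 0))
  counts <- c(1, 2, 4, 8)
  expect_equal(phrase_score(counts, 10), counts * phrase_score(1, 10))
})

test_that("central_papers ranks by within-cluster relatedness", {
  ## 5-document star with equal weights: hub ranked first with score 1
  docs <- make_docs(c("hub", "l1", "l2", "l3", "l4"))
  asn <- data.table(doc_id = docs$doc_id, PM5 = 1L, removed = FALSE)
  e <- data.table(i = "hub", j = c("l1", "l2", "l3", "l4"), r_hyb = 0.2)
  cp <- central_papers(docs, asn, e)
  expect_equal(cp$core[rank == 1]$score, 1.0)
  expect_true(grepl("^hub", cp$core[rank == 1]$source))
  expect_equal(nrow(cp$review), 0L)

  ## all reviews: core empty, review list populated
  docs2 <- copy(docs)[, doc_types := list(rep(list("review"), 5))]
  cp2 <- central_papers(docs2, asn, e)
  expect_equal(nrow(cp2$core), 0L)
  expect_gt(nrow(cp2$review), 0L)
})

test_that("central_papers matches brute-force pairwise summation", {
  corp <- generate_corpus(small_config(seed = 31L, n_topics = 1L,
                                       docs_per_topic = 30L))
  rel <- build_relatedness(corp$citations, corp$similarity,
                           corp$documents$doc_id)
  asn <- data.table(doc_id = corp$documents$doc_id, PM5 = 1L, removed = FALSE)
  cp <- central_papers(corp$documents, asn, rel$edges, n_core = 30L)

  ## oracle: plain loop over the edge list
  cent <- setNames(rep(0, nrow(corp$documents)), corp$documents$doc_id)
  for (r in seq_len(nrow(rel$edges))) {
    cent[rel$edges$i[r]] <- cent[rel$edges$i[r]] + rel$edges$r_hyb[r]
    cent[rel$edges$j[r]] <- cent[rel$edges$j[r]] + rel$edges$r_hyb[r]
  }
  cent <- cent / max(cent)
  is_rev <- vapply(corp$documents$doc_types, function(t) "review" %in% t,
                   logical(1))
  ord <- order(-cent, names(cent))
  want <- names(cent)[ord][!is_rev[ord]]
  got <- sub(",.*$", "", cp$core$source)
  expect_equal(got, want[seq_along(got)])
  expect_equal(sort(cp$core$score, decreasing = TRUE), cp$core$score)
})

test_that("top_descriptors counts documents with deterministic ties", {
  docs <- make_docs(c("d1", "d2", "d3"))
  docs[, mesh_terms := list(list(c("A", "B"), "A", "C"))]
  asn <- data.table(doc_id = docs$doc_id, PM5 = 1L, removed = FALSE)
  got <- top_descriptors(docs, asn, "mesh")
  expect_equal(got$descriptor, c("A", "B", "C"))  # count 2, then alphabetical
  expect_equal(got$score, c(2, 1, 1))

  ## no padding below the number of distinct descriptors
  expect_equal(nrow(got), 3L)
  ## author cites-per-paper
  docs2 <- make_docs(c("d1", "d2"))
  docs2[, authors := list(list("smith j", "smith j"))]
  docs2[, cites := c(4, 6)]
  got2 <- top_descriptors(docs2, asn[1:2], "author")
  expect_equal(got2$cpp, 5.0)
  ## empty window
  expect_equal(nrow(top_descriptors(docs, asn, "mesh", window = 1900L)), 0L)
})

test_that("cluster_metrics computes indicators as stated", {
  docs <- make_docs(sprintf("d%02d", 1:8), years = c(2016:2019, 2019, 2019, 2016, 2016))
  docs[, cites := c(4, 6, 4, 6, 5, 5, 5, 5)]
  docs[, authors := list(rep(list(c("au1")), 8))]
  asn <- data.table(doc_id = docs$doc_id, PM5 = 1L, removed = FALSE)
  ## references all exactly 1 year old -> vitality 1
  cit <- data.table(citing_id = c("d02", "d03"), cited_id = c("d01", "d07"))
  docs[doc_id == "d02", year := 2017]
  docs[doc_id == "d03", year := 2017]
  m <- cluster_metrics(docs, asn, cit, window = 2016:2019, ref_year = 2019L)
  expect_equal(m$cpp, 5.0)
  expect_equal(m$vitality, 1.0)
  expect_equal(m$nauth2, 1L)  # one author with >= 2 papers
  expect_equal(m$nauth5, 1L)
  expect_equal(m$age, 2019 - mean(docs$year))

  ## growth with +1 smoothing: n_first (2016) = 3, n_last (2019) = 3
  expect_equal(m$growth, (4 / 4)^(1 / 3) - 1)
  ## the smoothed formula on the 100 -> 200 case
  g <- cluster_metrics(
    make_docs(sprintf("x%03d", 1:300), years = rep(c(2016L, 2019L), c(100, 200))),
    data.table(doc_id = sprintf("x%03d", 1:300), PM5 = 1L, removed = FALSE),
    ref_year = 2019L)$growth
  expect_equal(g, (201 / 101)^(1 / 3) - 1, tolerance = 1e-12)
  expect_equal(round(g, 4), 0.2578)
})

test_that("percentile_ranks uses midranks over non-missing values", {
  expect_equal(percentile_ranks(c(1, 2, 3, 4)), c(25, 50, 75, 100))
  expect_equal(percentile_ranks(rep(7, 4)), rep(62.5, 4))
  expect_equal(percentile_ranks(5), 100)
  expect_equal(percentile_ranks(c(2, NA, 1)), c(100, NA, 50))
  ## monotone in the underlying value; max maps to 100
  set.seed(1)
  v <- runif(50)
  p <- percentile_ranks(v)
  expect_equal(order(p), order(v))
  expect_equal(p[which.max(v)], 100)
})

test_that("overlay counts and thresholds follow the subset rules", {
  asn <- data.table(doc_id = c(paste0("a", 1:10), paste0("b", 1:100)),
                    PM5 = rep(c(1L, 2L), c(10L, 100L)), removed = FALSE)
  sub <- c("a1", "a2", "a3", "b1", "b2")
  ov <- overlay(sub, asn, min_count = 25L, min_fraction = 0.10)
  expect_equal(ov$table[cluster == 1L]$subset_count, 3L)
  expect_equal(ov$table[cluster == 1L]$subset_fraction, 0.3)
  expect_equal(ov$table[cluster == 2L]$subset_fraction, 0.02)
  expect_length(ov$passing, 0L)
  ## conservation: counts sum to |subset inside corpus|
  expect_equal(sum(ov$table$subset_count), 5L)
  ## unknown ids ignored with a message
  expect_message(ov2 <- overlay(c(sub, "zz"), asn), "not in the corpus")
  expect_equal(ov2$n_unknown, 1L)
  expect_equal(sum(ov2$table$subset_count), 5L)
  ## empty subset
  expect_equal(sum(overlay(character(0), asn)$table$subset_count), 0L)
})

test_that("top idio phrases recover planted topic vocabulary", {
  corp <- generate_corpus(small_config(seed = 41L))
  asn <- data.table(doc_id = corp$truth$doc_id, PM5 = corp$truth$topic,
                    PM4 = 1L, PM3 = 1L, removed = FALSE)
  ph <- cluster_phrases(corp$documents, asn, seed = 41L)
  vocab <- attr(corp$truth, "vocab")
  top1 <- ph$idio[rank == 1]
  hits <- vapply(seq_len(nrow(top1)), function(r) {
    words <- strsplit(top1$descriptor[r], " ")[[1]]
    any(words %in% vocab[[top1$PM5[r]]])
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  ## ranked tables carry at most top_k rows per cluster
  expect_true(all(ph$phrase[, .N, by = PM5]$N <= 10L))
})
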