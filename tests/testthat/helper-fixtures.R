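library(data.table)

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- tiny corpus builders ------------------------------------------------

## documents with the minimal fields most operations need
make_docs <- function(ids, years = 2019L, journal = "j1",
                      title = "a title", abstract = "an abstract") {
  n <- length(ids)
  data.table(
    doc_id = as.character(ids),
    year = rep_len(years, n),
    journal = rep_len(journal, n),
    title = rep_len(title, n),
    abstract = rep_len(abstract, n),
    mesh_terms = rep(list(character(0)), n),
    authors = rep(list(character(0)), n),
    doc_types = rep(list("article"), n)
  )
}

## a clique edge list (unordered pairs) with constant weight
clique_edges <- function(ids, weight = 1) {
  cmb <- t(combn(as.character(ids), 2))
  data.table(i = pmin(cmb[, 1], cmb[, 2]), j = pmax(cmb[, 1], cmb[, 2]),
             weight = weight)
}

## ---- independent brute-force relatedness oracle --------------------------
## Plain-matrix recomputation of the full hybrid relatedness pipeline from
## raw inputs, written without data.table joins so it shares no code path
## with the implementation. Suitable for corpora of <= ~60 documents.
oracle_relatedness <- function(citations, similarity, ids, top_k = 20) {
  ids <- as.character(ids)
  n <- length(ids)
  C <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(citations))) {
    a <- as.character(citations$citing_id[r])
    b <- as.character(citations$cited_id[r])
    if (a %in% ids && b %in% ids && a != b) C[a, b] <- 1
  }
  nref <- rowSums(C)
  cmat <- C
  for (k in seq_len(n)) if (nref[k] > 0) cmat[k, ] <- C[k, ] / nref[k]
  rdc <- pmax(cmat, t(cmat))
  if (max(rdc) > 0) rdc <- rdc / max(rdc)

  S <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(similarity))) {
    a <- as.character(similarity$id_a[r]); b <- as.character(similarity$id_b[r])
    s <- similarity$score[r]
    if (a %in% ids && b %in% ids && a != b) {
      S[a, b] <- max(S[a, b], s); S[b, a] <- max(S[b, a], s)
    }
  }
  ## per-document top-k retention, ties at the k-th score kept
  keep <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (k in seq_len(n)) {
    sc <- S[k, ]
    pos <- sc[sc > 0]
    if (length(pos) == 0) next
    thr <- sort(pos, decreasing = TRUE)[min(top_k, length(pos))]
    keep[k, sc >= thr & sc > 0] <- TRUE
  }
  keepu <- keep | t(keep)
  Sk <- S * keepu
  mx <- max(Sk)
  rsa <- if (mx > 0) Sk / mx else Sk
  ## imputation for citation pairs without a retained similarity score
  minr <- rep(NA_real_, n); names(minr) <- ids
  for (k in seq_len(n)) {
    v <- rsa[k, ][rsa[k, ] > 0]
    if (length(v)) minr[k] <- min(v)
  }
  imputed <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (b <= a) next
    if (rdc[a, b] > 0 && rsa[a, b] == 0) {
      fl <- 0.5 * min(minr, na.rm = TRUE)
      va <- if (is.na(minr[a])) 2 * fl else minr[a]
      vb <- if (is.na(minr[b])) 2 * fl else minr[b]
      rsa[a, b] <- rsa[b, a] <- 0.5 * min(va, vb)
      imputed[a, b] <- imputed[b, a] <- TRUE
    }
  }
  sum_dc <- sum(rdc[upper.tri(rdc)])
  sum_sa <- sum(rsa[upper.tri(rsa)])
  alpha <- sum_sa / (sum_dc + sum_sa)
  hyb <- alpha * rdc + (1 - alpha) * rsa
  list(rdc = rdc, rsa = rsa, hyb = hyb, alpha = alpha,
       sum_dc = sum_dc, sum_sa = sum_sa, imputed = imputed)
}

## edge table -> symmetric matrix lookup helper
edge_matrix <- function(edges, ids, col) {
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(edges))) {
    m[edges$i[r], edges$j[r]] <- edges[[col]][r]
    m[edges$j[r], edges$i[r]] <- edges[[col]][r]
  }
  m
}

## zero nesting violations: every finer cluster maps into exactly one coarser
nesting_violations <- function(assignment) {
  a <- as.data.table(assignment)
  v54 <- a[, uniqueN(PM4), by = PM5][V1 > 1, .N]
  v43 <- a[, uniqueN(PM3), by = PM4][V1 > 1, .N]
  v54 + v43
}

## small synthetic config used throughout unit tests (fast)
small_config <- function(seed = 1L, n_topics = 5L, docs_per_topic = 40L, ...) {
  synthetic_config(n_topics = n_topics, docs_per_topic = docs_per_topic,
                   seed = seed, ...)
}

small_levels <- function() list(
  level_config(0.02, 20L), level_config(0.002, 40L), level_config(2e-4, 80L))
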