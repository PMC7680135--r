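## Hybrid citation + text relatedness network.
##
## r_hyb = alpha * r_dc + (1 - alpha) * r_sa, with alpha calibrated so the
## summed citation and text contributions are equal across all pairs.

#' Direct-citation relatedness
#'
#' A citation from document i to document j contributes `c_ij = 1/nref(i)`,
#' where `nref(i)` is the number of references of i that fall inside the
#' document set. The pair value is the larger direction,
#' `r_dc = max(c_ij, c_ji)`, and the whole map is divided by its observed
#' maximum so values lie in (0, 1]. Pairs with value zero are absent.
#'
#' @param citations data.frame/data.table with columns `citing_id`, `cited_id`.
#' @param docset character vector of document ids defining the corpus; edges
#'   with an endpoint outside `docset` are ignored, and `nref` counts only
#'   in-set references.
#' @return data.table with columns `i`, `j` (canonical unordered pair) and
#'   `r_dc`; attribute `max_raw_dc` holds the pre-normalization maximum.
#' @examples
#' cit <- data.frame(citing_id = c("a", "a", "b"), cited_id = c("b", "c", "c"))
#' compute_dc(cit, c("a", "b", "c"))
#' @export
compute_dc <- function(citations, docset) {
  cit <- as.data.table(citations)[, .(citing_id = as.character(citing_id),
                                      cited_id = as.character(cited_id))]
  docset <- as.character(docset)
  cit <- cit[citing_id %in% docset & cited_id %in% docset & citing_id != cited_id]
  cit <- unique(cit)
  if (nrow(cit) == 0L) {
    out <- data.table(i = character(0), j = character(0), r_dc = numeric(0))
    setattr(out, "max_raw_dc", NA_real_)
    return(out)
  }
  cit[, nref := .N, by = citing_id]
  cit[, c_ij := 1 / nref]
  pairs <- pair_key(cit$citing_id, cit$cited_id)
  pairs[, c_ij := cit$c_ij]
  ## max over the two directions of each unordered pair
  dc <- pairs[, .(r_dc = max(c_ij)), by = .(i, j)]
  mx <- max(dc$r_dc)
  dc[, r_dc := r_dc / mx]
  order_pairs(dc)
  setattr(dc, "max_raw_dc", mx)
  dc[]
}

#' Normalize text-similarity records to top-k relatedness
#'
#' Deduplicates unordered pairs, keeps for every document only the pairs that
#' rank in its `top_k` highest raw scores (a pair survives if it is in the
#' top-k of *either* endpoint; ties at the k-th score are all kept), and
#' divides retained scores by the global maximum retained score so values lie
#' in (0, 1].
#'
#' @param records data.frame/data.table with columns `id_a`, `id_b`, `score`
#'   (raw non-negative similarity S_ij).
#' @param top_k number of partners retained per document (default 20).
#' @return data.table with columns `i`, `j`, `r_sa`; attributes `max_raw_sa`
#'   (the normalization constant) and `min_rsa_by_doc` (named numeric vector
#'   of each document's minimum retained normalized score, used by
#'   [impute_sa()]).
#' @export
normalize_sa <- function(records, top_k = 20L) {
  if (top_k < 1L) stop_litmap("`top_k` must be >= 1")
  rec <- as.data.table(records)[, .(id_a = as.character(id_a),
                                    id_b = as.character(id_b),
                                    score = as.numeric(score))]
  if (any(rec$score < 0)) stop_litmap("similarity scores must be non-negative")
  rec <- rec[id_a != id_b & score > 0]
  pairs <- pair_key(rec$id_a, rec$id_b)
  pairs[, score := rec$score]
  ## unordered-pair dedup: symmetric duplicates should agree; keep the max
  sa <- pairs[, .(score = max(score)), by = .(i, j)]
  if (nrow(sa) == 0L) {
    out <- data.table(i = character(0), j = character(0), r_sa = numeric(0))
    setattr(out, "max_raw_sa", NA_real_)
    setattr(out, "min_rsa_by_doc", numeric(0))
    return(out)
  }
  ## per-document rank of each incident pair; ties at rank k all kept
  long <- rbind(sa[, .(doc = i, i, j, score)], sa[, .(doc = j, i, j, score)])
  long[, rnk := frank(-score, ties.method = "min"), by = doc]
  keep_pairs <- unique(long[rnk <= top_k, .(i, j)])
  sa <- sa[keep_pairs, on = c("i", "j")]
  mx <- max(sa$score)
  sa[, r_sa := score / mx]
  sa[, score := NULL]
  order_pairs(sa)
  mins <- rbind(sa[, .(doc = i, r_sa)], sa[, .(doc = j, r_sa)])[
    , .(min_rsa = min(r_sa)), by = doc]
  setattr(sa, "max_raw_sa", mx)
  setattr(sa, "min_rsa_by_doc", setNames(mins$min_rsa, mins$doc))
  sa[]
}

#' Impute text relatedness for citation-only pairs
#'
#' Citation-linked pairs without a retained top-k similarity score receive an
#' estimated one. If a raw score is known (outside the top-k) it is normalized
#' by the same global maximum; otherwise the pair gets half the smaller of the
#' two endpoints' minimum retained normalized scores, flagged `sa_imputed`.
#' An endpoint with no retained score at all falls back to a global floor
#' (half the overall minimum retained score unless configured).
#'
#' @param dc_pairs data.table of citation pairs (columns `i`, `j`), e.g. the
#'   output of [compute_dc()].
#' @param sa_pairs output of [normalize_sa()] (needs its attributes).
#' @param raw_lookup optional data.table `i`, `j`, `score` of raw similarity
#'   scores for pairs outside the top-k.
#' @param floor optional global floor for endpoints without any retained
#'   score; default `0.5 * min(r_sa)` over all retained pairs.
#' @return data.table `i`, `j`, `r_sa`, `sa_imputed` covering every retained
#'   similarity pair plus every citation pair.
#' @export
impute_sa <- function(dc_pairs, sa_pairs, raw_lookup = NULL, floor = NULL) {
  sa <- as.data.table(sa_pairs)[, .(i, j, r_sa)]
  sa[, sa_imputed := FALSE]
  dc <- as.data.table(dc_pairs)[, .(i, j)]
  missing <- dc[!sa, on = c("i", "j")]
  if (nrow(missing) == 0L) return(order_pairs(sa)[])

  mx <- attr(sa_pairs, "max_raw_sa")
  min_by_doc <- attr(sa_pairs, "min_rsa_by_doc") %||% numeric(0)
  if (is.null(floor)) {
    floor <- if (length(min_by_doc)) 0.5 * min(min_by_doc) else 1e-6
  }

  ## pairs whose raw score is known but was outside the top-k
  known <- data.table(i = character(0), j = character(0), r_sa = numeric(0))
  if (!is.null(raw_lookup) && nrow(raw_lookup) > 0L && !is.na(mx)) {
    rl <- as.data.table(raw_lookup)
    rl <- cbind(pair_key(rl$i, rl$j), score = as.numeric(rl$score))
    rl <- rl[, .(score = max(score)), by = .(i, j)]
    known <- rl[missing, on = c("i", "j"), nomatch = NULL][, .(i, j, r_sa = score / mx)]
    known[, sa_imputed := FALSE]
    missing <- missing[!known, on = c("i", "j")]
  }

  imput <- copy(missing)
  mi <- min_by_doc[imput$i]
  mj <- min_by_doc[imput$j]
  n_floor <- sum(is.na(mi)) + sum(is.na(mj))
  if (n_floor > 0L) {
    message(sprintf("impute_sa: %d endpoint(s) without retained SA scores; using floor %.3g",
                    n_floor, floor))
  }
  mi[is.na(mi)] <- 2 * floor  # so 0.5 * floor-side min == floor
  mj[is.na(mj)] <- 2 * floor
  imput[, r_sa := 0.5 * pmin(mi, mj)]
  imput[, sa_imputed := TRUE]

  out <- rbind(sa, if (nrow(known)) known else NULL, imput, fill = TRUE)
  order_pairs(out)[]
}

#' Calibrate the hybrid mixing parameter
#'
#' Solves `alpha * sum_dc = (1 - alpha) * sum_sa` so that the citation and
#' text components contribute equal total weight across all pairs:
#' `alpha = sum_sa / (sum_dc + sum_sa)`.
#'
#' @param sum_dc,sum_sa positive sums of the normalized citation and text
#'   relatedness values over all pairs.
#' @return alpha in (0, 1).
#' @examples
#' calibrate_alpha(9359293, 26297313)  # 0.7375
#' @export
calibrate_alpha <- function(sum_dc, sum_sa) {
  if (!is.finite(sum_dc) || !is.finite(sum_sa) || sum_dc <= 0 || sum_sa <= 0)
    stop_litmap("`sum_dc` and `sum_sa` must be positive")
  sum_sa / (sum_dc + sum_sa)
}

#' Combine citation and text relatedness into the hybrid measure
#'
#' `r_hyb = alpha * r_dc + (1 - alpha) * r_sa` over the union of pair keys.
#' Pairs present only in the similarity map have `r_dc = 0`; citation pairs
#' are expected to have been through [impute_sa()] so `r_sa > 0`.
#'
#' @param dc_map data.table `i`, `j`, `r_dc` from [compute_dc()].
#' @param sa_map data.table `i`, `j`, `r_sa`, optionally `sa_imputed`, from
#'   [normalize_sa()] or [impute_sa()].
#' @param alpha mixing weight in (0, 1) (weight on the citation component).
#' @return data.table `i`, `j`, `r_dc`, `r_sa`, `r_hyb`, `sa_imputed`.
#' @export
combine_hybrid <- function(dc_map, sa_map, alpha) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop_litmap("`alpha` must be in (0, 1)")
  dc <- as.data.table(dc_map)[, .(i, j, r_dc)]
  sa <- as.data.table(sa_map)
  if (!"sa_imputed" %in% names(sa)) sa[, sa_imputed := FALSE]
  sa <- sa[, .(i, j, r_sa, sa_imputed)]
  out <- merge(dc, sa, by = c("i", "j"), all = TRUE)
  out[is.na(r_dc), r_dc := 0]
  out[is.na(r_sa), r_sa := 0]
  out[is.na(sa_imputed), sa_imputed := FALSE]
  out[, r_hyb := alpha * r_dc + (1 - alpha) * r_sa]
  order_pairs(out)[]
}

#' Build the full hybrid relatedness network
#'
#' Driver running [compute_dc()], [normalize_sa()], [impute_sa()],
#' [calibrate_alpha()] and [combine_hybrid()] in sequence, with bookkeeping.
#' By default alpha is calibrated on the final edge set, i.e. after similarity
#' imputation; set `calibrate_before_imputation = TRUE` to calibrate on the
#' retained top-k similarity pairs only.
#'
#' @param citations citation edge table (`citing_id`, `cited_id`).
#' @param similarity raw similarity table (`id_a`, `id_b`, `score`).
#' @param docset character vector of in-corpus document ids.
#' @param sa_top_k similarity partners retained per document (default 20).
#' @param alpha either the string "calibrate" (default) or a numeric override.
#' @param calibrate_before_imputation logical; see Details.
#' @param sa_floor optional global imputation floor (see [impute_sa()]).
#' @return list with `edges` (RelatednessEdge table), `alpha`, `sum_dc`,
#'   `sum_sa`, and `accounting` (edge counts and overlap percentage).
#' @export
build_relatedness <- function(citations, similarity, docset,
                              sa_top_k = 20L, alpha = "calibrate",
                              calibrate_before_imputation = FALSE,
                              sa_floor = NULL) {
  dc <- compute_dc(citations, docset)
  sa <- normalize_sa(similarity, top_k = sa_top_k)
  n_overlap <- nrow(dc[sa, on = c("i", "j"), nomatch = NULL])
  sa_full <- impute_sa(dc, sa, floor = sa_floor)

  sum_dc <- sum(dc[order(i, j)]$r_dc)
  sa_for_sum <- if (calibrate_before_imputation) sa else sa_full
  sum_sa <- sum(sa_for_sum[order(i, j)]$r_sa)

  if (identical(alpha, "calibrate")) {
    alpha_val <- calibrate_alpha(sum_dc, sum_sa)
    calibrated <- TRUE
  } else {
    alpha_val <- as.numeric(alpha)
    calibrated <- FALSE
  }
  edges <- combine_hybrid(dc, sa_full, alpha_val)
  acct <- relatedness_accounting(n_dc = nrow(dc), n_sa = nrow(sa),
                                 n_overlap = n_overlap)
  list(edges = edges, alpha = alpha_val, calibrated = calibrated,
       sum_dc = sum_dc, sum_sa = sum_sa, accounting = acct)
}

#' Edge-count accounting for the hybrid network
#'
#' Bookkeeping identities over the citation (DC) and retained-similarity (SA)
#' pair sets: hybrid size is the union, `n_dc + n_sa - n_overlap`, and the
#' overlap percentage is `100 * n_overlap / n_dc` (the share of citation links
#' that also have a retained similarity link).
#'
#' @param n_dc,n_sa,n_overlap pair counts.
#' @return list with `n_dc`, `n_sa`, `n_overlap`, `n_dc_only`, `n_hybrid`,
#'   `overlap_pct`.
#' @export
relatedness_accounting <- function(n_dc, n_sa, n_overlap) {
  if (n_overlap > min(n_dc, n_sa)) stop_litmap("overlap exceeds a component count")
  list(n_dc = n_dc, n_sa = n_sa, n_overlap = n_overlap,
       n_dc_only = n_dc - n_overlap,
       n_hybrid = n_dc + n_sa - n_overlap,
       overlap_pct = if (n_dc > 0) 100 * n_overlap / n_dc else NA_real_)
}
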