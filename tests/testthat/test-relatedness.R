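test_that("compute_dc follows the 1/nref rule with max symmetrization", {
  ## doc "i" cites 26 in-set papers (one of them "j"); doc "s" has a single
  ## in-set reference so the observed maximum r_dc is 1 and normalization is
  ## the identity
  cit <- data.table(
    citing_id = c(rep("i", 26L), "s"),
    cited_id = c(paste0("r", 1:25), "j", "r1"))
  ids <- unique(c(cit$citing_id, cit$cited_id))
  dc <- compute_dc(cit, ids)
  expect_equal(attr(dc, "max_raw_dc"), 1)
  expect_equal(round(dc[i == "i" & j == "j"]$r_dc, 6), 0.038462)

  ## reciprocal citation takes the larger direction: i cites j (4 refs ->
  ## 0.25), j cites i (2 refs -> 0.5) -> 0.5
  cit2 <- data.table(
    citing_id = c("a", "a", "a", "a", "b", "b", "z"),
    cited_id = c("b", "x", "y", "w", "a", "x", "x"))
  dc2 <- compute_dc(cit2, c("a", "b", "x", "y", "w", "z"))
  expect_equal(attr(dc2, "max_raw_dc"), 1)  # z has a single in-set reference
  expect_equal(dc2[i == "a" & j == "b"]$r_dc, 0.5)

  ## no citation in either direction -> no pair at all
  expect_equal(nrow(dc2[i == "y" & j == "z"]), 0L)
  ## out-of-set references do not count toward nref
  dc3 <- compute_dc(data.table(citing_id = c("a", "a"), cited_id = c("b", "q")),
                    c("a", "b"))
  expect_equal(attr(dc3, "max_raw_dc"), 1)  # nref(a) = 1 in-set
})

test_that("normalize_sa deduplicates, truncates to top-k and max-normalizes", {
  rec <- data.table(id_a = c("i", "j", "i"), id_b = c("j", "i", "k"),
                    score = c(50, 50, 100))
  sa <- normalize_sa(rec, top_k = 20L)
  expect_equal(nrow(sa), 2L)
  expect_equal(sa[i == "i" & j == "j"]$r_sa, 0.5)
  expect_equal(sa[i == "i" & j == "k"]$r_sa, 1.0)

  ## top-k truncation with rescue through the partner's list
  set.seed(5)
  rec2 <- data.table(id_a = "hub", id_b = paste0("p", 1:25),
                     score = 25:1)
  sa2 <- normalize_sa(rec2, top_k = 20L)
  ## hub keeps its 20 best, but every pair is in the partner's top-20 (it is
  ## the partner's only pair) so all 25 survive via the either-endpoint rule
  expect_equal(nrow(sa2), 25L)
  sa3 <- normalize_sa(rec2, top_k = 1L)
  expect_equal(nrow(sa3), 25L)  # rescued by partners even at k = 1

  ## equal scores all normalize to 1 and ties at the boundary are all kept
  rec3 <- data.table(id_a = "a", id_b = paste0("b", 1:5), score = 7)
  sa4 <- normalize_sa(rec3, top_k = 2L)
  expect_equal(nrow(sa4), 5L)
  expect_true(all(sa4$r_sa == 1))

  expect_error(normalize_sa(rec, top_k = 0L), "top_k")
})

test_that("impute_sa halves the smaller endpoint minimum and flags", {
  sa <- data.table(i = c("i", "j"), j = c("x", "y"), r_sa = c(0.2, 0.1))
  setattr(sa, "max_raw_sa", 100)
  setattr(sa, "min_rsa_by_doc", c(i = 0.2, x = 0.2, j = 0.1, y = 0.1))
  dc <- data.table(i = "i", j = "j")
  out <- impute_sa(dc, sa)
  got <- out[i == "i" & j == "j"]
  expect_equal(got$r_sa, 0.05)
  expect_true(got$sa_imputed)
  ## pairs already retained are untouched
  expect_equal(out[i == "i" & j == "x"]$r_sa, 0.2)
  expect_false(out[i == "i" & j == "x"]$sa_imputed)

  ## raw score outside the top-k is normalized, not imputed
  out2 <- impute_sa(dc, sa, raw_lookup = data.table(i = "i", j = "j", score = 30))
  expect_equal(out2[i == "i" & j == "j"]$r_sa, 0.3)
  expect_false(out2[i == "i" & j == "j"]$sa_imputed)

  ## endpoint with no retained scores falls back to the global floor
  dc2 <- data.table(i = c("i", "q"), j = c("j", "z"))
  expect_message(out3 <- impute_sa(dc2, sa), "floor")
  expect_equal(out3[i == "q" & j == "z"]$r_sa, 0.5 * 0.1)  # global floor
})

test_that("calibrate_alpha reproduces the balance condition", {
  a <- calibrate_alpha(9359293, 26297313)
  expect_equal(round(a, 4), 0.7375)
  expect_equal(a * 9359293, (1 - a) * 26297313, tolerance = 1e-9)
  expect_equal(calibrate_alpha(5, 5), 0.5)
  expect_gt(calibrate_alpha(1e-9, 1), 0.999)
  expect_error(calibrate_alpha(0, 1), "positive")
  expect_error(calibrate_alpha(1, -2), "positive")
})

test_that("combine_hybrid applies the convex combination over the union", {
  dc <- data.table(i = "a", j = "b", r_dc = 1 / 26)
  sa <- data.table(i = c("a", "b"), j = c("b", "c"), r_sa = c(0.136923, 0.4))
  hyb <- combine_hybrid(dc, sa, alpha = 0.7375)
  expect_lt(abs(hyb[i == "a" & j == "b"]$r_hyb - 0.064307), 1e-5)
  ## SA-only pair: r_dc treated as 0
  expect_equal(hyb[i == "b" & j == "c"]$r_hyb, 0.2625 * 0.4)
  expect_equal(nrow(hyb), 2L)
  expect_error(combine_hybrid(dc, sa, alpha = 1), "alpha")
})

test_that("build_relatedness matches the brute-force oracle on small corpora", {
  for (seed in 1:3) {
    cf <- small_config(seed = seed, n_topics = 3L, docs_per_topic = 15L,
                       sa_partners_within = 6L, sa_partners_cross = 2L,
                       refs_per_doc = 4)
    corp <- generate_corpus(cf)
    ids <- corp$documents$doc_id
    expect_lte(length(ids), 50L)
    rel <- build_relatedness(corp$citations, corp$similarity, ids, sa_top_k = 5L)
    orc <- oracle_relatedness(corp$citations, corp$similarity, ids, top_k = 5)

    expect_equal(rel$alpha, orc$alpha, tolerance = 1e-12)
    expect_equal(rel$sum_dc, orc$sum_dc, tolerance = 1e-12)
    expect_equal(rel$sum_sa, orc$sum_sa, tolerance = 1e-12)
    got_h <- edge_matrix(rel$edges, ids, "r_hyb")
    expect_equal(got_h, orc$hyb, tolerance = 1e-12)
    got_d <- edge_matrix(rel$edges, ids, "r_dc")
    expect_equal(got_d, orc$rdc, tolerance = 1e-12)
    got_s <- edge_matrix(rel$edges, ids, "r_sa")
    expect_equal(got_s, orc$rsa, tolerance = 1e-12)
  }
})

test_that("relatedness invariants hold on generated corpora", {
  corp <- generate_corpus(small_config(seed = 11L))
  rel <- build_relatedness(corp$citations, corp$similarity,
                           corp$documents$doc_id)
  e <- rel$edges
  ## balance after calibration
  expect_equal(rel$alpha * rel$sum_dc, (1 - rel$alpha) * rel$sum_sa,
               tolerance = 1e-9)
  ## ranges and attained maxima
  expect_true(all(e$r_dc >= 0 & e$r_dc <= 1))
  expect_true(all(e$r_sa >= 0 & e$r_sa <= 1))
  expect_true(all(e$r_hyb >= 0 & e$r_hyb <= 1))
  expect_equal(max(e$r_dc), 1)
  expect_equal(max(e$r_sa), 1)
  expect_true(all(e$r_dc > 0 | e$r_sa > 0))
  ## imputed pairs all carry a citation link (hence r_dc > 0)
  expect_true(all(e[sa_imputed == TRUE]$r_dc > 0))
  ## edge-count accounting: |hybrid| = |dc| + |sa| - |overlap|
  acct <- rel$accounting
  expect_equal(nrow(e), acct$n_hybrid)
  expect_equal(acct$n_dc_only + acct$n_overlap, acct$n_dc)
})

test_that("relatedness_accounting reports union size and overlap share", {
  a <- relatedness_accounting(n_dc = 200, n_sa = 500, n_overlap = 50)
  expect_equal(a$n_hybrid, 650)
  expect_equal(a$overlap_pct, 25)
  expect_error(relatedness_accounting(10, 10, 11), "overlap")
})
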