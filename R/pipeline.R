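## End-to-end pipeline driver with a JSON config, seeded reproducibility and
## a run manifest.

#' Default pipeline configuration
#'
#' Full-corpus defaults follow the published model where stated: top-20
#' similarity partners, top-15 cluster neighbours, layout edge cut 0.7,
#' 20 bootstrap samples of one third, minimum cluster sizes 75/750/7500 and
#' the published per-level resolutions. The `synthetic` profile (default)
#' rescales resolutions and minimum sizes for the 2,000-document validation
#' corpus, since constant-Potts resolutions are corpus-scale dependent.
#'
#' @param profile "synthetic" (desk-scale defaults) or "full" (published
#'   full-corpus parameters).
#' @return nested configuration list.
#' @export
default_config <- function(profile = c("synthetic", "full")) {
  profile <- match.arg(profile)
  levels <- if (profile == "full") list(
    level_config(resolution = 7.75e-5, min_size = 75L),
    level_config(resolution = 7.75e-6, min_size = 750L),
    level_config(resolution = 7.75e-7, min_size = 7500L)
  ) else list(
    level_config(resolution = 0.02, min_size = 75L),
    level_config(resolution = 0.002, min_size = 150L),
    level_config(resolution = 0.0002, min_size = 400L)
  )
  list(
    profile = profile,
    seed = 1L,
    excluded_journals = character(0),
    sa_top_k = 20L,
    alpha = "calibrate",
    calibrate_before_imputation = FALSE,
    levels = levels,
    degenerate = degenerate_rules(),
    cluster_top_k = 15L,
    edge_cut = 0.7,
    window_years = 5L,
    bootstrap = list(n_samples = 20L, sample_frac = 1 / 3),
    idio_log_base = exp(1),
    top_k = 10L,
    overlay = list(min_count = 25L, min_fraction = 0.10),
    synthetic = synthetic_config()
  )
}

#' Load a pipeline configuration from JSON
#'
#' Unset keys fall back to [default_config()] values.
#'
#' @param path JSON file.
#' @param profile default profile when the file does not set one.
#' @return configuration list.
#' @export
load_config <- function(path, profile = "synthetic") {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- default_config(raw$profile %||% profile)
  cfg <- modifyList(cfg, raw, keep.null = TRUE)
  if (!is.null(raw$levels)) {
    lv <- raw$levels
    cfg$levels <- Map(level_config, as.numeric(lv$resolution),
                      as.integer(lv$min_size))
  }
  if (!is.null(raw$synthetic))
    cfg$synthetic <- do.call(synthetic_config,
                             modifyList(unclass(default_config(cfg$profile)$synthetic),
                                        as.list(raw$synthetic)))
  cfg
}

#' Run a pipeline stage
#'
#' Stages: `simulate` (write a synthetic corpus), `build` (relatedness +
#' clustering), `map` (cluster graph + layout + fields), `characterize`
#' (descriptor/indicator sheets), `evaluate` (recovery vs ground truth).
#' Every stage writes its artifacts under `out_dir` and appends to
#' `manifest.json` (config hash, seeds, alpha, edge and cluster counts).
#'
#' @param stage stage name.
#' @param config configuration list (see [default_config()]).
#' @param out_dir artifact directory.
#' @return invisible list of stage outputs.
#' @export
run_pipeline <- function(stage = c("simulate", "build", "map", "characterize",
                                   "evaluate", "all"),
                         config = default_config(), out_dir) {
  stage <- match.arg(stage)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (stage == "all") {
    for (s in c("simulate", "build", "map", "characterize", "evaluate"))
      run_pipeline(s, config, out_dir)
    return(invisible(read_manifest(out_dir)))
  }
  res <- switch(stage,
    simulate = stage_simulate(config, out_dir),
    build = stage_build(config, out_dir),
    map = stage_map(config, out_dir),
    characterize = stage_characterize(config, out_dir),
    evaluate = stage_evaluate(config, out_dir))
  invisible(res)
}

artifact <- function(out_dir, name) file.path(out_dir, name)

need_artifact <- function(out_dir, name, producer) {
  p <- artifact(out_dir, name)
  if (!file.exists(p))
    stop_litmap("missing artifact '", name, "'; run the '", producer,
                "' stage first")
  p
}

update_manifest <- function(out_dir, stage, info, config) {
  p <- artifact(out_dir, "manifest.json")
  man <- if (file.exists(p)) jsonlite::fromJSON(p, simplifyVector = FALSE) else list()
  js <- jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE, digits = NA)
  b <- utf8ToInt(js)
  ## small deterministic FNV-style hash of the serialized config
  h <- 2166136261
  for (x in b) h <- ((h * 16777619) %% 2^32 + x) %% 2^32
  man$config_hash <- sprintf("%04x%04x", as.integer(h %/% 65536),
                             as.integer(h %% 65536))
  man$seed <- config$seed
  man[[stage]] <- info
  writeLines(jsonlite::toJSON(man, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null", force = TRUE), p)
}

read_manifest <- function(out_dir) {
  jsonlite::fromJSON(artifact(out_dir, "manifest.json"), simplifyVector = FALSE)
}

stage_simulate <- function(config, out_dir) {
  corp <- generate_corpus(config$synthetic)
  write_documents(corp$documents, artifact(out_dir, "documents.jsonl"))
  fwrite(corp$citations, artifact(out_dir, "citations.tsv"), sep = "\t")
  fwrite(corp$similarity, artifact(out_dir, "similarity.tsv"), sep = "\t")
  fwrite(corp$truth, artifact(out_dir, "truth.tsv"), sep = "\t")
  ## example overlay subset (a planted topic plus background noise), the
  ## analogue of projecting an external topical corpus onto the model
  tr <- corp$truth
  set.seed(config$synthetic$seed + 1L)
  ov <- c(tr[topic == 1L, doc_id],
          sample(tr[topic != 1L, doc_id], max(1L, nrow(tr) %/% 50L)))
  writeLines(sort(ov), artifact(out_dir, "overlay_example.txt"))
  update_manifest(out_dir, "simulate",
                  list(n_documents = nrow(corp$documents),
                       n_citations = nrow(corp$citations),
                       n_similarity = nrow(corp$similarity),
                       seed = config$synthetic$seed), config)
  invisible(corp)
}

stage_build <- function(config, out_dir) {
  corp <- read_corpus(need_artifact(out_dir, "documents.jsonl", "simulate"),
                      need_artifact(out_dir, "citations.tsv", "simulate"),
                      need_artifact(out_dir, "similarity.tsv", "simulate"),
                      excluded_journals = config$excluded_journals)
  rel <- build_relatedness(
    corp$citations, corp$similarity, corp$documents$doc_id,
    sa_top_k = config$sa_top_k, alpha = config$alpha,
    calibrate_before_imputation = config$calibrate_before_imputation)
  write_edges(rel$edges, artifact(out_dir, "edges.tsv"))
  asn <- build_hierarchy(rel$edges[, .(i, j, weight = r_hyb)],
                         configs = config$levels, seed = config$seed,
                         nodes = corp$documents$doc_id)
  fd <- flag_degenerate(asn, corp$documents, corp$citations,
                        rules = config$degenerate)
  asn <- fd$assignment
  fwrite(asn[, .(doc_id, PM5, PM4, PM3, removed = as.integer(removed))],
         artifact(out_dir, "assignment.tsv"), sep = "\t")
  update_manifest(out_dir, "build",
                  list(alpha = rel$alpha, calibrated = rel$calibrated,
                       sum_dc = rel$sum_dc, sum_sa = rel$sum_sa,
                       accounting = rel$accounting,
                       clusters = list(PM5 = uniqueN(asn$PM5),
                                       PM4 = uniqueN(asn$PM4),
                                       PM3 = uniqueN(asn$PM3)),
                       removed_clusters = fd$counts$removed,
                       docs_dropped = corp$log$docs_dropped), config)
  invisible(list(edges = rel$edges, assignment = asn, alpha = rel$alpha))
}

read_assignment <- function(out_dir) {
  asn <- fread(need_artifact(out_dir, "assignment.tsv", "build"), sep = "\t",
               colClasses = list(character = "doc_id"))
  asn[, removed := as.logical(removed)]
  asn[]
}

stage_map <- function(config, out_dir) {
  edges <- read_edges(need_artifact(out_dir, "edges.tsv", "build"))
  asn <- read_assignment(out_dir)
  ce <- cluster_relatedness(asn, edges)
  ce15 <- topk_neighbors(ce, k = config$cluster_top_k)
  lay <- map_layout(ce15, seed = config$seed, edge_cut = config$edge_cut)
  docs <- read_documents(need_artifact(out_dir, "documents.jsonl", "simulate"))
  jmap <- config$journal_field_map %||%
    data.table(journal = unique(docs$journal),
               field = rep(default_fields(),
                           length.out = length(unique(docs$journal))))
  fld <- assign_field(docs, asn, jmap)
  layout_tab <- merge(lay, fld, by = "cluster", all.x = TRUE)
  fwrite(ce15, artifact(out_dir, "cluster_edges.tsv"), sep = "\t")
  fwrite(layout_tab, artifact(out_dir, "layout.tsv"), sep = "\t")
  update_manifest(out_dir, "map",
                  list(n_cluster_edges = nrow(ce15),
                       layout_algorithm = attr(lay, "algorithm"),
                       edge_cut = config$edge_cut), config)
  invisible(list(cluster_edges = ce15, layout = layout_tab))
}

stage_characterize <- function(config, out_dir) {
  docs <- read_documents(need_artifact(out_dir, "documents.jsonl", "simulate"))
  asn <- read_assignment(out_dir)
  edges <- read_edges(need_artifact(out_dir, "edges.tsv", "build"))
  cit <- fread(need_artifact(out_dir, "citations.tsv", "simulate"), sep = "\t",
               colClasses = list(character = c("citing_id", "cited_id")))
  layout_tab <- NULL; fields_tab <- NULL
  lp <- artifact(out_dir, "layout.tsv")
  if (file.exists(lp)) {
    lt <- fread(lp, sep = "\t")
    layout_tab <- lt[, .(cluster, X, Y)]
    if ("field" %in% names(lt)) fields_tab <- lt[, .(cluster, field)]
  }
  ymax <- max(docs$year)
  window <- (ymax - config$window_years + 1L):ymax
  overlay_files <- config$overlay_files
  if (is.null(overlay_files) &&
      file.exists(artifact(out_dir, "overlay_example.txt")))
    overlay_files <- list(example = artifact(out_dir, "overlay_example.txt"))
  overlays <- lapply(overlay_files %||% list(), readLines, warn = FALSE)
  profiles <- characterize_clusters(
    docs, asn, edges, cit, layout = layout_tab, fields = fields_tab,
    window = window, overlays = overlays, seed = config$seed,
    n_samples = config$bootstrap$n_samples,
    sample_frac = config$bootstrap$sample_frac,
    idio_log_base = config$idio_log_base, top_k = config$top_k)
  write_tables(profiles, asn, artifact(out_dir, "tables"))
  update_manifest(out_dir, "characterize",
                  list(sheets = names(Filter(Negate(is.null), profiles)),
                       window = range(window)), config)
  invisible(profiles)
}

stage_evaluate <- function(config, out_dir) {
  tp <- artifact(out_dir, "truth.tsv")
  if (!file.exists(tp))
    stop_litmap("no ground truth file (truth.tsv); run 'simulate' first")
  truth <- fread(tp, sep = "\t", colClasses = list(character = "doc_id"))
  asn <- read_assignment(out_dir)
  sc <- evaluate_recovery(asn, truth)
  writeLines(jsonlite::toJSON(sc, auto_unbox = TRUE, digits = NA),
             artifact(out_dir, "recovery.json"))
  update_manifest(out_dir, "evaluate", sc, config)
  invisible(sc)
}
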