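## Three-level nested document clustering.
##
## Finest level: Leiden with a constant-Potts quality on the hybrid document
## network. Coarser levels: Leiden on the aggregated cluster graph (size-
## normalized cluster relatedness as weights, document counts as node sizes),
## which guarantees nesting by construction.

#' Cluster a weighted network at one level
#'
#' Runs the Leiden algorithm with a constant-Potts-model quality function
#' (modularity available as an alternative) at the given resolution, then
#' enforces a minimum cluster size: every undersized cluster is merged into
#' the neighbouring cluster to which it has the highest summed edge weight
#' (smallest clusters first, recomputed after each merge); undersized clusters
#' with no external edges are collected into a designated residual cluster.
#'
#' @param edges data.table with columns `i`, `j`, `weight` (positive).
#' @param resolution positive resolution parameter.
#' @param min_size minimum retained cluster size, counted in documents.
#' @param seed integer seed; output is deterministic given the seed.
#' @param node_sizes optional named numeric vector of node sizes (document
#'   counts) used for min-size accounting and as CPM node weights when nodes
#'   are aggregates; default 1 per node.
#' @param objective "cpm" (default) or "modularity".
#' @param nodes optional character vector of all node ids; nodes absent from
#'   `edges` are placed in the residual cluster.
#' @return named integer vector of cluster ids (dense, 1..K) indexed by node
#'   id; attribute `residual` gives the residual cluster id or NA.
#' @export
cluster_level <- function(edges, resolution, min_size, seed,
                          node_sizes = NULL, objective = c("cpm", "modularity"),
                          nodes = NULL) {
  objective <- match.arg(objective)
  edges <- as.data.table(edges)
  if (nrow(edges) == 0L) stop_litmap("empty edge list")
  if (any(edges$weight <= 0)) stop_litmap("edge weights must be positive")

  ids <- sort(unique(c(edges$i, edges$j, nodes)))
  g <- igraph::graph_from_data_frame(
    edges[, .(from = i, to = j, weight = weight)],
    directed = FALSE, vertices = data.frame(name = ids))
  sizes <- rep(1, length(ids))
  names(sizes) <- ids
  if (!is.null(node_sizes)) sizes[names(node_sizes)] <- node_sizes

  set.seed(seed)
  memb <- if (objective == "cpm") {
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "CPM", weights = igraph::E(g)$weight,
      resolution = resolution, vertex_weights = sizes, n_iterations = 10))
  } else {
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity", weights = igraph::E(g)$weight,
      resolution = resolution, n_iterations = 10))
  }
  memb <- setNames(as.integer(memb), ids)
  merge_small_clusters(memb, edges, sizes, min_size)
}

## Min-size enforcement. Repeatedly merge the smallest undersized cluster
## into its strongest neighbour (highest summed edge weight); isolated
## undersized clusters go to a shared residual cluster.
merge_small_clusters <- function(memb, edges, sizes, min_size) {
  edges <- as.data.table(edges)[, .(i, j, weight)]
  residual <- integer(0)
  repeat {
    csize <- tapply(sizes[names(memb)], memb, sum)
    live <- as.integer(names(csize))
    small <- live[csize < min_size & !(live %in% residual)]
    if (length(small) == 0L || length(setdiff(live, residual)) <= 1L) break
    ## smallest first; deterministic tie-break on id
    small <- small[order(csize[as.character(small)], small)]
    s <- small[1L]
    e <- copy(edges)
    e[, `:=`(ci = memb[i], cj = memb[j])]
    ext <- e[(ci == s) != (cj == s)]
    ext[, other := ifelse(ci == s, cj, ci)]
    if (nrow(ext) == 0L) {
      residual <- c(residual, s)
      next
    }
    wsum <- ext[, .(w = sum(weight)), by = other]
    setorder(wsum, -w, other)
    target <- wsum$other[1L]
    memb[memb == s] <- target
  }
  if (length(residual) > 1L) {
    memb[memb %in% residual] <- residual[1L]
    residual <- residual[1L]
  }
  dense <- dense_ids(memb)
  names(dense) <- names(memb)
  res_id <- if (length(residual)) unique(dense[memb == residual]) else NA_integer_
  setattr(dense, "residual", res_id)
  dense
}

#' Per-level configuration for the nested clustering
#'
#' @param resolution positive constant-Potts resolution.
#' @param min_size minimum cluster size in documents.
#' @return a `level_config` list.
#' @export
level_config <- function(resolution, min_size) {
  stopifnot(resolution > 0, min_size >= 1)
  structure(list(resolution = resolution, min_size = as.integer(min_size)),
            class = "level_config")
}

#' Build the three-level nested cluster hierarchy
#'
#' The finest level clusters documents directly. Each coarser level clusters
#' the aggregated graph of the level below, with size-normalized
#' cluster-cluster relatedness as edge weights and document counts as node
#' sizes, so nesting holds by construction. Levels are labelled PM5 (finest),
#' PM4 and PM3.
#'
#' @param edges hybrid relatedness table with columns `i`, `j`, `r_hyb` (or
#'   `weight`).
#' @param configs list of three [level_config()] objects ordered finest to
#'   coarsest; resolutions must strictly decrease.
#' @param seed integer seed.
#' @param nodes optional character vector of all document ids.
#' @return data.table `doc_id`, `PM5`, `PM4`, `PM3`, `removed` (all FALSE;
#'   see [flag_degenerate()]).
#' @export
build_hierarchy <- function(edges, configs, seed, nodes = NULL) {
  stopifnot(length(configs) == 3L)
  res <- vapply(configs, `[[`, numeric(1), "resolution")
  if (any(diff(res) >= 0))
    stop_litmap("resolutions must strictly decrease from finest to coarsest")
  e <- as.data.table(edges)
  if (!"weight" %in% names(e)) e[, weight := r_hyb]
  e <- e[, .(i, j, weight)]

  m5 <- cluster_level(e, configs[[1]]$resolution, configs[[1]]$min_size,
                      seed = seed, nodes = nodes)
  asn <- data.table(doc_id = names(m5), PM5 = as.integer(m5))

  ## aggregate to the PM5 cluster graph and re-cluster
  agg5 <- aggregate_cluster_graph(asn$PM5, asn$doc_id, e)
  m4 <- cluster_coarser(agg5, configs[[2]], seed + 1L)
  asn[, PM4 := m4[as.character(PM5)]]

  asn4 <- asn[, .(doc_id, cl = PM4)]
  agg4 <- aggregate_cluster_graph(asn4$cl, asn4$doc_id, e)
  m3 <- cluster_coarser(agg4, configs[[3]], seed + 2L)
  asn[, PM3 := m3[as.character(PM4)]]

  asn[, removed := FALSE]
  setorder(asn, doc_id)
  asn[]
}

## Aggregated graph of a partition: nodes = clusters (with doc-count sizes),
## edges = size-normalized summed relatedness between clusters.
aggregate_cluster_graph <- function(membership, doc_ids, edges) {
  map <- setNames(membership, doc_ids)
  e <- as.data.table(edges)
  e[, `:=`(cm = map[i], cn = map[j])]
  csize <- table(membership)
  cross <- e[cm != cn]
  if (nrow(cross) > 0L) {
    cross[, `:=`(m = pmin(cm, cn), n = pmax(cm, cn))]
    ce <- cross[, .(weight = sum(weight)), by = .(m, n)]
    ce[, weight := weight / sqrt(as.numeric(csize[as.character(m)]) *
                                 as.numeric(csize[as.character(n)]))]
  } else {
    ce <- data.table(m = integer(0), n = integer(0), weight = numeric(0))
  }
  list(edges = ce, sizes = setNames(as.numeric(csize), names(csize)))
}

cluster_coarser <- function(agg, config, seed) {
  node_ids <- names(agg$sizes)
  if (nrow(agg$edges) == 0L) {
    ## no inter-cluster edges: each node keeps its own coarse cluster unless
    ## undersized, in which case all undersized nodes pool into a residual
    sz <- agg$sizes
    memb <- seq_along(node_ids)
    names(memb) <- node_ids
    small <- sz < config$min_size
    if (any(small) && sum(small) > 0L) memb[small] <- min(memb[small])
    d <- dense_ids(memb); names(d) <- node_ids
    return(d)
  }
  ce <- agg$edges[, .(i = as.character(m), j = as.character(n), weight)]
  cluster_level(ce, config$resolution, config$min_size, seed = seed,
                node_sizes = agg$sizes, nodes = node_ids)
}

#' Flag degenerate clusters for removal
#'
#' Replaces manual curation with explicit rules: a cluster is flagged when
#' the fraction of its titles matching an erratum/correction pattern exceeds
#' a threshold, or when it simultaneously has a high fraction of missing
#' abstracts and a low mean reference count. Removal is by whole cluster,
#' never by individual document.
#'
#' @param assignment data.table from [build_hierarchy()].
#' @param documents corpus document table (needs `doc_id`, `title`,
#'   `abstract`).
#' @param citations citation table, used for per-document reference counts.
#' @param rules list with `title_pattern` (regex, case-insensitive),
#'   `title_frac`, `abstract_missing_frac`, `mean_refs_lt`.
#' @return list with `flagged` (integer PM5 ids), `assignment` (copy with
#'   `removed` set), and `counts` (clusters before/after).
#' @export
flag_degenerate <- function(assignment, documents, citations = NULL,
                            rules = degenerate_rules()) {
  asn <- copy(as.data.table(assignment))
  docs <- as.data.table(documents)
  nref <- if (!is.null(citations) && nrow(citations) > 0L) {
    as.data.table(citations)[, .N, by = .(doc_id = as.character(citing_id))]
  } else data.table(doc_id = character(0), N = integer(0))
  d <- docs[, .(doc_id, title, abstract)]
  d <- nref[d, on = "doc_id"]
  d[is.na(N), N := 0L]
  d <- d[asn[, .(doc_id, PM5)], on = "doc_id", nomatch = NULL]

  stats <- d[, .(
    frac_errata = mean(grepl(rules$title_pattern, title, ignore.case = TRUE)),
    frac_noabs  = mean(is.na(abstract) | !nzchar(abstract)),
    mean_refs   = mean(N)
  ), by = PM5]
  flagged <- stats[frac_errata > rules$title_frac |
                   (frac_noabs > rules$abstract_missing_frac &
                    mean_refs < rules$mean_refs_lt), PM5]
  asn[, removed := PM5 %in% flagged]
  list(flagged = sort(flagged), assignment = asn,
       counts = list(before = uniqueN(asn$PM5),
                     removed = length(flagged),
                     after = uniqueN(asn$PM5) - length(flagged)))
}

#' Default degenerate-cluster rules
#'
#' @param title_pattern regex for erratum-type titles.
#' @param title_frac flag when this fraction of titles match the pattern.
#' @param abstract_missing_frac missing-abstract fraction threshold.
#' @param mean_refs_lt mean reference-count threshold (applies jointly with
#'   the abstract rule).
#' @return rules list for [flag_degenerate()].
#' @export
degenerate_rules <- function(title_pattern = "erratum|corrigendum|correction",
                             title_frac = 0.5,
                             abstract_missing_frac = 0.8,
                             mean_refs_lt = 1) {
  list(title_pattern = title_pattern, title_frac = title_frac,
       abstract_missing_frac = abstract_missing_frac,
       mean_refs_lt = mean_refs_lt)
}
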