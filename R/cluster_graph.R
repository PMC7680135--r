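## Cluster-level graph and 2-D map.

#' Size-normalized cluster-cluster relatedness
#'
#' For clusters m and n, `R = sum(r_hyb over cross pairs) / sqrt(Nm * Nn)`,
#' where Nm and Nn are document counts. The denominator removes the bias of
#' raw summed relatedness toward large clusters. Cluster pairs with no cross
#' edge are absent; there are no self-edges.
#'
#' @param assignment data.table with `doc_id` and a cluster column (default
#'   `PM5`); rows with `removed == TRUE` are excluded.
#' @param edges document relatedness table `i`, `j`, `r_hyb`.
#' @param level cluster column name.
#' @return data.table `m`, `n`, `R` with m < n.
#' @export
cluster_relatedness <- function(assignment, edges, level = "PM5") {
  asn <- as.data.table(assignment)
  if ("removed" %in% names(asn)) asn <- asn[removed == FALSE | is.na(removed)]
  map <- setNames(asn[[level]], asn$doc_id)
  e <- as.data.table(edges)[, .(i, j, r_hyb)]
  e[, `:=`(cm = map[i], cn = map[j])]
  e <- e[!is.na(cm) & !is.na(cn) & cm != cn]
  csize <- table(asn[[level]])
  if (nrow(e) == 0L) return(data.table(m = integer(0), n = integer(0), R = numeric(0)))
  e[, `:=`(m = pmin(cm, cn), n = pmax(cm, cn))]
  out <- e[, .(R = sum(r_hyb)), by = .(m, n)]
  out[, R := R / sqrt(as.numeric(csize[as.character(m)]) *
                      as.numeric(csize[as.character(n)]))]
  setorder(out, m, n)
  out[]
}

#' Filter cluster edges to each cluster's strongest neighbours
#'
#' An edge survives when it ranks within the top `k` by relatedness for
#' *either* endpoint; ties at rank k are all kept.
#'
#' @param cluster_edges data.table `m`, `n`, `R`.
#' @param k neighbours kept per cluster (default 15).
#' @return filtered data.table.
#' @export
topk_neighbors <- function(cluster_edges, k = 15L) {
  if (k < 1L) stop_litmap("`k` must be >= 1")
  ce <- as.data.table(cluster_edges)
  if (nrow(ce) == 0L) return(ce)
  long <- rbind(ce[, .(cl = m, m, n, R)], ce[, .(cl = n, m, n, R)])
  long[, rnk := frank(-R, ties.method = "min"), by = cl]
  keep <- unique(long[rnk <= k, .(m, n)])
  out <- ce[keep, on = c("m", "n")]
  setorder(out, m, n)
  out[]
}

#' Seeded 2-D layout of the cluster graph
#'
#' Force-directed embedding with an edge-cutting refinement inspired by
#' OpenOrd: an initial Fruchterman-Reingold layout is computed, the
#' `edge_cut` fraction of the longest edges (in the embedding) is removed,
#' and the layout is refined on the cut graph starting from the initial
#' coordinates. Deterministic given `seed`. The full OpenOrd simulated-
#' annealing schedule is not reproduced; the contract is seeded determinism,
#' the cutting knob, and neighbour proximity.
#'
#' @param cluster_edges (filtered) cluster edge table `m`, `n`, `R`.
#' @param seed integer seed.
#' @param edge_cut fraction in [0, 1] of longest edges ignored during
#'   refinement (default 0.7).
#' @return data.table `cluster`, `X`, `Y`; attribute `algorithm` records the
#'   layout used.
#' @export
map_layout <- function(cluster_edges, seed, edge_cut = 0.7) {
  if (edge_cut < 0 || edge_cut > 1) stop_litmap("`edge_cut` must be in [0, 1]")
  ce <- as.data.table(cluster_edges)
  if (nrow(ce) == 0L) stop_litmap("empty cluster graph")
  ids <- sort(unique(c(ce$m, ce$n)))
  g <- igraph::graph_from_data_frame(
    ce[, .(from = as.character(m), to = as.character(n), weight = R)],
    directed = FALSE, vertices = data.frame(name = as.character(ids)))
  set.seed(seed)
  xy <- igraph::layout_with_fr(g, weights = igraph::E(g)$weight, niter = 500)
  if (edge_cut > 0 && igraph::ecount(g) > 1L) {
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    len <- sqrt(rowSums((xy[ends[, 1], , drop = FALSE] -
                         xy[ends[, 2], , drop = FALSE])^2))
    n_cut <- floor(edge_cut * length(len))
    if (n_cut > 0L && n_cut < length(len)) {
      drop <- order(len, decreasing = TRUE)[seq_len(n_cut)]
      g2 <- igraph::delete_edges(g, drop)
      set.seed(seed + 1L)
      xy <- igraph::layout_with_fr(g2, coords = xy,
                                   weights = igraph::E(g2)$weight, niter = 250)
    }
  }
  out <- data.table(cluster = ids, X = xy[, 1], Y = xy[, 2])
  setattr(out, "algorithm", sprintf("fruchterman-reingold + edge-cut %.2f", edge_cut))
  out[]
}

#' Default high-level field vocabulary
#'
#' The twelve major fields used to colour the cluster map.
#' @return character vector of field names.
#' @export
default_fields <- function() {
  c("Biology", "Brain Science", "Chemistry", "Computer Science",
    "Earth Sciences", "Engineering", "Health Sciences", "Humanities",
    "Infectious Disease", "Medicine", "Physics", "Social Sciences")
}

#' Assign each cluster a dominant high-level field
#'
#' Every document maps to a field through its journal; a cluster takes the
#' field with the plurality of its documents, ties broken alphabetically.
#' Journals absent from the map count as "unassigned".
#'
#' @param documents corpus document table (`doc_id`, `journal`).
#' @param assignment cluster assignment (`doc_id`, cluster column).
#' @param journal_field_map data.frame/data.table `journal`, `field`.
#' @param level cluster column name (default "PM5").
#' @return data.table `cluster`, `field`.
#' @export
assign_field <- function(documents, assignment, journal_field_map,
                         level = "PM5") {
  docs <- as.data.table(documents)[, .(doc_id, journal)]
  jmap <- as.data.table(journal_field_map)[, .(journal, field)]
  d <- jmap[docs, on = "journal"]
  d[is.na(field), field := "unassigned"]
  asn <- as.data.table(assignment)
  d <- d[asn[, .(doc_id, cluster = get(level))], on = "doc_id", nomatch = NULL]
  cnt <- d[, .N, by = .(cluster, field)]
  setorder(cnt, cluster, -N, field)  # plurality; alphabetical tie-break
  out <- cnt[, .(field = field[1L]), by = cluster]
  setorder(out, cluster)
  out[]
}
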