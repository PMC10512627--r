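# igraph from the retained edges of a consensus network (data.frame with
# from/to and optionally retained)
.network_graph <- function(network) {
  ed <- network
  if (!is.null(ed$retained)) ed <- ed[ed$retained, , drop = FALSE]
  igraph::graph_from_data_frame(ed[, c("from", "to")], directed = TRUE)
}

#' K-step subnetwork around a module
#'
#' All nodes within undirected graph distance `K` of any module member,
#' united with the module members themselves (members absent from the
#' network are still part of the background).  This set is the enrichment
#' background for key driver analysis.
#'
#' @param network consensus network data.frame (retained edges are used).
#' @param module_members character vector of module gene IDs (non-empty).
#' @param K neighborhood radius (default 7).
#' @return character vector of node IDs.
#' @export
extract_subnetwork <- function(network, module_members, K = 7) {
  if (length(module_members) == 0L) stop("module member list is empty")
  g <- .network_graph(network)
  inn <- intersect(module_members, igraph::V(g)$name)
  near <- character(0)
  if (length(inn) > 0 && K > 0) {
    d <- igraph::distances(g, v = inn, mode = "all")
    near <- colnames(d)[apply(d, 2L, min) <= K]
  }
  sort(unique(c(module_members, near)))
}

#' Key driver analysis
#'
#' For each node of the K-step subnetwork, the directed downstream
#' neighborhoods `D_k` (nodes reachable in at most k steps, k = 1..K,
#' excluding the node itself) are tested for over-representation of module
#' members against the subnetwork background (hypergeometric upper tail).
#' Only neighborhoods with at least `min_downstream` nodes are tested.  The
#' per-node p-value is Bonferroni-corrected over the k values tested, then
#' BH-adjusted across nodes.  A node is a key driver iff its FDR is at or
#' below `alpha` and its fold enrichment exceeds 1.
#'
#' @param network consensus network data.frame (retained edges are used).
#' @param module_members character vector of module gene IDs.
#' @param K maximum neighborhood depth (default 7).
#' @param min_downstream minimum downstream-neighborhood size tested.
#' @param alpha FDR threshold.
#' @return data.frame node, best_k, downstream_size, overlap,
#'   fold_enrichment, p, fdr, is_key_driver, sorted by fdr then p.
#' @export
find_key_drivers <- function(network, module_members, K = 7,
                             min_downstream = 5, alpha = 0.05) {
  bg <- extract_subnetwork(network, module_members, K)
  g <- .network_graph(network)
  sub <- igraph::induced_subgraph(g, intersect(bg, igraph::V(g)$name))
  nodes <- igraph::V(sub)$name
  members_bg <- intersect(module_members, bg)
  U <- length(bg)
  tgt <- length(members_bg)
  rows <- lapply(nodes, function(h) {
    d <- igraph::distances(sub, v = h, mode = "out")[1, ]
    best <- NULL
    tested <- 0L
    for (k in seq_len(K)) {
      dk <- names(d)[d >= 1 & d <= k]
      if (length(dk) < min_downstream) next
      tested <- tested + 1L
      ov <- length(intersect(dk, members_bg))
      he <- hypergeom_enrichment(ov, length(dk), tgt, U)
      if (is.null(best) || he$p < best$p)
        best <- list(k = k, size = length(dk), overlap = ov,
                     fold = he$fold_enrichment, p = he$p)
    }
    if (is.null(best)) return(NULL)
    data.frame(node = h, best_k = best$k, downstream_size = best$size,
               overlap = best$overlap, fold_enrichment = best$fold,
               p = min(1, best$p * tested), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(node = character(0), best_k = integer(0),
                      downstream_size = integer(0), overlap = integer(0),
                      fold_enrichment = numeric(0), p = numeric(0),
                      fdr = numeric(0), is_key_driver = logical(0)))
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out$is_key_driver <- out$fdr <= alpha & out$fold_enrichment > 1
  out <- out[order(out$fdr, out$p, -out$fold_enrichment, out$node), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-set validation of key drivers
#'
#' A node is a validated key driver iff it is flagged a key driver in both
#' the discovery and the test analysis of the same module.
#'
#' @param discovery,test results of [find_key_drivers()] on the two sets.
#' @return the discovery table with a `validated` column added.
#' @export
validate_key_drivers <- function(discovery, test) {
  test_kd <- test$node[test$is_key_driver]
  out <- discovery
  out$validated <- out$is_key_driver & out$node %in% test_kd
  out
}
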