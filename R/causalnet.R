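#' Discretize expression into three ordered states
#'
#' Per gene, 1-D K-means with K = 3 (10 restarts, seeded per gene) on the
#' expression values; clusters are relabelled by ascending mean so state 0
#' is lowest expression and state 2 highest.  Genes with fewer than three
#' distinct values fall back to a rank-based assignment (distinct values in
#' ascending order map to states 0, 1, ...).
#'
#' @param expr gene x sample matrix (>= 3 samples).
#' @param seed integer seed (per-gene seeds are derived from it, so the
#'   assignment of one gene does not depend on the others).
#' @return integer matrix of states in {0, 1, 2} with the same dimnames.
#' @export
discretize_expression <- function(expr, seed = 1) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  out <- matrix(0L, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  for (i in seq_len(nrow(expr))) {
    x <- expr[i, ]
    ux <- sort(unique(x))
    if (length(ux) < 3L) {
      out[i, ] <- match(x, ux) - 1L
      next
    }
    set.seed(derive_seed(seed, paste0("kmeans", i)))
    km <- suppressWarnings(kmeans(x, centers = 3L, nstart = 10L))
    relab <- order(order(km$centers[, 1]))  # rank of each cluster's mean
    out[i, ] <- relab[km$cluster] - 1L
  }
  out
}

.edges_to_parents <- function(edges, genes) {
  if (is.null(edges) || NROW(edges) == 0L)
    return(setNames(rep(list(integer(0)), length(genes)), genes))
  edges <- as.matrix(edges[, 1:2, drop = FALSE])
  if (!all(edges %in% genes)) stop("edge endpoints must be data genes")
  pl <- setNames(rep(list(integer(0)), length(genes)), genes)
  for (r in seq_len(nrow(edges)))
    pl[[edges[r, 2]]] <- c(pl[[edges[r, 2]]], match(edges[r, 1], genes))
  pl
}

# instruments: integer matrix (rows = subset of genes, dosage/state 0..2
# per sample) -> (geno matrix, per-gene row index or -1)
.instrument_index <- function(instruments, genes, n_samples) {
  if (is.null(instruments) || nrow(instruments) == 0L)
    return(list(geno = matrix(0L, 0, n_samples),
                ginst = rep(-1L, length(genes))))
  instruments <- as.matrix(instruments)
  storage.mode(instruments) <- "integer"
  stopifnot(ncol(instruments) == n_samples, all(instruments %in% 0:2))
  list(geno = instruments,
       ginst = as.integer(match(genes, rownames(instruments),
                                nomatch = 0L) - 1L))
}

#' Score a directed network on discretized data
#'
#' Decomposable score: per node, the multinomial maximum-likelihood
#' log-likelihood given the parent-state configurations minus the BIC
#' penalty `(d/2) log n` with `d = 2 * 3^|parents|`, plus a structure prior
#' of `-kappa` per edge and `+lambda` per edge from an eQTL-anchored source
#' to a non-anchored target.  Genes with a row in `instruments` are scored
#' with their genotype as a fixed additional parent (a genetic instrument):
#' this makes the score differ across Markov-equivalent orientations and is
#' what lets genetic anchors orient edges.
#'
#' @param edges two-column matrix/data.frame of directed edges (from, to) by
#'   gene name; may be empty.
#' @param states [discretize_expression()] output.
#' @param anchored character vector of eQTL-anchored gene IDs.
#' @param kappa sparsity penalty per edge (nats).
#' @param lambda anchor orientation bonus (nats; default `log(2)`).
#' @param instruments optional integer matrix (genes x samples, values
#'   0/1/2): each row is the eQTL genotype of the named gene.
#' @return total score (numeric scalar).
#' @export
score_network <- function(edges, states, anchored = character(0),
                          kappa = 1, lambda = log(2), instruments = NULL) {
  genes <- rownames(states)
  pl <- .edges_to_parents(edges, genes)
  if (NROW(edges) > 0L) {
    g <- igraph::graph_from_edgelist(as.matrix(edges[, 1:2, drop = FALSE]))
    if (!igraph::is_dag(g)) stop("graph is cyclic")
  }
  anch <- genes %in% anchored
  ii <- .instrument_index(instruments, genes, ncol(states))
  tot <- 0
  for (i in seq_along(genes))
    tot <- tot + bn_family_score_cpp(states, i - 1L, pl[[i]] - 1L, anch,
                                     kappa, lambda, ii$geno, ii$ginst[i])
  tot
}

#' Sample network structures by Metropolis-Hastings MCMC
#'
#' Runs `n_networks` independent chains (distinct derived seeds).  Each move
#' adds, deletes, or reverses a uniformly chosen candidate edge, subject to
#' acyclicity and the parent cap, and is accepted with probability
#' `min(1, exp(delta score) * Hastings ratio)`.  Each chain contributes its
#' final graph after `sweeps` proposed moves.
#'
#' @param states [discretize_expression()] output (>= 2 genes).
#' @param anchored character vector of eQTL-anchored gene IDs.
#' @param n_networks number of chains (one sampled network each).
#' @param sweeps proposed moves per chain; default `200 * n_genes`.
#' @param max_parents in-degree cap.
#' @param kappa,lambda structure-prior parameters (see [score_network()]).
#' @param seed master seed; chain seeds are derived deterministically.
#' @param temp0,temp_end annealing temperatures: acceptance decays
#'   geometrically from `temp0` to `temp_end` over the first 60% of the
#'   sweeps, then holds, so each chain settles into a high-scoring
#'   structure (`temp0 = temp_end = 1` gives plain Metropolis-Hastings).
#' @param instruments optional genotype matrix (see [score_network()]).
#' @param init chain initialization: `"chowliu"` (default) starts each
#'   chain from a jittered maximum-mutual-information spanning tree
#'   oriented away from the anchored genes (the classical consistent
#'   estimator for tree-like dependence); `"empty"` starts from no edges.
#' @return list of two-column character edge matrices, one per network.
#' @export
mcmc_networks <- function(states, anchored = character(0),
                          n_networks = 100, sweeps = NULL, max_parents = 3,
                          kappa = 1, lambda = log(2), seed = 1,
                          temp0 = 2, temp_end = 0.2, instruments = NULL,
                          init = c("chowliu", "empty")) {
  init <- match.arg(init)
  genes <- rownames(states)
  if (length(genes) < 2L) stop("need at least 2 genes")
  if (is.null(sweeps)) sweeps <- 200L * length(genes)
  anch <- genes %in% anchored
  ii <- .instrument_index(instruments, genes, ncol(states))
  mi <- if (init == "chowliu") bn_mi_cpp(states) else NULL
  empty_init <- matrix(0L, 0, 2)
  lapply(seq_len(n_networks), function(ch) {
    chain_seed <- derive_seed(seed, paste0("bnchain", ch))
    ini <- empty_init
    if (init == "chowliu")
      ini <- .chowliu_init(mi, anch, chain_seed)
    e <- bn_mcmc_chain_cpp(states, anch, as.integer(sweeps),
                           as.integer(max_parents), kappa, lambda,
                           chain_seed, ii$geno, ii$ginst, ini,
                           temp0, temp_end)
    matrix(genes[e], ncol = 2, dimnames = list(NULL, c("from", "to")))
  })
}

# jittered Chow-Liu warm start: maximum spanning tree on the pairwise MI
# (5% multiplicative noise per chain for diversity), oriented by BFS away
# from the anchored nodes (arbitrary root if none)
.chowliu_init <- function(mi, anch, chain_seed) {
  V <- nrow(mi)
  set.seed(chain_seed)
  w <- mi * matrix(exp(rnorm(V * V, sd = 0.05)), V, V)
  w <- (w + t(w)) / 2
  g <- igraph::graph_from_adjacency_matrix(max(w) + 1e-9 - w,
                                           mode = "upper", weighted = TRUE)
  tre <- igraph::mst(g)
  roots <- which(anch)
  if (length(roots) == 0) roots <- 1L
  ord <- igraph::bfs(tre, root = roots[1], unreachable = TRUE,
                     father = TRUE)
  fa <- as.integer(ord$father)
  out <- cbind(fa, seq_len(V))
  out <- out[!is.na(fa) & fa > 0, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Edge-frequency consensus network
#'
#' Per directed edge, the frequency is the fraction of sampled networks
#' containing it; an edge is retained iff its frequency is at or above
#' `threshold` (closed inequality, so exactly 30% of 1000 networks is
#' retained at the default).
#'
#' @param nets list of edge matrices from [mcmc_networks()].
#' @param threshold consensus frequency threshold.
#' @return data.frame from, to, frequency, retained (sorted by frequency
#'   descending).
#' @export
consensus_network <- function(nets, threshold = 0.30) {
  if (length(nets) == 0L) stop("need at least one sampled network")
  keys <- unlist(lapply(nets, function(e)
    if (NROW(e) > 0) paste(e[, 1], e[, 2], sep = "\r") else character(0)))
  if (length(keys) == 0L)
    return(data.frame(from = character(0), to = character(0),
                      frequency = numeric(0), retained = logical(0)))
  tab <- table(keys)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    from = vapply(parts, `[`, "", 1L),
    to = vapply(parts, `[`, "", 2L),
    frequency = as.numeric(tab) / length(nets),
    stringsAsFactors = FALSE
  )
  out$retained <- out$frequency >= threshold - 1e-12
  out <- out[order(-out$frequency, out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}
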