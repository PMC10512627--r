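# Independent oracles and fixtures shared across test files.

# Exhaustive two-sided Fisher p by direct enumeration of all tables with the
# observed margins, using binomial-coefficient products (not dhyper).
fisher_enum_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  N <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  prob <- function(x) choose(r1, x) * choose(r2, c1 - x) / choose(N, c1)
  p_obs <- prob(a)
  ps <- vapply(lo:hi, prob, numeric(1))
  sum(ps[ps <= p_obs * (1 + 1e-9)])
}

# Brute-force BH step-up: adjusted value of the i-th order statistic is
# min over j >= i of m * p_(j) / j, applied in the original order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# plain Rand index between two labelled partitions
rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  sx <- outer(x, x, "==")
  sy <- outer(y, y, "==")
  ut <- upper.tri(sx)
  mean(sx[ut] == sy[ut])
}

# all 25 DAGs on three labelled nodes, as edge matrices
all_dags3 <- function(nodes = c("A", "B", "C")) {
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  out <- list()
  for (s in 0:(3^3 - 1)) {  # per pair: 0 none, 1 forward, 2 backward
    code <- c(s %% 3, (s %/% 3) %% 3, (s %/% 9) %% 3)
    ed <- NULL
    for (k in 1:3) {
      if (code[k] == 1) ed <- rbind(ed, pairs[k, ])
      if (code[k] == 2) ed <- rbind(ed, rev(pairs[k, ]))
    }
    if (!is.null(ed)) {
      g <- igraph::graph_from_edgelist(matrix(nodes[ed], ncol = 2))
      if (!igraph::is_dag(g)) next
      ed <- matrix(nodes[ed], ncol = 2)
    }
    out[length(out) + 1L] <- list(ed)  # keeps NULL (empty graph) entries
  }
  out
}

# canonical string key for an edge set (order-independent)
edge_key <- function(ed) {
  if (is.null(ed) || nrow(ed) == 0) return("")
  paste(sort(paste(ed[, 1], ed[, 2], sep = ">")), collapse = "|")
}

# small cached cohorts so expensive generation runs once per session
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(key, cfg) {
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- generate_cohort(cfg)
  .cohort_cache[[key]]
}

small_cfg <- function(...) {
  args <- list(n_samples = 120, n_genes_per_tissue = 300, n_modules = 3,
               module_size = 40, n_snps = 60, seed = 7)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(sim_config, args)
}

# correlated block fixture: `blocks` groups of genes sharing a latent factor
block_expr <- function(blocks, size, n, rho, seed) {
  set.seed(seed)
  ex <- NULL
  lab <- character(0)
  for (b in seq_len(blocks)) {
    f <- rnorm(n)
    g <- sqrt(rho) * matrix(f, size, n, byrow = TRUE) +
      sqrt(1 - rho) * matrix(rnorm(size * n), size, n)
    ex <- rbind(ex, g)
    lab <- c(lab, rep(paste0("blk", b), size))
  }
  rownames(ex) <- sprintf("g%03d", seq_len(nrow(ex)))
  colnames(ex) <- sprintf("s%03d", seq_len(n))
  list(expr = ex, labels = setNames(lab, rownames(ex)))
}

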