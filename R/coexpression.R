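#' Soft-threshold power selection by scale-free topology fit
#'
#' Returns the smallest power in `powers` whose connectivity distribution
#' gives a log-log linear fit with R-squared at or above `rsq_cut`; if none
#' qualifies, returns `fallback`.
#'
#' @param cor_abs absolute gene-gene correlation matrix.
#' @param powers candidate integer powers.
#' @param rsq_cut scale-free fit threshold.
#' @param fallback power used when no candidate reaches `rsq_cut`.
#' @return selected power (integer).
#' @export
pick_soft_power <- function(cor_abs, powers = 1:20, rsq_cut = 0.8,
                            fallback = 6) {
  for (beta in powers) {
    a <- cor_abs^beta
    diag(a) <- 0
    k <- rowSums(a)
    if (all(k <= 0)) next
    br <- cut(k, breaks = 10)
    dk <- tapply(k, br, mean)
    pk <- as.numeric(table(br)) / length(k)
    ok <- !is.na(dk) & pk > 0 & dk > 0
    if (sum(ok) < 3) next
    fit <- lm(log10(pk[ok]) ~ log10(dk[ok]))
    if (summary(fit)$r.squared >= rsq_cut && coef(fit)[2] < 0) return(beta)
  }
  fallback
}

#' Topological overlap matrix from expression
#'
#' Unsigned weighted network: adjacency `a_ij = |cor(x_i, x_j)|^beta` with
#' zero diagonal, then
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu`; the diagonal is set to 1.  Constant genes get zero
#' correlation (with a warning).
#'
#' @param expr gene x sample matrix of log-scale expression (>= 3 samples).
#' @param beta soft-threshold power, or `"auto"` to pick the smallest power
#'   in 1..20 with scale-free fit R-squared >= 0.8 (else 6).
#' @return list with `tom` (gene x gene), `adjacency`, and the `beta` used.
#' @export
build_tom <- function(expr, beta = 6) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  cc <- suppressWarnings(cor(t(expr)))
  if (any(is.na(cc))) {
    warning("constant gene(s): correlations set to 0")
    cc[is.na(cc)] <- 0
  }
  ca <- abs(cc)
  if (identical(beta, "auto")) beta <- pick_soft_power(ca)
  a <- ca^beta
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- list(rownames(expr), rownames(expr))
  list(tom = tom, adjacency = a, beta = beta)
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on `1 - TOM` with a static cut at
#' `cut_height`; clusters smaller than `min_module_size` become
#' "unassigned"; modules whose eigengenes correlate above `merge_corr` are
#' iteratively merged (closest pair first).  Deterministic given inputs.
#' Modules are labelled `M1, M2, ...` in decreasing size order.
#'
#' @param tom topological overlap matrix (from [build_tom()]).
#' @param expr expression matrix used for eigengene merging; `NULL` skips
#'   the merge step.
#' @param min_module_size minimum module size.
#' @param merge_corr eigengene correlation above which modules merge.
#' @param cut_height static tree-cut height on the `1 - TOM` dendrogram.
#' @return named character vector gene -> module label ("unassigned"
#'   allowed).
#' @export
detect_modules <- function(tom, expr = NULL, min_module_size = 30,
                           merge_corr = 0.75, cut_height = 0.99) {
  d <- as.dist(1 - tom)
  hc <- hclust(d, method = "average")
  cl <- cutree(hc, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  lab <- ifelse(cl %in% as.integer(keep), as.character(cl), "unassigned")
  names(lab) <- rownames(tom)
  if (!is.null(expr) && length(keep) > 1) {
    repeat {
      mods <- setdiff(unique(lab), "unassigned")
      if (length(mods) < 2) break
      eg <- vapply(mods, function(m)
        compute_eigengene(expr[names(lab)[lab == m], , drop = FALSE]),
        numeric(ncol(expr)))
      cc <- abs(cor(eg))
      diag(cc) <- 0
      if (max(cc) <= merge_corr) break
      ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      lab[lab == mods[ij[2]]] <- mods[ij[1]]
    }
  }
  # relabel by decreasing size, deterministically
  mods <- setdiff(unique(lab), "unassigned")
  sz <- vapply(mods, function(m) sum(lab == m), integer(1))
  ord <- mods[order(-sz, mods)]
  new <- setNames(paste0("M", seq_along(ord)), ord)
  out <- ifelse(lab == "unassigned", "unassigned", new[lab])
  names(out) <- names(lab)
  out
}

#' Module eigengene
#'
#' First right singular vector of the gene-standardized module submatrix:
#' one value per sample, unit norm, sign-oriented so its correlation with
#' the module-average standardized expression is non-negative.
#'
#' @param expr_mod module gene x sample matrix (>= 2 genes).
#' @return numeric per-sample vector of unit norm.
#' @export
compute_eigengene <- function(expr_mod) {
  expr_mod <- as.matrix(expr_mod)
  if (nrow(expr_mod) < 2L) stop("module must have at least 2 genes")
  sds <- apply(expr_mod, 1L, sd)
  if (all(sds == 0)) stop("zero-variance module: eigengene undefined")
  if (any(sds == 0)) {
    warning("dropping zero-variance gene(s) from eigengene computation")
    expr_mod <- expr_mod[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  Z <- (expr_mod - rowMeans(expr_mod)) / sds
  sv <- svd(Z, nu = 0, nv = 1)
  v <- sv$v[, 1]
  avg <- colMeans(Z)
  s <- sum(v * avg)
  if (s < 0) v <- -v
  setNames(v, colnames(expr_mod))
}

#' Module enrichment for a validated gene set
#'
#' Hypergeometric over-representation of `asthma_genes` in each module
#' against the analyzed-gene universe; BH across modules.  A module is
#' flagged an "asthma module" iff fold enrichment exceeds 1 and FDR is at or
#' below `alpha`.  Rows are ordered by fold (descending) then FDR.
#'
#' @param assignment named gene -> module vector from [detect_modules()].
#' @param asthma_genes character vector of validated DE genes (must be a
#'   subset of `universe`).
#' @param universe character vector of all analyzed genes.
#' @param alpha FDR threshold for the flag.
#' @return data.frame module, size, overlap, fold_enrichment, p, fdr,
#'   asthma_module.
#' @export
enrich_modules <- function(assignment, asthma_genes, universe,
                           alpha = 0.05) {
  if (is.list(asthma_genes)) asthma_genes <- asthma_genes$genes
  if (!all(asthma_genes %in% universe))
    stop("asthma_genes must be a subset of the universe")
  assignment <- assignment[names(assignment) %in% universe]
  mods <- setdiff(unique(assignment), "unassigned")
  if (length(mods) == 0L)
    return(data.frame(module = character(0), size = integer(0),
                      overlap = integer(0), fold_enrichment = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      asthma_module = logical(0)))
  U <- length(universe)
  tgt <- length(asthma_genes)
  rows <- lapply(sort(mods), function(m) {
    mg <- names(assignment)[assignment == m]
    ov <- length(intersect(mg, asthma_genes))
    he <- hypergeom_enrichment(ov, length(mg), tgt, U)
    data.frame(module = m, size = length(mg), overlap = ov,
               fold_enrichment = he$fold_enrichment, p = he$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out$asthma_module <- out$fold_enrichment > 1 & out$fdr <= alpha
  out[order(-out$fold_enrichment, out$fdr, out$module), , drop = FALSE]
}

#' Eigengene-phenotype association
#'
#' Logistic regression of the phenotype on each module eigengene plus
#' covariates; Wald p-values, BH across modules.  Under (quasi-)separation
#' or non-convergence the Wald p is replaced by a Rao score test against the
#' covariate-only model and the module is flagged.
#'
#' @param eigengenes samples x modules matrix (columns named by module).
#' @param samples sample table with `asthma` and the covariates.
#' @param covariates covariate column names.
#' @return data.frame module, effect, p, fdr, flag, ordered by `|effect|`
#'   (descending) then FDR.
#' @export
associate_eigengenes <- function(eigengenes, samples,
                                 covariates = c("age", "sex", "race")) {
  eigengenes <- as.matrix(eigengenes)
  stopifnot(nrow(eigengenes) == nrow(samples))
  covariates <- intersect(covariates, names(samples))
  df0 <- samples[, c("asthma", covariates), drop = FALSE]
  rows <- lapply(colnames(eigengenes), function(m) {
    e <- eigengenes[, m]
    if (sd(e) == 0)
      return(data.frame(module = m, effect = NA_real_, p = NA_real_,
                        flag = "constant", stringsAsFactors = FALSE))
    df <- cbind(df0, eigengene = e)
    fml <- as.formula(paste("asthma ~ eigengene",
                            if (length(covariates))
                              paste("+", paste(covariates, collapse = "+"))
                            else ""))
    sep <- FALSE
    fit <- withCallingHandlers(
      glm(fml, data = df, family = binomial()),
      warning = function(w) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    eff <- coef(fit)["eigengene"]
    if (sep || !fit$converged || abs(eff) > 15) {
      fml0 <- as.formula(paste("asthma ~",
                               if (length(covariates))
                                 paste(covariates, collapse = "+") else "1"))
      fit0 <- suppressWarnings(glm(fml0, data = df, family = binomial()))
      p <- tryCatch(
        anova(fit0, fit, test = "Rao")[2, "Pr(>Chi)"],
        error = function(e) NA_real_)
      data.frame(module = m, effect = unname(eff), p = p,
                 flag = "score_test", stringsAsFactors = FALSE)
    } else {
      p <- summary(fit)$coefficients["eigengene", 4]
      data.frame(module = m, effect = unname(eff), p = p, flag = "ok",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  out$fdr[ok] <- bh_adjust(out$p[ok])
  out[order(-abs(out$effect), out$fdr), , drop = FALSE]
}
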