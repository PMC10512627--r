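#' Minor-allele-frequency filter for genotypes
#'
#' @param genotypes list with `info` and snp x sample `dosage` (0/1/2).
#' @param min_maf retain variants with sample MAF at or above this value;
#'   MAF is `min(f, 1 - f)` with `f = mean(dosage) / 2`.
#' @return filtered genotype list (the `info` table gains/updates `maf`).
#' @export
filter_variants <- function(genotypes, min_maf = 0.01) {
  f <- rowMeans(genotypes$dosage) / 2
  maf <- pmin(f, 1 - f)
  keep <- maf >= min_maf - 1e-12
  info <- genotypes$info[keep, , drop = FALSE]
  info$maf <- maf[keep]
  list(info = info, dosage = genotypes$dosage[keep, , drop = FALSE])
}

#' Genotype principal components (genetic ancestry)
#'
#' Top-k principal components of the centered, variance-scaled dosage
#' matrix.  Zero-variance variants are dropped.  Each component's sign is
#' fixed so that its largest-magnitude variant loading is positive.
#'
#' @param genotypes genotype list (see [filter_variants()]).
#' @param k number of components (must be `< n` samples).
#' @return samples x k matrix of PC scores (columns `PC1..PCk`).
#' @export
genotype_pcs <- function(genotypes, k = 3) {
  X <- t(genotypes$dosage)  # samples x snps
  n <- nrow(X)
  if (k >= n) stop("k must be smaller than the number of samples")
  v <- apply(X, 2L, var)
  X <- X[, v > 0, drop = FALSE]
  X <- scale(X)
  sv <- svd(X, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    l <- sv$v[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2L, flip, "*")
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(k)))
  scores
}

#' cis-eQTL mapping by per-pair linear regression
#'
#' Tests every (gene, variant) pair whose variant lies within `window` bases
#' of the gene's transcription start or end site (closed interval,
#' `[tss - window, tes + window]`, same chromosome).  Ordinary least squares
#' of expression on dosage plus covariates; t-test on the dosage slope;
#' BH adjustment across all tested pairs.
#'
#' @param expr gene x sample matrix of log-scale expression (e.g.
#'   `log(cpm + 1)`), sample columns aligned with the genotype samples.
#' @param genotypes genotype list (after [filter_variants()]).
#' @param annotation data.frame with gene_id, chrom, tss, tes.
#' @param covariates optional per-sample covariate matrix/data.frame (e.g.
#'   age, sex dummies, ancestry PCs from [genotype_pcs()]).
#' @param window cis window in bases (default 1 Mb).
#' @param alpha FDR threshold for the `significant` flag.
#' @return data.frame with gene, snp, beta, t, p, fdr, significant.
#' @export
map_cis_eqtl <- function(expr, genotypes, annotation, covariates = NULL,
                         window = 1e6, alpha = 0.05) {
  dos <- genotypes$dosage
  stopifnot(ncol(expr) == ncol(dos))
  if (!is.null(colnames(expr)) && !is.null(colnames(dos)) &&
      !identical(colnames(expr), colnames(dos)))
    dos <- dos[, colnames(expr), drop = FALSE]
  n <- ncol(expr)
  C <- cbind(Intercept = rep(1, n))
  if (!is.null(covariates)) {
    cv <- as.matrix(data.frame(covariates, check.names = FALSE))
    storage.mode(cv) <- "double"
    C <- cbind(C, cv)
  }
  qC <- qr(C)
  if (qC$rank < ncol(C)) stop("covariate matrix is rank deficient")
  # Frisch-Waugh: residualize expression and dosage on covariates once,
  # then per-pair slopes/t-stats are exact full-model statistics.
  Er <- t(qr.resid(qC, t(expr)))
  Gr <- t(qr.resid(qC, t(dos)))
  df <- n - ncol(C) - 1L
  if (df < 1L) stop("not enough samples for the covariate-adjusted model")
  missing_ann <- setdiff(rownames(expr), annotation$gene_id)
  if (length(missing_ann) > 0)
    warning("genes absent from annotation were skipped: ",
            paste(head(missing_ann, 5), collapse = ", "),
            if (length(missing_ann) > 5) ", ...")
  ann <- annotation[match(rownames(expr), annotation$gene_id), ]
  res <- vector("list", nrow(expr))
  gss <- rowSums(Gr^2)
  for (i in seq_len(nrow(expr))) {
    if (is.na(ann$gene_id[i])) next
    cis <- which(genotypes$info$chrom == ann$chrom[i] &
                   genotypes$info$pos >= ann$tss[i] - window &
                   genotypes$info$pos <= ann$tes[i] + window)
    if (length(cis) == 0L) next
    y <- Er[i, ]
    sxy <- Gr[cis, , drop = FALSE] %*% y
    sxx <- gss[cis]
    ok <- sxx > 0
    beta <- as.numeric(sxy) / ifelse(ok, sxx, 1)
    rss <- sum(y^2) - beta^2 * sxx
    se <- sqrt(pmax(rss, 0) / df / ifelse(ok, sxx, 1))
    # perfect fits (rss = 0) get an infinite statistic, p = 0
    tstat <- ifelse(ok, ifelse(se > 0, beta / se, sign(beta) * Inf), 0)
    res[[i]] <- data.frame(
      gene = ann$gene_id[i],
      snp = genotypes$info$snp_id[cis],
      beta = ifelse(ok, beta, NA_real_),
      t = tstat,
      p = 2 * pt(-abs(tstat), df),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(gene = character(0), snp = character(0),
                      beta = numeric(0), t = numeric(0), p = numeric(0),
                      fdr = numeric(0), significant = logical(0)))
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr <= alpha
  rownames(out) <- NULL
  out
}
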