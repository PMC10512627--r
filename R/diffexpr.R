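# Build the DE design matrix: condition + standardized age + one-hot factors
# with the largest category as reference.  Returns the matrix and the name of
# the condition column.
.dge_design <- function(samples, condition, covariates) {
  df <- data.frame(row.names = samples$sample_id)
  df[[condition]] <- as.numeric(samples[[condition]])
  for (cv in covariates) {
    v <- samples[[cv]]
    if (is.null(v)) stop("covariate not found in sample table: ", cv)
    if (is.numeric(v)) {
      df[[cv]] <- if (sd(v) > 0) (v - mean(v)) / sd(v) else v * 0
    } else {
      tab <- sort(table(v), decreasing = TRUE)
      df[[cv]] <- factor(v, levels = names(tab))  # largest level = reference
    }
  }
  X <- model.matrix(as.formula(paste("~", paste(names(df), collapse = "+"))),
                    df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  list(X = X, coef = condition)
}

#' Per-gene negative-binomial differential expression
#'
#' For each gene, fits a negative-binomial log-link GLM of counts on the
#' condition and covariates with a log-library-size offset, and tests the
#' condition coefficient with a Wald test.  Dispersion is estimated per gene
#' by maximum likelihood (floored at 1e-8) unless a fixed value is supplied,
#' in which case the GLM is fitted at that dispersion (a value near zero
#' reproduces a Poisson fit).  P-values are BH-adjusted across genes.
#'
#' @param counts filtered gene x sample integer matrix.
#' @param samples sample table aligned with `colnames(counts)`.
#' @param covariates covariate column names (numeric columns standardized,
#'   factors one-hot with largest level as reference).
#' @param condition name of the 0/1 condition column (default `"asthma"`).
#' @param libsize per-sample library sizes for the offset; defaults to the
#'   column sums of `counts` (pass pre-filter sizes if available).
#' @param dispersion optional fixed dispersion (variance = mu + disp * mu^2).
#' @return data.frame with gene, log2_fold_change, wald_stat, p, fdr,
#'   dispersion and a `converged` flag (non-converged genes get p = 1).
#' @export
fit_nb_glm <- function(counts, samples, covariates = character(0),
                       condition = "asthma", libsize = colSums(counts),
                       dispersion = NULL) {
  stopifnot(ncol(counts) == nrow(samples))
  if (!is.null(samples$sample_id) &&
      !identical(as.character(samples$sample_id), colnames(counts)))
    samples <- samples[match(colnames(counts), samples$sample_id), ]
  des <- .dge_design(samples, condition, covariates)
  X <- des$X
  off <- log(libsize)
  ci <- match(condition, colnames(X))
  ng <- nrow(counts)
  lfc <- stat <- pval <- disp <- rep(NA_real_, ng)
  conv <- rep(TRUE, ng)
  for (i in seq_len(ng)) {
    y <- counts[i, ]
    fit <- NULL
    if (is.null(dispersion)) {
      fit <- tryCatch(
        suppressWarnings(MASS::glm.nb(y ~ X - 1 + offset(off))),
        error = function(e) NULL)
      if (!is.null(fit)) disp[i] <- max(1 / fit$theta, 1e-8)
    }
    if (is.null(fit)) {
      th <- if (is.null(dispersion)) 1e8 else 1 / max(dispersion, 1e-8)
      fit <- tryCatch(
        suppressWarnings(glm(y ~ X - 1 + offset(off),
                             family = MASS::negative.binomial(theta = th))),
        error = function(e) NULL)
      disp[i] <- max(1 / th, 1e-8)
    }
    if (is.null(fit) || !fit$converged) {
      conv[i] <- FALSE
      pval[i] <- 1
      next
    }
    sm <- suppressWarnings(summary(fit)$coefficients)
    b <- coef(fit)[ci]
    se <- sm[ci, 2L]
    lfc[i] <- b / log(2)
    stat[i] <- b / se
    pval[i] <- 2 * pnorm(-abs(stat[i]))
  }
  pval[!is.finite(pval)] <- 1
  data.frame(
    gene = rownames(counts),
    log2_fold_change = lfc,
    wald_stat = stat,
    p = pval,
    fdr = bh_adjust(pval),
    dispersion = disp,
    converged = conv,
    stringsAsFactors = FALSE
  )
}

#' Cross-set directional validation of DE results
#'
#' A gene is validated iff its discovery FDR is at or below `alpha` and its
#' test-set fold change is non-zero with the same sign as in discovery.
#' With `strict = TRUE` the test-set FDR must also be at or below `alpha`.
#'
#' @param discovery,test results of [fit_nb_glm()] on the two sample sets
#'   (same gene universe).
#' @param alpha discovery FDR threshold.
#' @param strict also require test-set significance.
#' @return list with `genes` (validated IDs), `direction` (named sign
#'   vector) and the merged `table`.
#' @export
validate_across_sets <- function(discovery, test, alpha = 0.05,
                                 strict = FALSE) {
  if (!setequal(discovery$gene, test$gene))
    stop("discovery and test results cover different gene universes")
  test <- test[match(discovery$gene, test$gene), ]
  ok <- discovery$fdr <= alpha &
    sign(discovery$log2_fold_change) == sign(test$log2_fold_change) &
    test$log2_fold_change != 0 &
    discovery$converged & test$converged
  if (strict) ok <- ok & test$fdr <= alpha
  ok[is.na(ok)] <- FALSE
  tab <- data.frame(
    gene = discovery$gene,
    discovery_lfc = discovery$log2_fold_change,
    discovery_fdr = discovery$fdr,
    test_lfc = test$log2_fold_change,
    test_fdr = test$fdr,
    validated = ok,
    stringsAsFactors = FALSE
  )
  list(
    genes = discovery$gene[ok],
    direction = setNames(sign(discovery$log2_fold_change)[ok],
                         discovery$gene[ok]),
    table = tab
  )
}
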