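# covariates -> numeric matrix (factors one-hot, no intercept column)
.cov_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  df <- as.data.frame(covariates)
  stopifnot(nrow(df) == n)
  mm <- model.matrix(~ ., df)
  mm[, -1, drop = FALSE]
}

# OLS with HC0 sandwich SEs, tolerating rank deficiency: aliased
# coefficients are set to 0 with zero SE (the pivoted full-rank fit is
# unchanged, e.g. a noise-free chain where mediator and exposure coincide).
.ols_robust <- function(X, y) {
  qx <- qr(X)
  r <- qx$rank
  cols <- qx$pivot[seq_len(r)]
  Xr <- X[, cols, drop = FALSE]
  f <- lm.fit(Xr, y)
  e <- f$residuals
  B <- chol2inv(chol(crossprod(Xr)))
  V <- B %*% crossprod(Xr * e) %*% B
  coefs <- ses <- numeric(ncol(X))
  coefs[cols] <- f$coefficients
  ses[cols] <- sqrt(pmax(diag(V), 0))
  list(coef = coefs, se = ses, residuals = e)
}

#' Single-pair causal mediation model
#'
#' Three least-squares regressions on the same sample: `Y ~ X (+cov)` for
#' the total effect c, `M ~ X (+cov)` for the X-to-mediator path a, and
#' `Y ~ M + X (+cov)` for the mediator path b and the direct effect c'.
#' A binary outcome is treated numerically (linear probability model).
#' Standard errors are heteroskedasticity-robust (HC0 sandwich); the Sobel
#' standard error of the indirect effect `a*b` is
#' `sqrt(b^2 se_a^2 + a^2 se_b^2)` with a two-sided normal p-value.
#' For these nested linear fits `c = c' + a*b` holds exactly.
#'
#' @param x exposure values (per sample).
#' @param m mediator values.
#' @param y outcome (0/1 or continuous).
#' @param covariates optional per-sample covariates (data.frame or matrix).
#' @return list of class `mediation_fit` with a, b, c, c_prime, indirect,
#'   se_a, se_b, sobel_se, sobel_p.
#' @export
fit_mediation <- function(x, m, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(m) == n, length(y) == n)
  if (n < 30L) stop("need at least 30 samples")
  if (sd(x) == 0 || sd(m) == 0) stop("constant exposure or mediator")
  C <- .cov_matrix(covariates, n)
  y <- as.numeric(y)
  X1 <- cbind(1, x, C)                # y ~ x
  X3 <- cbind(1, m, x, C)             # y ~ m + x
  f1 <- .ols_robust(X1, y)
  f2 <- .ols_robust(X1, m)            # same design: m ~ x
  f3 <- .ols_robust(X3, y)
  a <- f2$coef[2]
  b <- f3$coef[2]
  cc <- f1$coef[2]
  cp <- f3$coef[3]
  se_a <- f2$se[2]
  se_b <- f3$se[2]
  ind <- a * b
  sobel_se <- sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  sobel_p <- if (sobel_se > 0) 2 * pnorm(-abs(ind) / sobel_se) else
    as.numeric(ind == 0)
  structure(list(a = a, b = b, c = cc, c_prime = cp, indirect = ind,
                 se_a = se_a, se_b = se_b, sobel_se = sobel_se,
                 sobel_p = sobel_p, n = n),
            class = "mediation_fit")
}

#' Percentile bootstrap CI for the indirect effect
#'
#' Case-resamples the data `B` times, refits the a and b paths, and returns
#' the 2.5/97.5 percentile interval of `a*b`.  Degenerate resamples
#' (constant exposure or mediator) are redrawn, up to `10 * B` attempts.
#'
#' @inheritParams fit_mediation
#' @param B number of bootstrap resamples.
#' @param seed integer seed.
#' @return numeric length-2 vector (lower, upper).
#' @export
bootstrap_indirect <- function(x, m, y, covariates = NULL, B = 2000,
                               seed = 1) {
  n <- length(x)
  C <- .cov_matrix(covariates, n)
  y <- as.numeric(y)
  set.seed(seed)
  ind <- numeric(B)
  attempts <- 0L
  b_done <- 0L
  while (b_done < B) {
    attempts <- attempts + 1L
    if (attempts > 10L * B)
      stop("too many degenerate bootstrap resamples")
    idx <- sample.int(n, n, replace = TRUE)
    xs <- x[idx]; ms <- m[idx]
    if (sd(xs) == 0 || sd(ms) == 0) next
    Cs <- if (is.null(C)) NULL else C[idx, , drop = FALSE]
    cf_a <- lm.fit(cbind(1, xs, Cs), ms)$coefficients
    cf_b <- lm.fit(cbind(1, ms, xs, Cs), y[idx])$coefficients
    cf_a[is.na(cf_a)] <- 0; cf_b[is.na(cf_b)] <- 0
    a <- unname(cf_a[2])
    b <- unname(cf_b[2])
    b_done <- b_done + 1L
    ind[b_done] <- a * b
  }
  unname(quantile(ind, c(0.025, 0.975)))
}

#' Permutation test of the indirect effect
#'
#' Permutes the mediator across samples (breaking both the a and b paths
#' while preserving the X-Y association) and recomputes the indirect effect
#' each iteration.  Returns
#' `(1 + #\{|indirect_perm| >= |indirect_obs|\}) / (1 + iterations)`;
#' zero iterations give 1.
#'
#' @inheritParams fit_mediation
#' @param iterations number of permutations.
#' @param seed integer seed.
#' @return permutation p-value.
#' @export
permutation_test <- function(x, m, y, covariates = NULL,
                             iterations = 10000, seed = 1) {
  if (iterations <= 0) return(1)
  n <- length(x)
  C <- cbind(rep(1, n), .cov_matrix(covariates, n))
  y <- as.numeric(y)
  qC <- qr(C)
  xr <- qr.resid(qC, x)
  C2 <- cbind(C, x)
  q2 <- qr(C2)
  yr2 <- qr.resid(q2, y)
  sxx <- sum(xr^2)
  stat <- function(mv) {
    mr <- qr.resid(qC, mv)
    a <- sum(mr * xr) / sxx
    mr2 <- qr.resid(q2, mv)
    b <- sum(mr2 * yr2) / sum(mr2^2)
    a * b
  }
  obs <- abs(stat(m))
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(iterations)) {
    if (abs(stat(m[sample.int(n)])) >= obs - 1e-15) hits <- hits + 1L
  }
  (1 + hits) / (1 + iterations)
}

#' Mediation screen between two tissues' key drivers
#'
#' Tests every (exposure gene, mediator gene) pair in both directions:
#' exposure from tissue 1 mediated by tissue 2, and the converse.  The
#' Sobel p-values are BH-adjusted across pairs within each direction;
#' significance is FDR at or below `alpha`.  Optionally adds a
#' mediator-permutation p-value per pair.
#'
#' @param drivers named list of two character vectors of key driver genes,
#'   one per tissue (names = tissue labels).
#' @param expr named list of two gene x sample expression matrices (log
#'   scale) with matching tissue names and aligned sample columns.
#' @param samples sample table with `asthma` and any covariates.
#' @param covariates covariate column names (default none).
#' @param alpha FDR threshold.
#' @param iterations permutation iterations per pair (0 = skip).
#' @param seed integer seed for permutations.
#' @return data.frame with direction (`"<x_tissue>-><m_tissue>"`), x_gene,
#'   m_gene, a, b, c, c_prime, indirect, sobel_p, perm_p, fdr, significant.
#' @export
mediation_screen <- function(drivers, expr, samples, covariates = NULL,
                             alpha = 0.05, iterations = 0, seed = 1) {
  stopifnot(length(drivers) == 2L, length(expr) == 2L,
            setequal(names(drivers), names(expr)))
  tiss <- names(drivers)
  if (any(lengths(drivers) == 0L)) {
    warning("empty key driver list: no mediation pairs to test")
    return(data.frame(direction = character(0), x_gene = character(0),
                      m_gene = character(0), a = numeric(0), b = numeric(0),
                      c = numeric(0), c_prime = numeric(0),
                      indirect = numeric(0), sobel_p = numeric(0),
                      perm_p = numeric(0), fdr = numeric(0),
                      significant = logical(0)))
  }
  y <- as.numeric(samples$asthma)
  cov_df <- if (length(covariates))
    samples[, covariates, drop = FALSE] else NULL
  res <- list()
  for (dir in 1:2) {
    xt <- tiss[dir]; mt <- tiss[3 - dir]
    rows <- list()
    for (xg in drivers[[xt]]) for (mg in drivers[[mt]]) {
      fit <- fit_mediation(expr[[xt]][xg, ], expr[[mt]][mg, ], y, cov_df)
      pp <- if (iterations > 0)
        permutation_test(expr[[xt]][xg, ], expr[[mt]][mg, ], y, cov_df,
                         iterations = iterations,
                         seed = derive_seed(seed, paste(xg, mg))) else
        NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        direction = paste0(xt, "->", mt), x_gene = xg, m_gene = mg,
        a = fit$a, b = fit$b, c = fit$c, c_prime = fit$c_prime,
        indirect = fit$indirect, sobel_p = fit$sobel_p, perm_p = pp,
        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    tab$fdr <- bh_adjust(tab$sobel_p)
    tab$significant <- tab$fdr <= alpha
    res[[dir]] <- tab
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
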