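#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact conditional test on a 2x2 contingency table (rows = group, columns =
#' trait).  The two-sided p-value uses the probability-ordering convention:
#' the sum of hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table.
#'
#' @param tab a 2x2 non-negative count matrix, or a length-4 numeric vector
#'   `c(a, b, c, d)` read row-wise.
#' @return the two-sided p-value.  If a row or column margin is zero the test
#'   is undefined and 1 is returned with a warning.
#' @examples
#' fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE))  # 1/3
#' @export
fisher_exact_2x2 <- function(tab) {
  if (is.matrix(tab)) {
    stopifnot(all(dim(tab) == c(2L, 2L)))
    v <- c(t(tab))
  } else {
    stopifnot(length(tab) == 4L)
    v <- as.numeric(tab)
  }
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop("table entries must be finite non-negative integers")
  if (sum(v) == 0) stop("table total must be positive")
  a <- v[1]; b <- v[2]; cc <- v[3]; d <- v[4]
  m <- a + b; n <- cc + d; k <- a + cc
  if (m == 0 || n == 0 || k == 0 || (b + d) == 0) {
    warning("empty margin: Fisher test undefined, returning p = 1")
    return(1)
  }
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  pr <- dhyper(x, m, n, k)
  obs <- dhyper(a, m, n, k)
  # relative tolerance guards against FP noise in dhyper when deciding
  # "at most as probable as observed"
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

#' Hypergeometric over-representation (enrichment) test
#'
#' Fold enrichment and one-sided upper-tail hypergeometric p-value for the
#' overlap between a query set and a target set drawn from a finite universe.
#' The fold ("enrichment score") is observed overlap over the overlap
#' expected under random sampling.
#'
#' @param overlap observed overlap count.
#' @param set_size size of the query set.
#' @param target_size size of the target set.
#' @param universe size of the universe both sets are drawn from.
#' @return list with `fold_enrichment` and `p` (`P[X >= overlap]`).
#' @examples
#' hypergeom_enrichment(5, 5, 5, 100)   # fold 20, p = 1/choose(100, 5)
#' @export
hypergeom_enrichment <- function(overlap, set_size, target_size, universe) {
  v <- c(overlap, set_size, target_size, universe)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
    stop("all arguments must be finite non-negative integers")
  if (set_size == 0 || target_size > universe || set_size > universe ||
      overlap > min(set_size, target_size))
    stop("inconsistent counts: need overlap <= min(set, target) <= universe")
  fold <- (overlap / set_size) / (target_size / universe)
  p <- phyper(overlap - 1, target_size, universe - target_size, set_size,
              lower.tail = FALSE)
  list(fold_enrichment = fold, p = min(1, p))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values in the input order (monotone in rank, capped at 1).
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}
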