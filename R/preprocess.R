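#' Counts-per-million normalization
#'
#' Scales each sample (column) of a gene x sample count matrix to counts per
#' million.  Library sizes are the column sums of the full, pre-filter
#' matrix, so every column of the returned matrix sums to 1e6.
#'
#' @param counts non-negative integer matrix, genes in rows, samples in
#'   columns; row and column names required.
#' @return numeric matrix of CPM values with the same dimnames.
#' @export
cpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  libsize <- colSums(counts)
  if (any(libsize == 0)) {
    bad <- colnames(counts)[libsize == 0]
    if (is.null(bad)) bad <- which(libsize == 0)
    stop("zero library size for sample(s): ", paste(bad, collapse = ", "))
  }
  sweep(counts, 2L, libsize, "/") * 1e6
}

#' Median-of-ratios size factors
#'
#' DESeq-style normalization factors: per sample, the median ratio of its
#' counts to the per-gene geometric mean, over genes expressed in every
#' sample.  Robust to library composition (a handful of strongly shifted
#' genes cannot drag every other gene's apparent expression).
#'
#' @param counts gene x sample count matrix.
#' @return named per-sample factor vector scaled to geometric mean 1.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts == 0) == 0
  if (sum(pos) < 10)
    stop("too few genes expressed in all samples for size factors")
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  sf <- apply(lg, 2L, function(col) exp(median(col - ref)))
  sf / exp(mean(log(sf)))
}

#' Low-abundance gene filter
#'
#' A gene is kept iff the fraction of samples in which its CPM is at or below
#' `threshold` does not exceed `max_low_fraction` (genes low in *more* than
#' that fraction of samples are removed; the boundary fraction itself is
#' kept).
#'
#' @param cpm CPM matrix from [cpm_normalize()].
#' @param threshold CPM value at or below which a sample counts as "low".
#' @param max_low_fraction maximum tolerated fraction of low samples.
#' @return character vector of retained gene IDs.
#' @export
filter_low_abundance <- function(cpm, threshold = 5, max_low_fraction = 0.10) {
  cpm <- as.matrix(cpm)
  low_frac <- rowMeans(cpm <= threshold)
  keep <- low_frac <= max_low_fraction + 1e-12
  rownames(cpm)[keep]
}

#' Random 2:1 discovery/test split
#'
#' Partitions the sample IDs uniformly at random into a discovery set of size
#' `ceiling(2n/3)` and a test set of the remaining samples.  With
#' `stratify = TRUE` the split is performed within each phenotype group.
#'
#' @param samples data.frame with a `sample_id` column (and `asthma` when
#'   stratifying).
#' @param seed integer seed; the same seed always yields the same split.
#' @param stratify split within phenotype strata (default unstratified).
#' @return list with character vectors `discovery` and `test`.
#' @export
split_discovery_test <- function(samples, seed, stratify = FALSE) {
  ids <- as.character(samples$sample_id)
  n <- length(ids)
  if (n < 3L) stop("need at least 3 samples to split 2:1")
  if (anyDuplicated(ids)) stop("duplicate sample IDs")
  set.seed(seed)
  if (stratify) {
    disc <- character(0)
    for (g in unique(samples$asthma)) {
      sub <- ids[samples$asthma == g]
      disc <- c(disc, sample(sub, ceiling(2 * length(sub) / 3)))
    }
    # rebalance to the global ceiling rule if stratum ceilings overshoot
    target <- ceiling(2 * n / 3)
    if (length(disc) > target) disc <- sample(disc, target)
  } else {
    disc <- sample(ids, ceiling(2 * n / 3))
  }
  list(discovery = sort(disc), test = sort(setdiff(ids, disc)))
}

#' Cohort characteristics summary
#'
#' Tabulates binary traits by phenotype group: overall and per-group counts,
#' percentages (rounded half-up to one decimal), and a two-sided Fisher exact
#' p-value per trait.
#'
#' @param samples data.frame with `asthma` (0/1) and the traits to summarize.
#' @param traits character vector of binary (0/1 coercible) column names;
#'   default: all 0/1 columns other than `asthma`.
#' @return data.frame with one row per trait.
#' @export
cohort_summary <- function(samples, traits = NULL) {
  if (nrow(samples) == 0L) stop("empty sample table")
  if (!"asthma" %in% names(samples)) stop("sample table must have 'asthma'")
  grp <- as.integer(samples$asthma)
  if (!all(grp %in% c(0L, 1L))) stop("asthma must be coded 0/1")
  if (is.null(traits)) {
    is_bin <- vapply(samples, function(col) {
      v <- suppressWarnings(as.numeric(col))
      !any(is.na(v)) && all(v %in% c(0, 1))
    }, logical(1))
    traits <- setdiff(names(samples)[is_bin], c("asthma", "sample_id"))
  }
  n <- length(grp); n1 <- sum(grp == 1L); n0 <- sum(grp == 0L)
  pheno_row <- data.frame(
    trait = "asthma", overall_count = n1,
    overall_pct = round_half_up(100 * n1 / n, 1),
    asthma_count = n1, asthma_pct = 100,
    control_count = 0L, control_pct = 0,
    p = NA_real_, stringsAsFactors = FALSE
  )
  rows <- lapply(traits, function(tr) {
    v <- as.integer(as.numeric(samples[[tr]]))
    a <- sum(v == 1L & grp == 1L); b <- sum(v == 1L & grp == 0L)
    p <- fisher_exact_2x2(c(a, b, n1 - a, n0 - b))
    data.frame(
      trait = tr,
      overall_count = a + b,
      overall_pct = round_half_up(100 * (a + b) / n, 1),
      asthma_count = a,
      asthma_pct = round_half_up(100 * a / n1, 1),
      control_count = b,
      control_pct = round_half_up(100 * b / n0, 1),
      p = p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, c(list(pheno_row), rows))
  attr(out, "n_total") <- n
  attr(out, "n_asthma") <- n1
  attr(out, "n_control") <- n0
  out
}
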