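#' Write a gene x sample count matrix as TSV
#'
#' Gene IDs go in the first column (`gene_id`), one column per sample.
#'
#' @param counts integer matrix with row and column names.
#' @param path output file.
#' @export
write_count_matrix <- function(counts, path) {
  dt <- data.table::data.table(gene_id = rownames(counts))
  for (s in colnames(counts)) dt[[s]] <- counts[, s]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a gene x sample count matrix from TSV
#'
#' @param path TSV with gene IDs in the first column.
#' @return integer matrix, genes in rows.
#' @export
read_count_matrix <- function(path) {
  dt <- data.table::fread(path)
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- dt[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write genotype dosages as a minimal VCF v4.2
#'
#' Biallelic sites with a GT-only FORMAT; dosages 0/1/2 become genotypes
#' `0/0`, `0/1`, `1/1`.
#'
#' @param genotypes list with `info` (snp_id, chrom, pos) and `dosage`
#'   (snp x sample integer matrix).
#' @param path output file.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  info <- genotypes$info
  dos <- genotypes$dosage
  stopifnot(all(dos %in% 0:2))
  gt <- matrix(c("0/0", "0/1", "1/1")[dos + 1L], nrow = nrow(dos))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=netmed",
    paste0("##contig=<ID=", sort(unique(info$chrom)), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(dos)), collapse = "\t")
  ), con)
  body <- paste(info$chrom, info$pos, info$snp_id, "A", "G", ".", "PASS",
                ".", "GT", apply(gt, 1L, paste, collapse = "\t"),
                sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read GT genotypes from a VCF into dosages
#'
#' Parses the minimal dialect written by [write_genotypes_vcf()] (plain-text
#' VCF, biallelic sites, GT as the first FORMAT field; `/` or `|` phasing).
#'
#' @param path VCF file.
#' @return list with `info` (snp_id, chrom, pos, maf) and `dosage`
#'   (snp x sample matrix).
#' @export
read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("not a VCF: missing #CHROM header line")
  cols <- strsplit(sub("^#", "", lines[hdr]), "\t")[[1]]
  if (length(cols) < 10L || cols[9] != "FORMAT")
    stop("VCF must carry a FORMAT column with sample genotypes")
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  n_snp <- length(fields)
  info <- data.frame(
    snp_id = vapply(fields, `[`, "", 3L),
    chrom = vapply(fields, `[`, "", 1L),
    pos = as.integer(vapply(fields, `[`, "", 2L)),
    stringsAsFactors = FALSE
  )
  gt_index <- vapply(fields, function(f) {
    which(strsplit(f[9], ":", fixed = TRUE)[[1]] == "GT")[1]
  }, integer(1))
  dosage <- matrix(NA_integer_, n_snp, length(samples),
                   dimnames = list(info$snp_id, samples))
  for (i in seq_len(n_snp)) {
    g <- vapply(strsplit(fields[[i]][-(1:9)], ":", fixed = TRUE),
                `[`, "", gt_index[i])
    alleles <- strsplit(g, "[/|]")
    dosage[i, ] <- vapply(alleles, function(a)
      sum(as.integer(a) > 0L), integer(1))
  }
  f <- rowMeans(dosage) / 2
  info$maf <- pmin(f, 1 - f)
  list(info = info, dosage = dosage)
}
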