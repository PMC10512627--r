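test_that("sim_config validates its invariants by name", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_samples = 10), "n_samples")
  expect_error(sim_config(case_fraction = 1), "case_fraction")
  expect_error(sim_config(module_size = 3, n_key_drivers_per_module = 2),
               "module_size")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(n_genes_per_tissue = 100, n_modules = 5,
                          module_size = 30), "exceeds")
  expect_error(sim_config(n_snps = 5), "n_snps")
})

test_that("generation is deterministic in the seed", {
  c1 <- generate_cohort(small_cfg(seed = 1))
  c2 <- generate_cohort(small_cfg(seed = 1))
  c3 <- generate_cohort(small_cfg(seed = 2))
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$genotypes$dosage, c2$genotypes$dosage)
  expect_false(identical(c1$counts$PBMC, c3$counts$PBMC))
  expect_identical(dim(c1$counts$PBMC), dim(c3$counts$PBMC))
  expect_identical(dim(c1$counts$nasal), dim(c3$counts$nasal))
})

test_that("cohort structure and truth respect the planted design", {
  coh <- cached_cohort("base", small_cfg())
  cfg <- small_cfg()
  expect_equal(dim(coh$counts$PBMC),
               c(cfg$n_genes_per_tissue, cfg$n_samples))
  expect_true(all(coh$counts$nasal >= 0))
  tr <- coh$truth
  # every key driver is a member of its module
  for (ts in c("PBMC", "nasal")) {
    memb <- unlist(tr$module_membership[[ts]])
    for (m in names(tr$key_drivers[[ts]]))
      expect_true(all(memb[tr$key_drivers[[ts]][[m]]] == m))
    # causal edges form a DAG
    g <- igraph::graph_from_edgelist(
      as.matrix(tr$causal_edges[[ts]][, c("from", "to")]))
    expect_true(igraph::is_dag(g))
  }
  # every eQTL gene exists in the annotation; snps are cis to their gene
  expect_true(all(tr$eqtl_pairs$gene %in% coh$annotation$gene_id))
  ai <- match(tr$eqtl_pairs$gene, coh$annotation$gene_id)
  gi <- match(tr$eqtl_pairs$snp, coh$genotypes$info$snp_id)
  expect_true(all(abs(coh$genotypes$info$pos[gi] -
                        coh$annotation$tss[ai]) <= 1e6))
  # mediation chain genes are key drivers of module M1
  expect_identical(tr$mediation$x_gene, tr$key_drivers$PBMC$M1[1])
  expect_identical(tr$mediation$m_gene, tr$key_drivers$nasal$M1[1])
})

test_that("realized case fraction tracks the target", {
  coh <- cached_cohort("n300", small_cfg(n_samples = 300, case_fraction = 0.4))
  expect_lt(abs(mean(coh$samples$asthma) - 0.4), 0.02)
})

test_that("planted eQTL genes show the configured genotype effect sign", {
  coh <- cached_cohort("n300", small_cfg(n_samples = 300, case_fraction = 0.4))
  expr <- log(cpm_normalize(coh$counts$PBMC) + 1)
  tr <- coh$truth
  pb <- tr$eqtl_pairs[startsWith(tr$eqtl_pairs$gene, "PBMC"), ]
  for (i in seq_len(nrow(pb))) {
    r <- cor(coh$genotypes$dosage[pb$snp[i], ], expr[pb$gene[i], ])
    expect_gt(r * sign(pb$effect[i]), 0)
  }
})

test_that("method-of-moments dispersion recovers the planted value", {
  # constant-latent (background) genes at n = 2000; library-size
  # normalization removes the size factors
  cfg <- small_cfg(n_samples = 2000, n_genes_per_tissue = 150,
                   n_modules = 2, module_size = 20, seed = 3)
  coh <- generate_cohort(cfg)
  cts <- coh$counts$PBMC
  bg <- names(which(unlist(coh$truth$module_membership$PBMC) == "unassigned"))
  bg <- setdiff(bg, unlist(coh$truth$peripheral))  # peripherals vary
  # median-of-ratios size factors over the constant genes (robust to the
  # heavy-tailed module genes that dominate raw library sizes)
  logg <- rowMeans(log(cts[bg, ] + 0.5))
  nf <- apply(cts[bg, ], 2L, function(col)
    median(exp(log(col + 0.5) - logg)))
  nf <- nf / mean(nf)
  est <- vapply(bg, function(g) {
    y <- cts[g, ] / nf
    mu <- mean(y)
    (var(y) - mu * mean(1 / nf)) / mu^2
  }, numeric(1))
  expect_lt(abs(median(est) - cfg$nb_dispersion) / cfg$nb_dispersion, 0.25)
  expect_gt(mean(abs(est - cfg$nb_dispersion) / cfg$nb_dispersion < 0.25),
            0.9)
})

test_that("null configuration yields exchangeable groups", {
  cfg <- small_cfg(n_samples = 200, de_log_fold_change = 0, mediation_a = 0,
                   mediation_b = 0, direct_c = 0, seed = 5)
  coh <- generate_cohort(cfg)
  # calibration is assessed on constant-mean genes, which match the NB
  # sampling model exactly; module genes carry extra latent noise that the
  # per-gene NB dispersion absorbs only approximately
  bg <- setdiff(names(which(unlist(coh$truth$module_membership$nasal) ==
                              "unassigned")),
                unlist(coh$truth$peripheral))
  cts <- coh$counts$nasal[bg, ]
  d <- fit_nb_glm(cts[rowSums(cts) > 0, ], coh$samples)
  fpr <- mean(d$p <= 0.05)
  expect_gt(fpr, 0.01)
  expect_lt(fpr, 0.12)
})

test_that("edge_weight 0 gives pairwise-independent genes, no modules", {
  cfg <- small_cfg(edge_weight = 0, eqtl_effect = 0, de_log_fold_change = 0,
                   mediation_a = 0, mediation_b = 0, seed = 9)
  coh <- generate_cohort(cfg)
  expr <- log(cpm_normalize(coh$counts$PBMC) + 1)
  mod_genes <- names(which(unlist(coh$truth$module_membership$PBMC) != "unassigned"))
  cc <- cor(t(expr[mod_genes, ]))
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.12)
  tom <- build_tom(expr[mod_genes, ], beta = 6)
  mods <- detect_modules(tom$tom, expr[mod_genes, ], min_module_size = 30)
  expect_true(all(mods == "unassigned"))
})

test_that("write_cohort round-trips through the readers", {
  coh <- cached_cohort("base", small_cfg())
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_identical(back$counts$PBMC, coh$counts$PBMC)
  expect_identical(back$counts$nasal, coh$counts$nasal)
  expect_identical(back$genotypes$dosage, coh$genotypes$dosage)
  expect_equal(back$samples$age, coh$samples$age)
  expect_identical(back$annotation$gene_id, coh$annotation$gene_id)
  # truth JSON contains every planted key driver name
  txt <- paste(readLines(file.path(dir, "truth.json")), collapse = "")
  for (kd in unlist(coh$truth$key_drivers)) expect_match(txt, kd)
  expect_identical(sort(unlist(back$truth$key_drivers)),
                   sort(unlist(coh$truth$key_drivers)))
})

test_that("VCF output parses under an established VCF reader", {
  coh <- cached_cohort("base", small_cfg())
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  lines <- readLines(file.path(dir, "genotypes.vcf"))
  expect_match(lines[1], "^##fileformat=VCFv4\\.2$")
  hdr <- grep("^#CHROM", lines, value = TRUE)
  expect_length(hdr, 1)
  expect_identical(strsplit(hdr, "\t")[[1]][1:9],
                   c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT"))
  vcf <- VariantAnnotation::readVcf(file.path(dir, "genotypes.vcf"))
  expect_equal(nrow(vcf), nrow(coh$genotypes$dosage))
  gt <- VariantAnnotation::geno(vcf)$GT
  dos <- matrix(c(`0/0` = 0L, `0/1` = 1L, `1/1` = 2L)[gt], nrow = nrow(gt),
                dimnames = dimnames(gt))
  expect_equal(unname(dos), unname(coh$genotypes$dosage))
})
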