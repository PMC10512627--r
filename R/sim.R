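#' Simulation configuration for a dual-tissue cohort
#'
#' Parameters of the synthetic-cohort generator.  Defaults describe a
#' desk-scale cohort with moderate, detectable effects: 300 participants
#' (half cases), 1000 genes per tissue organized into five 50-gene causal
#' modules with two key-driver roots each, cis-eQTLs at every key driver,
#' a half-natural-log case/control shift at planted DE genes (small enough
#' that the planted network, not the exogenous shift, dominates the
#' members' covariance), and a planted
#' complete-mediation chain systemic-driver -> airway-driver -> phenotype
#' with path coefficients a = b = 0.5 and no direct path.
#'
#' @param n_samples number of participants (>= 20).
#' @param case_fraction target fraction of cases, in (0, 1).
#' @param n_genes_per_tissue genes simulated per tissue.
#' @param n_modules number of causal modules per tissue.
#' @param module_size genes per module (>= n_key_drivers_per_module + 2).
#' @param n_key_drivers_per_module root key drivers per module.
#' @param n_snps number of biallelic variants.
#' @param maf_range range of minor-allele frequencies, within (0, 0.5].
#' @param eqtl_effect per-alternate-allele shift on log expression at
#'   key-driver genes.
#' @param de_log_fold_change case/control shift (natural log) planted at
#'   non-chain DE genes.
#' @param mediation_a path coefficient X -> M of the mediation chain.
#' @param mediation_b path coefficient M -> liability.
#' @param direct_c direct X -> liability path (0 = complete mediation, so
#'   the converse mediation direction is exactly false).
#' @param nb_dispersion negative-binomial dispersion shared by all genes
#'   (variance = mu + dispersion * mu^2).
#' @param edge_weight parent -> child coefficient on the log scale in the
#'   module DAGs.
#' @param seed integer RNG seed; same seed, same cohort.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300, case_fraction = 0.5,
                       n_genes_per_tissue = 1000, n_modules = 5,
                       module_size = 50, n_key_drivers_per_module = 2,
                       n_snps = 200, maf_range = c(0.1, 0.5),
                       eqtl_effect = 1, de_log_fold_change = 0.5,
                       mediation_a = 0.5, mediation_b = 0.5, direct_c = 0,
                       nb_dispersion = 0.1, edge_weight = 0.8, seed = 1) {
  cfg <- as.list(environment())
  if (n_samples < 20) stop("invariant violated: n_samples >= 20")
  if (!(case_fraction > 0 && case_fraction < 1))
    stop("invariant violated: 0 < case_fraction < 1")
  if (module_size < n_key_drivers_per_module + 2)
    stop("invariant violated: module_size >= n_key_drivers_per_module + 2")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("invariant violated: maf_range within (0, 0.5]")
  if (nb_dispersion <= 0) stop("invariant violated: nb_dispersion > 0")
  if (n_modules * module_size > n_genes_per_tissue)
    stop("infeasible config: n_modules * module_size exceeds n_genes_per_tissue")
  n_kd_total <- 2 * n_modules * n_key_drivers_per_module
  if (n_snps < n_kd_total)
    stop("infeasible config: n_snps < total key drivers (", n_kd_total,
         "), cannot anchor every key driver")
  structure(cfg, class = "sim_config")
}

# module DAG with hierarchical hub (master-regulator) topology: the key
# drivers form a chain KD1 -> KD2 -> ... (KD1 is the apex regulator), and
# every other gene hangs off exactly one parent -- a uniformly chosen key
# driver with probability 0.9 (direct regulon target), otherwise a
# uniformly chosen earlier non-driver gene (shallow secondary cascades).
# Single parentage gives every gene a unique strongest upstream partner,
# which is what makes reconstructed hub edges stable across networks;
# shallow hub modules are what key driver analysis presumes (regulators
# with large, mostly direct downstream target sets).
.module_dag <- function(genes, n_kd) {
  s <- length(genes)
  from <- character(0); to <- character(0)
  if (n_kd > 1) {
    from <- genes[1:(n_kd - 1)]
    to <- genes[2:n_kd]
  }
  for (j in (n_kd + 1):s) {
    p1 <- if (runif(1) < 0.9 || j == n_kd + 1) sample.int(n_kd, 1L) else {
      cand <- seq.int(n_kd + 1L, j - 1L)
      cand[sample.int(length(cand), 1L)]
    }
    from <- c(from, genes[p1]); to <- c(to, genes[j])
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Generate a synthetic dual-tissue cohort with planted ground truth
#'
#' Builds latent log-expression by topological propagation over planted
#' module DAGs (root key drivers receive a cis-eQTL genotype effect plus
#' noise; children receive `edge_weight` times the sum of their parents plus
#' noise), plants a mediation chain from a systemic-tissue key driver X to an
#' airway-tissue key driver M (`M = a X + eqtl + noise`) to a thresholded
#' liability (`L = b M + c' X + noise`), adds a case shift at non-chain DE
#' genes (the remaining members of module M1 of each tissue), and draws
#' negative-binomial counts with log-normal size factors.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (named list of gene x sample integer matrices,
#'   one per tissue), `samples` (data.frame), `genotypes` (list with `info`
#'   data.frame and snp x sample `dosage` matrix), `annotation` (data.frame
#'   gene_id/chrom/tss/tes), and `truth` (planted parameters; see details).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  tissues <- c("PBMC", "nasal")
  n <- cfg$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))

  ## covariates (independent of phenotype; no planted confounding)
  samples <- data.frame(
    sample_id = sample_ids,
    age = round(runif(n, 6, 18), 1),
    sex = sample(c("F", "M"), n, replace = TRUE),
    race = sample(c("W", "B", "L"), n, replace = TRUE,
                  prob = c(0.5, 0.3, 0.2)),
    stringsAsFactors = FALSE
  )

  ## gene annotation: tissues on separate chromosomes, genes every 2 Mb so
  ## a key driver's cis SNP falls inside the 1 Mb window of its own gene
  ## only (co-regulated neighbours sharing an eQTL would otherwise act as
  ## false instruments)
  ann <- do.call(rbind, lapply(seq_along(tissues), function(ti) {
    g <- cfg$n_genes_per_tissue
    data.frame(
      gene_id = sprintf("%s_g%04d", tissues[ti], seq_len(g)),
      chrom = as.character(ti),
      tss = 2e6 * seq_len(g),
      tes = 2e6 * seq_len(g) + 1e4,
      stringsAsFactors = FALSE
    )
  }))

  ## modules, key drivers, DAGs
  membership <- list(); dags <- list(); key_drivers <- list()
  for (ts in tissues) {
    gids <- ann$gene_id[startsWith(ann$gene_id, ts)]
    memb <- setNames(rep("unassigned", length(gids)), gids)
    kd <- list(); edges <- NULL
    prev_kd1 <- NULL
    for (m in seq_len(cfg$n_modules)) {
      idx <- ((m - 1) * cfg$module_size + 1):(m * cfg$module_size)
      mg <- gids[idx]
      lab <- paste0("M", m)
      memb[mg] <- lab
      kd[[lab]] <- mg[seq_len(cfg$n_key_drivers_per_module)]
      # modules are chained lead-driver to lead-driver so the tissue
      # network is connected (key driver neighborhoods then reach beyond
      # the module, as in a real transcriptome network); full edge weight
      # keeps the bridge detectable by the BIC score at cohort sample
      # sizes while inter-module gene correlations stay far below the
      # module-merging range
      if (!is.null(prev_kd1))
        edges <- rbind(edges, data.frame(
          from = prev_kd1, to = mg[1], weight = 1.3 * cfg$edge_weight,
          stringsAsFactors = FALSE))
      ed_m <- .module_dag(mg, cfg$n_key_drivers_per_module)
      ed_m$weight <- cfg$edge_weight
      # driver-to-driver edges (within-module chain and the inter-module
      # bridge above) are 1.3x the regulon weight: regulator coupling must
      # stay reconstructable at test-set sample sizes for the subnetwork
      # background to reach beyond one module
      nkd <- cfg$n_key_drivers_per_module
      if (nkd > 1) ed_m$weight[seq_len(nkd - 1)] <- 1.3 * cfg$edge_weight
      edges <- rbind(edges, ed_m)
      prev_kd1 <- mg[1]
    }
    # peripheral genes: one per two module genes, each a high-noise child
    # of a random module gene.  They are causally attached (so the network
    # places them downstream of the drivers) but too weakly correlated to
    # join the co-expression module -- the non-member background real key
    # driver analysis relies on.
    n_mod_genes <- cfg$n_modules * cfg$module_size
    n_periph <- min(round(n_mod_genes / 2),
                    length(gids) - n_mod_genes)
    periph <- character(0)
    if (n_periph > 0) {
      periph <- gids[n_mod_genes + seq_len(n_periph)]
      edges <- rbind(edges, data.frame(
        from = sample(gids[seq_len(n_mod_genes)], n_periph, replace = TRUE),
        to = periph, weight = cfg$edge_weight, stringsAsFactors = FALSE))
    }
    membership[[ts]] <- memb
    dags[[ts]] <- edges
    key_drivers[[ts]] <- kd
    if (ts == tissues[1]) peripheral <- list()
    peripheral[[ts]] <- periph
  }

  ## genotypes: one cis SNP per key driver, plus background SNPs
  kd_all <- c(unlist(key_drivers$PBMC, use.names = FALSE),
              unlist(key_drivers$nasal, use.names = FALSE))
  maf <- runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
  snp_id <- sprintf("rs%05d", seq_len(cfg$n_snps))
  chrom <- character(cfg$n_snps); pos <- integer(cfg$n_snps)
  for (i in seq_along(kd_all)) {
    ai <- match(kd_all[i], ann$gene_id)
    chrom[i] <- ann$chrom[ai]
    pos[i] <- ann$tss[ai] - 100L  # 100 bp upstream: well inside the window
  }
  n_bg <- cfg$n_snps - length(kd_all)
  if (n_bg > 0) {
    bg <- length(kd_all) + seq_len(n_bg)
    chrom[bg] <- as.character(1 + (bg %% 2))
    pos[bg] <- sort(sample.int(2e6 * cfg$n_genes_per_tissue, n_bg)) + 50L
  }
  dosage <- matrix(rbinom(cfg$n_snps * n, 2, rep(maf, each = n)),
                   nrow = cfg$n_snps, byrow = TRUE,
                   dimnames = list(snp_id, sample_ids))
  geno_info <- data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
                          maf = maf, stringsAsFactors = FALSE)
  eqtl_pairs <- data.frame(snp = snp_id[seq_along(kd_all)], gene = kd_all,
                           effect = cfg$eqtl_effect, stringsAsFactors = FALSE)

  ## latent log-expression by topological propagation
  x_gene <- key_drivers$PBMC$M1[1]
  m_gene <- key_drivers$nasal$M1[1]
  snp_of <- setNames(eqtl_pairs$snp, eqtl_pairs$gene)
  latent <- list()
  for (ts in tissues) {
    gids <- names(membership[[ts]])
    # module genes carry unit-variance intrinsic noise; background genes
    # have constant latent means (their only variation is NB sampling and
    # size factors), which keeps the planted dispersion identifiable
    z <- matrix(0, nrow = length(gids), ncol = n,
                dimnames = list(gids, sample_ids))
    # roots carry unit intrinsic noise; module children get sd 0.8 --
    # strong enough coupling for coherent co-expression modules, enough
    # per-hop decay that a parent is clearly distinguishable from a
    # sibling when the network is reconstructed; peripheral genes are
    # loosely coupled (sd 1.5), keeping them out of the modules while
    # still network-detectable
    mod_rows <- gids[membership[[ts]][gids] != "unassigned"]
    roots <- unlist(key_drivers[[ts]], use.names = FALSE)
    z[mod_rows, ] <- rnorm(length(mod_rows) * n, sd = 0.8)
    z[roots, ] <- rnorm(length(roots) * n)
    z[peripheral[[ts]], ] <- rnorm(length(peripheral[[ts]]) * n, sd = 1.5)
    for (g in names(snp_of)) {
      if (g %in% gids) z[g, ] <- z[g, ] + cfg$eqtl_effect * dosage[snp_of[g], ]
    }
    if (ts == "nasal")  # mediation chain: M = a * X + eqtl + noise
      z[m_gene, ] <- z[m_gene, ] + cfg$mediation_a * latent$PBMC[x_gene, ]
    ed <- dags[[ts]]
    for (k in seq_len(nrow(ed)))  # rows are in global topological order
      z[ed$to[k], ] <- z[ed$to[k], ] + ed$weight[k] * z[ed$from[k], ]
    latent[[ts]] <- z
  }

  ## thresholded liability -> phenotype with realized fraction ~ target
  liab <- cfg$mediation_b * latent$nasal[m_gene, ] +
    cfg$direct_c * latent$PBMC[x_gene, ] + rnorm(n)
  n_case <- round(n * cfg$case_fraction)
  case_idx <- order(liab, decreasing = TRUE)[seq_len(n_case)]
  asthma <- integer(n); asthma[case_idx] <- 1L
  samples$asthma <- asthma

  ## planted DE genes: module M1 members of each tissue minus chain genes
  de_genes <- list()
  for (ts in tissues) {
    memb <- membership[[ts]]
    # one-directional shift: asthma-module genes move together, matching
    # the concerted up-regulation the disease modules show in real cohorts
    # (and avoiding cancellation against the phenotype-correlated latent
    # the chain module inherits from its key drivers)
    cand <- setdiff(names(memb)[memb == "M1"], c(x_gene, m_gene))
    lfc <- setNames(rep(cfg$de_log_fold_change, length(cand)), cand)
    de_genes[[ts]] <- lfc
    latent[[ts]][cand, asthma == 1L] <-
      latent[[ts]][cand, asthma == 1L] + lfc
  }

  ## counts: NB around size-factor-scaled exp(baseline + latent)
  counts <- list()
  for (ts in tissues) {
    z <- latent[[ts]]
    # baselines are variance-corrected (log-normal mean e^{b + v/2}) so
    # genes with deep-propagation latents do not dominate library sizes,
    # keeping CPM normalization realistic
    base <- runif(nrow(z), log(50), log(500)) - apply(z, 1L, var) / 2
    sf <- rlnorm(n, 0, 0.2)
    mu <- exp(z + base) * rep(sf, each = nrow(z))
    cts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                  nrow = nrow(z), dimnames = dimnames(z))
    storage.mode(cts) <- "integer"
    counts[[ts]] <- cts
  }

  truth <- list(
    de_genes = lapply(de_genes, as.list),
    module_membership = lapply(membership, as.list),
    causal_edges = dags,
    key_drivers = key_drivers,
    eqtl_pairs = eqtl_pairs,
    peripheral = peripheral,
    mediation = list(x_gene = x_gene, m_gene = m_gene,
                     a = cfg$mediation_a, b = cfg$mediation_b,
                     c_prime = cfg$direct_c),
    config = unclass(cfg)
  )

  list(counts = counts, samples = samples,
       genotypes = list(info = geno_info, dosage = dosage),
       annotation = ann, truth = truth)
}

#' Write a cohort to disk
#'
#' Counts (one TSV per tissue, gene IDs in the first column), sample table
#' (TSV), genotypes (minimal VCF v4.2 with GT genotypes), gene annotation
#' (TSV), and the planted truth (JSON).  Output round-trips losslessly
#' through [read_cohort()].
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (ts in names(cohort$counts)) {
    f <- file.path(dir, paste0("counts_", ts, ".tsv"))
    write_count_matrix(cohort$counts[[ts]], f)
    files <- c(files, f)
  }
  f <- file.path(dir, "samples.tsv")
  data.table::fwrite(cohort$samples, f, sep = "\t")
  files <- c(files, f)
  f <- file.path(dir, "annotation.tsv")
  data.table::fwrite(cohort$annotation, f, sep = "\t")
  files <- c(files, f)
  f <- file.path(dir, "genotypes.vcf")
  write_genotypes_vcf(cohort$genotypes, f)
  files <- c(files, f)
  f <- file.path(dir, "truth.json")
  jsonlite::write_json(cohort$truth, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)
  invisible(files)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return list with the same structure as [generate_cohort()] output.
#' @export
read_cohort <- function(dir) {
  cfiles <- list.files(dir, pattern = "^counts_.*\\.tsv$", full.names = TRUE)
  counts <- list()
  for (f in cfiles) {
    ts <- sub("^counts_(.*)\\.tsv$", "\\1", basename(f))
    counts[[ts]] <- read_count_matrix(f)
  }
  list(
    counts = counts,
    samples = as.data.frame(data.table::fread(file.path(dir, "samples.tsv"))),
    genotypes = read_genotypes_vcf(file.path(dir, "genotypes.vcf")),
    annotation = as.data.frame(
      data.table::fread(file.path(dir, "annotation.tsv"))),
    truth = jsonlite::fromJSON(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  )
}
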