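#' Pipeline parameters
#'
#' All stage thresholds in one place.  Defaults follow the published
#' analysis where it states them: CPM filter (<= 5 CPM in > 10% of
#' samples), BH FDR 0.05 at every validation step, fold-enrichment > 1 for
#' module flagging, 1 Mb cis window, MAF >= 0.01, three expression states,
#' 30% edge consensus, K = 7 key-driver neighborhoods.  Desk-scale knobs
#' (number of MCMC networks, sweeps, mediation permutation iterations) are
#' smaller than the published runs and documented as such.
#'
#' @param ... overrides of the defaults listed in the function definition.
#' @return named list of class `pipeline_params`.
#' @export
pipeline_params <- function(...) {
  p <- list(
    cpm_threshold = 5, max_low_fraction = 0.10,
    alpha = 0.05,
    covariates = c("age", "sex", "race"),
    beta = 6, min_module_size = 30, merge_corr = 0.75, cut_height = 0.99,
    min_maf = 0.01, n_pcs = 3, window = 1e6,
    n_networks = 100, sweeps = NULL, max_parents = 3,
    kappa = 1, lambda = log(2), consensus_threshold = 0.30,
    bn_max_genes = 120,
    K = 7, min_downstream = 5,
    mediation_iterations = 0,
    stratify_split = FALSE,
    seed = 1
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stop("unknown parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  structure(p, class = "pipeline_params")
}

# numeric covariate matrix for eQTL mapping: age + sex dummies + ancestry PCs
.eqtl_covariates <- function(samples, pcs) {
  df <- data.frame(age = as.numeric(samples$age),
                   sex = factor(samples$sex))
  mm <- model.matrix(~ ., df)[, -1, drop = FALSE]
  cbind(mm, pcs)
}

#' Run the per-tissue pipeline
#'
#' Executes normalization and filtering, the 2:1 discovery/test split,
#' covariate-adjusted differential expression with directional validation,
#' co-expression module detection with enrichment and eigengene-phenotype
#' association, cis-eQTL mapping (ancestry PCs + age + sex as covariates),
#' eQTL-anchored Bayesian network reconstruction with edge consensus
#' (discovery and test separately), and key driver analysis with
#' discovery/test validation.  With `out_dir` set, writes the eight stage
#' artifacts as TSV files.
#'
#' @param counts gene x sample integer matrix for this tissue.
#' @param samples sample table (`sample_id`, `asthma`, covariates).
#' @param genotypes genotype list (`info`, `dosage`).
#' @param annotation gene annotation data.frame.
#' @param params [pipeline_params()].
#' @param tissue tissue label used in logs and artifact names.
#' @param out_dir optional artifact directory.
#' @return list with all stage outputs (`split`, `dge`, `validated`,
#'   `modules`, `enrichment`, `eigengene_assoc`, `eqtl`, `network_discovery`,
#'   `network_test`, `key_drivers`, `log_expr`, `log`).
#' @export
run_tissue <- function(counts, samples, genotypes, annotation,
                       params = pipeline_params(), tissue = "tissue",
                       out_dir = NULL) {
  p <- params
  log <- list(tissue = tissue, seed = p$seed)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' (", tissue, ") failed: ",
           conditionMessage(e), call. = FALSE))
  }

  cpm <- step("normalize", cpm_normalize(counts))
  keep <- step("filter", filter_low_abundance(cpm, p$cpm_threshold,
                                              p$max_low_fraction))
  log$n_genes_kept <- length(keep)
  # Downstream analyses (networks, modules, eQTL, mediation) run on
  # log counts normalized by median-of-ratios size factors rather than raw
  # CPM: composition-robust, so strongly shifted genes cannot induce
  # spurious anti-correlation or differential expression in the rest of
  # the transcriptome.  CPM is still what the abundance filter sees.
  sf <- step("size_factors", size_factors(counts))
  log_expr <- log(sweep(counts[keep, , drop = FALSE], 2L, sf, "/") + 1)
  libsize <- sf

  split <- step("split", split_discovery_test(
    samples, derive_seed(p$seed, "split"), stratify = p$stratify_split))
  disc <- split$discovery; test <- split$test
  log$n_discovery <- length(disc); log$n_test <- length(test)
  s_disc <- samples[match(disc, samples$sample_id), ]
  s_test <- samples[match(test, samples$sample_id), ]

  dge_d <- step("dge_discovery", fit_nb_glm(
    counts[keep, disc, drop = FALSE], s_disc, p$covariates,
    libsize = libsize[disc]))
  dge_t <- step("dge_test", fit_nb_glm(
    counts[keep, test, drop = FALSE], s_test, p$covariates,
    libsize = libsize[test]))
  validated <- step("validate_dge",
                    validate_across_sets(dge_d, dge_t, p$alpha))
  log$n_validated_genes <- length(validated$genes)

  e_disc <- log_expr[, disc, drop = FALSE]
  tom <- step("tom", build_tom(e_disc, p$beta))
  assignment <- step("modules", detect_modules(
    tom$tom, e_disc, p$min_module_size, p$merge_corr, p$cut_height))
  mods <- setdiff(unique(assignment), "unassigned")
  log$n_modules <- length(mods)
  enrichment <- step("enrich", enrich_modules(
    assignment, validated$genes, keep, p$alpha))
  eg <- NULL; eg_assoc <- NULL
  if (length(mods) > 0) {
    eg <- vapply(sort(mods), function(m) compute_eigengene(
      e_disc[names(assignment)[assignment == m], , drop = FALSE]),
      numeric(length(disc)))
    rownames(eg) <- disc
    eg_assoc <- step("eigengene_assoc",
                     associate_eigengenes(eg, s_disc, p$covariates))
  }

  geno <- step("maf_filter", filter_variants(genotypes, p$min_maf))
  pcs <- step("ancestry_pcs", genotype_pcs(geno, p$n_pcs))
  cov_d <- .eqtl_covariates(s_disc, pcs[disc, , drop = FALSE])
  eqtl <- step("eqtl", map_cis_eqtl(
    e_disc, list(info = geno$info,
                 dosage = geno$dosage[, disc, drop = FALSE]),
    annotation, cov_d, p$window, p$alpha))
  egenes <- unique(eqtl$gene[eqtl$significant])
  log$n_eqtl_genes <- length(egenes)

  ## network genes: members of the flagged asthma modules (fallback: the
  ## top-enriched module), capped at bn_max_genes
  am <- enrichment$module[enrichment$asthma_module]
  if (length(am) == 0 && nrow(enrichment) > 0) am <- enrichment$module[1]
  # the network spans the asthma module(s) plus the other detected modules
  # (enrichment order) up to the gene cap: key driver analysis needs
  # non-member nodes in the neighborhood background
  bn_genes <- character(0)
  for (m in c(am, setdiff(enrichment$module, am))) {
    mg <- names(assignment)[assignment == m]
    bn_genes <- c(bn_genes, mg)
    if (length(bn_genes) >= p$bn_max_genes) break
  }
  bn_genes <- head(bn_genes, p$bn_max_genes)
  net_d <- net_t <- NULL; kd <- NULL
  if (length(bn_genes) >= 2) {
    anchored <- intersect(bn_genes, egenes)
    # each anchored gene carries its best cis-eQTL genotype as a fixed
    # instrument parent, which is what lets the likelihood orient edges
    inst <- NULL
    if (length(anchored) > 0) {
      sig <- eqtl[eqtl$significant & eqtl$gene %in% anchored, ]
      sig <- sig[order(sig$p), ]
      sig <- sig[!duplicated(sig$gene), ]
      inst <- geno$dosage[sig$snp, , drop = FALSE]
      rownames(inst) <- sig$gene
    }
    # ~10 proposals per ordered node pair: enough for the chains to mix on
    # module-scale networks (a per-gene default is far too few here)
    sweeps <- if (is.null(p$sweeps)) 10L * length(bn_genes)^2 else p$sweeps
    st_d <- step("discretize_discovery", discretize_expression(
      log_expr[bn_genes, disc, drop = FALSE], derive_seed(p$seed, "disc_d")))
    st_t <- step("discretize_test", discretize_expression(
      log_expr[bn_genes, test, drop = FALSE], derive_seed(p$seed, "disc_t")))
    nets_d <- step("mcmc_discovery", mcmc_networks(
      st_d, anchored, p$n_networks, sweeps, p$max_parents, p$kappa,
      p$lambda, derive_seed(p$seed, paste0(tissue, "_bn_d")),
      instruments = if (is.null(inst)) NULL else
        inst[, disc, drop = FALSE]))
    nets_t <- step("mcmc_test", mcmc_networks(
      st_t, anchored, p$n_networks, sweeps, p$max_parents, p$kappa,
      p$lambda, derive_seed(p$seed, paste0(tissue, "_bn_t")),
      instruments = if (is.null(inst)) NULL else
        inst[, test, drop = FALSE]))
    net_d <- consensus_network(nets_d, p$consensus_threshold)
    net_t <- consensus_network(nets_t, p$consensus_threshold)
    kd_rows <- list()
    for (m in am) {
      members <- intersect(names(assignment)[assignment == m], bn_genes)
      if (length(members) == 0) next
      kda_d <- step("kda_discovery", find_key_drivers(
        net_d, members, p$K, p$min_downstream, p$alpha))
      kda_t <- step("kda_test", find_key_drivers(
        net_t, members, p$K, p$min_downstream, p$alpha))
      v <- validate_key_drivers(kda_d, kda_t)
      if (nrow(v)) v$module <- m
      kd_rows[[m]] <- v
    }
    kd <- do.call(rbind, kd_rows)
    if (!is.null(kd)) rownames(kd) <- NULL
    log$n_key_drivers <- if (is.null(kd)) 0L else sum(kd$validated)
  }

  res <- list(tissue = tissue, split = split, keep = keep,
              log_expr = log_expr, dge_discovery = dge_d, dge_test = dge_t,
              validated = validated, modules = assignment,
              enrichment = enrichment, eigengenes = eg,
              eigengene_assoc = eg_assoc, eqtl = eqtl,
              network_discovery = net_d, network_test = net_t,
              key_drivers = kd, log = log)
  if (!is.null(out_dir)) write_tissue_artifacts(res, out_dir)
  res
}

#' Write the eight per-tissue artifact files
#'
#' @param res a [run_tissue()] result.
#' @param out_dir output directory (created if absent).
#' @return invisibly, the files written.
#' @export
write_tissue_artifacts <- function(res, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ts <- res$tissue
  fw <- function(df, name) {
    f <- file.path(out_dir, paste0(ts, "_", name, ".tsv"))
    if (is.null(df))
      df <- data.frame(note = "stage produced no output")
    data.table::fwrite(as.data.frame(df), f, sep = "\t")
    f
  }
  files <- c(
    fw(res$validated$table, "validated_genes"),
    fw(data.frame(gene = names(res$modules), module = unname(res$modules)),
       "modules"),
    fw(res$enrichment, "module_enrichment"),
    fw(res$eigengene_assoc, "eigengene_assoc"),
    fw(res$eqtl, "eqtl"),
    fw(res$network_discovery, "network_discovery"),
    fw(res$network_test, "network_test"),
    fw(res$key_drivers, "key_drivers")
  )
  invisible(files)
}

#' Cross-tissue integration: mediation screen between key drivers
#'
#' Takes two completed [run_tissue()] results, extracts each tissue's
#' validated key drivers, and screens causal mediation in both directions.
#'
#' @param res_a,res_b [run_tissue()] results for the two tissues.
#' @param samples sample table shared by both tissues.
#' @param params [pipeline_params()].
#' @param out_dir optional directory for `mediation.tsv`.
#' @return list with `mediation` (the screen table) and `significant`
#'   (subset with FDR at or below alpha), or an empty report with a warning
#'   when a tissue has no validated key drivers.
#' @export
run_integration <- function(res_a, res_b, samples,
                            params = pipeline_params(), out_dir = NULL) {
  p <- params
  get_kd <- function(res) {
    if (is.null(res$key_drivers)) character(0)
    else unique(res$key_drivers$node[res$key_drivers$validated])
  }
  drivers <- setNames(list(get_kd(res_a), get_kd(res_b)),
                      c(res_a$tissue, res_b$tissue))
  expr <- setNames(list(res_a$log_expr, res_b$log_expr),
                   c(res_a$tissue, res_b$tissue))
  med <- mediation_screen(drivers, expr, samples,
                          covariates = intersect(p$covariates,
                                                 names(samples)),
                          alpha = p$alpha,
                          iterations = p$mediation_iterations,
                          seed = derive_seed(p$seed, "mediation"))
  out <- list(mediation = med,
              significant = med[med$significant, , drop = FALSE])
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    data.table::fwrite(med, file.path(out_dir, "mediation.tsv"), sep = "\t")
  }
  out
}

#' Run the full dual-tissue pipeline on a cohort
#'
#' Convenience wrapper: [run_tissue()] on each tissue of a cohort (as
#' produced by [generate_cohort()] or [read_cohort()]) followed by
#' [run_integration()].
#'
#' @param cohort cohort list with `counts` (named per tissue), `samples`,
#'   `genotypes`, `annotation`.
#' @param params [pipeline_params()].
#' @param out_dir optional artifact directory.
#' @return list with one entry per tissue plus `integration`.
#' @export
run_cohort_pipeline <- function(cohort, params = pipeline_params(),
                                out_dir = NULL) {
  tissues <- names(cohort$counts)
  stopifnot(length(tissues) == 2L)
  res <- list()
  for (ts in tissues) {
    res[[ts]] <- run_tissue(cohort$counts[[ts]], cohort$samples,
                            cohort$genotypes, cohort$annotation,
                            params, tissue = ts, out_dir = out_dir)
  }
  res$integration <- run_integration(res[[tissues[1]]], res[[tissues[2]]],
                                     cohort$samples, params, out_dir)
  res
}

#' Read a flat key=value pipeline configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Values are
#' parsed as numbers where possible, comma-separated lists become vectors.
#'
#' @param path configuration file.
#' @return [pipeline_params()] with the file's overrides applied.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "=", fixed = TRUE)
  ov <- list()
  for (p in kv) {
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    ov[[key]] <- if (any(is.na(num))) parts else num
  }
  do.call(pipeline_params, ov)
}
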