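test_that("TOM limits: perfect correlation and single-edge identity", {
  x <- rnorm(30)
  expr <- rbind(g1 = x, g2 = 2 * x + 1)
  colnames(expr) <- paste0("s", 1:30)
  tm <- build_tom(expr, beta = 1)
  expect_equal(tm$adjacency[1, 2], 1, tolerance = 1e-12)
  expect_equal(tm$tom[1, 2], 1, tolerance = 1e-12)
  expect_error(build_tom(expr[, 1:2]), "3 samples")
  expect_warning(build_tom(rbind(expr, flat = rep(1, 30)), beta = 2),
                 "constant")
})

test_that("automatic soft power picks a small beta on scale-free-ish data", {
  # hub-structured blocks give a broad connectivity distribution; the
  # chosen power must lie in the documented range and not be the fallback
  # for clearly structured input
  bx <- block_expr(4, 30, 120, 0.6, seed = 49)
  tm <- build_tom(bx$expr, beta = "auto")
  expect_true(tm$beta %in% 1:20)
  # independent noise has no scale-free fit at any power -> fallback 6
  set.seed(50)
  noise <- matrix(rnorm(40 * 60), 40, 60,
                  dimnames = list(sprintf("g%02d", 1:40), NULL))
  expect_equal(pick_soft_power(abs(cor(t(noise))), rsq_cut = 0.999), 6)
})

test_that("TOM is symmetric with entries in [0, 1]", {
  set.seed(41)
  expr <- matrix(rnorm(40 * 25), 40, 25,
                 dimnames = list(sprintf("g%02d", 1:40),
                                 sprintf("s%02d", 1:25)))
  tm <- build_tom(expr, beta = 6)$tom
  expect_equal(tm, t(tm), tolerance = 1e-12)
  expect_true(all(tm >= -1e-12 & tm <= 1 + 1e-12))
})

test_that("independent genes give low topological overlap", {
  set.seed(42)
  expr <- matrix(rnorm(30 * 1000), 30, 1000,
                 dimnames = list(sprintf("g%02d", 1:30), NULL))
  tm <- build_tom(expr, beta = 6)$tom
  expect_lt(mean(tm[upper.tri(tm)]), 0.05)
})

test_that("planted blocks are recovered and order-invariant", {
  bx <- block_expr(2, 50, 100, 0.8, seed = 43)
  tm <- build_tom(bx$expr, beta = 6)
  mods <- detect_modules(tm$tom, bx$expr, min_module_size = 30)
  expect_length(setdiff(unique(mods), "unassigned"), 2)
  expect_gte(rand_index(unname(mods), unname(bx$labels[names(mods)])), 0.95)
  # permuting gene order yields the same partition up to labels
  set.seed(44)
  perm <- sample(nrow(bx$expr))
  ex2 <- bx$expr[perm, ]
  mods2 <- detect_modules(build_tom(ex2, beta = 6)$tom, ex2,
                          min_module_size = 30)
  expect_equal(rand_index(unname(mods2[names(mods)]), unname(mods)), 1)
})

test_that("module detection calibrates on the planted block model", {
  # within-block correlation 0.7: recover the block count in >= 18/20 seeds
  ok <- 0L
  for (s in 1:20) {
    bx <- block_expr(2, 40, 80, 0.7, seed = 100 + s)
    mods <- detect_modules(build_tom(bx$expr, beta = 6)$tom, bx$expr,
                           min_module_size = 30)
    if (length(setdiff(unique(mods), "unassigned")) == 2) ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})

test_that("eigengene equals the dominant singular direction", {
  set.seed(45)
  n <- 40
  prof <- rnorm(n)
  expr <- matrix(rep(prof, each = 5), 5, n) +
    matrix(rnorm(5 * n, sd = 1e-6), 5, n)
  dimnames(expr) <- list(paste0("g", 1:5), paste0("s", 1:n))
  eg <- compute_eigengene(expr)
  expect_equal(sum(eg^2), 1, tolerance = 1e-9)
  expect_gt(cor(eg, prof), 0.999)
  # flipping the sign of every gene leaves the oriented eigengene unchanged
  eg2 <- compute_eigengene(-expr)
  expect_equal(abs(cor(eg, eg2)), 1, tolerance = 1e-6)
  expect_gt(sum(eg * colMeans(scale(t(expr)))), -1e-12)
  # variance explained is maximal (matches the top singular value)
  bx <- block_expr(1, 20, 50, 0.6, seed = 46)
  Z <- t(scale(t(bx$expr)))
  eg3 <- compute_eigengene(bx$expr)
  expect_equal(sum((Z %*% eg3)^2), svd(Z)$d[1]^2, tolerance = 1e-8)
  expect_error(compute_eigengene(matrix(1, 3, 4)), "zero-variance")
})

test_that("module enrichment flags and ranks planted concentration", {
  universe <- sprintf("g%03d", 1:200)
  assignment <- setNames(rep("unassigned", 200), universe)
  assignment[1:40] <- "M1"
  assignment[41:80] <- "M2"
  asthma <- universe[c(1:25, 81:85)]  # concentrated in M1
  en <- enrich_modules(assignment, asthma, universe)
  expect_identical(en$module[1], "M1")
  expect_true(en$asthma_module[en$module == "M1"])
  expect_false(en$asthma_module[en$module == "M2"])
  expect_equal(en$fold_enrichment[en$module == "M2"], 0)
  # module equal to the gene set: fold = universe / target size
  a2 <- setNames(rep("unassigned", 200), universe)
  a2[1:30] <- "M1"
  en2 <- enrich_modules(a2, universe[1:30], universe)
  expect_equal(en2$fold_enrichment[1], 200 / 30)
  expect_error(enrich_modules(assignment, "not_a_gene", universe), "subset")
})

test_that("eigengene association is calibrated and detects the liability", {
  set.seed(47)
  n <- 100
  smp <- data.frame(asthma = rbinom(n, 1, 0.5), age = rnorm(n, 12, 3),
                    sex = sample(c("F", "M"), n, TRUE))
  ps <- replicate(200, {
    eg <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "M1"))
    associate_eigengenes(eg, smp)$p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # planted effect: eigengene equal to the liability scores strongly
  set.seed(48)
  n2 <- 300
  liab <- rnorm(n2)
  smp2 <- data.frame(asthma = as.integer(liab > 0), age = rnorm(n2, 12, 3),
                     sex = sample(c("F", "M"), n2, TRUE))
  eg2 <- matrix(liab / sqrt(sum(liab^2)), n2, 1,
                dimnames = list(NULL, "M1"))
  r <- associate_eigengenes(eg2, smp2)
  expect_lte(r$fdr[1], 0.05)
  # constant eigengene is flagged
  r0 <- associate_eigengenes(matrix(1, n2, 1, dimnames = list(NULL, "M0")),
                             smp2)
  expect_identical(r0$flag, "constant")
})
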