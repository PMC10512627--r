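chain_data <- function(n, a = 1, b = 1, noise = 0.1, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  m <- a * x + rnorm(n, sd = noise)
  y <- b * m + rnorm(n, sd = noise)
  list(x = x, m = m, y = y)
}

test_that("noise-free chain yields a = b = 1, c' = 0", {
  x <- rnorm(50)
  f <- fit_mediation(x, x, x)
  expect_equal(f$a, 1, tolerance = 1e-12)
  expect_equal(f$b, 1, tolerance = 1e-12)
  expect_equal(f$c_prime, 0, tolerance = 1e-12)
  expect_equal(f$indirect, 1, tolerance = 1e-12)
  expect_lt(f$sobel_p, 1e-10)
})

test_that("c = c' + a*b holds exactly for nested OLS", {
  set.seed(71)
  for (i in 1:10) {
    n <- 80
    x <- rnorm(n); m <- 0.4 * x + rnorm(n)
    y <- rbinom(n, 1, plogis(0.5 * m))
    cov <- data.frame(age = rnorm(n), sex = sample(c("F", "M"), n, TRUE))
    f <- fit_mediation(x, m, y, cov)
    expect_equal(f$c, f$c_prime + f$a * f$b, tolerance = 1e-10)
  }
  expect_error(fit_mediation(rnorm(10), rnorm(10), rnorm(10)), "30")
  expect_error(fit_mediation(rep(1, 40), rnorm(40), rnorm(40)), "constant")
})

test_that("Sobel p is uniform when only the a path is null", {
  set.seed(72)
  ps <- replicate(500, {
    n <- 100
    m <- rnorm(n); y <- m + rnorm(n); x <- rnorm(n)  # x independent
    fit_mediation(x, m, y)$sobel_p
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("bootstrap CI collapses on deterministic chains, is seeded", {
  x <- rnorm(60)
  ci <- bootstrap_indirect(x, x, x, B = 100, seed = 3)
  expect_equal(ci, c(1, 1), tolerance = 1e-12)
  d <- chain_data(80, seed = 73)
  ci1 <- bootstrap_indirect(d$x, d$m, d$y, B = 200, seed = 4)
  ci2 <- bootstrap_indirect(d$x, d$m, d$y, B = 200, seed = 4)
  expect_identical(ci1, ci2)
  expect_lte(ci1[1], ci1[2])
})

test_that("bootstrap CI covers zero at the nominal rate under the null", {
  set.seed(74)
  cover <- replicate(200, {
    n <- 50
    x <- rnorm(n); m <- rnorm(n); y <- rnorm(n)
    ci <- bootstrap_indirect(x, m, y, B = 300,
                             seed = sample.int(1e6, 1))
    ci[1] <= 0 && ci[2] >= 0
  })
  expect_gte(mean(cover), 0.90)
  expect_lte(mean(cover), 0.99)
})

test_that("permutation p-value behaves at its extremes and under the null", {
  d <- chain_data(300, a = 1, b = 1, noise = 0.1, seed = 75)
  expect_equal(permutation_test(d$x, d$m, d$y, iterations = 200, seed = 5),
               1 / 201, tolerance = 1e-12)
  expect_equal(permutation_test(d$x, d$m, d$y, iterations = 0), 1)
  set.seed(76)
  pp <- replicate(200, {
    n <- 60
    permutation_test(rnorm(n), rnorm(n), rnorm(n), iterations = 99,
                     seed = sample.int(1e6, 1))
  })
  expect_lt(abs(mean(pp) - 0.5), 0.05)
})

test_that("Sobel and permutation p agree in rank across an effect grid", {
  # effects kept modest so the permutation p stays off its 1/(B+1) floor
  # (floor ties would degrade the rank correlation artificially)
  grid <- seq(0, 0.4, by = 0.05)
  sp <- pp <- numeric(length(grid))
  for (i in seq_along(grid)) {
    d <- chain_data(100, a = grid[i], b = grid[i], noise = 1,
                    seed = 80 + i)
    f <- fit_mediation(d$x, d$m, d$y)
    sp[i] <- f$sobel_p
    pp[i] <- permutation_test(d$x, d$m, d$y, iterations = 1000, seed = i)
  }
  expect_gte(cor(sp, pp, method = "spearman"), 0.9)
})

test_that("swapping exposure and mediator roles breaks significance", {
  d <- chain_data(300, a = 0.8, b = 0.8, noise = 0.6, seed = 77)
  fwd <- fit_mediation(d$x, d$m, d$y)
  rev <- fit_mediation(d$m, d$x, d$y)
  expect_lt(fwd$sobel_p, 1e-6)
  expect_gt(rev$sobel_p, 0.05)
})

test_that("mediation screen finds the planted pair, not the converse", {
  coh <- cached_cohort("n300", small_cfg(n_samples = 300,
                                         case_fraction = 0.4))
  tr <- coh$truth
  expr <- list(PBMC = log(cpm_normalize(coh$counts$PBMC) + 1),
               nasal = log(cpm_normalize(coh$counts$nasal) + 1))
  drivers <- list(PBMC = unlist(tr$key_drivers$PBMC$M1),
                  nasal = unlist(tr$key_drivers$nasal$M1))
  scr <- mediation_screen(drivers, expr, coh$samples,
                          covariates = c("age", "sex", "race"))
  fwd <- scr[scr$direction == "PBMC->nasal", ]
  planted <- fwd[fwd$x_gene == tr$mediation$x_gene &
                   fwd$m_gene == tr$mediation$m_gene, ]
  expect_true(planted$significant)
  conv <- scr[scr$direction == "nasal->PBMC" &
                scr$x_gene == tr$mediation$m_gene &
                scr$m_gene == tr$mediation$x_gene, ]
  expect_false(conv$significant)
  expect_warning(
    empty <- mediation_screen(list(PBMC = character(0), nasal = "g"),
                              expr, coh$samples),
    "empty")
  expect_equal(nrow(empty), 0)
})
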