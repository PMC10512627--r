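# continuous chain X -> Y -> Z with strong dependence, for recovery tests
chain3 <- function(n, seed, noise = 0.4) {
  set.seed(seed)
  x <- rnorm(n)
  y <- x + rnorm(n, sd = noise)
  z <- y + rnorm(n, sd = noise)
  rbind(X = x, Y = y, Z = z)
}

test_that("discretization handles separated, constant, and affine inputs", {
  v <- rep(c(0, 5, 10), each = 10)
  expr <- rbind(sep = v, flat = rep(2, 30), two = rep(c(1, 9), 15))
  colnames(expr) <- paste0("s", 1:30)
  st <- discretize_expression(expr, seed = 1)
  expect_identical(unname(st["sep", ]), rep(0:2, each = 10))
  expect_true(all(st["flat", ] == 0))
  expect_setequal(unique(st["two", ]), 0:1)
  # positive affine transforms preserve the assignment (same derived seed)
  set.seed(5)
  x <- rnorm(40)
  e1 <- matrix(x, 1, 40); e2 <- matrix(2 * x + 3, 1, 40)
  expect_identical(discretize_expression(e1, seed = 2),
                   discretize_expression(e2, seed = 2))
  # states are ordered by mean expression
  st2 <- discretize_expression(matrix(sort(rnorm(60)), 1), seed = 3)[1, ]
  expect_true(all(diff(st2) >= 0))
})

test_that("single-node score matches the hand multinomial MLE", {
  st <- matrix(0:2, 1, 3, dimnames = list("g", NULL))
  # logL = 3 log(1/3); BIC penalty (2/2) log 3 => total -4 log 3
  expect_equal(score_network(NULL, st, kappa = 0, lambda = 0),
               -4 * log(3), tolerance = 1e-12)
})

test_that("score is decomposable: edge moves change one family only", {
  set.seed(51)
  genes <- paste0("g", 1:6)
  st <- matrix(sample(0:2, 6 * 50, TRUE), 6, 50,
               dimnames = list(genes, NULL))
  edges <- rbind(c("g1", "g2"), c("g2", "g3"), c("g1", "g4"))
  base <- score_network(edges, st, anchored = "g1")
  # adding g5 -> g6 changes only g6's family score
  e2 <- rbind(edges, c("g5", "g6"))
  anch <- genes %in% "g1"
  g0 <- matrix(0L, 0, ncol(st))
  d_family <-
    bn_family_score_cpp(st, 5L, 4L, anch, 1, log(2), g0, -1L) -
    bn_family_score_cpp(st, 5L, integer(0), anch, 1, log(2), g0, -1L)
  expect_equal(score_network(e2, st, anchored = "g1") - base, d_family,
               tolerance = 1e-10)
  expect_error(score_network(rbind(edges, c("g3", "g1")), st), "cyclic")
})

test_that("score equivalence holds without anchors and breaks with them", {
  st <- discretize_expression(chain3(500, seed = 52), seed = 1)
  chains <- list(rbind(c("X", "Y"), c("Y", "Z")),   # X -> Y -> Z
                 rbind(c("Y", "X"), c("Z", "Y")),   # X <- Y <- Z
                 rbind(c("Y", "X"), c("Y", "Z")))   # X <- Y -> Z
  s0 <- vapply(chains, score_network, numeric(1), states = st, lambda = 0)
  expect_equal(max(s0) - min(s0), 0, tolerance = 1e-9)
  # with X anchored, the causal orientation scores strictly higher
  s1 <- vapply(chains, score_network, numeric(1), states = st,
               anchored = "X", lambda = log(2))
  expect_gt(s1[1], max(s1[2:3]))
  # v-structure X -> Y <- Z is NOT equivalent to the chain
  sv <- score_network(rbind(c("X", "Y"), c("Z", "Y")), st, lambda = 0)
  expect_gt(abs(sv - s0[1]), 1e-6)
})

test_that("a genotype instrument at X orients the chain by likelihood", {
  set.seed(56)
  n <- 500
  g <- rbinom(n, 2, 0.4)
  x <- g + rnorm(n)
  y <- x + rnorm(n, sd = 0.4)
  z <- y + rnorm(n, sd = 0.4)
  st <- discretize_expression(rbind(X = x, Y = y, Z = z), seed = 4)
  inst <- matrix(as.integer(g), 1, n, dimnames = list("X", NULL))
  chains <- list(rbind(c("X", "Y"), c("Y", "Z")),
                 rbind(c("Y", "X"), c("Z", "Y")),
                 rbind(c("Y", "X"), c("Y", "Z")))
  s <- vapply(chains, score_network, numeric(1), states = st, lambda = 0,
              instruments = inst)
  # with no orientation prior at all, the instrument alone prefers the
  # causal orientation over both Markov-equivalent alternatives
  expect_gt(s[1], max(s[2:3]))
})

test_that("independent data yields near-empty consensus", {
  set.seed(53)
  st <- matrix(sample(0:2, 2 * 200, TRUE), 2, 200,
               dimnames = list(c("a", "b"), NULL))
  nets <- mcmc_networks(st, n_networks = 100, sweeps = 400, kappa = 1,
                        seed = 4)
  freq <- mean(vapply(nets, nrow, integer(1)) > 0)
  expect_lte(freq, 0.2)
})

test_that("MCMC recovers a planted anchored chain", {
  st <- discretize_expression(chain3(500, seed = 54), seed = 2)
  nets <- mcmc_networks(st, anchored = "X", n_networks = 50, sweeps = 600,
                        seed = 5)
  cons <- consensus_network(nets)
  ret <- paste(cons$from[cons$retained], cons$to[cons$retained])
  expect_true(all(c("X Y", "Y Z") %in% ret))
  # most frequent sampled graph attains the exhaustive-enumeration optimum
  keys <- vapply(nets, edge_key, "")
  top_sampled <- names(sort(table(keys), decreasing = TRUE))[1]
  dags <- all_dags3(c("X", "Y", "Z"))
  expect_length(dags, 25)
  scores <- vapply(dags, score_network, numeric(1), states = st,
                   anchored = "X")
  expect_identical(top_sampled, edge_key(dags[[which.max(scores)]]))
})

test_that("consensus threshold is a closed inequality", {
  ab <- matrix(c("a", "b"), 1, 2)
  none <- matrix(character(0), 0, 2)
  nets300 <- c(rep(list(ab), 300), rep(list(none), 700))
  cons <- consensus_network(nets300, threshold = 0.30)
  expect_equal(cons$frequency, 0.3)
  expect_true(cons$retained)
  nets299 <- c(rep(list(ab), 299), rep(list(none), 701))
  cons2 <- consensus_network(nets299, threshold = 0.30)
  expect_false(cons2$retained)
  consall <- consensus_network(rep(list(ab), 10))
  expect_equal(consall$frequency, 1)
  # retained edge mass is monotone non-increasing in the threshold
  st <- discretize_expression(chain3(200, seed = 55), seed = 3)
  nets <- mcmc_networks(st, n_networks = 30, sweeps = 300, seed = 6)
  cc <- consensus_network(nets, threshold = 0)
  n_ret <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                  function(th) sum(cc$frequency >= th), integer(1))
  expect_true(all(diff(n_ret) <= 0))
})
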