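test_that("local scores match closed forms", {
  # continuous node, no parents, values {-1, +1}: sigma^2 = 1
  d <- cont_data(x = c(-1, 1))
  ll <- local_score(d, "x", spec = score_spec("loglik"))
  expect_equal(ll$loglik, -(2 / 2) * (log(2 * pi) + 1), tolerance = 1e-10)
  expect_equal(ll$nparams, 2)
  bic <- local_score(d, "x", spec = score_spec("bic"))
  expect_equal(bic$score, -2.837877 - 1 * log(2), tolerance = 1e-5)
  # discrete binary node, counts 3/1, no parents
  dd <- mixed_data(data.frame(g = c("a", "a", "a", "b")))
  ls <- local_score(dd, "g", spec = score_spec("loglik"))
  expect_equal(ls$loglik, 3 * log(3 / 4) + log(1 / 4), tolerance = 1e-10)
  expect_equal(ls$nparams, 1)
  # regression score agrees with an independent OLS evaluation
  set.seed(42)
  x <- rnorm(50); y <- 0.7 * x + rnorm(50)
  d2 <- cont_data(x = x, y = y)
  ls2 <- local_score(d2, "y", "x", score_spec("loglik"))
  expect_equal(ls2$loglik, oracle_gauss_loglik(y, x), tolerance = 1e-9)
  expect_equal(ls2$nparams, 3)
})

test_that("degenerate fits are signalled, not scored", {
  # child equals parent exactly: zero residual variance
  x <- rnorm(20)
  d <- cont_data(x = x, y = x)
  ls <- local_score(d, "y", "x")
  expect_true(ls$degenerate)
  expect_true(is.na(ls$score))
  # discrete-parent configuration with fewer rows than parameters
  dm <- mixed_data(data.frame(g = factor(c("a", "a", "a", "b")),
                              y = rnorm(4)))
  expect_true(local_score(dm, "y", "g")$degenerate)
})

test_that("mixed conditional-Gaussian score splits by configuration", {
  set.seed(7)
  n <- 200
  g <- factor(sample(c("a", "b"), n, TRUE))
  x <- rnorm(n)
  y <- ifelse(g == "a", 1 + 0.5 * x, -2 + 2 * x) + rnorm(n)
  d <- mixed_data(data.frame(g = g, x = x, y = y))
  ls <- local_score(d, "y", c("g", "x"), score_spec("loglik"))
  byhand <- oracle_gauss_loglik(y[g == "a"], x[g == "a"]) +
    oracle_gauss_loglik(y[g == "b"], x[g == "b"])
  expect_equal(ls$loglik, byhand, tolerance = 1e-9)
  expect_equal(ls$nparams, 2 * (1 + 2))
  # discrete child with continuous parent is structurally impossible
  expect_error(local_score(d, "g", "x"), "continuous parent")
})

test_that("network scores decompose and obey the penalty ordering", {
  set.seed(11)
  sc <- builtin_scenario("fig1A", beta = 0.5, n = 100, seed = 3)
  d <- sc$full
  dag <- sc$truth
  for (type in c("loglik", "aic", "bic")) {
    spec <- score_spec(type)
    total <- sum(vapply(dag$nodes, function(v)
      local_score(d, v, dag$nodes[dag$amat[, v] == 1L], spec)$score,
      numeric(1)))
    expect_equal(network_score(d, dag, spec), total, tolerance = 1e-9)
  }
  # loglik >= aic >= bic whenever n >= 8, and scores negative here
  s_ll <- network_score(d, dag, score_spec("loglik"))
  s_aic <- network_score(d, dag, score_spec("aic"))
  s_bic <- network_score(d, dag, score_spec("bic"))
  expect_true(s_ll >= s_aic)
  expect_true(s_aic >= s_bic)
  expect_true(s_bic < 0)
})

test_that("weighted score adds log-priors exactly", {
  set.seed(5)
  x <- rnorm(300); y <- 0.6 * x + rnorm(300)
  d <- cont_data(A = x, B = y)
  fwd <- bn_dag(c("A", "B"), "A->B")
  rev <- bn_dag(c("A", "B"), "B->A")
  cons <- constraint_set(priors = data.frame(from = "A", to = "B", p = 0.8))
  # Gaussian BIC is score-equivalent across the two orientations, so the
  # entire difference is the prior odds log(0.8/0.2) = log 4
  expect_equal(network_score(d, fwd, constraints = cons) -
                 network_score(d, rev, constraints = cons),
               log(4), tolerance = 1e-8)
  # empty priors: weighted score equals plain BIC
  expect_equal(network_score(d, fwd, constraints = constraint_set()),
               network_score(d, fwd), tolerance = 1e-12)
  # prior of 1 contributes log 1 = 0
  cons1 <- constraint_set(priors = data.frame(from = "A", to = "B", p = 1))
  expect_equal(network_score(d, fwd, constraints = cons1),
               network_score(d, fwd), tolerance = 1e-12)
  # prior of 0 on a present edge rejects the network outright
  cons0 <- constraint_set(priors = data.frame(from = "A", to = "B", p = 0))
  expect_equal(network_score(d, fwd, constraints = cons0), -Inf)
  # priors demand the BIC score
  expect_error(network_score(d, fwd, score_spec("aic"), cons), "BIC")
})

test_that("score_delta equals full rescoring on random moves", {
  set.seed(21)
  nodes <- paste0("V", 1:6)
  dag0 <- bn_dag(nodes, c("V1->V2", "V2->V3", "V4->V5"))
  m <- sim_model(dag0, beta = 0.5)
  d <- simulate_data(m, 150, seed = 8)
  cons <- constraint_set(priors = data.frame(from = "V1", to = "V2", p = 0.7))
  cache <- new.env()
  amat <- dag0$amat
  checked <- 0
  for (rep in 1:100) {
    dag <- bn_dag(nodes); dag$amat <- amat
    # propose a random valid move
    mv <- NULL
    for (tries in 1:50) {
      i <- sample(6, 1); j <- sample(setdiff(1:6, i), 1)
      type <- sample(c("add", "delete", "reverse"), 1)
      a2 <- tryCatch(bnimpute:::apply_move_amat(amat, type, i, j),
                     error = function(e) NULL)
      if (!is.null(a2)) { mv <- list(type = type, from = nodes[i], to = nodes[j]); break }
    }
    if (is.null(mv)) next
    delta <- score_delta(d, dag, mv, score_spec("bic"), cons, cache)
    dag2 <- bn_dag(nodes)
    dag2$amat <- bnimpute:::apply_move_amat(amat, mv$type,
                                            match(mv$from, nodes),
                                            match(mv$to, nodes))
    full <- network_score(d, dag2, score_spec("bic"), cons) -
      network_score(d, dag, score_spec("bic"), cons)
    expect_equal(delta, full, tolerance = 1e-9)
    amat <- dag2$amat
    checked <- checked + 1
  }
  expect_gte(checked, 90)
})

test_that("inverse moves cancel exactly", {
  set.seed(3)
  d <- cont_data(A = rnorm(50), B = rnorm(50))
  dag <- bn_dag(c("A", "B"))
  d1 <- score_delta(d, dag, list(type = "add", from = "A", to = "B"))
  dag2 <- bn_dag(c("A", "B"), "A->B")
  d2 <- score_delta(d, dag2, list(type = "delete", from = "A", to = "B"))
  expect_equal(d1 + d2, 0, tolerance = 1e-12)
})

test_that("score equivalence holds across Markov classes on Gaussian data", {
  dags <- oracle_all_dags(3)
  nodes <- c("A", "B", "C")
  set.seed(19)
  gen <- bn_dag(nodes, c("A->B", "B->C"))
  d <- simulate_data(sim_model(gen, beta = 0.6), 400, seed = 77)
  scores <- cp_keys <- character(0)
  vals <- numeric(0)
  for (a in dags) {
    dimnames(a) <- list(nodes, nodes)
    dag <- bn_dag(nodes); dag$amat <- a
    vals <- c(vals, network_score(d, dag))
    cp_keys <- c(cp_keys, paste(cpdag(dag)$amat, collapse = ""))
  }
  for (k in unique(cp_keys)) {
    v <- vals[cp_keys == k]
    expect_lt(max(v) - min(v), 1e-8)
  }
})
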