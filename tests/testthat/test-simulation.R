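test_that("the simulator is seed-deterministic and matches SEM moments", {
  dag <- bn_dag(c("A", "B"), "A->B")
  m <- sim_model(dag, beta = 0.5)
  d1 <- simulate_data(m, 500, seed = 3)
  d2 <- simulate_data(m, 500, seed = 3)
  expect_identical(d1$values, d2$values)
  # cov(A, B) = beta * var(A); check within 3 Monte-Carlo standard errors
  big <- simulate_data(m, 20000, seed = 9)
  a <- big$values$A; b <- big$values$B
  se <- sqrt((1 + 2 * 0.5^2) / 20000)  # approx se of sample cov, var(A)=1
  expect_lt(abs(cov(a, b) - 0.5 * 1), 3 * se)
  expect_lt(abs(var(b) - (0.5^2 + 1)), 4 * sqrt(2 / 20000) * var(b))
})

test_that("beta = 0 gives marginal independence; colliders leave a signature", {
  nodes <- c("A", "B", "C")
  ok <- 0
  for (r in 1:20) {
    d <- simulate_data(sim_model(bn_dag(nodes, c("A->B", "C->B")), beta = 0),
                       5000, seed = 40 + r)
    cc <- cor(as.matrix(as.data.frame(lapply(d$values, as.numeric))))
    ok <- ok + all(abs(cc[upper.tri(cc)]) < 0.05)
  }
  expect_gte(ok, 19)
  # collider: corr(A, C) ~ 0 marginally but not within slices of B
  d <- simulate_data(sim_model(bn_dag(nodes, c("A->B", "C->B")), beta = 0.5),
                     5000, seed = 77)
  a <- d$values$A; b <- d$values$B; cc <- d$values$C
  expect_lt(abs(cor(a, cc)), 0.05)
  low <- b < stats::median(b)
  expect_gt(max(abs(cor(a[low], cc[low])), abs(cor(a[!low], cc[!low]))), 0.1)
})

test_that("SNP nodes are dosages and discrete nodes follow their CPT", {
  dag <- bn_dag(variable_spec(c("S", "G"), c("c", "d"),
                              levels = list(G = c("lo", "hi"))),
                NULL)
  cpt <- list(G = list(parents = character(),
                       table = matrix(c(0.3, 0.7), 1,
                                      dimnames = list(NULL, c("lo", "hi")))))
  m <- sim_model(dag, snp = "S", allele_freq = 0.3, cpt = cpt)
  d <- simulate_data(m, 20000, seed = 5)
  expect_true(all(d$values$S %in% 0:2))
  expect_true(d$vars$genetic[d$vars$name == "S"])
  expect_lt(abs(mean(d$values$S) - 2 * 0.3), 0.02)
  expect_lt(abs(mean(d$values$G == "hi") - 0.7), 0.02)
})

test_that("missingness injectors match their patterns exactly", {
  d <- simulate_data(sim_model(bn_dag(c("A", "B", "C"))), 500, seed = 2)
  # fixed count: exactly 450 of 500 rows lose the variable
  p1 <- missingness_pattern("fixed_count", "B", count = 450)
  m1 <- inject_missingness(d, p1, seed = 3)
  expect_equal(sum(!m1$observed[, "B"]), 450)
  expect_true(all(m1$observed[, c("A", "C")]))
  # split: every affected row misses exactly one of the two variables
  p2 <- missingness_pattern("split", c("A", "C"), count = 450)
  m2 <- inject_missingness(d, p2, seed = 4)
  miss <- !m2$observed
  expect_equal(sum(rowSums(miss) > 0), 450)
  expect_true(all(rowSums(miss) <= 1))
  expect_equal(sum(miss[, "A"]) + sum(miss[, "C"]), 450)
  expect_lte(abs(sum(miss[, "A"]) - sum(miss[, "C"])), 1)  # 50/50 split
  # probability 0 leaves the data unchanged
  p0 <- missingness_pattern("prob", "A", prob = 0)
  expect_true(all(inject_missingness(d, p0, seed = 5)$observed))
  # MAR: masking rate rises with the covariate through the logistic link
  pm <- missingness_pattern("mar", "B", prob = 0.3, covariate = "A",
                            slope = 2)
  m3 <- inject_missingness(d, pm, seed = 6)
  hi <- d$values$A > stats::quantile(d$values$A, 2 / 3)
  lo <- d$values$A < stats::quantile(d$values$A, 1 / 3)
  expect_gt(mean(!m3$observed[hi, "B"]), mean(!m3$observed[lo, "B"]))
  expect_error(inject_missingness(d, missingness_pattern(
    "fixed_count", "A", count = 600), seed = 1), "exceeds")
})

test_that("the scenario catalogue reproduces the stated shapes", {
  sc <- builtin_scenario("fig1A", beta = 0.5, seed = 8)
  miss <- !sc$data$observed
  expect_equal(dim(sc$data), c(2000, 3))
  expect_equal(sum(rowSums(miss) > 0), 1800)   # 1800 of 2000 individuals
  expect_true(all(rowSums(miss) <= 1))         # one variable per individual
  expect_equal(sum(miss[, "C"]), 1800)         # all in the starred column
  sc2 <- builtin_scenario("collider5", beta = 0.4, seed = 8)
  expect_equal(bnimpute:::edge_key(dag_edges(sc2$truth)),
               c("A->B", "C->B", "C->D", "E->D"))
  expect_equal(sum(!sc2$data$observed[, "B"]) + sum(!sc2$data$observed[, "D"]),
               1800)
  sc3 <- builtin_scenario("omics31", beta = 0.3, seed = 8)
  expect_equal(ncol(sc3$data$observed), 31)
  expect_equal(sum(sc3$data$vars$genetic), 20)
  excols <- grep("^ex", sc3$data$vars$name, value = TRUE)
  rate <- mean(!sc3$data$observed[, excols])
  expect_lt(abs(rate - 0.2), 3 * sqrt(0.2 * 0.8 / (500 * 10)))
  expect_true(all(sc3$data$observed[, !grepl("^ex", sc3$data$vars$name)]))
  expect_error(builtin_scenario("nope"), "unknown scenario")
})

test_that("BIF files round-trip and recover their CPTs from samples", {
  bif <- c(
    "network toy {", "}",
    "variable rain {",
    "  type discrete [ 2 ] { yes, no };", "}",
    "variable sprinkler {",
    "  type discrete [ 2 ] { on, off };", "}",
    "variable wet {",
    "  type discrete [ 2 ] { yes, no };", "}",
    "probability ( rain ) {", "  table 0.25, 0.75;", "}",
    "probability ( sprinkler | rain ) {",
    "  ( yes ) 0.05, 0.95;",
    "  ( no ) 0.6, 0.4;", "}",
    "probability ( wet | rain, sprinkler ) {",
    "  ( yes, on ) 0.99, 0.01;",
    "  ( yes, off ) 0.8, 0.2;",
    "  ( no, on ) 0.9, 0.1;",
    "  ( no, off ) 0.05, 0.95;", "}")
  f <- withr::local_tempfile(fileext = ".bif")
  writeLines(bif, f)
  m <- load_bif(f)
  expect_equal(sort(m$dag$nodes), c("rain", "sprinkler", "wet"))
  for (nm in names(m$cpt))
    expect_equal(unname(rowSums(m$cpt[[nm]]$table)), rep(1, nrow(m$cpt[[nm]]$table)))
  # lossless write/read round trip
  f2 <- withr::local_tempfile(fileext = ".bif")
  write_bif(m, f2)
  m2 <- load_bif(f2)
  expect_equal(m2$cpt, m$cpt)
  expect_equal(dag_edges(m2$dag), dag_edges(m$dag))
  # parameter recovery from forward samples at n = 20000
  d <- simulate_data(m, 20000, seed = 4)
  expect_lt(abs(mean(d$values$rain == "yes") - 0.25), 0.03)
  r_yes <- d$values$rain == "yes"
  expect_lt(abs(mean(d$values$sprinkler[r_yes] == "on") - 0.05), 0.03)
  expect_lt(abs(mean(d$values$sprinkler[!r_yes] == "on") - 0.6), 0.03)
  both <- r_yes & d$values$sprinkler == "on"
  expect_lt(abs(mean(d$values$wet[both] == "yes") - 0.99), 0.03)
})

test_that("malformed BIF input is rejected with a line number", {
  f <- withr::local_tempfile(fileext = ".bif")
  # undeclared parent level
  writeLines(c("network x {", "}",
               "variable a {", "  type discrete [ 2 ] { y, n };", "}",
               "variable b {", "  type discrete [ 2 ] { y, n };", "}",
               "probability ( a ) {", "  table 0.5, 0.5;", "}",
               "probability ( b | a ) {",
               "  ( y ) 0.1, 0.9;",
               "  ( maybe ) 0.2, 0.8;", "}"), f)
  expect_error(load_bif(f), "line.*undeclared level")
  # CPT rows that do not sum to one
  writeLines(c("variable a {", "  type discrete [ 2 ] { y, n };", "}",
               "probability ( a ) {", "  table 0.5, 0.2;", "}"), f)
  expect_error(load_bif(f), "sum to 1")
})

test_that("Gaussian network text format round-trips", {
  dag <- bn_dag(c("A", "B", "C"), c("A->B", "B->C"))
  cf <- matrix(0, 3, 3, dimnames = list(dag$nodes, dag$nodes))
  cf["A", "B"] <- 0.7; cf["B", "C"] <- -0.4
  m <- sim_model(dag, coef = cf, noise_sd = c(1, 2, 0.5))
  f <- withr::local_tempfile(fileext = ".txt")
  write_gaussian_network(m, f)
  m2 <- read_gaussian_network(f)
  expect_equal(m2$coef, m$coef)
  expect_equal(unname(m2$noise_sd), c(1, 2, 0.5))
  expect_equal(dag_edges(m2$dag), dag_edges(m$dag))
})
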