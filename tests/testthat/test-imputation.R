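test_that("complete data pass through imputation untouched", {
  set.seed(1)
  d <- cont_data(A = rnorm(40), B = rnorm(40))
  res <- impute_nn(d, imputation_config(seed = 2))
  expect_equal(res$data$values, d$values)
  expect_equal(nrow(res$provenance), 0)
})

test_that("imputation preserves observed values and copies donors", {
  for (r in 1:20) {
    sc <- builtin_scenario("collider5", beta = 0.5, n = 300, seed = 900 + r)
    res <- impute_nn(sc$data, imputation_config(seed = r))
    out <- res$data
    expect_true(all(out$observed))
    # observed entries never altered
    obs <- sc$data$observed
    for (v in colnames(obs))
      expect_equal(out$values[[v]][obs[, v]], sc$data$values[[v]][obs[, v]])
    # donor-copy: every imputed value appears among observed values of the
    # same variable, hence inside the observed range
    for (v in colnames(obs)) {
      imp <- out$values[[v]][!obs[, v]]
      pool <- sc$data$values[[v]][obs[, v]]
      expect_true(all(imp %in% pool))
    }
    # provenance names real donors holding the copied value
    pv <- res$provenance
    expect_equal(nrow(pv), sum(!obs))
    idx <- cbind(match(pv$individual, rownames(out$values)),
                 match(pv$variable, out$vars$name))
    don <- cbind(match(pv$donor, rownames(out$values)),
                 match(pv$variable, out$vars$name))
    expect_equal(as.matrix(out$values)[idx], as.matrix(sc$data$values)[don])
  }
})

test_that("imputation does not depend on the physical row order", {
  sc <- builtin_scenario("collider5", beta = 0.4, n = 250, seed = 77)
  d1 <- sc$data
  set.seed(123)
  perm <- sample(d1$n)
  d2 <- mixed_data(d1$values[perm, , drop = FALSE], d1$vars)
  r1 <- impute_nn(d1, imputation_config(seed = 5))
  r2 <- impute_nn(d2, imputation_config(seed = 5))
  expect_equal(r1$data$values,
               r2$data$values[rownames(r1$data$values), , drop = FALSE])
  # same donors per (individual, variable); only provenance order differs
  k1 <- paste(r1$provenance$individual, r1$provenance$variable)
  k2 <- paste(r2$provenance$individual, r2$provenance$variable)
  expect_setequal(k1, k2)
  expect_equal(r1$provenance$donor, r2$provenance$donor[match(k1, k2)])
})

test_that("variants behave as documented", {
  sc <- builtin_scenario("collider5", beta = 0.4, n = 250, seed = 31)
  for (variant in c("default", "complete_training", "all_nn")) {
    res <- impute_nn(sc$data, imputation_config(variant = variant, seed = 9))
    expect_true(all(res$data$observed))
  }
  # complete_training needs complete individuals
  allm <- mixed_data(data.frame(x = c(1, NA, 2), y = c(NA, 1, NA)))
  expect_error(impute_nn(allm, imputation_config(variant = "complete_training",
                                                 seed = 1)),
               "complete")
  # a variable observed nowhere is unimputable, named in the error
  bad <- mixed_data(data.frame(x = c(1, 2, 3), y = rep(NA_real_, 3)))
  expect_error(impute_nn(bad, imputation_config(seed = 1)), "y")
})

test_that("adjusted nearby variables recover the regression structure", {
  # y = 2x + 3z + noise(var 0.01): v = y - beta_x x should track z closely
  set.seed(8)
  n <- 200
  x <- rnorm(n); z <- rnorm(n); y <- 2 * x + 3 * z + rnorm(n, 0, 0.1)
  vals <- data.frame(x = x, z = z, y = y)
  vals$z[1] <- NA
  d <- mixed_data(vals)
  dag <- bn_dag(c("x", "z", "y"), c("x->y", "z->y"))
  nb <- select_nearby_variables(dag, d, 1, "z")
  expect_equal(nb$labels, "adj:y")
  tm <- nb$terms[[1]]
  beta_x <- (y[-1] - tm$values[-1])[1] / x[-1][1]   # recover the coefficient
  expect_lt(abs(beta_x - 2), 0.05)
  expect_gt(cor(tm$values[-1], z[-1]), 0.99)
  # child with the target as only parent stays unadjusted
  dag2 <- bn_dag(c("x", "z", "y"), c("z->y"))
  nb2 <- select_nearby_variables(dag2, d, 1, "z")
  expect_equal(nb2$labels, "y")
  # no adjacent observed variables: empty set, fallback donor is random
  dag3 <- bn_dag(c("x", "z", "y"))
  nb3 <- select_nearby_variables(dag3, d, 1, "z")
  expect_equal(length(nb3$terms), 0)
  don <- find_nearest_neighbour(d, 1, "z", nb3)
  expect_true(don$donor %in% rownames(vals)[-1])
  expect_true(is.na(don$distance))
})

test_that("distances follow the printed formula", {
  vals <- data.frame(w = c(1, 3, 5, 1), g = factor(c("a", "b", "a", "a")),
                     h = factor(c("x", "x", "y", "x")),
                     z = c(0.5, 1, 2, NA))
  d <- mixed_data(vals)
  dag <- bn_dag(d$vars, c("w->z", "g->w", "h->w"))
  # nearby set for the index case: one continuous variable
  nb <- select_nearby_variables(dag, d, 4, "z")
  expect_setequal(nb$labels, "w")        # g,h are not adjacent to z
  nb$terms[[1]]$variance <- 2            # printed example: (3-1)^2 / 2 = 2
  expect_equal(nn_distance(d, 2, 1, nb), 2)
  expect_equal(nn_distance(d, 1, 1, nb), 0)   # identical rows
  # discrete 0/1 rule: one matching + one differing = 1
  dag2 <- bn_dag(d$vars, c("g->w", "h->w"))
  vals2 <- vals; vals2$w[1] <- NA
  d2 <- mixed_data(vals2)
  nb2 <- select_nearby_variables(dag2, d2, 1, "w")
  expect_setequal(nb2$labels, c("g", "h"))
  expect_equal(nn_distance(d2, 3, 2, nb2), 0 + 1 + 1)  # differs on both
  expect_equal(nn_distance(d2, 4, 2, nb2), 1 + 0)      # differs on g only
})

test_that("nearest neighbour is the distance argmin with uniform ties", {
  # 4-candidate toy table: argmin agrees with exhaustive computation
  vals <- data.frame(a = c(0, 0.1, 2, -1, 0.05), z = c(NA, 1, 2, 3, 4))
  d <- mixed_data(vals)
  dag <- bn_dag(c("a", "z"), "a->z")
  nb <- select_nearby_variables(dag, d, 1, "z")
  dists <- vapply(2:5, function(i) nn_distance(d, i, 1, nb), numeric(1))
  set.seed(2)
  sel <- find_nearest_neighbour(d, 1, "z", nb)
  expect_equal(sel$donor, rownames(vals)[1 + which.min(dists)])
  expect_equal(sel$distance, min(dists))
  # all-tied distances: each candidate chosen about 1/k of the time
  vals2 <- data.frame(a = c(1, 1, 1, 1), z = c(NA, 10, 20, 30))
  d2 <- mixed_data(vals2)
  nb2 <- select_nearby_variables(bn_dag(c("a", "z"), "a->z"), d2, 1, "z")
  set.seed(4)
  picks <- table(vapply(1:1000, function(.)
    find_nearest_neighbour(d2, 1, "z", nb2)$donor, character(1)))
  expect_equal(length(picks), 3)
  se <- sqrt((1 / 3) * (2 / 3) / 1000)
  expect_true(all(abs(picks / 1000 - 1 / 3) < 3 * se))
})

test_that("subset fraction controls the training subset size", {
  cfg <- imputation_config(subset_fraction = 0.5, seed = 3)
  expect_equal(cfg$subset_fraction, 0.5)
  expect_error(imputation_config(subset_fraction = 0), "subset_fraction")
  expect_error(imputation_config(subset_fraction = 1.2), "subset_fraction")
})
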