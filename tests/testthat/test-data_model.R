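test_that("structure validation reports the printed rules", {
  vars <- variable_spec(c("A", "B", "C"), c("c", "c", "d"))
  # empty graph, empty constraints: vacuously valid
  v <- validate_structure(bn_dag(vars))
  expect_true(v$valid)
  expect_equal(nrow(v$violations), 0)
  # continuous parent of a discrete node
  v <- validate_structure(bn_dag(vars, c("A->C")))
  expect_false(v$valid)
  expect_true("mixed-parent" %in% v$violations$rule)
  # 3-cycle (built by hand: bn_dag itself permits any directed edges)
  dag <- bn_dag(variable_spec(c("A", "B", "C")))
  dag$amat["A", "B"] <- dag$amat["B", "C"] <- dag$amat["C", "A"] <- 1L
  v <- validate_structure(dag)
  expect_false(v$valid)
  expect_true("cycle" %in% v$violations$rule)
  # genetic in-edge
  gvars <- variable_spec(c("G", "X"), genetic = c(TRUE, FALSE))
  v <- validate_structure(bn_dag(gvars, "X->G"))
  expect_true("genetic-in-edge" %in% v$violations$rule)
  # blacklist hit and whitelist miss
  vars2 <- variable_spec(c("A", "B", "C"))
  cons <- constraint_set(whitelist = rbind(c("A", "B")),
                         blacklist = rbind(c("B", "C")))
  v <- validate_structure(bn_dag(vars2, "B->C"), cons)
  expect_setequal(v$violations$rule, c("blacklist", "whitelist-missing"))
  # both-direction whitelist is satisfied by either orientation
  cons2 <- constraint_set(whitelist = rbind(c("A", "B"), c("B", "A")))
  expect_true(validate_structure(bn_dag(vars2, "B->A"), cons2)$valid)
  # unknown node names in constraints are a configuration error
  expect_error(validate_structure(bn_dag(vars2),
                                  constraint_set(blacklist = rbind(c("A", "Z")))),
               "unknown")
})

test_that("constraint sets enforce their invariants", {
  expect_error(constraint_set(whitelist = rbind(c("A", "B")),
                              blacklist = rbind(c("A", "B"))),
               "whitelist and blacklist")
  # reverse-direction priors must sum to one
  expect_error(constraint_set(priors = data.frame(
    from = c("A", "B"), to = c("B", "A"), p = c(0.8, 0.5))),
    "sum to 1")
  cs <- constraint_set(priors = data.frame(
    from = c("A", "B"), to = c("B", "A"), p = c(0.8, 0.2)))
  expect_equal(nrow(cs$priors), 1)   # stored once; reverse is implicit
  expect_error(constraint_set(priors = data.frame(from = "A", to = "B",
                                                  p = 1.2)),
               "\\[0, 1\\]")
  # whitelist into a genetic node is absolute, not a reported violation
  gvars <- variable_spec(c("G", "X"), genetic = c(TRUE, FALSE))
  expect_error(
    validate_structure(bn_dag(gvars),
                       constraint_set(whitelist = rbind(c("X", "G")))),
    "genetic")
})

test_that("cpdag matches the Markov equivalence classes of small DAGs", {
  # chain: no v-structure, both edges undirected
  cp <- cpdag(bn_dag(c("A", "B", "C"), c("A->B", "B->C")))
  expect_equal(sum(cp$amat == 1L & t(cp$amat) == 1L), 4) # 2 undirected edges
  # collider: both edges stay directed
  cp <- cpdag(bn_dag(c("A", "B", "C"), c("A->B", "C->B")))
  expect_equal(unname(cp$amat["A", "B"]), 1L)
  expect_equal(unname(cp$amat["B", "A"]), 0L)
  expect_equal(unname(cp$amat["C", "B"]), 1L)
  # chain and reversed chain share a CPDAG; chain and collider do not
  c1 <- cpdag(bn_dag(c("A", "B", "C"), c("A->B", "B->C")))
  c2 <- cpdag(bn_dag(c("A", "B", "C"), c("C->B", "B->A")))
  c3 <- cpdag(bn_dag(c("A", "B", "C"), c("A->B", "C->B")))
  expect_true(all(c1$amat == c2$amat))
  expect_false(all(c1$amat == c3$amat))
})

test_that("cpdag equality partitions all 4-node DAGs exactly as d-separation", {
  dags <- oracle_all_dags(4)
  expect_equal(length(dags), 543)      # known labelled-DAG count a(4)
  nodes <- c("A", "B", "C", "D")
  cps <- lapply(dags, function(a) {
    dag <- bn_dag(nodes)
    dimnames(a) <- list(nodes, nodes)
    dag$amat <- a
    cpdag(dag)$amat
  })
  sigs <- lapply(dags, oracle_ci_signature)
  cp_key <- vapply(cps, function(m) paste(m, collapse = ""), character(1))
  ci_key <- vapply(sigs, function(s) paste(as.integer(s), collapse = ""),
                   character(1))
  # identical equivalence partition: same-class iff same CI statements
  expect_equal(as.integer(factor(cp_key, levels = unique(cp_key))),
               as.integer(factor(ci_key, levels = unique(ci_key))))
})

test_that("cpdag is idempotent over consensus DAGs of its own class", {
  dags <- oracle_all_dags(3)
  expect_equal(length(dags), 25)
  nodes <- c("A", "B", "C")
  for (a in dags) {
    dimnames(a) <- list(nodes, nodes)
    dag <- bn_dag(nodes); dag$amat <- a
    cp <- cpdag(dag)
    # every DAG consistent with the CPDAG maps back to the same CPDAG
    for (b in dags) {
      skel_b <- (b + t(b)) > 0
      skel_cp <- (cp$amat + t(cp$amat)) > 0
      dimnames(b) <- list(nodes, nodes)
      if (!all(skel_b == skel_cp)) next
      # b consistent: every directed cpdag edge agrees
      dir_edges <- which(cp$amat == 1L & t(cp$amat) == 0L)
      if (!all(b[dir_edges] == 1L)) next
      dag_b <- bn_dag(nodes); dag_b$amat <- b
      if (!isTRUE(all.equal(oracle_ci_signature(a), oracle_ci_signature(b))))
        next
      expect_true(all(cpdag(dag_b)$amat == cp$amat))
    }
  }
})

test_that("complete_rows implements the reduced-data strategy", {
  df <- data.frame(x = c(1, 2, NA, 4), y = c(NA, 1, 2, 3))
  md <- mixed_data(df)
  red <- complete_rows(md)
  expect_equal(red$n, 2)
  expect_equal(rownames(red$values), c("2", "4"))  # identifiers preserved
  # identity on complete data, idempotent
  full <- mixed_data(data.frame(x = 1:3, y = 4:6))
  expect_equal(complete_rows(full)$values, full$values)
  expect_equal(complete_rows(red)$values, red$values)
  # all rows incomplete: explicit empty signal, fitting refuses
  allm <- mixed_data(data.frame(x = c(1, NA), y = c(NA, 2)))
  expect_warning(empty <- complete_rows(allm), "no individuals")
  expect_equal(empty$n, 0)
  expect_error(suppressWarnings(greedy_search(empty)), "empty")
})

test_that("mixed_data enforces typing and tracks missingness", {
  df <- data.frame(x = c(1.5, NA), g = c("a", "b"), stringsAsFactors = FALSE)
  md <- mixed_data(df)
  expect_equal(md$vars$kind, c("continuous", "discrete"))
  expect_equal(unname(md$observed[, "x"]), c(TRUE, FALSE))
  # undeclared observed levels appended with a warning
  vars <- variable_spec(c("g"), "d", levels = list(g = c("a", "b")))
  expect_warning(md2 <- mixed_data(data.frame(g = c("a", "b", "c")), vars),
                 "undeclared")
  expect_equal(levels(md2$values$g), c("a", "b", "c"))
  expect_error(mixed_data(data.frame(g = c("a", "a"))), "fewer than 2")
  expect_error(variable_spec(c("x", "x")), "unique")
})
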