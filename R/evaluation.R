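# Recall/precision metrics on directed edges, observational-equivalence
# verdicts, simple fill-in baselines, and the head-to-head comparison
# harness over the built-in scenarios.

#' Recall and precision of directed edges
#'
#' Recall is the proportion of true edges retrieved in the estimated
#' network; precision is the proportion of retrieved edges that are true.
#' Only exact directed matches count: a reversed edge is neither recalled
#' nor correct.  Precision is undefined (`NA`) when the estimate has no
#' edges; such replicates are excluded from comparison averages.
#'
#' @param truth,estimate [bn_dag()] objects over the same node set.
#' @return Object of class `evaluation_result`: list with `recall`,
#'   `precision`, `tp`, `n_true`, `n_est` and `labels`, a data frame
#'   classifying every edge as `true`, `reversed`, `absent` (truth edges) or
#'   `extra` (estimate-only edges).
#' @export
recall_precision <- function(truth, estimate) {
  stopifnot(inherits(truth, "bn_dag"), inherits(estimate, "bn_dag"))
  if (!setequal(truth$nodes, estimate$nodes))
    stop("truth and estimate must share the same node set")
  te <- dag_edges(truth)
  ee <- dag_edges(estimate)
  tk <- edge_key(te); ek <- edge_key(ee)
  rk <- paste(te[, 2], te[, 1], sep = "->")   # reversed truth edges
  lab_truth <- ifelse(tk %in% ek, "true",
                      ifelse(rk %in% ek, "reversed", "absent"))
  extra <- !(ek %in% tk) & !(ek %in% rk)
  labels <- rbind(
    if (nrow(te)) data.frame(from = te[, 1], to = te[, 2], label = lab_truth,
                             stringsAsFactors = FALSE),
    if (any(extra)) data.frame(from = ee[extra, 1], to = ee[extra, 2],
                               label = "extra", stringsAsFactors = FALSE))
  if (is.null(labels))
    labels <- data.frame(from = character(), to = character(),
                         label = character(), stringsAsFactors = FALSE)
  tp <- sum(lab_truth == "true")
  structure(list(
    recall = if (nrow(te)) tp / nrow(te) else NA_real_,
    precision = if (nrow(ee)) tp / nrow(ee) else NA_real_,
    tp = tp, n_true = nrow(te), n_est = nrow(ee), labels = labels),
    class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("recall %.3f  precision %s  (TP %d / true %d / retrieved %d)\n",
              x$recall,
              if (is.na(x$precision)) "NA" else sprintf("%.3f", x$precision),
              x$tp, x$n_true, x$n_est))
  invisible(x)
}

#' Are two DAGs observationally equivalent?
#'
#' Networks representing the same conditional dependencies and
#' independencies cannot be distinguished by score and are all considered
#' correct: two DAGs are equivalent iff their CPDAGs are identical.
#'
#' @inheritParams recall_precision
#' @return Logical.
#' @export
correct_or_equivalent <- function(truth, estimate) {
  if (!setequal(truth$nodes, estimate$nodes))
    stop("truth and estimate must share the same node set")
  est <- estimate
  if (!identical(est$nodes, truth$nodes)) {
    # align node order before comparing patterns
    est <- bn_dag(truth$vars, dag_edges(estimate))
  }
  cpdag_equal(cpdag(truth), cpdag(est))
}

#' Simple fill-in baselines for missing data
#'
#' `"random"` replaces each missing entry with a value sampled with
#' replacement from the variable's observed values; `"mean"` uses the
#' observed mean for continuous variables and the modal level for discrete
#' ones (first level in declaration order on ties).
#'
#' @param data a [mixed_data()].
#' @param method `"random"` or `"mean"`.
#' @param seed optional seed (random fill only).
#' @return A complete `mixed_data`; observed entries are unchanged.
#' @export
baseline_fill <- function(data, method = c("random", "mean"), seed = NULL) {
  stopifnot(inherits(data, "mixed_data"))
  method <- match.arg(method)
  with_seed(seed, {
    vals <- data$values
    for (j in seq_along(vals)) {
      ms <- which(!data$observed[, j])
      if (!length(ms)) next
      obs <- vals[[j]][data$observed[, j]]
      if (!length(obs)) stop("variable '", names(vals)[j],
                             "' has no observed values")
      vals[[j]][ms] <- if (method == "random")
        sample(obs, length(ms), replace = TRUE)
      else if (is.numeric(obs)) mean(obs)
      else names(which.max(table(obs)))
    }
    mixed_data(vals, data$vars)
  })
}

#' Head-to-head comparison of missing-data strategies
#'
#' For each effect strength and replicate: simulate a scenario, inject its
#' missingness pattern, apply each strategy, learn the best-fit network and
#' measure recall, precision and whether the result is the generating
#' network or an observational equivalent.  Strategies: `full` (the data
#' before masking), `reduced` (complete rows only), `random`/`mean`
#' ([baseline_fill()]), `all_nn`, `imputed` (default algorithm) and
#' `imputed_ct` (complete training data).  Fully seeded; replicate-level
#' failures (e.g. no complete rows) are recorded as `NA` rows.
#'
#' @param scenario a [builtin_scenario()] name.
#' @param methods subset of
#'   `c("full","reduced","random","mean","all_nn","imputed","imputed_ct")`.
#' @param replicates replicates per effect strength.
#' @param beta_grid effect strengths to sweep.
#' @param seed master seed.
#' @param n scenario sample-size override.
#' @param spec,config score and search settings for the outer fit.
#' @param subset_fraction training-subset fraction for the imputation
#'   strategies.
#' @return Data frame with one row per (beta, replicate, method): columns
#'   `scenario`, `method`, `beta`, `replicate`, `recall`, `precision`,
#'   `correct`.  Summarise with [summarise_comparison()].
#' @export
run_comparison <- function(scenario, methods = c("full", "reduced", "imputed"),
                           replicates = 10, beta_grid = 0.5, seed = 1,
                           n = NULL, spec = score_spec(),
                           config = search_config(),
                           subset_fraction = 0.9) {
  all_methods <- c("full", "reduced", "random", "mean", "all_nn", "imputed",
                   "imputed_ct")
  methods <- match.arg(methods, all_methods, several.ok = TRUE)
  out <- list()
  for (bi in seq_along(beta_grid)) {
    beta <- beta_grid[bi]
    for (r in seq_len(replicates)) {
      s0 <- substream_seed(seed, bi * 100003 + r)
      sc <- builtin_scenario(scenario, beta = beta, n = n, seed = s0)
      for (mth in methods) {
        row <- evaluate_method(sc, mth, spec, config, subset_fraction,
                               substream_seed(s0, match(mth, all_methods)))
        out[[length(out) + 1L]] <- data.frame(
          scenario = scenario, method = mth, beta = beta, replicate = r,
          recall = row$recall, precision = row$precision,
          correct = row$correct, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

evaluate_method <- function(sc, method, spec, config, subset_fraction,
                            seed) {
  fail <- list(recall = NA_real_, precision = NA_real_, correct = NA)
  suppressWarnings(
    tryCatch(evaluate_method_core(sc, method, spec, config, subset_fraction,
                                  seed),
             error = function(e) fail))
}

evaluate_method_core <- function(sc, method, spec, config, subset_fraction,
                                 seed) {
  dat <- switch(method,
    full = sc$full,
    reduced = complete_rows(sc$data),
    random = baseline_fill(sc$data, "random", seed = seed),
    mean = baseline_fill(sc$data, "mean"),
    all_nn = impute_nn(sc$data, imputation_config(
      subset_fraction, "all_nn", seed = seed, search = config,
      score = spec))$data,
    imputed = impute_nn(sc$data, imputation_config(
      subset_fraction, "default", seed = seed, search = config,
      score = spec))$data,
    imputed_ct = impute_nn(sc$data, imputation_config(
      subset_fraction, "complete_training", seed = seed, search = config,
      score = spec))$data)
  cfg <- config
  cfg$seed <- substream_seed(seed, 777)
  fit <- greedy_search(dat, spec, constraints = sc$constraints, config = cfg)
  m <- recall_precision(sc$truth, fit$dag)
  list(recall = m$recall, precision = m$precision,
       correct = correct_or_equivalent(sc$truth, fit$dag))
}

#' Summarise a comparison table
#'
#' Per-method, per-beta means of recall, precision and the proportion
#' correct-or-equivalent, with Monte-Carlo standard errors.  Replicates with
#' undefined precision (no retrieved edges) are excluded from the precision
#' average and counted in `n_undefined_precision`; failed replicates are
#' excluded everywhere and counted in `n_failed`.
#'
#' @param results output of [run_comparison()].
#' @return Data frame with one row per (method, beta).
#' @export
summarise_comparison <- function(results) {
  key <- interaction(results$method, results$beta, drop = TRUE)
  rows <- lapply(split(results, key), function(d) {
    ok <- !is.na(d$recall)
    prec <- d$precision[ok & !is.na(d$precision)]
    data.frame(
      scenario = d$scenario[1], method = d$method[1], beta = d$beta[1],
      n = sum(ok), n_failed = sum(!ok),
      n_undefined_precision = sum(ok & is.na(d$precision)),
      recall = mean(d$recall[ok]),
      recall_se = sd(d$recall[ok]) / sqrt(max(1, sum(ok))),
      precision = if (length(prec)) mean(prec) else NA_real_,
      precision_se = if (length(prec) > 1) sd(prec) / sqrt(length(prec))
                     else NA_real_,
      prop_correct = mean(d$correct[ok]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$method, out$beta), ]
}

#' Soft-prior sweep
#'
#' Varies the prior probability assigned to selected directed edges and
#' tallies, over simulation replicates, how often each true edge is detected
#' (exact direction) in the best-fit network, plus mean recall and
#' precision.  The same simulated datasets are reused across the prior grid
#' so the comparison is paired.
#'
#' @param scenario a [builtin_scenario()] name (default `"priornet"`).
#' @param prior_edges two-column matrix of directed edges to flag; defaults
#'   to the scenario's own `prior_edges`.
#' @param p_grid prior probabilities to sweep (all in `[0, 1]`).
#' @param replicates simulation replicates per grid point.
#' @param beta effect strength.
#' @param seed master seed.
#' @param n scenario sample-size override.
#' @param spec,config score and search settings.
#' @return List with `edges` (data frame: p, from, to, detected proportion)
#'   and `metrics` (data frame: p, recall, precision and standard errors).
#' @export
prior_sweep <- function(scenario = "priornet", prior_edges = NULL,
                        p_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                        replicates = 100, beta = 0.3, seed = 1, n = NULL,
                        spec = score_spec(), config = search_config()) {
  if (any(p_grid < 0 | p_grid > 1)) stop("prior probabilities must lie in [0, 1]")
  sc0 <- builtin_scenario(scenario, beta = beta, n = n, seed = 1)
  if (is.null(prior_edges)) prior_edges <- sc0$prior_edges
  if (is.null(prior_edges)) stop("no prior edges given")
  prior_edges <- as_edge_matrix(prior_edges, sc0$truth$nodes)
  tkey <- edge_key(dag_edges(sc0$truth))
  if (!all(edge_key(prior_edges) %in% tkey))
    stop("prior edges must be edges of the scenario's true network")
  truth_edges <- dag_edges(sc0$truth)
  edges_rows <- list()
  metric_rows <- list()
  for (pp in p_grid) {
    cons <- constraint_set(
      whitelist = sc0$constraints$whitelist,
      blacklist = sc0$constraints$blacklist,
      priors = data.frame(from = prior_edges[, 1], to = prior_edges[, 2],
                          p = pp))
    det <- matrix(0, nrow(truth_edges), 1)
    rec <- prec <- numeric(0)
    for (r in seq_len(replicates)) {
      s0 <- substream_seed(seed, r)
      sc <- builtin_scenario(scenario, beta = beta, n = n, seed = s0)
      cfg <- config
      cfg$seed <- substream_seed(s0, 31 + round(100 * pp))
      fit <- tryCatch(greedy_search(sc$full, spec, cons, cfg),
                      bnimpute_degenerate = function(e) NULL)
      if (is.null(fit)) next
      ek <- edge_key(dag_edges(fit$dag))
      det <- det + as.numeric(edge_key(truth_edges) %in% ek)
      m <- recall_precision(sc$truth, fit$dag)
      rec <- c(rec, m$recall)
      if (!is.na(m$precision)) prec <- c(prec, m$precision)
    }
    nr <- length(rec)
    edges_rows[[length(edges_rows) + 1L]] <- data.frame(
      p = pp, from = truth_edges[, 1], to = truth_edges[, 2],
      detected = as.numeric(det) / max(1, nr), stringsAsFactors = FALSE)
    metric_rows[[length(metric_rows) + 1L]] <- data.frame(
      p = pp, n = nr, recall = mean(rec),
      recall_se = sd(rec) / sqrt(max(1, nr)),
      precision = if (length(prec)) mean(prec) else NA_real_,
      precision_se = if (length(prec) > 1) sd(prec) / sqrt(length(prec))
                     else NA_real_,
      stringsAsFactors = FALSE)
  }
  list(edges = do.call(rbind, edges_rows),
       metrics = do.call(rbind, metric_rows))
}
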