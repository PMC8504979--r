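# Synthetic-data generators: linear-Gaussian structural models with effect
# strength beta, multinomial discrete nodes driven by conditional probability
# tables, SNP allele-dosage roots, and the missingness injectors used by the
# evaluation scenarios.

#' Structural simulation model
#'
#' Continuous nodes are generated as the coefficient-weighted sum of their
#' parents plus Gaussian noise; SNP nodes are allele dosages drawn as
#' Binomial(2, allele frequency) and stored as continuous variables; discrete
#' nodes are sampled from a conditional probability table over their
#' (discrete) parents.  An effect coefficient of 0 makes the child marginally
#' independent of that parent.
#'
#' @param dag a [bn_dag()]; its variable metadata fixes node kinds.
#' @param beta default effect coefficient applied to every edge into a
#'   continuous node (overridable per edge via `coef`).
#' @param coef optional numeric matrix (parents in rows, children in
#'   columns) of per-edge coefficients.
#' @param cpt named list of conditional probability tables for discrete
#'   nodes: each entry a list with `parents` (character, possibly empty) and
#'   `table` (configurations x levels matrix, rows summing to 1, the first
#'   parent varying fastest as in [expand.grid()]).
#' @param snp character vector of SNP (allele dosage) node names; these must
#'   be parentless continuous nodes and are flagged genetic.
#' @param allele_freq allele frequency for SNP nodes (recycled).
#' @param noise_sd standard deviation of the Gaussian noise added to each
#'   continuous node (recycled over continuous nodes; default 1).
#' @return Object of class `sim_model`.
#' @export
sim_model <- function(dag, beta = 0.5, coef = NULL, cpt = NULL,
                      snp = character(), allele_freq = 0.5, noise_sd = 1) {
  stopifnot(inherits(dag, "bn_dag"))
  if (!amat_is_acyclic(dag$amat)) stop("simulation structure must be acyclic")
  nodes <- dag$nodes
  p <- length(nodes)
  cf <- matrix(0, p, p, dimnames = list(nodes, nodes))
  cf[dag$amat == 1L] <- beta
  if (!is.null(coef)) {
    coef <- as.matrix(coef)
    cf[rownames(coef), colnames(coef)] <- coef
  }
  cf[dag$amat == 0L] <- 0
  vars <- dag$vars
  if (length(snp)) {
    bad <- setdiff(snp, nodes)
    if (length(bad)) stop("unknown SNP node(s): ", paste(bad, collapse = ", "))
    if (any(colSums(dag$amat[, snp, drop = FALSE]) > 0))
      stop("SNP nodes must be parentless")
    vars$genetic[vars$name %in% snp] <- TRUE
  }
  for (nm in nodes[vars$kind == "discrete"]) {
    entry <- cpt[[nm]]
    if (is.null(entry)) stop("discrete node '", nm, "' needs a CPT")
    pa <- nodes[dag$amat[, nm] == 1L]
    if (!setequal(entry$parents %||% character(), pa))
      stop("CPT parents for '", nm, "' do not match the graph")
    if (any(abs(rowSums(entry$table) - 1) > 1e-6))
      stop("CPT rows for '", nm, "' do not sum to 1")
    lev <- vars$levels[[nm]] %||% colnames(entry$table)
    if (is.null(lev)) stop("discrete node '", nm, "' has no declared levels")
    if (ncol(entry$table) != length(lev))
      stop("CPT for '", nm, "' has the wrong number of columns")
    vars$levels[[nm]] <- lev
  }
  af <- stats::setNames(rep_len(allele_freq, length(snp)), snp)
  nsd <- stats::setNames(rep_len(noise_sd, sum(vars$kind == "continuous")),
                         nodes[vars$kind == "continuous"])
  structure(list(dag = bn_dag(vars, dag_edges(dag)), coef = cf, cpt = cpt,
                 snp = snp, allele_freq = af, noise_sd = nsd),
            class = "sim_model")
}

#' Forward (ancestral) sampling from a simulation model
#'
#' Nodes are generated in topological order: SNP roots as Binomial(2, allele
#' frequency) dosages, continuous nodes as the weighted sum of parent values
#' plus Gaussian noise (discrete parents contribute through their 0-based
#' level index), and discrete nodes from their CPT row.
#'
#' @param model a [sim_model()].
#' @param n number of individuals.
#' @param seed optional integer seed (bit-identical output for identical
#'   model, `n` and seed).
#' @return A complete [mixed_data()].
#' @export
simulate_data <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "sim_model"), n >= 1)
  with_seed(seed, {
    dag <- model$dag
    vars <- dag$vars
    nodes <- dag$nodes
    ord <- topological_order(dag$amat)
    vals <- vector("list", length(nodes))
    names(vals) <- nodes
    num <- matrix(0, n, length(nodes), dimnames = list(NULL, nodes))
    for (j in ord) {
      nm <- nodes[j]
      pa <- nodes[dag$amat[, j] == 1L]
      if (nm %in% model$snp) {
        x <- rbinom(n, 2, model$allele_freq[nm])
        vals[[nm]] <- as.numeric(x)
        num[, nm] <- x
      } else if (vars$kind[j] == "continuous") {
        mu <- rep(0, n)
        for (pp in pa) mu <- mu + model$coef[pp, nm] * num[, pp]
        x <- mu + rnorm(n, 0, model$noise_sd[nm])
        vals[[nm]] <- x
        num[, nm] <- x
      } else {
        entry <- model$cpt[[nm]]
        lev <- vars$levels[[nm]]
        tab <- entry$table
        if (length(pa)) {
          key <- do.call(paste, c(lapply(entry$parents,
                                         function(pp) as.character(vals[[pp]])),
                                  sep = "\r"))
          cfg_key <- do.call(paste, c(expand.grid(
            lapply(entry$parents,
                   function(pp) vars$levels[[pp]] %||%
                     sort(unique(as.character(vals[[pp]])))),
            stringsAsFactors = FALSE), sep = "\r"))
          row <- match(key, cfg_key)
          if (anyNA(row)) stop("parent configuration missing from CPT of '",
                               nm, "'")
          x <- character(n)
          for (g in unique(row)) {
            idx <- which(row == g)
            x[idx] <- sample(lev, length(idx), replace = TRUE,
                             prob = tab[g, ])
          }
        } else {
          x <- sample(lev, n, replace = TRUE, prob = tab[1, ])
        }
        vals[[nm]] <- factor(x, levels = lev)
        num[, nm] <- as.integer(vals[[nm]]) - 1L
      }
    }
    mixed_data(as.data.frame(vals, stringsAsFactors = FALSE), vars)
  })
}

## -------------------------------------------------------- missingness ----

#' Missingness pattern
#'
#' Describes which entries of a dataset are set to missing.  All patterns are
#' missing at random (MAR): masking never depends on the value being removed.
#'
#' @param mode one of
#'   * `"fixed_count"`: exactly `count` individuals lose their value of the
#'     single variable in `variables`;
#'   * `"split"`: exactly `count` individuals each lose exactly one of the
#'     `variables`, allocated in equal alternation;
#'   * `"prob"`: each entry of each variable is masked independently with
#'     probability `prob` (MCAR);
#'   * `"mar"`: each entry of each variable is masked with probability
#'     `plogis(qlogis(prob) + slope * z)` where `z` is the standardised
#'     value of the fully observed `covariate`.
#' @param variables variables to mask.
#' @param count number of affected individuals (fixed modes).
#' @param prob masking probability (probability modes).
#' @param covariate,slope MAR link: covariate name and logistic slope.
#' @return Object of class `missingness_pattern`.
#' @export
missingness_pattern <- function(mode = c("fixed_count", "split", "prob", "mar"),
                                variables, count = NULL, prob = NULL,
                                covariate = NULL, slope = 1) {
  mode <- match.arg(mode)
  if (mode %in% c("fixed_count", "split") && is.null(count))
    stop("'count' is required for fixed modes")
  if (mode %in% c("prob", "mar") && is.null(prob))
    stop("'prob' is required for probability modes")
  if (mode == "fixed_count" && length(variables) != 1)
    stop("'fixed_count' masks a single variable")
  if (mode == "mar" && is.null(covariate))
    stop("'mar' needs a covariate")
  structure(list(mode = mode, variables = as.character(variables),
                 count = count, prob = prob, covariate = covariate,
                 slope = slope),
            class = "missingness_pattern")
}

#' Apply a missingness pattern to a dataset
#'
#' @param data a [mixed_data()].
#' @param pattern a [missingness_pattern()].
#' @param seed optional seed.
#' @return A `mixed_data` with the selected entries set to `NA`.  Fixed-count
#'   modes are exact; probability modes are exact in expectation.
#' @export
inject_missingness <- function(data, pattern, seed = NULL) {
  stopifnot(inherits(data, "mixed_data"),
            inherits(pattern, "missingness_pattern"))
  bad <- setdiff(pattern$variables, data$vars$name)
  if (length(bad)) stop("unknown variable(s): ", paste(bad, collapse = ", "))
  with_seed(seed, {
    vals <- data$values
    n <- data$n
    if (pattern$mode == "fixed_count") {
      if (pattern$count > n) stop("requested missing count exceeds n")
      rows <- sample.int(n, pattern$count)
      vals[rows, pattern$variables] <- NA
    } else if (pattern$mode == "split") {
      if (pattern$count > n) stop("requested missing count exceeds n")
      rows <- sample.int(n, pattern$count)
      k <- length(pattern$variables)
      which_var <- rep_len(seq_len(k), pattern$count)  # equal alternation
      for (v in seq_len(k))
        vals[rows[which_var == v], pattern$variables[v]] <- NA
    } else if (pattern$mode == "prob") {
      for (v in pattern$variables)
        vals[runif(n) < pattern$prob, v] <- NA
    } else {
      z <- vals[[pattern$covariate]]
      if (anyNA(z)) stop("MAR covariate must be fully observed")
      z <- as.numeric(scale(as.numeric(z)))
      pr <- stats::plogis(stats::qlogis(pattern$prob) + pattern$slope * z)
      for (v in pattern$variables)
        vals[runif(n) < pr, v] <- NA
    }
    mixed_data(vals, data$vars)
  })
}

## ----------------------------------------------------------- scenarios ----

#' Built-in simulation scenarios
#'
#' A catalogue of small benchmark scenarios: six 3-variable models in which
#' 1800 of 2000 individuals are missing one value; the 5-variable collider
#' chain `A -> B <- C -> D <- E` and the plain chain
#' `A -> B -> C -> D -> E`, each with 1800 of 2000 individuals missing one of
#' the two starred variables in equal alternation; a 31-variable multi-omics
#' network (20 SNP dosages feeding 10 expression variables, two SNPs each in
#' round robin, which all feed one trait) with expression values missing with
#' probability 0.2; and a 6-node soft-prior demonstration network.
#'
#' @param name scenario name: `"fig1A"` ... `"fig1F"`, `"collider5"`,
#'   `"chain5"`, `"omics31"` or `"priornet"`.
#' @param beta effect strength used for every simulated edge.
#' @param n number of individuals (scenario default when `NULL`: 2000 for
#'   the 3- and 5-variable scenarios, 500 otherwise).
#' @param seed optional seed covering both simulation and masking.
#' @return List with `data` (masked [mixed_data()]), `full` (the same data
#'   before masking), `truth` (generating [bn_dag()]), `pattern`
#'   ([missingness_pattern()]), and for `"priornet"` also `constraints` (a
#'   whitelist [constraint_set()]) and `prior_edges` (the edges to flag).
#' @export
builtin_scenario <- function(name, beta = 0.5, n = NULL, seed = NULL) {
  sc <- scenario_catalogue(name, beta, n)
  with_seed(seed, {
    full <- simulate_data(sc$model, sc$n)
    data <- inject_missingness(full, sc$pattern)
    out <- list(data = data, full = full, truth = sc$model$dag,
                pattern = sc$pattern)
    out[names(sc$extra)] <- sc$extra
    out
  })
}

scenario_names <- function() {
  c(paste0("fig1", LETTERS[1:6]), "collider5", "chain5", "omics31", "priornet")
}

scenario_catalogue <- function(name, beta, n) {
  # 90% of individuals carry one missing value (1800 of 2000 at the default
  # sample size); the count scales with an overridden n
  three <- function(edges, star, n) {
    n <- n %||% 2000
    dag <- bn_dag(c("A", "B", "C"), edges)
    pattern <- if (length(star) == 1)
      missingness_pattern("fixed_count", star, count = round(0.9 * n))
    else missingness_pattern("split", star, count = round(0.9 * n))
    list(model = sim_model(dag, beta), n = n, pattern = pattern,
         extra = list())
  }
  five <- function(edges, n) {
    n <- n %||% 2000
    dag <- bn_dag(c("A", "B", "C", "D", "E"), edges)
    list(model = sim_model(dag, beta), n = n,
         pattern = missingness_pattern("split", c("B", "D"),
                                       count = round(0.9 * n)),
         extra = list())
  }
  switch(name,
    fig1A = three(c("A->B", "B->C"), "C", n),
    fig1B = three(c("A->B", "B->C"), "B", n),
    fig1C = three(c("A->B", "C->B"), "B", n),
    fig1D = three(c("B->A", "B->C"), "B", n),
    fig1E = three(c("A->B", "B->C"), c("A", "C"), n),
    fig1F = three(c("A->B", "C->B"), c("A", "C"), n),
    collider5 = five(c("A->B", "C->B", "C->D", "E->D"), n),
    chain5 = five(c("A->B", "B->C", "C->D", "D->E"), n),
    omics31 = {
      snps <- sprintf("snp%02d", 1:20)
      expr <- sprintf("ex%d", 1:10)
      nodes <- c(snps, expr, "trait")
      edges <- rbind(
        cbind(snps, rep(expr, each = 2)),  # two SNP parents per expression
        cbind(expr, "trait"))
      dag <- bn_dag(nodes, edges)
      model <- sim_model(dag, beta, snp = snps, allele_freq = 0.5)
      list(model = model, n = n %||% 500,
           pattern = missingness_pattern("prob", expr, prob = 0.2),
           extra = list())
    },
    priornet = {
      # soft-prior demonstration: F -> A is direction-constrained (white
      # both ways would relax it; here the direction itself is whitelisted),
      # A -> B is the prior-flagged edge, B -> C shares node B with it, and
      # D -> E sits in a less connected part of the graph.
      dag <- bn_dag(c("A", "B", "C", "D", "E", "F"),
                    c("F->A", "A->B", "B->C", "D->E", "C->E"))
      cons <- constraint_set(whitelist = rbind(c("F", "A")))
      list(model = sim_model(dag, beta), n = n %||% 500,
           pattern = missingness_pattern("prob", "A", prob = 0),
           extra = list(constraints = cons,
                        prior_edges = rbind(c("A", "B"))))
    },
    stop("unknown scenario '", name, "'; available: ",
         paste(scenario_names(), collapse = ", "))
  )
}

## ------------------------------------- plain-text Gaussian network format ----

#' Read a linear-Gaussian network from its text description
#'
#' One node per line, tab-separated: `node`, comma-separated parent names
#' (empty for roots), comma-separated coefficients (same order), and the
#' noise standard deviation.  Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return A [sim_model()] over continuous variables.
#' @export
read_gaussian_network <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nodes <- vapply(fields, `[`, character(1), 1)
  parents <- lapply(fields, function(f)
    if (length(f) >= 2 && nzchar(f[2]))
      strsplit(f[2], ",", fixed = TRUE)[[1]] else character())
  coefs <- lapply(fields, function(f)
    if (length(f) >= 3 && nzchar(f[3]))
      as.numeric(strsplit(f[3], ",", fixed = TRUE)[[1]]) else numeric())
  nsd <- vapply(fields, function(f)
    if (length(f) >= 4) as.numeric(f[4]) else 1, numeric(1))
  edges <- do.call(rbind, lapply(seq_along(nodes), function(i)
    if (length(parents[[i]])) cbind(parents[[i]], nodes[i]) else NULL))
  dag <- bn_dag(nodes, edges)
  cf <- matrix(0, length(nodes), length(nodes),
               dimnames = list(nodes, nodes))
  for (i in seq_along(nodes)) {
    if (length(parents[[i]]) != length(coefs[[i]]))
      stop("line ", i, ": parent/coefficient length mismatch")
    cf[parents[[i]], nodes[i]] <- coefs[[i]]
  }
  sim_model(dag, coef = cf, noise_sd = stats::setNames(nsd, nodes))
}

#' Write a linear-Gaussian network in the text format of
#' [read_gaussian_network()]
#' @param model a continuous [sim_model()].
#' @param path file path.
#' @export
write_gaussian_network <- function(model, path) {
  nodes <- model$dag$nodes
  lines <- vapply(nodes, function(nm) {
    pa <- nodes[model$dag$amat[, nm] == 1L]
    paste(nm, paste(pa, collapse = ","),
          paste(model$coef[pa, nm], collapse = ","),
          model$noise_sd[nm], sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
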