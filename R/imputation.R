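# Network-guided nearest-neighbour imputation.  Missing data are imputed for
# each index individual separately: a training subset is resampled, a
# best-fit network learned on it, and the variables adjacent to the missing
# variable in that network (observed for the index individual) define the
# distance used to pick a donor, whose observed value is copied.  Continuous
# children of the missing variable may be replaced by regression-adjusted
# versions with the contribution of their other continuous parents removed.

#' Imputation configuration
#'
#' @param subset_fraction fraction of individuals resampled (without
#'   replacement) into the training subset for each index individual;
#'   default 0.9.  The subset size is `floor(fraction * n)`, minimum 2.
#' @param variant `"default"` (subset drawn from all individuals, remaining
#'   missing entries in the subset filled with values sampled with
#'   replacement from the variable's observed values), `"complete_training"`
#'   (subset drawn from the fully observed individuals only, so nothing needs
#'   random filling) or `"all_nn"` (all other observed variables inform the
#'   neighbour choice; no inner network is used).
#' @param seed master seed; per-individual substreams are derived from it so
#'   results do not depend on the order in which individuals are processed.
#' @param search [search_config()] for the inner best-fit network.
#' @param score [score_spec()] for the inner search (default BIC).
#' @return Object of class `imputation_config`.
#' @export
imputation_config <- function(subset_fraction = 0.9,
                              variant = c("default", "complete_training",
                                          "all_nn"),
                              seed = NULL, search = search_config(),
                              score = score_spec("bic")) {
  stopifnot(subset_fraction > 0, subset_fraction <= 1)
  structure(list(subset_fraction = subset_fraction,
                 variant = match.arg(variant), seed = seed,
                 search = search, score = score),
            class = "imputation_config")
}

# deterministic per-individual seed keyed to the row identifier, so that row
# order never matters
row_substream <- function(master, rowname) {
  h <- sum(utf8ToInt(rowname) * (31^(seq_len(nchar(rowname)) %% 7))) %% 2147483647
  substream_seed(master, h)
}

#' Impute missing data by network-guided nearest neighbours
#'
#' For each individual with at least one missing value, independently:
#' (1) a `subset_fraction` sample of individuals is drawn without replacement
#' (from everyone, or from the complete cases under `"complete_training"`);
#' (2) a best-fit network is learned on that subset by greedy search;
#' (3) for each missing variable the nearby-variable set is built from the
#' network (or from all observed variables under `"all_nn"`) and the nearest
#' neighbour located; (4) the neighbour's observed value is copied.  Observed
#' entries are never altered and donor pools contain only originally observed
#' values, never freshly imputed ones.  Missingness is assumed MAR.
#'
#' @param data a [mixed_data()] with missing entries.
#' @param config an [imputation_config()].
#' @param constraints optional [constraint_set()] applied to every inner
#'   search.
#' @return List with `data` (the completed [mixed_data()]) and `provenance`
#'   (data frame: individual, variable, donor, distance, nearby-variable
#'   list; one row per imputed entry).
#' @export
impute_nn <- function(data, config = imputation_config(),
                      constraints = NULL) {
  stopifnot(inherits(data, "mixed_data"),
            inherits(config, "imputation_config"))
  enc <- md_encode(data)
  X <- enc$x
  O <- data$observed
  n <- data$n
  p <- ncol(X)
  never <- colSums(O) == 0
  if (any(never))
    stop("variable(s) with no observed values cannot be imputed: ",
         paste(data$vars$name[never], collapse = ", "))
  rn <- rownames(data$values)
  rk <- rank(rn, ties.method = "first")   # canonical per-individual order
  csort <- order(rk)                      # rows in canonical order
  master <- config$seed %||% sample.int(2^31 - 2, 1)
  cm <- constraint_matrices(data$vars, constraints)
  pen_for <- function(m) score_penalty(config$score, m)
  all_cont <- all(enc$kind == "continuous")
  # observed-value pools in canonical row order (row-order invariance)
  obs_vals <- lapply(seq_len(p), function(j) {
    cs <- csort[O[csort, j]]
    X[cs, j]
  })
  col_var <- vapply(obs_vals, function(v) if (length(v) > 1) var(v) else 0,
                    numeric(1))
  complete <- which(rowSums(O) == p)
  if (config$variant == "complete_training" && length(complete) < 2)
    stop("complete_training requires at least 2 complete individuals")
  ccanon <- csort[csort %in% complete]    # complete rows, canonical order
  need <- which(rowSums(!O) > 0)
  np <- sum(rowSums(!O[need, , drop = FALSE]))
  pv_ind <- character(np); pv_var <- character(np); pv_don <- character(np)
  pv_dist <- numeric(np); pv_nb <- character(np)
  pk <- 0L
  out <- X
  zero_var_warned <- FALSE
  ols_warned <- FALSE
  degen_warned <- FALSE
  for (ii in seq_along(need)) {
    i <- need[ii]
    set.seed(row_substream(master, rn[i]))
    # ---- step 1: training subset (drawn in canonical row order, so the
    # result does not depend on the physical row order) ------------------
    if (config$variant == "complete_training") {
      m <- max(2L, floor(config$subset_fraction * length(ccanon)))
      sub <- ccanon[sample.int(length(ccanon), m)]
      Tm <- X[sub, , drop = FALSE]
    } else {
      m <- max(2L, floor(config$subset_fraction * n))
      sub <- csort[sample.int(n, m)]
      Tm <- X[sub, , drop = FALSE]
      Osub <- O[sub, , drop = FALSE]
      for (j in seq_len(p)) {
        mr <- which(!Osub[, j])
        if (!length(mr)) next
        mr <- mr[order(rk[sub[mr]])]
        Tm[mr, j] <- sample(obs_vals[[j]], length(mr), replace = TRUE)
      }
    }
    # ---- step 2: inner best-fit network ------------------------------
    amat <- NULL
    if (config$variant != "all_nn") {
      amat <- tryCatch(
        inner_search_amat(Tm, enc, cm, config, pen_for(nrow(Tm))),
        bnimpute_degenerate = function(e) NULL)
      if (is.null(amat)) {
        if (!degen_warned) {
          warning("inner search degenerate for some individuals; ",
                  "falling back to random donors")
          degen_warned <- TRUE
        }
        amat <- matrix(0L, p, p)
      }
    }
    # ---- steps 3-4: nearest-neighbour donor per missing variable -----
    miss <- which(!O[i, ])
    for (z in miss) {
      nb <- build_nearby(z, i, amat, X, O, enc, col_var, rk,
                         all_nn = config$variant == "all_nn")
      if (nb$ols_fallback && !ols_warned) {
        warning("underdetermined adjustment regression; ",
                "using the unadjusted child variable")
        ols_warned <- TRUE
      }
      sel <- nn_donor(nb, z, i, X, O, rk)
      if (sel$zero_var && !zero_var_warned) {
        warning("zero-variance nearby variable contributes no distance")
        zero_var_warned <- TRUE
      }
      out[i, z] <- X[sel$donor, z]
      pk <- pk + 1L
      pv_ind[pk] <- rn[i]; pv_var[pk] <- data$vars$name[z]
      pv_don[pk] <- rn[sel$donor]; pv_dist[pk] <- sel$distance
      pv_nb[pk] <- paste(nb$labels, collapse = ",")
    }
  }
  prov <- data.frame(individual = pv_ind[seq_len(pk)],
                     variable = pv_var[seq_len(pk)],
                     donor = pv_don[seq_len(pk)],
                     distance = pv_dist[seq_len(pk)],
                     nearby = pv_nb[seq_len(pk)], stringsAsFactors = FALSE)
  list(data = md_decode(out, data), provenance = prov)
}

# Learn the inner network on a (filled) training matrix.  All-continuous
# data takes the compiled engine; mixed data the generic climber.
inner_search_amat <- function(Tm, enc, cm, config, pen) {
  p <- ncol(Tm)
  if (all(enc$kind == "continuous")) {
    Tc <- Tm - rep(colMeans(Tm), each = nrow(Tm))
    C <- crossprod(cbind(1, Tc))
    res <- cpp_hc_gauss(C, nrow(Tm), pen, cm$allowed, cm$mustpair, cm$lp,
                        cm$start, config$search$random_restarts,
                        config$search$jitter_restarts,
                        config$search$jitter_moves, config$search$restart_q,
                        config$search$max_iterations)
  } else {
    ctx <- list(x = Tm, nlev = enc$nlev, kind = enc$kind, n = nrow(Tm),
                all_cont = FALSE)
    res <- hc_generic(ctx, pen, cm, config$search)
  }
  if (is.na(res$score)) degenerate_error("inner search degenerate")
  res$amat
}

# Nearby-variable set for one (index individual, missing variable) pair.
# Plain nearby variables are the network neighbours of z observed for the
# index individual; each continuous child y of a continuous z with at least
# one other continuous, index-observed parent is replaced by the adjusted
# variable v = y - sum(beta_x * x), with coefficients from the OLS of y on
# all its continuous parents (including z) over originally observed rows.
build_nearby <- function(z, i, amat, X, O, enc, col_var, rk, all_nn = FALSE) {
  p <- ncol(X)
  ols_fallback <- FALSE
  terms <- list()
  labels <- character()
  add_plain <- function(w) {
    terms[[length(terms) + 1L]] <<- list(
      kind = if (enc$kind[w] == "discrete") "discrete" else "continuous",
      values = X[, w], variance = col_var[w], requires = w, var_index = w)
    labels <<- c(labels, colnames(X)[w])
  }
  if (all_nn) {
    for (w in setdiff(which(O[i, ]), z)) add_plain(w)
    return(list(target = z, index = i, terms = terms, labels = labels,
                ols_fallback = FALSE))
  }
  adj <- which((amat[z, ] + amat[, z]) > 0)
  adj <- adj[O[i, adj]]
  children <- which(amat[z, ] == 1L)
  for (w in adj) {
    adjusted <- FALSE
    if (enc$kind[z] == "continuous" && w %in% children &&
        enc$kind[w] == "continuous") {
      # other continuous parents of child w, observed for the index case
      op <- setdiff(which(amat[, w] == 1L), z)
      op <- op[enc$kind[op] == "continuous"]
      xs <- op[O[i, op]]
      if (length(xs)) {
        reg <- c(z, op)                      # all continuous parents incl. z
        rows <- which(O[, w] & rowSums(!O[, reg, drop = FALSE]) == 0)
        rows <- rows[order(rk[rows])]        # row-order invariance of the fit
        if (length(rows) >= length(reg) + 2) {
          fit <- tryCatch(lm.fit(cbind(1, X[rows, reg, drop = FALSE]),
                                 X[rows, w]),
                          error = function(e) NULL)
          if (!is.null(fit) && fit$rank == length(reg) + 1) {
            beta <- fit$coefficients[-1]
            names(beta) <- as.character(reg)
            usable <- which(O[, w] &
                              rowSums(!O[, xs, drop = FALSE]) == 0)
            v <- X[, w]
            for (x in xs) v <- v - beta[as.character(x)] * X[, x]
            v[setdiff(seq_len(nrow(X)), usable)] <- NA
            vv <- v[usable[order(rk[usable])]]
            terms[[length(terms) + 1L]] <- list(
              kind = "continuous", values = v,
              variance = if (length(vv) > 1) var(vv) else 0,
              requires = c(w, xs), var_index = w)
            labels <- c(labels, paste0("adj:", colnames(X)[w]))
            adjusted <- TRUE
          } else ols_fallback <- TRUE
        } else ols_fallback <- TRUE
      }
    }
    if (!adjusted) add_plain(w)
  }
  list(target = z, index = i, terms = terms, labels = labels,
       ols_fallback = ols_fallback)
}

# Distance between the index individual and every candidate row, plus donor
# selection with uniform tie-breaking in canonical row order.
nn_donor <- function(nb, z, i, X, O, rk) {
  n <- nrow(X)
  zero_var <- FALSE
  elig <- O[, z]
  elig[i] <- FALSE
  for (tm in nb$terms)
    for (w in tm$requires) elig <- elig & O[, w]
  cand <- which(elig)
  if (!length(nb$terms) || !length(cand)) {
    pool <- setdiff(which(O[, z]), i)
    pool <- pool[order(rk[pool])]
    donor <- pool[sample.int(length(pool), 1)]
    return(list(donor = donor, distance = NA_real_, zero_var = FALSE))
  }
  d <- numeric(length(cand))
  for (tm in nb$terms) {
    vi <- tm$values[i]
    vc <- tm$values[cand]
    if (tm$kind == "discrete") d <- d + (vc != vi)
    else if (tm$variance > 0) d <- d + (vc - vi)^2 / tm$variance
    else zero_var <- TRUE
  }
  dmin <- min(d)
  ties <- cand[d <= dmin]
  if (length(ties) > 1) {
    ties <- ties[order(rk[ties])]
    donor <- ties[sample.int(length(ties), 1)]
  } else donor <- ties
  list(donor = donor, distance = dmin, zero_var = zero_var)
}

#' Nearby variables for one index individual and target variable
#'
#' The plain nearby variables are the variables adjacent to the target in
#' the supplied network that are observed for the index individual.  When
#' the target is continuous, each of its continuous children with at least
#' one other continuous, index-observed parent is replaced by the adjusted
#' variable `v = y - sum(beta_x x)` over those observed parents, with
#' coefficients from the OLS of the child on all its continuous parents
#' (including the target) fitted on originally observed rows; a discrete
#' target is never adjusted.  An underdetermined regression falls back to
#' the unadjusted child with a warning.
#'
#' @param dag the inner best-fit [bn_dag()].
#' @param data the original [mixed_data()].
#' @param individual row identifier (name) or row index of the index case.
#' @param target name of the missing variable.
#' @return Object of class `nearby_set` with one term per nearby variable
#'   (values across all individuals, variance for distance normalisation,
#'   and which columns a candidate must observe).
#' @export
select_nearby_variables <- function(dag, data, individual, target) {
  stopifnot(inherits(dag, "bn_dag"), inherits(data, "mixed_data"))
  enc <- md_encode(data)
  i <- resolve_row(data, individual)
  z <- match(target, data$vars$name)
  if (is.na(z)) stop("unknown target variable '", target, "'")
  amat <- dag$amat[data$vars$name, data$vars$name]
  rk <- rank(rownames(data$values), ties.method = "first")
  csort <- order(rk)
  obs_vals <- lapply(seq_len(ncol(enc$x)), function(j) {
    cs <- csort[data$observed[csort, j]]
    enc$x[cs, j]
  })
  col_var <- vapply(obs_vals, function(v) if (length(v) > 1) var(v) else 0,
                    numeric(1))
  nb <- build_nearby(z, i, amat, enc$x, data$observed, enc, col_var, rk)
  if (nb$ols_fallback)
    warning("underdetermined adjustment regression; ",
            "using the unadjusted child variable")
  structure(nb, class = "nearby_set")
}

resolve_row <- function(data, individual) {
  if (is.character(individual)) {
    i <- match(individual, rownames(data$values))
    if (is.na(i)) stop("unknown individual '", individual, "'")
    i
  } else as.integer(individual)
}

#' Distance between two individuals over a nearby-variable set
#'
#' Sum over nearby variables of the per-variable distance: squared
#' difference divided by the variable's variance (estimated from all its
#' observed values) for continuous variables, and 0/1 agreement for discrete
#' ones.  A zero-variance variable contributes 0 with a warning, as it
#' cannot discriminate.
#'
#' @param data the [mixed_data()] the nearby set was built from.
#' @param candidate,index row identifiers or indices.
#' @param nearby a `nearby_set` from [select_nearby_variables()].
#' @return Non-negative distance.
#' @export
nn_distance <- function(data, candidate, index, nearby) {
  stopifnot(inherits(nearby, "nearby_set"))
  ci <- resolve_row(data, candidate)
  ii <- resolve_row(data, index)
  d <- 0
  for (tm in nearby$terms) {
    vi <- tm$values[ii]; vc <- tm$values[ci]
    if (is.na(vi) || is.na(vc))
      stop("candidate or index does not observe a nearby variable")
    if (tm$kind == "discrete") d <- d + (vc != vi)
    else if (tm$variance > 0) d <- d + (vc - vi)^2 / tm$variance
    else warning("zero-variance nearby variable contributes no distance")
  }
  unname(d)
}

#' Nearest-neighbour donor for one missing value
#'
#' The donor is the individual minimising [nn_distance()] among those
#' observing the target variable and every nearby variable; exact ties are
#' broken uniformly at random.  With no nearby variables or no eligible
#' candidate, a random individual observing the target is chosen.
#'
#' @inheritParams nn_distance
#' @param target name of the missing variable.
#' @return List with `donor` (row name), `distance` (`NA` for a random
#'   fallback donor).
#' @export
find_nearest_neighbour <- function(data, index, target, nearby) {
  stopifnot(inherits(nearby, "nearby_set"))
  i <- resolve_row(data, index)
  z <- match(target, data$vars$name)
  if (is.na(z)) stop("unknown target variable '", target, "'")
  if (!any(data$observed[-i, z]))
    stop("no individual observes '", target, "'")
  rk <- rank(rownames(data$values), ties.method = "first")
  enc <- md_encode(data)
  sel <- nn_donor(nearby, z, i, enc$x, data$observed, rk)
  list(donor = rownames(data$values)[sel$donor], distance = sel$distance)
}
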