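# Decomposable network scores: multinomial local distributions for discrete
# nodes, Gaussian linear regressions for continuous nodes (one regression per
# discrete-parent configuration in the mixed case), penalised as AIC or BIC.
# Scores follow the structure-learning convention: larger is better, and on
# non-degenerate continuous data they are negative.

#' Network score specification
#'
#' @param type `"bic"` (default), `"aic"` or `"loglik"`.  All three are the
#'   maximised log-likelihood minus a penalty: none (loglik), `d` (AIC) or
#'   `(d/2) log n` (BIC), with `d` the number of free parameters.
#' @return Object of class `score_spec`.
#' @export
score_spec <- function(type = c("bic", "aic", "loglik")) {
  structure(list(type = match.arg(type)), class = "score_spec")
}

score_penalty <- function(spec, n) {
  switch(spec$type, loglik = 0, aic = 1, bic = log(n) / 2)
}

# Scoring context: numeric encoding of the dataset plus (for all-continuous
# data) the centred crossproduct matrix feeding the fast Gaussian path.
score_ctx <- function(data) {
  stopifnot(inherits(data, "mixed_data"))
  if (any(!data$observed))
    stop("data must be complete for scoring; impute or reduce first")
  enc <- md_encode(data)
  all_cont <- all(enc$kind == "continuous")
  C <- NULL
  if (all_cont && data$n > 0) {
    x <- scale(enc$x, center = TRUE, scale = FALSE)
    C <- crossprod(cbind(1, x))
  }
  list(x = enc$x, nlev = enc$nlev, kind = enc$kind, genetic = enc$genetic,
       nodes = data$vars$name, n = data$n, all_cont = all_cont, C = C)
}

# Local score of one node given a parent set; returns list(loglik, nparams,
# score, degenerate).  A degenerate fit (singular or zero-variance regression,
# or a discrete-parent configuration with fewer rows than parameters) yields
# NA score: callers treat the candidate parent set as inadmissible.
local_score_ctx <- function(ctx, j, parents, pen) {
  kind <- ctx$kind
  n <- ctx$n
  if (n == 0) stop("cannot score an empty dataset")
  bad <- list(loglik = NA_real_, nparams = NA_real_, score = NA_real_,
              degenerate = TRUE)
  if (kind[j] == "discrete") {
    if (any(kind[parents] == "continuous"))
      stop("a discrete node cannot have a continuous parent")
    xj <- ctx$x[, j]
    r <- ctx$nlev[j]
    q <- if (length(parents)) prod(ctx$nlev[parents]) else 1L
    cfg <- rep(1L, n)
    stride <- 1L
    for (pp in parents) {
      cfg <- cfg + (ctx$x[, pp] - 1L) * stride
      stride <- stride * ctx$nlev[pp]
    }
    counts <- matrix(tabulate((cfg - 1L) * r + xj, nbins = r * q), r, q)
    ntot <- colSums(counts)
    nz <- counts > 0
    ll <- sum(counts[nz] * log(counts[nz] /
                                 rep(ntot, each = r)[as.vector(nz)]))
    d <- (r - 1) * q
    list(loglik = ll, nparams = d, score = ll - pen * d, degenerate = FALSE)
  } else {
    dpar <- parents[kind[parents] == "discrete"]
    cpar <- parents[kind[parents] == "continuous"]
    q <- if (length(dpar)) prod(ctx$nlev[dpar]) else 1L
    d <- q * (length(cpar) + 2)
    y <- ctx$x[, j]
    cfg <- rep(1L, n)
    stride <- 1L
    for (pp in dpar) {
      cfg <- cfg + (ctx$x[, pp] - 1L) * stride
      stride <- stride * ctx$nlev[pp]
    }
    ll <- 0
    for (g in unique(cfg)) {
      rows <- which(cfg == g)
      m <- length(rows)
      # an observed configuration needs at least as many rows as parameters
      if (m < length(cpar) + 2) return(bad)
      X <- cbind(1, ctx$x[rows, cpar, drop = FALSE])
      fit <- tryCatch(lm.fit(X, y[rows]), error = function(e) NULL)
      if (is.null(fit) || fit$rank < ncol(X)) return(bad)
      rss <- sum(fit$residuals^2)
      if (rss <= 1e-12 * max(1, sum(y[rows]^2))) return(bad)
      ll <- ll - m / 2 * (log(2 * pi * rss / m) + 1)
    }
    list(loglik = ll, nparams = d, score = ll - pen * d, degenerate = FALSE)
  }
}

#' Local score of one node given a parent set
#'
#' Discrete nodes take a multinomial distribution (log-likelihood
#' \eqn{\sum_{jk} N_{jk} \log(N_{jk}/N_{j\cdot})}, \eqn{(r-1)q} parameters);
#' continuous nodes take a Gaussian linear regression on their continuous
#' parents, fitted separately within each discrete-parent configuration, with
#' the variance MLE using denominator `n`.  Small or rare discrete
#' configurations can make a fit degenerate, in which case the score is `NA`
#' and the parent set is treated as inadmissible.
#'
#' @param data complete [mixed_data()].
#' @param node node name.
#' @param parents character vector of parent names (may be empty).
#' @param spec a [score_spec()].
#' @return List with `loglik`, `nparams`, `score` and `degenerate`.
#' @export
local_score <- function(data, node, parents = character(), spec = score_spec()) {
  ctx <- score_ctx(data)
  j <- match(node, ctx$nodes)
  pj <- match(parents, ctx$nodes)
  if (anyNA(c(j, pj))) stop("unknown node name")
  local_score_ctx(ctx, j, pj, score_penalty(spec, ctx$n))
}

# Sum of local scores for a full structure given a prepared context.
network_score_ctx <- function(ctx, amat, pen, lp = NULL) {
  p <- ncol(amat)
  total <- 0
  for (j in seq_len(p)) {
    s <- local_score_ctx(ctx, j, which(amat[, j] == 1L), pen)$score
    if (is.na(s)) return(NA_real_)
    total <- total + s
  }
  if (!is.null(lp)) total <- total + sum(lp[amat == 1L])
  total
}

#' Score of a network structure, optionally prior-weighted
#'
#' The network score is the sum of local scores over nodes.  When soft
#' directed-edge priors are supplied and the score is BIC, the weighted score
#' \eqn{\mathrm{BIC} + \sum_e \log p(e)} is returned, summing over prior-
#' flagged edges present in the network (presence of the reverse direction
#' contributes \eqn{\log(1 - p)}).  A present edge with prior 0 gives
#' \eqn{-\infty}: the network is rejected outright.  Priors with a score
#' other than BIC are a configuration error, as the weighting is derived from
#' the BIC approximation to the model evidence.
#'
#' @inheritParams local_score
#' @param dag a [bn_dag()] over the data's variables.
#' @param constraints optional [constraint_set()] carrying the soft priors.
#' @return Numeric score (`NA` if any local fit is degenerate).
#' @export
network_score <- function(data, dag, spec = score_spec(),
                          constraints = NULL) {
  stopifnot(inherits(dag, "bn_dag"))
  ctx <- score_ctx(data)
  if (!all(dag$nodes %in% ctx$nodes)) stop("dag nodes missing from data")
  lp <- NULL
  if (!is.null(constraints) && NROW(constraints$priors)) {
    if (spec$type != "bic")
      stop("soft priors require the BIC score")
    lp <- prior_log_matrix(dag$nodes, constraints)
  }
  ctx2 <- ctx
  ord <- match(dag$nodes, ctx$nodes)
  ctx2$x <- ctx$x[, ord, drop = FALSE]
  ctx2$nlev <- ctx$nlev[ord]
  ctx2$kind <- ctx$kind[ord]
  ctx2$nodes <- dag$nodes
  network_score_ctx(ctx2, dag$amat, score_penalty(spec, ctx$n), lp)
}

#' Score change of a single-arc move
#'
#' Exploits decomposability: only the local scores of the affected child
#' nodes (plus any prior term) are recomputed, giving a result identical to
#' rescoring the whole network.
#'
#' @inheritParams network_score
#' @param move list with `type` (`"add"`, `"delete"` or `"reverse"`), `from`
#'   and `to`; the move must keep the graph a valid DAG.
#' @param cache optional environment used to memoise local scores across
#'   calls (create with `new.env()`).
#' @return Numeric delta: score after the move minus score before.
#' @export
score_delta <- function(data, dag, move, spec = score_spec(),
                        constraints = NULL, cache = NULL) {
  stopifnot(inherits(dag, "bn_dag"),
            move$type %in% c("add", "delete", "reverse"))
  ctx <- score_ctx(data)
  if (!identical(ctx$nodes, dag$nodes))
    stop("data and dag must list the same variables in the same order")
  pen <- score_penalty(spec, ctx$n)
  lp <- prior_log_matrix(dag$nodes, constraints)
  f <- match(move$from, dag$nodes)
  t <- match(move$to, dag$nodes)
  if (anyNA(c(f, t))) stop("unknown node in move")
  a0 <- dag$amat
  a1 <- apply_move_amat(a0, move$type, f, t)
  local_cached <- function(amat, j) {
    pa <- which(amat[, j] == 1L)
    key <- paste0(j, "|", paste(pa, collapse = ","))
    if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
    s <- local_score_ctx(ctx, j, pa, pen)$score
    if (!is.null(cache)) cache[[key]] <- s
    s
  }
  affected <- if (move$type == "reverse") c(f, t) else t
  delta <- 0
  for (j in affected) {
    s_new <- local_cached(a1, j)
    s_old <- local_cached(a0, j)
    if (is.na(s_new) || is.na(s_old)) return(NA_real_)
    delta <- delta + s_new - s_old
  }
  delta + sum(lp[a1 == 1L]) - sum(lp[a0 == 1L])
}

apply_move_amat <- function(amat, type, f, t) {
  if (type == "add") {
    if (amat[f, t] == 1L) stop("edge already present")
    amat[f, t] <- 1L
  } else if (type == "delete") {
    if (amat[f, t] == 0L) stop("edge not present")
    amat[f, t] <- 0L
  } else {
    if (amat[f, t] == 0L) stop("edge not present")
    amat[f, t] <- 0L
    amat[t, f] <- 1L
  }
  if (!amat_is_acyclic(amat)) stop("move creates a cycle")
  amat
}
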