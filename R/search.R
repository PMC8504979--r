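# Score-based structure search: greedy hill climbing over single-arc
# additions, deletions and reversals, with random and jitter restarts, plus
# an exhaustive-enumeration search for small node counts.  All-continuous
# data takes a compiled fast path working on the crossproduct matrix; mixed
# discrete/continuous data uses the generic R implementation.

#' Search configuration
#'
#' @param random_restarts number of restarts from a random valid network.
#' @param jitter_restarts number of restarts from the incumbent best network
#'   perturbed by `jitter_moves` random valid single-arc moves.
#' @param jitter_moves perturbations per jitter restart.
#' @param seed optional integer; identical configuration, data and seed give
#'   an identical result.  When `NULL` the current RNG stream is used.
#' @param max_iterations cap on hill-climbing steps per climb.
#' @param restart_q probability that an order-compatible edge is included in
#'   a random starting network.
#' @return Object of class `search_config`.
#' @export
search_config <- function(random_restarts = 2, jitter_restarts = 2,
                          jitter_moves = 3, seed = NULL,
                          max_iterations = 1000, restart_q = 0.25) {
  stopifnot(random_restarts >= 0, jitter_restarts >= 0, jitter_moves >= 0)
  structure(list(random_restarts = as.integer(random_restarts),
                 jitter_restarts = as.integer(jitter_restarts),
                 jitter_moves = as.integer(jitter_moves), seed = seed,
                 max_iterations = as.integer(max_iterations),
                 restart_q = restart_q),
            class = "search_config")
}

# Translate variable metadata + constraints into the matrices consumed by the
# engines: allowed[i, j] (edge i -> j may exist), mustpair (pair must stay
# connected), the log-prior matrix, and a valid starting graph containing the
# whitelist.  Raises a configuration error when the constraints are
# contradictory.
constraint_matrices <- function(vars, constraints = NULL) {
  nodes <- vars$name
  p <- length(nodes)
  allowed <- matrix(1L, p, p, dimnames = list(nodes, nodes))
  diag(allowed) <- 0L
  disc <- vars$kind == "discrete"
  allowed[!disc, disc] <- 0L            # no continuous parent of a discrete node
  allowed[, vars$genetic] <- 0L         # causal anchors: no incoming edges
  mustpair <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  lp <- prior_log_matrix(nodes, constraints)
  start <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  if (!is.null(constraints)) {
    stopifnot(inherits(constraints, "constraint_set"))
    ref <- unique(c(constraints$whitelist, constraints$blacklist,
                    constraints$priors$from, constraints$priors$to))
    unknown <- setdiff(ref, nodes)
    if (length(unknown))
      stop("constraints reference unknown node(s): ",
           paste(unknown, collapse = ", "))
    bl <- constraints$blacklist
    if (nrow(bl)) allowed[bl] <- 0L
    allowed[lp == -Inf] <- 0L           # prior probability 0 bans the edge
    wl <- constraints$whitelist
    if (nrow(wl)) {
      wk <- edge_key(wl)
      for (i in seq_len(nrow(wl))) {
        f <- wl[i, 1]; t <- wl[i, 2]
        both <- paste(t, f, sep = "->") %in% wk
        if (vars$genetic[match(t, nodes)] && !both)
          stop("whitelist points into genetic node '", t, "'")
        mustpair[f, t] <- 1L
        mustpair[t, f] <- 1L
        if (!both) {
          if (!allowed[f, t])
            stop("whitelisted edge ", f, " -> ", t,
                 " conflicts with another constraint")
          allowed[t, f] <- 0L
        } else if (!allowed[f, t] && !allowed[t, f])
          stop("whitelisted pair ", f, " - ", t, " has no permitted direction")
      }
      # place one direction per whitelisted pair, keeping the graph acyclic
      done <- matrix(FALSE, p, p)
      for (i in seq_len(nrow(wl))) {
        f <- match(wl[i, 1], nodes); t <- match(wl[i, 2], nodes)
        if (done[f, t] || done[t, f]) next
        pick <- NULL
        for (d in list(c(f, t), c(t, f)))
          if (allowed[d[1], d[2]] && !amat_has_path(start, d[2], d[1])) {
            pick <- d; break
          }
        if (is.null(pick))
          stop("whitelist is contradictory (cycle or banned direction)")
        start[pick[1], pick[2]] <- 1L
        done[f, t] <- TRUE; done[t, f] <- TRUE
      }
    }
  }
  list(allowed = allowed, mustpair = mustpair, lp = lp, start = start)
}

degenerate_error <- function(msg) {
  stop(structure(class = c("bnimpute_degenerate", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Greedy structure search
#'
#' Hill climbing from the whitelist-only graph: at each step every valid
#' single-arc addition, deletion and reversal is evaluated and the best
#' strictly improving move applied, until a local maximum; the climb is
#' repeated per the restart policy and the highest-scoring structure seen is
#' returned.  Whitelisted edges are never removed; blacklisted, cycle-forming,
#' genetic-in-edge and continuous-into-discrete moves are never proposed.
#'
#' @param data complete [mixed_data()] (impute or reduce first).
#' @param spec a [score_spec()]; soft priors require `"bic"`.
#' @param constraints optional [constraint_set()].
#' @param config a [search_config()].
#' @return List of class `bn_fit` with elements `dag` ([bn_dag()]) and
#'   `score`.
#' @export
greedy_search <- function(data, spec = score_spec(), constraints = NULL,
                          config = search_config()) {
  stopifnot(inherits(data, "mixed_data"), inherits(config, "search_config"))
  if (data$n < 1) degenerate_error("cannot fit a network to an empty dataset")
  if (!is.null(constraints) && NROW(constraints$priors) && spec$type != "bic")
    stop("soft priors require the BIC score")
  cm <- constraint_matrices(data$vars, constraints)
  ctx <- score_ctx(data)
  pen <- score_penalty(spec, ctx$n)
  with_seed(config$seed, {
    if (ctx$all_cont) {
      res <- cpp_hc_gauss(ctx$C, ctx$n, pen, cm$allowed, cm$mustpair, cm$lp,
                          cm$start, config$random_restarts,
                          config$jitter_restarts, config$jitter_moves,
                          config$restart_q, config$max_iterations)
    } else {
      res <- hc_generic(ctx, pen, cm, config)
    }
    if (is.na(res$score))
      degenerate_error("all candidate structures give degenerate fits")
    amat <- res$amat
    dimnames(amat) <- list(ctx$nodes, ctx$nodes)
    dag <- bn_dag(data$vars)
    dag$amat <- amat
    structure(list(dag = dag, score = res$score, spec = spec),
              class = "bn_fit")
  })
}

#' @export
print.bn_fit <- function(x, ...) {
  cat("Best-fit network (", x$spec$type, " score ",
      format(x$score, digits = 8), ")\n", sep = "")
  print(x$dag)
  invisible(x)
}

# Generic (mixed-data) hill climber mirroring the compiled engine: same move
# ordering, same strict-improvement tolerance, restarts included.
hc_generic <- function(ctx, pen, cm, config) {
  p <- length(ctx$nodes)
  tol <- 1e-9
  local_cache <- new.env(parent = emptyenv())
  local_sc <- function(j, pa) {
    key <- paste0(j, "|", paste(pa, collapse = ","))
    v <- local_cache[[key]]
    if (is.null(v)) {
      v <- local_score_ctx(ctx, j, pa, pen)$score
      local_cache[[key]] <- v
    }
    v
  }
  climb <- function(amat) {
    ls <- vapply(seq_len(p), function(j) local_sc(j, which(amat[, j] == 1L)),
                 numeric(1))
    if (anyNA(ls)) return(list(amat = amat, score = NA_real_))
    total <- function() sum(ls) + sum(cm$lp[amat == 1L])
    for (iter in seq_len(config$max_iterations)) {
      best <- tol; bm <- NULL
      # first-in-order wins among deltas within tol, as in the fast engine
      better <- function(d) !is.na(d) &&
        (if (is.null(bm)) d > best else d > best + tol)
      for (i in seq_len(p)) for (j in seq_len(p)) {
        if (i == j) next
        pa <- which(amat[, j] == 1L)
        if (!amat[i, j] && !amat[j, i] && cm$allowed[i, j] &&
            !amat_has_path(amat, j, i)) {
          d <- local_sc(j, sort(c(pa, i))) - ls[j] + cm$lp[i, j]
          if (better(d)) { best <- d; bm <- list("add", i, j) }
        }
        if (amat[i, j]) {
          dj <- local_sc(j, setdiff(pa, i)) - ls[j] - cm$lp[i, j]
          if (!cm$mustpair[i, j] && better(dj)) {
            best <- dj; bm <- list("delete", i, j)
          }
          if (cm$allowed[j, i] && !is.na(dj)) {
            a2 <- amat; a2[i, j] <- 0L
            if (!amat_has_path(a2, i, j)) {
              di <- local_sc(i, sort(c(which(amat[, i] == 1L), j))) -
                ls[i] + cm$lp[j, i]
              d <- dj + di
              if (better(d)) { best <- d; bm <- list("reverse", i, j) }
            }
          }
        }
      }
      if (is.null(bm)) break
      i <- bm[[2]]; j <- bm[[3]]
      if (bm[[1]] == "add") amat[i, j] <- 1L
      else if (bm[[1]] == "delete") amat[i, j] <- 0L
      else { amat[i, j] <- 0L; amat[j, i] <- 1L }
      ls[j] <- local_sc(j, which(amat[, j] == 1L))
      if (bm[[1]] == "reverse") ls[i] <- local_sc(i, which(amat[, i] == 1L))
    }
    list(amat = amat, score = total())
  }
  best <- climb(cm$start)
  for (r in seq_len(config$random_restarts)) {
    g <- random_start_amat(cm, config$restart_q)
    cand <- climb(g)
    if (!is.na(cand$score) &&
        (is.na(best$score) || cand$score > best$score + tol)) best <- cand
  }
  for (r in seq_len(config$jitter_restarts)) {
    if (is.na(best$score)) break
    g <- jitter_amat(best$amat, cm, config$jitter_moves)
    cand <- climb(g)
    if (!is.na(cand$score) && cand$score > best$score + tol) best <- cand
  }
  best
}

# Random valid DAG: uniform node ordering, each order-compatible allowed edge
# included with probability q, layered over the mandatory whitelist edges.
random_start_amat <- function(cm, q) {
  p <- nrow(cm$start)
  amat <- cm$start
  perm <- sample.int(p)
  rank <- order(perm)
  rank[perm] <- seq_len(p)
  for (u in seq_len(p)) for (v in seq_len(p)) {
    if (u >= v) next
    if (amat[u, v] || amat[v, u]) next
    if (runif(1) >= q) next
    a <- if (rank[u] < rank[v]) u else v
    b <- if (a == u) v else u
    if (!cm$allowed[a, b] || cm$lp[a, b] == -Inf) next
    if (amat_has_path(amat, b, a)) next
    amat[a, b] <- 1L
  }
  amat
}

jitter_amat <- function(amat, cm, nmoves) {
  p <- nrow(amat)
  for (m in seq_len(nmoves)) {
    moves <- list()
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j) next
      if (!amat[i, j] && !amat[j, i] && cm$allowed[i, j] &&
          cm$lp[i, j] != -Inf && !amat_has_path(amat, j, i))
        moves[[length(moves) + 1L]] <- c(0L, i, j)
      if (amat[i, j]) {
        if (!cm$mustpair[i, j]) moves[[length(moves) + 1L]] <- c(1L, i, j)
        if (cm$allowed[j, i] && cm$lp[j, i] != -Inf) {
          a2 <- amat; a2[i, j] <- 0L
          if (!amat_has_path(a2, i, j))
            moves[[length(moves) + 1L]] <- c(2L, i, j)
        }
      }
    }
    if (!length(moves)) return(amat)
    mv <- moves[[sample.int(length(moves), 1)]]
    if (mv[1] == 0L) amat[mv[2], mv[3]] <- 1L
    else if (mv[1] == 1L) amat[mv[2], mv[3]] <- 0L
    else { amat[mv[2], mv[3]] <- 0L; amat[mv[3], mv[2]] <- 1L }
  }
  amat
}

#' Random valid starting network
#'
#' Draws a uniformly random node ordering and includes each order-compatible,
#' constraint-valid edge with probability `q`; whitelisted edges are always
#' present.  Uses the current RNG stream.
#'
#' @param nodes node names, a [variable_spec()] or a [mixed_data()].
#' @param constraints optional [constraint_set()].
#' @param q edge inclusion probability (default 0.25).
#' @return A valid [bn_dag()].
#' @export
random_start <- function(nodes, constraints = NULL, q = 0.25) {
  vars <- if (inherits(nodes, "mixed_data")) nodes$vars
          else if (inherits(nodes, "variable_spec")) nodes
          else variable_spec(as.character(nodes))
  cm <- constraint_matrices(vars, constraints)
  dag <- bn_dag(vars)
  dag$amat <- random_start_amat(cm, q)
  dag
}

#' Exhaustive structure search
#'
#' Enumerates every labelled DAG over the variables that satisfies the
#' constraints and returns a global score maximiser (ties broken by the
#' lexicographically smallest edge set).  Feasible only for small networks;
#' refuses above `max_nodes`.
#'
#' @inheritParams greedy_search
#' @param max_nodes refusal bound on the node count (default 5).
#' @return List of class `bn_fit` with `dag`, `score` and `n_structures`,
#'   the number of candidate DAGs enumerated.
#' @export
exhaustive_search <- function(data, spec = score_spec(), constraints = NULL,
                              max_nodes = 5) {
  stopifnot(inherits(data, "mixed_data"))
  p <- nrow(data$vars)
  if (p > max_nodes)
    stop("exhaustive search refused for ", p, " nodes (bound ", max_nodes,
         "); use greedy_search()")
  if (data$n < 1) degenerate_error("cannot fit a network to an empty dataset")
  cm <- constraint_matrices(data$vars, constraints)
  ctx <- score_ctx(data)
  pen <- score_penalty(spec, ctx$n)
  cache <- new.env(parent = emptyenv())
  local_sc <- function(j, pa) {
    key <- paste0(j, "|", paste(pa, collapse = ","))
    v <- cache[[key]]
    if (is.null(v)) {
      v <- local_score_ctx(ctx, j, pa, pen)$score
      cache[[key]] <- v
    }
    v
  }
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  m <- nrow(pairs)
  n_structures <- 0L
  best_score <- NA_real_
  best_amat <- NULL
  best_edges <- NULL
  state <- integer(m)   # 0 none, 1 u->v, 2 v->u
  repeat {
    amat <- matrix(0L, p, p)
    ok <- TRUE
    for (k in seq_len(m)) {
      if (state[k] == 0L) next
      u <- pairs[k, 1]; v <- pairs[k, 2]
      f <- if (state[k] == 1L) u else v
      t <- if (state[k] == 1L) v else u
      if (!cm$allowed[f, t] || cm$lp[f, t] == -Inf) { ok <- FALSE; break }
      amat[f, t] <- 1L
    }
    if (ok && any(cm$mustpair == 1L & amat == 0L & t(amat) == 0L)) ok <- FALSE
    if (ok && amat_is_acyclic(amat)) {
      n_structures <- n_structures + 1L
      total <- 0
      for (j in seq_len(p)) {
        s <- local_sc(j, which(amat[, j] == 1L))
        if (is.na(s)) { total <- NA_real_; break }
        total <- total + s
      }
      if (!is.na(total)) {
        total <- total + sum(cm$lp[amat == 1L])
        edges <- amat_edge_string(amat, data$vars$name)
        take <- is.na(best_score) || total > best_score + 1e-9 ||
          (abs(total - best_score) <= 1e-9 &&
             edge_string_less(edges, best_edges))
        if (take) { best_score <- total; best_amat <- amat; best_edges <- edges }
      }
    }
    k <- 1L
    while (k <= m && state[k] == 2L) { state[k] <- 0L; k <- k + 1L }
    if (k > m) break
    state[k] <- state[k] + 1L
  }
  if (is.na(best_score))
    degenerate_error("no admissible structure could be scored")
  dimnames(best_amat) <- list(data$vars$name, data$vars$name)
  dag <- bn_dag(data$vars)
  dag$amat <- best_amat
  structure(list(dag = dag, score = best_score, spec = spec,
                 n_structures = n_structures),
            class = "bn_fit")
}

amat_edge_string <- function(amat, nodes) {
  idx <- which(amat == 1L, arr.ind = TRUE)
  e <- paste(nodes[idx[, 1]], nodes[idx[, 2]], sep = "->")
  sort(e)
}

# lexicographic comparison of sorted edge-string vectors (prefix-shorter wins)
edge_string_less <- function(a, b) {
  k <- min(length(a), length(b))
  if (k > 0) for (i in seq_len(k)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}
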