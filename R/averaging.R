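# Bootstrap model averaging: the data are resampled with replacement, the
# best-fit network learned on each resample, and per-pair appearance tallies
# turned into edge strength (probability an edge links the pair), direction
# (probability it points in the reference direction, given that it exists)
# and directed-edge probability (their product).

#' Bootstrap average network
#'
#' Resamples `B` datasets of `n` individuals with replacement, runs
#' [greedy_search()] on each, and tallies how often each unordered pair of
#' nodes is connected and in which direction.  The reference direction of a
#' pair is lexicographic (`node1 < node2`).  Per-resample seeds are derived
#' from `seed` as independent substreams, so increasing `B` extends rather
#' than reshuffles earlier resamples.  A resample on which every structure is
#' degenerate is recorded as an empty graph with a warning.
#'
#' @inheritParams greedy_search
#' @param B number of bootstrap resamples (default 1000; reduce for tests).
#' @param seed master seed for the resampling and searches.
#' @return Object of class `avg_network`: a data frame with columns `node1`,
#'   `node2`, `strength`, `direction` (NA when the pair never appears) and
#'   `edge_prob`, sorted by strength descending then lexicographically, with
#'   the bootstrap count in attribute `B`.
#' @export
bootstrap_average <- function(data, spec = score_spec(), constraints = NULL,
                              config = search_config(), B = 1000,
                              seed = NULL) {
  stopifnot(inherits(data, "mixed_data"), B >= 1)
  nodes <- data$vars$name
  p <- length(nodes)
  appear <- matrix(0, p, p, dimnames = list(nodes, nodes)) # directed tallies
  n_empty <- 0L
  seed <- seed %||% sample.int(2^31 - 2, 1)
  for (b in seq_len(B)) {
    res <- with_seed(substream_seed(seed, b), {
      rows <- sample.int(data$n, data$n, replace = TRUE)
      boot <- mixed_data(data$values[rows, , drop = FALSE], data$vars)
      tryCatch(greedy_search(boot, spec, constraints, config)$dag$amat,
               bnimpute_degenerate = function(e) NULL)
    })
    if (is.null(res)) {
      n_empty <- n_empty + 1L
      next
    }
    appear <- appear + res
  }
  if (n_empty > 0)
    warning(n_empty, " resample(s) had no admissible structure; ",
            "recorded as empty graphs")
  ut <- which(upper.tri(appear), arr.ind = TRUE)
  node1 <- nodes[ut[, 1]]; node2 <- nodes[ut[, 2]]
  swap <- node1 > node2
  fwd <- ifelse(swap, appear[cbind(ut[, 2], ut[, 1])],
                appear[cbind(ut[, 1], ut[, 2])])
  rev <- ifelse(swap, appear[cbind(ut[, 1], ut[, 2])],
                appear[cbind(ut[, 2], ut[, 1])])
  n1 <- ifelse(swap, node2, node1)
  n2 <- ifelse(swap, node1, node2)
  total <- fwd + rev
  out <- data.frame(node1 = n1, node2 = n2, strength = total / B,
                    direction = ifelse(total > 0, fwd / total, NA_real_),
                    stringsAsFactors = FALSE)
  out$edge_prob <- ifelse(total > 0, out$strength * out$direction, 0)
  out <- out[order(-out$strength, out$node1, out$node2), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, B = B, class = c("avg_network", "data.frame"))
}

#' Directed-edge probability
#'
#' The probability that the network has an edge between two nodes *and* that
#' it points in the reference direction: the product of the bootstrap
#' strength and direction.  Reported values are rounded half away from zero
#' when `digits` is given, matching the display convention of reported
#' average-network tables.
#'
#' @param strength,direction values in `[0, 1]`.
#' @param digits optional number of decimals for display rounding.
#' @return `strength * direction` (0 whenever `strength` is 0, regardless of
#'   direction).
#' @export
directed_edge_probability <- function(strength, direction, digits = NULL) {
  if (any(strength < 0 | strength > 1, na.rm = TRUE) ||
      any(direction < 0 | direction > 1, na.rm = TRUE))
    stop("strength and direction must lie in [0, 1]")
  out <- ifelse(strength == 0, 0, strength * direction)
  if (!is.null(digits)) out <- round_half_up(out, digits)
  out
}

#' Data-driven strength threshold
#'
#' Significance threshold for average-network strengths: assuming noise arcs
#' have true strength 0 and significant arcs true strength 1, picks the
#' threshold `t` whose induced two-point distribution is L1-closest to the
#' empirical CDF of the observed strengths.  Candidate thresholds are the
#' observed strength values; ties take the smallest.
#'
#' @param avg an `avg_network` from [bootstrap_average()], or a numeric
#'   vector of strengths.
#' @return Threshold in `[0, 1]`; edges with `strength >= t` are retained.
#' @export
strength_threshold <- function(avg) {
  s <- if (inherits(avg, "avg_network")) avg$strength else as.numeric(avg)
  if (!length(s)) stop("no strengths supplied")
  if (length(unique(s)) == 1L) {
    warning("all strengths identical; returning that value")
    return(s[1])
  }
  s <- sort(s)
  N <- length(s)
  # empirical CDF evaluated on the partition induced by the sorted strengths
  knots <- unique(c(0, s, 1))
  widths <- diff(knots)
  Fhat <- vapply(knots[-length(knots)], function(x) mean(s <= x), numeric(1))
  cand <- unique(s)
  l1 <- vapply(cand, function(t) {
    pi0 <- mean(s < t)   # proportion of arcs treated as noise
    sum(abs(Fhat - pi0) * widths)
  }, numeric(1))
  cand[which.min(l1)]   # which.min takes the first, i.e. smallest t
}

#' Likelihood-ratio significance of one edge
#'
#' Removes the edge, refits the child's local distribution, and compares the
#' maximised log-likelihoods: chi-squared statistic
#' \eqn{2(\log\hat L_{full} - \log\hat L_{reduced})} with degrees of freedom
#' equal to the difference in the child's free-parameter count.  Used to
#' scale plot line widths; no multiple-testing adjustment is applied.
#'
#' @inheritParams network_score
#' @param edge length-2 character vector `c(from, to)`; must be in `dag`.
#' @return List with `statistic`, `df` and `p.value`, or `NULL` components
#'   with a warning if the reduced fit is degenerate.
#' @export
edge_significance_lrt <- function(data, dag, edge, spec = score_spec()) {
  stopifnot(inherits(dag, "bn_dag"), length(edge) == 2)
  f <- edge[1]; t <- edge[2]
  if (dag$amat[f, t] != 1L) stop("edge ", f, " -> ", t, " not in the network")
  ctx <- score_ctx(data)
  pen <- score_penalty(spec, ctx$n)
  j <- match(t, ctx$nodes)
  pa <- match(dag$nodes[dag$amat[, t] == 1L], ctx$nodes)
  full <- local_score_ctx(ctx, j, pa, pen)
  red <- local_score_ctx(ctx, j, setdiff(pa, match(f, ctx$nodes)), pen)
  if (full$degenerate || red$degenerate) {
    warning("degenerate refit; significance unavailable")
    return(list(statistic = NA_real_, df = NA_real_, p.value = NA_real_))
  }
  stat <- 2 * (full$loglik - red$loglik)
  df <- full$nparams - red$nparams
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE))
}
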