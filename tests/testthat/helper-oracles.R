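# Independent oracles used to check the package's own implementations.
# These deliberately avoid the code paths they verify.

# --- d-separation by moralised ancestral graph reachability ---------------
# amat: adjacency matrix (amat[i, j] = 1 for i -> j), x, y node indices,
# S integer vector of conditioning nodes.
oracle_dsep <- function(amat, x, y, S) {
  p <- nrow(amat)
  # ancestors of {x, y} u S (including themselves)
  anc <- rep(FALSE, p)
  stack <- c(x, y, S)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (anc[v]) next
    anc[v] <- TRUE
    stack <- c(stack, which(amat[, v] == 1L))
  }
  keep <- which(anc)
  a <- amat[keep, keep, drop = FALSE]
  # moralise: marry parents, drop directions
  u <- (a + t(a)) > 0
  for (k in seq_along(keep)) {
    pa <- which(a[, k] == 1L)
    if (length(pa) > 1)
      for (ii in pa) for (jj in pa) if (ii != jj) u[ii, jj] <- TRUE
  }
  # reachability from x to y avoiding S
  xi <- match(x, keep); yi <- match(y, keep)
  Si <- match(intersect(S, keep), keep)
  blocked <- rep(FALSE, length(keep))
  blocked[Si] <- TRUE
  seen <- rep(FALSE, length(keep))
  stack <- xi
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[v] || blocked[v]) next
    seen[v] <- TRUE
    if (v == yi) return(FALSE)      # connected => not d-separated
    stack <- c(stack, which(u[v, ]))
  }
  TRUE
}

# full conditional-independence signature of a DAG: one logical per
# (pair, conditioning set) statement, in a fixed enumeration order
oracle_ci_signature <- function(amat) {
  p <- nrow(amat)
  out <- logical(0)
  for (x in seq_len(p - 1)) for (y in seq((x + 1), p)) {
    others <- setdiff(seq_len(p), c(x, y))
    subsets <- list(integer(0))
    for (o in others) subsets <- c(subsets, lapply(subsets, c, o))
    for (S in subsets) out <- c(out, oracle_dsep(amat, x, y, S))
  }
  out
}

# --- enumeration of all labelled DAGs over p nodes -----------------------
oracle_all_dags <- function(p) {
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  m <- nrow(pairs)
  out <- list()
  state <- integer(m)
  repeat {
    amat <- matrix(0L, p, p)
    for (k in seq_len(m)) {
      if (state[k] == 1L) amat[pairs[k, 1], pairs[k, 2]] <- 1L
      if (state[k] == 2L) amat[pairs[k, 2], pairs[k, 1]] <- 1L
    }
    # acyclicity by repeated sink removal
    a <- amat; ok <- TRUE
    act <- rep(TRUE, p)
    repeat {
      deg <- colSums(a[act, , drop = FALSE][, act, drop = FALSE])
      src <- which(deg == 0)
      if (!length(src)) break
      act[which(act)[src]] <- FALSE
    }
    if (any(act)) ok <- FALSE
    if (ok) out[[length(out) + 1L]] <- amat
    k <- 1L
    while (k <= m && state[k] == 2L) { state[k] <- 0L; k <- k + 1L }
    if (k > m) break
    state[k] <- state[k] + 1L
  }
  out
}

# --- closed-form Gaussian log-likelihood for a regression ----------------
oracle_gauss_loglik <- function(y, X = NULL) {
  n <- length(y)
  X <- cbind(rep(1, n), X)
  beta <- solve(crossprod(X), crossprod(X, y))
  rss <- sum((y - X %*% beta)^2)
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

# --- brute-force L1 threshold scan over a fine grid ----------------------
oracle_threshold <- function(strengths) {
  s <- sort(strengths)
  grid <- seq(0, 1, length.out = 2001)
  ecdf_s <- stats::ecdf(s)
  best <- Inf; best_t <- NA
  for (t in unique(s)) {
    pi0 <- mean(s < t)
    # integrate |ecdf - pi0| over [0, 1] on the fine grid
    l1 <- mean(abs(ecdf_s(grid[-length(grid)]) - pi0))
    if (l1 < best - 1e-12) { best <- l1; best_t <- t }
  }
  best_t
}

# small helper: continuous dataset from named columns
cont_data <- function(...) mixed_data(data.frame(...))
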