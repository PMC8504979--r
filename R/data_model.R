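# Typed representation of mixed discrete/continuous datasets, network
# structures and edge constraints, plus the structural validity rules that
# every other module relies on.

#' Variable metadata table
#'
#' Builds the per-variable metadata consumed by [mixed_data()]: each variable
#' is declared discrete or continuous and may carry a `genetic` flag marking
#' it as a causal anchor (a variable fixed at conception, such as a SNP, that
#' is never allowed to have incoming edges).  The flag is permitted on either
#' kind, since SNPs may be coded as continuous allele dosages.
#'
#' @param name character vector of unique variable names.
#' @param kind `"continuous"` or `"discrete"` (recycled; abbreviations
#'   `"c"`/`"d"` accepted).
#' @param genetic logical, recycled.
#' @param levels optional named list of level labels for discrete variables.
#' @return A data frame of class `variable_spec` with columns `name`, `kind`,
#'   `genetic` and a list column `levels`.
#' @export
variable_spec <- function(name, kind = "continuous", genetic = FALSE,
                          levels = NULL) {
  name <- as.character(name)
  if (anyDuplicated(name))
    stop("variable names must be unique: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  kind <- match_kind(rep_len(kind, length(name)))
  genetic <- rep_len(as.logical(genetic), length(name))
  lv <- rep(list(NULL), length(name))
  names(lv) <- name
  if (!is.null(levels))
    for (nm in names(levels)) lv[[nm]] <- as.character(levels[[nm]])
  out <- data.frame(name = name, kind = kind, genetic = genetic,
                    stringsAsFactors = FALSE)
  out$levels <- lv
  class(out) <- c("variable_spec", "data.frame")
  out
}

match_kind <- function(kind) {
  full <- c(c = "continuous", d = "discrete",
            continuous = "continuous", discrete = "discrete")
  kind <- full[tolower(as.character(kind))]
  if (anyNA(kind)) stop("variable kind must be 'discrete' or 'continuous'")
  unname(kind)
}

#' Mixed discrete/continuous dataset
#'
#' The individual-by-variable table consumed throughout the package.
#' Continuous variables are numeric columns; discrete variables are factors.
#' Missing entries are `NA` and are tracked in an observed mask.  Discrete
#' levels observed in the data but absent from the declared metadata are
#' appended with a warning.
#'
#' @param values a data frame (rows = individuals, columns = variables).
#'   Numeric columns are taken as continuous, factor/character columns as
#'   discrete, unless `vars` says otherwise.
#' @param vars optional [variable_spec()] table; defaults to inference from
#'   the column classes with no genetic flags.
#' @return An object of class `mixed_data`: a list with elements `values`
#'   (the typed data frame), `vars` (the metadata), `observed` (logical
#'   matrix) and `n` (number of individuals).  Row names of `values` are the
#'   individual identifiers (1-based row numbers when none are supplied).
#' @export
mixed_data <- function(values, vars = NULL) {
  values <- as.data.frame(values, stringsAsFactors = FALSE)
  if (is.null(vars)) {
    kinds <- ifelse(vapply(values, is.numeric, logical(1)),
                    "continuous", "discrete")
    vars <- variable_spec(names(values), kinds)
  }
  if (!inherits(vars, "variable_spec")) stop("'vars' must be a variable_spec")
  if (!setequal(vars$name, names(values)))
    stop("variable metadata does not match the data columns")
  values <- values[, vars$name, drop = FALSE]
  for (j in seq_along(vars$name)) {
    nm <- vars$name[j]
    if (vars$kind[j] == "continuous") {
      if (!is.numeric(values[[nm]]))
        stop("column '", nm, "' is declared continuous but is not numeric")
    } else {
      x <- values[[nm]]
      declared <- vars$levels[[nm]]
      # a factor's own levels are a declaration; otherwise use observed values
      obs <- if (is.factor(x)) levels(x) else
        sort(unique(as.character(x[!is.na(x)])))
      extra <- setdiff(obs, declared)
      if (!is.null(declared) && length(extra))
        warning("column '", nm, "' has undeclared levels appended: ",
                paste(extra, collapse = ", "))
      lev <- if (is.null(declared)) obs else c(declared, extra)
      if (length(lev) < 2)
        stop("discrete variable '", nm, "' has fewer than 2 levels")
      values[[nm]] <- factor(as.character(x), levels = lev)
      vars$levels[[nm]] <- lev
    }
  }
  if (is.null(attr(values, "row.names")) ||
      is.integer(attr(values, "row.names")))
    rownames(values) <- as.character(seq_len(nrow(values)))
  observed <- !is.na(as.matrix(values))
  dimnames(observed) <- list(rownames(values), vars$name)
  structure(list(values = values, vars = vars, observed = observed,
                 n = nrow(values)),
            class = "mixed_data")
}

#' @export
print.mixed_data <- function(x, ...) {
  cat("Mixed dataset:", x$n, "individuals x", nrow(x$vars), "variables\n")
  cat("  continuous:", sum(x$vars$kind == "continuous"),
      " discrete:", sum(x$vars$kind == "discrete"),
      " genetic:", sum(x$vars$genetic), "\n")
  miss <- sum(!x$observed)
  cat("  missing entries:", miss,
      sprintf("(%.1f%%)", 100 * miss / length(x$observed)), "\n")
  invisible(x)
}

#' @export
dim.mixed_data <- function(x) c(x$n, nrow(x$vars))

# Numeric encoding used by the scoring and imputation hot paths: continuous
# columns verbatim, discrete columns as 1-based level indices.
md_encode <- function(md) {
  p <- nrow(md$vars)
  m <- matrix(NA_real_, md$n, p, dimnames = dimnames(md$observed))
  nlev <- integer(p)
  for (j in seq_len(p)) {
    x <- md$values[[j]]
    if (md$vars$kind[j] == "discrete") {
      m[, j] <- as.integer(x)
      nlev[j] <- nlevels(x)
    } else m[, j] <- x
  }
  list(x = m, nlev = nlev, kind = md$vars$kind, genetic = md$vars$genetic)
}

# Rebuild a mixed_data from an encoded numeric matrix (inverse of md_encode
# for the same variable table).
md_decode <- function(enc_x, md) {
  vals <- as.data.frame(enc_x)
  names(vals) <- md$vars$name
  for (j in seq_len(nrow(md$vars)))
    if (md$vars$kind[j] == "discrete") {
      lev <- md$vars$levels[[md$vars$name[j]]]
      vals[[j]] <- factor(lev[enc_x[, j]], levels = lev)
    }
  rownames(vals) <- rownames(md$values)
  mixed_data(vals, md$vars)
}

#' Rows with no missing data
#'
#' Returns the subset of individuals with every variable observed (the
#' "reduced" analysis strategy).  Original row identifiers are preserved.  If
#' no complete rows exist, a zero-row dataset is returned with a warning;
#' model fitting refuses such input rather than crashing.
#'
#' @param data a [mixed_data()] object.
#' @return A `mixed_data` with the complete rows only.
#' @export
complete_rows <- function(data) {
  stopifnot(inherits(data, "mixed_data"))
  keep <- rowSums(data$observed) == ncol(data$observed)
  if (!any(keep)) warning("no individuals with complete data")
  mixed_data(data$values[keep, , drop = FALSE], data$vars)
}

## ---------------------------------------------------------------- DAGs ----

#' Directed acyclic graph over a set of variables
#'
#' @param nodes character vector of node names, or a [variable_spec()] /
#'   [mixed_data()] carrying kind and genetic metadata (needed to enforce the
#'   mixed-parent and causal-anchor rules).
#' @param edges `NULL`, a two-column matrix/data frame of directed edges
#'   (from, to), or a character vector like `"A->B"`.
#' @return An object of class `bn_dag` with an adjacency matrix `amat`
#'   (`amat[i, j] == 1` means an edge i -> j) and the node metadata.
#' @export
bn_dag <- function(nodes, edges = NULL) {
  vars <- NULL
  if (inherits(nodes, "mixed_data")) { vars <- nodes$vars; nodes <- vars$name }
  else if (inherits(nodes, "variable_spec")) { vars <- nodes; nodes <- vars$name }
  else nodes <- as.character(nodes)
  if (is.null(vars)) vars <- variable_spec(nodes)
  p <- length(nodes)
  amat <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  edges <- as_edge_matrix(edges, nodes)
  if (nrow(edges)) {
    if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
    amat[edges] <- 1L
    if (any(amat == 1L & t(amat) == 1L))
      stop("at most one edge per pair of nodes")
  }
  structure(list(nodes = nodes, amat = amat, vars = vars), class = "bn_dag")
}

# Normalise edge input to a 2-column character matrix; checks node names.
as_edge_matrix <- function(edges, nodes) {
  if (is.null(edges) || (is.data.frame(edges) && !nrow(edges)))
    return(matrix(character(), 0, 2,
                  dimnames = list(NULL, c("from", "to"))))
  if (is.character(edges) && is.null(dim(edges)) && any(grepl("->", edges, fixed = TRUE))) {
    parts <- strsplit(edges, "->", fixed = TRUE)
    edges <- do.call(rbind, lapply(parts, trimws))
  }
  edges <- as.matrix(edges)
  if (ncol(edges) < 2) stop("edges must have a 'from' and a 'to' column")
  edges <- matrix(as.character(edges[, 1:2]), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  if (!is.null(nodes)) {
    bad <- setdiff(c(edges), nodes)
    if (length(bad)) stop("unknown node name(s): ", paste(bad, collapse = ", "))
  }
  edges
}

#' Edge list of a DAG
#' @param dag a [bn_dag()].
#' @return Two-column character matrix (from, to), ordered row-major by the
#'   node ordering of the graph.
#' @export
dag_edges <- function(dag) {
  idx <- which(dag$amat == 1L, arr.ind = TRUE)
  out <- cbind(from = dag$nodes[idx[, 1]], to = dag$nodes[idx[, 2]])
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' @export
print.bn_dag <- function(x, ...) {
  e <- dag_edges(x)
  cat("DAG with", length(x$nodes), "nodes and", nrow(e), "edges\n")
  if (nrow(e)) cat(paste0("  ", e[, 1], " -> ", e[, 2]), sep = "\n")
  invisible(x)
}

# TRUE if the adjacency matrix (directed) is acyclic; repeated removal of
# sink-free... standard Kahn peeling of zero-in-degree nodes.
amat_is_acyclic <- function(amat) {
  p <- nrow(amat)
  if (p == 0) return(TRUE)
  indeg <- colSums(amat)
  active <- rep(TRUE, p)
  repeat {
    src <- which(active & indeg == 0)
    if (!length(src)) break
    for (s in src) indeg <- indeg - amat[s, ]
    active[src] <- FALSE
  }
  !any(active)
}

# TRUE if a path from -> ... -> to exists (used for cycle checks on moves).
amat_has_path <- function(amat, from, to) {
  if (from == to) return(TRUE)
  p <- nrow(amat)
  seen <- logical(p)
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    nxt <- which(amat[v, ] == 1L & !seen)
    if (to %in% nxt) return(TRUE)
    seen[nxt] <- TRUE
    stack <- c(stack, nxt)
  }
  FALSE
}

topological_order <- function(amat) {
  p <- nrow(amat)
  indeg <- colSums(amat)
  active <- rep(TRUE, p)
  ord <- integer(0)
  repeat {
    src <- which(active & indeg == 0)
    if (!length(src)) break
    ord <- c(ord, src)
    for (s in src) indeg <- indeg - amat[s, ]
    active[src] <- FALSE
  }
  if (any(active)) stop("graph is cyclic")
  ord
}

## --------------------------------------------------------- constraints ----

#' Hard and soft edge constraints
#'
#' Whitelisted directed edges must appear in every network; if both
#' directions of a pair are whitelisted the pair must be connected but may
#' take either direction.  Blacklisted directed edges may never appear.  Soft
#' priors attach a probability `p` in `[0, 1]` to a directed edge, with the
#' reverse direction implicitly carrying `1 - p`; declaring both directions
#' explicitly with probabilities not summing to one is an error.
#'
#' @param whitelist,blacklist `NULL`, a two-column matrix/data frame of
#'   directed edges, or `"A->B"` strings.
#' @param priors `NULL` or a data frame with columns `from`, `to`, `p`.
#' @param nodes optional node names used to validate the references now;
#'   otherwise they are checked when the constraints are first used.
#' @return Object of class `constraint_set`.
#' @export
constraint_set <- function(whitelist = NULL, blacklist = NULL, priors = NULL,
                           nodes = NULL) {
  # node-name checking is deferred to first use when 'nodes' is NULL
  wl <- unique(as_edge_matrix(whitelist, nodes))
  bl <- unique(as_edge_matrix(blacklist, nodes))
  if (nrow(wl) && nrow(bl)) {
    both <- intersect(edge_key(wl), edge_key(bl))
    if (length(both))
      stop("edge(s) in both whitelist and blacklist: ",
           paste(both, collapse = ", "))
  }
  pr <- normalise_priors(priors)
  structure(list(whitelist = wl, blacklist = bl, priors = pr),
            class = "constraint_set")
}

edge_key <- function(e) paste(e[, 1], e[, 2], sep = "->")

normalise_priors <- function(priors) {
  if (is.null(priors) || !NROW(priors))
    return(data.frame(from = character(), to = character(), p = numeric(),
                      stringsAsFactors = FALSE))
  priors <- as.data.frame(priors, stringsAsFactors = FALSE)
  if (!all(c("from", "to", "p") %in% names(priors)))
    stop("priors need columns 'from', 'to', 'p'")
  priors$p <- as.numeric(priors$p)
  if (any(priors$p < 0 | priors$p > 1)) stop("prior probabilities must lie in [0, 1]")
  key <- edge_key(as.matrix(priors[, c("from", "to")]))
  if (anyDuplicated(key)) stop("duplicate prior for edge ", key[duplicated(key)][1])
  rev_key <- paste(priors$to, priors$from, sep = "->")
  dup <- match(rev_key, key)
  both <- which(!is.na(dup) & seq_along(key) < dup)
  for (i in both) {
    j <- dup[i]
    if (abs(priors$p[i] + priors$p[j] - 1) > 1e-8)
      stop("priors for both directions of ", priors$from[i], " - ",
           priors$to[i], " do not sum to 1")
  }
  drop <- both_rev <- dup[both]
  if (length(drop)) priors <- priors[-drop, , drop = FALSE]
  rownames(priors) <- NULL
  priors[, c("from", "to", "p")]
}

# p x p matrix of log prior weights: lp[i, j] is added to the network score
# when edge i -> j is present.  Unflagged edges contribute 0; a prior of 0
# yields -Inf (network rejected).
prior_log_matrix <- function(nodes, constraints) {
  p <- length(nodes)
  lp <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (is.null(constraints)) return(lp)
  pr <- constraints$priors
  if (!NROW(pr)) return(lp)
  bad <- setdiff(c(pr$from, pr$to), nodes)
  if (length(bad)) stop("priors reference unknown node(s): ",
                        paste(bad, collapse = ", "))
  for (i in seq_len(nrow(pr))) {
    lp[pr$from[i], pr$to[i]] <- log(pr$p[i])
    lp[pr$to[i], pr$from[i]] <- log1p(-pr$p[i])
  }
  lp
}

## ----------------------------------------------------------- validation ----

#' Validate a network structure against the structural rules
#'
#' Checks the rules every search obeys: acyclicity, no edge into a genetic
#' (causal anchor) node, no continuous parent of a discrete node, no
#' blacklisted edge, and all whitelisted edges present (a pair whitelisted in
#' both directions may take either).  A whitelist entry pointing into a
#' genetic node is a configuration error, not a reported violation: the
#' causal-anchor rule is absolute.
#'
#' @param dag a [bn_dag()].
#' @param constraints optional [constraint_set()].
#' @return A list with `valid` (logical) and `violations` (data frame with
#'   columns `rule` and `detail`); valid iff no violations.
#' @export
validate_structure <- function(dag, constraints = NULL) {
  stopifnot(inherits(dag, "bn_dag"))
  viol <- list()
  add <- function(rule, detail)
    viol[[length(viol) + 1L]] <<- data.frame(rule = rule, detail = detail,
                                             stringsAsFactors = FALSE)
  if (!amat_is_acyclic(dag$amat)) add("cycle", "graph contains a directed cycle")
  e <- dag_edges(dag)
  kind <- stats::setNames(dag$vars$kind, dag$vars$name)
  genetic <- stats::setNames(dag$vars$genetic, dag$vars$name)
  for (i in seq_len(nrow(e))) {
    f <- e[i, 1]; t <- e[i, 2]
    if (genetic[t]) add("genetic-in-edge", paste0(f, " -> ", t))
    if (kind[f] == "continuous" && kind[t] == "discrete")
      add("mixed-parent", paste0(f, " -> ", t))
  }
  if (!is.null(constraints)) {
    stopifnot(inherits(constraints, "constraint_set"))
    cn <- unique(c(constraints$whitelist, constraints$blacklist,
                   constraints$priors$from, constraints$priors$to))
    unknown <- setdiff(cn, dag$nodes)
    if (length(unknown))
      stop("constraints reference unknown node(s): ",
           paste(unknown, collapse = ", "))
    wl <- constraints$whitelist
    if (nrow(wl)) {
      into_genetic <- genetic[wl[, 2]] &
        !(edge_key(wl[, c(2, 1), drop = FALSE]) %in% edge_key(wl))
      if (any(into_genetic))
        stop("whitelist points into genetic node(s): ",
             paste(wl[into_genetic, 2], collapse = ", "))
    }
    ek <- if (nrow(e)) edge_key(e) else character()
    bl <- constraints$blacklist
    for (i in seq_len(nrow(bl)))
      if (edge_key(bl[i, , drop = FALSE]) %in% ek)
        add("blacklist", paste0(bl[i, 1], " -> ", bl[i, 2]))
    wk <- if (nrow(wl)) edge_key(wl) else character()
    for (i in seq_len(nrow(wl))) {
      fwd <- edge_key(wl[i, , drop = FALSE])
      rev <- paste(wl[i, 2], wl[i, 1], sep = "->")
      either <- rev %in% wk       # both directions listed: any direction ok
      hit <- if (either) (fwd %in% ek) || (rev %in% ek) else fwd %in% ek
      if (!hit) add("whitelist-missing", paste0(wl[i, 1], " -> ", wl[i, 2]))
    }
  }
  viol <- if (length(viol)) unique(do.call(rbind, viol)) else
    data.frame(rule = character(), detail = character())
  list(valid = nrow(viol) == 0L, violations = viol)
}

## ---------------------------------------------------------------- CPDAG ----

#' Completed partially directed graph of a DAG's equivalence class
#'
#' Two DAGs are observationally equivalent -- representing the same
#' conditional dependencies and independencies -- exactly when they share a
#' skeleton and v-structures; such networks cannot be distinguished by score
#' and are all treated as "correct" in the evaluation module.  The CPDAG
#' keeps v-structure edges (and their Meek-rule consequences) directed and
#' leaves the rest undirected.
#'
#' @param dag a [bn_dag()] (must be acyclic).
#' @return Object of class `bn_cpdag`: node names plus an adjacency matrix
#'   where a directed edge i -> j has `amat[i, j] == 1` only, and an
#'   undirected edge has both entries 1.
#' @export
cpdag <- function(dag) {
  stopifnot(inherits(dag, "bn_dag"))
  if (!amat_is_acyclic(dag$amat)) stop("graph is cyclic")
  a <- dag$amat
  p <- nrow(a)
  skel <- (a + t(a)) > 0
  # start fully undirected, then pin v-structure orientations
  g <- matrix(as.integer(skel), p, p, dimnames = dimnames(a))
  for (k in seq_len(p)) {
    pa <- which(a[, k] == 1L)
    if (length(pa) < 2) next
    for (u in seq_along(pa)) for (v in seq_len(u - 1L)) {
      i <- pa[u]; j <- pa[v]
      if (!skel[i, j]) {          # unshielded collider i -> k <- j
        g[k, i] <- 0L; g[k, j] <- 0L
      }
    }
  }
  g <- meek_closure(g)
  structure(list(nodes = dag$nodes, amat = g), class = "bn_cpdag")
}

# Meek rules R1-R3 applied to a pattern (1/1 = undirected, 1/0 = directed).
meek_closure <- function(g) {
  p <- nrow(g)
  repeat {
    changed <- FALSE
    und <- which(g == 1L & t(g) == 1L, arr.ind = TRUE)
    for (r in seq_len(nrow(und))) {
      a <- und[r, 1]; b <- und[r, 2]   # candidate orientation a -> b
      if (g[a, b] != 1L || g[b, a] != 1L) next
      orient <- FALSE
      # R1: c -> a, c and b non-adjacent  =>  a -> b
      cs <- which(g[, a] == 1L & g[a, ] == 0L)
      if (any(g[cs, b] == 0L & g[b, cs] == 0L)) orient <- TRUE
      # R2: directed path a -> c -> b  =>  a -> b
      if (!orient) {
        cs <- which(g[a, ] == 1L & g[, a] == 0L)
        if (any(g[cs, b] == 1L & g[b, cs] == 0L)) orient <- TRUE
      }
      # R3: a - c -> b, a - d -> b, c/d non-adjacent  =>  a -> b
      if (!orient) {
        cs <- which(g[a, ] == 1L & g[, a] == 1L &
                    g[, b] == 1L & g[b, ] == 0L)
        if (length(cs) >= 2) {
          for (u in seq_along(cs)) for (v in seq_len(u - 1L)) {
            cc <- cs[u]; dd <- cs[v]
            if (g[cc, dd] == 0L && g[dd, cc] == 0L) orient <- TRUE
          }
        }
      }
      if (orient) { g[b, a] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  g
}

#' @export
print.bn_cpdag <- function(x, ...) {
  a <- x$amat
  dir <- which(a == 1L & t(a) == 0L, arr.ind = TRUE)
  und <- which(a == 1L & t(a) == 1L & upper.tri(a), arr.ind = TRUE)
  cat("CPDAG with", length(x$nodes), "nodes\n")
  for (r in seq_len(nrow(dir)))
    cat("  ", x$nodes[dir[r, 1]], "->", x$nodes[dir[r, 2]], "\n")
  for (r in seq_len(nrow(und)))
    cat("  ", x$nodes[und[r, 1]], "--", x$nodes[und[r, 2]], "\n")
  invisible(x)
}

cpdag_equal <- function(c1, c2) {
  identical(c1$nodes, c2$nodes) && all(c1$amat == c2$amat)
}
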