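# Reader and writer for discrete networks in BIF (Bayesian Interchange
# Format), the format used by the common benchmark network repositories.
# Only discrete variables are supported, as in the format itself.

#' Load a discrete network from a BIF file
#'
#' Parses variable declarations and conditional probability tables into a
#' [sim_model()] that [simulate_data()] can sample from.  Malformed input is
#' rejected with the offending line number; a parent level used in a
#' probability block but never declared is an error.
#'
#' @param path path to a BIF file.
#' @return A discrete [sim_model()].
#' @export
load_bif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  perr <- function(i, msg) stop("BIF parse error at line ", i, ": ", msg)
  # strip comments, keep line numbers
  txt <- sub("//.*$", "", lines)
  levels <- list()
  cpt <- list()
  parents <- list()
  i <- 1L
  n <- length(txt)
  skip_blank <- function(i) {
    while (i <= n && !nzchar(trimws(txt[i]))) i <- i + 1L
    i
  }
  # read a braced block from line i, tracking nesting depth ('{ ... }' may
  # appear within a single line, e.g. a level list)
  read_block <- function(i) {
    start <- i
    depth <- 0L
    block <- character()
    repeat {
      if (i > n) perr(start, "unterminated block")
      line <- txt[i]
      block <- c(block, line)
      depth <- depth + lengths(regmatches(line, gregexpr("{", line, fixed = TRUE))) -
        lengths(regmatches(line, gregexpr("}", line, fixed = TRUE)))
      i <- i + 1L
      if (depth <= 0L && any(grepl("{", block, fixed = TRUE))) break
    }
    list(block = block, next_i = i)
  }
  while ((i <- skip_blank(i)) <= n) {
    line <- trimws(txt[i])
    if (grepl("^network\\b", line)) {
      blk <- read_block(i)
      i <- blk$next_i
    } else if (grepl("^variable\\b", line)) {
      nm <- sub("^variable[ \t]+([^ \t{]+).*$", "\\1", line)
      start <- i
      blk <- read_block(i)
      i <- blk$next_i
      body <- paste(blk$block, collapse = " ")
      m <- regmatches(body,
        regexec("type\\s+discrete\\s*\\[\\s*(\\d+)\\s*\\]\\s*\\{([^}]*)\\}", body))[[1]]
      if (length(m) < 3) perr(start, "variable '" %+% nm %+%
                                "' lacks a discrete type declaration")
      lev <- trimws(strsplit(m[3], ",", fixed = TRUE)[[1]])
      lev <- lev[nzchar(lev)]
      if (length(lev) != as.integer(m[2]))
        perr(start, "level count mismatch for variable '" %+% nm %+% "'")
      if (length(lev) < 2) perr(start, "variable '" %+% nm %+%
                                  "' needs at least 2 levels")
      levels[[nm]] <- lev
    } else if (grepl("^probability\\b", line)) {
      start <- i
      blk <- read_block(i)
      i <- blk$next_i
      body <- paste(blk$block, collapse = "\n")
      hdr <- regmatches(body, regexec(
        "probability[ \t]*\\(([^)]*)\\)", body))[[1]]
      if (length(hdr) < 2) perr(start, "malformed probability header")
      parts <- strsplit(hdr[2], "|", fixed = TRUE)[[1]]
      child <- trimws(parts[1])
      if (!nzchar(child)) perr(start, "malformed probability header")
      pa <- if (length(parts) > 1) {
        v <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
        v[nzchar(v)]
      } else character()
      if (is.null(levels[[child]]))
        perr(start, "probability block for undeclared variable '" %+%
               child %+% "'")
      for (pp in pa) if (is.null(levels[[pp]]))
        perr(start, "undeclared parent '" %+% pp %+% "'")
      r <- length(levels[[child]])
      q <- if (length(pa)) prod(vapply(levels[pa], length, integer(1))) else 1L
      tab <- matrix(NA_real_, q, r)
      cfg_keys <- if (length(pa))
        do.call(paste, c(expand.grid(levels[pa], stringsAsFactors = FALSE),
                         sep = "\r"))
      else "\r"
      inner <- sub("^[^{]*\\{", "", body)
      inner <- sub("\\}[^}]*$", "", inner)
      stmts <- trimws(strsplit(inner, ";", fixed = TRUE)[[1]])
      stmts <- stmts[nzchar(stmts)]
      for (s in stmts) {
        if (grepl("^table\\b", s)) {
          if (length(pa)) perr(start, "'table' entry with parents present")
          pr <- as.numeric(trimws(strsplit(sub("^table", "", s), ",")[[1]]))
          if (length(pr) != r || anyNA(pr))
            perr(start, "wrong number of probabilities for '" %+% child %+% "'")
          tab[1, ] <- pr
        } else {
          m <- regmatches(s, regexec("^\\(([^)]*)\\)\\s*(.*)$", s))[[1]]
          if (length(m) < 3) perr(start, "malformed table row '" %+% s %+% "'")
          cfg <- trimws(strsplit(m[2], ",", fixed = TRUE)[[1]])
          if (length(cfg) != length(pa))
            perr(start, "configuration arity mismatch in '" %+% s %+% "'")
          for (k in seq_along(pa))
            if (!cfg[k] %in% levels[[pa[k]]])
              perr(start, "undeclared level '" %+% cfg[k] %+%
                     "' of parent '" %+% pa[k] %+% "'")
          row <- match(paste(cfg, collapse = "\r"), cfg_keys)
          pr <- as.numeric(trimws(strsplit(m[3], ",")[[1]]))
          if (length(pr) != r || anyNA(pr))
            perr(start, "wrong number of probabilities in '" %+% s %+% "'")
          tab[row, ] <- pr
        }
      }
      if (anyNA(tab)) perr(start, "incomplete CPT for '" %+% child %+% "'")
      if (any(abs(rowSums(tab) - 1) > 1e-6))
        perr(start, "CPT rows for '" %+% child %+% "' do not sum to 1")
      colnames(tab) <- levels[[child]]
      cpt[[child]] <- list(parents = pa, table = tab)
      parents[[child]] <- pa
    } else {
      perr(i, "unexpected content '" %+% line %+% "'")
    }
  }
  nodes <- names(levels)
  missing_cpt <- setdiff(nodes, names(cpt))
  if (length(missing_cpt))
    stop("BIF parse error: no probability block for ",
         paste(missing_cpt, collapse = ", "))
  edges <- do.call(rbind, lapply(nodes, function(nm)
    if (length(parents[[nm]])) cbind(parents[[nm]], nm) else NULL))
  vars <- variable_spec(nodes, "discrete", levels = levels)
  dag <- bn_dag(vars, edges)
  sim_model(dag, cpt = cpt)
}

`%+%` <- function(a, b) paste0(a, b)

#' Write a discrete network to a BIF file
#'
#' Canonical output that [load_bif()] reads back losslessly (same nodes,
#' levels, parents and probabilities).
#'
#' @param model a discrete [sim_model()].
#' @param path output path.
#' @export
write_bif <- function(model, path) {
  stopifnot(inherits(model, "sim_model"))
  vars <- model$dag$vars
  if (any(vars$kind != "discrete"))
    stop("BIF supports discrete networks only")
  out <- c("network unknown {", "}")
  for (nm in vars$name) {
    lev <- vars$levels[[nm]]
    out <- c(out,
             paste0("variable ", nm, " {"),
             paste0("  type discrete [ ", length(lev), " ] { ",
                    paste(lev, collapse = ", "), " };"),
             "}")
  }
  for (nm in vars$name) {
    entry <- model$cpt[[nm]]
    pa <- entry$parents
    if (!length(pa)) {
      out <- c(out,
               paste0("probability ( ", nm, " ) {"),
               paste0("  table ", paste(format(entry$table[1, ],
                                               digits = 15, trim = TRUE),
                                        collapse = ", "), ";"),
               "}")
    } else {
      cfgs <- expand.grid(vars$levels[pa], stringsAsFactors = FALSE)
      rows <- vapply(seq_len(nrow(cfgs)), function(g)
        paste0("  ( ", paste(unlist(cfgs[g, ]), collapse = ", "), " ) ",
               paste(format(entry$table[g, ], digits = 15, trim = TRUE),
                     collapse = ", "), ";"),
        character(1))
      out <- c(out,
               paste0("probability ( ", nm, " | ",
                      paste(pa, collapse = ", "), " ) {"),
               rows, "}")
    }
  }
  writeLines(out, path)
  invisible(path)
}
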