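# Delimited-text readers and writers: data tables with a variable-metadata
# sidecar, constraint files, edge lists and DOT export.

#' Read a mixed dataset from delimited text
#'
#' The data file has a header row of variable names and one row per
#' individual (tab-separated by default; comma accepted).  The optional
#' sidecar declares each variable's kind and genetic status; without it,
#' numeric columns are taken as continuous and the rest as discrete.
#'
#' @param file data file path.
#' @param vars_file optional sidecar path (see [read_variable_spec()]).
#' @param sep field separator; `NULL` auto-detects tab versus comma from the
#'   header line.
#' @param missing the missing-value code (default `"NA"`).
#' @return A [mixed_data()].
#' @export
read_mixed_data <- function(file, vars_file = NULL, sep = NULL,
                            missing = "NA") {
  if (is.null(sep)) {
    hdr <- readLines(file, n = 1)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- read.table(file, header = TRUE, sep = sep, na.strings = missing,
                   stringsAsFactors = FALSE, check.names = FALSE)
  vars <- if (!is.null(vars_file)) read_variable_spec(vars_file) else NULL
  if (!is.null(vars))
    for (j in which(vars$kind == "continuous"))
      df[[vars$name[j]]] <- as.numeric(df[[vars$name[j]]])
  mixed_data(df, vars)
}

#' Read a variable-metadata sidecar
#'
#' Two or three whitespace-separated columns per line: variable name, kind
#' (`d`/`discrete` or `c`/`continuous`), and optionally the flag `genetic`.
#'
#' @param file sidecar path.
#' @return A [variable_spec()].
#' @export
read_variable_spec <- function(file) {
  lines <- readLines(file)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[ \t]+")
  name <- vapply(fields, `[`, character(1), 1)
  kind <- vapply(fields, `[`, character(1), 2)
  genetic <- vapply(fields, function(f)
    length(f) >= 3 && tolower(f[3]) == "genetic", logical(1))
  variable_spec(name, kind, genetic)
}

#' Read an edge-list constraint file
#'
#' One directed edge per line, `from<TAB>to` (whitespace tolerated).
#'
#' @param file path.
#' @return Two-column character matrix usable as a white or black list.
#' @export
read_edge_list <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(matrix(character(), 0, 2, dimnames = list(NULL, c("from", "to"))))
  fields <- strsplit(lines, "[ \t]+")
  do.call(rbind, lapply(fields, function(f) {
    if (length(f) < 2) stop("edge line needs 'from' and 'to': ", paste(f, collapse = " "))
    c(from = f[1], to = f[2])
  }))
}

#' Read a soft-prior file
#'
#' One line per flagged edge: `from<TAB>to<TAB>p`.
#'
#' @param file path.
#' @return Data frame with columns `from`, `to`, `p`.
#' @export
read_priors <- function(file) {
  lines <- trimws(readLines(file))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[ \t]+")
  out <- do.call(rbind, lapply(fields, function(f) {
    if (length(f) < 3) stop("prior line needs 'from', 'to' and 'p'")
    data.frame(from = f[1], to = f[2], p = as.numeric(f[3]),
               stringsAsFactors = FALSE)
  }))
  normalise_priors(out)
}

#' Write a dataset as tab-separated text
#' @param data a [mixed_data()].
#' @param file output path.
#' @param missing code written for missing entries.
#' @export
write_mixed_data <- function(data, file, missing = "NA") {
  stopifnot(inherits(data, "mixed_data"))
  write.table(data$values, file, sep = "\t", quote = FALSE,
              row.names = FALSE, na = missing)
  invisible(file)
}

#' Write a network as an edge-list TSV
#' @param dag a [bn_dag()] or `bn_fit`.
#' @param file output path.
#' @export
write_edges <- function(dag, file) {
  score <- NULL
  if (inherits(dag, "bn_fit")) { score <- dag$score; dag <- dag$dag }
  e <- dag_edges(dag)
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(score)) writeLines(paste0("# score\t", format(score, digits = 12)), con)
  writeLines("from\tto", con)
  if (nrow(e)) writeLines(paste(e[, 1], e[, 2], sep = "\t"), con)
  invisible(file)
}

#' Write an average network as TSV
#'
#' Columns node1, node2, strength, direction, edge_prob (the directed-edge
#' probability towards node2; both orientations are derivable since the
#' reverse direction carries `1 - direction`).
#'
#' @param avg an `avg_network` from [bootstrap_average()].
#' @param file output path.
#' @export
write_average_network <- function(avg, file) {
  stopifnot(inherits(avg, "avg_network"))
  write.table(as.data.frame(avg), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' DOT export of a network
#'
#' Writes a Graphviz DOT file.  For an average network, edges below the
#' strength threshold are omitted, each remaining pair is drawn in its
#' majority direction and labelled with its strength.
#'
#' @param x a [bn_dag()], `bn_fit` or `avg_network`.
#' @param file output path.
#' @param threshold strength threshold for average networks: a number or
#'   `"auto"` ([strength_threshold()]).
#' @export
write_dot <- function(x, file, threshold = "auto") {
  if (inherits(x, "bn_fit")) x <- x$dag
  lines <- c("digraph network {")
  if (inherits(x, "bn_dag")) {
    e <- dag_edges(x)
    lines <- c(lines, paste0("  \"", x$nodes, "\";"),
               if (nrow(e)) paste0("  \"", e[, 1], "\" -> \"", e[, 2], "\";"))
  } else if (inherits(x, "avg_network")) {
    t <- if (identical(threshold, "auto")) strength_threshold(x)
         else as.numeric(threshold)
    keep <- x[x$strength >= t & x$strength > 0, , drop = FALSE]
    nodes <- unique(c(x$node1, x$node2))
    lines <- c(lines, paste0("  \"", nodes, "\";"))
    for (r in seq_len(nrow(keep))) {
      fwd <- is.na(keep$direction[r]) || keep$direction[r] >= 0.5
      a <- if (fwd) keep$node1[r] else keep$node2[r]
      b <- if (fwd) keep$node2[r] else keep$node1[r]
      lines <- c(lines, sprintf("  \"%s\" -> \"%s\" [label=\"%.3f\"];",
                                a, b, keep$strength[r]))
    }
  } else stop("cannot export this object")
  lines <- c(lines, "}")
  writeLines(lines, file)
  invisible(file)
}
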