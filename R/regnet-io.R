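REGULATION_LEVELS <- c("Unknown", "Activation", "Repression")

#' Parse a TRRUST-layout interaction table
#'
#' Reads a tab- (or general whitespace-) separated table of transcription
#' factor to target-gene annotations. The expected layout is the TRRUST v2
#' one: \code{TF <tab> Target_Gene <tab> Regulation <tab> PMIDs}, where the
#' regulation label is one of \code{Activation}, \code{Repression} or
#' \code{Unknown}, and the optional fourth column holds \code{";"}-separated
#' PubMed ids. A header row is auto-detected (or forced/suppressed via
#' \code{dialect}) by the literal first cell \code{"TF"}.
#'
#' @param source Path to a file, or a character vector of raw lines
#'   (anything containing a newline, or of length > 1, is treated as text).
#' @param dialect One of \code{"auto"}, \code{"header"}, \code{"no_header"}.
#' @return A data frame of class \code{regulatory_interactions} with columns
#'   \code{tf}, \code{target}, \code{regulation} (factor with levels
#'   Unknown/Activation/Repression) and \code{pmids} (list column of
#'   character vectors), one row per annotation row in file order.
#' @examples
#' txt <- c("AHR\tIL6\tActivation\t20511231",
#'          "AHR\tIL6\tUnknown\t18483242; 23349129")
#' ints <- parse_interaction_table(txt)
#' ints$pmids[[2]]
#' @export
parse_interaction_table <- function(source, dialect = c("auto", "header", "no_header")) {
  dialect <- match.arg(dialect)
  lines <- interaction_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(empty_interactions())
  }
  fields <- lapply(lines, split_interaction_row)
  first_cell <- trimws(fields[[1L]][1L])
  has_header <- switch(dialect,
    header = TRUE,
    no_header = FALSE,
    auto = identical(first_cell, "TF")
  )
  if (has_header) {
    fields <- fields[-1L]
    lines <- lines[-1L]
    if (length(fields) == 0L) return(empty_interactions())
  }
  n <- length(fields)
  tf <- character(n); target <- character(n); regulation <- character(n)
  pmids <- vector("list", n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 3L) {
      stop(sprintf("row %d has %d column(s); at least 3 (TF, target, regulation) required: %s",
                   i, length(f), lines[i]), call. = FALSE)
    }
    tf[i] <- trimws(f[1L]); target[i] <- trimws(f[2L])
    reg <- trimws(f[3L])
    if (!reg %in% REGULATION_LEVELS) {
      stop(sprintf("row %d: unrecognized regulation label '%s' (expected %s)",
                   i, reg, paste(REGULATION_LEVELS, collapse = "/")), call. = FALSE)
    }
    regulation[i] <- reg
    pmids[[i]] <- if (length(f) >= 4L) {
      ids <- trimws(strsplit(paste(f[-(1:3)], collapse = " "), ";", fixed = TRUE)[[1L]])
      ids[nzchar(ids)]
    } else character(0)
    if (!nzchar(tf[i]) || !nzchar(target[i])) {
      stop(sprintf("row %d: empty TF or target symbol", i), call. = FALSE)
    }
  }
  new_interactions(tf, target, regulation, pmids)
}

interaction_lines <- function(source) {
  if (!is.character(source)) stop("source must be a path or character text", call. = FALSE)
  if (length(source) == 1L && !grepl("\n", source, fixed = TRUE) && file.exists(source)) {
    return(readLines(source, warn = FALSE))
  }
  unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
}

# TRRUST rows are tab-separated; fall back to runs of whitespace so that
# hand-written fixtures with spaces also parse. The PMID cell may contain
# "id; id" -- splitting on tabs first keeps it as one field.
split_interaction_row <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) {
    strsplit(line, "\t", fixed = TRUE)[[1L]]
  } else {
    # rejoin "12345; 67890" style pmid cells broken by the whitespace split
    f <- strsplit(trimws(line), "[ ]+")[[1L]]
    if (length(f) > 4L) f <- c(f[1:3], paste(f[-(1:3)], collapse = " "))
    f
  }
}

new_interactions <- function(tf, target, regulation, pmids) {
  out <- data.frame(tf = tf, target = target,
                    regulation = factor(regulation, levels = REGULATION_LEVELS),
                    stringsAsFactors = FALSE)
  out$pmids <- pmids
  class(out) <- c("regulatory_interactions", "data.frame")
  out
}

empty_interactions <- function() {
  new_interactions(character(0), character(0), character(0), list())
}

#' Write interactions back to a TRRUST-layout TSV
#'
#' Round-trips losslessly through [parse_interaction_table()]. Multiple
#' PubMed ids are joined with \code{"; "} as in the source database.
#'
#' @param interactions A \code{regulatory_interactions} data frame.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_interaction_table <- function(interactions, path) {
  stopifnot(inherits(interactions, "data.frame"))
  header <- "TF\tTarget_Gene\tRegulation\tPMID"
  rows <- if (nrow(interactions) == 0L) character(0) else {
    pmid_cell <- vapply(interactions$pmids, paste, "", collapse = "; ")
    paste(interactions$tf, interactions$target,
          as.character(interactions$regulation), pmid_cell, sep = "\t")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Build the directed regulatory graph from annotation rows
#'
#' Nodes are ordered by first appearance (TFs in row order, then unseen
#' targets); duplicate (tf, target) rows collapse to a single directed edge
#' whose annotation multiset retains every contributing regulation label.
#' Symbols are compared case-sensitively after whitespace trimming.
#'
#' @param interactions Nonempty \code{regulatory_interactions} data frame.
#' @return An object of class \code{regulatory_graph}: a list with
#'   \describe{
#'     \item{nodes}{character vector of unique symbols}
#'     \item{node_index}{named integer vector, symbol to 0-based index}
#'     \item{edges}{m x 2 integer matrix of 0-based (source, target) pairs,
#'       unique, in first-appearance order}
#'     \item{edge_annotations}{list of character vectors, per unique edge}
#'     \item{is_tf, is_target}{logical role flags per node}
#'     \item{interactions}{the input rows (kept for per-row statistics)}
#'   }
#' @export
build_graph <- function(interactions) {
  if (!inherits(interactions, "data.frame") || nrow(interactions) == 0L) {
    stop("interactions must be a nonempty interaction table", call. = FALSE)
  }
  tf <- interactions$tf; target <- interactions$target
  nodes <- unique(c(tf, target))
  node_index <- stats::setNames(seq_along(nodes) - 1L, nodes)
  src <- node_index[tf]; dst <- node_index[target]
  key <- paste(src, dst)
  first <- !duplicated(key)
  edges <- cbind(source = unname(src[first]), target = unname(dst[first]))
  ann <- split(as.character(interactions$regulation), factor(key, levels = key[first]))
  structure(list(
    nodes = nodes,
    node_index = node_index,
    edges = edges,
    edge_annotations = unname(ann),
    is_tf = nodes %in% tf,
    is_target = nodes %in% target,
    interactions = interactions
  ), class = "regulatory_graph")
}

#' @export
print.regulatory_graph <- function(x, ...) {
  cat(sprintf("regulatory_graph: %d nodes, %d unique directed edges (%d annotation rows)\n",
              length(x$nodes), nrow(x$edges), nrow(x$interactions)))
  cat(sprintf("  roles: %d TFs, %d targets, %d both\n",
              sum(x$is_tf), sum(x$is_target), sum(x$is_tf & x$is_target)))
  invisible(x)
}

n_nodes <- function(graph) length(graph$nodes)
n_edges <- function(graph) nrow(graph$edges)

#' Summarize a regulatory graph
#'
#' @param object A \code{regulatory_graph}.
#' @param ... Unused.
#' @return A list with node/edge/row counts, role counts and the
#'   regulation-label distribution over annotation rows (the row denominator)
#'   together with label proportions over both rows and unique edges.
#' @export
summary.regulatory_graph <- function(object, ...) {
  reg_rows <- table(object$interactions$regulation)
  list(
    n_nodes = length(object$nodes),
    n_edges = nrow(object$edges),
    n_rows = nrow(object$interactions),
    n_tf = sum(object$is_tf),
    n_target = sum(object$is_target),
    n_both = sum(object$is_tf & object$is_target),
    regulation_counts = as.list(reg_rows),
    regulation_frac_rows = as.list(reg_rows / max(1L, nrow(object$interactions))),
    regulation_frac_edges = as.list(reg_rows / max(1L, nrow(object$edges)))
  )
}
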