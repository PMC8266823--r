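#' Construct a heterogeneous signaling network
#'
#' A `signaling_network` holds an ordered node set and a list of typed
#' links. Directed links carry signal-flow orientation `source -> target`
#' (activation, inhibition, expression, phosphorylation, ...); undirected
#' links represent symmetric protein-protein interactions such as
#' binding/association and dissociation. Edge weights lie in `(0, 1]` and
#' default to 1 for unweighted pathway data.
#'
#' Construction normalizes the edge set: self-loops are dropped with a
#' warning (a node's own state cancels out of the consensus update), and
#' duplicate edges -- same endpoint pair and same directedness -- are
#' collapsed keeping the maximum weight. A directed and an undirected edge
#' between the same pair both survive; they are distinct interaction types
#' and contribute additively to the influence matrix.
#'
#' @param nodes character vector of unique node identifiers (gene symbols
#'   or synthetic ids); their order fixes the row/column order of every
#'   derived matrix.
#' @param edges a data frame with columns `source`, `target`, `directed`
#'   (logical), and optionally `weight` (default 1) and `subtype`
#'   (free-text interaction label, default `""`). `NULL` means no edges.
#' @param name free-text label for the network.
#' @return an object of class `signaling_network`: a list with elements
#'   `nodes`, `edges` (normalized data frame), and `name`.
#' @seealso [read_edge_list()], [read_kgml()], [to_influence_matrix()]
#' @examples
#' net <- signaling_network(
#'   nodes = c("a", "b", "c"),
#'   edges = data.frame(source = c("a", "b"), target = c("b", "c"),
#'                      directed = c(TRUE, FALSE))
#' )
#' net
#' @export
signaling_network <- function(nodes, edges = NULL, name = "network") {
  nodes <- as.character(nodes)
  if (length(nodes) < 1L) {
    stop("a signaling network needs at least one node", call. = FALSE)
  }
  if (anyDuplicated(nodes)) {
    stop("duplicate node identifiers: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "),
         call. = FALSE)
  }
  edges <- normalize_edges(edges, nodes)
  structure(list(nodes = nodes, edges = edges, name = name),
            class = "signaling_network")
}

# Canonical empty edge table; keeps column types stable everywhere.
empty_edges <- function() {
  data.frame(source = character(), target = character(),
             directed = logical(), weight = numeric(),
             subtype = character(), stringsAsFactors = FALSE)
}

# Validate endpoints/weights, drop self-loops (warning), collapse duplicate
# (pair, directedness) edges to the maximum weight. Undirected pairs are
# compared unordered.
normalize_edges <- function(edges, nodes) {
  if (is.null(edges) || nrow(edges) == 0L) return(empty_edges())
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  required <- c("source", "target", "directed")
  missing_cols <- setdiff(required, names(edges))
  if (length(missing_cols)) {
    stop("edge table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(edges$weight)) edges$weight <- 1
  if (is.null(edges$subtype)) edges$subtype <- ""
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  edges$directed <- as.logical(edges$directed)
  edges$weight <- as.numeric(edges$weight)
  edges$subtype <- as.character(edges$subtype)

  unknown <- setdiff(c(edges$source, edges$target), nodes)
  if (length(unknown)) {
    stop("edge endpoint(s) not declared as nodes: ",
         paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  bad_w <- !is.finite(edges$weight) | edges$weight <= 0 | edges$weight > 1
  if (any(bad_w)) {
    stop("edge weight outside (0, 1] at edge row(s) ",
         paste(which(bad_w), collapse = ", "), call. = FALSE)
  }

  loops <- edges$source == edges$target
  if (any(loops)) {
    warning(sum(loops), " self-loop edge(s) dropped", call. = FALSE)
    edges <- edges[!loops, , drop = FALSE]
  }
  if (nrow(edges) == 0L) return(empty_edges())

  # unordered key for undirected edges, ordered for directed ones
  a <- ifelse(edges$directed, edges$source, pmin(edges$source, edges$target))
  b <- ifelse(edges$directed, edges$target, pmax(edges$source, edges$target))
  key <- paste(a, b, ifelse(edges$directed, "d", "u"), sep = "\r")
  keep <- !logical(nrow(edges))
  if (anyDuplicated(key)) {
    ord <- order(key, -edges$weight)
    edges <- edges[ord, , drop = FALSE]
    keep <- !duplicated(key[ord])
    edges <- edges[keep, , drop = FALSE]
    edges <- edges[order(as.integer(rownames(edges))), , drop = FALSE]
  }
  rownames(edges) <- NULL
  edges[, c("source", "target", "directed", "weight", "subtype")]
}

#' @export
print.signaling_network <- function(x, ...) {
  n_dir <- sum(x$edges$directed)
  cat(sprintf("signaling_network '%s': %d nodes, %d edges (%d directed, %d undirected)\n",
              x$name, length(x$nodes), nrow(x$edges), n_dir,
              nrow(x$edges) - n_dir))
  invisible(x)
}

#' Read a signaling network from a TSV edge list
#'
#' Expects a UTF-8 tab-separated file with header
#' `source<TAB>target<TAB>type<TAB>weight`; the `weight` column may be
#' omitted (all weights then default to 1). `type` must be `directed` or
#' `undirected`. Lines starting with `#` and blank lines are skipped.
#' Malformed rows, weights outside `(0, 1]`, and unknown types are
#' rejected with the offending file line number. Nodes are declared in
#' first-appearance order; self-loops are dropped with a warning and
#' duplicate edges collapsed to the maximum weight.
#'
#' @param path path to the edge-list file.
#' @param name network label; defaults to the file name.
#' @return a [signaling_network()].
#' @seealso [write_edge_list()]
#' @export
read_edge_list <- function(path, name = basename(path)) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop("empty edge-list file: ", path, call. = FALSE)
  content <- !grepl("^\\s*(#|$)", lines)
  idx <- which(content)
  if (length(idx) == 0L) stop("no data rows in ", path, call. = FALSE)
  header <- strsplit(lines[idx[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L || any(header[1:3] != c("source", "target", "type"))) {
    stop("line ", idx[1L],
         ": header must start with 'source\\ttarget\\ttype'", call. = FALSE)
  }
  has_weight <- length(header) >= 4L && header[4L] == "weight"

  rows <- idx[-1L]
  src <- tgt <- character(length(rows))
  dir <- logical(length(rows))
  wt <- numeric(length(rows))
  for (k in seq_along(rows)) {
    ln <- rows[k]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L || any(!nzchar(f[1:3]))) {
      stop("line ", ln, ": malformed row (need source, target, type)",
           call. = FALSE)
    }
    if (!f[3L] %in% c("directed", "undirected")) {
      stop("line ", ln, ": unknown edge type '", f[3L], "'", call. = FALSE)
    }
    w <- if (has_weight && length(f) >= 4L && nzchar(f[4L])) {
      suppressWarnings(as.numeric(f[4L]))
    } else 1
    if (is.na(w)) stop("line ", ln, ": unreadable weight '", f[4L], "'",
                       call. = FALSE)
    if (w <= 0 || w > 1) {
      stop("line ", ln, ": weight ", w, " outside (0, 1]", call. = FALSE)
    }
    src[k] <- f[1L]; tgt[k] <- f[2L]
    dir[k] <- f[3L] == "directed"; wt[k] <- w
  }
  nodes <- unique(c(rbind(src, tgt)))
  edges <- data.frame(source = src, target = tgt, directed = dir,
                      weight = wt, subtype = "", stringsAsFactors = FALSE)
  signaling_network(nodes, edges, name = name)
}

#' Write a signaling network as a TSV edge list
#'
#' Emits the normalized edge set in the dialect read by
#' [read_edge_list()]: header `source target type weight` (tab-separated),
#' one edge per row. Reading the file back reproduces the edge set
#' exactly (nodes incident to at least one edge; isolated nodes have no
#' row to carry them).
#'
#' @param net a [signaling_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "signaling_network"))
  e <- net$edges
  lines <- c("source\ttarget\ttype\tweight",
             sprintf("%s\t%s\t%s\t%s", e$source, e$target,
                     ifelse(e$directed, "directed", "undirected"),
                     format(e$weight, digits = 15, trim = TRUE)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Expand group (complex) nodes into their member nodes
#'
#' A group node stands for a protein complex. Expansion removes the group
#' node, connects its members pairwise by undirected weight-1 links, and
#' replicates every edge incident to the group onto every member with the
#' original direction, type and weight -- an interaction `A -> group` with
#' members `B1..Bk` becomes the k interactions `A -> B1, ..., A -> Bk`.
#' Duplicate edges created by the expansion collapse under the usual
#' maximum-weight rule.
#'
#' @param net a [signaling_network()] whose nodes include the group ids.
#' @param groups named list mapping each group node id to a character
#'   vector of at least two member node ids (all declared nodes).
#' @return a [signaling_network()] without the group nodes.
#' @export
expand_group_nodes <- function(net, groups) {
  stopifnot(inherits(net, "signaling_network"))
  if (length(groups) == 0L) return(net)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("'groups' must be a named list (group id -> member ids)",
         call. = FALSE)
  }
  edges <- net$edges
  for (gid in names(groups)) {
    members <- as.character(groups[[gid]])
    if (!gid %in% net$nodes) {
      stop("group node '", gid, "' is not a declared node", call. = FALSE)
    }
    if (length(members) < 2L) {
      stop("group '", gid, "' must have at least 2 members", call. = FALSE)
    }
    bad <- setdiff(members, net$nodes)
    if (length(bad)) {
      stop("group '", gid, "' member(s) not declared nodes: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    touches <- edges$source == gid | edges$target == gid
    inherited <- empty_edges()
    if (any(touches)) {
      rep_rows <- edges[touches, , drop = FALSE]
      inherited <- do.call(rbind, lapply(members, function(m) {
        r <- rep_rows
        r$source[r$source == gid] <- m
        r$target[r$target == gid] <- m
        r
      }))
    }
    mutual <- expand.grid(i = seq_along(members), j = seq_along(members))
    mutual <- mutual[mutual$i < mutual$j, , drop = FALSE]
    mutual_edges <- data.frame(source = members[mutual$i],
                               target = members[mutual$j],
                               directed = FALSE, weight = 1,
                               subtype = "complex", stringsAsFactors = FALSE)
    edges <- rbind(edges[!touches, , drop = FALSE], inherited, mutual_edges)
  }
  nodes <- setdiff(net$nodes, names(groups))
  # expansion may produce member self-loops from group<->member edges;
  # normalization drops them silently here (they are artifacts, not data)
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  signaling_network(nodes, edges, name = net$name)
}
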