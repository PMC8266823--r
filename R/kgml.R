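#' Read a KEGG KGML pathway file as a signaling network
#'
#' Parses a KGML (KEGG Markup Language) XML document into a
#' heterogeneous network. `entry` elements of type `gene` become nodes,
#' named by the leading symbol(s) of their `graphics` name attribute
#' (comma-separated alias list, trailing "..." stripped). An entry whose
#' `name` attribute lists several gene identifiers (paralogous
#' alternatives) is expanded into one node per symbol, each inheriting
#' the entry's relations; no edges are added among the alternatives
#' themselves, unlike group members.
#'
#' `relation` elements become edges between the nodes of `entry1` and
#' `entry2`, with weight 1: subtypes `binding/association` and
#' `dissociation` map to undirected links; `activation`, `inhibition`,
#' `expression`, `indirect effect`, `compound`/`interaction via
#' compound`, `missing interaction`, `phosphorylation` and
#' `dephosphorylation` map to directed links `entry1 -> entry2` (KEGG
#' arrow orientation). Any other subtype is kept as a directed link with
#' its label recorded and a warning. Group entries (protein complexes)
#' are expanded: members gain pairwise undirected links and inherit
#' every relation of the group. Standalone `compound` and `map` entries
#' are ignored with a warning; relations touching them are skipped.
#'
#' @param path path to a KGML file.
#' @param name network label; defaults to the pathway `title` attribute
#'   or the file name.
#' @return a [signaling_network()].
#' @seealso [make_kgml_fixture()], [expand_group_nodes()]
#' @export
read_kgml <- function(path, name = NULL) {
  doc <- xml2::read_xml(path)  # errors on malformed XML
  if (is.null(name)) {
    name <- xml2::xml_attr(doc, "title")
    if (is.na(name) || !nzchar(name)) name <- basename(path)
  }

  entries <- xml2::xml_find_all(doc, ".//entry")
  entry_id <- xml2::xml_attr(entries, "id")
  entry_type <- xml2::xml_attr(entries, "type")

  node_map <- list()   # entry id -> character vector of node names
  group_members <- list()  # group entry id -> component entry ids
  nodes <- character()
  ignored <- character()

  for (k in seq_along(entries)) {
    id <- entry_id[k]
    type <- entry_type[k]
    if (identical(type, "gene")) {
      syms <- kgml_entry_symbols(entries[[k]], id)
      node_map[[id]] <- syms
      nodes <- c(nodes, setdiff(syms, nodes))
    } else if (identical(type, "group")) {
      comp <- xml2::xml_attr(xml2::xml_find_all(entries[[k]], "./component"),
                             "id")
      if (length(comp) < 2L) {
        stop("group entry '", id, "' has fewer than 2 components",
             call. = FALSE)
      }
      group_members[[id]] <- comp
    } else {
      ignored <- c(ignored, id)
    }
  }
  if (length(ignored)) {
    warning("ignored ", length(ignored), " non-gene entr",
            if (length(ignored) == 1L) "y" else "ies",
            " (compound/map/...): id ", paste(ignored, collapse = ", "),
            call. = FALSE)
  }
  # resolve groups to member node names (components must be gene entries
  # or nested groups; nesting resolved recursively)
  resolve <- function(id, seen = character()) {
    if (id %in% seen) stop("cyclic group nesting at entry '", id, "'",
                           call. = FALSE)
    if (!is.null(node_map[[id]])) return(node_map[[id]])
    if (!is.null(group_members[[id]])) {
      return(unique(unlist(lapply(group_members[[id]], resolve,
                                  seen = c(seen, id)))))
    }
    NULL
  }
  for (gid in names(group_members)) {
    members <- resolve(gid)
    if (is.null(members) || length(members) < 2L) {
      stop("group entry '", gid, "' does not resolve to >= 2 gene nodes",
           call. = FALSE)
    }
    node_map[[gid]] <- members
  }

  undirected_subtypes <- c("binding/association", "dissociation")
  directed_subtypes <- c("activation", "inhibition", "expression",
                         "repression", "indirect effect", "compound",
                         "interaction via compound", "missing interaction",
                         "phosphorylation", "dephosphorylation",
                         "ubiquitination", "state change")

  src <- tgt <- sub <- character()
  dir <- logical()
  relations <- xml2::xml_find_all(doc, ".//relation")
  for (rel in relations) {
    e1 <- xml2::xml_attr(rel, "entry1")
    e2 <- xml2::xml_attr(rel, "entry2")
    for (eid in c(e1, e2)) {
      if (!eid %in% entry_id) {
        stop("relation references unknown entry id '", eid, "'",
             call. = FALSE)
      }
    }
    if (e1 %in% ignored || e2 %in% ignored) {
      warning("skipped relation ", e1, "->", e2,
              " touching an ignored entry", call. = FALSE)
      next
    }
    subs <- xml2::xml_attr(xml2::xml_find_all(rel, "./subtype"), "name")
    if (length(subs) == 0L) {
      warning("relation ", e1, "->", e2,
              " has no subtype; kept as directed", call. = FALSE)
      subs <- "unknown"
    }
    unknown_subs <- setdiff(subs, c(undirected_subtypes, directed_subtypes,
                                    "unknown"))
    if (length(unknown_subs)) {
      warning("unlisted relation subtype(s) '",
              paste(unknown_subs, collapse = "', '"),
              "' kept as directed", call. = FALSE)
    }
    is_undirected <- all(subs %in% undirected_subtypes)
    label <- paste(subs, collapse = "+")
    for (n1 in node_map[[e1]]) {
      for (n2 in node_map[[e2]]) {
        src <- c(src, n1); tgt <- c(tgt, n2)
        dir <- c(dir, !is_undirected); sub <- c(sub, label)
      }
    }
  }

  # pairwise undirected links among the members of every group (complex)
  for (gid in names(group_members)) {
    members <- node_map[[gid]]
    pairs <- utils::combn(members, 2L)
    src <- c(src, pairs[1L, ]); tgt <- c(tgt, pairs[2L, ])
    dir <- c(dir, rep(FALSE, ncol(pairs)))
    sub <- c(sub, rep("complex", ncol(pairs)))
  }

  if (length(nodes) == 0L) stop("no gene entries in ", path, call. = FALSE)
  edges <- if (length(src)) {
    data.frame(source = src, target = tgt, directed = dir, weight = 1,
               subtype = sub, stringsAsFactors = FALSE)
  } else NULL
  edges <- if (is.null(edges)) NULL else
    edges[edges$source != edges$target, , drop = FALSE]  # paralog self-pairs
  signaling_network(nodes, edges, name = name)
}

# Node symbols of a gene entry: graphics name is a comma-separated alias
# list; the entry name attribute lists one database id per (paralogous)
# gene. One node per id, named by the corresponding leading symbols.
kgml_entry_symbols <- function(entry, id) {
  gr <- xml2::xml_find_first(entry, "./graphics")
  gname <- if (inherits(gr, "xml_missing")) NA_character_ else
    xml2::xml_attr(gr, "name")
  if (is.na(gname) || !nzchar(gname)) {
    stop("gene entry '", id, "' lacks a graphics name", call. = FALSE)
  }
  syms <- trimws(strsplit(gname, ",", fixed = TRUE)[[1L]])
  syms <- sub("\\.\\.\\.$", "", syms)
  syms <- syms[nzchar(syms)]
  if (length(syms) == 0L) {
    stop("gene entry '", id, "' has an empty graphics name", call. = FALSE)
  }
  ids <- strsplit(trimws(xml2::xml_attr(entry, "name")), "\\s+")[[1L]]
  n_genes <- max(1L, length(ids))
  unique(syms[seq_len(min(n_genes, length(syms)))])
}

#' Write a minimal KGML fixture file
#'
#' Serializes a small pathway description into well-formed KGML, for
#' tests, examples and demos. The description is a list with elements:
#'
#' * `entries`: list of lists with `id`, `name` (database id string, may
#'   list several ids separated by spaces), `type` (default `"gene"`),
#'   and `graphics` (alias string for the graphics name; default =
#'   `name`).
#' * `groups`: optional list of lists with `id` and `components`
#'   (character vector of entry ids).
#' * `relations`: optional list of lists with `entry1`, `entry2`,
#'   `subtype` (character vector of subtype names, default
#'   `"activation"`).
#'
#' @param spec pathway description (see Details).
#' @param path output path; defaults to a temporary `.xml` file.
#' @param title pathway title attribute.
#' @return the output path, invisibly.
#' @examples
#' f <- make_kgml_fixture(list(
#'   entries = list(list(id = "1", name = "hsa:10", graphics = "GENEA"),
#'                  list(id = "2", name = "hsa:20", graphics = "GENEB")),
#'   relations = list(list(entry1 = "1", entry2 = "2",
#'                         subtype = "activation"))))
#' read_kgml(f)
#' @export
make_kgml_fixture <- function(spec, path = tempfile(fileext = ".xml"),
                              title = "synthetic pathway") {
  known <- vapply(spec$entries, function(e) e$id, character(1))
  known <- c(known, vapply(spec$groups, function(g) g$id, character(1)))
  for (g in spec$groups) {
    bad <- setdiff(g$components, known)
    if (length(bad)) stop("group '", g$id, "' references undefined entr",
                          "y/ies: ", paste(bad, collapse = ", "),
                          call. = FALSE)
  }
  for (r in spec$relations) {
    bad <- setdiff(c(r$entry1, r$entry2), known)
    if (length(bad)) stop("relation references undefined entry id(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }
  doc <- xml2::xml_new_root("pathway", name = "path:synthetic",
                            org = "hsa", number = "00000", title = title)
  for (e in spec$entries) {
    type <- if (is.null(e$type)) "gene" else e$type
    node <- xml2::xml_add_child(doc, "entry", id = e$id, name = e$name,
                                type = type)
    gname <- if (is.null(e$graphics)) e$name else e$graphics
    xml2::xml_add_child(node, "graphics", name = gname, type = "rectangle")
  }
  for (g in spec$groups) {
    node <- xml2::xml_add_child(doc, "entry", id = g$id, name = "undefined",
                                type = "group")
    for (cid in g$components) xml2::xml_add_child(node, "component", id = cid)
  }
  for (r in spec$relations) {
    node <- xml2::xml_add_child(doc, "relation", entry1 = r$entry1,
                                entry2 = r$entry2, type = "PPrel")
    subs <- if (is.null(r$subtype)) "activation" else r$subtype
    for (s in subs) xml2::xml_add_child(node, "subtype", name = s, value = "")
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
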