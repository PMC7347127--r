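#' Parse an OBO 1.2/1.4 flat file into an ontology graph
#'
#' Reads `[Term]` stanzas and builds a validated directed acyclic graph of
#' child-to-parent subsumption edges. `is_a:` lines and
#' `relationship: part_of` lines become traversal edges; any other
#' `relationship:` type is recorded with its label but excluded from
#' traversal (ancestors, depth, information content). Obsolete terms are
#' kept out of the graph entirely but are indexed so that annotations to
#' them can be recognised and dropped; `alt_id:` lines are indexed to their
#' canonical term.
#'
#' Validation enforced at parse time: the traversal graph is acyclic, every
#' namespace has exactly one root (a non-obsolete term without traversal
#' parents), and every non-obsolete term reaches its namespace root.
#'
#' @param path path to an OBO flat file.
#' @return An object of class `ontology_graph`: a list with elements
#'   `ids` (character vector of non-obsolete term ids), `name`, `namespace`
#'   (named character vectors), `parents` and `parent_relation` (named lists
#'   of traversal parents and their relation labels), `other_parents`
#'   (non-traversal relationships, recorded but inert), `roots` (named
#'   character vector, namespace -> root id), `alt` (alt_id -> canonical id),
#'   `obsolete` (ids of obsolete terms), `anc` (named list of inclusive
#'   ancestor sets), `depth` (named integer, shortest path to the namespace
#'   root) and `ig` (the igraph used for path queries).
#' @seealso [parse_annotations()], [ancestors()], [term_depth()]
#' @examples
#' obo <- toy5_obo_text()
#' f <- tempfile(fileext = ".obo")
#' writeLines(obo, f)
#' g <- parse_obo(f)
#' g$roots
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) data_error(sprintf("OBO file not found: %s", path))
  parse_obo_lines(readLines(path, warn = FALSE))
}

# Core parser over a character vector of lines (used by parse_obo and the
# synthetic generator, which builds OBO text in memory).
parse_obo_lines <- function(lines) {
  lines <- sub("\r$", "", lines)
  # locate stanza boundaries
  stanza_starts <- grep("^\\[[^]]+\\]\\s*$", lines)
  header_end <- if (length(stanza_starts)) stanza_starts[1] - 1L else length(lines)
  default_ns <- ""
  if (header_end > 0L) {
    dn <- grep("^default-namespace:", lines[seq_len(header_end)], value = TRUE)
    if (length(dn)) default_ns <- trimws(sub("^default-namespace:", "", dn[1]))
  }

  is_term <- grepl("^\\[Term\\]\\s*$", lines[stanza_starts])
  term_starts <- stanza_starts[is_term]
  if (!length(term_starts)) data_error("no [Term] stanza found in OBO input")
  stanza_ends <- c(stanza_starts[-1] - 1L, length(lines))
  term_ends <- stanza_ends[is_term]

  n <- length(term_starts)
  ids <- character(n)
  nm <- character(n)
  ns <- character(n)
  obsolete <- logical(n)
  parents <- vector("list", n)
  parent_rel <- vector("list", n)
  other_par <- vector("list", n)
  other_rel <- vector("list", n)
  alt_from <- character(0)
  alt_to <- character(0)

  strip_comment <- function(x) trimws(sub("!.*$", "", x))

  for (k in seq_len(n)) {
    body_idx <- seq.int(term_starts[k] + 1L, term_ends[k])
    body <- lines[body_idx]
    tag_line <- grepl("^[A-Za-z_]+:", body)
    tags <- sub(":.*$", "", body[tag_line])
    vals <- sub("^[A-Za-z_]+:\\s*", "", body[tag_line])
    abs_lines <- body_idx[tag_line]

    id_i <- which(tags == "id")
    if (!length(id_i)) {
      data_error(sprintf(
        "[Term] stanza starting at line %d has no id: tag", term_starts[k]
      ))
    }
    ids[k] <- strip_comment(vals[id_i[1]])
    name_i <- which(tags == "name")
    nm[k] <- if (length(name_i)) trimws(vals[name_i[1]]) else ids[k]
    ns_i <- which(tags == "namespace")
    ns[k] <- if (length(ns_i)) strip_comment(vals[ns_i[1]]) else default_ns
    obsolete[k] <- any(tags == "is_obsolete" &
                         grepl("^true", strip_comment(vals)[tags == "is_obsolete"]))

    isa <- strip_comment(vals[tags == "is_a"])
    p <- isa
    r <- rep("is_a", length(isa))
    op <- character(0)
    orl <- character(0)
    for (v in strip_comment(vals[tags == "relationship"])) {
      fld <- strsplit(v, "\\s+")[[1]]
      if (length(fld) < 2L) {
        data_error(sprintf(
          "malformed relationship line near line %d: '%s'",
          abs_lines[1], v
        ))
      }
      if (fld[1] == "part_of") {
        p <- c(p, fld[2])
        r <- c(r, "part_of")
      } else {
        op <- c(op, fld[2])
        orl <- c(orl, fld[1])
      }
    }
    parents[[k]] <- p
    parent_rel[[k]] <- r
    other_par[[k]] <- op
    other_rel[[k]] <- orl

    av <- strip_comment(vals[tags == "alt_id"])
    if (length(av)) {
      alt_from <- c(alt_from, av)
      alt_to <- c(alt_to, rep(ids[k], length(av)))
    }
  }

  if (anyDuplicated(ids)) {
    data_error(sprintf(
      "duplicate term id in OBO input: %s", ids[duplicated(ids)][1]
    ))
  }

  # obsolete terms: no edges retained; their ids stay findable for lookup
  keep <- !obsolete
  obsolete_ids <- ids[obsolete]
  live <- ids[keep]
  live_name <- stats::setNames(nm[keep], live)
  live_ns <- stats::setNames(ns[keep], live)
  parents <- stats::setNames(parents[keep], live)
  parent_rel <- stats::setNames(parent_rel[keep], live)
  other_par <- stats::setNames(other_par[keep], live)
  other_rel <- stats::setNames(other_rel[keep], live)

  # drop parent references to unknown or obsolete terms
  for (t in live) {
    ok <- parents[[t]] %in% live
    parents[[t]] <- parents[[t]][ok]
    parent_rel[[t]] <- parent_rel[[t]][ok]
  }

  alt <- stats::setNames(alt_to, alt_from)
  # obsolete ids are indexed (recognisable) but resolve to nothing
  alt <- c(alt, stats::setNames(rep(NA_character_, length(obsolete_ids)),
                                obsolete_ids))

  graph <- build_graph(live, live_name, live_ns, parents, parent_rel,
                       other_par, other_rel, alt, obsolete_ids)
  graph
}

# Assemble and validate the ontology_graph from parsed components.
build_graph <- function(ids, nm, ns, parents, parent_rel,
                        other_par, other_rel, alt, obsolete_ids) {
  edge_child <- rep(ids, lengths(parents))
  edge_parent <- unlist(parents, use.names = FALSE)
  if (is.null(edge_parent)) edge_parent <- character(0)

  ig <- igraph::graph_from_data_frame(
    data.frame(from = edge_child, to = edge_parent,
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )

  if (!igraph::is_dag(ig)) {
    comp <- igraph::components(ig, mode = "strong")
    bad <- names(comp$membership)[comp$membership %in%
                                    which(comp$csize > 1)]
    if (!length(bad)) { # self-loop cycle
      bad <- edge_child[edge_child == edge_parent]
    }
    data_error(sprintf(
      "cycle detected in ontology graph involving term %s", sort(bad)[1]
    ))
  }

  # roots: exactly one per namespace
  is_root <- lengths(parents) == 0L
  roots <- character(0)
  for (nsp in unique(ns)) {
    r <- ids[is_root & ns == nsp]
    if (length(r) != 1L) {
      data_error(sprintf(
        "namespace '%s' must have exactly one root, found %d (%s)",
        nsp, length(r), paste(sort(r), collapse = ", ")
      ))
    }
    roots[nsp] <- r
  }

  # inclusive ancestor closure for every term (edges run child -> parent)
  anc_raw <- igraph::ego(ig, order = length(ids), nodes = ids, mode = "out")
  anc <- lapply(anc_raw, function(v) sort(names(v)))
  names(anc) <- ids

  # reachability: each term's closure must contain its namespace root
  root_of <- roots[ns]
  reached <- mapply(function(a, r) r %in% a, anc, root_of)
  if (!all(reached)) {
    data_error(sprintf(
      "term %s does not reach its namespace root %s",
      ids[!reached][1], root_of[!reached][1]
    ))
  }

  # shortest directed path to the namespace root
  depth <- stats::setNames(integer(length(ids)), ids)
  for (nsp in names(roots)) {
    members <- ids[ns == nsp]
    d <- igraph::distances(ig, v = members, to = roots[nsp], mode = "out")
    depth[members] <- as.integer(d[, 1])
  }

  structure(
    list(
      ids = ids, name = nm, namespace = ns,
      parents = parents, parent_relation = parent_rel,
      other_parents = other_par, other_relation = other_rel,
      roots = roots, alt = alt, obsolete = obsolete_ids,
      anc = anc, depth = depth, ig = ig
    ),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf(
    "ontology_graph: %d terms, %d edges, %d namespace(s) [%s], %d obsolete\n",
    length(x$ids), sum(lengths(x$parents)), length(x$roots),
    paste(names(x$roots), collapse = ", "), length(x$obsolete)
  ))
  invisible(x)
}

# Resolve a term id through the alt_id index. Returns canonical id,
# NA_character_ for obsolete ids, or NULL if unknown.
resolve_term <- function(graph, id) {
  if (id %in% graph$ids) return(id)
  if (id %in% names(graph$alt)) return(unname(graph$alt[[id]]))
  NULL
}

check_term <- function(graph, t) {
  if (!t %in% graph$ids) {
    data_error(sprintf("unknown term id: %s", t))
  }
  invisible(TRUE)
}

# Single-namespace resolution shared by IC/similarity/enrichment entry
# points: explicit namespace wins; otherwise the ontology must have one.
resolve_namespace <- function(graph, namespace = NULL) {
  if (is.null(namespace)) {
    if (length(graph$roots) != 1L) {
      data_error(sprintf(
        "ontology has %d namespaces (%s); specify one",
        length(graph$roots), paste(names(graph$roots), collapse = ", ")
      ))
    }
    return(names(graph$roots))
  }
  if (!namespace %in% names(graph$roots)) {
    data_error(sprintf("unknown namespace: %s", namespace))
  }
  namespace
}
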