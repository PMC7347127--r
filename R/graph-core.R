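#' Ancestors of a term
#'
#' Transitive closure over the child-to-parent traversal edges
#' (`is_a` and `part_of`).
#'
#' @param graph an [ontology_graph][parse_obo].
#' @param t a term id.
#' @param inclusive include `t` itself in the result?
#' @return Sorted character vector of term ids.
#' @examples
#' g <- toy5()$graph
#' ancestors(g, "C")            # "A" "R"
#' ancestors(g, "C", inclusive = TRUE)
#' @export
ancestors <- function(graph, t, inclusive = FALSE) {
  check_term(graph, t)
  a <- graph$anc[[t]]
  if (!inclusive) a <- setdiff(a, t)
  a
}

#' Depth of a term
#'
#' Minimum number of traversal edges on any path from `t` to its namespace
#' root; the root has depth 0.
#'
#' @inheritParams ancestors
#' @return Non-negative integer.
#' @examples
#' g <- toy5()$graph
#' term_depth(g, "C") # 2
#' @export
term_depth <- function(graph, t) {
  check_term(graph, t)
  unname(graph$depth[t])
}

#' Common ancestors of two terms
#'
#' Intersection of the two inclusive ancestor sets, so that
#' `common_ancestors(g, t, t)` contains `t` itself. Both terms must belong
#' to the same namespace.
#'
#' @inheritParams ancestors
#' @param t1,t2 term ids in the same namespace.
#' @return Sorted character vector of term ids (never empty: at minimum
#'   the shared namespace root).
#' @export
common_ancestors <- function(graph, t1, t2) {
  check_term(graph, t1)
  check_term(graph, t2)
  if (graph$namespace[t1] != graph$namespace[t2]) {
    data_error(sprintf(
      "terms %s and %s belong to different namespaces (%s vs %s)",
      t1, t2, graph$namespace[t1], graph$namespace[t2]
    ))
  }
  intersect(graph$anc[[t1]], graph$anc[[t2]])
}

#' Most informative common ancestor (MICA)
#'
#' The common ancestor with the highest information content. Ties are
#' broken by lexicographically smallest term id so matrix exports are
#' reproducible.
#'
#' @inheritParams common_ancestors
#' @param ic an [ic_table][compute_ic] for the terms' namespace.
#' @return List with elements `term` and `ic`.
#' @examples
#' toy <- toy5()
#' ic <- compute_ic(toy$graph, toy$corpus)
#' mica(toy$graph, ic, "C", "D") # term "A", ic ln(3/2)
#' @export
mica <- function(graph, ic, t1, t2) {
  ca <- common_ancestors(graph, t1, t2)
  vals <- ic$ic[ca]
  if (anyNA(vals)) {
    data_error(sprintf(
      "IC undefined for common ancestor(s) %s (never annotated in corpus)",
      paste(ca[is.na(vals)], collapse = ", ")
    ))
  }
  ord <- order(-vals, ca)
  list(term = ca[ord[1]], ic = unname(vals[ord[1]]))
}

#' Disjoint common ancestors (DCA)
#'
#' The common ancestors of `t1` and `t2` that do not subsume (are not
#' strict ancestors of) any other common ancestor; i.e. the most specific
#' ones. These are the ancestors averaged by the GraSM measure variants.
#'
#' @inheritParams common_ancestors
#' @return Sorted character vector of term ids.
#' @examples
#' g <- toy5()$graph
#' dca(g, "C", "D") # "A" (the root R subsumes A and is removed)
#' @export
dca <- function(graph, t1, t2) {
  ca <- common_ancestors(graph, t1, t2)
  strict_anc <- unique(unlist(
    lapply(ca, function(a) setdiff(graph$anc[[a]], a)),
    use.names = FALSE
  ))
  sort(setdiff(ca, strict_anc))
}

#' Corpus-based information content
#'
#' Estimates, for every term of one namespace, the probability that a
#' randomly drawn annotated entity is annotated (after true-path
#' propagation) with the term: `p(t) = counts(t) / counts(root)`, where
#' `counts(t)` is the number of distinct entities whose propagated set
#' contains `t`. Information content is `IC(t) = -ln p(t)` in nats, so
#' `IC(root) = 0` and IC is monotone non-decreasing from root to leaves.
#' Terms with no annotated entity have undefined (absent) IC rather than a
#' silent infinity.
#'
#' @param graph an [ontology_graph][parse_obo].
#' @param corpus an [annotation_corpus][parse_annotations].
#' @param namespace namespace to use; may be omitted for single-namespace
#'   ontologies.
#' @return Object of class `ic_table`: list with `namespace`, `counts`
#'   (named integer), `total`, `p` and `ic` (named numeric over annotated
#'   terms).
#' @examples
#' toy <- toy5()
#' ic <- compute_ic(toy$graph, toy$corpus)
#' ic$ic[c("R", "A", "C")]
#' @export
compute_ic <- function(graph, corpus, namespace = NULL) {
  nsp <- resolve_namespace(graph, namespace)
  sets <- lapply(corpus$propagated, function(ts) {
    ts[graph$namespace[ts] == nsp]
  })
  sets <- sets[lengths(sets) > 0L]
  if (!length(sets)) {
    data_error(sprintf("no entity is annotated in namespace '%s'", nsp))
  }
  # distinct-entity counts: each entity contributes each term once, so
  # multiple inheritance can never double-count
  tab <- table(unlist(sets, use.names = FALSE))
  counts <- stats::setNames(as.integer(tab), names(tab))
  total <- counts[[graph$roots[nsp]]]
  p <- counts / total
  structure(
    list(namespace = nsp, counts = counts, total = total,
         p = p, ic = -log(p)),
    class = "ic_table"
  )
}

#' @export
print.ic_table <- function(x, ...) {
  cat(sprintf(
    "ic_table: namespace '%s', %d annotated terms, %d entities\n",
    x$namespace, length(x$counts), x$total
  ))
  invisible(x)
}

#' Export an IC table as a data frame
#'
#' @param x an [ic_table][compute_ic].
#' @param ... unused.
#' @return Data frame with columns `term`, `count`, `p`, `ic`, sorted by
#'   term id.
#' @export
as.data.frame.ic_table <- function(x, ...) {
  terms <- sort(names(x$counts))
  data.frame(
    term = terms,
    count = unname(x$counts[terms]),
    p = unname(x$p[terms]),
    ic = unname(x$ic[terms]),
    stringsAsFactors = FALSE
  )
}

# IC of terms, erroring on any term never seen in the corpus.
ic_of <- function(ic, terms) {
  vals <- ic$ic[terms]
  if (anyNA(vals)) {
    data_error(sprintf(
      "IC undefined for term(s): %s (never annotated in corpus)",
      paste(terms[is.na(vals)], collapse = ", ")
    ))
  }
  stats::setNames(as.numeric(vals), terms)
}

# Shortest directed path lengths (in traversal edges) from `t` up to each
# of its ancestors `to`.
path_len_up <- function(graph, t, to) {
  d <- igraph::distances(graph$ig, v = t, to = to, mode = "out")
  stats::setNames(as.numeric(d[1, ]), to)
}
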