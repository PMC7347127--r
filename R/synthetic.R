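# Deterministic synthetic fixtures: random DAG ontologies serialized as
# valid OBO text and random annotation corpora. These stand in for real
# ontology/annotation downloads in every test; same seed, same bytes.

#' Generate a random single-rooted DAG ontology
#'
#' Terms are created in topological order; each non-root term draws
#' between 1 and `max_parents` parents uniformly among the earlier terms,
#' so the result is acyclic and single-rooted by construction. Each edge
#' is `part_of` with probability `part_of_fraction`, otherwise `is_a`.
#' The graph is serialized as OBO text and re-parsed through
#' [parse_obo()]'s validation path, so every generated fixture is also a
#' parser round-trip.
#'
#' @param n_terms number of terms (>= 2).
#' @param max_parents maximum parents per non-root term.
#' @param part_of_fraction probability that an edge is `part_of`.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param namespace namespace written into every stanza.
#' @return List with `obo` (character vector of OBO lines) and `graph`
#'   (the parsed [ontology_graph][parse_obo]).
#' @examples
#' fx <- make_dag(n_terms = 8, seed = 1)
#' fx$graph
#' @export
make_dag <- function(n_terms, max_parents = 2, part_of_fraction = 0,
                     seed = 1, namespace = "synthetic") {
  n_terms <- as.integer(n_terms)
  if (is.na(n_terms) || n_terms < 2L) data_error("n_terms must be >= 2")
  if (max_parents < 1L) data_error("max_parents must be >= 1")
  ids <- sprintf("ST:%07d", seq_len(n_terms))
  with_seed(seed, {
    lines <- c("format-version: 1.2",
               sprintf("default-namespace: %s", namespace), "")
    for (i in seq_len(n_terms)) {
      stanza <- c("[Term]",
                  sprintf("id: %s", ids[i]),
                  sprintf("name: synthetic term %d", i))
      if (i > 1L) {
        np <- sample.int(min(max_parents, i - 1L), 1L)
        parents <- sort(sample.int(i - 1L, np))
        for (p in parents) {
          if (stats::runif(1) < part_of_fraction) {
            stanza <- c(stanza,
                        sprintf("relationship: part_of %s", ids[p]))
          } else {
            stanza <- c(stanza, sprintf("is_a: %s", ids[p]))
          }
        }
      }
      lines <- c(lines, stanza, "")
    }
    list(obo = lines, graph = parse_obo_lines(lines))
  })
}

#' Generate a random annotation corpus for an ontology
#'
#' Each entity is annotated to a uniformly drawn number of distinct
#' non-root terms; evidence codes, when requested, are drawn uniformly
#' from `EXP`, `IEA`, `TAS`.
#'
#' @param graph an [ontology_graph][parse_obo].
#' @param n_entities number of entities.
#' @param annotations_per_entity integer range `c(min, max)` of direct
#'   annotations per entity.
#' @param with_evidence attach evidence codes?
#' @param seed integer seed.
#' @return List with `tsv` (character vector of annotation lines) and
#'   `corpus` (the parsed [annotation_corpus][parse_annotations]).
#' @examples
#' fx <- make_dag(n_terms = 8, seed = 1)
#' cp <- make_corpus(fx$graph, n_entities = 5, seed = 1)
#' cp$corpus
#' @export
make_corpus <- function(graph, n_entities,
                        annotations_per_entity = c(1L, 3L),
                        with_evidence = FALSE, seed = 1) {
  n_entities <- as.integer(n_entities)
  if (is.na(n_entities) || n_entities < 1L) {
    data_error("n_entities must be >= 1")
  }
  pool <- sort(setdiff(graph$ids, graph$roots))
  if (!length(pool)) data_error("ontology has no non-root terms to annotate")
  lo <- max(1L, as.integer(annotations_per_entity[1]))
  hi <- min(length(pool), as.integer(annotations_per_entity[2]))
  if (lo > hi) lo <- hi
  codes <- c("EXP", "IEA", "TAS")
  with_seed(seed, {
    lines <- character(0)
    for (e in seq_len(n_entities)) {
      k <- if (lo == hi) lo else sample(lo:hi, 1L)
      terms <- sort(sample(pool, k))
      ev <- if (with_evidence) sample(codes, k, replace = TRUE) else NULL
      lines <- c(lines, if (with_evidence) {
        paste(sprintf("ent%03d", e), terms, ev, sep = "\t")
      } else {
        paste(sprintf("ent%03d", e), terms, sep = "\t")
      })
    }
    list(tsv = lines, corpus = parse_annotation_lines(lines, graph))
  })
}

#' The five-term worked-example ontology text
#'
#' Terms `R`, `A`, `B`, `C`, `D` with `C is_a A`, `D is_a A`, `A is_a R`,
#' `B is_a R` — the fixture on which every worked value in the package
#' documentation is computed by hand.
#'
#' @return Character vector of OBO lines.
#' @export
toy5_obo_text <- function() {
  c("format-version: 1.2",
    "default-namespace: toy",
    "",
    "[Term]", "id: R", "name: root",
    "",
    "[Term]", "id: A", "name: branch a", "is_a: R",
    "",
    "[Term]", "id: B", "name: branch b", "is_a: R",
    "",
    "[Term]", "id: C", "name: leaf c", "is_a: A",
    "",
    "[Term]", "id: D", "name: leaf d", "is_a: A",
    "")
}

#' The canonical five-term worked example
#'
#' The [toy5_obo_text()] ontology together with the three-entity corpus
#' `e1 -> C`, `e2 -> D`, `e3 -> B`. On this fixture `IC(A) = ln(3/2)`,
#' `IC(C) = ln 3`, and all worked similarity values in the documentation
#' follow by hand.
#'
#' @return List with `graph` and `corpus`.
#' @examples
#' toy <- toy5()
#' compute_ic(toy$graph, toy$corpus)$ic["A"] # log(3/2)
#' @export
toy5 <- function() {
  graph <- parse_obo_lines(toy5_obo_text())
  corpus <- parse_annotation_lines(
    c("e1\tC", "e2\tD", "e3\tB"), graph
  )
  list(graph = graph, corpus = corpus)
}
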