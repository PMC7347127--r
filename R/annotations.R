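#' Read a tab-separated annotation corpus
#'
#' Each line annotates one entity with one ontology term:
#' `EntityID<tab>TermID[<tab>EvidenceCode]`. Term ids are resolved through
#' the ontology's alt_id index; annotations to obsolete terms are dropped
#' with a warning, as are annotations to unknown terms and malformed
#' (single-field) lines. Duplicate (entity, term) records are deduplicated
#' silently. If `evidence_filter` is given, records carrying an evidence
#' code outside the filter are removed; records with no evidence column are
#' always kept, evidence being an optional attribute of an annotation
#' rather than a requirement.
#'
#' Propagated ("extended") annotation sets follow the true-path rule: an
#' annotation to a term implies annotation to all of its ancestors along
#' `is_a`/`part_of` edges.
#'
#' @param path path to the annotation TSV.
#' @param graph an [ontology_graph][parse_obo] the annotations refer to.
#' @param evidence_filter optional character vector of evidence codes to
#'   keep (e.g. `c("EXP", "TAS")`).
#' @return An object of class `annotation_corpus`: list with `direct`
#'   (named list entity -> direct term ids), `evidence` (named list,
#'   parallel codes, `""` when absent), `propagated` (named list entity ->
#'   ancestor-closed term set), `entities`, `term_universe` (sorted ids of
#'   directly used terms), `skipped` (named counts of dropped lines) and
#'   `graph` (the ontology the corpus was validated against).
#' @examples
#' toy <- toy5()
#' toy$corpus$propagated[["e1"]]
#' @export
parse_annotations <- function(path, graph, evidence_filter = NULL) {
  if (!file.exists(path)) data_error(sprintf("annotation file not found: %s", path))
  parse_annotation_lines(readLines(path, warn = FALSE), graph, evidence_filter)
}

parse_annotation_lines <- function(lines, graph, evidence_filter = NULL) {
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)

  skipped <- c(malformed = 0L, unknown_term = 0L, obsolete_term = 0L,
               evidence_filtered = 0L)
  skipped["malformed"] <- sum(nf < 2L)
  keep <- nf >= 2L
  fields <- fields[keep]

  ent <- vapply(fields, `[`, "", 1L)
  term <- vapply(fields, `[`, "", 2L)
  evid <- vapply(fields, function(f) if (length(f) >= 3L) f[3] else "", "")

  if (!is.null(evidence_filter)) {
    ok <- evid == "" | evid %in% evidence_filter
    skipped["evidence_filtered"] <- sum(!ok)
    ent <- ent[ok]; term <- term[ok]; evid <- evid[ok]
  }

  resolved <- character(length(term))
  for (i in seq_along(term)) {
    r <- resolve_term(graph, term[i])
    resolved[i] <- if (is.null(r)) "__unknown__" else if (is.na(r)) "__obsolete__" else r
  }
  skipped["unknown_term"] <- sum(resolved == "__unknown__")
  skipped["obsolete_term"] <- sum(resolved == "__obsolete__")
  ok <- !resolved %in% c("__unknown__", "__obsolete__")
  ent <- ent[ok]; evid <- evid[ok]; term <- resolved[ok]

  if (sum(skipped) > 0L) {
    warning(sprintf(
      "dropped %d annotation line(s): %s",
      sum(skipped),
      paste(sprintf("%s=%d", names(skipped)[skipped > 0],
                    skipped[skipped > 0]), collapse = ", ")
    ), call. = FALSE)
  }
  if (!length(ent)) data_error("no annotation records survived parsing")

  # silent dedup on (entity, term); first evidence code wins
  dup <- duplicated(paste(ent, term, sep = "\r"))
  ent <- ent[!dup]; term <- term[!dup]; evid <- evid[!dup]

  ord <- order(ent, term)
  ent <- ent[ord]; term <- term[ord]; evid <- evid[ord]

  direct <- split(term, ent)
  evidence <- split(evid, ent)
  propagated <- lapply(direct, function(ts) {
    sort(unique(unlist(graph$anc[ts], use.names = FALSE)))
  })

  structure(
    list(
      direct = direct,
      evidence = evidence,
      propagated = propagated,
      entities = names(direct),
      term_universe = sort(unique(term)),
      skipped = skipped,
      graph = graph
    ),
    class = "annotation_corpus"
  )
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf(
    "annotation_corpus: %d entities, %d direct annotations over %d terms\n",
    length(x$entities), sum(lengths(x$direct)), length(x$term_universe)
  ))
  invisible(x)
}

check_entity <- function(corpus, e) {
  if (!e %in% corpus$entities) {
    data_error(sprintf("entity %s has no annotations in the corpus", e))
  }
  invisible(TRUE)
}

# Direct / propagated term sets of an entity restricted to one namespace.
# Errors when the entity has nothing in that namespace (cross-namespace
# comparisons are rejected rather than silently returning empty sets).
entity_terms <- function(corpus, e, namespace, view = c("direct", "extended")) {
  view <- match.arg(view)
  check_entity(corpus, e)
  ts <- if (view == "direct") corpus$direct[[e]] else corpus$propagated[[e]]
  ts <- ts[corpus$graph$namespace[ts] == namespace]
  if (!length(ts)) {
    data_error(sprintf(
      "entity %s has no annotations in namespace '%s'", e, namespace
    ))
  }
  sort(unique(ts))
}
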