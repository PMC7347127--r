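# Between-entity similarity: four pairwise combiners over a term-term
# similarity matrix and seven groupwise measures over annotation sets.

#' @rdname entity_similarity
#' @export
ENTITY_MEASURES <- c("avg", "max", "bma", "rcmax",
                     "to", "nto", "ui", "lp", "gic", "cosine", "kappa")

PAIRWISE_MEASURES <- c("avg", "max", "bma", "rcmax")

#' Combine a term-term similarity matrix into one score
#'
#' The four pairwise between-entity strategies:
#' * `avg`: mean over all entries.
#' * `max`: maximum entry.
#' * `bma`: best-match average — mean of the row-wise maxima and the
#'   column-wise maxima, `(sum_i max_j + sum_j max_i) / (n + m)`.
#' * `rcmax`: the larger of the mean row-wise maximum and the mean
#'   column-wise maximum.
#'
#' @param S numeric matrix of term-term similarities (rows: terms of the
#'   first entity, columns: terms of the second).
#' @param mode one of `"avg"`, `"max"`, `"bma"`, `"rcmax"`.
#' @return A single numeric score.
#' @examples
#' S <- matrix(c(0.2, 0.4, 0.8, 0.6), 2, 2)
#' pairwise_combine(S, "bma") # 0.65
#' @export
pairwise_combine <- function(S, mode = PAIRWISE_MEASURES) {
  mode <- match.arg(mode)
  S <- as.matrix(S)
  if (!length(S)) data_error("empty similarity matrix")
  row_max <- apply(S, 1, max)
  col_max <- apply(S, 2, max)
  switch(mode,
    avg = mean(S),
    max = max(S),
    bma = (sum(row_max) + sum(col_max)) / (nrow(S) + ncol(S)),
    rcmax = max(mean(row_max), mean(col_max))
  )
}

#' Between-entity semantic similarity
#'
#' Similarity between two annotated entities under one of eleven measures.
#'
#' Pairwise measures (`avg`, `max`, `bma`, `rcmax`) build the term-term
#' similarity matrix between the two entities' direct annotation sets
#' under `term_measure` and reduce it with [pairwise_combine()].
#'
#' Groupwise measures compare annotation sets directly. The graph-based
#' ones (`to`, `nto`, `ui`, `lp`, `gic`) default to the extended
#' (ancestor-closed) sets `X1`, `X2`:
#' * `to`: term overlap, the raw count `|X1 ∩ X2|`.
#' * `nto`: normalized term overlap, `|X1 ∩ X2| / min(|X1|, |X2|)`.
#' * `ui`: union–intersection (simUI), `|X1 ∩ X2| / |X1 ∪ X2|`.
#' * `lp`: longest path — the maximum depth over shared terms.
#' * `gic`: simGIC, `sum IC(X1 ∩ X2) / sum IC(X1 ∪ X2)`.
#'
#' The vector-based ones (`cosine`, `kappa`) default to binary vectors of
#' the direct annotation sets over the corpus term universe:
#' * `cosine`: `|T1 ∩ T2| / sqrt(|T1| |T2|)`.
#' * `kappa`: Cohen's chance-corrected agreement of the two binary
#'   vectors, in `[-1, 1]`.
#'
#' @param corpus an [annotation_corpus][parse_annotations].
#' @param e1,e2 entity ids present in the corpus.
#' @param measure one of `ENTITY_MEASURES`.
#' @param term_measure between-term measure used by the pairwise modes
#'   (one of `TERM_MEASURES`).
#' @param ic an [ic_table][compute_ic]; required by `gic` and by pairwise
#'   modes whose `term_measure` is IC-based. Computed on the fly from the
#'   corpus when omitted and needed.
#' @param namespace namespace to compare in; may be omitted for
#'   single-namespace ontologies.
#' @param annotation_view override the per-measure default annotation
#'   view (`"extended"` for graph-based, `"direct"` for vector-based and
#'   pairwise measures).
#' @param wang_weights,normalize passed to [term_similarity()].
#' @return A single numeric score.
#' @examples
#' toy <- toy5()
#' entity_similarity(toy$corpus, "e1", "e2", "ui")           # 0.5
#' entity_similarity(toy$corpus, "e1", "e2", "bma", "lin")   # 0.369070
#' @export
entity_similarity <- function(corpus, e1, e2, measure,
                              term_measure = "lin", ic = NULL,
                              namespace = NULL, annotation_view = NULL,
                              wang_weights = DEFAULT_WANG_WEIGHTS,
                              normalize = FALSE) {
  measure <- match.arg(measure, ENTITY_MEASURES)
  graph <- corpus$graph
  nsp <- resolve_namespace(graph, namespace)
  needs_ic <- measure == "gic" ||
    (measure %in% PAIRWISE_MEASURES &&
       !term_measure %in% c("wu2005", "yu2005", "wang2007"))
  if (needs_ic && is.null(ic)) ic <- compute_ic(graph, corpus, nsp)

  if (measure %in% PAIRWISE_MEASURES) {
    view <- if (is.null(annotation_view)) "direct" else annotation_view
    t1 <- entity_terms(corpus, e1, nsp, view)
    t2 <- entity_terms(corpus, e2, nsp, view)
    S <- matrix(0, length(t1), length(t2), dimnames = list(t1, t2))
    for (i in seq_along(t1)) {
      for (j in seq_along(t2)) {
        S[i, j] <- term_similarity(graph, t1[i], t2[j], term_measure, ic,
                                   wang_weights, normalize)
      }
    }
    return(pairwise_combine(S, measure))
  }

  if (measure %in% c("to", "nto", "ui", "lp", "gic")) {
    view <- if (is.null(annotation_view)) "extended" else annotation_view
    x1 <- entity_terms(corpus, e1, nsp, view)
    x2 <- entity_terms(corpus, e2, nsp, view)
    inter <- intersect(x1, x2)
    uni <- union(x1, x2)
    return(switch(measure,
      to = length(inter),
      nto = length(inter) / min(length(x1), length(x2)),
      ui = length(inter) / length(uni),
      lp = if (length(inter)) max(graph$depth[inter]) else 0,
      gic = {
        num <- sum(ic_of(ic, inter))
        den <- sum(ic_of(ic, uni))
        if (den == 0) 1 else num / den # both sets reduce to the root
      }
    ))
  }

  # vector-based: binary profiles over the corpus term universe
  view <- if (is.null(annotation_view)) "direct" else annotation_view
  t1 <- entity_terms(corpus, e1, nsp, view)
  t2 <- entity_terms(corpus, e2, nsp, view)
  universe <- corpus$term_universe
  universe <- universe[graph$namespace[universe] == nsp]
  if (view == "extended") {
    universe <- sort(unique(unlist(graph$anc[universe], use.names = FALSE)))
  }
  a <- length(intersect(t1, t2))
  if (measure == "cosine") {
    return(a / sqrt(length(t1) * length(t2)))
  }
  # kappa over the 2x2 presence/absence agreement table
  m <- length(universe)
  b <- length(setdiff(t1, t2))
  c_ <- length(setdiff(t2, t1))
  d <- m - a - b - c_
  p_o <- (a + d) / m
  p_e <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / m^2
  if (p_e == 1) return(if (b + c_ == 0) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Entity-by-entity similarity matrix
#'
#' Symmetric labeled matrix of between-entity similarities. Entities with
#' no annotation in the namespace are dropped with a warning, or raise an
#' error when `strict = TRUE`.
#'
#' @inheritParams entity_similarity
#' @param entities character vector of entity ids.
#' @param strict error (rather than warn and drop) on entities that fail
#'   the annotation precondition.
#' @return Numeric matrix with the surviving entities as dimnames and
#'   attribute `"measure"` recording provenance.
#' @examples
#' toy <- toy5()
#' entity_matrix(toy$corpus, c("e1", "e2", "e3"), "ui")
#' @export
entity_matrix <- function(corpus, entities, measure,
                          term_measure = "lin", ic = NULL,
                          namespace = NULL, annotation_view = NULL,
                          wang_weights = DEFAULT_WANG_WEIGHTS,
                          normalize = FALSE, strict = FALSE) {
  measure <- match.arg(measure, ENTITY_MEASURES)
  entities <- as.character(entities)
  if (!length(entities)) data_error("empty entity list")
  nsp <- resolve_namespace(corpus$graph, namespace)

  ok <- vapply(entities, function(e) {
    !is.null(tryCatch(entity_terms(corpus, e, nsp), error = function(c) NULL))
  }, logical(1))
  if (any(!ok)) {
    if (strict) {
      data_error(sprintf(
        "entities without annotations in namespace '%s': %s",
        nsp, paste(entities[!ok], collapse = ", ")
      ))
    }
    warning(sprintf(
      "dropping %d unannotated entit%s: %s",
      sum(!ok), if (sum(!ok) == 1) "y" else "ies",
      paste(entities[!ok], collapse = ", ")
    ), call. = FALSE)
    entities <- entities[ok]
  }
  if (!length(entities)) data_error("no annotated entities left")

  needs_ic <- measure == "gic" ||
    (measure %in% PAIRWISE_MEASURES &&
       !term_measure %in% c("wu2005", "yu2005", "wang2007"))
  if (needs_ic && is.null(ic)) ic <- compute_ic(corpus$graph, corpus, nsp)

  n <- length(entities)
  m <- matrix(0, n, n, dimnames = list(entities, entities))
  for (i in seq_len(n)) {
    m[i, i] <- entity_similarity(corpus, entities[i], entities[i], measure,
                                 term_measure, ic, nsp, annotation_view,
                                 wang_weights, normalize)
  }
  idx <- upper_pairs(n)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    s <- entity_similarity(corpus, entities[i], entities[j], measure,
                           term_measure, ic, nsp, annotation_view,
                           wang_weights, normalize)
    m[i, j] <- s
    m[j, i] <- s
  }
  attr(m, "measure") <- if (measure %in% PAIRWISE_MEASURES) {
    paste(measure, term_measure, sep = "+")
  } else {
    measure
  }
  m
}
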