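# Functional-similarity networks: thresholded construction from a
# similarity matrix, weighting of imported edge lists, set-vs-set scores.

#' Build a similarity network from a symmetric matrix
#'
#' Emits one undirected edge per unordered label pair whose similarity
#' lies inside the closed interval `[min_t, max_t]`; the diagonal is
#' ignored. Edges are stored with `source < target` lexicographically and
#' sorted, so outputs are reproducible.
#'
#' @param matrix square symmetric numeric matrix with dimnames (e.g. from
#'   [entity_matrix()]).
#' @param min_t,max_t inclusive similarity thresholds.
#' @return Data frame with columns `source`, `target`, `weight`.
#' @examples
#' toy <- toy5()
#' m <- entity_matrix(toy$corpus, c("e1", "e2", "e3"), "ui")
#' similarity_network(m, 0.4, 1)
#' @export
similarity_network <- function(matrix, min_t = 0, max_t = Inf) {
  if (min_t > max_t) data_error("min threshold exceeds max threshold")
  m <- as.matrix(matrix)
  labs <- rownames(m)
  if (is.null(labs) || nrow(m) != ncol(m)) {
    data_error("similarity matrix must be square with labels")
  }
  idx <- upper_pairs(nrow(m))
  w <- m[idx]
  keep <- w >= min_t & w <= max_t
  edges <- data.frame(
    source = labs[idx[keep, 1]],
    target = labs[idx[keep, 2]],
    weight = w[keep],
    stringsAsFactors = FALSE
  )
  canonical_edges(edges)
}

# Canonical undirected storage: source < target, rows sorted.
canonical_edges <- function(edges) {
  if (nrow(edges)) {
    swap <- edges$source > edges$target
    tmp <- edges$source[swap]
    edges$source[swap] <- edges$target[swap]
    edges$target[swap] <- tmp
    edges <- edges[order(edges$source, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
  }
  edges
}

#' Weigh an imported entity network by functional similarity
#'
#' Re-emits each edge of an imported entity edge list with weight equal to
#' the similarity of its endpoints under the chosen between-entity
#' measure. Self-loops are dropped with a warning. Edges with an
#' unannotated endpoint are dropped (`missing_policy = "drop"`, with a
#' warning count) or kept at weight zero (`"zero"`).
#'
#' @param edges data frame with columns `source`, `target` (extra columns
#'   are ignored), e.g. from [read_network()].
#' @inheritParams entity_similarity
#' @param missing_policy `"drop"` or `"zero"`.
#' @return Data frame with columns `source`, `target`, `weight`.
#' @examples
#' toy <- toy5()
#' weigh_network(data.frame(source = "e1", target = "e2"),
#'               toy$corpus, "ui")
#' @export
weigh_network <- function(edges, corpus, measure, term_measure = "lin",
                          ic = NULL, namespace = NULL,
                          annotation_view = NULL,
                          wang_weights = DEFAULT_WANG_WEIGHTS,
                          missing_policy = c("drop", "zero")) {
  missing_policy <- match.arg(missing_policy)
  if (is.null(edges) || !nrow(edges)) data_error("empty input edge list")
  self <- edges$source == edges$target
  if (any(self)) {
    warning(sprintf("dropping %d self-loop(s)", sum(self)), call. = FALSE)
    edges <- edges[!self, , drop = FALSE]
  }
  if (!nrow(edges)) data_error("no edges left after dropping self-loops")

  nsp <- resolve_namespace(corpus$graph, namespace)
  w <- numeric(nrow(edges))
  ok <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    s <- tryCatch(
      entity_similarity(corpus, edges$source[i], edges$target[i], measure,
                        term_measure, ic, nsp, annotation_view,
                        wang_weights),
      ontosim_data_error = function(c) NULL
    )
    ok[i] <- !is.null(s)
    w[i] <- if (ok[i]) s else 0
  }
  if (any(!ok)) {
    warning(sprintf(
      "%d edge(s) with unannotated endpoint(s): %s",
      sum(!ok), if (missing_policy == "drop") "dropped" else "weighted 0"
    ), call. = FALSE)
    if (missing_policy == "drop") {
      edges <- edges[ok, , drop = FALSE]
      w <- w[ok]
    }
  }
  out <- data.frame(source = edges$source, target = edges$target,
                    weight = w, stringsAsFactors = FALSE)
  canonical_edges(out)
}

#' Similarity between two entity sets
#'
#' Builds the cross similarity matrix between the two sets under the
#' chosen between-entity measure and reduces it with a pairwise combiner
#' (best-match average by default). Symmetric in its arguments for the
#' symmetric combiners.
#'
#' @param set1,set2 character vectors of entity ids.
#' @inheritParams entity_similarity
#' @param combine combiner over the cross matrix (default `"bma"`).
#' @return A single numeric score.
#' @examples
#' toy <- toy5()
#' set_similarity(toy$corpus, "e1", "e2", "ui") # 0.5
#' @export
set_similarity <- function(corpus, set1, set2, measure,
                           term_measure = "lin", ic = NULL,
                           namespace = NULL, annotation_view = NULL,
                           wang_weights = DEFAULT_WANG_WEIGHTS,
                           combine = c("bma", "avg", "max", "rcmax")) {
  combine <- match.arg(combine)
  set1 <- unique(as.character(set1))
  set2 <- unique(as.character(set2))
  if (!length(set1) || !length(set2)) data_error("empty entity set")
  nsp <- resolve_namespace(corpus$graph, namespace)
  needs_ic <- measure == "gic" ||
    (measure %in% PAIRWISE_MEASURES &&
       !term_measure %in% c("wu2005", "yu2005", "wang2007"))
  if (needs_ic && is.null(ic)) ic <- compute_ic(corpus$graph, corpus, nsp)

  S <- matrix(0, length(set1), length(set2), dimnames = list(set1, set2))
  for (i in seq_along(set1)) {
    for (j in seq_along(set2)) {
      S[i, j] <- entity_similarity(corpus, set1[i], set2[j], measure,
                                   term_measure, ic, nsp, annotation_view,
                                   wang_weights)
    }
  }
  pairwise_combine(S, combine)
}
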