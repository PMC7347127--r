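# Term-enrichment analysis: one-sided over-representation tests with
# multiple-testing correction.

#' One-sided Fisher's exact (hypergeometric upper-tail) p-value
#'
#' Probability of drawing at least `k` annotated entities when sampling
#' `n` entities without replacement from a background of `N` entities of
#' which `K` are annotated: `P(X >= k)`, `X ~ Hypergeom(N, K, n)`.
#'
#' @param k annotated entities in the query set.
#' @param K annotated entities in the background.
#' @param n query-set size.
#' @param N background size.
#' @return p-value in `(0, 1]`.
#' @examples
#' fisher_pvalue(3, 4, 5, 20) # 496/15504
#' @export
fisher_pvalue <- function(k, K, n, N) {
  check_counts(k, K, n, N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' One-sided binomial upper-tail p-value
#'
#' `P(X >= k)` with `X ~ Binomial(n, p0)`; `p0` is typically the
#' background annotation rate `K / N`.
#'
#' @param k observed successes.
#' @param n number of trials.
#' @param p0 success probability under the null.
#' @return p-value in `(0, 1]`.
#' @examples
#' binomial_pvalue(3, 5, 0.2) # 0.05792
#' @export
binomial_pvalue <- function(k, n, p0) {
  if (any(k < 0 | n < 0 | k > n | p0 < 0 | p0 > 1)) {
    data_error("inconsistent binomial counts")
  }
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

check_counts <- function(k, K, n, N) {
  ok <- k >= 0 & K >= 0 & n >= 0 & N >= 0 &
    k <= n & k <= K & n <= N & K <= N & k >= n + K - N
  if (!all(ok)) data_error("inconsistent contingency counts (need 0 <= k <= min(n, K), max counts <= N)")
  invisible(TRUE)
}

#' Multiple-testing correction
#'
#' Bonferroni (`min(1, m p)`) or Benjamini–Hochberg step-up adjustment,
#' returned in input order.
#'
#' @param p numeric vector of raw p-values.
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03), "bh") # all 0.03
#' @export
adjust_pvalues <- function(p, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Term-enrichment analysis for an entity set
#'
#' Tests, for every ontology term appearing in the propagated annotation
#' of at least one query entity (the namespace root excluded), whether the
#' query set is annotated with the term more often than expected from the
#' background corpus. Counts use propagated (true-path) annotation sets
#' and distinct entities. The correction multiplicity `m` is the number of
#' candidate terms actually tested.
#'
#' @param corpus an [annotation_corpus][parse_annotations].
#' @param entity_set character vector of query entity ids; unknown ids are
#'   dropped with a warning.
#' @param test `"fisher"` (hypergeometric) or `"binomial"` (with
#'   `p0 = K / N`).
#' @param correction `"bh"` or `"bonferroni"`.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param background optional character vector of entity ids defining the
#'   background universe; defaults to every annotated entity in the
#'   namespace.
#' @param namespace namespace to test in; may be omitted for
#'   single-namespace ontologies.
#' @return Data frame of class `enrichment_table` with columns `term_id`,
#'   `name`, `k`, `K`, `n`, `N`, `p`, `p_adj`, `significant`, sorted by
#'   `p_adj` then term id.
#' @examples
#' toy <- toy5()
#' enrich(toy$corpus, c("e1", "e2"), test = "fisher")
#' @export
enrich <- function(corpus, entity_set, test = c("fisher", "binomial"),
                   correction = c("bh", "bonferroni"), alpha = 0.05,
                   background = NULL, namespace = NULL) {
  test <- match.arg(test)
  correction <- match.arg(correction)
  graph <- corpus$graph
  nsp <- resolve_namespace(graph, namespace)
  root <- graph$roots[nsp]

  ns_set <- function(e) {
    ts <- corpus$propagated[[e]]
    ts[graph$namespace[ts] == nsp]
  }
  annotated <- corpus$entities[vapply(corpus$entities,
                                      function(e) length(ns_set(e)) > 0L,
                                      logical(1))]

  bg <- if (is.null(background)) annotated else {
    unknown <- setdiff(background, annotated)
    if (length(unknown)) {
      warning(sprintf(
        "dropping %d background entit%s without annotations",
        length(unknown), if (length(unknown) == 1) "y" else "ies"
      ), call. = FALSE)
    }
    intersect(background, annotated)
  }
  if (!length(bg)) data_error("empty annotated background")

  entity_set <- unique(as.character(entity_set))
  unknown <- setdiff(entity_set, bg)
  if (length(unknown)) {
    warning(sprintf(
      "dropping %d query entit%s not in the annotated background: %s",
      length(unknown), if (length(unknown) == 1) "y" else "ies",
      paste(unknown, collapse = ", ")
    ), call. = FALSE)
  }
  query <- intersect(entity_set, bg)
  if (!length(query)) data_error("no query entity is annotated in the corpus")

  q_sets <- lapply(query, ns_set)
  bg_sets <- lapply(bg, ns_set)
  n <- length(query)
  N <- length(bg)

  candidates <- sort(setdiff(unique(unlist(q_sets, use.names = FALSE)), root))
  if (!length(candidates)) {
    data_error("no candidate terms beyond the namespace root")
  }

  k_tab <- table(factor(unlist(q_sets, use.names = FALSE), levels = candidates))
  K_tab <- table(factor(unlist(bg_sets, use.names = FALSE), levels = candidates))
  k <- as.integer(k_tab)
  K <- as.integer(K_tab)

  p <- if (test == "fisher") {
    fisher_pvalue(k, K, n, N)
  } else {
    binomial_pvalue(k, n, K / N)
  }
  p_adj <- adjust_pvalues(p, correction)

  out <- data.frame(
    term_id = candidates,
    name = unname(graph$name[candidates]),
    k = k, K = K, n = n, N = N,
    p = p, p_adj = p_adj,
    significant = p_adj <= alpha,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_adj, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
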