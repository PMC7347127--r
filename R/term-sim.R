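# Between-term semantic similarity: four MICA-based IC measures, their
# four GraSM (disjoint-common-ancestor) variants, two edge-based measures
# and the Wang hybrid measure.

#' @rdname term_similarity
#' @export
TERM_MEASURES <- c("resnik", "lin", "jc", "rel",
                   "resnik_grasm", "lin_grasm", "jc_grasm", "rel_grasm",
                   "wu2005", "yu2005", "wang2007")

#' Default Wang semantic-contribution weights per edge relation.
#' @export
DEFAULT_WANG_WEIGHTS <- c(is_a = 0.8, part_of = 0.6)

#' Between-term semantic similarity
#'
#' Computes the similarity between two ontology terms under one of eleven
#' measures:
#'
#' * `resnik`: `IC(MICA)` — unnormalized, 0 when the only shared ancestor
#'   is the root.
#' * `lin`: `2 IC(MICA) / (IC(t1) + IC(t2))`, in `[0, 1]`; the degenerate
#'   root/root pair (0/0) is defined as 1.
#' * `jc`: Jiang–Conrath distance `IC(t1) + IC(t2) - 2 IC(MICA)` mapped to
#'   a similarity by `1 / (1 + d)`, in `(0, 1]`.
#' * `rel`: Schlicker relevance, `lin * (1 - p(MICA))`.
#' * `resnik_grasm`, `lin_grasm`, `jc_grasm`, `rel_grasm`: the same four
#'   formulas with `IC(MICA)` replaced by the arithmetic mean IC over the
#'   disjoint common ancestors ([dca()]); for `rel_grasm`, `p(MICA)` is
#'   replaced by `exp(-share)`.
#' * `wu2005` (edge-based): with `a` the deepest common ancestor,
#'   `2 depth(a) / (len(t1, a) + len(t2, a) + 2 depth(a))` where `len` is
#'   the shortest directed path length; ties on depth are broken by the
#'   smaller summed path length, then lexicographically.
#' * `yu2005` (edge-based): `1 / (1 + d)` with `d` the minimum over common
#'   ancestors of `len(t1, a) + len(t2, a)`.
#' * `wang2007` (hybrid): semantic-contribution S-values accumulated along
#'   edges with per-relation weights (`wang_weights`), combined over the
#'   common inclusive ancestors.
#'
#' All measures are symmetric in `t1`, `t2`.
#'
#' @param graph an [ontology_graph][parse_obo].
#' @param t1,t2 term ids in the same namespace.
#' @param measure one of `TERM_MEASURES`.
#' @param ic an [ic_table][compute_ic]; required by the eight IC-based
#'   measures, ignored by `wu2005`, `yu2005` and `wang2007`.
#' @param wang_weights named numeric in `(0, 1)`, contribution factor per
#'   edge relation (default `is_a` 0.8, `part_of` 0.6).
#' @param normalize for `resnik`/`resnik_grasm` only: divide by the
#'   maximum IC in the namespace so scores land in `[0, 1]`.
#' @return A single numeric score.
#' @examples
#' toy <- toy5()
#' ic <- compute_ic(toy$graph, toy$corpus)
#' term_similarity(toy$graph, "C", "D", "lin", ic)      # 0.369070
#' term_similarity(toy$graph, "C", "D", "wang2007")     # 0.590164
#' @export
term_similarity <- function(graph, t1, t2, measure, ic = NULL,
                            wang_weights = DEFAULT_WANG_WEIGHTS,
                            normalize = FALSE) {
  measure <- match.arg(measure, TERM_MEASURES)
  needs_ic <- !measure %in% c("wu2005", "yu2005", "wang2007")
  if (needs_ic && is.null(ic)) {
    usage_error(sprintf("measure '%s' requires an IC table", measure))
  }
  s <- switch(measure,
    resnik = sim_resnik(graph, ic, t1, t2),
    lin = sim_lin(graph, ic, t1, t2),
    jc = sim_jc(graph, ic, t1, t2),
    rel = sim_rel(graph, ic, t1, t2),
    resnik_grasm = sim_grasm(graph, ic, t1, t2, "resnik"),
    lin_grasm = sim_grasm(graph, ic, t1, t2, "lin"),
    jc_grasm = sim_grasm(graph, ic, t1, t2, "jc"),
    rel_grasm = sim_grasm(graph, ic, t1, t2, "rel"),
    wu2005 = sim_wu2005(graph, t1, t2),
    yu2005 = sim_yu2005(graph, t1, t2),
    wang2007 = sim_wang2007(graph, t1, t2, wang_weights)
  )
  if (normalize && measure %in% c("resnik", "resnik_grasm")) {
    mx <- max(ic$ic)
    s <- if (mx > 0) s / mx else 1
  }
  s
}

#' @rdname term_similarity
#' @export
sim_resnik <- function(graph, ic, t1, t2) {
  mica(graph, ic, t1, t2)$ic
}

#' @rdname term_similarity
#' @export
sim_lin <- function(graph, ic, t1, t2) {
  m <- mica(graph, ic, t1, t2)
  denom <- sum(ic_of(ic, c(t1, t2)))
  if (denom == 0) {
    # both terms are the root: identical, similarity 1 by convention
    return(1)
  }
  2 * m$ic / denom
}

#' @rdname term_similarity
#' @export
sim_jc <- function(graph, ic, t1, t2) {
  m <- mica(graph, ic, t1, t2)
  d <- sum(ic_of(ic, c(t1, t2))) - 2 * m$ic
  1 / (1 + d)
}

#' @rdname term_similarity
#' @export
sim_rel <- function(graph, ic, t1, t2) {
  m <- mica(graph, ic, t1, t2)
  sim_lin(graph, ic, t1, t2) * (1 - exp(-m$ic))
}

# Mean IC over the disjoint common ancestors: the quantity GraSM variants
# substitute for IC(MICA).
grasm_share <- function(graph, ic, t1, t2) {
  d <- dca(graph, t1, t2)
  mean(ic_of(ic, d))
}

#' @rdname term_similarity
#' @param base for [sim_grasm()]: which of the four IC formulas to apply
#'   on top of the DCA share.
#' @export
sim_grasm <- function(graph, ic, t1, t2,
                      base = c("resnik", "lin", "jc", "rel")) {
  base <- match.arg(base)
  share <- grasm_share(graph, ic, t1, t2)
  denom <- sum(ic_of(ic, c(t1, t2)))
  switch(base,
    resnik = share,
    lin = if (denom == 0) 1 else 2 * share / denom,
    jc = 1 / (1 + denom - 2 * share),
    rel = {
      lin <- if (denom == 0) 1 else 2 * share / denom
      lin * (1 - exp(-share))
    }
  )
}

#' @rdname term_similarity
#' @export
sim_wu2005 <- function(graph, t1, t2) {
  ca <- common_ancestors(graph, t1, t2)
  len1 <- path_len_up(graph, t1, ca)
  len2 <- path_len_up(graph, t2, ca)
  dep <- graph$depth[ca]
  # deepest common ancestor; ties -> smaller summed path, then smaller id
  ord <- order(-dep, len1 + len2, ca)
  a <- ca[ord[1]]
  num <- 2 * dep[[a]]
  den <- len1[[a]] + len2[[a]] + num
  if (den == 0) return(1) # root vs root
  num / den
}

#' @rdname term_similarity
#' @export
sim_yu2005 <- function(graph, t1, t2) {
  ca <- common_ancestors(graph, t1, t2)
  d <- min(path_len_up(graph, t1, ca) + path_len_up(graph, t2, ca))
  1 / (1 + d)
}

# Wang S-values of `t` over its inclusive ancestor set: S_t(t) = 1 and
# S_t(a) = max over children c of a (within the ancestor set) of
# w(relation(c -> a)) * S_t(c), accumulated in topological order.
wang_svalues <- function(graph, t, wang_weights) {
  anc <- graph$anc[[t]] # inclusive
  s <- stats::setNames(rep(-Inf, length(anc)), anc)
  s[t] <- 1
  sub <- igraph::induced_subgraph(graph$ig, anc)
  ord <- names(igraph::topo_sort(sub, mode = "out")) # children first
  for (c_ in ord) {
    pars <- graph$parents[[c_]]
    rels <- graph$parent_relation[[c_]]
    keep <- pars %in% anc
    pars <- pars[keep]; rels <- rels[keep]
    if (!length(pars)) next
    w <- wang_weights[rels]
    if (anyNA(w)) {
      data_error(sprintf(
        "no Wang contribution weight configured for relation(s): %s",
        paste(unique(rels[is.na(w)]), collapse = ", ")
      ))
    }
    upd <- unname(w) * s[c_]
    s[pars] <- pmax(s[pars], upd)
  }
  s
}

#' @rdname term_similarity
#' @export
sim_wang2007 <- function(graph, t1, t2,
                         wang_weights = DEFAULT_WANG_WEIGHTS) {
  if (any(wang_weights <= 0 | wang_weights >= 1)) {
    usage_error("Wang contribution weights must lie in (0, 1)")
  }
  s1 <- wang_svalues(graph, t1, wang_weights)
  s2 <- wang_svalues(graph, t2, wang_weights)
  ca <- common_ancestors(graph, t1, t2)
  (sum(s1[ca]) + sum(s2[ca])) / (sum(s1) + sum(s2))
}

#' Term-by-term similarity matrix
#'
#' Symmetric labeled matrix of between-term similarities for a set of
#' terms, filled over the unordered pairs returned by [upper_pairs()];
#' the diagonal holds each term's self-similarity under the measure.
#'
#' @inheritParams term_similarity
#' @param terms character vector of term ids (all in one namespace).
#' @return Numeric matrix with `terms` as dimnames and the measure name in
#'   attribute `"measure"`.
#' @examples
#' toy <- toy5()
#' ic <- compute_ic(toy$graph, toy$corpus)
#' term_matrix(toy$graph, c("C", "D"), "lin", ic)
#' @export
term_matrix <- function(graph, terms, measure, ic = NULL,
                        wang_weights = DEFAULT_WANG_WEIGHTS,
                        normalize = FALSE) {
  terms <- as.character(terms)
  if (!length(terms)) data_error("empty term list")
  for (t in terms) check_term(graph, t)
  n <- length(terms)
  m <- matrix(0, n, n, dimnames = list(terms, terms))
  for (i in seq_len(n)) {
    m[i, i] <- term_similarity(graph, terms[i], terms[i], measure, ic,
                               wang_weights, normalize)
  }
  idx <- upper_pairs(n)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    s <- term_similarity(graph, terms[i], terms[j], measure, ic,
                         wang_weights, normalize)
    m[i, j] <- s
    m[j, i] <- s
  }
  attr(m, "measure") <- measure
  m
}
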