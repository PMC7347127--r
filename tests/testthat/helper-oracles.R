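# Independent oracles used by property tests. These deliberately avoid
# every code path of the package: plain recursive closures, explicit
# enumeration and direct textbook formulas.

# Transitive parent closure by naive depth-first search over the raw
# parents lists.
oracle_ancestors <- function(parents, t, inclusive = FALSE) {
  seen <- character(0)
  stack <- t
  while (length(stack)) {
    x <- stack[1]
    stack <- stack[-1]
    if (x %in% seen) next
    seen <- c(seen, x)
    stack <- c(stack, parents[[x]])
  }
  if (!inclusive) seen <- setdiff(seen, t)
  sort(seen)
}

# Breadth-first search distance from t up to the root over parents lists.
oracle_depth <- function(parents, t, root) {
  level <- t
  d <- 0L
  repeat {
    if (root %in% level) return(d)
    level <- unique(unlist(parents[level], use.names = FALSE))
    if (!length(level)) return(NA_integer_)
    d <- d + 1L
  }
}

# Disjoint common ancestors by the O(n^2) definition: drop every common
# ancestor that is a strict ancestor of another common ancestor.
oracle_dca <- function(parents, t1, t2) {
  ca <- intersect(oracle_ancestors(parents, t1, TRUE),
                  oracle_ancestors(parents, t2, TRUE))
  keep <- vapply(ca, function(a) {
    !any(vapply(setdiff(ca, a), function(b) {
      a %in% oracle_ancestors(parents, b)
    }, logical(1)))
  }, logical(1))
  sort(ca[keep])
}

# Full-support hypergeometric upper-tail enumeration.
oracle_hyper_tail <- function(k, K, n, N) {
  i <- seq.int(k, min(n, K))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up by the direct formula, returned in input
# order: adjusted p at ascending rank i is min over j >= i of m p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- pmin(1, rev(cummin(rev(m * sorted / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

# A seeded random ontology + corpus, parsed through the package readers.
rand_fixture <- function(seed, n_terms = 12, n_entities = 6,
                         max_parents = 2, part_of_fraction = 0.25) {
  fx <- make_dag(n_terms = n_terms, max_parents = max_parents,
                 part_of_fraction = part_of_fraction, seed = seed)
  cp <- make_corpus(fx$graph, n_entities = n_entities, seed = seed + 10000L)
  list(graph = fx$graph, corpus = cp$corpus,
       ic = compute_ic(fx$graph, cp$corpus))
}

# Seeded RNG scope that restores the caller's stream.
with_seed_local <- function(seed, expr) ontosim:::with_seed(seed, expr)

# Write lines to a temp file and return the path.
tmp_file <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

toy_files <- function() {
  list(obo = tmp_file(toy5_obo_text(), ".obo"),
       annot = tmp_file(c("e1\tC", "e2\tD", "e3\tB"), ".tsv"))
}

# Diamond ontology: E below both A and B, used for multiple-inheritance
# and two-DCA checks.
diamond_graph <- function() {
  ontosim:::parse_obo_lines(c(
    "format-version: 1.2", "default-namespace: toy", "",
    "[Term]", "id: R", "name: root", "",
    "[Term]", "id: A", "name: a", "is_a: R", "",
    "[Term]", "id: B", "name: b", "is_a: R", "",
    "[Term]", "id: C", "name: c", "is_a: R", "",
    "[Term]", "id: D", "name: d", "is_a: R", "",
    "[Term]", "id: E", "name: e", "is_a: A", "is_a: B", "",
    "[Term]", "id: F", "name: f", "is_a: A", "is_a: B", ""
  ))
}
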