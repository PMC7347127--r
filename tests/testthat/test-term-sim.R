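# Worked values on the five-term fixture, computed by hand from the
# closed forms: IC(A) = ln(3/2), IC(C) = IC(D) = ln 3 on the 3-entity
# corpus.

toy <- toy5()
toy_ic <- compute_ic(toy$graph, toy$corpus)

test_that("the four MICA-based IC measures match hand computation", {
  g <- toy$graph
  expect_equal(sim_resnik(g, toy_ic, "C", "D"), log(3 / 2), tolerance = 1e-9)
  expect_equal(sim_resnik(g, toy_ic, "C", "B"), 0)
  expect_equal(sim_resnik(g, toy_ic, "C", "C"), log(3), tolerance = 1e-9)

  expect_equal(sim_lin(g, toy_ic, "C", "D"),
               2 * log(3 / 2) / (2 * log(3)), tolerance = 1e-9)
  expect_equal(sim_lin(g, toy_ic, "C", "C"), 1)
  expect_equal(sim_lin(g, toy_ic, "R", "R"), 1) # 0/0 convention

  # distance ln 4, similarity 1 / (1 + ln 4)
  expect_equal(sim_jc(g, toy_ic, "C", "D"), 1 / (1 + log(4)),
               tolerance = 1e-9)
  expect_equal(sim_jc(g, toy_ic, "C", "C"), 1)

  expect_equal(sim_rel(g, toy_ic, "C", "D"),
               2 * log(3 / 2) / (2 * log(3)) * (1 - 2 / 3),
               tolerance = 1e-9)
  expect_equal(sim_rel(g, toy_ic, "C", "B"), 0)
  expect_equal(sim_rel(g, toy_ic, "C", "C"), 1 - 1 / 3, tolerance = 1e-9)
})

test_that("GraSM variants collapse to base measures on a single DCA", {
  g <- toy$graph
  # dca(C, D) = {A}: every GraSM variant equals its base measure
  for (base in c("resnik", "lin", "jc", "rel")) {
    expect_equal(
      sim_grasm(g, toy_ic, "C", "D", base),
      term_similarity(g, "C", "D", base, toy_ic),
      tolerance = 1e-12
    )
  }
})

test_that("GraSM averages the ICs of two disjoint common ancestors", {
  d <- diamond_graph()
  cp <- ontosim:::parse_annotation_lines(
    c("x1\tE", "x2\tF", "x3\tC", "x4\tD"), d
  )
  ic <- compute_ic(d, cp)
  expect_equal(unname(ic$ic["A"]), log(2), tolerance = 1e-12)
  expect_equal(ontosim:::grasm_share(d, ic, "E", "F"), log(2),
               tolerance = 1e-12)
  expect_equal(sim_grasm(d, ic, "E", "F", "resnik"), log(2),
               tolerance = 1e-12)
})

test_that("edge-based measures count shortest paths as specified", {
  g <- toy$graph
  expect_equal(sim_wu2005(g, "C", "D"), 0.5)
  expect_equal(sim_wu2005(g, "C", "C"), 1)
  expect_equal(sim_wu2005(g, "C", "B"), 0)
  expect_equal(sim_wu2005(g, "R", "R"), 1)

  expect_equal(sim_yu2005(g, "C", "D"), 1 / 3)
  expect_equal(sim_yu2005(g, "C", "C"), 1)
  expect_equal(sim_yu2005(g, "C", "B"), 1 / 4) # d = 2 + 1 via R
})

test_that("path distance underlying yu2005 satisfies the triangle inequality", {
  for (seed in 1:15) {
    fx <- make_dag(n_terms = 10, max_parents = 2, seed = seed)
    g <- fx$graph
    dist_of <- function(a, b) 1 / term_similarity(g, a, b, "yu2005") - 1
    ids <- g$ids
    trip <- with_seed_local(seed, {
      matrix(sample(ids, 9, replace = TRUE), ncol = 3)
    })
    for (r in seq_len(nrow(trip))) {
      a <- trip[r, 1]; b <- trip[r, 2]; c_ <- trip[r, 3]
      expect_lte(dist_of(a, c_), dist_of(a, b) + dist_of(b, c_) + 1e-9)
    }
  }
})

test_that("the Wang hybrid measure reproduces the hand S-value recursion", {
  g <- toy$graph
  # S_C = {C: 1, A: 0.8, R: 0.64}, SV(C) = 2.44
  s <- ontosim:::wang_svalues(g, "C", DEFAULT_WANG_WEIGHTS)
  expect_equal(s[c("C", "A", "R")], c(C = 1, A = 0.8, R = 0.64))
  expect_equal(sim_wang2007(g, "C", "D"), 2.88 / 4.88, tolerance = 1e-9)
  expect_equal(sim_wang2007(g, "C", "C"), 1)
  expect_equal(sim_wang2007(g, "C", "B"), 1.44 / 4.24, tolerance = 1e-9)
})

test_that("Wang weights are validated and honour part_of edges", {
  expect_error(sim_wang2007(toy$graph, "C", "D",
                            wang_weights = c(is_a = 1.2)),
               "\\(0, 1\\)")
  po <- ontosim:::parse_obo_lines(c(
    "format-version: 1.2", "default-namespace: toy", "",
    "[Term]", "id: R", "name: root", "",
    "[Term]", "id: A", "name: a", "relationship: part_of R", "",
    "[Term]", "id: B", "name: b", "is_a: R", ""
  ))
  s <- ontosim:::wang_svalues(po, "A", DEFAULT_WANG_WEIGHTS)
  expect_equal(unname(s["R"]), 0.6)
  # an edge whose relation has no weight raises a clear error
  expect_error(sim_wang2007(po, "A", "B", wang_weights = c(is_a = 0.8)),
               "relation")
})

test_that("unnormalized Resnik can be rescaled by the namespace maximum IC", {
  g <- toy$graph
  raw <- term_similarity(g, "C", "C", "resnik", toy_ic)
  nrm <- term_similarity(g, "C", "C", "resnik", toy_ic, normalize = TRUE)
  expect_equal(nrm, raw / max(toy_ic$ic), tolerance = 1e-12)
  expect_lte(nrm, 1)
})

test_that("term matrices are symmetric with self-similarity diagonals", {
  g <- toy$graph
  m <- term_matrix(g, c("C", "D"), "lin", toy_ic)
  expect_equal(m["C", "D"], 2 * log(3 / 2) / (2 * log(3)), tolerance = 1e-9)
  expect_equal(m, t(m))
  expect_equal(diag(m), c(C = 1, D = 1))
  m1 <- term_matrix(g, "B", "wu2005")
  expect_equal(dim(m1), c(1L, 1L))
  expect_equal(m1["B", "B"], 1)
  expect_error(term_matrix(g, character(0), "lin", toy_ic), "empty")
})

test_that("all eleven term measures are symmetric and bounded on random data", {
  normalized <- c("lin", "jc", "rel", "lin_grasm", "jc_grasm", "rel_grasm",
                  "wu2005", "yu2005", "wang2007")
  for (seed in 1:25) {
    fx <- rand_fixture(seed)
    g <- fx$graph
    covered <- names(fx$ic$counts)
    pair <- with_seed_local(seed + 500L, sample(covered, 2, replace = TRUE))
    for (meas in TERM_MEASURES) {
      s12 <- term_similarity(g, pair[1], pair[2], meas, fx$ic)
      s21 <- term_similarity(g, pair[2], pair[1], meas, fx$ic)
      expect_equal(s12, s21, tolerance = 1e-12)
      expect_gte(s12, 0)
      if (meas %in% normalized) expect_lte(s12, 1 + 1e-12)
    }
  }
})

test_that("specificity is monotone: sim(t, t) >= sim(t, parent)", {
  for (seed in 1:15) {
    fx <- rand_fixture(seed)
    g <- fx$graph
    covered <- names(fx$ic$counts)
    for (t in covered) {
      for (p in intersect(g$parents[[t]], covered)) {
        for (meas in c("resnik", "lin")) {
          expect_gte(term_similarity(g, t, t, meas, fx$ic) + 1e-12,
                     term_similarity(g, t, p, meas, fx$ic))
        }
      }
    }
  }
})
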