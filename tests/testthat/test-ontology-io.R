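test_that("the five-term fixture parses to the expected graph", {
  g <- parse_obo(toy_files()$obo)
  expect_setequal(g$ids, c("R", "A", "B", "C", "D"))
  expect_equal(sum(lengths(g$parents)), 4L)
  expect_equal(unname(g$roots["toy"]), "R")
  expect_equal(g$parents[["C"]], "A")
  expect_equal(g$parent_relation[["C"]], "is_a")
  expect_equal(unname(g$name["C"]), "leaf c")
})

test_that("cyclic and malformed OBO inputs are rejected with clear errors", {
  cyc <- c(toy5_obo_text()[1:3],
           "[Term]", "id: R", "name: root", "",
           "[Term]", "id: A", "name: a", "is_a: R", "is_a: C", "",
           "[Term]", "id: C", "name: c", "is_a: A", "")
  expect_error(parse_obo(tmp_file(cyc, ".obo")), "cycle")

  no_id <- c("format-version: 1.2", "", "[Term]", "name: orphan stanza")
  expect_error(parse_obo(tmp_file(no_id, ".obo")), "line")

  expect_error(parse_obo(tmp_file(c("format-version: 1.2", ""), ".obo")),
               "Term")
})

test_that("obsolete terms leave the graph but stay recognisable", {
  obo <- c(toy5_obo_text(),
           "[Term]", "id: X", "name: gone", "is_a: A",
           "is_obsolete: true", "")
  g <- parse_obo(tmp_file(obo, ".obo"))
  expect_false("X" %in% g$ids)
  expect_true("X" %in% names(g$alt))
  expect_true("X" %in% g$obsolete)
  # annotations to it are dropped with a warning, not kept
  expect_warning(
    cp <- ontosim:::parse_annotation_lines(c("e1\tC", "e2\tX"), g),
    "obsolete"
  )
  expect_equal(cp$entities, "e1")
})

test_that("alt_id lines remap annotations to the canonical term", {
  obo <- sub("^id: C$", "id: C", toy5_obo_text())
  obo <- append(obo, "alt_id: C_OLD", after = which(obo == "id: C") + 1L)
  g <- parse_obo(tmp_file(obo, ".obo"))
  cp <- ontosim:::parse_annotation_lines("e1\tC_OLD", g)
  expect_equal(cp$direct[["e1"]], "C")
})

test_that("annotation parsing propagates, filters and skips as specified", {
  toy <- toy5()
  expect_equal(lengths(toy$corpus$direct), c(e1 = 1L, e2 = 1L, e3 = 1L))
  expect_equal(toy$corpus$propagated[["e1"]], c("A", "C", "R"))

  # evidence filter keeps records that carry no evidence column
  cp <- ontosim:::parse_annotation_lines(
    c("e1\tC", "e2\tD", "e3\tB"), toy$graph, evidence_filter = "IEA"
  )
  expect_equal(length(cp$entities), 3L)

  # records failing the filter are removed
  expect_warning(
    cp2 <- ontosim:::parse_annotation_lines(
      c("e1\tC\tEXP", "e2\tD\tIEA", "e3\tB"), toy$graph,
      evidence_filter = "IEA"
    ),
    "evidence"
  )
  expect_setequal(cp2$entities, c("e2", "e3"))

  # unknown term skipped with warning; malformed single-field line too
  expect_warning(
    cp3 <- ontosim:::parse_annotation_lines(
      c("e1\tC", "e2\tD", "e3\tB", "e4\tZZ:999", "stray"), toy$graph
    ),
    "dropped"
  )
  expect_equal(length(cp3$entities), 3L)

  # duplicates collapse silently
  cp4 <- ontosim:::parse_annotation_lines(c("e1\tC", "e1\tC"), toy$graph)
  expect_equal(lengths(cp4$direct), c(e1 = 1L))

  expect_error(
    suppressWarnings(
      ontosim:::parse_annotation_lines("e1\tZZ:999", toy$graph)
    ),
    "no annotation records"
  )
})

test_that("propagated sets are closed and idempotent under re-closure", {
  for (seed in 1:20) {
    fx <- rand_fixture(seed)
    for (e in fx$corpus$entities) {
      prop <- fx$corpus$propagated[[e]]
      reclosed <- sort(unique(unlist(fx$graph$anc[prop], use.names = FALSE)))
      expect_identical(reclosed, prop)
      expect_true(all(fx$corpus$direct[[e]] %in% prop))
    }
  }
})

test_that("matrix export round-trips and follows the format contract", {
  toy <- toy5()
  ic <- compute_ic(toy$graph, toy$corpus)
  m <- term_matrix(toy$graph, c("C", "D"), "lin", ic)
  f <- tempfile(fileext = ".tsv")
  write_matrix(m, f)
  lines <- readLines(f)
  expect_equal(length(lines), 4L) # provenance comment + header + 2 rows
  expect_match(lines[1], "^# measure: lin$")
  back <- read_matrix(f)
  expect_equal(back, m, tolerance = 1e-6)
})

test_that("network export handles empty inputs and SIF round-trips", {
  empty <- data.frame(source = character(0), target = character(0),
                      weight = numeric(0))
  f <- tempfile(fileext = ".tsv")
  write_network(empty, f, "tsv")
  expect_equal(readLines(f), "source\ttarget\tweight")

  edges <- data.frame(source = c("a", "b"), target = c("b", "c"),
                      weight = c(0.5, 0.25))
  fs <- tempfile(fileext = ".sif")
  write_network(edges, fs, "sif")
  back <- read_network(fs, "sif")
  expect_equal(back[c("source", "target")], edges[c("source", "target")])

  ft <- tempfile(fileext = ".tsv")
  write_network(edges, ft, "tsv")
  back2 <- read_network(ft, "tsv")
  expect_equal(back2$weight, edges$weight, tolerance = 1e-6)
})

test_that("enrichment tables export with the documented header", {
  toy <- toy5()
  tab <- enrich(toy$corpus, c("e1", "e2"))
  f <- tempfile(fileext = ".tsv")
  write_enrichment(tab, f)
  lines <- readLines(f)
  expect_equal(lines[1],
               "term_id\tname\tk\tK\tn\tN\tp\tp_adj\tsignificant")
  expect_equal(length(lines), nrow(tab) + 1L)
})

test_that("synthetic OBO round-trips preserve terms, edges and roots", {
  for (seed in c(1, 7, 42)) {
    fx <- make_dag(n_terms = 15, max_parents = 3,
                   part_of_fraction = 0.3, seed = seed)
    g2 <- parse_obo(tmp_file(fx$obo, ".obo"))
    expect_identical(g2$ids, fx$graph$ids)
    expect_identical(g2$parents, fx$graph$parents)
    expect_identical(g2$roots, fx$graph$roots)
  }
})

test_that("the parser never accepts a cyclic file", {
  for (seed in 1:25) {
    fx <- make_dag(n_terms = 10, max_parents = 2, seed = seed)
    # add a back-edge from a root-adjacent term to a leaf: guaranteed cycle
    ids <- fx$graph$ids
    leaf <- ids[length(ids)]
    anc_of_leaf <- ancestors(fx$graph, leaf)
    victim <- anc_of_leaf[1]
    obo <- fx$obo
    at <- which(obo == sprintf("id: %s", victim))
    obo <- append(obo, sprintf("is_a: %s", leaf), after = at)
    expect_error(ontosim:::parse_obo_lines(obo), "cycle")
  }
})
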