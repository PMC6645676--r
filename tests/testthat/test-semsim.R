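chain_obo <- function() {
  p <- tempfile(fileext = ".obo")
  writeLines(c(
    "format-version: 1.2", "",
    "[Term]", "id: T:1", "name: root", "",
    "[Term]", "id: T:2", "name: middle", "is_a: T:1 ! root", "",
    "[Term]", "id: T:3", "name: leaf", "is_a: T:2 ! middle", ""), p)
  p
}

test_that("OBO parsing builds the DAG, keeps relations, rejects cycles", {
  dag <- loadOBO(chain_obo())
  expect_identical(ontologyTerms(dag), c("T:1", "T:2", "T:3"))
  expect_identical(nrow(ontologyEdges(dag)), 2L)
  expect_identical(ontologyRoots(dag), "T:1")

  # two parents via is_a and part_of both retained
  p2 <- tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: A", "name: a", "",
    "[Term]", "id: B", "name: b", "",
    "[Term]", "id: C", "name: c", "is_a: A",
    "relationship: part_of B", ""), p2)
  dag2 <- loadOBO(p2)
  ed <- ontologyEdges(dag2)
  expect_setequal(ed$relation[ed$child == "C"], c("is_a", "part_of"))

  # obsolete terms skipped
  p3 <- tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: A", "name: a", "",
    "[Term]", "id: B", "name: gone", "is_obsolete: true", ""), p3)
  expect_identical(ontologyTerms(loadOBO(p3)), "A")

  # cycle is an error naming the terms involved
  p4 <- tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: A", "name: a", "is_a: B", "",
    "[Term]", "id: B", "name: b", "is_a: A", ""), p4)
  expect_error(loadOBO(p4), "cycle")

  # round trip through the OBO writer
  p5 <- tempfile(fileext = ".obo")
  writeOBO(dag, p5)
  dag5 <- loadOBO(p5)
  expect_identical(ontologyTerms(dag5), ontologyTerms(dag))
  expect_identical(ontologyEdges(dag5)$parent, ontologyEdges(dag)$parent)
})

test_that("Wang similarity reproduces hand-worked values and boundary behaviour", {
  dag <- loadOBO(chain_obo())
  # identity
  expect_equal(termSimilarity("T:2", "T:2", dag), 1)
  # direct parent-child with an is_a edge: (0.8 + 1) / (1.8 + 1)
  expect_equal(termSimilarity("T:2", "T:1", dag), 1.8 / 2.8,
               tolerance = 1e-10)
  expect_equal(termSimilarity("T:2", "T:1", dag), 0.64286, tolerance = 1e-4)
  # symmetry
  expect_equal(termSimilarity("T:1", "T:2", dag),
               termSimilarity("T:2", "T:1", dag))
  # disjoint components share nothing
  p <- tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: A", "name: a", "",
               "[Term]", "id: B", "name: b", ""), p)
  dag2 <- loadOBO(p)
  expect_equal(termSimilarity("A", "B", dag2), 0)
  expect_error(termSimilarity("A", "ZZ", dag2), "unknown")
})

test_that("Wang S-values agree with exhaustive path enumeration on random DAGs", {
  set.seed(44)
  for (i in 1:6) {
    dag <- randomDAG(sample(6:12, 1))
    terms <- ontologyTerms(dag)
    pair <- sample(terms, 2)
    got <- termSimilarity(pair[1], pair[2], dag)
    want <- wangOracleSim(pair[1], pair[2], ontologyEdges(dag))
    expect_equal(got, want, tolerance = 1e-12)
    # properties: symmetric, in [0, 1], 1 on the diagonal
    expect_equal(got, termSimilarity(pair[2], pair[1], dag),
                 tolerance = 1e-12)
    expect_gte(got, 0); expect_lte(got, 1 + 1e-12)
    expect_equal(termSimilarity(pair[1], pair[1], dag), 1)
  }
})

test_that("set similarity computes the best-match average", {
  dag <- loadOBO(chain_obo())
  expect_equal(termSetSimilarity("T:2", "T:2", dag)$bma, 1)
  # {A} vs {A, B} with sim(A, B) = 1.8/2.8
  res <- termSetSimilarity("T:2", c("T:2", "T:1"), dag)
  s <- 1.8 / 2.8
  expect_equal(res$bma, (1 + (1 + s) / 2) / 2, tolerance = 1e-10)
  expect_equal(res$bma, 0.91071, tolerance = 1e-4)
  expect_error(termSetSimilarity(character(), "T:1", dag), "non-empty")
})

test_that("specificity screen uses a strict cutoff over all opposite terms", {
  # two disjoint components: X alone; root R with children C1, C2
  p <- tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: R", "name: r", "",
    "[Term]", "id: C1", "name: c1", "is_a: R", "",
    "[Term]", "id: C2", "name: c2", "is_a: R", "",
    "[Term]", "id: X", "name: x", ""), p)
  dag <- loadOBO(p)
  res <- specificTerms(c("X", "C1"), c("C1", "C2"), dag)
  rep <- res$report
  # X shares no ancestors with the opposite set: specific
  expect_true(rep$specific[rep$term == "X"])
  # C1 has a twin (similarity 1) in the opposite set: not specific
  expect_false(rep$specific[rep$term == "C1"])
  expect_true(any(res$high_pairs$similarity > 0.8))

  # boundary: a maximum cross-similarity exactly at the cutoff is NOT specific
  sib <- specificTerms("C1", "C2", dag)
  s_sib <- sib$report$max_similarity[1]
  at_cut <- specificTerms("C1", "C2", dag, cutoff = s_sib)
  expect_false(at_cut$report$specific[1])
  just_above <- specificTerms("C1", "C2", dag, cutoff = s_sib + 1e-9)
  expect_true(just_above$report$specific[1])
})

test_that("deepening a term under the same parentage does not raise cross-branch similarity", {
  p <- tempfile(fileext = ".obo")
  writeLines(c(
    "[Term]", "id: R", "name: r", "",
    "[Term]", "id: L", "name: left", "is_a: R", "",
    "[Term]", "id: L2", "name: left2", "is_a: L", "",
    "[Term]", "id: Q", "name: right", "is_a: R", ""), p)
  dag <- loadOBO(p)
  expect_lte(termSimilarity("L2", "Q", dag), termSimilarity("L", "Q", dag))
})
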