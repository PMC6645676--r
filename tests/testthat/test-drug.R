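test_that("connectivity score hits the stated scale endpoints", {
  dis <- DiseaseSignature(up = c("g1", "g2"), down = c("g3", "g4"))
  # perfect reversal
  expect_equal(connectivityScore(dis, drugUp = c("g3", "g4"),
                                 drugDown = c("g1", "g2")), 100)
  # perfect mimic
  expect_equal(connectivityScore(dis, drugUp = c("g1", "g2"),
                                 drugDown = c("g3", "g4")), -100)
  # no shared genes
  expect_equal(connectivityScore(dis, drugUp = c("x1"), drugDown = c("x2")), 0)
})

test_that("score is antisymmetric, bounded, and diluted by untouched genes", {
  set.seed(23)
  pool <- sprintf("g%03d", 1:60)
  for (i in 1:20) {
    d_up <- sample(pool, 8); d_dn <- sample(setdiff(pool, d_up), 8)
    s_up <- sample(pool, 10); s_dn <- sample(setdiff(pool, s_up), 10)
    dis <- DiseaseSignature(d_up, d_dn)
    sc <- connectivityScore(dis, s_up, s_dn)
    expect_gte(sc, -100); expect_lte(sc, 100)
    # swapping the drug lists negates the score exactly
    expect_equal(connectivityScore(dis, s_dn, s_up), -sc)
  }
  # adding disease genes a drug does not touch shrinks |score| monotonically
  dis1 <- DiseaseSignature("g1", "g2")
  sc1 <- connectivityScore(dis1, "g2", "g1")
  dis2 <- DiseaseSignature(c("g1", "zz1"), c("g2", "zz2"))
  sc2 <- connectivityScore(dis2, "g2", "g1")
  dis3 <- DiseaseSignature(c("g1", "zz1", "zz3"), c("g2", "zz2", "zz4"))
  sc3 <- connectivityScore(dis3, "g2", "g1")
  expect_true(abs(sc1) > abs(sc2) && abs(sc2) > abs(sc3))
  expect_error(connectivityScore(DiseaseSignature(character(), character()),
                                 "g1", "g2"), "empty")
})

test_that("disease signatures are built from top-kME genes of significant modules", {
  # 16 genes: a 4-gene positive module and a 12-gene negative module
  set.seed(66)
  genes <- sprintf("g%02d", 1:16)
  asg <- setNames(c(rep("M1", 4), rep("M2", 12)), genes)
  E <- cbind(M1 = rnorm(10), M2 = rnorm(10))
  E <- apply(E, 2, function(v) v / sqrt(sum(v^2)))
  rownames(E) <- paste0("s", 1:10)
  kme <- matrix(runif(32, -1, 1), 16, 2, dimnames = list(genes, c("M1", "M2")))
  ms <- new("ModuleSet", assignment = asg, eigengenes = E, kme = kme,
            powerUsed = 1L, fitTable = data.frame())
  tests <- data.frame(module = c("M1", "M2"),
                      u_statistic = c(1, 2), p_value = c(0.01, 0.02),
                      q_value = c(0.02, 0.02), direction = c(1L, -1L),
                      significant = c(TRUE, TRUE))
  sig <- buildDiseaseSignature(ms, tests, nTop = 10)
  # small module contributes all members
  expect_setequal(upGenes(sig), genes[1:4])
  # large module contributes exactly its 10 highest-kME members
  want <- genes[5:16][order(-kme[genes[5:16], "M2"])][1:10]
  expect_setequal(downGenes(sig), want)

  # a gene reaching both top lists (module significant in both directions,
  # e.g. under a tied median) is dropped from both
  tests_both <- data.frame(module = c("M1", "M1"), u_statistic = c(1, 1),
                           p_value = c(0.01, 0.01), q_value = c(0.02, 0.02),
                           direction = c(1L, -1L),
                           significant = c(TRUE, TRUE))
  expect_message(sig_b <- buildDiseaseSignature(ms, tests_both),
                 "removed from both")
  expect_length(upGenes(sig_b), 0L)
  expect_length(downGenes(sig_b), 0L)

  tests_one <- tests[1, , drop = FALSE]
  expect_warning(sig_one <- buildDiseaseSignature(ms, tests_one),
                 "one-sided")
  expect_length(downGenes(sig_one), 0L)
  expect_error(buildDiseaseSignature(ms, tests[tests$p_value > 1, ]),
               "no module")
})

test_that("drug ranking orders by score with lexicographic tie-breaks", {
  dis <- DiseaseSignature(c("g1", "g2"), c("g3", "g4"))
  lib <- new("DrugSignatureLibrary", compounds = list(
    bb = list(up = c("g3", "g4"), down = c("g1", "g2"), mechanism = "rev"),
    aa = list(up = "x1", down = "x2", mechanism = "null1"),
    ab = list(up = "x3", down = "x4", mechanism = "null2"),
    cc = list(up = c("g1", "g2"), down = c("g3", "g4"), mechanism = "mimic")))
  rk <- rankDrugs(dis, lib)
  expect_identical(rk$compound_id, c("bb", "aa", "ab", "cc"))
  expect_identical(rk$rank, 1:4)
  expect_equal(rk$score, c(100, 0, 0, -100))
  # single-compound library: rank 1 regardless of score
  rk1 <- rankDrugs(dis, new("DrugSignatureLibrary", compounds = list(
    only = list(up = "g1", down = character(), mechanism = NA_character_))))
  expect_identical(rk1$rank, 1L)

  # library round trip through the tab-delimited format
  path <- tempfile(fileext = ".tsv")
  writeDrugLibrary(lib, path)
  lib2 <- readDrugLibrary(path)
  expect_setequal(compoundIds(lib2), compoundIds(lib))
  expect_setequal(compoundSignature(lib2, "bb")$up, c("g3", "g4"))
  expect_identical(compoundSignature(lib2, "bb")$mechanism, "rev")
})
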