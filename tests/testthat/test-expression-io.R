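test_that("expression matrix reader round-trips, collapses duplicates, rejects bad cells", {
  m <- matrix(c(1.5, 2.25, -3.125, 4e-3), 2, 2,
              dimnames = list(c("gA", "gB"), c("s1", "s2")))
  path <- tempfile(fileext = ".tsv")
  writeExpressionMatrix(m, path)
  back <- readExpressionMatrix(path)
  expect_identical(back, m)

  # duplicated gene row collapsed by mean: g1 at 1 and 3 -> 2
  p2 <- writeTinyMatrix(c("gene\ts1\ts2", "g1\t1\t10", "g2\t5\t6",
                          "g1\t3\t20"))
  expect_message(dup <- readExpressionMatrix(p2), "collapsed 1")
  expect_equal(dup["g1", ], c(s1 = 2, s2 = 15))
  expect_equal(nrow(dup), 2L)

  # blank cell named in the error
  p3 <- writeTinyMatrix(c("gene\ts1\ts2", "g1\t1\t", "g2\t3\t4"))
  expect_error(readExpressionMatrix(p3), "g1.*s2")
  # non-numeric cell
  p4 <- writeTinyMatrix(c("gene\ts1", "g1\tabc"))
  expect_error(readExpressionMatrix(p4), "abc")
  # duplicate samples
  p5 <- writeTinyMatrix(c("gene\ts1\ts1", "g1\t1\t2"))
  expect_error(readExpressionMatrix(p5), "duplicate sample")
})

test_that("merging keeps the common genes, unions samples, is order-insensitive", {
  mk <- function(genes, samples, offset = 0) {
    matrix(seq_along(genes) %o% seq_along(samples) + offset,
           length(genes), length(samples),
           dimnames = list(genes, samples))
  }
  m1 <- mk(c("a", "b", "c"), c("s1", "s2"))
  m2 <- mk(c("b", "c", "d"), c("s3", "s4"), offset = 10)
  out <- mergeOnCommonGenes(list(m1, m2))
  expect_identical(rownames(out), c("b", "c"))
  expect_identical(colnames(out), c("s1", "s2", "s3", "s4"))
  expect_identical(rownames(mergeOnCommonGenes(list(m2, m1))), c("b", "c"))

  # identical gene sets: all genes kept
  m3 <- mk(c("a", "b", "c"), c("s5", "s6"))
  expect_equal(nrow(mergeOnCommonGenes(list(m1, m3))), 3L)

  # disjoint gene sets
  m4 <- mk(c("x", "y"), c("s7", "s8"))
  expect_error(mergeOnCommonGenes(list(m1, m4)), "no genes common")
  # overlapping samples rejected
  expect_error(mergeOnCommonGenes(list(m1, mk(c("a", "b"), c("s1", "s9")))),
               "overlap")
})

test_that("quantile normalization equalizes column distributions and is idempotent", {
  m <- matrix(c(1, 5, 3, 7), 2, 2, dimnames = list(c("g1", "g2"),
                                                   c("s1", "s2")))
  qn <- quantileNormalize(m)
  expect_equal(unname(qn), matrix(c(2, 6, 2, 6), 2, 2))

  set.seed(5)
  big <- matrix(rexp(300), 30, 10,
                dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10)))
  q1 <- quantileNormalize(big)
  # all columns share the same sorted values
  sorted <- apply(q1, 2L, sort)
  expect_true(all(abs(sorted - sorted[, 1L]) < 1e-12))
  # idempotent
  expect_equal(quantileNormalize(q1), q1, tolerance = 1e-10)
  # single column is a fixed point
  one <- big[, 1L, drop = FALSE]
  expect_equal(quantileNormalize(one), one)
})

test_that("log2 transform and global scaling behave as documented", {
  m <- matrix(c(8, 1, 2, 4), 2, 2, dimnames = list(c("g1", "g2"),
                                                   c("s1", "s2")))
  lt <- log2Transform(m)
  expect_equal(unname(lt[1, 1]), 3)
  expect_equal(unname(lt[2, 1]), 0)
  m0 <- m; m0[1, 1] <- 0
  expect_error(log2Transform(m0), "non-positive")

  z <- matrix(c(0, 2, 0, 2), 2, 2, dimnames = dimnames(m))
  gs <- globalScale(z)
  expect_equal(sort(unique(as.vector(gs))), c(-1, 1))
  # fixed point
  expect_equal(globalScale(gs), gs, tolerance = 1e-12)
  expect_error(globalScale(matrix(1, 2, 2,
                                  dimnames = dimnames(m))), "constant")
  # property: always mean 0, sd 1 (population)
  set.seed(9)
  for (i in 1:5) {
    r <- matrix(rnorm(40, sd = runif(1, 0.5, 4)), 8, 5,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
    sc <- globalScale(r)
    expect_lt(abs(mean(sc)), 1e-10)
    expect_lt(abs(sqrt(mean((sc - mean(sc))^2)) - 1), 1e-10)
  }
})

test_that("cohort summary reproduces the published study-population totals", {
  tab <- utils::read.delim(system.file("extdata", "cohort_series.tsv",
                                       package = "ruptureNet"))
  cs <- summarizeCohort(tab)
  expect_identical(cs$n_patients, 33L)
  expect_identical(cs$n_ruptured, 19L)
  expect_identical(unname(cs$location_counts["MCA"]), 21L)
  expect_equal(unname(cs$location_counts[c("ICA", "AComm", "PComm", "PC")]),
               c(3L, 5L, 2L, 2L))
  # weighted mean of the per-series means over ruptured patients
  expect_equal(cs$mean_tts, (11 * 2.1 + 8 * 7.0) / 19)

  # single series: identity
  one <- summarizeCohort(tab[1, ])
  expect_identical(one$n_patients, 19L)
  expect_identical(one$n_ruptured, 11L)
  expect_equal(one$mean_tts, 2.1)
  expect_equal(one$sd_tts, 3.4)

  bad <- tab; bad$patients[1] <- -1
  expect_error(summarizeCohort(bad), "negative")
})

test_that("GMT and marker-panel readers parse their formats", {
  gmt <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tfirst set\tg1\tg2\tg3", "setB\t\tg2\tg4"), gmt)
  sets <- readGMT(gmt)
  expect_identical(names(sets), c("setA", "setB"))
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  expect_identical(attr(sets, "descriptions")[["setA"]], "first set")
  # round trip
  gmt2 <- tempfile(fileext = ".gmt")
  writeGMT(sets, gmt2)
  expect_identical(readGMT(gmt2)$setB, c("g2", "g4"))

  panel <- readMarkerPanel()
  expect_identical(sort(names(panel)),
                   sort(c("smooth_muscle", "endothelial", "macrophage",
                          "mast_cell", "t_cell")))
  expect_true(all(c("CD14", "CD68") %in% panel$macrophage))
  expect_identical(panel$smooth_muscle, c("MCAM", "DES"))
})
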