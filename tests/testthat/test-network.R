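rand_mat <- function(G, N, seed) {
  set.seed(seed)
  matrix(rnorm(G * N), G, N,
         dimnames = list(sprintf("g%02d", seq_len(G)),
                         sprintf("s%02d", seq_len(N))))
}

test_that("absolute correlation matrix is unsigned with unit diagonal", {
  m <- rand_mat(5, 10, 1)
  m["g02", ] <- m["g01", ]          # duplicate gene
  m["g03", ] <- -m["g01", ]         # negated gene
  r <- correlationMatrix(m)
  expect_equal(unname(r["g01", "g02"]), 1)
  expect_equal(unname(r["g01", "g03"]), 1)
  expect_true(all(r >= 0 & r <= 1 + 1e-12))
  expect_equal(unname(diag(r)), rep(1, 5))

  # hand-computed Pearson
  m2 <- matrix(c(1, 2, 3, 1, 2, 4), 2, 3, byrow = TRUE,
               dimnames = list(c("x", "y"), c("s1", "s2", "s3")))
  expect_equal(unname(correlationMatrix(m2)["x", "y"]), 0.98198,
               tolerance = 1e-5)

  mz <- m; mz["g04", ] <- 2
  expect_error(correlationMatrix(mz), "g04")
})

test_that("soft-threshold selection finds scale-free fits and breaks ties downward", {
  # rank-1 'correlation-like' matrix whose connectivities follow a power
  # law: u drawn Pareto-like so k_i ~ u_i * sum(u) has density ~ k^-gamma
  set.seed(21)
  n <- 400
  u <- (seq_len(n) / n)^(-0.7)
  u <- u / max(u) * 0.9
  cm <- outer(u, u); diag(cm) <- 1
  dimnames(cm) <- list(sprintf("g%03d", 1:n), sprintf("g%03d", 1:n))
  st <- pickSoftThreshold(cm, powers = 1:3, targetR2 = 0.95)
  expect_gte(st$fitTable$signed_r2[1L], 0.95)
  expect_identical(st$power, 1L)

  # target 0: the smallest candidate qualifies immediately
  st0 <- pickSoftThreshold(cm, powers = c(2L, 5L), targetR2 = 0)
  expect_identical(st0$power, 2L)

  # degenerate degree distribution
  ones <- matrix(1, 10, 10)
  expect_error(pickSoftThreshold(ones, powers = 1:2), "degenerate")
})

test_that("TOM matches its formula on hand-worked cases and a brute-force oracle", {
  # 3-gene fixture: a12 = a13 = 0.5, a23 = 0
  a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- 0.5; a[1, 3] <- a[3, 1] <- 0.5
  tom <- tomSimilarity(a)
  expect_equal(tom[1, 2], 0.5)
  expect_equal(tom[2, 3], 0.25 / 1.5)

  # complete graph with unit weights: maximal overlap everywhere
  k3 <- matrix(1, 3, 3)
  expect_true(all(tomSimilarity(k3) == 1))
  # empty graph
  z <- matrix(0, 4, 4)
  expect_true(all(tomSimilarity(z)[upper.tri(z)] == 0))

  # oracle equivalence and [0, 1] bounds on random adjacencies
  set.seed(8)
  for (i in 1:10) {
    r <- matrix(runif(100), 10, 10)
    r <- (r + t(r)) / 2; diag(r) <- 0
    tom <- tomSimilarity(r)
    expect_equal(unname(tom), tomOracle(r), tolerance = 1e-12)
    expect_true(all(tom >= -1e-15 & tom <= 1 + 1e-15))
  }
  expect_error(tomSimilarity(matrix(runif(9), 3, 3)), "symmetric")
})

test_that("module detection recovers planted blocks and applies the size rule", {
  blk <- matrix(0.1, 20, 20)
  blk[1:10, 1:10] <- 0.9; blk[11:20, 11:20] <- 0.9
  diag(blk) <- 1
  dimnames(blk) <- list(sprintf("g%02d", 1:20), sprintf("g%02d", 1:20))
  lab <- clusterModules(blk, minModuleSize = 3)
  expect_identical(length(unique(lab)), 2L)
  expect_identical(length(unique(lab[1:10])), 1L)
  expect_identical(length(unique(lab[11:20])), 1L)
  expect_true(all(lab[1:10] != lab[11:20]))

  # identical rows collapse into one module
  same <- matrix(1, 6, 6,
                 dimnames = list(paste0("g", 1:6), paste0("g", 1:6)))
  expect_identical(unname(unique(clusterModules(same))), "M1")

  # singleton outlier becomes unclassified at minModuleSize 2
  out <- matrix(0.05, 5, 5)
  out[1:4, 1:4] <- 0.9; diag(out) <- 1
  dimnames(out) <- list(paste0("g", 1:5), paste0("g", 1:5))
  lab2 <- clusterModules(out, minModuleSize = 2)
  expect_identical(unname(lab2[5]), "unclassified")
  expect_true(all(lab2[1:4] == "M1"))

  expect_warning(clusterModules(out[1, 1, drop = FALSE], minModuleSize = 2),
                 "unclassified")
})

test_that("eigengenes are unit-norm first PCs, sign-oriented, with coherent kME", {
  # rank-1 module: all genes equal to one vector v
  set.seed(3)
  v <- rnorm(8)
  m <- rbind(g1 = v, g2 = v, g3 = v)
  colnames(m) <- paste0("s", 1:8)
  asg <- setNames(rep("M1", 3), rownames(m))
  ms <- moduleEigengenes(m, asg)
  e <- eigengenes(ms)[, "M1"]
  vs <- (v - mean(v)) / sd(v); vs <- vs / sqrt(sum(vs^2))
  expect_equal(unname(e), unname(vs), tolerance = 1e-10)
  expect_equal(unname(kME(ms)[, "M1"]), rep(1, 3), tolerance = 1e-10)

  # mixed-sign members: orientation keeps mean kME non-negative
  m2 <- rbind(g1 = v, g2 = -v, g3 = v)
  colnames(m2) <- paste0("s", 1:8)
  ms2 <- moduleEigengenes(m2, asg)
  expect_equal(abs(unname(kME(ms2)[, "M1"])), rep(1, 3), tolerance = 1e-10)
  expect_gte(mean(kME(ms2)[, "M1"]), 0)

  # eigengene optimality: explains at least as much variance as any member
  set.seed(14)
  X <- matrix(rnorm(12 * 10), 12, 10,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:10)))
  asg3 <- setNames(rep("M1", 12), rownames(X))
  ms3 <- moduleEigengenes(X, asg3)
  Xs <- t(scale(t(X)))
  ev <- sum((Xs %*% eigengenes(ms3)[, 1])^2)
  for (g in seq_len(12)) {
    u <- Xs[g, ] / sqrt(sum(Xs[g, ]^2))
    expect_gte(ev + 1e-9, sum((Xs %*% u)^2))
  }

  # planted two-factor data: own-module kME dominates
  set.seed(31)
  f1 <- rnorm(20); f2 <- rnorm(20)
  Y <- rbind(matrix(rep(f1, 25), 25, byrow = TRUE),
             matrix(rep(f2, 25), 25, byrow = TRUE)) +
    matrix(rnorm(50 * 20, sd = 0.4), 50, 20)
  dimnames(Y) <- list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:20))
  asg4 <- setNames(rep(c("M1", "M2"), each = 25), rownames(Y))
  ms4 <- moduleEigengenes(Y, asg4)
  own <- ifelse(asg4 == "M1", kME(ms4)[, "M1"], kME(ms4)[, "M2"])
  other <- ifelse(asg4 == "M1", kME(ms4)[, "M2"], kME(ms4)[, "M1"])
  expect_gte(mean(own > other), 0.95)
})

test_that("module-phenotype testing is exact where enumeration is feasible", {
  E <- cbind(M1 = c(1, 2, 3, 4))
  rownames(E) <- paste0("s", 1:4)
  res <- modulePhenotypeTest(E, c("ruptured", "ruptured", "unruptured",
                                  "unruptured"))
  expect_equal(res$p_value, 1 / 3)
  expect_identical(res$direction, -1L)

  # identical groups: p = 1
  E2 <- cbind(M1 = c(5, 7, 5, 7))
  rownames(E2) <- paste0("s", 1:4)
  res2 <- modulePhenotypeTest(E2, c("ruptured", "ruptured", "unruptured",
                                    "unruptured"))
  expect_equal(res2$p_value, 1)

  # exact p agrees with full enumeration for all group sizes <= 6
  set.seed(77)
  for (nx in 2:6) for (ny in c(2L, 6L)) {
    x <- rnorm(nx); y <- rnorm(ny)
    E3 <- cbind(M1 = c(x, y))
    rownames(E3) <- paste0("s", seq_len(nx + ny))
    got <- modulePhenotypeTest(E3, rep(c("ruptured", "unruptured"),
                                       c(nx, ny)))$p_value
    expect_equal(got, mannWhitneyOracle(x, y), tolerance = 1e-12)
  }

  expect_error(modulePhenotypeTest(E, rep("ruptured", 4)), "non-empty")
})

test_that("a 2-sd phenotype shift on one module factor is detected with high power", {
  # 16 samples per phenotype group, the generator's default cohort split
  n <- 32L
  pheno <- rep(c("ruptured", "unruptured"), each = n / 2)
  hits <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    set.seed(1000 + r)
    f_sig <- rnorm(n) + 2 * (pheno == "ruptured")
    f_nul <- rnorm(n)
    E <- cbind(M1 = f_sig / sqrt(sum(f_sig^2)),
               M2 = f_nul / sqrt(sum(f_nul^2)))
    rownames(E) <- paste0("s", seq_len(n))
    res <- modulePhenotypeTest(E, pheno)
    hits <- hits + (res$p_value[res$module == "M1"] < 0.05)
  }
  expect_gte(hits / reps, 0.95)
})
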