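#' Absolute Pearson correlation matrix between genes
#'
#' The similarity underlying the unsigned weighted co-expression network:
#' `|cor(g_i, g_j)|` across samples, unit diagonal.
#'
#' @param m expression matrix (genes x samples, >= 3 samples).
#' @return symmetric gene x gene matrix with entries in \[0, 1\].
#' @export
correlationMatrix <- function(m) {
  .validateExpressionMatrix(m)
  if (ncol(m) < 3L) stop("need at least 3 samples")
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s): ",
         paste(rownames(m)[utils::head(which(sds == 0), 5L)], collapse = ", "))
  r <- abs(stats::cor(t(m)))
  diag(r) <- 1
  r
}

#' Choose a soft-threshold power approximating scale-free topology
#'
#' For each candidate power, the correlation matrix is raised elementwise
#' to that power (adjacency), connectivities `k_i = sum_j a_ij` are binned
#' on a log10 scale, and `log10(frequency)` is regressed on `log10(mean k)`
#' per bin. The signed fit index is `R^2 x sign(-slope)`, so only a
#' decreasing degree distribution counts as scale-free. The chosen power is
#' the smallest whose signed R^2 reaches `targetR2`, else the argmax
#' (ties broken toward the smaller power).
#'
#' @param corMat absolute correlation matrix from [correlationMatrix()].
#' @param powers increasing candidate powers (default `c(1:10, seq(12, 20, 2))`).
#' @param targetR2 signed R^2 to aim for (default 0.8).
#' @param nBins number of logarithmic connectivity bins (default 10; empty
#'   bins are dropped).
#' @return list with `power` (chosen) and `fitTable` (data.frame of
#'   `power`, `signed_r2`, `slope`, `mean_k`).
#' @export
pickSoftThreshold <- function(corMat, powers = c(1:10, seq(12L, 20L, 2L)),
                              targetR2 = 0.8, nBins = 10L) {
  stopifnot(is.matrix(corMat), nrow(corMat) == ncol(corMat))
  if (is.unsorted(powers, strictly = TRUE) || any(powers <= 0))
    stop("candidate powers must be positive and increasing")
  fit <- data.frame(power = powers, signed_r2 = NA_real_,
                    slope = NA_real_, mean_k = NA_real_)
  for (i in seq_along(powers)) {
    a <- corMat^powers[i]
    diag(a) <- 0
    k <- rowSums(a)
    if (max(k) - min(k) < .Machine$double.eps * length(k))
      stop("degenerate degree distribution: all connectivities identical")
    sf <- .scaleFreeFit(k, nBins)
    fit$signed_r2[i] <- sf$signed_r2
    fit$slope[i] <- sf$slope
    fit$mean_k[i] <- mean(k)
  }
  ok <- which(!is.na(fit$signed_r2) & fit$signed_r2 >= targetR2)
  power <- if (length(ok)) powers[ok[1L]] else
    powers[which.max(replace(fit$signed_r2, is.na(fit$signed_r2), -Inf))]
  list(power = as.integer(power), fitTable = fit)
}

# log-log regression of binned degree frequency; empty bins dropped
.scaleFreeFit <- function(k, nBins) {
  k <- k[k > 0]
  lk <- log10(k)
  breaks <- seq(min(lk), max(lk), length.out = nBins + 1L)
  bin <- cut(lk, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(lk, bin, length)
  meank <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3L) return(list(signed_r2 = NA_real_, slope = NA_real_))
  x <- log10(meank[keep]); y <- log10(freq[keep])
  f <- stats::lm(y ~ x)
  r2 <- summary(f)$r.squared
  slope <- stats::coef(f)[[2L]]
  list(signed_r2 = r2 * sign(-slope), slope = slope)
}

#' Topological overlap similarity
#'
#' Converts an adjacency matrix into the topological overlap matrix:
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `L_ij = sum_u a_iu a_uj` over `u != i, j` and `k_i = sum_u a_iu`, so two
#' genes are similar when they share network neighbours, not merely when
#' they correlate directly. Diagonal set to 1.
#'
#' @param adjacency symmetric matrix with entries in \[0, 1\]; the diagonal
#'   is ignored (treated as 0 for connectivity).
#' @return symmetric TOM matrix with entries in \[0, 1\], unit diagonal.
#' @export
tomSimilarity <- function(adjacency) {
  stopifnot(is.matrix(adjacency))
  if (nrow(adjacency) != ncol(adjacency) ||
      !isTRUE(all.equal(adjacency, t(adjacency), tolerance = 1e-10)))
    stop("adjacency must be symmetric")
  if (any(adjacency < 0 | adjacency > 1))
    stop("adjacency entries must lie in [0, 1]")
  a <- adjacency
  diag(a) <- 0
  L <- a %*% a                 # diag(a)=0 makes u=i and u=j terms vanish
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the dissimilarity `1 - TOM`,
#' cut statically at `cutHeightFraction` of the maximum merge height.
#' Clusters smaller than `minModuleSize` are relabelled `"unclassified"`;
#' surviving modules are named `"M1"`, `"M2"`, ... by decreasing size (ties
#' broken by first gene position).
#'
#' @param tom TOM matrix from [tomSimilarity()].
#' @param minModuleSize smallest allowed module (default 2).
#' @param cutHeightFraction static cut height as a fraction of the tallest
#'   merge (default 0.9).
#' @return named character vector, gene -> module label.
#' @export
clusterModules <- function(tom, minModuleSize = 2L, cutHeightFraction = 0.9) {
  stopifnot(is.matrix(tom), nrow(tom) == ncol(tom))
  genes <- rownames(tom)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(tom)))
  if (nrow(tom) < minModuleSize) {
    warning("fewer genes than minModuleSize: all genes unclassified")
    return(stats::setNames(rep("unclassified", nrow(tom)), genes))
  }
  tree <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  h <- cutHeightFraction * max(tree$height)
  cl <- stats::cutree(tree, h = h)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= minModuleSize]
  lab <- rep("unclassified", length(cl))
  if (length(keep)) {
    first_pos <- vapply(keep, function(k) which(cl == k)[1L], integer(1))
    ord <- keep[order(-sizes[keep], first_pos)]
    for (i in seq_along(ord))
      lab[cl == ord[i]] <- paste0("M", i)
  }
  stats::setNames(lab, genes)
}

#' Module eigengenes and module membership (kME)
#'
#' The eigengene of a module is the first right singular vector (over
#' samples) of the gene-standardized module submatrix — the first principal
#' component of the module's expression — normalised to unit Euclidean norm
#' and sign-oriented so the mean correlation with the module's own genes is
#' non-negative. kME is the Pearson correlation of every gene (classified
#' or not) with every eigengene.
#'
#' @param m expression matrix (genes x samples, >= 3 samples).
#' @param assignment named gene -> module vector as from [clusterModules()].
#' @param powerUsed optional integer recorded in the result.
#' @param fitTable optional scale-free fit table recorded in the result.
#' @return a [ModuleSet-class].
#' @export
moduleEigengenes <- function(m, assignment, powerUsed = NA_integer_,
                             fitTable = data.frame()) {
  .validateExpressionMatrix(m)
  if (ncol(m) < 3L) stop("need at least 3 samples")
  if (is.null(names(assignment)) || !all(names(assignment) %in% rownames(m)))
    stop("assignment must be named by genes present in the matrix")
  mods <- setdiff(unique(assignment), "unclassified")
  sizes <- table(assignment)
  if (any(sizes[mods] < 2L))
    stop("module(s) with a single gene: ",
         paste(mods[sizes[mods] < 2L], collapse = ", "))
  num <- suppressWarnings(as.integer(sub("^M", "", mods)))
  mods <- mods[order(num, mods, na.last = TRUE)]
  E <- matrix(NA_real_, ncol(m), length(mods),
              dimnames = list(colnames(m), mods))
  for (mod in mods) {
    g <- names(assignment)[assignment == mod]
    X <- m[g, , drop = FALSE]
    Xs <- (X - rowMeans(X)) / apply(X, 1L, stats::sd)
    if (anyNA(Xs)) stop("zero-variance gene in module ", mod)
    v1 <- svd(Xs, nu = 0L, nv = 1L)$v[, 1L]
    if (mean(stats::cor(t(X), v1)) < 0) v1 <- -v1
    E[, mod] <- v1 / sqrt(sum(v1^2))
  }
  kme <- stats::cor(t(m), E)
  methods::new("ModuleSet", assignment = assignment, eigengenes = E,
               kme = kme, powerUsed = as.integer(powerUsed),
               fitTable = fitTable)
}

#' Full network construction in one call
#'
#' Correlation -> soft threshold -> TOM -> clustering -> eigengenes/kME.
#'
#' @inheritParams correlationMatrix
#' @inheritParams pickSoftThreshold
#' @inheritParams clusterModules
#' @return a [ModuleSet-class].
#' @export
buildCoexpressionNetwork <- function(m, powers = c(1:10, seq(12L, 20L, 2L)),
                                     targetR2 = 0.8, nBins = 10L,
                                     minModuleSize = 2L,
                                     cutHeightFraction = 0.9) {
  corMat <- correlationMatrix(m)
  st <- pickSoftThreshold(corMat, powers, targetR2, nBins)
  adj <- corMat^st$power
  tom <- tomSimilarity(adj)
  assignment <- clusterModules(tom, minModuleSize, cutHeightFraction)
  moduleEigengenes(m, assignment, powerUsed = st$power,
                   fitTable = st$fitTable)
}

#' Test module eigengenes for association with rupture phenotype
#'
#' Two-sided Mann-Whitney U test of each module's eigengene between the
#' phenotype groups: exact distribution when both groups have <= 8 samples
#' and no ties, normal approximation with tie correction otherwise. The
#' direction sign is +1 when the median eigengene is higher in the first
#' (case) group. Benjamini-Hochberg q-values are reported alongside the raw
#' p-values for transparency, but significance calls use the uncorrected
#' p < alpha convention.
#'
#' @param moduleSet a [ModuleSet-class] (or a samples x modules eigengene
#'   matrix).
#' @param phenotype per-sample labels, same order as the eigengene rows.
#' @param case label treated as the case group (default `"ruptured"`).
#' @param alpha significance level for the `significant` flag (default 0.05).
#' @return data.frame with columns `module`, `u_statistic`, `p_value`,
#'   `q_value`, `direction`, `significant`.
#' @export
modulePhenotypeTest <- function(moduleSet, phenotype, case = "ruptured",
                                alpha = 0.05) {
  E <- if (methods::is(moduleSet, "ModuleSet")) eigengenes(moduleSet)
       else as.matrix(moduleSet)
  phenotype <- as.character(phenotype)
  if (length(phenotype) != nrow(E))
    stop("one phenotype label per sample required")
  grp1 <- phenotype == case
  if (!any(grp1) || all(grp1)) stop("both phenotype groups must be non-empty")
  if (!ncol(E))
    return(data.frame(module = character(), u_statistic = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      direction = integer(), significant = logical()))
  res <- lapply(colnames(E), function(mod) {
    x <- E[grp1, mod]; y <- E[!grp1, mod]
    ties <- anyDuplicated(c(x, y)) > 0L
    exact <- length(x) <= 8L && length(y) <= 8L && !ties
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                         correct = !exact))
    dmed <- stats::median(x) - stats::median(y)
    data.frame(module = mod, u_statistic = unname(wt$statistic),
               p_value = wt$p.value,
               direction = if (dmed > 0) 1L else if (dmed < 0) -1L else 0L)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  out[order(out$p_value, out$module), c("module", "u_statistic", "p_value",
                                        "q_value", "direction",
                                        "significant")]
}
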