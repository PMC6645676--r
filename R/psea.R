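#' Marker-derived reference signal for one cell population
#'
#' Each marker gene's expression row is divided by its own mean (so every
#' marker contributes on a comparable scale) and the normalized rows are
#' averaged; the resulting per-sample vector has mean 1 and tracks the
#' relative abundance of the cell population across samples. Markers
#' absent from the matrix are dropped with a message; at least one must
#' remain. Requires a positive-scale matrix (marker means must be > 0) —
#' use the quantile-normalized matrix *before* global z-scaling.
#'
#' @param m expression matrix (genes x samples).
#' @param markers character vector of marker gene identifiers.
#' @return named numeric vector over samples, mean 1.
#' @export
referenceSignal <- function(m, markers) {
  .validateExpressionMatrix(m)
  present <- intersect(markers, rownames(m))
  dropped <- setdiff(markers, present)
  if (length(dropped))
    message("marker(s) not in matrix, dropped: ",
            paste(dropped, collapse = ", "))
  if (!length(present)) stop("no marker genes present in the matrix")
  X <- m[present, , drop = FALSE]
  mu <- rowMeans(X)
  if (any(mu <= 0))
    stop("marker(s) with non-positive mean expression: ",
         paste(present[mu <= 0], collapse = ", "),
         " (use the pre-scaling expression checkpoint)")
  colMeans(X / mu)
}

#' Regress one gene on a reference signal and apply the acceptance filter
#'
#' Ordinary least squares `y = alpha + beta * ref`; a gene is attributed to
#' the cell population when all four criteria hold: positive slope,
#' two-sided slope p-value < 0.05, adjusted R^2 > 0.6, and
#' `|intercept| / |mean(y)| < 0.5` (genes whose expression is mostly
#' proportional to population abundance, with little abundance-independent
#' baseline). A zero mean makes the ratio infinite and fails the criterion.
#'
#' @param y numeric expression vector for one gene (>= 4 samples).
#' @param ref non-constant reference from [referenceSignal()].
#' @return one-row data.frame: `slope`, `intercept`, `p_slope`, `adj_r2`,
#'   `intercept_mean_ratio`, `passes`.
#' @export
fitGene <- function(y, ref) {
  if (length(y) != length(ref)) stop("y and ref lengths differ")
  n <- length(y)
  if (n < 4L) stop("need at least 4 samples")
  if (stats::sd(ref) == 0) stop("constant reference signal")
  fits <- .pseaFitMatrix(matrix(y, nrow = 1L), ref)
  fits
}

# Vectorized simple-regression engine: Y is genes x samples.
.pseaFitMatrix <- function(Y, ref) {
  n <- ncol(Y)
  rc <- ref - mean(ref)
  Sxx <- sum(rc^2)
  ym <- rowMeans(Y)
  Sxy <- as.vector((Y - ym) %*% rc)
  beta <- Sxy / Sxx
  alpha <- ym - beta * mean(ref)
  fittedv <- alpha + outer(beta, ref)
  rss <- rowSums((Y - fittedv)^2)
  tss <- rowSums((Y - ym)^2)
  r2 <- ifelse(tss > 0, 1 - rss / tss, 0)
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - 2)
  se <- sqrt(pmax(rss, 0) / (n - 2) / Sxx)
  tstat <- ifelse(se > 0, beta / se, sign(beta) * Inf)
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p <- pmax(p, .Machine$double.xmin)        # keep p in (0, 1]
  ratio <- ifelse(ym == 0, Inf, abs(alpha) / abs(ym))
  passes <- beta > 0 & p < 0.05 & adj_r2 > 0.6 & ratio < 0.5
  data.frame(slope = beta, intercept = alpha, p_slope = p, adj_r2 = adj_r2,
             intercept_mean_ratio = ratio, passes = passes,
             row.names = rownames(Y))
}

#' Cell-population-specific genes for one cell type and sample subset
#'
#' Builds the reference signal from the panel's markers on the given
#' sample subset, regresses every non-marker gene on it with
#' [fitGene()]'s criteria, and returns the passing fits sorted by adjusted
#' R^2 (descending). The cell type's own marker genes are excluded as
#' candidates.
#'
#' @param m expression matrix (positive scale; pre-z-scaling checkpoint).
#' @param markers marker genes for the cell type.
#' @param sampleIds samples to fit on (>= 4), e.g. one phenotype's samples.
#' @param allPassing if `TRUE` return every fit, not only the passing ones.
#' @return data.frame of fits with a leading `gene` column.
#' @export
cellSpecificGenes <- function(m, markers, sampleIds = colnames(m),
                              allPassing = FALSE) {
  .validateExpressionMatrix(m)
  sampleIds <- as.character(sampleIds)
  if (!all(sampleIds %in% colnames(m)))
    stop("unknown sample(s): ",
         paste(setdiff(sampleIds, colnames(m)), collapse = ", "))
  if (length(sampleIds) < 4L)
    stop("need at least 4 samples in the subset")
  sub <- m[, sampleIds, drop = FALSE]
  ref <- referenceSignal(sub, markers)
  cand <- setdiff(rownames(sub), markers)
  fits <- .pseaFitMatrix(sub[cand, , drop = FALSE], ref)
  fits <- cbind(gene = cand, fits)
  rownames(fits) <- NULL
  if (!allPassing) fits <- fits[fits$passes, , drop = FALSE]
  fits[order(-fits$adj_r2, fits$gene), , drop = FALSE]
}

#' Population-specific expression analysis across cell types and phenotypes
#'
#' Runs one regression model per (cell type, phenotype) combination — ten
#' models for the default five-cell-type panel and two phenotypes — each on
#' that phenotype's samples only.
#'
#' @param m expression matrix (positive scale; pre-z-scaling checkpoint).
#' @param panel named list cell type -> markers (see [readMarkerPanel()]).
#' @param sampleTable data.frame with `sample_id` and `phenotype` columns.
#' @return data.frame of passing fits with `cell_type` and `phenotype`
#'   columns prepended.
#' @export
pseaAnalysis <- function(m, panel, sampleTable) {
  stopifnot(is.list(panel), length(panel) >= 1L)
  phenos <- unique(sampleTable$phenotype)
  out <- list()
  for (ct in names(panel)) {
    for (ph in phenos) {
      ids <- intersect(sampleTable$sample_id[sampleTable$phenotype == ph],
                       colnames(m))
      fits <- cellSpecificGenes(m, panel[[ct]], ids)
      if (nrow(fits))
        out[[paste(ct, ph)]] <- cbind(cell_type = ct, phenotype = ph, fits)
    }
  }
  if (!length(out))
    return(data.frame(cell_type = character(), phenotype = character(),
                      gene = character(), slope = numeric(),
                      intercept = numeric(), p_slope = numeric(),
                      adj_r2 = numeric(), intercept_mean_ratio = numeric(),
                      passes = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
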