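#' Fit a parametric empirical-Bayes batch-effect model
#'
#' Location/scale batch model for merged microarray series: each gene is
#' standardized by its grand mean and pooled variance, per-batch per-gene
#' additive (gamma) and multiplicative (delta^2) effects are estimated, and
#' both are shrunk toward batch-level priors (normal for gamma,
#' inverse-gamma for delta^2, hyperparameters by moment matching) via the
#' usual conditional-posterior fixed-point iteration.
#'
#' No covariates are protected during correction; when a phenotype vector
#' is supplied, a significant phenotype/batch association (Fisher's exact
#' test, p < 0.05) is flagged with a warning because phenotype signal is
#' then partially absorbable by the correction.
#'
#' @param m expression matrix (genes x samples).
#' @param batch character/factor of batch labels, one per column of `m`
#'   (or a data.frame with `sample_id` and `series` columns as returned by
#'   [readSampleTable()]).
#' @param phenotype optional per-sample phenotype labels for the
#'   confounding check.
#' @param tol convergence tolerance on the maximum absolute change of the
#'   EB estimates (default 1e-4).
#' @param maxIter iteration cap (default 500).
#' @return a [BatchModel-class] object.
#' @seealso [adjustBatches()]
#' @export
fitBatchModel <- function(m, batch, phenotype = NULL, tol = 1e-4,
                          maxIter = 500L) {
  .validateExpressionMatrix(m)
  if (is.data.frame(batch)) {
    st <- batch
    if (!all(colnames(m) %in% st$sample_id))
      stop("sample(s) missing from the sample table: ",
           paste(setdiff(colnames(m), st$sample_id), collapse = ", "))
    idx <- match(colnames(m), st$sample_id)
    if (is.null(phenotype) && "phenotype" %in% colnames(st))
      phenotype <- st$phenotype[idx]
    batch <- st$series[idx]
  }
  batch <- as.character(batch)
  if (length(batch) != ncol(m))
    stop("one batch label per sample required")
  if (anyNA(batch) || any(batch == ""))
    stop("every sample must be assigned a batch")
  levs <- unique(batch)
  n_i <- table(factor(batch, levels = levs))
  if (length(levs) >= 2L && any(n_i < 2L))
    stop("batch(es) with fewer than 2 samples: ",
         paste(names(n_i)[n_i < 2L], collapse = ", "))
  if (!is.null(phenotype) && length(levs) >= 2L) {
    ft <- stats::fisher.test(table(batch, as.character(phenotype)))
    if (ft$p.value < 0.05)
      warning(sprintf(paste0("phenotype is associated with batch (Fisher ",
                             "p = %.3g); phenotype signal may be partially ",
                             "removed by the correction"), ft$p.value))
  }

  G <- nrow(m); N <- ncol(m)
  design <- vapply(levs, function(b) as.numeric(batch == b), numeric(N))
  # per-batch per-gene means, grand mean weighted by batch size
  batch_means <- m %*% design %*% diag(1 / as.vector(n_i),
                                       length(levs), length(levs))
  colnames(batch_means) <- levs
  grand_mean <- as.vector(batch_means %*% (as.vector(n_i) / N))
  fitted <- batch_means %*% t(design)
  pooled_var <- rowSums((m - fitted)^2) / N
  zv <- which(pooled_var <= 0)
  if (length(zv))
    stop("zero-variance gene(s): ",
         paste(rownames(m)[utils::head(zv, 5L)], collapse = ", "))

  Z <- (m - grand_mean) / sqrt(pooled_var)   # standardized data

  gamma_star <- matrix(0, length(levs), G, dimnames = list(levs, rownames(m)))
  delta2_star <- matrix(1, length(levs), G, dimnames = list(levs, rownames(m)))
  priors <- data.frame(batch = levs, gamma_bar = NA_real_, t2 = NA_real_,
                       a_prior = NA_real_, b_prior = NA_real_)
  iters <- integer(length(levs))

  if (length(levs) >= 2L) {
    for (b in seq_along(levs)) {
      zb <- Z[, batch == levs[b], drop = FALSE]
      nb <- ncol(zb)
      g_hat <- rowMeans(zb)
      d_hat <- apply(zb, 1L, stats::var)
      gamma_bar <- mean(g_hat); t2 <- stats::var(g_hat)
      md <- mean(d_hat); s2d <- stats::var(d_hat)
      a_prior <- (2 * s2d + md^2) / s2d
      b_prior <- (md * s2d + md^3) / s2d
      g_old <- g_hat; d_old <- d_hat
      it <- 0L
      repeat {
        it <- it + 1L
        g_new <- (t2 * nb * g_hat + d_old * gamma_bar) / (t2 * nb + d_old)
        sum2 <- rowSums((zb - g_new)^2)
        d_new <- (0.5 * sum2 + b_prior) / (nb / 2 + a_prior - 1)
        change <- max(abs(g_new - g_old), abs(d_new - d_old))
        g_old <- g_new; d_old <- d_new
        if (change < tol || it >= maxIter) break
      }
      gamma_star[b, ] <- g_old
      delta2_star[b, ] <- pmax(d_old, .Machine$double.eps)
      priors[b, -1L] <- c(gamma_bar, t2, a_prior, b_prior)
      iters[b] <- it
    }
  }

  methods::new("BatchModel",
    genes = rownames(m), samples = colnames(m),
    batch = stats::setNames(batch, colnames(m)),
    grandMean = stats::setNames(grand_mean, rownames(m)),
    pooledVar = stats::setNames(pooled_var, rownames(m)),
    gammaStar = gamma_star, delta2Star = delta2_star,
    priors = priors, iterations = iters)
}

#' Apply a fitted batch model to an expression matrix
#'
#' Returns `((z - gamma*)/delta*) * sigma_g + alpha_g` gene-wise, where `z`
#' is the model-standardized value — the empirical-Bayes adjusted matrix.
#' With a single batch the transformation is the identity (a message is
#' emitted and the input returned unchanged).
#'
#' @param m expression matrix over the same gene/sample universe the model
#'   was fitted on.
#' @param model a [BatchModel-class].
#' @return adjusted matrix, same shape and dimnames as `m`.
#' @export
adjustBatches <- function(m, model) {
  .validateExpressionMatrix(m)
  stopifnot(methods::is(model, "BatchModel"))
  if (!identical(rownames(m), model@genes))
    stop("gene universe differs from the fitted model")
  missing_s <- setdiff(colnames(m), model@samples)
  if (length(missing_s))
    stop("sample(s) absent from the fitted model: ",
         paste(missing_s, collapse = ", "))
  if (nrow(model@gammaStar) < 2L) {
    message("single batch: no correction applied")
    return(m)
  }
  batch <- model@batch[colnames(m)]
  Z <- (m - model@grandMean) / sqrt(model@pooledVar)
  out <- m
  for (b in rownames(model@gammaStar)) {
    sel <- which(batch == b)
    if (!length(sel)) next
    zb <- (Z[, sel, drop = FALSE] - model@gammaStar[b, ]) /
      sqrt(model@delta2Star[b, ])
    out[, sel] <- zb * sqrt(model@pooledVar) + model@grandMean
  }
  out
}

#' One-call batch correction
#'
#' Convenience wrapper: [fitBatchModel()] then [adjustBatches()].
#'
#' @inheritParams fitBatchModel
#' @export
batchCorrect <- function(m, batch, phenotype = NULL, tol = 1e-4,
                         maxIter = 500L) {
  adjustBatches(m, fitBatchModel(m, batch, phenotype, tol, maxIter))
}
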