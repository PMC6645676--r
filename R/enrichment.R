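#' Hypergeometric gene-set over-representation test
#'
#' For each gene set, the raw p-value is the upper hypergeometric tail
#' `P(X >= overlap)` for drawing `|query|` genes from a universe containing
#' `|set|` annotated genes. Sets are intersected with the universe first;
#' sets with fewer than 2 universe members are skipped and excluded from
#' the Bonferroni multiplier (which equals the number of sets actually
#' tested). This is a plain hypergeometric tail — not the EASE-modified
#' variant some annotation services use.
#'
#' @param queryGenes character vector, a subset of `universe`.
#' @param geneSets named list of character vectors (e.g. from [readGMT()]).
#' @param universe character vector of background genes (typically all
#'   genes on the merged matrix).
#' @param alpha significance level applied to the Bonferroni-corrected
#'   p-value (default 0.05).
#' @return data.frame sorted by raw p-value (ties by set id) with columns
#'   `set_id`, `overlap`, `set_size`, `query_size`, `universe_size`,
#'   `p_raw`, `p_bonferroni`, `significant`.
#' @export
hypergeometricEnrichment <- function(queryGenes, geneSets, universe,
                                     alpha = 0.05) {
  universe <- unique(universe)
  queryGenes <- unique(queryGenes)
  if (!length(universe)) stop("empty universe")
  if (!length(queryGenes)) stop("empty query")
  if (!all(queryGenes %in% universe))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(setdiff(queryGenes, universe), 5L), collapse = ", "))
  if (is.null(names(geneSets))) stop("gene sets must be named")
  N <- length(universe)
  n <- length(queryGenes)
  sets <- lapply(geneSets, function(s) intersect(unique(s), universe))
  sets <- sets[lengths(sets) >= 2L]
  if (!length(sets)) stop("no gene set has >= 2 members in the universe")
  m_tests <- length(sets)
  rows <- lapply(names(sets), function(id) {
    K <- length(sets[[id]])
    ov <- length(intersect(sets[[id]], queryGenes))
    p <- stats::phyper(ov - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, overlap = ov, set_size = K, query_size = n,
               universe_size = N, p_raw = p,
               p_bonferroni = min(1, p * m_tests))
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_bonferroni < alpha
  out <- out[order(out$p_raw, out$set_id), ]
  rownames(out) <- NULL
  out
}
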