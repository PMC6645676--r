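#' Read a gene x sample expression matrix from tab-delimited text
#'
#' The first column holds gene identifiers, the header row sample
#' identifiers. Gene identifiers are whitespace-trimmed and matched
#' case-sensitively. Duplicated gene rows are collapsed by their mean (a
#' message reports how many). Blank or non-numeric cells and duplicate
#' sample identifiers are load errors naming the offending row/column.
#'
#' @param path path to a tab-delimited file.
#' @return numeric matrix with gene rownames and sample colnames.
#' @seealso [writeExpressionMatrix()]
#' @export
readExpressionMatrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 2L || nrow(raw) < 1L)
    stop("empty or malformed expression matrix: ", path)
  samples <- trimws(colnames(raw)[-1L])
  if (any(samples == "")) stop("malformed header: blank sample identifier")
  if (anyDuplicated(samples))
    stop("duplicate sample identifiers: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  genes <- trimws(raw[[1L]])
  if (any(genes == "")) stop("blank gene identifier at row ",
                             which(genes == "")[1L])
  vals <- matrix(NA_real_, nrow(raw), length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    col <- trimws(raw[[j + 1L]])
    bad <- which(col == "" | is.na(col))
    if (length(bad))
      stop("missing value at gene '", genes[bad[1L]], "', sample '",
           samples[j], "'")
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad))
      stop("non-numeric value '", col[bad[1L]], "' at gene '",
           genes[bad[1L]], "', sample '", samples[j], "'")
    vals[, j] <- num
  }
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    vals <- rowsum(vals, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(genes)
    message("collapsed ", n_dup, " duplicated gene row(s) by mean")
  }
  rownames(vals) <- genes
  .validateExpressionMatrix(vals)
  vals
}

#' Write an expression matrix as tab-delimited text
#'
#' Inverse of [readExpressionMatrix()]; round-trips exactly (values written
#' with full double precision).
#'
#' @param m numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param idColumn header of the gene-identifier column.
#' @export
writeExpressionMatrix <- function(m, path, idColumn = "gene_id") {
  .validateExpressionMatrix(m)
  df <- data.frame(rownames(m),
                   apply(m, 2L, sprintf, fmt = "%.17g"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(idColumn, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.validateExpressionMatrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression data must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample identifiers")
  if (anyNA(m)) stop("expression matrix contains missing values")
  invisible(TRUE)
}

#' Read per-sample metadata
#'
#' Tab-delimited with required columns `sample_id`, `series` and
#' `phenotype` (values `ruptured` / `unruptured`); any further columns
#' (e.g. aneurysm location, time to surgery) are carried along.
#'
#' @param path path to a tab-delimited file.
#' @return data.frame keyed by unique `sample_id`.
#' @export
readSampleTable <- function(path) {
  st <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "series", "phenotype")
  miss <- setdiff(need, colnames(st))
  if (length(miss))
    stop("sample table missing column(s): ", paste(miss, collapse = ", "))
  st$sample_id <- trimws(st$sample_id)
  if (anyDuplicated(st$sample_id)) stop("duplicate sample_id values")
  if (any(is.na(st$series) | st$series == ""))
    stop("every sample needs a series (batch) label")
  if (!all(st$phenotype %in% c("ruptured", "unruptured")))
    stop("phenotype must be 'ruptured' or 'unruptured'")
  st
}

#' Read gene sets in GMT format
#'
#' One set per line: identifier, description, then tab-separated member
#' genes. Returns a named list of character vectors with per-set
#' descriptions in `attr(, "descriptions")` — the shape `fgsea` and friends
#' expect.
#'
#' @param path path to a GMT file.
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1L], " has no member genes")
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate gene-set identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(trimws(p[-c(1L, 2L)])))
  names(sets) <- ids
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, character(1), 2L), ids)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors (optionally with a
#'   `descriptions` attribute as produced by [readGMT()]).
#' @param path output path.
#' @export
writeGMT <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(id)
    paste(c(id, desc[[id]], sets[[id]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a marker-gene panel
#'
#' Two-column tab-delimited file (`cell_type`, `gene`). The default panel
#' shipped with the package lists literature-derived markers for smooth
#' muscle, endothelial cells, macrophages, mast cells and T cells.
#'
#' @param path path to the panel file; defaults to the built-in panel.
#' @return named list, cell type -> character vector of marker genes.
#' @export
readMarkerPanel <- function(path = system.file("extdata", "marker_panel.tsv",
                                               package = "ruptureNet")) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("cell_type", "gene") %in% colnames(df)))
    stop("marker panel needs columns cell_type, gene")
  panel <- lapply(split(trimws(df$gene), df$cell_type), unique)
  if (any(lengths(panel) == 0L)) stop("empty marker set in panel")
  panel
}

#' Merge expression matrices on their common genes
#'
#' Keeps only genes present in every input (the merge used when combining
#' independent microarray series), unions the samples, and orders genes
#' lexicographically (C locale) for determinism.
#'
#' @param matrices list of >= 2 expression matrices with pairwise-disjoint
#'   sample identifiers.
#' @return merged numeric matrix.
#' @export
mergeOnCommonGenes <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2L)
    stop("need at least two matrices to merge")
  lapply(matrices, .validateExpressionMatrix)
  all_samples <- unlist(lapply(matrices, colnames))
  if (anyDuplicated(all_samples))
    stop("sample identifiers overlap between matrices: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (!length(common)) stop("no genes common to all matrices")
  common <- sort(common, method = "radix")
  do.call(cbind, lapply(matrices, function(m) m[common, , drop = FALSE]))
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the vector of row-means of the column-sorted matrix. Ties within a
#' column receive the mean of the reference quantiles they span. Delegates
#' to `limma::normalizeQuantiles(ties = TRUE)`.
#'
#' @param m expression matrix (genes x samples).
#' @export
quantileNormalize <- function(m) {
  .validateExpressionMatrix(m)
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Log2-transform an expression matrix
#'
#' @param m expression matrix.
#' @param epsilon non-negative shift added before taking logs (default 0);
#'   any non-positive shifted value is an error.
#' @export
log2Transform <- function(m, epsilon = 0) {
  .validateExpressionMatrix(m)
  if (any(m + epsilon <= 0)) {
    idx <- which(m + epsilon <= 0, arr.ind = TRUE)[1L, ]
    stop("non-positive value after shift at gene '", rownames(m)[idx[1L]],
         "', sample '", colnames(m)[idx[2L]], "'")
  }
  log2(m + epsilon)
}

#' Scale a matrix to global mean 0 and standard deviation 1
#'
#' A single location/scale transform applied to the flattened matrix (not
#' per gene or per sample), so relative differences between genes are
#' preserved. The population convention (divide by N) is the default.
#'
#' @param m expression matrix with at least two distinct values.
#' @param sdType `"population"` (divide by N, default) or `"sample"`.
#' @export
globalScale <- function(m, sdType = c("population", "sample")) {
  .validateExpressionMatrix(m)
  sdType <- match.arg(sdType)
  mu <- mean(m)
  s <- if (sdType == "population") sqrt(mean((m - mu)^2)) else stats::sd(m)
  if (s == 0) stop("constant matrix cannot be scaled")
  (m - mu) / s
}

#' Summarize a multi-series cohort from per-series rows
#'
#' Input is one row per series with columns `series`, `patients`,
#' `ruptured`, `mean_tts`, `sd_tts` and one count column per aneurysm
#' location (e.g. `MCA`, `ICA`, `AComm`, `PComm`, `PC`). Totals are sums
#' across series; mean time-to-surgery is the ruptured-patient-weighted
#' mean of per-series means and its SD the correspondingly pooled standard
#' deviation.
#'
#' @param seriesTable data.frame of per-series summary rows.
#' @return list of class `CohortSummary` with elements `n_patients`,
#'   `n_ruptured`, `location_counts`, `mean_tts`, `sd_tts`.
#' @export
summarizeCohort <- function(seriesTable) {
  need <- c("series", "patients", "ruptured", "mean_tts", "sd_tts")
  miss <- setdiff(need, colnames(seriesTable))
  if (length(miss))
    stop("series table missing column(s): ", paste(miss, collapse = ", "))
  loc_cols <- setdiff(colnames(seriesTable), need)
  cnt <- as.matrix(seriesTable[, c("patients", "ruptured", loc_cols),
                               drop = FALSE])
  if (any(cnt < 0)) stop("negative counts in series table")
  if (any(seriesTable$ruptured > seriesTable$patients))
    stop("ruptured count exceeds patient count")
  w <- seriesTable$ruptured
  mean_tts <- sum(w * seriesTable$mean_tts) / sum(w)
  # pooled SD across series around the pooled mean
  ss <- sum((w - 1) * seriesTable$sd_tts^2 +
              w * (seriesTable$mean_tts - mean_tts)^2)
  sd_tts <- sqrt(ss / (sum(w) - 1))
  lc <- colSums(seriesTable[, loc_cols, drop = FALSE])
  if (all(lc == round(lc))) storage.mode(lc) <- "integer"
  out <- list(
    n_patients = as.integer(sum(seriesTable$patients)),
    n_ruptured = as.integer(sum(seriesTable$ruptured)),
    location_counts = lc,
    mean_tts = mean_tts,
    sd_tts = sd_tts
  )
  class(out) <- "CohortSummary"
  out
}

#' @export
print.CohortSummary <- function(x, ...) {
  cat("Cohort summary:", x$n_patients, "patients,",
      x$n_ruptured, "ruptured\n")
  cat("  mean time-to-surgery (ruptured):",
      sprintf("%.1f (SD %.1f) days\n", x$mean_tts, x$sd_tts))
  cat("  locations:", paste(names(x$location_counts),
                            x$location_counts, sep = "=", collapse = " "), "\n")
  invisible(x)
}
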