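#' Assemble a pipeline configuration
#'
#' Collects input paths and stage parameters for [runPipeline()]. Either
#' point the path fields at an existing fixture/data directory (the layout
#' [simulateAll()] writes) via `inputDir`, or set each path explicitly.
#'
#' @param inputDir directory holding `expression_<series>.tsv` files,
#'   `sample_table.tsv`, `marker_panel.tsv`, `ontology.obo`,
#'   `annotations.gmt` and `drug_library.tsv`; individual path arguments
#'   override the derived defaults.
#' @param expressionPaths character vector of per-series expression files.
#' @param sampleTablePath,markerPanelPath,oboPath,gmtPath,drugLibraryPath
#'   input file paths.
#' @param outputDir where stage outputs and the manifest are written.
#' @param log2Transform apply the log2 step during preprocessing (set
#'   `FALSE` for data already on a log-like scale, e.g. the synthetic
#'   generator's output).
#' @param epsilon shift for the log2 step.
#' @param batchCorrect apply empirical-Bayes batch correction.
#' @param powers,targetR2,nBins,minModuleSize,cutHeightFraction network
#'   parameters (see [buildCoexpressionNetwork()]).
#' @param alpha significance level used throughout.
#' @param nTop genes per module in the disease signature.
#' @param semsimCutoff,semsimHighCutoff specificity screen thresholds.
#' @param seed integer seed (the pipeline itself is deterministic; the
#'   seed is recorded and set for reproducibility of any downstream use).
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(inputDir = NULL,
                           expressionPaths = NULL,
                           sampleTablePath = NULL,
                           markerPanelPath = NULL,
                           oboPath = NULL,
                           gmtPath = NULL,
                           drugLibraryPath = NULL,
                           outputDir = tempfile("ruptureNet_run_"),
                           log2Transform = FALSE,
                           epsilon = 0,
                           batchCorrect = TRUE,
                           powers = c(1:10, seq(12L, 20L, 2L)),
                           targetR2 = 0.8,
                           nBins = 10L,
                           minModuleSize = 2L,
                           cutHeightFraction = 0.9,
                           alpha = 0.05,
                           nTop = 10L,
                           semsimCutoff = 0.2,
                           semsimHighCutoff = 0.8,
                           seed = 1L) {
  if (!is.null(inputDir)) {
    if (is.null(expressionPaths))
      expressionPaths <- sort(list.files(inputDir, "^expression_.*\\.tsv$",
                                         full.names = TRUE), method = "radix")
    pick <- function(given, name) {
      if (!is.null(given)) given else file.path(inputDir, name)
    }
    sampleTablePath <- pick(sampleTablePath, "sample_table.tsv")
    markerPanelPath <- pick(markerPanelPath, "marker_panel.tsv")
    oboPath <- pick(oboPath, "ontology.obo")
    gmtPath <- pick(gmtPath, "annotations.gmt")
    drugLibraryPath <- pick(drugLibraryPath, "drug_library.tsv")
  }
  cfg <- list(expressionPaths = expressionPaths,
              sampleTablePath = sampleTablePath,
              markerPanelPath = markerPanelPath,
              oboPath = oboPath, gmtPath = gmtPath,
              drugLibraryPath = drugLibraryPath,
              outputDir = outputDir,
              log2Transform = log2Transform, epsilon = epsilon,
              batchCorrect = batchCorrect,
              powers = powers, targetR2 = targetR2, nBins = nBins,
              minModuleSize = minModuleSize,
              cutHeightFraction = cutHeightFraction,
              alpha = alpha, nTop = nTop,
              semsimCutoff = semsimCutoff,
              semsimHighCutoff = semsimHighCutoff,
              seed = seed)
  class(cfg) <- "PipelineConfig"
  cfg
}

.validatePipelineConfig <- function(config) {
  if (is.null(config$expressionPaths) || length(config$expressionPaths) < 1L)
    stop("no expression matrices configured")
  paths <- c(config$expressionPaths, config$sampleTablePath,
             config$markerPanelPath, config$oboPath, config$gmtPath,
             config$drugLibraryPath)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing))
    stop("configured input file(s) do not exist: ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

.writeTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full rupture-transcriptomics pipeline
#'
#' Executes the seven analysis stages in order — preprocessing (per-series
#' quantile normalisation and optional log2, common-gene merge, global
#' scaling), batch correction, co-expression network with
#' module-phenotype testing, module over-representation, drug-signature
#' reversal ranking, cell-population-specific expression (on the
#' pre-scaling checkpoint, whose positive scale the intercept/mean
#' criterion needs), and the ontology specificity screen — writing each
#' stage's tab-delimited tables plus a machine-readable `manifest.json`
#' (parameters, input checksums, per-stage outputs). All inputs are
#' validated before any computation starts; stage failures propagate with
#' the stage name.
#'
#' @param config a `PipelineConfig` from [pipelineConfig()].
#' @return invisibly, a list with the output directory, the manifest, and
#'   the in-memory stage results.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  .validatePipelineConfig(config)
  set.seed(config$seed)
  out <- config$outputDir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "ruptureNet",
    version = as.character(utils::packageVersion("ruptureNet")),
    parameters = config[setdiff(names(config),
                                c("expressionPaths", "sampleTablePath",
                                  "markerPanelPath", "oboPath", "gmtPath",
                                  "drugLibraryPath", "outputDir"))],
    inputs = as.list(tools::md5sum(c(config$expressionPaths,
                                     config$sampleTablePath,
                                     config$markerPanelPath,
                                     config$oboPath, config$gmtPath,
                                     config$drugLibraryPath))),
    stages = list())
  results <- list()
  stage <- function(name, fn) {
    message("[", name, "] running")
    res <- tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[name]] <<- list(status = "completed",
                                     outputs = res$outputs)
    results[[name]] <<- res
    res
  }

  pre <- stage("preprocess", function() {
    mats <- lapply(config$expressionPaths, readExpressionMatrix)
    mats <- lapply(mats, quantileNormalize)
    if (config$log2Transform)
      mats <- lapply(mats, log2Transform, epsilon = config$epsilon)
    merged <- mergeOnCommonGenes(mats)
    scaled <- globalScale(merged)
    p1 <- .writeTable(data.frame(gene_id = rownames(merged), merged,
                                 check.names = FALSE),
                      file.path(out, "merged_qn.tsv"))
    p2 <- .writeTable(data.frame(gene_id = rownames(scaled), scaled,
                                 check.names = FALSE),
                      file.path(out, "merged_scaled.tsv"))
    st <- readSampleTable(config$sampleTablePath)
    if (!setequal(st$sample_id, colnames(merged)))
      stop("sample table does not match the merged matrix samples")
    list(merged = merged, scaled = scaled, samples = st,
         outputs = c(p1, p2))
  })

  bat <- stage("batch_correction", function() {
    if (config$batchCorrect &&
        length(unique(pre$samples$series)) >= 2L) {
      model <- fitBatchModel(pre$scaled, pre$samples)
      corrected <- adjustBatches(pre$scaled, model)
    } else {
      model <- NULL
      corrected <- pre$scaled
    }
    p <- .writeTable(data.frame(gene_id = rownames(corrected), corrected,
                                check.names = FALSE),
                     file.path(out, "batch_corrected.tsv"))
    list(corrected = corrected, model = model, outputs = p)
  })

  net <- stage("network", function() {
    ms <- buildCoexpressionNetwork(bat$corrected, powers = config$powers,
                                   targetR2 = config$targetR2,
                                   nBins = config$nBins,
                                   minModuleSize = config$minModuleSize,
                                   cutHeightFraction = config$cutHeightFraction)
    pheno <- pre$samples$phenotype[match(rownames(eigengenes(ms)),
                                         pre$samples$sample_id)]
    tests <- modulePhenotypeTest(ms, pheno, alpha = config$alpha)
    p <- c(
      .writeTable(data.frame(gene = names(moduleAssignment(ms)),
                             module = moduleAssignment(ms)),
                  file.path(out, "module_assignment.tsv")),
      .writeTable(data.frame(sample_id = rownames(eigengenes(ms)),
                             eigengenes(ms), check.names = FALSE),
                  file.path(out, "eigengenes.tsv")),
      .writeTable(data.frame(gene = rownames(kME(ms)), kME(ms),
                             check.names = FALSE),
                  file.path(out, "kme.tsv")),
      .writeTable(scaleFreeFitTable(ms),
                  file.path(out, "scale_free_fit.tsv")),
      .writeTable(tests, file.path(out, "module_phenotype_tests.tsv")))
    list(modules = ms, tests = tests, outputs = p)
  })

  enr <- stage("enrichment", function() {
    sets <- readGMT(config$gmtPath)
    universe <- rownames(bat$corrected)
    signature <- buildDiseaseSignature(net$modules, net$tests,
                                       nTop = config$nTop,
                                       alpha = config$alpha)
    # phenotype-wise query gene lists from the significant modules: a
    # member gene follows its module's rupture direction when its kME is
    # positive and the opposite direction when anti-correlated with the
    # eigengene, so gene-level direction = module direction x sign(kME)
    sig_mods <- net$tests[net$tests$significant & net$tests$direction != 0L, ]
    q_rupt <- character(); q_unrupt <- character()
    for (i in seq_len(nrow(sig_mods))) {
      mod <- sig_mods$module[i]
      g <- moduleGenes(net$modules, mod)
      s <- sign(kME(net$modules)[g, mod]) * sig_mods$direction[i]
      q_rupt <- c(q_rupt, g[s > 0])
      q_unrupt <- c(q_unrupt, g[s < 0])
    }
    q_rupt <- unique(q_rupt); q_unrupt <- unique(q_unrupt)
    res_up <- hypergeometricEnrichment(q_rupt, sets, universe,
                                       alpha = config$alpha)
    res_dn <- hypergeometricEnrichment(q_unrupt, sets, universe,
                                       alpha = config$alpha)
    p <- c(.writeTable(res_up, file.path(out, "enrichment_ruptured.tsv")),
           .writeTable(res_dn, file.path(out, "enrichment_unruptured.tsv")))
    list(signature = signature, up = res_up, down = res_dn,
         queries = list(ruptured = q_rupt, unruptured = q_unrupt),
         outputs = p)
  })

  stage("drug_repurposing", function() {
    lib <- readDrugLibrary(config$drugLibraryPath)
    ranking <- rankDrugs(enr$signature, lib)
    p <- .writeTable(ranking, file.path(out, "drug_ranking.tsv"))
    list(ranking = ranking, outputs = p)
  })

  stage("psea", function() {
    panel <- readMarkerPanel(config$markerPanelPath)
    fits <- pseaAnalysis(pre$merged, panel, pre$samples)
    paths <- character()
    for (ct in unique(fits$cell_type)) for (ph in unique(fits$phenotype)) {
      sub <- fits[fits$cell_type == ct & fits$phenotype == ph, , drop = FALSE]
      if (nrow(sub))
        paths <- c(paths, .writeTable(sub,
          file.path(out, paste0(ct, ".", ph, ".psea.tsv"))))
    }
    p_all <- .writeTable(fits, file.path(out, "psea_all.tsv"))
    list(fits = fits, outputs = c(p_all, paths))
  })

  stage("semsim", function() {
    dag <- loadOBO(config$oboPath)
    t_up <- enr$up$set_id[enr$up$significant]
    t_dn <- enr$down$set_id[enr$down$significant]
    if (!length(t_up) || !length(t_dn))
      stop("no significant terms for one phenotype; specificity screen ",
           "needs both term sets")
    spec <- specificTerms(t_up, t_dn, dag, cutoff = config$semsimCutoff,
                          highCutoff = config$semsimHighCutoff)
    p <- c(
      .writeTable(data.frame(term = rownames(spec$matrix), spec$matrix,
                             check.names = FALSE),
                  file.path(out, "semsim_matrix.tsv")),
      .writeTable(spec$report, file.path(out, "specificity_report.tsv")),
      .writeTable(spec$high_pairs, file.path(out, "high_similarity_pairs.tsv")))
    list(specificity = spec, outputs = p)
  })

  manifest$stages_completed <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message("pipeline finished: ", manifest$stages_completed,
          " stages completed -> ", out)
  invisible(list(outputDir = out, manifest = manifest, results = results))
}
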