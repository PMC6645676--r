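#' Default configuration for the synthetic-data generator
#'
#' Defaults emulate the merged two-series microarray design the pipeline
#' targets: two batches of 16 samples (half ruptured each, so phenotype is
#' balanced across batches), 2,000 genes, 10 planted co-expression modules
#' of 20-80 genes driven by latent factors, of which two are shifted up and
#' two down in ruptured samples by 2 factor-SD units; per-gene additive and
#' multiplicative batch effects; five cell populations (the default marker
#' panel) with log-normal abundances (CV 0.4), macrophage and T-cell
#' abundance raised 1.5x in ruptured samples, and 20 abundance-proportional
#' cell-specific genes per population; a toy ontology (depth 3, branching
#' 3) with a disjoint branch of planted rupture-specific terms; and a
#' 50-compound drug library optionally containing a planted perfect
#' reversal compound. Expression is generated on a log2-like scale
#' (baseline N(7, 1)), so the preprocessing log2 step is not needed on
#' synthetic data.
#'
#' @param ... overrides for any default field.
#' @return named list of generator settings.
#' @export
simulationConfig <- function(...) {
  cfg <- list(
    n_genes = 2000L,
    n_batches = 2L,
    n_samples_per_batch = 16L,
    n_modules = 10L,
    module_size_range = c(20L, 80L),
    factor_loading_range = c(0.7, 1.0),
    noise_sd = 0.5,
    rupture_modules_up = 2L,
    rupture_modules_down = 2L,
    phenotype_effect_size = 2,
    batch_offset_sd = 0.5,
    batch_scale_range = c(0.8, 1.25),
    marker_panel = NULL,            # NULL = built-in panel
    marker_scale_range = c(4, 8),
    marker_noise_sd = 0.05,
    n_cell_specific_genes = 20L,
    cell_coef_range = c(4, 8),
    cell_noise_sd = 0.3,
    abundance_cv = 0.4,
    abundance_phenotype_shift = 1.5,
    shifted_cell_types = c("macrophage", "t_cell"),
    baseline_mean = 7,
    baseline_sd = 1,
    n_private_genes = 5L,
    ontology_depth = 3L,
    ontology_branching = 3L,
    n_specific_terms = 3L,
    library_size = 50L,
    planted_reversal = TRUE,
    n_top = 10L,
    seed = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$n_modules < 1L || any(cfg$module_size_range < 2L))
    stop("module sizes must be >= 2")
  if (is.null(cfg$seed)) stop("a seed is mandatory for reproducibility")
  cfg
}

.defaultPanel <- function() {
  list(
    smooth_muscle = c("MCAM", "DES"),
    endothelial   = c("TJP1", "SLC2A1", "VCAM1", "SELE", "VWF"),
    macrophage    = c("CD14", "FCGR1A", "CD68", "TFRC", "CCR5"),
    mast_cell     = c("KIT", "ENPP3"),
    t_cell        = c("CD3D", "CD3E", "CD3G", "CD4", "CD8A", "CD8B",
                      "IL2RA", "IL7R", "CCR6")
  )
}

#' Simulate a merged multi-series expression dataset with planted truth
#'
#' Draws, in a fixed documented order from one seeded generator: module
#' sizes and loadings, latent module factors (with the rupture shift on
#' designated modules), gene-level noise, cell-population abundances,
#' marker and cell-specific gene expression, and finally per-batch
#' additive/multiplicative effects. See [simulationConfig()] for what the
#' defaults emulate.
#'
#' @param config list from [simulationConfig()].
#' @return list with `expression` (genes x samples matrix), `samples`
#'   (sample table data.frame) and `truth` (planted ground truth: module
#'   map including cell-population gene groups, rupture modules and
#'   directions, batch effects, abundances, cell-specific map, and the
#'   planted disease signature: the full gene unions of the up- and
#'   down-shifted modules, since every member moves with the phenotype).
#' @export
simulateExpression <- function(config = simulationConfig()) {
  set.seed(config$seed)
  panel <- config$marker_panel
  if (is.null(panel)) panel <- .defaultPanel()
  nspb <- config$n_samples_per_batch
  N <- config$n_batches * nspb

  sample_ids <- unlist(lapply(seq_len(config$n_batches), function(b)
    sprintf("S%s%02d", LETTERS[b], seq_len(nspb))))
  series <- rep(paste0("series", LETTERS[seq_len(config$n_batches)]),
                each = nspb)
  n_rupt <- ceiling(nspb / 2)
  phenotype <- rep(c(rep("ruptured", n_rupt),
                     rep("unruptured", nspb - n_rupt)), config$n_batches)
  samples <- data.frame(sample_id = sample_ids, series = series,
                        phenotype = phenotype, stringsAsFactors = FALSE)

  # gene budget
  sizes <- sample(seq(config$module_size_range[1L],
                      config$module_size_range[2L]), config$n_modules,
                  replace = TRUE)
  markers <- unlist(panel, use.names = FALSE)
  n_cell <- config$n_cell_specific_genes * length(panel)
  n_struct <- sum(sizes) + n_cell
  if (n_struct + length(markers) > config$n_genes)
    stop("module and cell-specific gene budget exceeds n_genes")
  plain_ids <- sprintf("G%04d", seq_len(config$n_genes - length(markers)))
  mod_genes <- split(plain_ids[seq_len(sum(sizes))],
                     rep(seq_len(config$n_modules), sizes))
  names(mod_genes) <- paste0("simM", seq_len(config$n_modules))
  cell_ids <- plain_ids[sum(sizes) + seq_len(n_cell)]
  cell_genes <- split(cell_ids, rep(names(panel),
                                    each = config$n_cell_specific_genes))
  bg_ids <- plain_ids[-seq_len(sum(sizes) + n_cell)]
  genes <- c(unlist(mod_genes, use.names = FALSE), cell_ids, bg_ids, markers)

  # rupture modules and directions
  dir_vec <- integer(config$n_modules)
  up_idx <- seq_len(config$rupture_modules_up)
  dn_idx <- config$rupture_modules_up + seq_len(config$rupture_modules_down)
  dir_vec[up_idx] <- 1L; dir_vec[dn_idx] <- -1L

  # latent factors and module genes
  loadings <- stats::runif(sum(sizes), config$factor_loading_range[1L],
                           config$factor_loading_range[2L])
  names(loadings) <- unlist(mod_genes, use.names = FALSE)
  X <- matrix(0, length(genes), N, dimnames = list(genes, sample_ids))
  is_rupt <- phenotype == "ruptured"
  factors <- matrix(stats::rnorm(config$n_modules * N), config$n_modules, N)
  for (mi in seq_len(config$n_modules)) {
    f <- factors[mi, ]
    if (dir_vec[mi] != 0L)
      f <- f + dir_vec[mi] * config$phenotype_effect_size * is_rupt
    g <- mod_genes[[mi]]
    X[g, ] <- outer(loadings[g], f)
  }
  base_genes <- c(unlist(mod_genes, use.names = FALSE), bg_ids)
  baseline <- stats::rnorm(length(base_genes), config$baseline_mean,
                           config$baseline_sd)
  X[base_genes, ] <- X[base_genes, ] + baseline
  X[base_genes, ] <- X[base_genes, ] +
    matrix(stats::rnorm(length(base_genes) * N, sd = config$noise_sd),
           length(base_genes), N)

  # cell-population abundances (log-normal, mean 1, given CV), with the
  # phenotype shift on designated populations
  s2 <- log(1 + config$abundance_cv^2)
  abund <- matrix(exp(stats::rnorm(length(panel) * N, -s2 / 2, sqrt(s2))),
                  length(panel), N, dimnames = list(names(panel), sample_ids))
  for (ct in intersect(config$shifted_cell_types, names(panel)))
    abund[ct, is_rupt] <- abund[ct, is_rupt] * config$abundance_phenotype_shift

  for (ct in names(panel)) {
    sc <- stats::runif(length(panel[[ct]]), config$marker_scale_range[1L],
                       config$marker_scale_range[2L])
    X[panel[[ct]], ] <- outer(sc, abund[ct, ]) +
      matrix(stats::rnorm(length(panel[[ct]]) * N,
                          sd = config$marker_noise_sd),
             length(panel[[ct]]), N)
    cf <- stats::runif(length(cell_genes[[ct]]), config$cell_coef_range[1L],
                       config$cell_coef_range[2L])
    X[cell_genes[[ct]], ] <- outer(cf, abund[ct, ]) +
      matrix(stats::rnorm(length(cell_genes[[ct]]) * N,
                          sd = config$cell_noise_sd),
             length(cell_genes[[ct]]), N)
  }

  # batch effects (batch 1 is the unperturbed reference)
  center <- rowMeans(X)
  batch_effects <- list()
  if (config$n_batches >= 2L) {
    for (b in 2:config$n_batches) {
      off <- stats::rnorm(length(genes), 0, config$batch_offset_sd)
      scl <- stats::runif(length(genes), config$batch_scale_range[1L],
                          config$batch_scale_range[2L])
      sel <- series == paste0("series", LETTERS[b])
      X[, sel] <- center + (X[, sel] - center) * scl + off
      batch_effects[[paste0("series", LETTERS[b])]] <-
        list(offset = stats::setNames(off, genes),
             scale = stats::setNames(scl, genes))
    }
  }

  # planted module map: latent-factor modules plus cell-population groups
  module_map <- stats::setNames(rep("background", length(genes)), genes)
  for (mn in names(mod_genes)) module_map[mod_genes[[mn]]] <- mn
  for (ct in names(panel)) {
    module_map[cell_genes[[ct]]] <- paste0("CT_", ct)
    module_map[panel[[ct]]] <- paste0("CT_", ct)
  }

  # planted disease signature: every member of a rupture module moves with
  # the phenotype, so the true signature is the full module gene unions
  truth <- list(
    module_map = module_map,
    module_genes = mod_genes,
    rupture_modules = data.frame(
      module = names(mod_genes)[dir_vec != 0L],
      direction = dir_vec[dir_vec != 0L], stringsAsFactors = FALSE),
    loadings = loadings,
    batch = stats::setNames(series, sample_ids),
    batch_effects = batch_effects,
    abundances = abund,
    cell_specific_map = stats::setNames(
      rep(names(panel), each = config$n_cell_specific_genes), cell_ids),
    marker_panel = panel,
    disease_signature = list(
      up = unique(unlist(mod_genes[up_idx], use.names = FALSE)),
      down = unique(unlist(mod_genes[dn_idx], use.names = FALSE)))
  )
  list(expression = X, samples = samples, truth = truth)
}

#' Simulate a toy ontology with planted rupture-specific terms
#'
#' Builds a rooted `is_a` tree of the configured depth and branching plus a
#' disjoint branch (its own root) housing the planted rupture-specific
#' terms, and gene-set annotations sized so that the planted terms enrich
#' in the top-loading genes of the rupture-positive modules, shared terms
#' enrich in both phenotypes' query lists, and a few filler terms carry
#' background genes only.
#'
#' @param config list from [simulationConfig()].
#' @param truth ground truth from [simulateExpression()] (provides the
#'   planted module genes the annotations draw from).
#' @return list with `dag` ([OntologyDAG-class]), `annotations` (named
#'   list of gene sets, GMT-writable), `ruptured_terms`,
#'   `unruptured_terms`, and `specific_terms` (the planted
#'   rupture-specific term ids).
#' @export
simulateOntology <- function(config = simulationConfig(), truth) {
  if (config$ontology_depth < 2L) stop("ontology depth must be >= 2")
  set.seed(config$seed + 1L)
  ids <- character(); nms <- character(); edges <- list()
  new_term <- function(name) {
    id <- sprintf("SIM:%07d", length(ids) + 1L)
    ids <<- c(ids, id); nms <<- c(nms, name)
    id
  }
  root <- new_term("biological_process")
  level <- root
  for (d in seq_len(config$ontology_depth - 1L)) {
    nxt <- character()
    for (p in level) {
      for (k in seq_len(config$ontology_branching)) {
        ch <- new_term(sprintf("process_d%d_%s", d,
                               length(ids)))
        edges[[length(edges) + 1L]] <- c(ch, p, "is_a")
        nxt <- c(nxt, ch)
      }
    }
    level <- nxt
  }
  leaves <- level
  # disjoint branch: separate root, children are the planted specific terms
  r2 <- new_term("rupture_specific_branch")
  specific <- vapply(seq_len(config$n_specific_terms), function(k) {
    ch <- new_term(sprintf("rupture_specific_process_%d", k))
    edges[[length(edges) + 1L]] <- c(ch, r2, "is_a")
    ch
  }, character(1))
  ed <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  colnames(ed) <- c("child", "parent", "relation")
  dag <- methods::new("OntologyDAG", terms = ids,
                      names = stats::setNames(nms, ids), edges = ed)

  # annotations: draw from the planted rupture-module genes so the planted
  # terms enrich in the phenotype query gene lists the pipeline builds
  rup <- truth$rupture_modules
  up_mods <- rup$module[rup$direction > 0]
  dn_mods <- rup$module[rup$direction < 0]
  draw <- function(mod, n) {
    g <- truth$module_genes[[mod]]
    sample(g, min(n, length(g)))
  }
  anns <- list()
  for (k in seq_along(specific)) {
    mod <- up_mods[(k - 1L) %% length(up_mods) + 1L]
    anns[[specific[k]]] <- draw(mod, 10L)
  }
  n_shared <- max(2L, length(up_mods) * length(dn_mods))
  shared <- leaves[seq_len(min(n_shared, length(leaves)))]
  for (k in seq_along(shared)) {
    um <- up_mods[(k - 1L) %% length(up_mods) + 1L]
    dm <- dn_mods[(k - 1L) %% length(dn_mods) + 1L]
    anns[[shared[k]]] <- unique(c(draw(um, 5L), draw(dm, 5L)))
  }
  extra <- leaves[min(n_shared, length(leaves)) +
                    seq_len(min(2L, length(leaves) - length(shared)))]
  extra <- extra[!is.na(extra)]
  for (k in seq_along(extra)) {
    dm <- dn_mods[(k - 1L) %% length(dn_mods) + 1L]
    anns[[extra[k]]] <- draw(dm, 8L)
  }
  bg <- names(truth$module_map)[truth$module_map == "background"]
  fillers <- setdiff(leaves, c(shared, extra))
  for (t in utils::head(fillers, 4L))
    anns[[t]] <- sample(bg, 12L)
  attr(anns, "descriptions") <- stats::setNames(
    unname(stats::setNames(nms, ids)[names(anns)]), names(anns))
  list(dag = dag, annotations = anns,
       ruptured_terms = c(specific, shared),
       unruptured_terms = c(shared, extra),
       specific_terms = specific)
}

#' Simulate a drug-signature library with an optional planted reversal
#'
#' Random up/down signatures drawn from a gene universe plus, when
#' `planted_reversal` is set, one compound (`"planted_reversal"`) whose
#' lists exactly invert the supplied disease signature.
#'
#' @param disease a [DiseaseSignature-class] the planted compound inverts.
#' @param universe character vector of genes to draw random signatures from.
#' @param config list from [simulationConfig()].
#' @return list with `library` ([DrugSignatureLibrary-class]) and
#'   `planted_compound` (its id, or `NA`).
#' @export
simulateDrugLibrary <- function(disease, universe,
                                config = simulationConfig()) {
  if (config$library_size < 1L) stop("library_size must be >= 1")
  set.seed(config$seed + 2L)
  mechs <- c("PKC activator", "BTK inhibitor", "HIF modulator",
             "NAE inhibitor", "prostanoid receptor agonist",
             "vasopressin receptor agonist", "HMT inhibitor",
             "ARFGAP inhibitor", "statin", "TNF blocker")
  n_up <- max(5L, length(upGenes(disease)))
  n_dn <- max(5L, length(downGenes(disease)))
  compounds <- list()
  for (i in seq_len(config$library_size)) {
    up <- sample(universe, n_up)
    down <- sample(setdiff(universe, up), n_dn)
    compounds[[sprintf("CMPD%03d", i)]] <-
      list(up = up, down = down, mechanism = sample(mechs, 1L))
  }
  planted <- NA_character_
  if (isTRUE(config$planted_reversal)) {
    planted <- "planted_reversal"
    compounds[[planted]] <- list(up = downGenes(disease),
                                 down = upGenes(disease),
                                 mechanism = "planted reversal control")
  }
  list(library = methods::new("DrugSignatureLibrary", compounds = compounds),
       planted_compound = planted)
}

#' Generate a complete synthetic fixture directory
#'
#' Emits everything the pipeline reads: one expression matrix per series
#' (each with a handful of series-private genes so the common-gene merge is
#' exercised), the sample table, the marker panel, the ontology (OBO), the
#' annotations (GMT), the drug library (built to invert the planted
#' disease signature) and the ground truth as JSON.
#'
#' @param config list from [simulationConfig()].
#' @param dir output directory (created if needed).
#' @return invisibly, the ground-truth list (with the ontology truth and
#'   planted compound appended).
#' @export
simulateAll <- function(config = simulationConfig(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateExpression(config)
  onto <- simulateOntology(config, sim$truth)
  set.seed(config$seed + 3L)
  series <- unique(sim$samples$series)
  for (i in seq_along(series)) {
    sel <- sim$samples$sample_id[sim$samples$series == series[i]]
    m <- sim$expression[, sel, drop = FALSE]
    if (config$n_private_genes > 0L) {
      priv <- matrix(stats::rnorm(config$n_private_genes * ncol(m),
                                  config$baseline_mean, config$baseline_sd),
                     config$n_private_genes, ncol(m),
                     dimnames = list(sprintf("PRIV%s%02d", LETTERS[i],
                                             seq_len(config$n_private_genes)),
                                     colnames(m)))
      m <- rbind(m, priv)
    }
    writeExpressionMatrix(m, file.path(dir, paste0("expression_", series[i],
                                                   ".tsv")))
  }
  utils::write.table(sim$samples, file.path(dir, "sample_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  panel <- sim$truth$marker_panel
  utils::write.table(
    data.frame(cell_type = rep(names(panel), lengths(panel)),
               gene = unlist(panel, use.names = FALSE)),
    file.path(dir, "marker_panel.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeOBO(onto$dag, file.path(dir, "ontology.obo"))
  writeGMT(onto$annotations, file.path(dir, "annotations.gmt"))
  ds <- DiseaseSignature(sim$truth$disease_signature$up,
                         sim$truth$disease_signature$down)
  lib <- simulateDrugLibrary(ds, rownames(sim$expression), config)
  writeDrugLibrary(lib$library, file.path(dir, "drug_library.tsv"))
  truth <- sim$truth
  truth$ruptured_terms <- onto$ruptured_terms
  truth$unruptured_terms <- onto$unruptured_terms
  truth$specific_terms <- onto$specific_terms
  truth$planted_compound <- lib$planted_compound
  truth$abundances <- NULL   # matrices stay in memory, not in the JSON
  truth$loadings <- NULL
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(sim$truth, list(ruptured_terms = onto$ruptured_terms,
                              unruptured_terms = onto$unruptured_terms,
                              specific_terms = onto$specific_terms,
                              planted_compound = lib$planted_compound)))
}
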