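#' @import methods
NULL

#' ModuleSet: co-expression modules, eigengenes and module membership
#'
#' Container for the output of co-expression network analysis: the
#' gene-to-module assignment, per-module eigengenes (meta-genes), the kME
#' (module-membership) table, the soft-threshold power used and the
#' scale-free fit table it was chosen from.
#'
#' @slot assignment named character vector, gene -> module label. The
#'   reserved label `"unclassified"` marks genes excluded from all modules.
#' @slot eigengenes numeric matrix, samples x modules; each column has unit
#'   Euclidean norm and is sign-oriented so the mean kME of the module's own
#'   genes is non-negative.
#' @slot kme numeric matrix, genes x modules, Pearson correlation of each
#'   gene's expression with each eigengene.
#' @slot powerUsed integer, the soft-threshold power.
#' @slot fitTable data.frame with columns `power` and `signed_r2`.
#'
#' @export
setClass("ModuleSet",
  representation(
    assignment = "character",
    eigengenes = "matrix",
    kme        = "matrix",
    powerUsed  = "integer",
    fitTable   = "data.frame"
  )
)

setValidity("ModuleSet", function(object) {
  msg <- character()
  mods <- setdiff(unique(object@assignment), "unclassified")
  if (ncol(object@eigengenes) > 0 &&
      !setequal(colnames(object@eigengenes), mods))
    msg <- c(msg, "eigengene columns must match module labels in assignment")
  if (ncol(object@eigengenes) > 0) {
    nrm <- sqrt(colSums(object@eigengenes^2))
    if (any(abs(nrm - 1) > 1e-6))
      msg <- c(msg, "eigengenes must have unit Euclidean norm")
  }
  if (nrow(object@kme) > 0 && any(abs(object@kme) > 1 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "kME values must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' BatchModel: fitted parametric empirical-Bayes batch-effect model
#'
#' Per-gene grand means and pooled variances together with per-batch
#' per-gene additive (gamma) and multiplicative (delta^2) effect estimates,
#' both raw and shrunk toward batch-level normal / inverse-gamma priors.
#'
#' @slot genes,samples character identifiers defining the fitted universe.
#' @slot batch named character vector, sample -> batch label.
#' @slot grandMean per-gene grand mean (alpha_g).
#' @slot pooledVar per-gene pooled variance (sigma^2_g), strictly positive.
#' @slot gammaStar,delta2Star batch x gene matrices of EB-shrunk location and
#'   scale effects; delta2Star strictly positive.
#' @slot priors data.frame, one row per batch, with the prior
#'   hyperparameters (gamma_bar, t2, a_prior, b_prior).
#' @slot iterations integer vector, EB fixed-point iterations used per batch.
#'
#' @export
setClass("BatchModel",
  representation(
    genes      = "character",
    samples    = "character",
    batch      = "character",
    grandMean  = "numeric",
    pooledVar  = "numeric",
    gammaStar  = "matrix",
    delta2Star = "matrix",
    priors     = "data.frame",
    iterations = "integer"
  )
)

setValidity("BatchModel", function(object) {
  msg <- character()
  if (any(object@pooledVar <= 0))
    msg <- c(msg, "pooled variances must be strictly positive")
  if (length(object@delta2Star) && any(object@delta2Star <= 0))
    msg <- c(msg, "delta2Star must be strictly positive")
  if (!identical(dim(object@gammaStar), dim(object@delta2Star)))
    msg <- c(msg, "gammaStar and delta2Star must have identical dimensions")
  if (length(msg)) msg else TRUE
})

#' OntologyDAG: a parsed ontology graph
#'
#' Directed acyclic graph of ontology terms with `is_a` / `part_of` edges
#' pointing from child to parent. Roots are terms with no parents; acyclicity
#' and root-reachability are enforced at construction.
#'
#' @slot terms character vector of term identifiers.
#' @slot names named character vector of human-readable term names.
#' @slot edges data.frame with columns `child`, `parent`, `relation`
#'   (one of `"is_a"`, `"part_of"`).
#'
#' @export
setClass("OntologyDAG",
  representation(
    terms = "character",
    names = "character",
    edges = "data.frame"
  )
)

setValidity("OntologyDAG", function(object) {
  msg <- character()
  if (anyDuplicated(object@terms))
    msg <- c(msg, "term identifiers must be unique")
  ed <- object@edges
  if (nrow(ed)) {
    if (!all(c("child", "parent", "relation") %in% colnames(ed)))
      msg <- c(msg, "edges need columns child, parent, relation")
    else {
      if (!all(ed$relation %in% c("is_a", "part_of")))
        msg <- c(msg, "edge relations must be is_a or part_of")
      if (!all(c(ed$child, ed$parent) %in% object@terms))
        msg <- c(msg, "edges reference unknown terms")
      cyc <- .findCycle(object@terms, ed)
      if (!is.null(cyc))
        msg <- c(msg, paste0("ontology contains a cycle: ",
                             paste(cyc, collapse = " -> ")))
    }
  }
  if (length(msg)) msg else TRUE
})

# Kahn's algorithm on the child->parent digraph; returns NULL if acyclic,
# else the set of terms stuck on a cycle. A term becomes removable once all
# of its children have been removed.
.findCycle <- function(terms, edges) {
  pending <- stats::setNames(integer(length(terms)), terms)
  tab <- table(edges$parent)
  pending[names(tab)] <- as.integer(tab)
  parentsOf <- split(edges$parent, edges$child)
  queue <- names(pending)[pending == 0L]
  done <- 0L
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]; done <- done + 1L
    for (p in parentsOf[[t]]) {
      pending[[p]] <- pending[[p]] - 1L
      if (pending[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (done == length(terms)) NULL else names(pending)[pending > 0L]
}

#' DiseaseSignature: up/down gene lists describing a disease state
#'
#' @slot up,down character vectors of gene identifiers; disjoint.
#'
#' @export
setClass("DiseaseSignature",
  representation(up = "character", down = "character")
)

setValidity("DiseaseSignature", function(object) {
  msg <- character()
  if (anyDuplicated(object@up) || anyDuplicated(object@down))
    msg <- c(msg, "up/down lists must not contain duplicates")
  if (length(intersect(object@up, object@down)))
    msg <- c(msg, "up and down lists must be disjoint")
  if (length(msg)) msg else TRUE
})

#' DrugSignatureLibrary: per-compound up/down transcriptional signatures
#'
#' @slot compounds named list; each element a list with components `up`,
#'   `down` (character gene vectors, disjoint) and `mechanism` (length-1
#'   character, possibly `NA`).
#'
#' @export
setClass("DrugSignatureLibrary",
  representation(compounds = "list")
)

setValidity("DrugSignatureLibrary", function(object) {
  msg <- character()
  cmp <- object@compounds
  if (is.null(names(cmp)) || anyDuplicated(names(cmp)))
    msg <- c(msg, "compound identifiers must be unique and named")
  bad <- vapply(cmp, function(x) {
    !is.list(x) || !all(c("up", "down") %in% names(x)) ||
      length(intersect(x$up, x$down)) > 0
  }, logical(1))
  if (any(bad))
    msg <- c(msg, paste0("malformed or non-disjoint signature for: ",
                         paste(names(cmp)[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})
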