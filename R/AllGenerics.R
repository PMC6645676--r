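#' Accessors for ruptureNet S4 classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object a `ModuleSet`, `BatchModel`, `OntologyDAG`,
#'   `DiseaseSignature` or `DrugSignatureLibrary`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("moduleAssignment", function(object) standardGeneric("moduleAssignment"))
#' @rdname accessors
#' @export
setGeneric("eigengenes", function(object) standardGeneric("eigengenes"))
#' @rdname accessors
#' @export
setGeneric("kME", function(object) standardGeneric("kME"))
#' @rdname accessors
#' @export
setGeneric("powerUsed", function(object) standardGeneric("powerUsed"))
#' @rdname accessors
#' @export
setGeneric("scaleFreeFitTable", function(object) standardGeneric("scaleFreeFitTable"))
#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))
#' @rdname accessors
#' @export
setGeneric("moduleGenes", function(object, module) standardGeneric("moduleGenes"))

#' @rdname accessors
#' @export
setMethod("moduleAssignment", "ModuleSet", function(object) object@assignment)
#' @rdname accessors
#' @export
setMethod("eigengenes", "ModuleSet", function(object) object@eigengenes)
#' @rdname accessors
#' @export
setMethod("kME", "ModuleSet", function(object) object@kme)
#' @rdname accessors
#' @export
setMethod("powerUsed", "ModuleSet", function(object) object@powerUsed)
#' @rdname accessors
#' @export
setMethod("scaleFreeFitTable", "ModuleSet", function(object) object@fitTable)
#' @rdname accessors
#' @export
setMethod("moduleLabels", "ModuleSet", function(object)
  colnames(object@eigengenes))
#' @param module a module label.
#' @rdname accessors
#' @export
setMethod("moduleGenes", "ModuleSet", function(object, module) {
  if (!module %in% object@assignment)
    stop("unknown module: ", module)
  names(object@assignment)[object@assignment == module]
})

setMethod("show", "ModuleSet", function(object) {
  mods <- moduleLabels(object)
  n_un <- sum(object@assignment == "unclassified")
  cat("ModuleSet with", length(mods), "modules over",
      length(object@assignment), "genes",
      sprintf("(%d unclassified)\n", n_un))
  cat("  soft-threshold power:", object@powerUsed, "\n")
  if (length(mods)) {
    sz <- sort(table(object@assignment[object@assignment != "unclassified"]),
               decreasing = TRUE)
    cat("  module sizes:", paste0(names(sz)[seq_len(min(8, length(sz)))], "=",
        sz[seq_len(min(8, length(sz)))], collapse = " "),
        if (length(sz) > 8) "...\n" else "\n")
  }
})

#' @rdname accessors
#' @export
setGeneric("batchLabels", function(object) standardGeneric("batchLabels"))
#' @rdname accessors
#' @export
setGeneric("gammaStar", function(object) standardGeneric("gammaStar"))
#' @rdname accessors
#' @export
setGeneric("delta2Star", function(object) standardGeneric("delta2Star"))
#' @rdname accessors
#' @export
setGeneric("batchPriors", function(object) standardGeneric("batchPriors"))

#' @rdname accessors
#' @export
setMethod("batchLabels", "BatchModel", function(object) object@batch)
#' @rdname accessors
#' @export
setMethod("gammaStar", "BatchModel", function(object) object@gammaStar)
#' @rdname accessors
#' @export
setMethod("delta2Star", "BatchModel", function(object) object@delta2Star)
#' @rdname accessors
#' @export
setMethod("batchPriors", "BatchModel", function(object) object@priors)

setMethod("show", "BatchModel", function(object) {
  cat("BatchModel:", length(object@genes), "genes,",
      length(object@samples), "samples,",
      nrow(object@gammaStar), "batches\n")
  cat("  batches:", paste(rownames(object@gammaStar), collapse = ", "), "\n")
  cat("  EB iterations per batch:",
      paste(object@iterations, collapse = ", "), "\n")
})

#' @rdname accessors
#' @export
setGeneric("ontologyTerms", function(object) standardGeneric("ontologyTerms"))
#' @rdname accessors
#' @export
setGeneric("ontologyEdges", function(object) standardGeneric("ontologyEdges"))
#' @rdname accessors
#' @export
setGeneric("ontologyRoots", function(object) standardGeneric("ontologyRoots"))
#' @rdname accessors
#' @export
setGeneric("termNames", function(object) standardGeneric("termNames"))

#' @rdname accessors
#' @export
setMethod("ontologyTerms", "OntologyDAG", function(object) object@terms)
#' @rdname accessors
#' @export
setMethod("ontologyEdges", "OntologyDAG", function(object) object@edges)
#' @rdname accessors
#' @export
setMethod("ontologyRoots", "OntologyDAG", function(object)
  setdiff(object@terms, unique(object@edges$child)))
#' @rdname accessors
#' @export
setMethod("termNames", "OntologyDAG", function(object) object@names)

setMethod("show", "OntologyDAG", function(object) {
  cat("OntologyDAG:", length(object@terms), "terms,",
      nrow(object@edges), "edges,",
      length(ontologyRoots(object)), "root(s)\n")
})

#' @rdname accessors
#' @export
setGeneric("upGenes", function(object) standardGeneric("upGenes"))
#' @rdname accessors
#' @export
setGeneric("downGenes", function(object) standardGeneric("downGenes"))

#' @rdname accessors
#' @export
setMethod("upGenes", "DiseaseSignature", function(object) object@up)
#' @rdname accessors
#' @export
setMethod("downGenes", "DiseaseSignature", function(object) object@down)

setMethod("show", "DiseaseSignature", function(object) {
  cat("DiseaseSignature:", length(object@up), "up,",
      length(object@down), "down genes\n")
})

#' @rdname accessors
#' @export
setGeneric("compoundIds", function(object) standardGeneric("compoundIds"))
#' @rdname accessors
#' @export
setGeneric("compoundSignature", function(object, id) standardGeneric("compoundSignature"))

#' @rdname accessors
#' @export
setMethod("compoundIds", "DrugSignatureLibrary", function(object)
  names(object@compounds))
#' @param id a compound identifier.
#' @rdname accessors
#' @export
setMethod("compoundSignature", "DrugSignatureLibrary", function(object, id) {
  if (!id %in% names(object@compounds))
    stop("unknown compound: ", id)
  object@compounds[[id]]
})

setMethod("show", "DrugSignatureLibrary", function(object) {
  cat("DrugSignatureLibrary with", length(object@compounds), "compounds\n")
})
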