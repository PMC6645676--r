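#' Construct a DiseaseSignature
#'
#' @param up,down disjoint character vectors of gene identifiers.
#' @return a [DiseaseSignature-class].
#' @export
DiseaseSignature <- function(up, down) {
  methods::new("DiseaseSignature", up = unique(as.character(up)),
               down = unique(as.character(down)))
}

#' Build an up/down disease signature from rupture-associated modules
#'
#' For every module significantly associated with rupture (uncorrected
#' p < alpha), its member genes are ranked by kME (correlation with the
#' module meta-gene) in decreasing order and the top `nTop` appended to the
#' up list (positive-direction modules) or the down list (negative
#' direction). Modules smaller than `nTop` contribute all their members.
#' Duplicates keep their first occurrence; genes landing in both lists are
#' removed from both (logged). A one-sided signature (only one direction
#' significant) is allowed with a warning; no significant module at all is
#' an error.
#'
#' @param moduleSet a [ModuleSet-class].
#' @param tests result of [modulePhenotypeTest()].
#' @param nTop genes taken per module (default 10).
#' @param alpha significance cutoff on the uncorrected p-value.
#' @return a [DiseaseSignature-class].
#' @export
buildDiseaseSignature <- function(moduleSet, tests, nTop = 10L,
                                  alpha = 0.05) {
  stopifnot(methods::is(moduleSet, "ModuleSet"))
  sig <- tests[tests$p_value < alpha & tests$direction != 0L, , drop = FALSE]
  if (!nrow(sig)) stop("no module significantly associated with phenotype")
  pick <- function(direction) {
    mods <- sig$module[sig$direction == direction]
    genes <- character()
    for (mod in mods) {
      members <- moduleGenes(moduleSet, mod)
      kme_own <- kME(moduleSet)[members, mod]
      top <- members[order(-kme_own, members)][seq_len(min(nTop,
                                                           length(members)))]
      genes <- c(genes, top)
    }
    unique(genes)
  }
  up <- pick(1L); down <- pick(-1L)
  if (!length(up) || !length(down))
    warning("one-sided signature: no significant module in one direction")
  both <- intersect(up, down)
  if (length(both)) {
    message("gene(s) in both top lists removed from both: ",
            paste(both, collapse = ", "))
    up <- setdiff(up, both); down <- setdiff(down, both)
  }
  DiseaseSignature(up, down)
}

#' Connectivity (reversal) score of a drug signature against a disease
#'
#' Signed overlap score on a -100..+100 scale:
#' `100 * (|Dup n Sdown| + |Ddown n Sup| - |Dup n Sup| - |Ddown n Sdown|)
#' / (|Dup| + |Ddown|)`. A drug that exactly inverts the disease signature
#' over all its genes scores +100 (a perfect match for reversal); a drug
#' identical to the disease signature scores -100 (it mimics, the exact
#' opposite of what is desired); a drug sharing no genes scores 0.
#'
#' @param disease a [DiseaseSignature-class] with non-empty lists.
#' @param drugUp,drugDown the drug signature's up/down gene lists (or pass
#'   a compound entry list with `up`/`down` components as `drugUp`).
#' @return numeric score in \[-100, 100\].
#' @export
connectivityScore <- function(disease, drugUp, drugDown = NULL) {
  stopifnot(methods::is(disease, "DiseaseSignature"))
  if (is.list(drugUp) && is.null(drugDown)) {
    drugDown <- drugUp$down; drugUp <- drugUp$up
  }
  d_up <- upGenes(disease); d_dn <- downGenes(disease)
  if (!length(d_up) && !length(d_dn)) stop("empty disease signature")
  reversed <- length(intersect(d_up, drugDown)) +
    length(intersect(d_dn, drugUp))
  mimicked <- length(intersect(d_up, drugUp)) +
    length(intersect(d_dn, drugDown))
  100 * (reversed - mimicked) / (length(d_up) + length(d_dn))
}

#' Rank a drug-signature library by reversal score
#'
#' @param disease a [DiseaseSignature-class].
#' @param library a [DrugSignatureLibrary-class].
#' @return data.frame `compound_id`, `score`, `rank`, `mechanism`, sorted
#'   by score descending, ties by compound id ascending.
#' @export
rankDrugs <- function(disease, library) {
  stopifnot(methods::is(library, "DrugSignatureLibrary"))
  ids <- compoundIds(library)
  if (!length(ids)) stop("empty drug library")
  scores <- vapply(ids, function(id)
    connectivityScore(disease, library@compounds[[id]]), numeric(1))
  mech <- vapply(ids, function(id) {
    mm <- library@compounds[[id]]$mechanism
    if (is.null(mm) || !length(mm)) NA_character_ else as.character(mm)
  }, character(1))
  out <- data.frame(compound_id = ids, score = scores, mechanism = mech,
                    row.names = NULL)
  out <- out[order(-out$score, out$compound_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("compound_id", "score", "rank", "mechanism")]
}

#' Read a drug-signature library from tab-delimited text
#'
#' Columns: `compound_id`, `direction` (`up`/`down`), `gene`, and optional
#' `mechanism`.
#'
#' @param path path to the library file.
#' @return a [DrugSignatureLibrary-class].
#' @export
readDrugLibrary <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("compound_id", "direction", "gene")
  if (!all(need %in% colnames(df)))
    stop("drug library needs columns: ", paste(need, collapse = ", "))
  if (!all(df$direction %in% c("up", "down")))
    stop("direction must be 'up' or 'down'")
  has_mech <- "mechanism" %in% colnames(df)
  compounds <- lapply(split(df, df$compound_id), function(d) {
    list(up = unique(d$gene[d$direction == "up"]),
         down = unique(d$gene[d$direction == "down"]),
         mechanism = if (has_mech) d$mechanism[1L] else NA_character_)
  })
  methods::new("DrugSignatureLibrary", compounds = compounds)
}

#' Write a drug-signature library as tab-delimited text
#'
#' @param library a [DrugSignatureLibrary-class].
#' @param path output path.
#' @export
writeDrugLibrary <- function(library, path) {
  stopifnot(methods::is(library, "DrugSignatureLibrary"))
  rows <- lapply(compoundIds(library), function(id) {
    cm <- library@compounds[[id]]
    mech <- if (is.null(cm$mechanism)) NA_character_ else cm$mechanism
    rbind(
      if (length(cm$up)) data.frame(compound_id = id, direction = "up",
                                    gene = cm$up, mechanism = mech),
      if (length(cm$down)) data.frame(compound_id = id, direction = "down",
                                      gene = cm$down, mechanism = mech))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
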