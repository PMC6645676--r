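#' Load an ontology from an OBO 1.2 file
#'
#' Parses `[Term]` stanzas (fields `id`, `name`, `is_a`,
#' `relationship: part_of`), skips obsolete terms and edges pointing to
#' unknown or obsolete terms, and validates acyclicity (a cycle is an
#' error listing the terms involved).
#'
#' @param path path to an OBO file.
#' @return an [OntologyDAG-class].
#' @export
loadOBO <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(); nms <- character()
  edges <- list()
  for (i in seq_along(starts)) {
    blk <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    blk <- blk[nzchar(blk) & !startsWith(blk, "[")]
    getv <- function(key) sub(paste0("^", key, ":\\s*"), "",
                              blk[startsWith(blk, paste0(key, ":"))])
    id <- getv("id")
    if (!length(id)) next
    id <- id[1L]
    if (any(grepl("^is_obsolete:\\s*true", blk))) next
    nm <- getv("name")
    ids <- c(ids, id)
    nms <- c(nms, if (length(nm)) nm[1L] else id)
    for (tgt in getv("is_a")) {
      parent <- trimws(sub("!.*$", "", tgt))
      edges[[length(edges) + 1L]] <- c(id, parent, "is_a")
    }
    rels <- getv("relationship")
    for (r in rels) {
      r <- trimws(sub("!.*$", "", r))
      pieces <- strsplit(r, "\\s+")[[1L]]
      if (length(pieces) >= 2L && pieces[1L] == "part_of")
        edges[[length(edges) + 1L]] <- c(ids[length(ids)], pieces[2L],
                                         "part_of")
    }
  }
  if (anyDuplicated(ids))
    stop("duplicate term identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  ed <- if (length(edges)) {
    e <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
    colnames(e) <- c("child", "parent", "relation")
    e[e$parent %in% ids, , drop = FALSE]
  } else data.frame(child = character(), parent = character(),
                    relation = character())
  methods::new("OntologyDAG", terms = ids,
               names = stats::setNames(nms, ids), edges = ed)
}

#' Write an ontology to an OBO 1.2 file
#'
#' @param dag an [OntologyDAG-class].
#' @param path output path.
#' @export
writeOBO <- function(dag, path) {
  stopifnot(methods::is(dag, "OntologyDAG"))
  ed <- ontologyEdges(dag)
  out <- c("format-version: 1.2", "")
  for (t in ontologyTerms(dag)) {
    out <- c(out, "[Term]", paste0("id: ", t),
             paste0("name: ", termNames(dag)[[t]]))
    mine <- ed[ed$child == t, , drop = FALSE]
    for (i in seq_len(nrow(mine))) {
      out <- c(out, if (mine$relation[i] == "is_a")
        paste0("is_a: ", mine$parent[i])
        else paste0("relationship: part_of ", mine$parent[i]))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

# Wang S-values for a term: contribution of every ancestor (including the
# term itself) to the term's semantics. S(term) = 1; for an ancestor t,
# S(t) = max over child-edges (c -> t) on paths toward the term of
# w(relation) * S(c). Returns a named vector over the ancestor closure.
.wangSValues <- function(term, dag, weights) {
  ed <- dag@edges
  parentsOf <- split(seq_len(nrow(ed)), ed$child)
  # ancestor closure by BFS over child -> parent edges
  closure <- term
  frontier <- term
  while (length(frontier)) {
    idx <- unlist(parentsOf[frontier], use.names = FALSE)
    nxt <- setdiff(unique(ed$parent[idx]), closure)
    closure <- c(closure, nxt)
    frontier <- nxt
  }
  sub <- ed[ed$child %in% closure & ed$parent %in% closure, , drop = FALSE]
  s <- stats::setNames(rep(-Inf, length(closure)), closure)
  s[term] <- 1
  # topological order within the closure (children before parents)
  pending <- stats::setNames(integer(length(closure)), closure)
  tab <- table(sub$parent)
  pending[names(tab)] <- as.integer(tab)
  queue <- names(pending)[pending == 0L]
  order_out <- character()
  childEdges <- split(seq_len(nrow(sub)), sub$parent)
  parentEdges <- split(seq_len(nrow(sub)), sub$child)
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    order_out <- c(order_out, t)
    for (i in parentEdges[[t]]) {
      p <- sub$parent[i]
      pending[[p]] <- pending[[p]] - 1L
      if (pending[[p]] == 0L) queue <- c(queue, p)
    }
  }
  for (t in order_out) {
    if (t == term) next
    idx <- childEdges[[t]]
    s[t] <- max(weights[sub$relation[idx]] * s[sub$child[idx]])
  }
  s
}

#' Wang semantic similarity between two ontology terms
#'
#' Corpus-free graph-based similarity: each term's semantics are the
#' relation-weighted contributions of its ancestors (`is_a` weight 0.8,
#' `part_of` weight 0.6 by default, max over paths), and
#' `sim(a, b) = sum over shared ancestors of (S_a(t) + S_b(t)) /
#' (SV(a) + SV(b))`. Always 1 on the diagonal, 0 for terms sharing no
#' ancestor.
#'
#' @param a,b term identifiers present in `dag`.
#' @param dag an [OntologyDAG-class].
#' @param weights named numeric edge weights (default
#'   `c(is_a = 0.8, part_of = 0.6)`).
#' @return similarity in \[0, 1\].
#' @export
termSimilarity <- function(a, b, dag,
                           weights = c(is_a = 0.8, part_of = 0.6)) {
  stopifnot(methods::is(dag, "OntologyDAG"))
  unknown <- setdiff(c(a, b), dag@terms)
  if (length(unknown)) stop("unknown term(s): ",
                            paste(unknown, collapse = ", "))
  sa <- .wangSValues(a, dag, weights)
  sb <- .wangSValues(b, dag, weights)
  shared <- intersect(names(sa), names(sb))
  if (!length(shared)) return(0)
  sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
}

#' Pairwise similarity matrix and best-match-average between two term sets
#'
#' @param set1,set2 non-empty character vectors of term identifiers.
#' @inheritParams termSimilarity
#' @return list with `matrix` (|set1| x |set2| similarities) and `bma`,
#'   the best-match average `(mean(row maxima) + mean(column maxima)) / 2`.
#' @export
termSetSimilarity <- function(set1, set2, dag,
                              weights = c(is_a = 0.8, part_of = 0.6)) {
  if (!length(set1) || !length(set2)) stop("term sets must be non-empty")
  set1 <- unique(set1); set2 <- unique(set2)
  sim <- matrix(NA_real_, length(set1), length(set2),
                dimnames = list(set1, set2))
  sv <- lapply(stats::setNames(union(set1, set2), union(set1, set2)),
               .wangSValues, dag = dag, weights = weights)
  for (i in set1) for (j in set2) {
    shared <- intersect(names(sv[[i]]), names(sv[[j]]))
    sim[i, j] <- if (!length(shared)) 0 else
      sum(sv[[i]][shared] + sv[[j]][shared]) /
        (sum(sv[[i]]) + sum(sv[[j]]))
  }
  list(matrix = sim,
       bma = (mean(apply(sim, 1L, max)) + mean(apply(sim, 2L, max))) / 2)
}

#' Phenotype-specific ontology terms by cross-set dissimilarity
#'
#' A term enriched in one phenotype is called *specific* when its maximum
#' Wang similarity against every term enriched in the opposite phenotype
#' falls strictly below `cutoff` (default 0.2) — i.e. it has low
#' association with all of the opposite phenotype's processes. Pairs above
#' `highCutoff` (default 0.8) are additionally reported as high-similarity
#' matches.
#'
#' @param termsA terms enriched in the phenotype of interest (e.g. ruptured).
#' @param termsB terms enriched in the opposite phenotype.
#' @inheritParams termSimilarity
#' @param cutoff specificity threshold on the maximum cross-similarity.
#' @param highCutoff threshold flagging highly similar pairs.
#' @return list with `report` (data.frame: `term`, `max_similarity`,
#'   `best_match`, `specific`), `high_pairs` (data.frame of pairs with
#'   similarity > `highCutoff`) and the full similarity `matrix`.
#' @export
specificTerms <- function(termsA, termsB, dag, cutoff = 0.2,
                          highCutoff = 0.8,
                          weights = c(is_a = 0.8, part_of = 0.6)) {
  res <- termSetSimilarity(termsA, termsB, dag, weights)
  sim <- res$matrix
  max_sim <- apply(sim, 1L, max)
  best <- colnames(sim)[apply(sim, 1L, which.max)]
  report <- data.frame(term = rownames(sim), max_similarity = max_sim,
                       best_match = best, specific = max_sim < cutoff,
                       row.names = NULL)
  hi <- which(sim > highCutoff, arr.ind = TRUE)
  high_pairs <- data.frame(term_a = rownames(sim)[hi[, 1L]],
                           term_b = colnames(sim)[hi[, 2L]],
                           similarity = sim[hi])
  list(report = report, high_pairs = high_pairs, matrix = sim)
}
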