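# Independent brute-force oracles used to validate the analytical
# implementations on small inputs. These deliberately avoid the package's
# own code paths.

# triple-loop topological overlap
tomOracle <- function(a) {
  n <- nrow(a)
  diag(a) <- 0
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    L <- 0
    for (u in seq_len(n)) if (u != i && u != j) L <- L + a[i, u] * a[u, j]
    ki <- sum(a[i, ]); kj <- sum(a[j, ])
    tom[i, j] <- (L + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  tom
}

# exact hypergeometric upper tail by enumeration of all query-sized subsets
hyperOracle <- function(universe_size, set_size, query_size, overlap) {
  universe <- seq_len(universe_size)
  inset <- seq_len(set_size)
  subs <- utils::combn(universe_size, query_size)
  hits <- apply(subs, 2L, function(s) sum(s %in% inset) >= overlap)
  mean(hits)
}

# exact two-sided Mann-Whitney p by enumeration of all group labelings
mannWhitneyOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pool <- c(x, y)
  u_of <- function(idx) {
    xx <- pool[idx]; yy <- pool[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_of(seq_len(nx))
  all_u <- apply(utils::combn(nx + ny, nx), 2L, u_of)
  p_lo <- mean(all_u <= u_obs)
  p_hi <- mean(all_u >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Wang S-values by exhaustive path enumeration: S(anc) is the max over all
# directed child->parent paths from `term` to `anc` of the product of edge
# weights; the similarity then follows the same combination formula.
wangOracleS <- function(term, edges, weights) {
  paths_from <- function(t) {
    out <- list()
    rec <- function(node, value) {
      out[[length(out) + 1L]] <<- c(node = node, value = value)
      up <- edges[edges$child == node, , drop = FALSE]
      for (i in seq_len(nrow(up)))
        rec(up$parent[i], value * weights[[up$relation[i]]])
    }
    rec(t, 1)
    out
  }
  visits <- paths_from(term)
  s <- list()
  for (v in visits) {
    nd <- v[["node"]]; val <- as.numeric(v[["value"]])
    if (is.null(s[[nd]]) || val > s[[nd]]) s[[nd]] <- val
  }
  unlist(s)
}

wangOracleSim <- function(a, b, edges, weights = c(is_a = 0.8, part_of = 0.6)) {
  sa <- wangOracleS(a, edges, weights)
  sb <- wangOracleS(b, edges, weights)
  shared <- intersect(names(sa), names(sb))
  if (!length(shared)) return(0)
  sum(sa[shared] + sb[shared]) / (sum(sa) + sum(sb))
}

# random DAG on n terms: term i may attach to earlier terms (guaranteed
# acyclic); always at least one edge per non-root term so roots are reachable
randomDAG <- function(n, p_extra = 0.3) {
  terms <- sprintf("T%02d", seq_len(n))
  edges <- data.frame(child = character(), parent = character(),
                      relation = character())
  for (i in 2:n) {
    parents <- sample(seq_len(i - 1L), 1L + stats::rbinom(1L, i - 2L, p_extra))
    rel <- sample(c("is_a", "part_of"), length(parents), replace = TRUE)
    edges <- rbind(edges, data.frame(child = terms[i],
                                     parent = terms[parents],
                                     relation = rel))
  }
  methods::new("OntologyDAG", terms = terms,
               names = stats::setNames(terms, terms), edges = edges)
}

# small deterministic expression fixture writer
writeTinyMatrix <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# adjusted Rand index (independent of any clustering package)
ariOracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n2
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}
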