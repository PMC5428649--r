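# Independent oracles and tiny fixture builders, kept deliberately
# naive (explicit loops, dense algebra) so they share no code path
# with the implementation they check.

# loop-based tag enrichment oracle: walk the ranking, collect tag
# positions, then evaluate both maxima term by term
oracle_ks <- function(tags, ranked) {
  pos <- integer(0)
  for (i in seq_along(ranked)) {
    if (ranked[i] %in% tags) pos <- c(pos, i)
  }
  t <- length(pos)
  n <- length(ranked)
  a <- -Inf
  b <- -Inf
  for (j in seq_len(t)) {
    if (j / t - pos[j] / n > a) a <- j / t - pos[j] / n
    if (pos[j] / n - (j - 1) / t > b) b <- pos[j] / n - (j - 1) / t
  }
  if (a > b) a else -b
}

# dense closed-form steady state: chi = r (I - (1-r) P)^{-1} chi0
oracle_rwr <- function(P, chi0, r) {
  P <- as.matrix(P)
  solve(diag(nrow(P)) - (1 - r) * P, r * chi0)
}

# random connected undirected graph as a column-stochastic operator:
# a spanning chain guarantees connectivity, plus random extra edges
random_stochastic_operator <- function(n, extra = n) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  for (k in seq_len(extra)) {
    ij <- sample.int(n, 2)
    A[ij[1], ij[2]] <- A[ij[2], ij[1]] <- 1
  }
  diag(A) <- 0
  P <- sweep(A, 2, colSums(A), "/")
  rownames(P) <- colnames(P) <- sprintf("v%03d", seq_len(n))
  P
}

# brute-force edge filter + flood-fill largest component, returning
# node and edge counts of the surviving graph
oracle_filter_component <- function(edges, threshold) {
  keep <- edges[edges$confidence > threshold &
                  edges$node_a != edges$node_b, , drop = FALSE]
  key <- ifelse(keep$node_a < keep$node_b,
                paste(keep$node_a, keep$node_b),
                paste(keep$node_b, keep$node_a))
  keep <- keep[!duplicated(key), , drop = FALSE]
  nodes <- unique(c(keep$node_a, keep$node_b))
  adj <- lapply(setNames(vector("list", length(nodes)), nodes),
                function(x) character(0))
  for (i in seq_len(nrow(keep))) {
    a <- keep$node_a[i]; b <- keep$node_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  best <- character(0)
  for (start in nodes) {
    if (seen[start]) next
    queue <- start
    comp <- character(0)
    seen[start] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in adj[[v]]) {
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    if (length(comp) > length(best)) best <- comp
  }
  in_best <- keep$node_a %in% best & keep$node_b %in% best
  list(n_nodes = length(best), n_edges = sum(in_best))
}

# wrap a plain stochastic matrix as a propagation_network so the
# z-score machinery can be exercised on hand-built operators
as_network <- function(P) {
  structure(list(node_ids = rownames(P),
                 P = Matrix::Matrix(P, sparse = TRUE),
                 n_nodes = nrow(P), n_edges = NA_integer_,
                 confidence_threshold = NA_real_, rescued = character(0)),
            class = "propagation_network")
}

# tiny two-condition expression matrix with explicit values
tiny_expression <- function(values, n_rep = 2) {
  expression_matrix(values, data.frame(
    sample_id = colnames(values),
    condition = rep(c("control", "treated"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2)))
}

# collection of uniformly random rankings over a shared universe
random_collection <- function(n_instances, universe, seed,
                              compound_names = NULL) {
  instances <- lapply(seq_len(n_instances), function(i) {
    reference_instance(sprintf("r%03d", i), sample(universe),
                       compound_name = if (is.null(compound_names))
                         sprintf("c%03d", i) else compound_names[i])
  })
  reference_collection(instances)
}
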