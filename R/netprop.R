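#' Read a weighted edge list
#'
#' Three tab-delimited columns: node_a, node_b, confidence. A header
#' row is detected automatically (third field not parseable as a
#' number). Identifiers are opaque strings.
#'
#' @param path file path.
#' @return data frame with columns `node_a`, `node_b`, `confidence`.
#' @export
read_edge_list <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  has_header <- length(first) >= 3L &&
    is.na(suppressWarnings(as.numeric(first[3L])))
  tab <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  tab <- tab[, 1:3]
  names(tab) <- c("node_a", "node_b", "confidence")
  tab$node_a <- as.character(tab$node_a)
  tab$node_b <- as.character(tab$node_b)
  tab$confidence <- as.numeric(tab$confidence)
  tab
}

#' Read a gene set (one identifier per line)
#'
#' @param path file path.
#' @return character vector.
#' @export
read_gene_set <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines[nzchar(trimws(lines))]
}

#' Build a column-normalised propagation network from an edge list
#'
#' Keeps edges with confidence strictly above `confidence_threshold`
#' (default 0.9); STRING-style 0-999 scores are auto-detected and
#' rescaled to 0-1. Each `rescue_targets` node whose edges were all
#' filtered out is re-attached through its single maximum-confidence
#' edge. Self-loops and duplicate edges are dropped, only the largest
#' connected component is retained, and the adjacency matrix of the
#' remaining simple undirected graph (unweighted after thresholding)
#' is column-normalised into the transition operator P.
#'
#' @param edges data frame as from [read_edge_list()].
#' @param confidence_threshold keep edges with confidence above this.
#' @param rescue_targets identifiers to re-attach via their best edge.
#' @return An object of class `propagation_network` with `node_ids`,
#'   sparse operator `P` (columns sum to 1), edge/node counts and the
#'   rescued node ids.
#' @export
build_network <- function(edges, confidence_threshold = 0.9,
                          rescue_targets = character(0)) {
  stopifnot(all(c("node_a", "node_b", "confidence") %in% names(edges)))
  conf <- edges$confidence
  if (any(!is.finite(conf)) || any(conf < 0)) {
    stop("confidence scores must be finite and >= 0", call. = FALSE)
  }
  if (max(conf) > 1) conf <- conf / 1000  # STRING 0-999 scale
  keep <- conf > confidence_threshold
  rescued <- character(0)
  if (length(rescue_targets) > 0L) {
    present <- unique(c(edges$node_a[keep], edges$node_b[keep]))
    for (tg in setdiff(unique(rescue_targets), present)) {
      incident <- which(edges$node_a == tg | edges$node_b == tg)
      if (length(incident) == 0L) next
      best <- incident[which.max(conf[incident])]
      if (!keep[best]) {
        keep[best] <- TRUE
        rescued <- c(rescued, tg)
      }
    }
  }
  kept <- edges[keep, , drop = FALSE]
  kept <- kept[kept$node_a != kept$node_b, , drop = FALSE]
  if (nrow(kept) == 0L) {
    stop("no edges survive the confidence filter", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(kept[, c("node_a", "node_b")],
                                     directed = FALSE)
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  if (igraph::vcount(g) < 2L) {
    stop("largest component has fewer than 2 nodes", call. = FALSE)
  }
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  deg <- Matrix::colSums(A)
  P <- A %*% Matrix::Diagonal(x = 1 / deg)
  dimnames(P) <- dimnames(A)
  structure(list(node_ids = rownames(A), P = P,
                 n_nodes = nrow(A), n_edges = igraph::ecount(g),
                 confidence_threshold = confidence_threshold,
                 rescued = rescued,
                 n_dropped_nodes = comp$n - igraph::vcount(g) +
                   (length(unique(c(edges$node_a, edges$node_b))) - comp$n)),
            class = "propagation_network")
}

#' @export
print.propagation_network <- function(x, ...) {
  cat(sprintf("<propagation_network> %d nodes, %d edges (confidence > %g)\n",
              x$n_nodes, x$n_edges, x$confidence_threshold))
  invisible(x)
}

#' Build a seed vector over the network nodes
#'
#' Disease genes conventionally get strength 1 and drug-target genes
#' strength 0.01; genes absent from the network are dropped with a
#' message counting them.
#'
#' @param network a [build_network()] result.
#' @param genes identifiers to seed.
#' @param strength seed strength (1 for disease, 0.01 for drug
#'   targets).
#' @param quiet suppress the dropped-gene message.
#' @return Named numeric vector over `network$node_ids`.
#' @export
seed_vector <- function(network, genes, strength = 1, quiet = FALSE) {
  stopifnot(inherits(network, "propagation_network"))
  genes <- unique(as.character(genes))
  hit <- genes %in% network$node_ids
  if (!quiet && any(!hit)) {
    message(sprintf("seed_vector: %d of %d gene(s) not in the network, dropped",
                    sum(!hit), length(genes)))
  }
  chi0 <- setNames(numeric(network$n_nodes), network$node_ids)
  chi0[genes[hit]] <- strength
  chi0
}

as_operator <- function(P) {
  if (inherits(P, "propagation_network")) P$P else P
}

#' Random walk with restart to steady state
#'
#' Iterates `chi <- (1 - r) * P %*% chi + r * chi0` from `chi = chi0`
#' until the L1 change falls below `tol`. With column-stochastic P the
#' iteration is a contraction with factor `1 - r`, so it converges and
#' conserves total mass: `sum(chi) = sum(chi0)`.
#'
#' @param P a `propagation_network` or a column-stochastic matrix.
#' @param chi0 seed vector matching P's dimension (see
#'   [seed_vector()]).
#' @param r restart probability in (0, 1); 0.3 is a well-working
#'   default for protein-interaction networks.
#' @param tol L1 stopping tolerance on the change per iteration.
#' @param max_iter iteration cap; exceeding it is an error that
#'   reports the final residual.
#' @return An object of class `effect_vector`: `chi` (named steady
#'   state), `r`, `iterations`, `residual`, and the seeds `chi0`.
#' @export
rwr <- function(P, chi0, r = 0.3, tol = 1e-10, max_iter = 10000L) {
  assert_scalar_number(r, "r")
  if (r <= 0 || r >= 1) stop("`r` must lie in (0, 1)", call. = FALSE)
  op <- as_operator(P)
  if (length(chi0) != nrow(op)) {
    stop("seed vector length does not match the operator dimension",
         call. = FALSE)
  }
  if (any(chi0 < 0)) stop("seed strengths must be >= 0", call. = FALSE)
  chi <- as.numeric(chi0)
  chi0_num <- as.numeric(chi0)
  residual <- Inf
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    chi_new <- (1 - r) * as.numeric(op %*% chi) + r * chi0_num
    residual <- sum(abs(chi_new - chi))
    chi <- chi_new
    iterations <- it
    if (residual < tol) break
  }
  if (residual >= tol) {
    stop(sprintf("rwr did not converge in %d iterations (L1 residual %.3g)",
                 max_iter, residual), call. = FALSE)
  }
  names(chi) <- names(chi0) %||% rownames(op)
  structure(list(chi = chi, chi0 = chi0_num, r = r,
                 iterations = iterations, residual = residual),
            class = "effect_vector")
}

#' @export
print.effect_vector <- function(x, ...) {
  cat(sprintf(
    "<effect_vector> %d nodes, r = %g, %d iterations (L1 residual %.2g)\n",
    length(x$chi), x$r, x$iterations, x$residual))
  invisible(x)
}

as_chi <- function(x) {
  if (inherits(x, "effect_vector")) x$chi else x
}

#' Inner-product effect score of two propagated vectors
#'
#' `s = <chi_disease, chi_drug>` measures how much the drug-affected
#' and disease-affected subnetworks overlap; it is non-negative for
#' non-negative vectors.
#'
#' @param chi_disease,chi_drug [rwr()] results (or named numeric
#'   vectors) over the same node set.
#' @return A single number, the inner product.
#' @export
effect_score <- function(chi_disease, chi_drug) {
  a <- as_chi(chi_disease)
  b <- as_chi(chi_drug)
  if (length(a) != length(b) ||
      (!is.null(names(a)) && !is.null(names(b)) &&
       !identical(names(a), names(b)))) {
    stop("effect vectors are not indexed by the same nodes", call. = FALSE)
  }
  sum(a * b)
}

# adjoint propagation of chi_disease: with K = r (I - (1-r) P)^{-1},
# <chi_disease, K chi0_drug> = <K^T chi_disease, chi0_drug>, so one RWR
# on t(P) seeded by chi_disease turns every null effect score into a
# subset sum over its target nodes.
adjoint_weights <- function(network, chi_disease, r, tol, max_iter) {
  op <- Matrix::t(as_operator(network))
  rwr(op, as_chi(chi_disease), r = r, tol = tol, max_iter = max_iter)$chi
}

#' Standardise an effect score against random target sets
#'
#' Draws `n_random` uniform random node subsets of the same size as
#' the drug-target set, computes their effect scores against the same
#' disease effect vector, and returns
#' `Z = (s - null_mean) / null_sd` with the sample (n-1) standard
#' deviation. Z greater than 3 is conventionally read as a
#' significantly stronger-than-random effect.
#'
#' The default `method = "adjoint"` evaluates the null scores through
#' the exact linear-algebra identity
#' `<chi_disease, K chi0> = <K' chi_disease, chi0>` (one propagation of
#' the disease vector through the transposed operator, then subset
#' sums); `method = "direct"` runs one full [rwr()] per random set.
#' Both use identical random subsets for a given seed and agree to the
#' iteration tolerance.
#'
#' @param network a [build_network()] result.
#' @param chi_disease propagated disease vector ([rwr()] result).
#' @param s observed effect score of the drug-target set.
#' @param n_targets size of the drug-target set (post network
#'   intersection).
#' @param n_random number of random counterparts (default 1000).
#' @param seed RNG seed; results are fully reproducible from it.
#' @param target_strength drug seed strength (default 0.01).
#' @param r,tol,max_iter propagation parameters, shared with the
#'   observed score.
#' @param method `"adjoint"` (default) or `"direct"`.
#' @param universe optional node-id subset to draw random targets
#'   from; default all network nodes.
#' @param label free-text label carried into the result.
#' @return An object of class `synergy_result`: `label`,
#'   `target_count`, `effect_score`, `null_mean`, `null_sd`, `z_score`
#'   (`NA` with a warning when the null sd is 0), `n_random`, `seed`,
#'   and the vector of `null_scores`.
#' @export
z_score <- function(network, chi_disease, s, n_targets,
                    n_random = 1000L, seed = 1L, target_strength = 0.01,
                    r = 0.3, tol = 1e-10, max_iter = 10000L,
                    method = c("adjoint", "direct"), universe = NULL,
                    label = NA_character_) {
  method <- match.arg(method)
  stopifnot(inherits(network, "propagation_network"))
  assert_scalar_number(n_targets, "n_targets", lower = 1)
  assert_scalar_number(n_random, "n_random", lower = 2)
  pool <- if (is.null(universe)) {
    seq_len(network$n_nodes)
  } else {
    idx <- match(universe, network$node_ids)
    if (anyNA(idx)) stop("universe contains unknown node ids", call. = FALSE)
    idx
  }
  if (n_targets > length(pool)) {
    stop("n_targets exceeds the sampling universe", call. = FALSE)
  }
  draws <- with_rng_seed(seed, {
    lapply(seq_len(n_random), function(i) sample(pool, n_targets))
  })
  null_scores <- if (method == "adjoint") {
    w <- adjoint_weights(network, chi_disease, r, tol, max_iter)
    vapply(draws, function(idx) target_strength * sum(w[idx]), numeric(1))
  } else {
    chi_d <- as_chi(chi_disease)
    vapply(draws, function(idx) {
      chi0 <- numeric(network$n_nodes)
      chi0[idx] <- target_strength
      sum(chi_d * rwr(network, chi0, r = r, tol = tol,
                      max_iter = max_iter)$chi)
    }, numeric(1))
  }
  null_mean <- mean(null_scores)
  null_sd <- sd(null_scores)
  z <- if (null_sd == 0) {
    warning("null standard deviation is 0; z-score undefined", call. = FALSE)
    NA_real_
  } else {
    (s - null_mean) / null_sd
  }
  structure(list(label = label, target_count = as.integer(n_targets),
                 effect_score = s, null_mean = null_mean, null_sd = null_sd,
                 z_score = z, n_random = as.integer(n_random),
                 seed = as.integer(seed), null_scores = null_scores),
            class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf(
    "<synergy_result> %s: %d targets, s = %.4g, Z = %.3f (null %d draws)\n",
    x$label, x$target_count, x$effect_score, x$z_score, x$n_random))
  invisible(x)
}

#' @export
as.data.frame.synergy_result <- function(x, ...) {
  data.frame(label = x$label, target_number = x$target_count,
             effect_score = x$effect_score, null_mean = x$null_mean,
             null_sd = x$null_sd, z_score = x$z_score,
             stringsAsFactors = FALSE)
}

#' Mixture-vs-component synergy table
#'
#' Scores each component's target set and the mixture against a
#' disease gene set on a shared network with a shared propagation and
#' null protocol, and reports one row per entry, mixture first. The
#' default mixture is the union of the component target sets (a
#' modelling choice; a separately measured mixture set can be supplied
#' instead). Reported target numbers are counts after intersection
#' with the network; a set that is empty after intersection yields a
#' flagged (all-`NA`) row while the others are still computed.
#'
#' @param network a [build_network()] result.
#' @param disease_genes identifiers seeding the disease vector
#'   (strength `disease_strength`, default 1).
#' @param components named list of character vectors, one per
#'   component (>= 1; synergy needs >= 2).
#' @param mixture `"union"` (default) or a character vector of the
#'   mixture's own target genes.
#' @param disease_strength,target_strength seed strengths.
#' @inheritParams z_score
#' @return data frame with columns `label`, `target_number`,
#'   `effect_score`, `null_mean`, `null_sd`, `z_score`; mixture row
#'   first.
#' @export
synergy_table <- function(network, disease_genes, components,
                          mixture = "union", r = 0.3, n_random = 1000L,
                          seed = 1L, disease_strength = 1,
                          target_strength = 0.01, tol = 1e-10,
                          max_iter = 10000L,
                          method = c("adjoint", "direct")) {
  method <- match.arg(method)
  stopifnot(inherits(network, "propagation_network"))
  if (!is.list(components) || length(components) < 1L ||
      is.null(names(components)) || any(!nzchar(names(components)))) {
    stop("`components` must be a non-empty named list of gene vectors",
         call. = FALSE)
  }
  mixture_set <- if (identical(mixture, "union")) {
    unique(unlist(components, use.names = FALSE))
  } else {
    as.character(mixture)
  }
  sets <- c(list(mixture = mixture_set), components)
  chi_disease <- rwr(network,
                     seed_vector(network, disease_genes, disease_strength),
                     r = r, tol = tol, max_iter = max_iter)
  rows <- lapply(seq_along(sets), function(i) {
    label <- names(sets)[i]
    targets <- intersect(unique(sets[[i]]), network$node_ids)
    if (length(targets) == 0L) {
      warning(sprintf("target set '%s' is empty after network intersection",
                      label), call. = FALSE)
      return(data.frame(label = label, target_number = 0L,
                        effect_score = NA_real_, null_mean = NA_real_,
                        null_sd = NA_real_, z_score = NA_real_,
                        stringsAsFactors = FALSE))
    }
    chi_drug <- rwr(network,
                    seed_vector(network, targets, target_strength,
                                quiet = TRUE),
                    r = r, tol = tol, max_iter = max_iter)
    s <- effect_score(chi_disease, chi_drug)
    zr <- z_score(network, chi_disease, s, n_targets = length(targets),
                  n_random = n_random, seed = child_seed(seed, i),
                  target_strength = target_strength, r = r, tol = tol,
                  max_iter = max_iter, method = method, label = label)
    as.data.frame(zr)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
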