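#' Scenario for a replicated treated-vs-control expression experiment
#'
#' Describes the planted truth for [simulate_expression()]: which
#' probes are up- or down-regulated under treatment, by what multiple,
#' and under how much multiplicative log-normal noise. The replicate
#' design mirrors a two-replicate microarray experiment with a
#' vehicle (DMSO) control.
#'
#' @param n_probes probe universe size.
#' @param n_replicates replicates per condition (default 2).
#' @param planted_up,planted_down probe ids (character) or counts
#'   (single integers, sampled from the universe); must be disjoint.
#' @param effect multiplicative effect applied to planted probes
#'   (> 1); up probes are multiplied, down probes divided.
#' @param noise_sd standard deviation of the multiplicative
#'   log-normal noise on the natural-log scale (0 = noiseless).
#' @param baseline_meanlog,baseline_sdlog log-normal baseline of
#'   control intensities (MAS5-like positive scale).
#' @param treatment_label,control_label condition labels.
#' @param seed RNG seed; generation is a pure function of the
#'   scenario.
#' @return An object of class `expression_scenario`.
#' @export
expression_scenario <- function(n_probes = 1000L, n_replicates = 2L,
                                planted_up = 50L, planted_down = 50L,
                                effect = 4, noise_sd = 0.1,
                                baseline_meanlog = log(100),
                                baseline_sdlog = 0.8,
                                treatment_label = "treated",
                                control_label = "control",
                                seed = 1L) {
  if (effect <= 1) stop("`effect` must be > 1", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  probe_ids <- sprintf("p%04d", seq_len(n_probes))
  resolve <- function(x, exclude = character(0)) {
    if (is.character(x)) {
      if (!all(x %in% probe_ids)) {
        stop("planted probes outside the universe", call. = FALSE)
      }
      x
    } else {
      if (x > n_probes - length(exclude)) {
        stop("planted sets exceed n_probes", call. = FALSE)
      }
      with_rng_seed(child_seed(seed, 777), {
        sample(setdiff(probe_ids, exclude), x)
      })
    }
  }
  up <- resolve(planted_up)
  down <- resolve(planted_down, exclude = up)
  if (length(intersect(up, down)) > 0L) {
    stop("planted_up and planted_down overlap", call. = FALSE)
  }
  structure(list(n_probes = as.integer(n_probes), probe_ids = probe_ids,
                 n_replicates = as.integer(n_replicates),
                 planted_up = up, planted_down = down, effect = effect,
                 noise_sd = noise_sd, baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 treatment_label = treatment_label,
                 control_label = control_label, seed = as.integer(seed)),
            class = "expression_scenario")
}

#' Simulate a replicated expression matrix with planted signatures
#'
#' Control intensities are drawn per probe from the scenario's
#' log-normal baseline; treated replicates multiply planted up-probes
#' by the effect multiplier and divide planted down-probes by it, then
#' apply multiplicative log-normal noise per replicate. Deterministic
#' per scenario seed.
#'
#' @param scenario an [expression_scenario()].
#' @return An [expression_matrix()]; the scenario (with its planted
#'   truth) is attached as attribute `"scenario"`.
#' @export
simulate_expression <- function(scenario) {
  stopifnot(inherits(scenario, "expression_scenario"))
  with_rng_seed(scenario$seed, {
    n <- scenario$n_probes
    k <- scenario$n_replicates
    base <- rlnorm(n, scenario$baseline_meanlog, scenario$baseline_sdlog)
    fold <- rep(1, n)
    fold[match(scenario$planted_up, scenario$probe_ids)] <- scenario$effect
    fold[match(scenario$planted_down, scenario$probe_ids)] <-
      1 / scenario$effect
    noise <- function() {
      if (scenario$noise_sd == 0) rep(1, n)
      else exp(rnorm(n, 0, scenario$noise_sd))
    }
    ctrl <- vapply(seq_len(k), function(i) base * noise(), numeric(n))
    trt <- vapply(seq_len(k), function(i) base * fold * noise(), numeric(n))
    values <- cbind(ctrl, trt)
    colnames(values) <- c(
      sprintf("%s_r%d", scenario$control_label, seq_len(k)),
      sprintf("%s_r%d", scenario$treatment_label, seq_len(k)))
    rownames(values) <- scenario$probe_ids
    cm <- data.frame(
      sample_id = colnames(values),
      condition = rep(c(scenario$control_label, scenario$treatment_label),
                      each = k),
      replicate = rep(seq_len(k), 2L), stringsAsFactors = FALSE)
    out <- expression_matrix(values, cm)
    attr(out, "scenario") <- scenario
    out
  })
}

#' Simulate a reference collection with planted concordance
#'
#' Builds rank-ordered instances over a shared probe universe.
#' Concordant instances (`+1`) place the query signature's up tags at
#' positions drawn from the top decile of the ranking and its down
#' tags in the bottom decile; discordant instances (`-1`) invert
#' this; null instances (`0`) are uniform permutations.
#'
#' @param signature the query [build_signature()] whose tags are
#'   planted.
#' @param universe character probe universe covering all signature
#'   tags.
#' @param concordance integer vector in `{-1, 0, 1}`, one entry per
#'   instance.
#' @param compound_names per-instance compound names (recycled);
#'   defaults to one name per instance.
#' @param decile fraction of the ranking used as the planting zone
#'   (default 0.1).
#' @param seed RNG seed.
#' @return A [reference_collection()]; planted concordance is attached
#'   as attribute `"concordance"`.
#' @export
simulate_reference_collection <- function(signature, universe, concordance,
                                          compound_names = NULL,
                                          decile = 0.1, seed = 1L) {
  if (!all(concordance %in% c(-1L, 0L, 1L))) {
    stop("concordance entries must be -1, 0 or 1", call. = FALSE)
  }
  universe <- as.character(universe)
  tags <- c(signature$up_tags, signature$down_tags)
  if (!all(tags %in% universe)) {
    stop("universe does not cover all signature tags", call. = FALSE)
  }
  n <- length(universe)
  zone <- max(ceiling(decile * n),
              length(signature$up_tags), length(signature$down_tags))
  if (2L * zone > n) {
    stop("universe too small for the planting zone", call. = FALSE)
  }
  n_instances <- length(concordance)
  compound_names <- compound_names %||% sprintf("cmpd_%03d",
                                                seq_len(n_instances))
  compound_names <- rep_len(compound_names, n_instances)
  instances <- with_rng_seed(seed, {
    lapply(seq_len(n_instances), function(i) {
      conc <- concordance[i]
      ranked <- character(n)
      if (conc == 0L) {
        ranked <- sample(universe)
      } else {
        top_set <- if (conc == 1L) signature$up_tags else signature$down_tags
        bottom_set <- if (conc == 1L) signature$down_tags else
          signature$up_tags
        top_pos <- sort(sample(seq_len(zone), length(top_set)))
        bottom_pos <- sort(sample(seq.int(n - zone + 1L, n),
                                  length(bottom_set)))
        ranked[top_pos] <- sample(top_set)
        ranked[bottom_pos] <- sample(bottom_set)
        rest <- setdiff(universe, c(top_set, bottom_set))
        ranked[ranked == ""] <- sample(rest)
      }
      reference_instance(sprintf("inst_%03d", i), ranked,
                         compound_name = compound_names[i],
                         dose = "10 uM", cell_line = "MCF7",
                         batch = sprintf("b%02d", (i - 1L) %/% 10L + 1L))
    })
  })
  out <- reference_collection(instances)
  attr(out, "concordance") <- concordance
  out
}

#' Scenario for a scale-free network with a planted disease module
#'
#' Describes a preferential-attachment graph whose disease module is
#' densified to a stated edge density, plus component target sets with
#' controlled overlap against that module. Degree heterogeneity of the
#' scale-free topology is what stresses the propagation null; an
#' Erdos-Renyi alternative is available for contrast experiments.
#'
#' @param n_nodes node count.
#' @param attachment edges per new node in preferential attachment
#'   (ignored for `topology = "erdos_renyi"`).
#' @param module_size disease-module size.
#' @param module_density target intra-module edge density after
#'   densification (fraction of possible pairs).
#' @param targets named list of specs `list(size=, overlap=,
#'   module_part=NULL, min_distance=NULL)`: each component draws
#'   `round(overlap * size)` targets from the module (or from the
#'   module positions in `module_part`), the rest from outside, at
#'   least `min_distance` hops from the module when given.
#' @param topology `"scale_free"` (default) or `"erdos_renyi"`.
#' @param edge_prob edge probability for the Erdos-Renyi alternative.
#' @param confidence_range interval confidences are drawn from;
#'   the default keeps every edge above the 0.9 filter so the planted
#'   graph survives [build_network()] intact.
#' @param seed RNG seed.
#' @return An object of class `network_scenario`.
#' @export
network_scenario <- function(n_nodes = 500L, attachment = 3L,
                             module_size = 30L, module_density = 0.25,
                             targets = list(),
                             topology = c("scale_free", "erdos_renyi"),
                             edge_prob = 0.02,
                             confidence_range = c(0.905, 0.999),
                             seed = 1L) {
  topology <- match.arg(topology)
  if (module_size > n_nodes) {
    stop("module_size exceeds n_nodes", call. = FALSE)
  }
  for (tg in targets) {
    ov <- tg$overlap %||% 0
    if (ov < 0 || ov > 1) stop("overlap fractions must lie in [0, 1]",
                               call. = FALSE)
  }
  structure(list(n_nodes = as.integer(n_nodes),
                 attachment = as.integer(attachment),
                 module_size = as.integer(module_size),
                 module_density = module_density, targets = targets,
                 topology = topology, edge_prob = edge_prob,
                 confidence_range = confidence_range,
                 seed = as.integer(seed)),
            class = "network_scenario")
}

#' Simulate a confidence-weighted network with planted structure
#'
#' Generates the scenario's topology, densifies a randomly placed
#' disease module with extra intra-module edges up to the stated
#' density, samples component target sets at their stated overlap
#' fractions with the module, and assigns edge confidences so that
#' default thresholding keeps the graph intact. The returned manifest
#' records all planted truth so tests never re-derive it.
#'
#' @param scenario a [network_scenario()].
#' @return List with `edges` (data frame `node_a`, `node_b`,
#'   `confidence`), `disease_module`, `target_sets` (named list) and
#'   `manifest` (planted truth, JSON-serialisable).
#' @export
simulate_network <- function(scenario) {
  stopifnot(inherits(scenario, "network_scenario"))
  with_rng_seed(scenario$seed, {
    n <- scenario$n_nodes
    g <- if (scenario$topology == "scale_free") {
      igraph::sample_pa(n, power = 1, m = scenario$attachment,
                        directed = FALSE)
    } else {
      igraph::sample_gnp(n, scenario$edge_prob)
    }
    node_ids <- sprintf("n%04d", seq_len(n))
    module_idx <- sort(sample.int(n, scenario$module_size))
    # densify the module to the requested intra-module edge density
    pairs <- combn(module_idx, 2L)
    want <- round(scenario$module_density * ncol(pairs))
    have <- which(igraph::get_edge_ids(g, as.vector(pairs)) != 0)
    missing_pairs <- setdiff(seq_len(ncol(pairs)), have)
    n_add <- max(0L, want - length(have))
    if (n_add > 0L) {
      add <- missing_pairs[sample.int(length(missing_pairs),
                                      min(n_add, length(missing_pairs)))]
      g <- igraph::add_edges(g, as.vector(pairs[, add, drop = FALSE]))
    }
    g <- igraph::simplify(g)
    # sample component target sets at their stated module overlap
    dists_to_module <- NULL
    target_sets <- lapply(scenario$targets, function(tg) {
      size <- tg$size
      n_in <- round((tg$overlap %||% 0) * size)
      pool_in <- if (is.null(tg$module_part)) module_idx else
        module_idx[tg$module_part]
      if (n_in > length(pool_in)) {
        stop("unsatisfiable overlap: module pool too small", call. = FALSE)
      }
      inside <- if (n_in > 0L) sample(pool_in, n_in) else integer(0)
      pool_out <- setdiff(seq_len(n), module_idx)
      if (!is.null(tg$min_distance)) {
        if (is.null(dists_to_module)) {
          d <- igraph::distances(g, v = module_idx)
          dists_to_module <<- apply(d, 2L, min)
        }
        pool_out <- intersect(pool_out,
                              which(dists_to_module >= tg$min_distance))
      }
      n_out <- size - n_in
      if (n_out > length(pool_out)) {
        stop("unsatisfiable overlap: outside pool too small", call. = FALSE)
      }
      outside <- if (n_out > 0L) sample(pool_out, n_out) else integer(0)
      sort(c(inside, outside))
    })
    el <- igraph::as_edgelist(g, names = FALSE)
    conf <- runif(nrow(el), scenario$confidence_range[1L],
                  scenario$confidence_range[2L])
    edges <- data.frame(node_a = node_ids[el[, 1L]],
                        node_b = node_ids[el[, 2L]],
                        confidence = conf, stringsAsFactors = FALSE)
    out <- list(
      edges = edges,
      disease_module = node_ids[module_idx],
      target_sets = lapply(target_sets, function(idx) node_ids[idx]),
      manifest = list(
        n_nodes = n, n_edges = nrow(edges),
        topology = scenario$topology, seed = scenario$seed,
        module_size = scenario$module_size,
        module_density = scenario$module_density,
        disease_module = node_ids[module_idx],
        target_sets = lapply(target_sets, function(idx) node_ids[idx]),
        overlap_fractions = lapply(scenario$targets,
                                   function(tg) tg$overlap %||% 0)))
    out
  })
}

#' Write a simulated network scenario to disk
#'
#' Emits exactly the formats the analysis modules read: a 3-column
#' edge list, one gene-set file per target set, a disease gene-set
#' file, and a JSON manifest of the planted truth.
#'
#' @param sim a [simulate_network()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_network_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(sim$edges, file.path(dir, "edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(sim$disease_module, file.path(dir, "disease_genes.txt"))
  comp_dir <- file.path(dir, "components")
  dir.create(comp_dir, showWarnings = FALSE)
  for (nm in names(sim$target_sets)) {
    writeLines(sim$target_sets[[nm]], file.path(comp_dir,
                                                paste0(nm, ".txt")))
  }
  jsonlite::write_json(sim$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
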