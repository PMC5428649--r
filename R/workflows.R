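#' Read a run configuration from YAML or JSON
#'
#' @param path configuration file.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

provenance_header <- function(config, seed) {
  c(sprintf("# herbconnect %s", as.character(packageVersion("herbconnect"))),
    sprintf("# config_hash: %s", config_hash(config)),
    sprintf("# seed: %s", seed))
}

write_report <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("%s stage: %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[herbconnect:%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the connectivity-query workflow
#'
#' Chains replicate averaging, fold-change filtering, signature
#' construction (persisted as paired `.grp` files), instance-level
#' connectivity scoring and by-compound enrichment, writing
#' tab-delimited reports with a provenance header (package version,
#' configuration hash, seed). Reruns with an identical configuration
#' give byte-identical reports.
#'
#' @param config named list or path to a YAML/JSON file. Recognised
#'   fields: `expression` (path or [expression_matrix()]),
#'   `condition_map` (path or data frame; needed when `expression` is
#'   a path), `treated` / `control` condition labels, `fc_up` (2),
#'   `fc_down` (0.5), `collection` (directory or
#'   [reference_collection()]), `n_permutations` (1e5), `seed` (1),
#'   `filter_positive_p` (optional: keep only positive-enrichment
#'   names with p below this in the name report), `label`, `out_dir`
#'   (required).
#' @return Invisibly, a list with the signature, the instance-level
#'   and name-level data frames, and the written file paths.
#' @export
run_connectivity_workflow <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config needs `out_dir`", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  header <- provenance_header(config[setdiff(names(config), "out_dir")], seed)

  expr <- run_stage("expression", {
    if (inherits(config$expression, "expression_matrix")) config$expression
    else read_expression_matrix(config$expression, config$condition_map)
  })
  treated <- config$treated %||% "treated"
  control <- config$control %||% "control"
  log_stage("expression", "%d probes, %d samples",
            nrow(expr$values), ncol(expr$values))

  sig <- run_stage("signature", {
    fc <- fold_change(average_replicates(expr, treated),
                      average_replicates(expr, control))
    s <- build_signature(fc, up_threshold = config$fc_up %||% 2,
                         down_threshold = config$fc_down %||% 0.5,
                         source_label = config$label %||% treated)
    if (length(s$up_tags) == 0L && length(s$down_tags) == 0L) {
      stop("empty signature: no probe passed the fold-change thresholds")
    }
    s
  })
  grp_paths <- suppressWarnings(write_signature(sig, out_dir))
  log_stage("signature", "%d up / %d down tags -> %s, %s",
            length(sig$up_tags), length(sig$down_tags),
            grp_paths[["up"]], grp_paths[["down"]])

  collection <- run_stage("collection", {
    if (inherits(config$collection, "reference_collection")) {
      config$collection
    } else {
      read_reference_collection(config$collection)
    }
  })
  instances <- run_stage("scoring", query_collection(sig, collection))
  names_df <- run_stage("enrichment", {
    name_enrichment(instances,
                    n_permutations = config$n_permutations %||% 1e5,
                    seed = seed)
  })
  if (!is.null(config$filter_positive_p)) {
    names_df <- names_df[names_df$enrichment > 0 &
                           names_df$p_value < config$filter_positive_p,
                         , drop = FALSE]
  }
  inst_path <- write_report(instances, file.path(out_dir, "instances.tsv"),
                            header)
  name_path <- write_report(names_df, file.path(out_dir, "names.tsv"),
                            header)
  log_stage("report", "wrote %s and %s", inst_path, name_path)
  invisible(list(signature = sig, instances = instances, names = names_df,
                 files = c(grp_paths, instances = inst_path,
                           names = name_path)))
}

#' Run the synergy-evaluation workflow
#'
#' Chains network construction (confidence filter with target-edge
#' rescue), disease and per-component propagation, effect scoring and
#' null standardisation into a mixture-first synergy report with a
#' provenance header.
#'
#' @param config named list or path to a YAML/JSON file. Recognised
#'   fields: `network` (edge-list path, data frame or
#'   [build_network()] result), `confidence_threshold` (0.9),
#'   `disease` (gene-set path or character vector), `components`
#'   (directory of gene-set files, one per component, or a named
#'   list), `mixture` (`"union"`, a gene-set path, or a character
#'   vector), `r` (0.3), `n_random` (1000; below 10 triggers a
#'   low-precision warning), `seed` (1), `method` (`"adjoint"`),
#'   `out_dir` (required).
#' @return Invisibly, a list with the synergy data frame, the network
#'   and the report path.
#' @export
run_synergy_workflow <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config needs `out_dir`", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  header <- provenance_header(config[setdiff(names(config), "out_dir")], seed)

  disease <- run_stage("disease", {
    if (is.character(config$disease) && length(config$disease) == 1L &&
        file.exists(config$disease)) {
      read_gene_set(config$disease)
    } else {
      as.character(config$disease)
    }
  })
  components <- run_stage("components", {
    if (is.list(config$components)) {
      lapply(config$components, as.character)
    } else {
      files <- list.files(config$components, full.names = TRUE)
      if (length(files) == 0L) stop("no component gene-set files found")
      sets <- lapply(files, read_gene_set)
      names(sets) <- sub("\\.[^.]*$", "", basename(files))
      sets
    }
  })
  mixture <- config$mixture %||% "union"
  if (is.character(mixture) && length(mixture) == 1L &&
      !identical(mixture, "union") && file.exists(mixture)) {
    mixture <- read_gene_set(mixture)
  }

  network <- run_stage("network", {
    if (inherits(config$network, "propagation_network")) {
      config$network
    } else {
      edges <- if (is.data.frame(config$network)) config$network
               else read_edge_list(config$network)
      rescue <- unique(c(disease, unlist(components, use.names = FALSE),
                         if (!identical(mixture, "union")) mixture))
      build_network(edges,
                    confidence_threshold =
                      config$confidence_threshold %||% 0.9,
                    rescue_targets = rescue)
    }
  })
  log_stage("network", "%d nodes, %d edges retained",
            network$n_nodes, network$n_edges)

  n_random <- config$n_random %||% 1000L
  if (n_random < 10) {
    warning(sprintf(
      "n_random = %d gives a low-precision null; z-scores are unstable",
      n_random), call. = FALSE)
  }
  table <- run_stage("synergy", {
    synergy_table(network, disease, components, mixture = mixture,
                  r = config$r %||% 0.3, n_random = n_random, seed = seed,
                  method = config$method %||% "adjoint")
  })
  path <- write_report(table, file.path(out_dir, "synergy.tsv"), header)
  log_stage("report", "wrote %s", path)
  invisible(list(synergy = table, network = network, file = path))
}
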