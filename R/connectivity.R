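#' Construct a rank-ordered reference instance
#'
#' One treatment experiment in a reference collection: a full ordering
#' of the probe universe from most up-regulated to most down-regulated
#' plus metadata (compound, dose, cell line, batch).
#'
#' @param instance_id unique identifier.
#' @param ranked_probes character vector, best-to-worst, a permutation
#'   of the collection's probe universe.
#' @param compound_name,dose,cell_line,batch metadata fields.
#' @return An object of class `reference_instance`.
#' @export
reference_instance <- function(instance_id, ranked_probes,
                               compound_name = NA_character_,
                               dose = NA_character_,
                               cell_line = NA_character_,
                               batch = NA_character_) {
  ranked_probes <- as.character(ranked_probes)
  if (anyDuplicated(ranked_probes)) {
    stop("ranked_probes contains duplicates", call. = FALSE)
  }
  structure(list(instance_id = as.character(instance_id),
                 compound_name = as.character(compound_name),
                 dose = as.character(dose),
                 cell_line = as.character(cell_line),
                 batch = as.character(batch),
                 ranked_probes = ranked_probes),
            class = "reference_instance")
}

#' Bundle reference instances into a collection
#'
#' All instances must rank the same probe universe (each ranking is a
#' permutation of it, no omissions or duplicates).
#'
#' @param instances list of [reference_instance()] objects.
#' @return An object of class `reference_collection`.
#' @export
reference_collection <- function(instances) {
  if (length(instances) < 1L) stop("empty collection", call. = FALSE)
  universe <- sort(instances[[1L]]$ranked_probes)
  for (inst in instances) {
    if (!inherits(inst, "reference_instance")) {
      stop("all elements must be reference_instance objects", call. = FALSE)
    }
    if (!identical(sort(inst$ranked_probes), universe)) {
      stop(sprintf("instance '%s' does not rank the shared probe universe",
                   inst$instance_id), call. = FALSE)
    }
  }
  ids <- vapply(instances, `[[`, "", "instance_id")
  if (anyDuplicated(ids)) stop("duplicate instance ids", call. = FALSE)
  names(instances) <- ids
  structure(list(instances = instances, universe = universe),
            class = "reference_collection")
}

#' @export
print.reference_collection <- function(x, ...) {
  cat(sprintf("<reference_collection> %d instances over %d probes\n",
              length(x$instances), length(x$universe)))
  invisible(x)
}

# core KS-style tag statistic from 1-based tag positions in a ranking
# of length n; in [-1, 1], +1 as tags lead, -1 as they trail.
ks_stat_from_positions <- function(positions, n) {
  v <- sort(positions)
  t <- length(v)
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

#' Kolmogorov-Smirnov-style tag-set enrichment in a ranking
#'
#' With `t` tags in a ranking of `n` probes and `V(j)` the position of
#' the j-th best-ranked tag, the statistic is `a = max_j(j/t - V(j)/n)`
#' if it exceeds `b = max_j(V(j)/n - (j-1)/t)`, else `-b`. It lies in
#' `[-1, 1]`, approaching +1 when the tags lead the ranking and -1 when
#' they trail it, and depends only on the tag positions.
#'
#' @param tags character vector of tag identifiers.
#' @param ranked a [reference_instance()] or a character ranking.
#' @param missing how to treat tags absent from the ranking:
#'   `"drop"` (default, with a warning counting them) or `"error"`.
#' @return The statistic, a number in `[-1, 1]`.
#' @export
ks_enrichment <- function(tags, ranked, missing = c("drop", "error")) {
  missing <- match.arg(missing)
  if (inherits(ranked, "reference_instance")) ranked <- ranked$ranked_probes
  positions <- match(tags, ranked)
  if (anyNA(positions)) {
    n_missing <- sum(is.na(positions))
    if (missing == "error") {
      stop(sprintf("%d tag(s) absent from the instance universe", n_missing),
           call. = FALSE)
    }
    warning(sprintf("dropping %d tag(s) absent from the instance universe",
                    n_missing), call. = FALSE)
    positions <- positions[!is.na(positions)]
  }
  if (length(positions) == 0L) {
    stop("no tags left after dropping those absent from the universe",
         call. = FALSE)
  }
  ks_stat_from_positions(positions, length(ranked))
}

#' Raw connectivity score of a signature against one instance
#'
#' Computes the tag enrichment of the up set (`ks_up`) and the down set
#' (`ks_down`) and combines them: the raw score is 0 when the two
#' statistics share a sign (discordant evidence) and `ks_up - ks_down`
#' otherwise. An empty tag set contributes a statistic of 0.
#'
#' @param sig a [build_signature()] result (or any list with `up_tags`
#'   and `down_tags`).
#' @param ranked a [reference_instance()].
#' @inheritParams ks_enrichment
#' @return One-row data frame: `instance_id`, metadata, `ks_up`,
#'   `ks_down`, `raw_score`.
#' @export
instance_score <- function(sig, ranked, missing = c("drop", "error")) {
  missing <- match.arg(missing)
  if (length(sig$up_tags) == 0L && length(sig$down_tags) == 0L) {
    stop("both tag lists are empty", call. = FALSE)
  }
  ks_up <- if (length(sig$up_tags) > 0L) {
    ks_enrichment(sig$up_tags, ranked, missing)
  } else 0
  ks_down <- if (length(sig$down_tags) > 0L) {
    ks_enrichment(sig$down_tags, ranked, missing)
  } else 0
  raw <- if (sign(ks_up) == sign(ks_down)) 0 else ks_up - ks_down
  data.frame(instance_id = ranked$instance_id,
             compound_name = ranked$compound_name,
             dose = ranked$dose, cell_line = ranked$cell_line,
             batch = ranked$batch,
             ks_up = ks_up, ks_down = ks_down, raw_score = raw,
             stringsAsFactors = FALSE)
}

#' Scale raw scores to connectivity scores in \[-1, 1\]
#'
#' With `p` the maximum positive and `q` the minimum negative raw score
#' across the collection, connectivity is `raw/p` for positive raws and
#' `raw/|q|` for negative raws, 0 otherwise, so the best positive
#' instance scores exactly 1 and the most negative exactly -1.
#'
#' @param scored data frame with a `raw_score` column (rows =
#'   instances).
#' @return The data frame with a `connectivity` column added.
#' @export
scale_scores <- function(scored) {
  raw <- scored$raw_score
  if (is.null(raw)) stop("`scored` lacks a raw_score column", call. = FALSE)
  conn <- numeric(length(raw))
  pos <- raw > 0
  neg <- raw < 0
  if (any(pos)) conn[pos] <- raw[pos] / max(raw[pos])
  if (any(neg)) conn[neg] <- raw[neg] / abs(min(raw[neg]))
  scored$connectivity <- conn
  scored
}

#' Score a signature against every instance of a collection
#'
#' Runs [instance_score()] on each instance, applies [scale_scores()],
#' and returns the instance-level report sorted by connectivity
#' (descending, ties in input order) with a `rank` column — the shape
#' of a detailed connectivity-map result table.
#'
#' @param sig a signature.
#' @param collection a [reference_collection()].
#' @inheritParams ks_enrichment
#' @return data frame: `rank`, `batch`, `compound_name`, `dose`,
#'   `cell_line`, `ks_up`, `ks_down`, `raw_score`, `connectivity`,
#'   `instance_id`.
#' @export
query_collection <- function(sig, collection, missing = c("drop", "error")) {
  missing <- match.arg(missing)
  stopifnot(inherits(collection, "reference_collection"))
  rows <- lapply(collection$instances, instance_score,
                 sig = sig, missing = missing)
  scored <- scale_scores(do.call(rbind, rows))
  ord <- order(-scored$connectivity)
  scored <- scored[ord, , drop = FALSE]
  scored$rank <- seq_len(nrow(scored))
  rownames(scored) <- NULL
  scored[, c("rank", "batch", "compound_name", "dose", "cell_line",
             "ks_up", "ks_down", "raw_score", "connectivity",
             "instance_id")]
}

# permutation null of the position statistic for k tags among n slots;
# exact enumeration when choose(n, k) is small enough.
position_null <- function(n, k, n_permutations, exact_limit) {
  if (choose(n, k) <= exact_limit) {
    sets <- combn(n, k)
    list(stats = apply(sets, 2L, ks_stat_from_positions, n = n),
         exact = TRUE)
  } else {
    stats <- vapply(seq_len(n_permutations), function(i) {
      ks_stat_from_positions(sample.int(n, k), n)
    }, numeric(1))
    list(stats = stats, exact = FALSE)
  }
}

#' By-compound enrichment of a scored instance list
#'
#' Orders all instances by connectivity (descending) and, for each
#' compound name with `k` instances, computes the tag enrichment
#' statistic of their positions in that ordering. Significance comes
#' from the permutation null of random `k`-subsets of positions:
#' `p_one_sided` is the fraction of subsets whose statistic is at
#' least as extreme on the side of the observed sign, and `p_value`
#' is the two-sided permutation p (the observed-side tail doubled,
#' capped at 1), which is what stays valid — `P(p <= alpha) <= alpha`
#' — under label shuffling. All C(N, k) subsets are enumerated
#' exactly when that count is at most `exact_limit`, otherwise
#' `n_permutations` Monte-Carlo subsets are drawn (a reported
#' one-sided p of 0 then means below 1/`n_permutations`).
#'
#' @param scored instance-level data frame with `compound_name` and
#'   `connectivity` columns (e.g. from [query_collection()]).
#' @param n_permutations Monte-Carlo subsets per distinct `k`
#'   (default 1e5; must be >= 1000).
#' @param seed RNG seed for the permutation draws.
#' @param exact_limit switch to exact enumeration when
#'   `choose(N, k) <=` this (default 1e4).
#' @return data frame sorted by p then enrichment: `rank`,
#'   `compound_name`, `n_instances`, `enrichment`, `p_value`,
#'   `p_one_sided`, `p_exact`.
#' @export
name_enrichment <- function(scored, n_permutations = 1e5, seed = 1L,
                            exact_limit = 1e4) {
  if (n_permutations < 1000) {
    stop("n_permutations must be >= 1000", call. = FALSE)
  }
  if (anyNA(scored$compound_name)) {
    stop("every instance must carry a compound name", call. = FALSE)
  }
  ord <- order(-scored$connectivity)
  names_in_order <- scored$compound_name[ord]
  n <- length(names_in_order)
  unique_names <- unique(names_in_order)
  null_cache <- new.env(parent = emptyenv())
  rows <- with_rng_seed(seed, {
    lapply(unique_names, function(nm) {
      positions <- which(names_in_order == nm)
      k <- length(positions)
      obs <- ks_stat_from_positions(positions, n)
      key <- as.character(k)
      if (is.null(null_cache[[key]])) {
        null_cache[[key]] <- position_null(n, k, n_permutations, exact_limit)
      }
      null <- null_cache[[key]]
      p_side <- if (obs >= 0) mean(null$stats >= obs)
                else mean(null$stats <= obs)
      data.frame(compound_name = nm, n_instances = k, enrichment = obs,
                 p_value = min(1, 2 * p_side), p_one_sided = p_side,
                 p_exact = null$exact, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, -out$enrichment), , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Write/read a reference collection as ranked-probe files + metadata
#'
#' The on-disk layout is one text file per instance
#' (`<instance_id>.txt`, one probe id per line, best-to-worst) next to
#' a tab-delimited `metadata.tsv` with columns `instance_id`,
#' `compound_name`, `dose`, `cell_line`, `batch`.
#'
#' @param collection a [reference_collection()].
#' @param dir directory (created if needed).
#' @return `write_reference_collection()` invisibly returns `dir`;
#'   `read_reference_collection()` returns the collection.
#' @export
write_reference_collection <- function(collection, dir) {
  stopifnot(inherits(collection, "reference_collection"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- do.call(rbind, lapply(collection$instances, function(inst) {
    data.frame(instance_id = inst$instance_id,
               compound_name = inst$compound_name, dose = inst$dose,
               cell_line = inst$cell_line, batch = inst$batch,
               stringsAsFactors = FALSE)
  }))
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (inst in collection$instances) {
    writeLines(inst$ranked_probes,
               file.path(dir, paste0(inst$instance_id, ".txt")))
  }
  invisible(dir)
}

#' @rdname write_reference_collection
#' @export
read_reference_collection <- function(dir) {
  meta <- read.delim(file.path(dir, "metadata.tsv"),
                     stringsAsFactors = FALSE, colClasses = "character")
  instances <- lapply(seq_len(nrow(meta)), function(i) {
    ranked <- readLines(file.path(dir, paste0(meta$instance_id[i], ".txt")))
    reference_instance(meta$instance_id[i], ranked,
                       compound_name = meta$compound_name[i],
                       dose = meta$dose[i], cell_line = meta$cell_line[i],
                       batch = meta$batch[i])
  })
  reference_collection(instances)
}
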