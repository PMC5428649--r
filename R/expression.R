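#' Construct an expression matrix with condition annotation
#'
#' Bundles a probes-by-samples matrix of normalised intensities with a
#' map from sample to condition and replicate index. Normalisation
#' (e.g. MAS 5.0) is upstream: values are taken as-is and must be
#' finite and non-negative.
#'
#' @param values numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids).
#' @param condition_map data frame with columns `sample_id`,
#'   `condition` and optionally `replicate`; every column of `values`
#'   must appear exactly once.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, condition_map) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs probe rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("probe and sample identifiers must be unique", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("expression values must be finite and >= 0", call. = FALSE)
  }
  condition_map <- as.data.frame(condition_map, stringsAsFactors = FALSE)
  required <- c("sample_id", "condition")
  if (!all(required %in% names(condition_map))) {
    stop("`condition_map` needs columns sample_id and condition", call. = FALSE)
  }
  if (!("replicate" %in% names(condition_map))) {
    condition_map$replicate <- stats::ave(
      seq_len(nrow(condition_map)), condition_map$condition, FUN = seq_along)
  }
  if (!setequal(condition_map$sample_id, colnames(values)) ||
      anyDuplicated(condition_map$sample_id)) {
    stop("condition_map must annotate each sample exactly once", call. = FALSE)
  }
  condition_map <- condition_map[
    match(colnames(values), condition_map$sample_id),
    c("sample_id", "condition", "replicate"), drop = FALSE]
  rownames(condition_map) <- NULL
  structure(list(values = values, condition_map = condition_map),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$condition_map$condition)
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression matrix from a delimited table or GCT file
#'
#' Accepts either a plain tab-delimited table (first column probe id,
#' header row of sample ids) or the GCT 1.2 dialect (first line
#' `#1.2`, second line dimensions, then `Name`/`Description` columns).
#' Sample-to-condition annotation comes from a YAML or JSON sidecar
#' read with [read_condition_map()].
#'
#' @param path path to the expression table.
#' @param condition_map data frame as in [expression_matrix()], or a
#'   path to a YAML/JSON sidecar.
#' @return An `expression_matrix`.
#' @export
read_expression_matrix <- function(path, condition_map) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#1.2")) {
    tab <- read.delim(path, skip = 2L, check.names = FALSE,
                      stringsAsFactors = FALSE)
    probe_col <- 1L
    drop_cols <- which(tolower(names(tab)) == "description")
    values <- as.matrix(tab[, -c(probe_col, drop_cols), drop = FALSE])
  } else {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    values <- as.matrix(tab[, -1L, drop = FALSE])
  }
  rownames(values) <- as.character(tab[[1L]])
  storage.mode(values) <- "double"
  if (is.character(condition_map)) {
    condition_map <- read_condition_map(condition_map)
  }
  expression_matrix(values, condition_map)
}

#' Write an expression matrix as a tab-delimited table plus sidecar
#'
#' @param x an `expression_matrix`.
#' @param path output path for the table; the condition map is written
#'   next to it as `<path>.conditions.yaml`.
#' @return Invisibly, the paths written.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  tab <- data.frame(probe_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- paste0(path, ".conditions.yaml")
  cm <- x$condition_map
  entries <- lapply(seq_len(nrow(cm)), function(i) {
    list(condition = cm$condition[i], replicate = as.integer(cm$replicate[i]))
  })
  names(entries) <- cm$sample_id
  yaml::write_yaml(entries, sidecar)
  invisible(c(table = path, conditions = sidecar))
}

#' Read a sample-to-condition map from YAML or JSON
#'
#' The file maps each sample id either to a condition label or to a
#' mapping with `condition` and `replicate` keys.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return data frame with columns `sample_id`, `condition`,
#'   `replicate`.
#' @export
read_condition_map <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  rows <- lapply(names(raw), function(sid) {
    entry <- raw[[sid]]
    if (is.character(entry)) {
      data.frame(sample_id = sid, condition = entry, replicate = NA_integer_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sample_id = sid, condition = entry$condition,
                 replicate = as.integer(entry$replicate %||% NA_integer_),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (anyNA(out$replicate)) {
    out$replicate <- stats::ave(seq_len(nrow(out)), out$condition,
                                FUN = seq_along)
  }
  out
}
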