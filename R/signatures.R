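#' Average replicate columns of one condition
#'
#' Collapses the replicate samples of a condition to the per-probe
#' arithmetic mean of their normalised intensities, preserving probe
#' order.
#'
#' @param x an [expression_matrix()].
#' @param condition condition label present in the condition map.
#' @return Named numeric vector of per-probe means.
#' @export
average_replicates <- function(x, condition) {
  stopifnot(inherits(x, "expression_matrix"))
  samples <- x$condition_map$sample_id[x$condition_map$condition == condition]
  if (length(samples) == 0L) {
    stop(sprintf("unknown condition label: '%s'", condition), call. = FALSE)
  }
  rowMeans(x$values[, samples, drop = FALSE])
}

#' Per-probe fold change of treated over control means
#'
#' Fold change is the replicate-averaged treated intensity divided by
#' the replicate-averaged vehicle-control intensity, on the normalised
#' intensity scale (not log). Probes whose control mean is zero get a
#' flagged-undefined (`NA`) entry rather than an infinity; they are
#' excluded from signatures downstream.
#'
#' @param treated_mean,control_mean named numeric vectors of equal
#'   length with matching probe order.
#' @param log2_input if `TRUE` the inputs are log2 intensities and are
#'   exponentiated before the ratio is formed.
#' @return Named numeric vector of fold changes (`NA` = undefined).
#' @export
fold_change <- function(treated_mean, control_mean, log2_input = FALSE) {
  if (length(treated_mean) != length(control_mean)) {
    stop("treated and control vectors differ in length", call. = FALSE)
  }
  if (!is.null(names(treated_mean)) && !is.null(names(control_mean)) &&
      !identical(names(treated_mean), names(control_mean))) {
    stop("probe order of treated and control vectors differs", call. = FALSE)
  }
  if (log2_input) {
    treated_mean <- 2^treated_mean
    control_mean <- 2^control_mean
  }
  fc <- treated_mean / control_mean
  fc[control_mean == 0] <- NA_real_
  fc
}

#' Select up/down tag sets from a fold-change vector
#'
#' Probes at or above `up_threshold` become up tags; probes at or
#' below `down_threshold` become down tags (defaults FC >= 2 and
#' <= 0.5, applied uniformly across compounds). Flagged-undefined fold
#' changes are excluded from both sets.
#'
#' @param fc named fold-change vector from [fold_change()].
#' @param up_threshold ratio above 1; default 2.
#' @param down_threshold ratio below 1; default 0.5.
#' @param source_label free-text label carried into outputs.
#' @return An object of class `signature` with `up_tags`, `down_tags`,
#'   the thresholds and the label.
#' @export
build_signature <- function(fc, up_threshold = 2, down_threshold = 0.5,
                            source_label = "") {
  if (!(down_threshold < up_threshold && up_threshold > 1 &&
        down_threshold < 1)) {
    stop("thresholds must satisfy down_threshold < 1 < up_threshold",
         call. = FALSE)
  }
  if (is.null(names(fc))) {
    stop("`fc` must carry probe names", call. = FALSE)
  }
  ok <- !is.na(fc)
  structure(list(
    up_tags = names(fc)[ok & fc >= up_threshold],
    down_tags = names(fc)[ok & fc <= down_threshold],
    up_threshold = up_threshold,
    down_threshold = down_threshold,
    source_label = source_label
  ), class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf(
    "<signature> '%s': %d up (FC >= %g), %d down (FC <= %g)\n",
    x$source_label, length(x$up_tags), x$up_threshold,
    length(x$down_tags), x$down_threshold))
  invisible(x)
}

#' Write a tag list in the `.grp` convention
#'
#' One identifier per line, no header. An empty tag list yields an
#' empty file with a warning.
#'
#' @param tags character vector of non-empty identifiers without
#'   whitespace.
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
write_grp <- function(tags, path) {
  tags <- as.character(tags)
  if (any(!nzchar(tags)) || any(grepl("[[:space:]]", tags))) {
    stop("tags must be non-empty strings without whitespace", call. = FALSE)
  }
  if (length(tags) == 0L) {
    warning(sprintf("writing empty tag list to '%s'", path), call. = FALSE)
  }
  writeLines(tags, path)
  invisible(path)
}

#' Read a `.grp` tag list
#'
#' Tolerates trailing blank lines and Windows line endings; a blank or
#' whitespace-containing line elsewhere is an error reported with its
#' line number.
#'
#' @param path source file.
#' @return Character vector of identifiers, order preserved.
#' @export
read_grp <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  while (length(lines) > 0L && !nzchar(lines[length(lines)])) {
    lines <- lines[-length(lines)]
  }
  bad <- which(!nzchar(trimws(lines)) | grepl("[[:space:]]", lines))
  if (length(bad) > 0L) {
    stop(sprintf("malformed grp line %d in '%s'", bad[1L], path),
         call. = FALSE)
  }
  lines
}

#' Write a signature as paired up/down `.grp` files
#'
#' @param sig a [build_signature()] result.
#' @param dir output directory.
#' @param label basename; defaults to the signature's source label.
#' @return Invisibly, the two paths (`up`, `down`).
#' @export
write_signature <- function(sig, dir, label = NULL) {
  stopifnot(inherits(sig, "signature"))
  label <- label %||% sig$source_label
  if (!nzchar(label)) label <- "signature"
  up <- file.path(dir, paste0(label, "_up.grp"))
  down <- file.path(dir, paste0(label, "_down.grp"))
  suppressWarnings({
    write_grp(sig$up_tags, up)
    write_grp(sig$down_tags, down)
  })
  if (length(sig$up_tags) == 0L || length(sig$down_tags) == 0L) {
    warning("signature has an empty tag list", call. = FALSE)
  }
  invisible(c(up = up, down = down))
}

#' Read paired `.grp` files back into a signature
#'
#' @param up_path,down_path the two tag files.
#' @param source_label label for the reconstructed signature.
#' @return A `signature` object (thresholds recorded as the defaults
#'   used to create it are not stored in `.grp` files).
#' @export
read_signature <- function(up_path, down_path, source_label = "") {
  structure(list(
    up_tags = read_grp(up_path),
    down_tags = read_grp(down_path),
    up_threshold = NA_real_,
    down_threshold = NA_real_,
    source_label = source_label
  ), class = "signature")
}
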