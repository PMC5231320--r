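# Phase labels used throughout, in fixed class order.
PHASE_LEVELS <- c("Int", "Pro", "Meta", "Ana", "Telo")

#' Fixed cell-cycle class order
#'
#' Interphase plus the four mitotic phases, in the order used for every
#' confusion matrix, classifier and tie-break in the package.
#'
#' @return Character vector `c("Int", "Pro", "Meta", "Ana", "Telo")`.
#' @export
phase_levels <- function() PHASE_LEVELS

#' Create a single-cell record
#'
#' A cell record holds the spatially registered per-channel images of one
#' cell: a named list of numeric matrices with intensities in `[0, 1]`, all
#' of identical dimensions, plus an identifier and an optional phase label.
#'
#' @param cell_id Unique cell identifier (string).
#' @param channels Named list of numeric matrices, one per channel (e.g.
#'   `list(BF = ..., DF = ...)`), all the same size, values in `[0, 1]`.
#' @param label Optional phase label, one of [phase_levels()], or `NA`.
#' @param meta Optional list of provenance metadata (e.g. ground-truth mask).
#'
#' @return An object of class `ifc_cell`.
#' @export
cell_record <- function(cell_id, channels, label = NA_character_, meta = list()) {
  stopifnot(is.character(cell_id), length(cell_id) == 1L, nzchar(cell_id))
  if (!is.list(channels) || is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("`channels` must be a named list of matrices", call. = FALSE)
  dims <- vapply(channels, function(m) {
    if (!is.matrix(m) || !is.numeric(m))
      stop("each channel must be a numeric matrix", call. = FALSE)
    if (nrow(m) < 1L || ncol(m) < 1L)
      stop("channel images must have height >= 1 and width >= 1", call. = FALSE)
    rng <- range(m)
    if (rng[1] < 0 || rng[2] > 1)
      stop("channel intensities must lie in [0, 1]", call. = FALSE)
    dim(m)
  }, integer(2))
  if (ncol(dims) > 1L && any(dims[, -1, drop = FALSE] != dims[, 1]))
    stop("all channels of a cell must share the same dimensions", call. = FALSE)
  if (!is.na(label) && !label %in% PHASE_LEVELS)
    stop("`label` must be one of ", paste(PHASE_LEVELS, collapse = ", "),
         " or NA", call. = FALSE)
  structure(list(cell_id = cell_id, channels = channels,
                 label = as.character(label), meta = meta),
            class = "ifc_cell")
}

#' Create an image set
#'
#' The in-memory container for a population of single-cell multi-channel
#' images, standing in for a proprietary cytometer file. Every cell carries
#' exactly the channels in `channel_labels`, in that order.
#'
#' @param cells List of [cell_record()] objects.
#' @param channel_labels Channel names; defaults to those of the first cell.
#' @param provenance Free-text metadata string.
#'
#' @return An object of class `ifc_imageset`.
#' @export
imageset <- function(cells, channel_labels = NULL, provenance = "") {
  stopifnot(is.list(cells))
  if (is.null(channel_labels)) {
    channel_labels <- if (length(cells)) names(cells[[1]]$channels) else character()
  }
  ids <- vapply(cells, function(cl) cl$cell_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate cell_id in image set: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  for (cl in cells) {
    if (!identical(names(cl$channels), channel_labels))
      stop("cell ", cl$cell_id, " does not carry channels [",
           paste(channel_labels, collapse = ", "), "] in order", call. = FALSE)
  }
  structure(list(cells = cells, channel_labels = channel_labels,
                 provenance = provenance),
            class = "ifc_imageset")
}

#' @export
length.ifc_imageset <- function(x) length(x$cells)

#' @export
print.ifc_imageset <- function(x, ...) {
  labs <- cell_labels(x)
  cat("<ifc_imageset> ", length(x$cells), " cells, channels [",
      paste(x$channel_labels, collapse = ", "), "]\n", sep = "")
  if (any(!is.na(labs))) {
    tab <- table(factor(labs, levels = PHASE_LEVELS))
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Cell identifiers of an image set
#' @param x An `ifc_imageset`.
#' @return Character vector of cell ids in container order.
#' @export
cell_ids <- function(x) vapply(x$cells, function(cl) cl$cell_id, character(1))

#' Phase labels of an image set
#' @param x An `ifc_imageset`.
#' @return Character vector of labels (`NA` where unlabelled), container order.
#' @export
cell_labels <- function(x) vapply(x$cells, function(cl) cl$label, character(1))

#' Subset an image set by cell id
#' @param x An `ifc_imageset`.
#' @param ids Cell ids to keep; order of `ids` is preserved.
#' @return A new `ifc_imageset`.
#' @export
subset_imageset <- function(x, ids) {
  idx <- match(ids, cell_ids(x))
  if (anyNA(idx))
    stop("unknown cell_id: ", paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  imageset(x$cells[idx], x$channel_labels, x$provenance)
}

# Intensity quantisation used on disk: 16-bit unsigned grayscale.
BITS_PER_SAMPLE <- 16L

#' Write an image set to a portable on-disk container
#'
#' Writes one multi-page 16-bit grayscale TIFF per cell (one page per
#' channel, page order = `channel_labels`), a CSV manifest with columns
#' `cell_id,file,label` (empty string when unlabelled) and a JSON sidecar
#' (`imageset.json`) recording channel labels, bit depth and provenance.
#' Intensities are quantised to 16 bits; a round trip through
#' [read_imageset()] reproduces pixels to within `1/65535`.
#'
#' @param x An `ifc_imageset`.
#' @param path Directory to write into (created if absent).
#'
#' @return `path`, invisibly.
#' @export
write_imageset <- function(x, path) {
  stopifnot(inherits(x, "ifc_imageset"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory ", path, call. = FALSE)
  ids <- cell_ids(x)
  files <- paste0(ids, ".tif")
  for (i in seq_along(x$cells)) {
    pages <- unname(x$cells[[i]]$channels)
    ok <- try(tiff::writeTIFF(pages, file.path(path, files[i]),
                              bits.per.sample = BITS_PER_SAMPLE),
              silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("failed to write image for cell ", ids[i], ": ",
           attr(ok, "condition")$message, call. = FALSE)
  }
  labs <- cell_labels(x)
  manifest <- tibble::tibble(
    cell_id = ids, file = files,
    label = ifelse(is.na(labs), "", labs))
  readr::write_csv(manifest, file.path(path, "manifest.csv"))
  jsonlite::write_json(
    list(channel_labels = x$channel_labels,
         bits_per_sample = BITS_PER_SAMPLE,
         provenance = x$provenance),
    file.path(path, "imageset.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read an image set from its on-disk container
#'
#' Inverse of [write_imageset()]. Cells are returned in manifest row order;
#' labels are parsed when present.
#'
#' @param path Directory containing `manifest.csv`, `imageset.json` and the
#'   per-cell TIFFs.
#'
#' @return An `ifc_imageset`.
#' @export
read_imageset <- function(path) {
  man_path <- file.path(path, "manifest.csv")
  meta_path <- file.path(path, "imageset.json")
  if (!file.exists(man_path)) stop("manifest.csv not found in ", path, call. = FALSE)
  if (!file.exists(meta_path)) stop("imageset.json not found in ", path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  manifest <- readr::read_csv(man_path, col_types = readr::cols(.default = "c"))
  req <- c("cell_id", "file", "label")
  if (!all(req %in% names(manifest)))
    stop("manifest must have columns cell_id, file, label", call. = FALSE)
  labels <- as.character(manifest$label)
  labels[is.na(labels) | labels == ""] <- NA_character_
  cells <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    f <- file.path(path, manifest$file[i])
    if (!file.exists(f))
      stop("image file missing for cell ", manifest$cell_id[i], ": ",
           manifest$file[i], call. = FALSE)
    pages <- tiff::readTIFF(f, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != length(meta$channel_labels))
      stop("cell ", manifest$cell_id[i], " has ", length(pages),
           " pages but ", length(meta$channel_labels),
           " channels are declared", call. = FALSE)
    chans <- stats::setNames(pages, meta$channel_labels)
    cells[[i]] <- cell_record(manifest$cell_id[i], chans, labels[i])
  }
  imageset(cells, meta$channel_labels, provenance = meta$provenance %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
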