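#' Pack an image set into montage tiles
#'
#' Packs single-cell frames into large grid images ("tiles"), one montage
#' per channel per tile, so that image-wise analysis software can process
#' thousands of cells per file instead of crawling over per-cell files.
#' Cells are taken in container order, at most `tile_capacity` per tile;
#' within a tile every frame is centred in a slot of the per-tile maximum
#' frame size and the grid is square-ish
#' (`grid_cols = ceiling(sqrt(n))`, `grid_rows = ceiling(n / grid_cols)`).
#' Slots are filled row-major; unused slots hold `pad_value`.
#'
#' Padding never destroys information: each slot-map row records the
#' original frame size and the offset at which it was placed, so
#' [unpack_montages()] recovers every cell pixel-exactly. Bright-field
#' frames are padded with their own border median (bright-field background
#' is non-zero); all other channels are padded with 0.
#'
#' @param x An `ifc_imageset` with at least one cell.
#' @param tile_capacity Maximum number of cells per tile (default 1000).
#'
#' @return A list of tiles. Each tile is a list with elements
#'   `tile` (1-based index), `montages` (named list of `ifc_montage`
#'   objects, one per channel) and `slot_map` (tibble with columns
#'   `tile, slot, cell_id, orig_h, orig_w, off_r, off_c, label`; slots are
#'   0-based row-major, empty slots omitted).
#' @export
pack_montages <- function(x, tile_capacity = 1000L) {
  stopifnot(inherits(x, "ifc_imageset"))
  if (length(x$cells) == 0L) stop("image set is empty", call. = FALSE)
  if (!is.numeric(tile_capacity) || tile_capacity < 1)
    stop("`tile_capacity` must be >= 1", call. = FALSE)
  tile_capacity <- as.integer(tile_capacity)
  n <- length(x$cells)
  tile_of <- ((seq_len(n) - 1L) %/% tile_capacity) + 1L
  lapply(seq_len(max(tile_of)), function(t) {
    cells <- x$cells[tile_of == t]
    n_tile <- length(cells)
    grid_cols <- ceiling(sqrt(n_tile))
    grid_rows <- ceiling(n_tile / grid_cols)
    hs <- vapply(cells, function(cl) nrow(cl$channels[[1]]), integer(1))
    ws <- vapply(cells, function(cl) ncol(cl$channels[[1]]), integer(1))
    cell_h <- max(hs); cell_w <- max(ws)
    off_r <- (cell_h - hs) %/% 2L
    off_c <- (cell_w - ws) %/% 2L
    slot_map <- tibble::tibble(
      tile = t,
      slot = seq_len(n_tile) - 1L,
      cell_id = vapply(cells, function(cl) cl$cell_id, character(1)),
      orig_h = hs, orig_w = ws, off_r = off_r, off_c = off_c,
      label = vapply(cells, function(cl) cl$label, character(1)))
    montages <- lapply(x$channel_labels, function(ch) {
      pads <- vapply(seq_along(cells), function(i) {
        if (!is_bf_label(ch)) return(0)
        m <- cells[[i]]$channels[[ch]]
        border_median(m)
      }, numeric(1))
      pad_value <- if (is_bf_label(ch) && length(pads)) median(pads) else 0
      px <- matrix(pad_value, nrow = grid_rows * cell_h, ncol = grid_cols * cell_w)
      for (i in seq_along(cells)) {
        s <- i - 1L
        r0 <- (s %/% grid_cols) * cell_h
        c0 <- (s %% grid_cols) * cell_w
        frame <- matrix(pads[i], cell_h, cell_w)
        m <- cells[[i]]$channels[[ch]]
        frame[off_r[i] + seq_len(hs[i]), off_c[i] + seq_len(ws[i])] <- m
        px[r0 + seq_len(cell_h), c0 + seq_len(cell_w)] <- frame
      }
      slots <- rep(NA_character_, grid_rows * grid_cols)
      slots[seq_len(n_tile)] <- slot_map$cell_id
      structure(list(channel_label = ch, grid_rows = grid_rows,
                     grid_cols = grid_cols, cell_h = cell_h, cell_w = cell_w,
                     pixels = px, slots = slots, pad_value = pad_value),
                class = "ifc_montage")
    })
    names(montages) <- x$channel_labels
    list(tile = t, montages = montages, slot_map = slot_map)
  })
}

is_bf_label <- function(ch) toupper(ch) %in% c("BF", "BRIGHTFIELD")

border_median <- function(m) {
  h <- nrow(m); w <- ncol(m)
  if (h < 3 || w < 3) return(median(m))
  median(c(m[1, ], m[h, ], m[2:(h - 1), 1], m[2:(h - 1), w]))
}

#' @export
print.ifc_montage <- function(x, ...) {
  cat("<ifc_montage> channel ", x$channel_label, ", grid ", x$grid_rows, "x",
      x$grid_cols, ", slot ", x$cell_h, "x", x$cell_w, ", ",
      sum(!is.na(x$slots)), " cells\n", sep = "")
  invisible(x)
}

#' Unpack montage tiles back into an image set
#'
#' Inverse of [pack_montages()]: crops every occupied slot back to its
#' original frame using the recorded sizes and offsets. The round trip
#' `unpack_montages(pack_montages(x))` is pixel-exact and preserves labels.
#'
#' @param tiles List of tiles as returned by [pack_montages()] (or rebuilt
#'   from montage TIFFs plus slot-map CSVs).
#'
#' @return An `ifc_imageset`, cells in slot order.
#' @export
unpack_montages <- function(tiles) {
  stopifnot(is.list(tiles))
  all_cells <- list()
  channel_labels <- NULL
  for (tl in tiles) {
    sm <- tl$slot_map
    if (anyDuplicated(sm$cell_id))
      stop("corrupted slot map: duplicate cell_id ",
           paste(unique(sm$cell_id[duplicated(sm$cell_id)]), collapse = ", "),
           call. = FALSE)
    if (is.null(channel_labels)) channel_labels <- names(tl$montages)
    for (mon in tl$montages) {
      if (length(mon$slots) != mon$grid_rows * mon$grid_cols)
        stop("slot map size does not match montage grid", call. = FALSE)
      if (nrow(sm) > 0 && max(sm$slot) >= mon$grid_rows * mon$grid_cols)
        stop("slot map refers to a slot outside the montage grid", call. = FALSE)
    }
    if (nrow(sm) == 0L) next
    for (i in seq_len(nrow(sm))) {
      s <- sm$slot[i]
      chans <- lapply(tl$montages, function(mon) {
        r0 <- (s %/% mon$grid_cols) * mon$cell_h
        c0 <- (s %% mon$grid_cols) * mon$cell_w
        mon$pixels[r0 + sm$off_r[i] + seq_len(sm$orig_h[i]),
                   c0 + sm$off_c[i] + seq_len(sm$orig_w[i]), drop = FALSE]
      })
      lab <- if ("label" %in% names(sm)) sm$label[i] else NA_character_
      if (is.null(lab) || is.na(lab) || identical(lab, "")) lab <- NA_character_
      all_cells[[length(all_cells) + 1L]] <-
        cell_record(sm$cell_id[i], chans, lab)
    }
  }
  imageset(all_cells, channel_labels %||% character())
}

#' Write montage tiles to disk
#'
#' One 16-bit grayscale TIFF per channel per tile
#' (`tile<k>_<channel>.tif`) plus one slot-map CSV per tile
#' (`tile<k>_slots.csv`).
#'
#' @param tiles Output of [pack_montages()].
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_montages <- function(tiles, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (tl in tiles) {
    for (ch in names(tl$montages)) {
      mon <- tl$montages[[ch]]
      tiff::writeTIFF(mon$pixels,
                      file.path(path, sprintf("tile%03d_%s.tif", tl$tile, ch)),
                      bits.per.sample = BITS_PER_SAMPLE)
    }
    readr::write_csv(tl$slot_map,
                     file.path(path, sprintf("tile%03d_slots.csv", tl$tile)))
  }
  invisible(path)
}
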