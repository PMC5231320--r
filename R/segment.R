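#' Segment one cell frame from its bright-field image
#'
#' Produces the primary object mask that all masked features are computed
#' on. Pipeline: invert the bright-field frame (cells are darker than the
#' background by container convention), global Otsu threshold, morphological
#' closing with a disk of radius 2 (bridges thin necks, e.g. the telophase
#' midbody), hole filling, keep the largest 8-connected component, and
#' discard it if smaller than `min_area`.
#'
#' The Otsu criterion operates on the intensity histogram, so the mask is
#' invariant to linear rescaling of the input. Ties between equal-sized
#' largest components are broken by the component containing the first
#' foreground pixel in raster order (top-most, then left-most).
#'
#' @param bf Numeric matrix, bright-field frame, intensities in `[0, 1]`.
#' @param min_area Minimum object area in px (default 9); smaller objects
#'   yield an empty mask.
#' @param invert Set `FALSE` for instruments whose cells are brighter than
#'   the background.
#' @param closing_radius Disk radius for the morphological closing.
#'
#' @return A logical matrix the size of `bf`; all-`FALSE` when no
#'   component reaches `min_area` (the caller gates such cells out).
#' @export
segment_cell_frame <- function(bf, min_area = 9, invert = TRUE,
                               closing_radius = 2) {
  stopifnot(is.matrix(bf), nrow(bf) >= 1, ncol(bf) >= 1)
  empty <- matrix(FALSE, nrow(bf), ncol(bf))
  img <- if (invert) 1 - bf else bf
  rng <- range(img)
  if (diff(rng) < 1e-9) return(empty)       # constant frame: nothing to segment
  img <- (img - rng[1]) / (rng[2] - rng[1]) # scale-invariant by construction
  thr <- EBImage::otsu(EBImage::Image(img))
  bin <- img > thr
  if (!any(bin)) return(empty)
  brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
  bin <- EBImage::closing(EBImage::Image(bin), brush)
  bin <- EBImage::fillHull(bin)
  lab <- EBImage::bwlabel(bin)
  ld <- EBImage::imageData(lab)
  if (max(ld) == 0) return(empty)
  sizes <- tabulate(ld[ld > 0])
  best <- which(sizes == max(sizes))[1]  # bwlabel labels in raster order
  if (sizes[best] < min_area) return(empty)
  ld == best
}

#' Segment every cell of an image set
#'
#' Applies [segment_cell_frame()] to the bright-field channel of each cell.
#'
#' @param x An `ifc_imageset` with a `BF` channel.
#' @param ... Passed to [segment_cell_frame()].
#' @return Named list mapping `cell_id` to a logical mask matrix.
#' @export
segment_imageset <- function(x, ...) {
  stopifnot(inherits(x, "ifc_imageset"))
  if (!"BF" %in% x$channel_labels)
    stop("image set has no BF channel", call. = FALSE)
  masks <- lapply(x$cells, function(cl) segment_cell_frame(cl$channels$BF, ...))
  stats::setNames(masks, cell_ids(x))
}

#' Intersection-over-union of two masks
#' @param a,b Logical matrices of identical size.
#' @return Scalar in `[0, 1]`; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  a <- a > 0; b <- b > 0
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
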