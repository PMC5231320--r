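#' Gradient-RMS focus score
#'
#' A normalised focus-quality measure of a grayscale frame: the root mean
#' square of the central-difference intensity gradient over interior
#' pixels, divided by the mean intensity so the score is invariant to
#' illumination scaling. Sharp frames score high; defocused frames low.
#' Constant frames (zero gradient) and frames with zero mean intensity
#' return 0 by convention.
#'
#' @param image Numeric matrix of intensities.
#' @return Non-negative scalar.
#' @export
gradient_rms <- function(image) {
  stopifnot(is.matrix(image), nrow(image) >= 1, ncol(image) >= 1)
  m <- mean(image)
  if (m <= 0) return(0)
  h <- nrow(image); w <- ncol(image)
  if (h < 3 || w < 3) return(0)
  ir <- 2:(h - 1); ic <- 2:(w - 1)
  gy <- (image[ir + 1, ic] - image[ir - 1, ic]) / 2
  gx <- (image[ir, ic + 1] - image[ir, ic - 1]) / 2
  sqrt(mean(gx^2 + gy^2)) / m
}

#' Mask aspect ratio
#'
#' Minor-to-major axis length ratio of a binary mask, from the
#' eigenvalues of its second-central-moment matrix; in `(0, 1]`, 1 for a
#' disk. A single-pixel mask returns 1 by convention.
#'
#' @param mask Logical (or 0/1) matrix with at least one foreground pixel.
#' @return Scalar in `(0, 1]`.
#' @export
mask_aspect_ratio <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask", call. = FALSE)
  if (sum(mask) == 1L) return(1)
  ax <- mask_axes(mask)
  if (ax$major <= 0) return(1)
  ax$minor / ax$major
}

# Second-central-moment axis lengths of a mask (shared with feature bank).
mask_axes <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  r <- idx[, 1]; c <- idx[, 2]
  u20 <- mean((c - mean(c))^2)
  u02 <- mean((r - mean(r))^2)
  u11 <- mean((c - mean(c)) * (r - mean(r)))
  com <- (u20 + u02) / 2
  dif <- sqrt(((u20 - u02) / 2)^2 + u11^2)
  l1 <- com + dif; l2 <- max(com - dif, 0)
  list(major = 4 * sqrt(l1), minor = 4 * sqrt(l2),
       orientation = 0.5 * atan2(2 * u11, u20 - u02))
}

#' Gate configuration
#'
#' Thresholds for the two-step pre-analysis gating: a focus gate on the
#' bright-field gradient RMS, then an area gate (removing debris and
#' oversized objects) and an aspect-ratio gate (removing clumps).
#'
#' `grms_min = "AUTO"` sets the focus threshold from the population: by
#' default (`auto_method = "half_median"`) to half the population median
#' focus score, which separates sharp cells from strongly defocused ones
#' and keeps everything when no defocused mode exists;
#' `auto_method = "percentile"` uses the `auto_percentile`-th percentile
#' instead, for histogram-style manual gating.
#'
#' @param grms_min Numeric threshold or `"AUTO"`.
#' @param area_min,area_max Mask area bounds, px^2.
#' @param aspect_min Minimum aspect ratio in `(0, 1]`.
#' @param auto_method `"half_median"` or `"percentile"`.
#' @param auto_percentile Percent used when `auto_method = "percentile"`.
#' @return A list of class `ifc_gate_config`.
#' @export
gate_config <- function(grms_min = "AUTO", area_min = 50, area_max = 460,
                        aspect_min = 0.2, auto_method = "half_median",
                        auto_percentile = 10) {
  stopifnot(area_min < area_max, aspect_min > 0, aspect_min <= 1,
            auto_method %in% c("half_median", "percentile"))
  structure(list(grms_min = grms_min, area_min = area_min,
                 area_max = area_max, aspect_min = aspect_min,
                 auto_method = auto_method,
                 auto_percentile = auto_percentile),
            class = "ifc_gate_config")
}

#' Apply focus, area and aspect gates to a population
#'
#' Reproduces sequential pre-analysis gating: first the focus gate on the
#' bright-field gradient RMS, then the area gate (`DEBRIS` below
#' `area_min`, `TOO_LARGE` above `area_max`), then the aspect gate
#' (`CLUMP` below `aspect_min`). Each rejected cell is annotated with the
#' first gate it failed. Cells whose segmentation produced an empty mask
#' are rejected as `DEBRIS`.
#'
#' @param x An `ifc_imageset` with a `BF` channel.
#' @param masks Named list mapping `cell_id` to a binary mask matrix (or
#'   `NULL` / empty matrix for cells segmentation failed on).
#' @param config A [gate_config()].
#'
#' @return A list of class `ifc_qc_result`: `kept_ids`, `rejected` (named
#'   character vector cell_id -> reason), `thresholds_used`, and a tidy
#'   `table` (tibble `cell_id, grms, area, aspect, kept, reason`).
#' @export
apply_gates <- function(x, masks, config = gate_config()) {
  stopifnot(inherits(x, "ifc_imageset"), inherits(config, "ifc_gate_config"))
  if (!"BF" %in% x$channel_labels)
    stop("image set has no BF channel", call. = FALSE)
  ids <- cell_ids(x)
  if (!all(ids %in% names(masks)))
    stop("every cell needs a mask; missing: ",
         paste(utils::head(setdiff(ids, names(masks)), 5), collapse = ", "),
         call. = FALSE)
  grms <- vapply(x$cells, function(cl) gradient_rms(cl$channels$BF), numeric(1))
  area <- vapply(ids, function(id) {
    m <- masks[[id]]
    if (is.null(m)) 0L else sum(m > 0)
  }, integer(1))
  aspect <- vapply(ids, function(id) {
    m <- masks[[id]]
    if (is.null(m) || !any(m > 0)) NA_real_ else mask_aspect_ratio(m)
  }, numeric(1))

  grms_thr <- config$grms_min
  if (identical(grms_thr, "AUTO")) {
    grms_thr <- switch(config$auto_method,
      half_median = 0.5 * median(grms),
      percentile = as.numeric(quantile(grms, config$auto_percentile / 100)))
  }

  reason <- rep(NA_character_, length(ids))
  reason[grms < grms_thr] <- "OUT_OF_FOCUS"
  sel <- is.na(reason) & area < config$area_min
  reason[sel] <- "DEBRIS"
  sel <- is.na(reason) & area > config$area_max
  reason[sel] <- "TOO_LARGE"
  sel <- is.na(reason) & (!is.na(aspect) & aspect < config$aspect_min)
  reason[sel] <- "CLUMP"

  kept <- is.na(reason)
  res <- list(
    kept_ids = ids[kept],
    rejected = stats::setNames(reason[!kept], ids[!kept]),
    thresholds_used = list(grms_min = grms_thr, area_min = config$area_min,
                           area_max = config$area_max,
                           aspect_min = config$aspect_min),
    table = tibble::tibble(cell_id = ids, grms = grms, area = area,
                           aspect = aspect, kept = kept, reason = reason))
  class(res) <- "ifc_qc_result"
  res
}

#' @export
print.ifc_qc_result <- function(x, ...) {
  cat("<ifc_qc_result> kept ", length(x$kept_ids), " / ",
      nrow(x$table), " cells\n", sep = "")
  if (length(x$rejected)) {
    tab <- table(x$rejected)
    cat("  rejected:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  }
  cat("  focus threshold:", format(x$thresholds_used$grms_min, digits = 4), "\n")
  invisible(x)
}

#' @rdname apply_gates
#' @param x An `ifc_qc_result`.
#' @param ... Unused.
#' @export
tidy.ifc_qc_result <- function(x, ...) x$table

#' Write a QC result as CSV plus a JSON threshold sidecar
#' @param x An `ifc_qc_result`.
#' @param path CSV output path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_qc_result <- function(x, path) {
  readr::write_csv(x$table, path)
  jsonlite::write_json(x$thresholds_used,
                       sub("\\.csv$", "_thresholds.json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
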