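# ---- area/shape ------------------------------------------------------------

#' Area and shape features of a cell mask
#'
#' Standard region properties of a single-component binary mask:
#' * `Area` — foreground pixel count;
#' * `Perimeter` — boundary chain length (1 per axial step, sqrt(2) per
#'   diagonal step along the traced 8-connected contour);
#' * `MajorAxisLength`, `MinorAxisLength` — `4 * sqrt(eigenvalue)` of the
#'   second-central-moment matrix of pixel centres;
#' * `Eccentricity` — `sqrt(1 - (minor/major)^2)`;
#' * `Compactness` — `Perimeter^2 / (4 * pi * Area)`, 1 for a circle;
#' * `MaxFeretDiameter` — maximum pairwise distance between convex-hull
#'   vertex pixel centres;
#' * `MeanRadius`, `MaximumRadius` — mean and maximum of the Euclidean
#'   distance transform over the mask interior;
#' * `Orientation` — major-axis angle (radians); registered but excluded
#'   from classification by default.
#'
#' @param mask Logical (or 0/1) matrix with at least one foreground pixel.
#' @return Named numeric vector.
#' @export
measure_area_shape <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask", call. = FALSE)
  area <- sum(mask)
  per <- mask_perimeter(mask)
  ax <- mask_axes(mask)
  ecc <- if (ax$major > 0) sqrt(max(0, 1 - (ax$minor / ax$major)^2)) else 0
  dt <- mask_distmap(mask)
  dtv <- dt[mask]
  feret <- mask_max_feret(mask)
  c(Area = area,
    Perimeter = per,
    MajorAxisLength = ax$major,
    MinorAxisLength = ax$minor,
    Eccentricity = ecc,
    Compactness = per^2 / (4 * pi * area),
    MaxFeretDiameter = feret,
    MeanRadius = mean(dtv),
    MaximumRadius = max(dtv),
    Orientation = ax$orientation)
}

mask_distmap <- function(mask) {
  EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1)))
}

mask_perimeter <- function(mask) {
  if (sum(mask) == 1L) return(4)
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  chain <- oc[[1]]
  if (nrow(chain) < 2) return(4)
  d <- sqrt(rowSums((chain - chain[c(2:nrow(chain), 1), ])^2))
  sum(d)
}

mask_max_feret <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 1L) return(0)
  hull <- grDevices::chull(idx[, 2], idx[, 1])
  pts <- idx[hull, , drop = FALSE]
  max(stats::dist(pts))
}

# ---- Zernike moments -------------------------------------------------------

#' Zernike moment magnitudes of a mask
#'
#' Rotation-invariant shape descriptors: the mask is mapped onto the unit
#' disk centred at its centroid, with radius equal to the maximum
#' centroid-to-pixel distance, and the magnitude of each Zernike moment
#' `Z_nm` (orders `0 <= n <= max_order`, `m <= n`, `n - m` even) is
#' computed as `(n + 1) / N_disk * |sum over mask pixels of V*_nm|`, where
#' `N_disk` counts the lattice points inside the unit disk at this scale.
#' The normalisation makes a solid disk yield `Zernike_0_0 = 1`; a
#' single-pixel mask returns `Z_0_0 = 1` and 0 elsewhere by convention.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param max_order Maximum radial order `n` (default 9, 30 magnitudes).
#' @return Named numeric vector `Zernike_n_m`.
#' @export
zernike_magnitudes <- function(mask, max_order = 9) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask", call. = FALSE)
  nm <- zernike_orders(max_order)
  out <- stats::setNames(numeric(nrow(nm)),
                         sprintf("Zernike_%d_%d", nm$n, nm$m))
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  dr <- idx[, 1] - cy; dc <- idx[, 2] - cx
  rad <- sqrt(max(dr^2 + dc^2))
  if (rad == 0) { out["Zernike_0_0"] <- 1; return(out) }
  rho <- sqrt(dr^2 + dc^2) / rad
  theta <- atan2(dr, dc)
  # lattice points inside the unit disk at this scale
  rs <- seq(floor(cy - rad), ceiling(cy + rad))
  cs <- seq(floor(cx - rad), ceiling(cx + rad))
  gg <- expand.grid(r = rs, c = cs)
  n_disk <- sum((gg$r - cy)^2 + (gg$c - cx)^2 <= rad^2)
  for (k in seq_len(nrow(nm))) {
    n <- nm$n[k]; m <- nm$m[k]
    R <- zernike_radial(n, m, rho)
    v <- sum(R * exp(complex(imaginary = -m * theta)))
    out[k] <- (n + 1) / n_disk * Mod(v)
  }
  out
}

zernike_orders <- function(max_order) {
  nm <- expand.grid(m = 0:max_order, n = 0:max_order)
  nm <- nm[nm$m <= nm$n & (nm$n - nm$m) %% 2 == 0, c("n", "m")]
  nm[order(nm$n, nm$m), ]
}

zernike_radial <- function(n, m, rho) {
  s_max <- (n - m) / 2
  R <- numeric(length(rho))
  for (s in 0:s_max) {
    R <- R + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s)) *
      rho^(n - 2 * s)
  }
  R
}

# ---- intensity -------------------------------------------------------------

#' Intensity features of a cell over its mask
#'
#' Over mask pixels: `IntegratedIntensity` (sum), `MeanIntensity`,
#' `LowerQuartileIntensity` (25th percentile, linear interpolation). Over
#' the 8-connected inner boundary: `IntegratedIntensityEdge`,
#' `MeanIntensityEdge`, `MinIntensityEdge`. `MassDisplacement` is the
#' distance in px between the binary centroid and the intensity-weighted
#' centroid (0 by convention when total intensity is zero).
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical matrix of the same size.
#' @return Named numeric vector.
#' @export
measure_intensity <- function(image, mask) {
  mask <- mask > 0
  stopifnot(identical(dim(image), dim(mask)))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  v <- image[mask]
  edge <- inner_boundary(mask)
  ev <- image[edge]
  idx <- which(mask, arr.ind = TRUE)
  tot <- sum(v)
  md <- if (tot > 0) {
    bc <- colMeans(idx)
    wc <- colSums(idx * v) / tot
    sqrt(sum((bc - wc)^2))
  } else 0
  c(IntegratedIntensity = tot,
    MeanIntensity = mean(v),
    LowerQuartileIntensity = as.numeric(quantile(v, 0.25, type = 7)),
    IntegratedIntensityEdge = sum(ev),
    MeanIntensityEdge = mean(ev),
    MinIntensityEdge = min(ev),
    MassDisplacement = md)
}

# Mask pixels with at least one 8-neighbour outside the mask.
inner_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  nb <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- nb & pad[2:(h + 1) + dr, 2:(w + 1) + dc]
  }
  mask & !nb
}

# ---- radial distribution ---------------------------------------------------

#' Radial intensity distribution over concentric rings
#'
#' Each mask pixel receives a normalised radial coordinate
#' `r = 1 - DT / max(DT)` from the Euclidean distance transform (0 at the
#' innermost point, 1 at the edge), which stays well defined for
#' non-star-shaped masks such as dumbbells. Rings `k = 1..n_rings` cover
#' `r` in `[(k-1)/n, k/n)` (last ring closed). Per ring:
#' `FracAtD` = ring intensity / total intensity; `MeanFrac` = `FracAtD`
#' divided by the ring's pixel fraction; `RadialCV` = sd/mean of the
#' ring's per-wedge mean intensities over `n_wedges` equal angular wedges
#' about the binary centroid (empty wedges excluded). Wedge means rather
#' than totals are used so the statistic reflects angular intensity
#' asymmetry, not rasterisation jitter in wedge pixel counts; wedge
#' boundaries are rotated by half a wedge off the lattice rays for the
#' same reason. Empty rings yield `NaN`.
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical matrix of the same size.
#' @param n_rings,n_wedges Ring and wedge counts (defaults 4 and 8).
#' @return Named numeric vector `FracAtD_kofn`, `MeanFrac_kofn`,
#'   `RadialCV_kofn`.
#' @export
measure_radial_distribution <- function(image, mask, n_rings = 4, n_wedges = 8) {
  mask <- mask > 0
  stopifnot(identical(dim(image), dim(mask)), n_rings >= 1)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  dt <- mask_distmap(mask)
  dtm <- max(dt)
  r <- 1 - dt / dtm
  ring <- pmin(floor(r * n_rings) + 1L, n_rings)  # last ring closed at r = 1
  ring[!mask] <- NA_integer_
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  ang <- atan2(idx[, 1] - cy, idx[, 2] - cx)            # (-pi, pi]
  # wedge boundaries are offset by half a wedge so they fall between the
  # lattice's axis/diagonal rays instead of along them
  shifted <- (ang + pi + pi / n_wedges) %% (2 * pi)
  wedge <- pmin(floor(shifted / (2 * pi) * n_wedges) + 1L, n_wedges)
  rv <- ring[mask]
  iv <- image[mask]
  total <- sum(iv)
  n_mask <- length(iv)
  out <- numeric(0)
  for (k in seq_len(n_rings)) {
    sel <- rv == k
    npx <- sum(sel)
    if (npx == 0 || total <= 0) {
      frac <- if (total > 0) 0 else NaN
      meanfrac <- NaN; cv <- NaN
    } else {
      frac <- sum(iv[sel]) / total
      meanfrac <- frac / (npx / n_mask)
      wt <- tapply(iv[sel], wedge[sel], mean)  # occupied wedges only
      cv <- if (length(wt) > 1 && mean(wt) > 0) sd(wt) / mean(wt) else NaN
    }
    out <- c(out, stats::setNames(
      c(frac, meanfrac, cv),
      sprintf(c("FracAtD_%dof%d", "MeanFrac_%dof%d", "RadialCV_%dof%d"),
              k, n_rings)))
  }
  out
}

# ---- granularity -----------------------------------------------------------

#' Granularity spectrum by grayscale openings
#'
#' Measures texture grain size as the fraction of masked intensity removed
#' by grayscale openings with disks of increasing radius. The masked image
#' (background zeroed) is first background-corrected by subtracting its
#' opening with a disk of `bg_radius` (clamped at 0), giving `I0` with
#' total `S0`; then for `k = 1..max_radius`,
#' `g_k = 100 * (S_{k-1} - S_k) / S0` where `S_k` is the total of the
#' opening of `I0` by a disk of radius `k`. `g_1` is the spectrum's first
#' element (fine grain). If `S0 = 0` the whole spectrum is 0 by convention.
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical matrix of the same size.
#' @param max_radius Largest opening radius (default 8).
#' @param bg_radius Background-correction opening radius (default 10).
#' @return Numeric vector `g_1 .. g_max_radius` (names `Granularity_k`).
#' @export
granularity_spectrum <- function(image, mask, max_radius = 8, bg_radius = 10) {
  mask <- mask > 0
  stopifnot(identical(dim(image), dim(mask)))
  img <- image
  img[!mask] <- 0
  bg <- gray_opening(img, bg_radius)
  i0 <- pmax(img - bg, 0)
  s0 <- sum(i0)
  out <- stats::setNames(numeric(max_radius),
                         sprintf("Granularity_%d", seq_len(max_radius)))
  if (s0 <= 0) return(out)
  s_prev <- s0
  for (k in seq_len(max_radius)) {
    s_k <- sum(gray_opening(i0, k))
    out[k] <- 100 * (s_prev - s_k) / s0
    s_prev <- s_k
  }
  out
}

gray_opening <- function(img, radius) {
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  EBImage::imageData(EBImage::opening(EBImage::Image(img), brush))
}

# ---- GLCM texture ----------------------------------------------------------

#' Information measure of correlation 2 from a co-occurrence matrix
#'
#' Haralick's InfoMeas2 texture statistic: masked pixels are quantised to
#' `levels` equal-width bins over the masked min-max range; the symmetric
#' gray-level co-occurrence matrix `P` is accumulated over pixel pairs at
#' offset `(dr, dc)` with both pixels inside the mask; with
#' `HXY = -sum P log2 P` and
#' `HXY2 = -sum_ij px(i) py(j) log2(px(i) py(j))`, the statistic is
#' `sqrt(1 - exp(-2 (HXY2 - HXY)))`, in `[0, 1)`. Degenerate inputs
#' (constant masked intensities, or no valid pixel pair at the offset)
#' return 0 by convention.
#'
#' @param image Numeric intensity matrix.
#' @param mask Logical matrix of the same size.
#' @param dr,dc Co-occurrence offset (default scale 3 at 0 degrees:
#'   `dr = 0, dc = 3`).
#' @param levels Number of gray levels (default 8).
#' @return Scalar in `[0, 1)`.
#' @export
glcm_infomeas2 <- function(image, mask, dr = 0, dc = 3, levels = 8) {
  mask <- mask > 0
  stopifnot(identical(dim(image), dim(mask)))
  if (!any(mask)) stop("empty mask", call. = FALSE)
  v <- image[mask]
  rng <- range(v)
  if (diff(rng) < 1e-12) return(0)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  q[mask] <- pmin(floor((image[mask] - rng[1]) / diff(rng) * levels) + 1L,
                  levels)
  h <- nrow(q); w <- ncol(q)
  r1 <- seq_len(h - abs(dr)); c1 <- seq_len(w - abs(dc))
  a <- q[r1 + max(dr, 0), c1 + max(dc, 0), drop = FALSE]
  b <- q[r1 + max(-dr, 0), c1 + max(-dc, 0), drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(0)
  counts <- tabulate((a[ok] - 1L) * levels + b[ok], nbins = levels^2)
  P <- matrix(counts, levels, levels, byrow = TRUE)
  P <- P + t(P)                                   # symmetric accumulation
  P <- P / sum(P)
  px <- rowSums(P); py <- colSums(P)
  nz <- P > 0
  hxy <- -sum(P[nz] * log2(P[nz]))
  pp <- outer(px, py)
  nz2 <- pp > 0
  hxy2 <- -sum(pp[nz2] * log2(pp[nz2]))
  sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
}

# ---- assembly --------------------------------------------------------------

channel_prefix <- function(ch) {
  switch(toupper(ch), BF = "BF", DF = "SSC", SSC = "SSC", ch)
}
channel_tag <- function(ch) {
  switch(toupper(ch), BF = "BF_image", DF = "DF_image", SSC = "DF_image",
         paste0(ch, "_image"))
}

#' Extract the full feature bank for one cell
#'
#' Computes shape features (including Zernike magnitudes) once on the
#' mask, and intensity, radial-distribution, granularity and texture
#' features per channel, under the `{CHN}_{Family}_{Name}` naming
#' convention: bright-field features are prefixed `BF_`, dark-field
#' features `SSC_`, with image tags `_BF_image` / `_DF_image`
#' (e.g. `SSC_Granularity_1_DF_image`, `BF_AreaShape_Zernike_2_2`,
#' `BF_Texture_InfoMeas2_BF_image_3_0`).
#'
#' @param cell An `ifc_cell`.
#' @param mask Logical mask matrix from [segment_cell_frame()].
#' @param channels Channels to measure (default all of the cell's).
#' @param n_rings,n_wedges Radial-distribution parameters.
#' @param granularity_max,granularity_bg Granularity radii.
#' @param glcm_dr,glcm_dc,glcm_levels Texture parameters.
#' @return Named numeric vector (>= 90 features for BF + DF).
#' @export
extract_features <- function(cell, mask, channels = names(cell$channels),
                             n_rings = 4, n_wedges = 8,
                             granularity_max = 8, granularity_bg = 10,
                             glcm_dr = 0, glcm_dc = 3, glcm_levels = 8) {
  stopifnot(inherits(cell, "ifc_cell"))
  if (!all(channels %in% names(cell$channels)))
    stop("cell ", cell$cell_id, " lacks channels: ",
         paste(setdiff(channels, names(cell$channels)), collapse = ", "),
         call. = FALSE)
  shp <- measure_area_shape(mask)
  zer <- zernike_magnitudes(mask)
  out <- c(stats::setNames(shp, paste0("BF_AreaShape_", names(shp))),
           stats::setNames(zer, paste0("BF_AreaShape_", names(zer))))
  for (ch in channels) {
    img <- cell$channels[[ch]]
    pre <- channel_prefix(ch)
    tag <- channel_tag(ch)
    ints <- measure_intensity(img, mask)
    rad <- measure_radial_distribution(img, mask, n_rings, n_wedges)
    gran <- granularity_spectrum(img, mask, granularity_max, granularity_bg)
    tex <- glcm_infomeas2(img, mask, glcm_dr, glcm_dc, glcm_levels)
    out <- c(out,
      stats::setNames(ints, sprintf("%s_Intensity_%s_%s", pre, names(ints), tag)),
      stats::setNames(rad, sprintf("%s_RadialDistribution_%s", pre,
                                   sub("^([A-Za-z]+)_", paste0("\\1_", tag, "_"),
                                       names(rad)))),
      stats::setNames(gran, sprintf("%s_%s_%s", pre, names(gran), tag)),
      stats::setNames(tex, sprintf("%s_Texture_InfoMeas2_%s_%d_%d", pre, tag,
                                   glcm_dc, 0L)))
  }
  out
}

#' Extract a feature table for an image set
#'
#' Runs [extract_features()] on every cell and returns a rectangular
#' tibble: `cell_id` first, one numeric column per feature, plus a
#' `flagged` column marking cells with any non-finite feature value
#' (non-finite values are kept as `NaN` sentinels). Cells whose mask is
#' empty are dropped with a warning (they are QC rejects).
#'
#' @param x An `ifc_imageset`.
#' @param masks Named list of masks from [segment_imageset()].
#' @param channels Channels to measure (default all).
#' @param ... Passed to [extract_features()].
#' @return A tibble with one row per segmented cell.
#' @export
extract_feature_table <- function(x, masks, channels = x$channel_labels, ...) {
  stopifnot(inherits(x, "ifc_imageset"))
  ids <- cell_ids(x)
  keep <- vapply(ids, function(id) {
    m <- masks[[id]]
    !is.null(m) && any(m > 0)
  }, logical(1))
  if (any(!keep))
    warning(sum(!keep), " cell(s) dropped: empty mask", call. = FALSE)
  rows <- lapply(which(keep), function(i) {
    extract_features(x$cells[[i]], masks[[ids[i]]], channels, ...)
  })
  if (!length(rows)) stop("no cell with a non-empty mask", call. = FALSE)
  mat <- do.call(rbind, rows)
  tbl <- tibble::as_tibble(mat)
  tbl <- tibble::add_column(tbl, cell_id = ids[keep], .before = 1)
  tbl$flagged <- apply(mat, 1, function(r) any(!is.finite(r)))
  tbl
}

#' Feature registry
#'
#' Parses the feature-naming convention into a registry: family, channel,
#' and an excluded-by-default flag for location/orientation features
#' (irrelevant for phase classification).
#'
#' @param table A feature table from [extract_feature_table()], or a
#'   character vector of feature names.
#' @return A tibble `feature, family, channel, excluded`.
#' @export
feature_registry <- function(table) {
  nms <- if (is.character(table)) table else
    setdiff(names(table), c("cell_id", "flagged"))
  parts <- strsplit(nms, "_")
  tibble::tibble(
    feature = nms,
    family = vapply(parts, function(p) p[2], character(1)),
    channel = vapply(parts, function(p) p[1], character(1)),
    excluded = grepl("Orientation|Location|Center", nms))
}

#' Drop irrelevant feature columns
#'
#' Removes feature columns whose name matches any of the exclusion
#' patterns (substring or glob); by default location, centre and angular
#' orientation features, which carry no phase information.
#'
#' @param table Feature table.
#' @param exclude_patterns Character patterns; `*` and `?` glob wildcards
#'   are honoured, otherwise substring match.
#' @return The filtered table (row count unchanged).
#' @export
filter_features <- function(table,
                            exclude_patterns = c("Orientation", "Location",
                                                 "Center")) {
  feats <- setdiff(names(table), c("cell_id", "flagged"))
  if (!length(exclude_patterns)) return(table)
  rx <- vapply(exclude_patterns, function(p) {
    if (grepl("[*?]", p)) utils::glob2rx(p) else p
  }, character(1))
  drop <- feats[Reduce(`|`, lapply(rx, function(r) grepl(r, feats)))]
  remaining <- setdiff(feats, drop)
  if (!length(remaining))
    stop("exclusion patterns would remove every feature column", call. = FALSE)
  table[, !(names(table) %in% drop), drop = FALSE]
}

#' Write a feature table plus its registry
#' @param table Feature table.
#' @param path CSV path; a registry JSON is written next to it.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  readr::write_csv(table, path)
  jsonlite::write_json(feature_registry(table),
                       sub("\\.csv$", "_registry.json", path),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
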