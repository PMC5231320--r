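#' Per-phase morphology parameters for the synthetic generator
#'
#' Each cell-cycle phase is emulated by a simple geometric and textural
#' model on two channels: bright-field (dark cell body on a bright
#' background, multiplicative speckle texture) and dark-field (dark
#' background, body intensity proportional to local texture energy, so
#' that granularity tracks chromatin condensation). Geometry by phase:
#' interphase and prophase are near-circular disks (prophase with
#' high-amplitude fine-grain texture, mimicking condensed chromatin),
#' metaphase an elongated ellipse, anaphase a wide-necked dumbbell and
#' telophase a well-separated dumbbell with a thin neck.
#'
#' @param phase One of [phase_levels()].
#' @param radius_mean,radius_sd Cell (or lobe) radius distribution, px.
#'   Draws are truncated at 2.5 standard deviations.
#' @param eccentricity_range Interval in `[0, 1)` the mask eccentricity is
#'   drawn from (disk/ellipse phases).
#' @param lobe_separation Distance between lobe centres, px (dumbbell
#'   phases; 0 otherwise).
#' @param neck_width Width of the bridge connecting the two lobes, px.
#' @param area_factor Scales the disk-equivalent area relative to
#'   `pi * radius^2` (condensed mitotic figures are smaller).
#' @param texture_grain_sd Correlation length of the speckle texture, px.
#' @param texture_amplitude Relative amplitude of the speckle, in `[0, 0.5]`.
#' @param df_gain Coupling of dark-field brightness to texture energy.
#'
#' @return A list of class `ifc_phase_params`.
#' @export
phase_params <- function(phase,
                         radius_mean, radius_sd = 1,
                         eccentricity_range = c(0, 0.2),
                         lobe_separation = 0, neck_width = 0,
                         area_factor = 1,
                         texture_grain_sd = 2, texture_amplitude = 0.1,
                         df_gain = 1) {
  stopifnot(phase %in% PHASE_LEVELS, radius_mean > 0, radius_sd >= 0,
            lobe_separation >= 0, neck_width >= 0,
            texture_amplitude >= 0, texture_amplitude <= 0.5,
            length(eccentricity_range) == 2,
            eccentricity_range[1] >= 0, eccentricity_range[2] < 1)
  structure(list(phase = phase, radius_mean = radius_mean,
                 radius_sd = radius_sd,
                 eccentricity_range = eccentricity_range,
                 lobe_separation = lobe_separation, neck_width = neck_width,
                 area_factor = area_factor,
                 texture_grain_sd = texture_grain_sd,
                 texture_amplitude = texture_amplitude, df_gain = df_gain),
            class = "ifc_phase_params")
}

#' Default per-phase generator parameters
#'
#' The frozen study conditions of the synthetic population: parameter
#' values chosen so that, with 50 cells per phase, every phase pair is
#' separated by at least three population standard deviations in at
#' least one of granularity, eccentricity, maximum Feret diameter or the
#' `Zernike_2_2` magnitude.
#'
#' @return Named list of [phase_params()] objects, one per phase.
#' @export
default_phase_params <- function() {
  list(
    Int  = phase_params("Int",  radius_mean = 9,   radius_sd = 1,
                        eccentricity_range = c(0, 0.2),
                        texture_grain_sd = 4, texture_amplitude = 0.12,
                        df_gain = 0.6),
    Pro  = phase_params("Pro",  radius_mean = 9.5, radius_sd = 1,
                        eccentricity_range = c(0, 0.2),
                        texture_grain_sd = 0.5, texture_amplitude = 0.35,
                        df_gain = 1),
    Meta = phase_params("Meta", radius_mean = 9,   radius_sd = 1,
                        eccentricity_range = c(0.88, 0.95),
                        area_factor = 0.7,
                        texture_grain_sd = 1.2, texture_amplitude = 0.2,
                        df_gain = 0.9),
    Ana  = phase_params("Ana",  radius_mean = 7,   radius_sd = 0.6,
                        lobe_separation = 10, neck_width = 6,
                        texture_grain_sd = 1.2, texture_amplitude = 0.2,
                        df_gain = 0.9),
    Telo = phase_params("Telo", radius_mean = 6,   radius_sd = 0.6,
                        lobe_separation = 22, neck_width = 2,
                        texture_grain_sd = 2.5, texture_amplitude = 0.15,
                        df_gain = 0.7))
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions at reduced scale: five phases
#' with extreme class imbalance (the rare mitotic classes keep their
#' literature counts of 15 anaphase and 25 telophase cells; the abundant
#' classes are scaled down proportionally), no contaminants unless
#' requested, 64-px frames.
#'
#' @param counts Named integer vector of cells per phase.
#' @param debris_frac,doublet_frac,defocus_frac Fractions of the
#'   population replaced by contaminants (deterministic counts,
#'   `round(frac * n)`); must sum to at most 1.
#' @param defocus_sigma Gaussian blur sigma (px) applied to defocused cells.
#' @param frame_size Square frame side, px.
#' @param noise_sd Additive Gaussian pixel noise, intensity units.
#' @param seed Integer RNG seed; a single RNG stream drives the whole
#'   population, so identical configurations give identical output.
#' @param phase_params Per-phase parameter list, as [default_phase_params()].
#'
#' @return A list of class `ifc_sim_config`.
#' @export
simulation_config <- function(counts = c(Int = 300, Pro = 38, Meta = 16,
                                         Ana = 15, Telo = 25),
                              debris_frac = 0, doublet_frac = 0,
                              defocus_frac = 0, defocus_sigma = 3,
                              frame_size = 64, noise_sd = 0.01,
                              seed = 42,
                              phase_params = default_phase_params()) {
  stopifnot(all(names(counts) %in% PHASE_LEVELS), all(counts >= 0),
            debris_frac >= 0, doublet_frac >= 0, defocus_frac >= 0,
            debris_frac + doublet_frac + defocus_frac <= 1,
            frame_size >= 16, noise_sd >= 0)
  counts <- counts[intersect(PHASE_LEVELS, names(counts))]
  structure(list(counts = counts, debris_frac = debris_frac,
                 doublet_frac = doublet_frac, defocus_frac = defocus_frac,
                 defocus_sigma = defocus_sigma, frame_size = frame_size,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 phase_params = phase_params),
            class = "ifc_sim_config")
}

# Smooth unit-variance speckle field.
speckle_field <- function(h, w, grain_sd) {
  z <- matrix(rnorm(h * w), h, w)
  if (grain_sd > 0.3) {
    z <- EBImage::imageData(EBImage::gblur(EBImage::Image(z), sigma = grain_sd))
  }
  s <- sd(z)
  if (s > 0) z / s else z
}

# Rasterise phase geometry onto an n x n grid; returns mask + lobe centres.
rasterize_phase_mask <- function(phase, p, n) {
  r <- p$radius_mean + min(max(rnorm(1, 0, p$radius_sd), -2.5 * p$radius_sd),
                           2.5 * p$radius_sd)
  theta <- runif(1, 0, pi)
  cx <- (n + 1) / 2 + runif(1, -1, 1)
  cy <- (n + 1) / 2 + runif(1, -1, 1)
  gr <- matrix(seq_len(n), n, n)          # row coordinate
  gc <- matrix(seq_len(n), n, n, byrow = TRUE)
  if (phase %in% c("Int", "Pro", "Meta")) {
    ecc <- runif(1, p$eccentricity_range[1], p$eccentricity_range[2])
    r_eff <- r * sqrt(p$area_factor)
    q <- (1 - ecc^2)^0.25
    a <- r_eff / q
    b <- r_eff * q
    if (2 * a + 4 > n)
      stop("frame too small to contain ", phase, " geometry", call. = FALSE)
    u <- (gc - cx) * cos(theta) + (gr - cy) * sin(theta)
    v <- -(gc - cx) * sin(theta) + (gr - cy) * cos(theta)
    mask <- (u / a)^2 + (v / b)^2 <= 1
    centres <- cbind(r = cy, c = cx)
  } else {
    sep <- p$lobe_separation
    if (sep + 2 * (r + 2.5 * p$radius_sd) + 4 > n)
      stop("frame too small to contain ", phase, " geometry", call. = FALSE)
    dx <- cos(theta) * sep / 2
    dy <- sin(theta) * sep / 2
    c1 <- c(cy - dy, cx - dx)   # (row, col)
    c2 <- c(cy + dy, cx + dx)
    lobe1 <- (gr - c1[1])^2 + (gc - c1[2])^2 <= r^2
    lobe2 <- (gr - c2[1])^2 + (gc - c2[2])^2 <= r^2
    # capsule of half-width neck_width/2 around the centre segment
    t <- ((gr - c1[1]) * (c2[1] - c1[1]) + (gc - c1[2]) * (c2[2] - c1[2])) /
      max(sep^2, 1e-9)
    tc <- pmin(pmax(t, 0), 1)
    d2 <- (gr - (c1[1] + tc * (c2[1] - c1[1])))^2 +
      (gc - (c1[2] + tc * (c2[2] - c1[2])))^2
    neck <- d2 <= (p$neck_width / 2)^2
    mask <- lobe1 | lobe2 | neck
    centres <- rbind(c1, c2)
    colnames(centres) <- c("r", "c")
  }
  list(mask = mask, lobe_centres = centres)
}

# Render BF/DF channels for a body mask with given texture parameters.
render_channels <- function(mask, p, noise_sd) {
  n <- nrow(mask)
  s <- speckle_field(n, n, p$texture_grain_sd)
  bf <- matrix(0.8, n, n)
  body <- 0.45 * (1 + p$texture_amplitude * s[mask])
  bf[mask] <- body
  # dark-field: flat body scattering plus local texture energy, both
  # proportional to the texture amplitude (zero amplitude => dark frame)
  df <- matrix(0, n, n)
  df[mask] <- p$df_gain * p$texture_amplitude * (0.6 + 1.8 * pmax(s[mask], 0))
  if (noise_sd > 0) {
    bf <- bf + matrix(rnorm(n * n, 0, noise_sd), n, n)
    df <- df + matrix(rnorm(n * n, 0, noise_sd), n, n)
  }
  list(BF = clamp01(bf), DF = clamp01(df))
}

clamp01 <- function(m) {
  m[m < 0] <- 0; m[m > 1] <- 1; m
}

#' Generate one synthetic cell
#'
#' Draws geometry and texture for a single cell of the given phase using
#' the current RNG stream (seed it, or use [generate_population()] which
#' manages a single stream). The ground-truth body mask and lobe centres
#' are stored in the record's `meta`.
#'
#' @param phase One of [phase_levels()].
#' @param params An `ifc_phase_params` object.
#' @param frame_size Square frame side, px.
#' @param noise_sd Additive Gaussian noise, intensity units.
#' @param cell_id Identifier for the record.
#'
#' @return An `ifc_cell` with channels `BF` and `DF`, labelled `phase`.
#' @export
generate_cell <- function(phase, params = default_phase_params()[[phase]],
                          frame_size = 64, noise_sd = 0.01,
                          cell_id = "cell_00001") {
  geo <- rasterize_phase_mask(phase, params, frame_size)
  ch <- render_channels(geo$mask, params, noise_sd)
  cell_record(cell_id, ch, label = phase,
              meta = list(gt_mask = geo$mask, lobe_centres = geo$lobe_centres))
}

generate_debris <- function(frame_size, noise_sd, cell_id, phase) {
  p <- phase_params(phase, radius_mean = 2, radius_sd = 0,
                    texture_grain_sd = 1, texture_amplitude = 0.1,
                    df_gain = 0.5)
  geo <- rasterize_phase_mask("Int", p, frame_size)
  ch <- render_channels(geo$mask, p, noise_sd)
  cell_record(cell_id, ch, label = phase,
              meta = list(gt_mask = geo$mask, contaminant = "debris"))
}

generate_doublet <- function(frame_size, noise_sd, cell_id, phase,
                             int_params) {
  r <- int_params$radius_mean
  # two touching equal disks; modelled as a zero-neck dumbbell
  p <- phase_params("Ana", radius_mean = r, radius_sd = 0,
                    lobe_separation = 2 * r, neck_width = 2,
                    texture_grain_sd = int_params$texture_grain_sd,
                    texture_amplitude = int_params$texture_amplitude,
                    df_gain = int_params$df_gain)
  geo <- rasterize_phase_mask("Ana", p, frame_size)
  ch <- render_channels(geo$mask, p, noise_sd)
  cell_record(cell_id, ch, label = phase,
              meta = list(gt_mask = geo$mask, contaminant = "doublet"))
}

#' Generate a labelled synthetic population
#'
#' Produces exactly the configured number of cells per phase, shuffled by
#' the seed, optionally replacing deterministic fractions with QC
#' contaminants: debris (tiny disk), doublets (two touching full-size
#' disks in one frame) and defocused cells (a normal cell blurred with a
#' Gaussian of `defocus_sigma`). Contaminant slots are chosen uniformly
#' across the shuffled population and flagged in the ground truth.
#'
#' @param config An [simulation_config()] object.
#'
#' @return A list with elements `images` (an `ifc_imageset`) and `truth`
#'   (tibble `cell_id, phase, contaminant`), plus the config as attribute.
#' @export
generate_population <- function(config = simulation_config()) {
  stopifnot(inherits(config, "ifc_sim_config"))
  withr::with_seed(config$seed, {
    phases <- rep(names(config$counts), config$counts)
    n <- length(phases)
    if (n == 0L) stop("configured counts are all zero", call. = FALSE)
    phases <- sample(phases)
    n_deb <- round(config$debris_frac * n)
    n_dbl <- round(config$doublet_frac * n)
    n_def <- round(config$defocus_frac * n)
    contaminant <- rep("none", n)
    if (n_deb + n_dbl + n_def > 0) {
      slots <- sample(n, n_deb + n_dbl + n_def)
      contaminant[slots[seq_len(n_deb)]] <- "debris"
      if (n_dbl > 0) contaminant[slots[n_deb + seq_len(n_dbl)]] <- "doublet"
      if (n_def > 0) contaminant[slots[n_deb + n_dbl + seq_len(n_def)]] <- "defocus"
    }
    ids <- sprintf("cell_%05d", seq_len(n))
    cells <- vector("list", n)
    for (i in seq_len(n)) {
      ph <- phases[i]
      cells[[i]] <- switch(
        contaminant[i],
        none = generate_cell(ph, config$phase_params[[ph]],
                             config$frame_size, config$noise_sd, ids[i]),
        debris = generate_debris(config$frame_size, config$noise_sd, ids[i], ph),
        doublet = generate_doublet(config$frame_size, config$noise_sd, ids[i],
                                   ph, config$phase_params$Int),
        defocus = {
          cl <- generate_cell(ph, config$phase_params[[ph]],
                              config$frame_size, config$noise_sd, ids[i])
          cl$channels <- lapply(cl$channels, function(m) {
            clamp01(EBImage::imageData(
              EBImage::gblur(EBImage::Image(m), sigma = config$defocus_sigma)))
          })
          cl$meta$contaminant <- "defocus"
          cl
        })
    }
    truth <- tibble::tibble(cell_id = ids, phase = phases,
                            contaminant = contaminant)
    out <- list(images = imageset(cells, c("BF", "DF"),
                                  provenance = "ifcml synthetic population"),
                truth = truth)
    attr(out, "config") <- config
    out
  })
}
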