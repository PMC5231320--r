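# Geometric rasterisers and independent oracles shared across tests.

rasterize_disk <- function(radius, frame = 2 * radius + 7) {
  ctr <- (frame + 1) / 2
  gr <- matrix(seq_len(frame), frame, frame)
  gc <- matrix(seq_len(frame), frame, frame, byrow = TRUE)
  (gr - ctr)^2 + (gc - ctr)^2 <= radius^2
}

rasterize_ellipse <- function(a, b, frame = 2 * max(a, b) + 7, angle = 0) {
  ctr <- (frame + 1) / 2
  gr <- matrix(seq_len(frame), frame, frame)
  gc <- matrix(seq_len(frame), frame, frame, byrow = TRUE)
  u <- (gc - ctr) * cos(angle) + (gr - ctr) * sin(angle)
  v <- -(gc - ctr) * sin(angle) + (gr - ctr) * cos(angle)
  (u / a)^2 + (v / b)^2 <= 1
}

rasterize_rectangle <- function(h, w, frame = max(h, w) + 10) {
  m <- matrix(FALSE, frame, frame)
  r0 <- floor((frame - h) / 2); c0 <- floor((frame - w) / 2)
  m[r0 + seq_len(h), c0 + seq_len(w)] <- TRUE
  m
}

# Two touching equal disks along the x axis.
rasterize_doublet <- function(radius, frame = 4 * radius + 9) {
  ctr <- (frame + 1) / 2
  gr <- matrix(seq_len(frame), frame, frame)
  gc <- matrix(seq_len(frame), frame, frame, byrow = TRUE)
  ((gr - ctr)^2 + (gc - ctr - radius)^2 <= radius^2) |
    ((gr - ctr)^2 + (gc - ctr + radius)^2 <= radius^2)
}

# Tiny random image set for container round trips.
make_random_imageset <- function(n, seed = 1, hw_range = c(8L, 16L),
                                 channels = c("BF", "DF")) {
  withr::with_seed(seed, {
    cells <- lapply(seq_len(n), function(i) {
      h <- sample(hw_range[1]:hw_range[2], 1)
      w <- sample(hw_range[1]:hw_range[2], 1)
      chans <- lapply(channels, function(ch) matrix(runif(h * w), h, w))
      names(chans) <- channels
      cell_record(sprintf("cell_%03d", i), chans,
                  label = sample(c(NA, phase_levels()), 1))
    })
    imageset(cells, channels)
  })
}

# Brute-force GLCM InfoMeas2 oracle: explicit loops, no shared code with
# the package implementation.
glcm_infomeas2_oracle <- function(img, mask, dr = 0, dc = 3, levels = 8) {
  v <- img[mask > 0]
  rng <- range(v)
  if (diff(rng) == 0) return(0)
  bin <- matrix(NA_integer_, nrow(img), ncol(img))
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    if (mask[r, c] > 0) {
      b <- floor((img[r, c] - rng[1]) / (rng[2] - rng[1]) * levels) + 1
      bin[r, c] <- min(b, levels)
    }
  }
  P <- matrix(0, levels, levels)
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    r2 <- r + dr; c2 <- c + dc
    if (r2 >= 1 && r2 <= nrow(img) && c2 >= 1 && c2 <= ncol(img) &&
        !is.na(bin[r, c]) && !is.na(bin[r2, c2])) {
      P[bin[r, c], bin[r2, c2]] <- P[bin[r, c], bin[r2, c2]] + 1
      P[bin[r2, c2], bin[r, c]] <- P[bin[r2, c2], bin[r, c]] + 1
    }
  }
  if (sum(P) == 0) return(0)
  P <- P / sum(P)
  px <- rowSums(P); py <- colSums(P)
  hxy <- 0; hxy2 <- 0
  for (i in seq_len(levels)) for (j in seq_len(levels)) {
    if (P[i, j] > 0) hxy <- hxy - P[i, j] * log2(P[i, j])
    if (px[i] * py[j] > 0)
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
  }
  sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
}

# Expensive shared fixtures, computed once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_population <- function() {
  cached("default_pop", generate_population(simulation_config(seed = 42)))
}

default_masks <- function() {
  cached("default_masks", segment_imageset(default_population()$images))
}

default_features <- function() {
  cached("default_features", {
    pop <- default_population()
    masks <- default_masks()
    qc <- apply_gates(pop$images, masks)
    kept <- subset_imageset(pop$images, qc$kept_ids)
    extract_feature_table(kept, masks)
  })
}

# Literal per-pixel Zernike oracle: textbook double loop, no vectorisation
# or code shared with the package implementation.
zernike_oracle <- function(mask, n, m) {
  idx <- which(mask > 0, arr.ind = TRUE)
  cy <- unname(mean(idx[, 1])); cx <- unname(mean(idx[, 2]))
  rad <- 0
  for (k in seq_len(nrow(idx))) {
    d <- sqrt((idx[k, 1] - cy)^2 + (idx[k, 2] - cx)^2)
    if (d > rad) rad <- d
  }
  if (rad == 0) return(if (n == 0 && m == 0) 1 else 0)
  re <- 0; im <- 0
  for (k in seq_len(nrow(idx))) {
    rho <- sqrt((idx[k, 1] - cy)^2 + (idx[k, 2] - cx)^2) / rad
    th <- atan2(idx[k, 1] - cy, idx[k, 2] - cx)
    R <- 0
    for (s in 0:((n - m) / 2)) {
      R <- R + (-1)^s * factorial(n - s) /
        (factorial(s) * factorial((n + m) / 2 - s) *
           factorial((n - m) / 2 - s)) * rho^(n - 2 * s)
    }
    re <- re + R * cos(m * th)
    im <- im - R * sin(m * th)
  }
  n_disk <- 0
  for (r in floor(cy - rad):ceiling(cy + rad)) {
    for (c in floor(cx - rad):ceiling(cx + rad)) {
      if ((r - cy)^2 + (c - cx)^2 <= rad^2) n_disk <- n_disk + 1
    }
  }
  unname((n + 1) / n_disk * sqrt(re^2 + im^2))
}

rot90cw <- function(m) t(m)[, nrow(m):1, drop = FALSE]
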