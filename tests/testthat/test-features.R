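test_that("area/shape features match closed forms on rasterised shapes", {
  disk <- rasterize_disk(20)
  f <- measure_area_shape(disk)
  expect_lte(f[["Eccentricity"]], 0.05)
  expect_gte(f[["Compactness"]], 1.0)
  expect_lte(f[["Compactness"]], 1.15)
  expect_equal(f[["MaximumRadius"]], 20, tolerance = 0.05)

  rect <- rasterize_rectangle(20, 40)
  fr <- measure_area_shape(rect)
  expect_equal(fr[["Area"]], 800)
  expect_equal(fr[["MaxFeretDiameter"]], sqrt(39^2 + 19^2))

  ell <- rasterize_ellipse(20, 10)
  fe <- measure_area_shape(ell)
  expect_equal(fe[["MajorAxisLength"]], 40, tolerance = 1)
  expect_equal(fe[["MinorAxisLength"]], 20, tolerance = 1)
  expect_equal(fe[["Eccentricity"]], sqrt(1 - 0.25), tolerance = 0.02)

  expect_error(measure_area_shape(matrix(FALSE, 4, 4)), "empty")
})

test_that("Zernike magnitudes reproduce the solid-disk spectrum and detect lobedness", {
  z <- zernike_magnitudes(rasterize_disk(18))
  expect_equal(z[["Zernike_0_0"]], 1, tolerance = 0.02)
  expect_lte(z[["Zernike_2_2"]], 0.02)
  # rotational symmetry: m != 0 magnitudes vanish on a disk (harmonics that
  # are multiples of 4 keep small residues from the square lattice's own
  # 4-fold symmetry, so they are excluded here)
  nm <- expand.grid(n = 0:9, m = 0:9)
  for (k in which(nm$m > 0 & nm$m %% 4 != 0 & nm$m <= nm$n &
                    (nm$n - nm$m) %% 2 == 0)) {
    expect_lte(z[[sprintf("Zernike_%d_%d", nm$n[k], nm$m[k])]], 0.03)
  }

  dumbbell <- rasterize_doublet(9)
  disk_eq <- rasterize_disk(round(sqrt(sum(dumbbell) / pi)))
  expect_gt(zernike_magnitudes(dumbbell)[["Zernike_2_2"]],
            zernike_magnitudes(disk_eq)[["Zernike_2_2"]])

  # single pixel: degenerate convention
  z1 <- zernike_magnitudes(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_equal(z1[["Zernike_0_0"]], 1)
  expect_equal(sum(z1), 1)
})

test_that("Zernike magnitudes agree with a per-pixel oracle on random blobs", {
  withr::with_seed(31, {
    for (rep in 1:6) {
      m <- rasterize_ellipse(sample(6:12, 1), sample(4:9, 1),
                             frame = 31, angle = runif(1, 0, pi))
      z <- zernike_magnitudes(m)
      for (nmpair in list(c(0, 0), c(2, 2), c(3, 1), c(4, 0), c(5, 5))) {
        expect_equal(z[[sprintf("Zernike_%d_%d", nmpair[1], nmpair[2])]],
                     zernike_oracle(m, nmpair[1], nmpair[2]),
                     tolerance = 1e-6)
      }
    }
  })
})

test_that("intensity features follow their definitions", {
  disk <- rasterize_disk(10)
  img <- matrix(0, nrow(disk), ncol(disk)); img[disk] <- 0.3
  f <- measure_intensity(img, disk)
  expect_equal(f[["IntegratedIntensity"]], 0.3 * sum(disk))
  expect_equal(f[["MeanIntensity"]], 0.3)
  expect_equal(f[["MassDisplacement"]], 0, tolerance = 1e-9)

  # interpolated lower quartile on a 4-px mask
  m4 <- matrix(FALSE, 2, 2); m4[] <- TRUE
  i4 <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2)
  expect_equal(measure_intensity(i4, m4)[["LowerQuartileIntensity"]], 0.175)

  # half-bright disk: mass shifts toward the bright half by 2/3 * 4R/(3 pi)
  R <- 15
  hd <- rasterize_disk(R)
  ctr <- (nrow(hd) + 1) / 2
  ih <- matrix(0, nrow(hd), ncol(hd))
  ih[hd] <- 0.2
  bright <- hd & col(hd) > ctr
  ih[bright] <- 1
  fh <- measure_intensity(ih, hd)
  expected <- (0.8 / 1.2) * 4 * R / (3 * pi)
  expect_equal(fh[["MassDisplacement"]], expected, tolerance = 0.1 * R)
  idx <- which(hd, arr.ind = TRUE)
  wc_col <- sum(idx[, 2] * ih[hd]) / sum(ih[hd])
  expect_gt(wc_col, mean(idx[, 2]))  # displaced toward the bright half
})

test_that("radial distribution fractions are exact for canonical intensity layouts", {
  disk <- rasterize_disk(14)
  uni <- matrix(0.6, nrow(disk), ncol(disk))
  f <- measure_radial_distribution(uni, disk)
  fracs <- f[grep("^FracAtD", names(f))]
  expect_equal(sum(fracs), 1, tolerance = 1e-9)
  expect_equal(unname(f[grep("^MeanFrac", names(f))]), rep(1, 4),
               tolerance = 1e-9)

  # angularly symmetric intensity: tiny RadialCV in every ring
  big <- rasterize_disk(30, frame = 65)
  ctr <- 33
  gr <- matrix(seq_len(65), 65, 65)
  gc <- t(gr)
  gauss <- exp(-((gr - ctr)^2 + (gc - ctr)^2) / (2 * 12^2))
  fg <- measure_radial_distribution(gauss, big)
  expect_true(all(fg[grep("^RadialCV", names(fg))] <= 0.05))

  # intensity confined to the outermost ring
  dt <- EBImage::imageData(EBImage::distmap(EBImage::Image(disk * 1)))
  rnorm_ <- 1 - dt / max(dt)
  outer_img <- matrix(0, nrow(disk), ncol(disk))
  outer_img[disk & rnorm_ >= 0.75] <- 0.5
  fo <- measure_radial_distribution(outer_img, disk)
  expect_equal(fo[["FracAtD_4of4"]], 1)
  expect_equal(fo[["FracAtD_1of4"]] + fo[["FracAtD_2of4"]] +
                 fo[["FracAtD_3of4"]], 0)
})

test_that("granularity spectrum has the expected degenerate and ordering behaviour", {
  # flat image: opening changes nothing, spectrum identically zero
  flat <- matrix(0.4, 40, 40)
  allmask <- matrix(TRUE, 40, 40)
  expect_equal(unname(granularity_spectrum(flat, allmask)), rep(0, 8))

  # single bright pixel: erased by the radius-1 opening
  spot <- matrix(0, 41, 41); spot[21, 21] <- 1
  g <- granularity_spectrum(spot, matrix(TRUE, 41, 41))
  expect_equal(g[["Granularity_1"]], 100)
  expect_equal(sum(g), 100)

  # fine-grain prophase texture out-granulates coarse interphase texture
  withr::with_seed(12, {
    g1 <- function(cl, m) granularity_spectrum(cl$channels$DF, m)[["Granularity_1"]]
    pro <- generate_cell("Pro"); int <- generate_cell("Int")
    expect_gt(g1(pro, pro$meta$gt_mask), g1(int, int$meta$gt_mask))
  })
})

test_that("GLCM InfoMeas2 matches a brute-force oracle and its analytic limits", {
  # constant image: degenerate, 0 by convention
  disk <- rasterize_disk(12)
  expect_equal(glcm_infomeas2(matrix(0.5, nrow(disk), ncol(disk)), disk), 0)

  # independent uniform noise: the joint distribution factorises, so
  # HXY2 - HXY -> 0 and InfoMeas2 -> 0 (finite-sample bias stays small)
  withr::with_seed(14, {
    big <- matrix(runif(100 * 100), 100, 100)
    v <- glcm_infomeas2(big, matrix(TRUE, 100, 100))
    expect_lte(v, 0.1)
    expect_equal(v, glcm_infomeas2_oracle(big, matrix(TRUE, 100, 100)),
                 tolerance = 1e-9)
  })

  # vertical stripes of period 6 px at offset (0, 3): pairs are perfectly
  # dependent (always opposite levels), so with HX = 1 bit the value is
  # sqrt(1 - exp(-2)); exact oracle match
  stripes <- matrix(rep(rep(c(0.2, 0.8), each = 3), length.out = 30 * 30),
                    30, 30, byrow = TRUE)
  m30 <- matrix(TRUE, 30, 30)
  expect_equal(glcm_infomeas2(stripes, m30), sqrt(1 - exp(-2)),
               tolerance = 1e-9)
  expect_equal(glcm_infomeas2(stripes, m30),
               glcm_infomeas2_oracle(stripes, m30), tolerance = 1e-9)

  # random masked fixtures: oracle equivalence
  withr::with_seed(15, {
    for (rep in 1:20) {
      img <- matrix(runif(24 * 24), 24, 24)
      msk <- rasterize_ellipse(sample(6:10, 1), sample(4:8, 1), frame = 24,
                               angle = runif(1, 0, pi))
      expect_equal(glcm_infomeas2(img, msk),
                   glcm_infomeas2_oracle(img, msk), tolerance = 1e-6)
    }
  })
})

test_that("feature assembly follows the naming convention and stays rectangular", {
  cl <- withr::with_seed(16, generate_cell("Int"))
  m <- segment_cell_frame(cl$channels$BF)
  v <- extract_features(cl, m)
  expect_true(all(c("SSC_Granularity_1_DF_image", "BF_AreaShape_Zernike_2_2",
                    "BF_Texture_InfoMeas2_BF_image_3_0",
                    "SSC_Intensity_MeanIntensity_DF_image",
                    "BF_RadialDistribution_MeanFrac_BF_image_4of4",
                    "BF_AreaShape_MaxFeretDiameter") %in% names(v)))
  expect_gte(length(v), 90)

  v_bf <- extract_features(cl, m, channels = "BF")
  expect_false(any(grepl("^SSC_", names(v_bf))))

  tab <- default_features()
  expect_gte(nrow(tab), 390)  # default population minus any QC rejects
  expect_false(anyNA(tab))
  reg <- feature_registry(tab)
  expect_setequal(reg$feature, setdiff(names(tab), c("cell_id", "flagged")))
  expect_true(all(reg$family[reg$feature == "SSC_Granularity_1_DF_image"] ==
                    "Granularity"))
  expect_true(reg$excluded[reg$feature == "BF_AreaShape_Orientation"])
})

test_that("features obey translation, rotation and intensity-scaling invariances", {
  cl <- withr::with_seed(17, generate_cell("Ana"))
  m <- segment_cell_frame(cl$channels$BF)

  embed <- function(mat, off, frame = 96, fill = 0) {
    out <- matrix(fill, frame, frame)
    out[off[1] + seq_len(nrow(mat)), off[2] + seq_len(ncol(mat))] <- mat
    out
  }
  mk_cell <- function(off) {
    cell_record(cl$cell_id, list(BF = embed(cl$channels$BF, off, fill = 0.8),
                                 DF = embed(cl$channels$DF, off)))
  }
  f1 <- extract_features(mk_cell(c(5, 5)), embed(m, c(5, 5)) > 0)
  f2 <- extract_features(mk_cell(c(10, 12)), embed(m, c(10, 12)) > 0)
  keep <- setdiff(names(f1), "BF_AreaShape_Orientation")
  expect_equal(f1[keep], f2[keep], tolerance = 1e-6)

  # 90-degree rotation: rotation-invariant families move < 1%
  rcl <- cell_record(cl$cell_id, lapply(cl$channels, rot90cw))
  fr <- extract_features(rcl, rot90cw(m) > 0)
  f0 <- extract_features(cl, m)
  inv <- c("BF_AreaShape_Area", "BF_AreaShape_Perimeter",
           "BF_AreaShape_Eccentricity", "BF_AreaShape_Zernike_2_2",
           "BF_AreaShape_Zernike_3_1", "SSC_Granularity_1_DF_image",
           "BF_Granularity_1_BF_image")
  for (nm in inv) {
    expect_equal(fr[[nm]], f0[[nm]], tolerance = 0.01 * max(abs(f0[[nm]]), 1e-6))
  }

  # intensity linearity
  half <- cell_record(cl$cell_id, lapply(cl$channels, function(x) x / 2))
  fh <- extract_features(half, m)
  expect_equal(fh[["SSC_Intensity_IntegratedIntensity_DF_image"]],
               f0[["SSC_Intensity_IntegratedIntensity_DF_image"]] / 2,
               tolerance = 1e-12)
  for (nm in c("SSC_RadialDistribution_MeanFrac_DF_image_2of4",
               "SSC_RadialDistribution_RadialCV_DF_image_2of4",
               "SSC_Texture_InfoMeas2_DF_image_3_0")) {
    expect_equal(fh[[nm]], f0[[nm]], tolerance = 1e-6)
  }
})

test_that("filter_features removes irrelevant columns and guards against emptying", {
  tab <- tibble::tibble(cell_id = c("a", "b"),
                        BF_AreaShape_Orientation = c(1, 2),
                        BF_AreaShape_Area = c(3, 4),
                        Location_Center_X = c(5, 6))
  out <- filter_features(tab)
  expect_identical(names(out), c("cell_id", "BF_AreaShape_Area"))
  expect_identical(filter_features(tab, character()), tab)
  expect_error(filter_features(tab, "*"), "every feature")
})
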