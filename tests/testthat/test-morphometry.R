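# Per-cell operators: Feret diameters/FDR, morphology classification,
# skeletonization, arborization hull, intensities, normalization.

test_that("Feret diameters agree with analytic shapes", {
  ang <- seq(0, 2 * pi, length.out = 361)[-361]
  circ <- cbind(15 * cos(ang), 15 * sin(ang))
  fd <- feret_diameters(circ)
  expect_lt(abs(fd["feret_max"] - 30) / 30, 0.005)
  expect_lt(abs(fd["feret_min"] - 30) / 30, 0.005)

  rect <- cbind(c(0, 40, 40, 0), c(0, 0, 10, 10))
  fd <- feret_diameters(rect)
  expect_equal(unname(fd["feret_max"]), sqrt(40^2 + 10^2))
  expect_equal(unname(fd["feret_min"]), 10)

  # micron scaling
  fd2 <- feret_diameters(rect, microns_per_pixel = 0.5)
  expect_equal(unname(fd2), unname(fd) / 2)

  expect_error(feret_diameters(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
})

test_that("rotating calipers match the brute-force oracle on 50 random convex polygons", {
  set.seed(123)
  for (k in 1:50) {
    poly <- random_convex_polygon(n = sample(6:25, 1))
    fd <- feret_diameters(poly)
    oracle <- feret_bruteforce(poly)
    expect_lt(abs(fd["feret_max"] - oracle["fmax"]) / oracle["fmax"], 0.005)
    expect_lt(abs(fd["feret_min"] - oracle["fmin"]) / oracle["fmin"], 0.005)
  }
})

test_that("FDR definition, bounds and classification rule", {
  expect_equal(feret_ratio(30, 30), 1)
  expect_equal(feret_ratio(20, 10), 2)
  expect_error(feret_ratio(20, 0), "positive")

  expect_equal(classify_morphology(2.5), "ramified")
  expect_equal(classify_morphology(3.5), "rod_amoeboid")
  expect_equal(classify_morphology(3.0), "rod_amoeboid")  # inclusive bound
  expect_error(classify_morphology(0.5), ">= 1")

  # 3:1 ellipse through the mask pipeline
  ell <- render_shape_mask("ellipse", a = 30, b = 10)
  hull <- microgliaMorph:::mask_center_hull(which(ell$mask), dim(ell$mask))
  fd <- feret_diameters(hull)
  expect_lt(abs(feret_ratio(fd[1], fd[2]) - 3), 0.05)
})

test_that("FDR of a rasterized ellipse is stable across orientations", {
  fdrs <- vapply(seq(0, 170, by = 10), function(deg) {
    m <- render_shape_mask("ellipse", a = 48, b = 24, theta = deg * pi / 180)
    hull <- microgliaMorph:::mask_center_hull(which(m$mask), dim(m$mask))
    fd <- feret_diameters(hull)
    unname(fd[1] / fd[2])
  }, numeric(1))
  expect_lt((max(fdrs) - min(fdrs)) / mean(fdrs), 0.02)
})

test_that("skeletonization reduces to centrelines, preserving topology", {
  cal <- pixel_calibration(1)
  bar <- matrix(FALSE, 20, 110)
  bar[9:11, 6:105] <- TRUE
  sk <- skeletonize_cell(bar, cal)
  expect_lte(abs(sk$skeleton_length_um - 100), 3)
  expect_true(all(sk$skeleton[bar == FALSE] == FALSE))  # skeleton inside mask
  expect_lte(sk$skeleton_area_um2, sum(bar))

  disk <- render_shape_mask("circle", r = 20)$mask
  expect_lte(sum(skeletonize_cell(disk, cal)$skeleton), 5)

  cross <- render_shape_mask("cross", arm_len = 80, arm_w = 3)$mask
  skc <- skeletonize_cell(cross, cal)
  expect_lt(abs(skc$skeleton_length_um - 160), 6)

  # same number of 8-connected components as the mask
  two <- matrix(FALSE, 40, 40)
  two[5:12, 5:30] <- TRUE
  two[25:32, 10:35] <- TRUE
  skt <- skeletonize_cell(two, cal)
  expect_equal(max(microgliaMorph:::label_components(skt$skeleton)), 2)
  expect_error(skeletonize_cell(matrix(FALSE, 5, 5), cal), "empty")

  # micron scaling: area scales with the square of the pitch
  sk2 <- skeletonize_cell(bar, pixel_calibration(2))
  expect_equal(sk2$skeleton_area_um2, 4 * sk$skeleton_area_um2)
  expect_equal(sk2$skeleton_length_um, 2 * sk$skeleton_length_um)
})

test_that("arborization hull area matches analytic and oracle values", {
  cal <- pixel_calibration(1)
  # filled right triangle, legs 400 and 300 (large enough that the +-0.5 px
  # pixel-corner quantization stays inside the 2% band)
  tri <- matrix(FALSE, 310, 410)
  xs <- matrix(rep(0:409, each = 310), 310, 410)
  ys <- matrix(rep(0:309, times = 410), 310, 410)
  tri[xs / 400 + ys / 300 <= 1] <- TRUE
  expect_lt(abs(arborization_area(tri, cal) - 60000) / 60000, 0.02)

  disk <- render_shape_mask("circle", r = 100)$mask
  expect_lt(abs(arborization_area(disk, cal) - sum(disk)) / sum(disk), 0.02)
  expect_error(arborization_area(matrix(FALSE, 4, 4), cal), "empty")
})

test_that("hull area equals the gift-wrapping + shoelace oracle on 50 star masks", {
  set.seed(99)
  cal <- pixel_calibration(1)
  for (k in 1:50) {
    m <- random_star_mask()
    area <- arborization_area(m, cal)
    pts <- microgliaMorph:::mask_corner_points(which(m), dim(m))
    oracle <- shoelace(gift_wrap_hull(pts))
    expect_lt(abs(area - oracle) / oracle, 0.001)
    expect_gte(area, sum(m))  # hull dominates the mask area
  }
})

test_that("soma mean intensity equals a per-pixel accumulation loop", {
  cal <- pixel_calibration(1)
  f <- field_image(matrix(128, 30, 30), cal)
  mask <- matrix(FALSE, 30, 30); mask[10:20, 10:20] <- TRUE
  expect_equal(soma_mean_intensity(f, mask), 128)

  half <- matrix(100, 30, 30); half[, 16:30] <- 200
  fh <- field_image(half, cal)
  m2 <- matrix(FALSE, 30, 30); m2[5, 11:20] <- TRUE  # 5 px at 100, 5 at 200
  expect_equal(soma_mean_intensity(fh, m2), 150)

  set.seed(4)
  rnd <- field_image(matrix(runif(900, 0, 255), 30, 30), cal)
  idx <- which(mask)
  acc <- 0
  for (i in idx) acc <- acc + rnd$pixels[i]
  expect_equal(soma_mean_intensity(rnd, mask), acc / length(idx))
  expect_error(soma_mean_intensity(rnd, matrix(FALSE, 30, 30)), "empty")
})

test_that("normalization maps anchors to targets and is affine-invariant", {
  syn <- noise_free_field(seed = 21)
  p <- recovery_params()
  somas <- segment_somas(syn$field, p)
  labs <- extract_cell_masks(syn$field, somas, p)
  model <- fit_normalization(syn$field, labs)
  expect_equal(normalized_soma_intensity(model, model$background_level),
               model$target_background)
  expect_equal(normalized_soma_intensity(model, model$foreground_anchor),
               model$target_anchor)
  mid <- (model$background_level + model$foreground_anchor) / 2
  expect_equal(normalized_soma_intensity(model, mid),
               (model$target_background + model$target_anchor) / 2)

  # identity when the field already sits at the target anchors
  id_model <- model
  id_model$background_level <- model$target_background
  id_model$foreground_anchor <- model$target_anchor
  id_model$slope <- 1; id_model$intercept <- 0
  expect_equal(normalized_soma_intensity(id_model, 123.4), 123.4)

  # gain/offset perturbation without clipping: normalized means invariant
  raw0 <- vapply(somas, function(s)
    soma_mean_intensity(syn$field, s$pixels), numeric(1))
  n0 <- normalized_soma_intensity(model, raw0)
  pert <- apply_gain_offset(syn$field, gain = 1.15, offset = 8)
  expect_equal(pert$clip_fraction, 0)
  somas2 <- segment_somas(pert$field, p)
  labs2 <- extract_cell_masks(pert$field, somas2, p)
  model2 <- fit_normalization(pert$field, labs2)
  raw2 <- vapply(somas2, function(s)
    soma_mean_intensity(pert$field, s$pixels), numeric(1))
  n2 <- normalized_soma_intensity(model2, raw2)
  expect_equal(length(n2), length(n0))
  expect_lt(max(abs(sort(n2) - sort(n0)) / sort(n0)), 0.01)

  blank <- field_image(matrix(20, 50, 50), pixel_calibration(1))
  expect_error(fit_normalization(blank, matrix(0L, 50, 50)), "infeasible")
})

test_that("measure_cell recovers planted geometry and composes all metrics", {
  syn <- noise_free_field(seed = 31)
  res <- measure_field(syn$field, recovery_params())
  tab <- as.data.frame(do.call(rbind, lapply(res$cells, as.data.frame)))
  tr <- syn$truth
  expect_equal(nrow(tab), nrow(tr))
  j <- match_truth(tab, tr)
  expect_equal(sort(j), seq_len(nrow(tr)))  # one-to-one match
  expect_true(all(abs(tab$soma_area_um2 / tr$soma_area_um2[j] - 1) < 0.1))
  expect_lt(median(abs(tab$fdr / tr$fdr[j] - 1)), 0.05)
  expect_lt(median(abs(tab$arborization_area_um2 / tr$hull_area_um2[j] - 1)),
            0.05)
  expect_true(all(tab$arborization_area_um2 >= tab$soma_area_um2))
  expect_true(all(tab$fdr >= 1))
  expect_true(all(tab$morph_class == "ramified"))  # planted a/b < 3
  expect_true(all(tab$mean_intensity_raw >= 0 & tab$mean_intensity_raw <= 255))
})

test_that("a circular soma without processes yields FDR ~ 1 and hull ~ soma", {
  cal <- default_field_geometry()$calibration
  circ <- render_shape_mask("circle", r = 25, margin = 30)
  px <- matrix(20, 128, 128)
  px[1:nrow(circ$mask), 1:ncol(circ$mask)][circ$mask] <- 200
  f <- field_image(px, cal)
  res <- measure_field(f, segmentation_params(smoothing_sigma_px = 0,
                                              max_soma_area_um2 = 500))
  expect_length(res$cells, 1)
  cell <- res$cells[[1]]
  # quantization plus the soma opening leave a few percent on a 25 px circle
  expect_lt(abs(cell$fdr - 1), 0.05)
  expect_equal(cell$morph_class, "ramified")
  expect_lt(abs(cell$arborization_area_um2 / cell$soma_area_um2 - 1), 0.05)

  # 3.5:1 elongated soma classifies as rod/amoeboid through the pipeline
  ell <- render_shape_mask("ellipse", a = 35, b = 10, margin = 25)
  px2 <- matrix(20, 128, 128)
  px2[1:nrow(ell$mask), 1:ncol(ell$mask)][ell$mask] <- 200
  f2 <- field_image(px2, cal)
  res2 <- measure_field(f2, segmentation_params(smoothing_sigma_px = 0,
                                                max_soma_area_um2 = 500))
  expect_equal(res2$cells[[1]]$morph_class, "rod_amoeboid")
})

test_that("morphometry is scale-equivariant in the calibration", {
  m <- render_shape_mask("ellipse", a = 20, b = 12)$mask
  a1 <- arborization_area(m, pixel_calibration(1))
  a2 <- arborization_area(m, pixel_calibration(2))
  expect_equal(a2, 4 * a1)
  hull <- microgliaMorph:::mask_center_hull(which(m), dim(m))
  f1 <- feret_diameters(hull, 1)
  f2 <- feret_diameters(hull, 2)
  expect_equal(unname(f2), 2 * unname(f1))
  expect_equal(f2[1] / f2[2], f1[1] / f1[2])  # FDR invariant
})

test_that("FDR >= 1 over 500 random synthetic shapes", {
  set.seed(2024)
  fdrs <- numeric(500)
  for (k in 1:500) {
    kind <- sample(c("ellipse", "rectangle", "blob"), 1)
    m <- switch(kind,
      ellipse = render_shape_mask("ellipse", a = runif(1, 6, 30),
                                  b = runif(1, 4, 20),
                                  theta = runif(1, 0, pi))$mask,
      rectangle = render_shape_mask("rectangle", w = runif(1, 8, 50),
                                    h = runif(1, 4, 30),
                                    theta = runif(1, 0, pi))$mask,
      blob = random_star_mask(71))
    fd <- feret_diameters(microgliaMorph:::mask_center_hull(which(m), dim(m)))
    fdrs[k] <- feret_ratio(fd[1], fd[2])
  }
  expect_true(all(fdrs >= 1))
})
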