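test_that("sum projection matches a loop oracle and is homogeneous", {
  expect_error(sum_project(list()), "non-empty")
  one <- matrix(runif(12), 3, 4)
  expect_equal(sum_project(list(one)), one)
  expect_equal(sum_project(list(matrix(2, 2, 2), matrix(2, 2, 2),
                                matrix(2, 2, 2))),
               matrix(6, 2, 2))

  set.seed(1)
  stack <- replicate(5, matrix(runif(30), 5, 6), simplify = FALSE)
  oracle <- matrix(0, 5, 6)
  for (s in stack) for (r in 1:5) for (c in 1:6) {
    oracle[r, c] <- oracle[r, c] + s[r, c]
  }
  expect_equal(sum_project(stack), oracle)
  # degree-1 homogeneity
  expect_equal(sum_project(lapply(stack, function(s) 3 * s)),
               3 * sum_project(stack))
})

test_that("soma ROI recovers bright components and respects the seed point", {
  img <- matrix(0, 40, 40)
  rows <- matrix(1:40, 40, 40); cols <- t(rows)
  disk_a <- (rows - 12)^2 + (cols - 12)^2 <= 36
  disk_b <- (rows - 30)^2 + (cols - 30)^2 <= 36
  img[disk_a | disk_b] <- 100
  expect_error(soma_roi(matrix(5, 10, 10)), "constant")

  roi <- soma_roi(img, seed_point = c(12, 12))
  expect_equal(roi, disk_a)
  roi_b <- soma_roi(img, seed_point = c(30, 30))
  expect_equal(roi_b, disk_b)
  expect_error(soma_roi(img, seed_point = c(1, 1)), "seed_point")

  # synthetic soma with noise: Jaccard vs true mask
  sm <- aisquant:::with_seed(3, generate_soma_image(32, 3, soma_level = 150,
                                                   texture_amp = 5))
  est <- soma_roi(sm$image, seed_point = round(dim(sm$image) / 2))
  jac <- sum(est & sm$mask) / sum(est | sm$mask)
  expect_gte(jac, 0.9)
})

test_that("mean intensity equals the loop oracle", {
  img <- matrix(c(0, 0, 10, 10), 2, 2)
  roi <- matrix(TRUE, 2, 2)
  expect_equal(mean_intensity(img, roi), 5)
  expect_equal(mean_intensity(matrix(7, 3, 3), matrix(TRUE, 3, 3)), 7)
  expect_error(mean_intensity(img, matrix(FALSE, 2, 2)), "empty")

  set.seed(2)
  img <- matrix(runif(64), 8, 8)
  roi <- matrix(runif(64) < 0.5, 8, 8); roi[1, 1] <- TRUE
  expect_equal(mean_intensity(img, roi), loop_mean(img, roi))
  expect_equal(mean_intensity(5 * img, roi), 5 * loop_mean(img, roi))
})

test_that("line profiles reproduce constant and linear fields", {
  img <- matrix(42, 30, 60)
  path <- rbind(c(10, 5), c(20, 40))
  prof <- profile_along_path(img, path, 5)
  expect_true(all(abs(prof$intensity - 42) < 1e-10))
  expect_equal(nrow(prof),
               floor(sqrt(sum((c(10, 35))^2))) + 1)

  # image f(r,c) = c: a horizontal path reads off the column coordinate
  lin <- matrix(rep(0:59, each = 30), 30, 60)
  hpath <- rbind(c(15, 3), c(15, 50))
  prof <- profile_along_path(lin, hpath, 5)
  expect_equal(prof$intensity, 3 + prof$position_px, tolerance = 1e-12)
  expect_equal(prof$n_clamped, rep(0L, nrow(prof)))
})

test_that("profiles are invariant to collinear vertex insertion", {
  set.seed(4)
  img <- matrix(runif(80 * 80, 0, 100), 80, 80)
  p2 <- rbind(c(20, 10), c(50, 60))
  mid <- (p2[1, ] + p2[2, ]) / 2
  p3 <- rbind(p2[1, ], mid, p2[2, ])
  a <- profile_along_path(img, p2, 5)
  b <- profile_along_path(img, p3, 5)
  expect_equal(a$intensity, b$intensity, tolerance = 1e-9)
})

test_that("out-of-bounds perpendicular samples are clamped and flagged", {
  img <- matrix(1, 10, 40)
  edge_path <- rbind(c(1, 5), c(1, 30))  # runs along the top edge
  prof <- profile_along_path(img, edge_path, 5)
  expect_true(all(prof$n_clamped > 0))
  expect_gt(attr(prof, "clamped_fraction"), 0)
})

test_that("AIS length follows threshold-crossing geometry", {
  pulse <- c(rep(0, 5), rep(10, 30), rep(0, 5))
  expect_equal(ais_length(pulse, 0.5, 0.1), 3.0)
  expect_equal(ais_length(rep(4, 25), 0.5, 0.1), 2.5)  # flat trace: full length
  expect_equal(ais_length(rep(0, 10)), 0)
  expect_error(ais_length(pulse, 1.2), "frac_of_peak")

  # noise-free rise/decay profile vs analytic crossings
  amp <- 100; rise <- 10; decay <- 30; frac <- 0.33
  tr <- generate_trace(amp, 200, rise, decay)
  x1 <- frac * rise
  x2 <- rise + decay * log(1 / frac)
  measured_px <- ais_length(tr$intensity, frac, 1)
  expect_lt(abs(measured_px - (x2 - x1)), 1.5)
})

test_that("AIS/soma ratio behaves and orders groups correctly", {
  rec <- tibble::tibble(ais_mean = c(100, 50), soma_mean = c(100, 100))
  expect_equal(ais_soma_ratio(rec)$ratio, c(1, 0.5))
  expect_error(ais_soma_ratio(tibble::tibble(ais_mean = 1, soma_mean = 0)),
               "positive")

  cfg <- synth_config(n_subjects_per_group = 4, cells_per_subject = 10,
                      groups = postmortem_groups(a_hc = 100, a_scz = 60),
                      subject_sd = 2, cell_noise_sd = 5, seed = 31)
  m <- quantify_cohort(generate_cohort(cfg))
  ratios <- tapply(m$ratio, m$diagnosis, mean)
  expect_lt(ratios["SCZ"], ratios["HC"])
})

test_that("rendered traces are recovered by profile extraction", {
  tr <- generate_trace(100, 70, baseline = 100)
  path <- rbind(c(20, 10), c(50, 70))  # oblique
  img <- render_trace_image(tr$intensity, path, dim = c(90, 90),
                            band_px = 6, background = 100)
  prof <- profile_along_path(img, path, 5)
  n <- min(nrow(prof), nrow(tr))
  err <- max(abs(prof$intensity[1:n] - tr$intensity[1:n]))
  expect_lt(err / max(tr$intensity), 0.02)
})

test_that("file-based quantification round-trips through TIFF", {
  dir <- withr::local_tempdir()
  tr <- generate_trace(100, 60, baseline = 50)
  img <- render_trace_image(tr$intensity, rbind(c(30, 10), c(30, 65)),
                            dim = c(64, 96), band_px = 6, background = 50)
  # add a bright soma blob for the ROI branch
  rows <- matrix(1:64, 64, 96); cols <- matrix(rep(1:96, each = 64), 64, 96)
  soma <- (rows - 12)^2 + (cols - 12)^2 <= 49
  img[soma] <- 400
  tiff::writeTIFF(img / 1000, file.path(dir, "cell1.tif"),
                  bits.per.sample = 16)
  ann <- list(list(cell_id = "c1", image = "cell1.tif",
                   path = list(c(30, 10), c(30, 65)),
                   soma_seed = c(12, 12), anchor_index = 0))
  sheet <- tibble::tibble(cell_id = "c1", subject_id = "s1", diagnosis = "HC",
                          treatment = "none", compartment = "AIS")
  out <- quantify_images(dir, ann, sheet)
  expect_equal(nrow(out$measurements), 1)
  # stored as 16-bit integers: intensities come back on the 0..65535 scale
  scale <- 65535 / 1000
  expect_equal(out$measurements$ais_mean, scale * mean(tr$intensity[1:56]),
               tolerance = 1e-3)
  expect_gt(out$measurements$soma_mean, 300 * scale)
  expect_equal(out$measurements$subject_id, "s1")
})
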