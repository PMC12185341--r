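test_that("gray-level quantization bins correctly", {
  img <- matrix(0:255, 16, 16)
  roi <- matrix(TRUE, 16, 16)
  q <- quantize_gray_levels(img, roi, 2)
  expect_equal(unique(as.integer(q[img < 128])), 1L)
  expect_equal(unique(as.integer(q[img >= 128])), 2L)

  const <- quantize_gray_levels(matrix(7, 4, 4), matrix(TRUE, 4, 4), 8)
  expect_equal(unique(as.integer(const)), 1L)

  set.seed(5)
  img <- matrix(runif(64, 10, 90), 8, 8)
  roi <- matrix(runif(64) < 0.8, 8, 8); roi[1, 1] <- TRUE
  q <- quantize_gray_levels(img, roi, 4)
  # loop-oracle binning
  lo <- min(img[roi]); hi <- max(img[roi])
  for (r in 1:8) for (c in 1:8) {
    if (!roi[r, c]) {
      expect_true(is.na(q[r, c]))
    } else {
      expect_equal(q[r, c],
                   min(floor((img[r, c] - lo) / (hi - lo) * 4) + 1, 4))
    }
  }
})

test_that("GLCM matches hand enumeration and oracle, with invariants", {
  img <- matrix(c(0, 255, 0, 255), 2, 2)  # [[0,0],[255,255]] by row
  q <- quantize_gray_levels(img, matrix(TRUE, 2, 2), 2)
  P <- glcm(q, 1, "0")
  expect_equal(P, diag(c(0.5, 0.5)))

  const <- quantize_gray_levels(matrix(3, 4, 4), matrix(TRUE, 4, 4), 8)
  Pc <- glcm(const)
  expect_equal(Pc[1, 1], 1)
  expect_equal(sum(Pc), 1)

  set.seed(6)
  for (i in 1:10) {
    q <- random_quantized(8, 8, 4)
    P <- glcm(q)
    expect_equal(P, oracle_glcm(q, 4, 1, c("0", "45", "90", "135")))
    expect_equal(P, t(P))            # symmetric
    expect_equal(sum(P), 1)          # normalised
  }
})

test_that("GLDM matches hand counts and the enumeration oracle", {
  const <- quantize_gray_levels(matrix(1, 3, 3), matrix(TRUE, 3, 3), 4)
  M <- gldm(const, alpha = 0, distance = 1)
  expect_equal(unname(M[1, "3"]), 4)  # corners
  expect_equal(unname(M[1, "5"]), 4)  # edges
  expect_equal(unname(M[1, "8"]), 1)  # centre

  single <- quantize_gray_levels(matrix(5, 1, 1), matrix(TRUE, 1, 1), 4)
  Ms <- gldm(single)
  expect_equal(sum(Ms), 1)
  expect_equal(unname(Ms[1, "0"]), 1)

  set.seed(7)
  for (i in 1:10) {
    q <- random_quantized(8, 8, 3)
    expect_equal(gldm(q, 0, 1), oracle_gldm(q, 3, 0, 1))
  }
})

test_that("GLSZM matches zone enumeration and conserves pixel mass", {
  img <- matrix(1, 5, 5)
  img[1, 1:3] <- 9; img[5, 3:5] <- 9  # two disjoint 3-pixel zones
  q <- quantize_gray_levels(img, matrix(TRUE, 5, 5), 2)
  Z <- glszm(q)
  expect_equal(unname(Z[2, "3"]), 2)

  const <- quantize_gray_levels(matrix(2, 4, 5), matrix(TRUE, 4, 5), 4)
  Zc <- glszm(const)
  expect_equal(unname(Zc[1, "20"]), 1)
  expect_equal(sum(Zc), 1)

  set.seed(8)
  for (i in 1:8) {
    q <- random_quantized(10, 10, 3)
    Z <- glszm(q)
    oz <- oracle_glszm(q, 3)
    # pad to common width before comparison
    w <- max(ncol(Z), ncol(oz))
    pad <- function(m) cbind(m, matrix(0, nrow(m), w - ncol(m)))
    expect_equal(unname(pad(Z)), unname(pad(oz)))
    # total zone pixel mass equals ROI pixel count
    sizes <- as.numeric(colnames(Z))
    expect_equal(sum(sweep(Z, 2, sizes, `*`)), sum(!is.na(q)))
  }
})

test_that("diagonally-touching zones are 8-connected", {
  img <- matrix(1, 4, 4)
  img[1, 1] <- 9; img[2, 2] <- 9; img[3, 3] <- 9
  q <- quantize_gray_levels(img, matrix(TRUE, 4, 4), 2)
  Z <- glszm(q)
  expect_equal(unname(Z[2, "3"]), 1)  # one 3-pixel diagonal zone, not three singletons
})

test_that("the 14-feature panel matches formulas on oracle matrices", {
  # degenerate constant region
  f <- texture_features(matrix(5, 6, 6), matrix(TRUE, 6, 6), n_bins = 8)
  expect_equal(f$glcm_contrast, 0)
  expect_equal(f$glcm_energy, 1)
  expect_equal(f$glcm_correlation, 1)
  expect_equal(f$glszm_zone_nonuniformity, 1)
  expect_equal(f$glszm_zone_entropy, 0)

  # hand-computed 2x2 case: P = diag(.5,.5)
  img <- matrix(c(0, 255, 0, 255), 2, 2)
  f <- texture_features(img, matrix(TRUE, 2, 2), n_bins = 2, directions = "0")
  expect_equal(f$glcm_contrast, 0)
  expect_equal(f$glcm_energy, 0.5)

  set.seed(9)
  for (i in 1:5) {
    img <- matrix(runif(256, 0, 100), 16, 16)
    roi <- matrix(runif(256) < 0.9, 16, 16); roi[1, 1] <- TRUE
    q <- quantize_gray_levels(img, roi, 6)
    P <- oracle_glcm(q, 6, 1, c("0", "45", "90", "135"))
    M <- oracle_gldm(q, 6, 0, 1)
    Z <- oracle_glszm(q, 6)
    got <- texture_features(img, roi, n_bins = 6)

    n <- 6; iidx <- matrix(1:n, n, n); jidx <- t(iidx)
    mu <- sum(iidx * P); sig2 <- sum((iidx - mu)^2 * P)
    expect_equal(got$glcm_contrast, sum((iidx - jidx)^2 * P), tolerance = 1e-9)
    expect_equal(got$glcm_correlation, (sum(iidx * jidx * P) - mu^2) / sig2,
                 tolerance = 1e-9)
    expect_equal(got$glcm_energy, sum(P^2), tolerance = 1e-9)
    expect_equal(got$glcm_homogeneity, sum(P / (1 + (iidx - jidx)^2)),
                 tolerance = 1e-9)
    pv <- P[P > 0]
    expect_equal(got$glcm_entropy, -sum(pv * log2(pv)), tolerance = 1e-9)
    pxy <- sapply(2:(2 * n), function(k) sum(P[iidx + jidx == k]))
    pxy <- pxy[pxy > 0]
    expect_equal(got$glcm_sum_entropy, -sum(pxy * log2(pxy)), tolerance = 1e-9)

    Nd <- sum(M); pd <- M / Nd
    dj <- matrix(as.numeric(colnames(M)) + 1, nrow(M), ncol(M), byrow = TRUE)
    expect_equal(got$gldm_small_dep_emphasis, sum(pd / dj^2), tolerance = 1e-9)
    expect_equal(got$gldm_large_dep_emphasis, sum(pd * dj^2), tolerance = 1e-9)
    expect_equal(got$gldm_dep_nonuniformity, sum(colSums(M)^2) / Nd^2,
                 tolerance = 1e-9)
    mu_d <- sum(pd * dj)
    expect_equal(got$gldm_dep_variance, sum(pd * (dj - mu_d)^2), tolerance = 1e-9)

    Nz <- sum(Z); pz <- Z / Nz
    sz <- matrix(as.numeric(colnames(Z)), nrow(Z), ncol(Z), byrow = TRUE)
    expect_equal(got$glszm_small_area_emphasis, sum(pz / sz^2), tolerance = 1e-9)
    expect_equal(got$glszm_large_area_emphasis, sum(pz * sz^2), tolerance = 1e-9)
    expect_equal(got$glszm_zone_nonuniformity, sum(colSums(Z)^2) / Nz^2,
                 tolerance = 1e-9)
    pzv <- pz[pz > 0]
    expect_equal(got$glszm_zone_entropy, -sum(pzv * log2(pzv)), tolerance = 1e-9)
  }
})

test_that("texture matrices are invariant to additive intensity shifts", {
  set.seed(10)
  img <- matrix(runif(144, 0, 50), 12, 12)
  roi <- matrix(runif(144) < 0.85, 12, 12); roi[1, 1] <- TRUE
  a <- texture_features(img, roi, n_bins = 8)
  b <- texture_features(img + 100, roi, n_bins = 8)
  expect_equal(a, b, tolerance = 1e-12)
})
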