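#' Quantize gray levels within a region of interest
#'
#' Equal-width binning of the ROI intensity range into integer levels
#' `1..n_bins` (the maximum maps into the top bin). Pixels outside the ROI are
#' set to `NA` and ignored by all downstream texture matrices. A constant
#' region quantizes to a single level.
#'
#' @param image Numeric matrix.
#' @param roi Logical matrix of the same shape.
#' @param n_bins Number of gray levels (>= 2).
#' @return An integer matrix of levels with `NA` outside the ROI and
#'   attribute `n_bins`.
#' @export
quantize_gray_levels <- function(image, roi, n_bins = 32L) {
  check_matrix_image(image)
  if (!is.logical(roi) || !identical(dim(roi), dim(image))) {
    abort("`roi` must be a logical matrix matching `image`.")
  }
  if (!any(roi)) abort("`roi` is empty.")
  check_number(n_bins, "n_bins", min = 2, integer = TRUE)
  vals <- image[roi]
  lo <- min(vals); hi <- max(vals)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  if (hi == lo) {
    q[roi] <- 1L
  } else {
    lv <- floor((image[roi] - lo) / (hi - lo) * n_bins) + 1L
    q[roi] <- pmin(lv, as.integer(n_bins))
  }
  attr(q, "n_bins") <- as.integer(n_bins)
  q
}

# Direction name -> (row, col) offset at unit distance.
direction_offsets <- function(directions, distance) {
  lookup <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
                 `135` = c(-1, -1))
  bad <- setdiff(directions, names(lookup))
  if (length(bad)) abort(paste("Unknown direction(s):", paste(bad, collapse = ", ")))
  lapply(lookup[directions], function(o) o * distance)
}

# Pairs of co-occurring levels for one offset (both pixels in ROI).
offset_pairs <- function(q, dr, dc) {
  nr <- nrow(q); nc <- ncol(q)
  if (max(1, 1 - dr) > min(nr, nr - dr) ||
      max(1, 1 - dc) > min(nc, nc - dc)) {
    return(matrix(integer(0), 0, 2))
  }
  r1 <- max(1, 1 - dr):min(nr, nr - dr)
  c1 <- max(1, 1 - dc):min(nc, nc - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  cbind(a[keep], b[keep])
}

#' Gray-level co-occurrence matrix
#'
#' Haralick co-occurrence matrix of a quantized ROI: counts of level pairs at
#' the given pixel distance, accumulated over the requested directions,
#' symmetrised (each pair counted in both orders) and normalised to sum 1.
#' Pairs with either pixel outside the ROI are skipped.
#'
#' @param quantized Output of [quantize_gray_levels()].
#' @param distance Pixel offset distance.
#' @param directions Subset of `c("0", "45", "90", "135")` (degrees).
#' @return An `n_bins` x `n_bins` numeric matrix summing to 1.
#' @export
glcm <- function(quantized, distance = 1L,
                 directions = c("0", "45", "90", "135")) {
  n_bins <- attr(quantized, "n_bins")
  if (is.null(n_bins)) abort("`quantized` must come from quantize_gray_levels().")
  offs <- direction_offsets(directions, distance)
  pairs <- do.call(rbind, lapply(offs, function(o) offset_pairs(quantized, o[1], o[2])))
  if (is.null(pairs) || nrow(pairs) == 0) {
    abort("No valid co-occurring pixel pairs in the ROI.")
  }
  P <- matrix(0, n_bins, n_bins)
  for (k in seq_len(nrow(pairs))) {
    P[pairs[k, 1], pairs[k, 2]] <- P[pairs[k, 1], pairs[k, 2]] + 1
    P[pairs[k, 2], pairs[k, 1]] <- P[pairs[k, 2], pairs[k, 1]] + 1
  }
  P / sum(P)
}

#' Gray-level dependence matrix
#'
#' `M[i, d+1]` counts ROI pixels of level `i` having exactly `d` neighbours
#' (Chebyshev distance at most `distance`, inside the ROI) whose level differs
#' from the centre by at most `alpha`. The dependence coordinate `d` runs from
#' 0 (no dependent neighbour) to the neighbourhood size; columns are named by
#' `d`.
#'
#' @param quantized Output of [quantize_gray_levels()].
#' @param alpha Level-difference tolerance for dependence.
#' @param distance Chebyshev neighbourhood radius.
#' @return An `n_bins` x `(max dependence + 1)` count matrix.
#' @export
gldm <- function(quantized, alpha = 0L, distance = 1L) {
  n_bins <- attr(quantized, "n_bins")
  if (is.null(n_bins)) abort("`quantized` must come from quantize_gray_levels().")
  nr <- nrow(quantized); nc <- ncol(quantized)
  dep <- matrix(0L, nr, nc)
  for (dr in -distance:distance) {
    for (dc in -distance:distance) {
      if (dr == 0 && dc == 0) next
      if (max(1, 1 - dr) > min(nr, nr - dr) ||
          max(1, 1 - dc) > min(nc, nc - dc)) next
      r1 <- max(1, 1 - dr):min(nr, nr - dr)
      c1 <- max(1, 1 - dc):min(nc, nc - dc)
      a <- quantized[r1, c1, drop = FALSE]
      b <- quantized[r1 + dr, c1 + dc, drop = FALSE]
      ok <- !is.na(a) & !is.na(b) & abs(a - b) <= alpha
      dep[r1, c1] <- dep[r1, c1] + ok
    }
  }
  in_roi <- !is.na(quantized)
  max_dep <- (2 * distance + 1)^2 - 1
  M <- matrix(0, n_bins, max_dep + 1,
              dimnames = list(NULL, as.character(0:max_dep)))
  tab <- table(factor(quantized[in_roi], levels = seq_len(n_bins)),
               factor(dep[in_roi], levels = 0:max_dep))
  M[] <- as.numeric(tab)
  # trim trailing all-zero dependence columns beyond the observed maximum
  last <- max(c(1L, which(colSums(M) > 0)))
  M[, seq_len(last), drop = FALSE]
}

# 8-connected zone sizes per level via flood fill (EBImage's labeller is
# 4-connected, so diagonal contacts need a hand-rolled pass).
label_zones_8 <- function(quantized) {
  nr <- nrow(quantized); nc <- ncol(quantized)
  visited <- is.na(quantized)
  zones <- list(); zi <- 0L
  neigh <- expand.grid(dr = -1:1, dc = -1:1)
  neigh <- neigh[!(neigh$dr == 0 & neigh$dc == 0), ]
  for (start in which(!visited)) {
    if (visited[start]) next
    lvl <- quantized[start]
    queue <- start
    visited[start] <- TRUE
    size <- 0L
    while (length(queue) > 0) {
      px <- queue[length(queue)]
      queue <- queue[-length(queue)]
      size <- size + 1L
      r <- ((px - 1) %% nr) + 1
      c <- ((px - 1) %/% nr) + 1
      rr <- r + neigh$dr; cc <- c + neigh$dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      idx <- (cc[ok] - 1) * nr + rr[ok]
      idx <- idx[!visited[idx] & quantized[idx] == lvl]
      if (length(idx)) {
        visited[idx] <- TRUE
        queue <- c(queue, idx)
      }
    }
    zi <- zi + 1L
    zones[[zi]] <- c(level = lvl, size = size)
  }
  do.call(rbind, zones)
}

#' Gray-level size-zone matrix
#'
#' `Z[i, s]` counts the 8-connected zones of level `i` containing exactly `s`
#' pixels within the ROI. The total pixel mass `sum(s * Z[i, s])` equals the
#' ROI pixel count.
#'
#' @param quantized Output of [quantize_gray_levels()].
#' @return An `n_bins` x `max zone size` count matrix with columns named by
#'   zone size.
#' @export
glszm <- function(quantized) {
  n_bins <- attr(quantized, "n_bins")
  if (is.null(n_bins)) abort("`quantized` must come from quantize_gray_levels().")
  if (!any(!is.na(quantized))) abort("`quantized` has an empty ROI.")
  zones <- label_zones_8(quantized)
  max_s <- max(zones[, "size"])
  Z <- matrix(0, n_bins, max_s, dimnames = list(NULL, as.character(seq_len(max_s))))
  for (k in seq_len(nrow(zones))) {
    Z[zones[k, "level"], zones[k, "size"]] <- Z[zones[k, "level"], zones[k, "size"]] + 1
  }
  Z
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# The 14 texture features from the three matrices. Degenerate (constant)
# regions take documented limits: contrast 0, energy 1, correlation 1.
texture_features_from_matrices <- function(P, M, Z) {
  n <- nrow(P)
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  mu <- sum(i * P)
  sig2 <- sum((i - mu)^2 * P)
  corr <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 1
  k <- 2:(2 * n)
  pxy <- sapply(k, function(kk) sum(P[i + j == kk]))

  Nd <- sum(M)
  pd <- M / Nd
  dj <- matrix(as.numeric(colnames(M)) + 1, nrow(M), ncol(M), byrow = TRUE)
  mu_d <- sum(pd * dj)

  Nz <- sum(Z)
  pz <- Z / Nz
  sz <- matrix(as.numeric(colnames(Z)), nrow(Z), ncol(Z), byrow = TRUE)

  c(
    glcm_contrast = sum((i - j)^2 * P),
    glcm_correlation = corr,
    glcm_energy = sum(P^2),
    glcm_homogeneity = sum(P / (1 + (i - j)^2)),
    glcm_entropy = entropy_bits(P),
    glcm_sum_entropy = entropy_bits(pxy),
    gldm_small_dep_emphasis = sum(pd / dj^2),
    gldm_large_dep_emphasis = sum(pd * dj^2),
    gldm_dep_nonuniformity = sum(colSums(M)^2) / Nd^2,
    gldm_dep_variance = sum(pd * (dj - mu_d)^2),
    glszm_small_area_emphasis = sum(pz / sz^2),
    glszm_large_area_emphasis = sum(pz * sz^2),
    glszm_zone_nonuniformity = sum(colSums(Z)^2) / Nz^2,
    glszm_zone_entropy = entropy_bits(pz)
  )
}

#' The 14-feature texture descriptor of a masked region
#'
#' Quantizes the ROI, builds the gray-level co-occurrence, dependence and
#' size-zone matrices, and evaluates a fixed 14-feature panel: GLCM contrast,
#' correlation, energy, homogeneity (inverse difference moment), entropy and
#' sum entropy; GLDM small/large dependence emphasis, dependence
#' non-uniformity (normalised) and dependence variance (dependence size taken
#' as neighbour count + 1); GLSZM small/large area emphasis, zone
#' non-uniformity (normalised) and zone entropy.
#'
#' @param image Numeric matrix.
#' @param roi Logical mask.
#' @param n_bins Gray levels for quantization.
#' @param distance GLCM/GLDM pixel distance.
#' @param alpha GLDM dependence tolerance.
#' @param directions GLCM directions.
#' @return A one-row tibble of the 14 named features, all finite.
#' @export
texture_features <- function(image, roi, n_bins = 32L, distance = 1L,
                             alpha = 0L, directions = c("0", "45", "90", "135")) {
  q <- quantize_gray_levels(image, roi, n_bins)
  feats <- texture_features_from_matrices(
    glcm(q, distance, directions),
    gldm(q, alpha, distance),
    glszm(q)
  )
  as_tibble(as.list(feats))
}

#' Texture features for every soma image of a cohort
#'
#' @param cohort A `synthetic_cohort` generated with soma images.
#' @param ... Passed to [texture_features()].
#' @return A tibble: metadata columns plus the 14 feature columns, one row per
#'   cell.
#' @export
texture_features_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (length(cohort$soma_images) == 0) abort("Cohort has no soma images.")
  feats <- purrr::imap(cohort$soma_images, function(sm, id) {
    out <- texture_features(sm$image, sm$mask, ...)
    out$cell_id <- id
    out
  }) %>% bind_rows()
  cohort$sample_sheet %>%
    select("cell_id", "subject_id", "diagnosis", "treatment") %>%
    dplyr::inner_join(feats, by = "cell_id")
}
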