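#' Sum-project a confocal z-stack
#'
#' Collapses a z-stack to a single 2D image by summing slice intensities per
#' pixel — the standard projection before intensity quantification.
#'
#' @param stack A list of numeric matrices (slices, identical dimensions) or a
#'   3D array with the third dimension indexing z.
#' @return A numeric matrix of per-pixel sums.
#' @export
sum_project <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3) {
    stack <- lapply(seq_len(dim(stack)[3]), function(z) stack[, , z])
  }
  if (!is.list(stack) || length(stack) == 0) {
    abort("`stack` must be a non-empty list of slices or a 3D array.")
  }
  dims <- unique(lapply(stack, dim))
  if (length(dims) != 1) abort("All slices must have identical dimensions.")
  for (s in stack) check_matrix_image(s, "slice")
  Reduce(`+`, stack)
}

#' Threshold-based soma region of interest
#'
#' Reproduces an intensity-threshold ROI: an automatic threshold (Otsu by
#' default) binarises the image, connected components are labelled, and the
#' component containing `seed_point` (or the largest component when no seed is
#' given) becomes the ROI mask.
#'
#' @param image Numeric matrix.
#' @param method Threshold method; currently `"otsu"`.
#' @param seed_point Optional `c(row, col)` (1-based) inside the wanted
#'   component.
#' @return A logical matrix of the same shape as `image`.
#' @export
soma_roi <- function(image, method = "otsu", seed_point = NULL) {
  check_matrix_image(image)
  method <- match.arg(method)
  rng <- range(image)
  if (diff(rng) == 0) {
    abort("Cannot threshold a constant image: no threshold exists.")
  }
  scaled <- (image - rng[1]) / diff(rng)
  thr01 <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256L)
  binary <- scaled >= thr01
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(binary * 1)))
  if (max(labels) == 0) abort("Threshold produced an empty foreground.")
  if (!is.null(seed_point)) {
    stopifnot(length(seed_point) == 2)
    lab <- labels[seed_point[1], seed_point[2]]
    if (lab == 0) abort("`seed_point` is not inside any thresholded component.")
  } else {
    sizes <- tabulate(labels[labels > 0])
    lab <- which.max(sizes)
  }
  labels == lab
}

#' Mean intensity within a region of interest
#'
#' @param image Numeric matrix.
#' @param roi Logical matrix of the same shape; at least one `TRUE` pixel.
#' @return The arithmetic mean intensity over ROI pixels.
#' @export
mean_intensity <- function(image, roi) {
  check_matrix_image(image)
  if (!is.logical(roi) || !identical(dim(roi), dim(image))) {
    abort("`roi` must be a logical matrix matching `image`.")
  }
  if (!any(roi)) abort("`roi` is empty.")
  mean(image[roi])
}

# Bilinear interpolation at 0-based (row, col) coordinates, clamped to the
# image; returns values and whether each point fell outside bounds.
bilinear_sample <- function(image, r, c) {
  nr <- nrow(image); nc <- ncol(image)
  out_of_bounds <- r < 0 | r > nr - 1 | c < 0 | c > nc - 1
  r <- pmin(pmax(r, 0), nr - 1)
  c <- pmin(pmax(c, 0), nc - 1)
  r0 <- pmin(floor(r), nr - 2); r0 <- pmax(r0, 0)
  c0 <- pmin(floor(c), nc - 2); c0 <- pmax(c0, 0)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0 + 1, c0 + 1); i01 <- cbind(r0 + 1, c0 + 2)
  i10 <- cbind(r0 + 2, c0 + 1); i11 <- cbind(r0 + 2, c0 + 2)
  v <- (1 - fr) * (1 - fc) * image[i00] + (1 - fr) * fc * image[i01] +
    fr * (1 - fc) * image[i10] + fr * fc * image[i11]
  list(values = v, clamped = out_of_bounds)
}

# Resample a polyline (0-based row/col vertex matrix) at unit arc-length
# steps; returns points and unit tangents at each step.
resample_polyline <- function(vertices) {
  if (nrow(vertices) < 2) abort("A path needs at least 2 vertices.")
  seg <- diff(vertices)
  seg_len <- sqrt(rowSums(seg^2))
  if (any(seg_len == 0)) {
    keep <- c(TRUE, seg_len > 0)
    vertices <- vertices[keep, , drop = FALSE]
    seg <- diff(vertices)
    seg_len <- sqrt(rowSums(seg^2))
  }
  cum <- c(0, cumsum(seg_len))
  total <- cum[length(cum)]
  s <- seq(0, floor(total), by = 1)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(vertices) - 1)
  t <- (s - cum[idx]) / seg_len[idx]
  pts <- vertices[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * t
  tangents <- seg[idx, , drop = FALSE] / seg_len[idx]
  list(s = s, points = pts, tangents = tangents)
}

#' Extract a wide line-intensity profile along a polyline path
#'
#' Samples the image at unit arc-length steps from the first vertex of the
#' path. At each step the reported intensity is the mean of `width_px`
#' bilinear samples spaced 1 px apart along the local perpendicular — the
#' digital equivalent of a segmented line of `width_px` pixels wide. Samples
#' whose perpendicular offset falls outside the image are clamped to the
#' nearest edge pixel and counted per step.
#'
#' @param image Numeric matrix.
#' @param vertices Path vertices as a two-column matrix of 0-based
#'   `(row, col)` coordinates, at least two rows.
#' @param width_px Odd profile width (number of perpendicular samples).
#' @return A tibble with `position_px` (0-based arc length), `intensity`
#'   (perpendicular mean) and `n_clamped` (out-of-bounds samples at that
#'   step); attribute `clamped_fraction` gives the overall clamped share.
#' @export
profile_along_path <- function(image, vertices, width_px = 5L) {
  check_matrix_image(image)
  vertices <- as.matrix(vertices)
  check_number(width_px, "width_px", min = 1, integer = TRUE)
  if (width_px %% 2 == 0) abort("`width_px` must be odd.")
  rs <- resample_polyline(vertices)
  offsets <- seq(-(width_px - 1) / 2, (width_px - 1) / 2)
  # normals: rotate tangent (dr, dc) by 90 degrees -> (-dc, dr)
  normals <- cbind(-rs$tangents[, 2], rs$tangents[, 1])
  n_steps <- length(rs$s)
  rr <- outer(rs$points[, 1], rep(1, width_px)) +
    outer(normals[, 1], offsets)
  cc <- outer(rs$points[, 2], rep(1, width_px)) +
    outer(normals[, 2], offsets)
  samp <- bilinear_sample(image, as.numeric(rr), as.numeric(cc))
  vals <- matrix(samp$values, n_steps, width_px)
  clamped <- matrix(samp$clamped, n_steps, width_px)
  out <- tibble(
    position_px = as.integer(rs$s),
    intensity = rowMeans(vals),
    n_clamped = as.integer(rowSums(clamped))
  )
  attr(out, "clamped_fraction") <- mean(clamped)
  out
}

#' AIS length from an intensity trace
#'
#' Measures staining length as the longest contiguous run of samples at or
#' above `frac_of_peak` times the trace maximum, converted to micrometres.
#' Intended for baseline-subtracted profiles; an all-zero trace has length 0.
#'
#' @param intensity Numeric vector of trace samples (1 px spacing).
#' @param frac_of_peak Threshold as a fraction of the trace maximum, in (0, 1).
#' @param pixel_size_um Physical pixel size (micrometres).
#' @return Length in micrometres.
#' @export
ais_length <- function(intensity, frac_of_peak = 0.33, pixel_size_um = 0.1) {
  stopifnot(is.numeric(intensity), length(intensity) > 0)
  if (frac_of_peak <= 0 || frac_of_peak >= 1) {
    abort("`frac_of_peak` must be in (0, 1).")
  }
  peak <- max(intensity)
  if (peak <= 0) return(0)
  above <- intensity >= frac_of_peak * peak
  runs <- rle(above)
  longest <- max(c(0, runs$lengths[runs$values]))
  longest * pixel_size_um
}

#' AIS/soma polarity ratio
#'
#' Adds `ratio = ais_mean / soma_mean` to a per-cell measurement table. The
#' ratio indexes neuronal polarity: how concentrated the protein is at the AIS
#' relative to the cell body.
#'
#' @param records Tibble with numeric columns `ais_mean` and `soma_mean`.
#' @return The input with a `ratio` column appended.
#' @export
ais_soma_ratio <- function(records) {
  stopifnot(all(c("ais_mean", "soma_mean") %in% names(records)))
  if (any(records$soma_mean <= 0, na.rm = TRUE)) {
    abort("`soma_mean` must be positive to form a ratio.")
  }
  mutate(records, ratio = .data$ais_mean / .data$soma_mean)
}

#' Render a known trace into a synthetic image along a path
#'
#' Paints a band of `band_px` around the polyline whose intensity at each
#' pixel is the trace value at the pixel's arc-length position (linearly
#' interpolated), on a constant background. This is the forward model used to
#' validate [profile_along_path()] by round trip: extract the profile from the
#' rendered image and compare with the input trace.
#'
#' @param intensity Numeric trace values at unit arc-length spacing.
#' @param vertices Polyline vertices (0-based row/col matrix).
#' @param dim Output image dimensions `c(rows, cols)`.
#' @param band_px Half-width of the painted band (px); should exceed the
#'   extraction half-width so perpendicular samples stay inside the band.
#' @param background Background intensity.
#' @return A numeric matrix.
#' @export
render_trace_image <- function(intensity, vertices, dim, band_px = 5,
                               background = 0) {
  vertices <- as.matrix(vertices)
  nr <- dim[1]; nc <- dim[2]
  img <- matrix(background, nr, nc)
  pr <- matrix(rep(0:(nr - 1), nc), nr, nc)
  pc <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  best_d2 <- matrix(Inf, nr, nc)
  best_t <- matrix(NA_real_, nr, nc)
  seg <- diff(vertices)
  seg_len <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seg_len))
  for (i in seq_len(nrow(seg))) {
    ar <- vertices[i, 1]; ac <- vertices[i, 2]
    dr <- seg[i, 1]; dc <- seg[i, 2]
    L2 <- seg_len[i]^2
    t <- ((pr - ar) * dr + (pc - ac) * dc) / L2
    t <- pmin(pmax(t, 0), 1)
    d2 <- (pr - (ar + t * dr))^2 + (pc - (ac + t * dc))^2
    upd <- d2 < best_d2
    best_d2[upd] <- d2[upd]
    best_t[upd] <- cum[i] + t[upd] * seg_len[i]
  }
  inside <- best_d2 <= band_px^2
  s <- best_t[inside]
  # linear interpolation of the trace at arc length s (trace sample k at s = k)
  v <- stats::approx(seq_along(intensity) - 1, intensity, xout = s,
                     rule = 2)$y
  img[inside] <- v
  img
}

#' Quantify a synthetic cohort into per-cell measurements
#'
#' Runs the measurement stage over a [generate_cohort()] result: mean AIS
#' intensity over the post-anchor trace, AIS staining length on the
#' baseline-subtracted post-anchor trace (baseline estimated from the
#' pre-anchor lead-in, or the trace minimum when there is none), soma mean
#' intensity through [soma_roi()] + [mean_intensity()] when soma images are
#' present, and the AIS/soma ratio.
#'
#' @param cohort A `synthetic_cohort`.
#' @param frac_of_peak Threshold fraction for [ais_length()].
#' @return A tibble with one row per cell: `cell_id`, `subject_id`,
#'   `diagnosis`, `treatment`, `ais_mean`, `ais_length_um`, and when soma
#'   images exist `soma_mean` and `ratio`.
#' @export
quantify_cohort <- function(cohort, frac_of_peak = 0.33) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (is.null(cohort$traces)) abort("Cohort has no traces to quantify.")
  px <- cohort$config$pixel_size_um
  per_cell <- cohort$traces %>%
    group_by(.data$cell_id, .data$subject_id, .data$diagnosis,
             .data$treatment) %>%
    summarise(
      ais_mean = mean(.data$intensity[.data$position_px >= .data$anchor_index[1]]),
      ais_length_um = {
        anchor <- .data$anchor_index[1]
        post <- .data$intensity[.data$position_px >= anchor]
        base <- if (anchor > 0) {
          median(.data$intensity[.data$position_px < anchor])
        } else min(post)
        ais_length(pmax(post - base, 0), frac_of_peak, px)
      },
      .groups = "drop"
    )
  if (length(cohort$soma_images) > 0) {
    soma <- purrr::imap(cohort$soma_images, function(sm, id) {
      ctr <- round(dim(sm$image) / 2)
      roi <- soma_roi(sm$image, seed_point = ctr)
      tibble(cell_id = id, soma_mean = mean_intensity(sm$image, roi))
    }) %>% bind_rows()
    per_cell <- per_cell %>%
      left_join(soma, by = "cell_id") %>%
      ais_soma_ratio()
  }
  per_cell
}

#' Quantify real images from disk
#'
#' File-based counterpart of [quantify_cohort()]: reads TIFF images (single
#' plane or z-stack, sum-projected), extracts wide line profiles along
#' annotated paths and soma means from seed-grown threshold ROIs, and joins
#' the result to the sample sheet.
#'
#' @param image_dir Directory containing TIFF files.
#' @param annotations A list (or path to a JSON file) of per-cell entries:
#'   `cell_id`, `image` (file name), `path` (list of 0-based `(row, col)`
#'   vertices), optional `soma_seed` (1-based `(row, col)`), optional
#'   `anchor_index`.
#' @param sample_sheet Tibble (or CSV path) with `cell_id`, `subject_id`,
#'   `diagnosis`, `treatment`, `compartment`.
#' @param width_px Profile width in pixels.
#' @param pixel_size_um Physical pixel size.
#' @param frac_of_peak Threshold fraction for [ais_length()].
#' @return A list with `measurements` (per-cell tibble) and `traces`
#'   (long tibble of extracted profiles).
#' @export
quantify_images <- function(image_dir, annotations, sample_sheet,
                            width_px = 5L, pixel_size_um = 0.1,
                            frac_of_peak = 0.33) {
  if (is.character(annotations)) {
    annotations <- jsonlite::read_json(annotations, simplifyVector = FALSE)
  }
  if (is.character(sample_sheet)) {
    sample_sheet <- readr::read_csv(sample_sheet, show_col_types = FALSE)
  }
  images <- new.env(parent = emptyenv())
  load_image <- function(fname) {
    if (!exists(fname, envir = images)) {
      planes <- tiff::readTIFF(file.path(image_dir, fname), all = TRUE,
                               as.is = TRUE)
      if (!is.list(planes)) planes <- list(planes)
      planes <- lapply(planes, function(p) {
        if (length(dim(p)) == 3) p <- p[, , 1]
        p * 1.0
      })
      assign(fname, sum_project(planes), envir = images)
    }
    get(fname, envir = images)
  }
  rows <- list(); trace_rows <- list()
  for (ann in annotations) {
    img <- load_image(ann$image)
    verts <- do.call(rbind, lapply(ann$path, unlist))
    tr <- profile_along_path(img, verts, width_px)
    anchor <- if (!is.null(ann$anchor_index)) ann$anchor_index else 0L
    soma_mean <- NA_real_
    if (!is.null(ann$soma_seed)) {
      roi <- soma_roi(img, seed_point = unlist(ann$soma_seed))
      soma_mean <- mean_intensity(img, roi)
    }
    post <- tr$intensity[tr$position_px >= anchor]
    base <- if (anchor > 0) median(tr$intensity[tr$position_px < anchor]) else min(post)
    rows[[ann$cell_id]] <- tibble(
      cell_id = ann$cell_id,
      ais_mean = mean(post),
      soma_mean = soma_mean,
      ais_length_um = ais_length(pmax(post - base, 0), frac_of_peak,
                                 pixel_size_um),
      clamped_fraction = attr(tr, "clamped_fraction")
    )
    tr$cell_id <- ann$cell_id
    tr$anchor_index <- as.integer(anchor)
    trace_rows[[ann$cell_id]] <- tr
  }
  measurements <- bind_rows(rows) %>%
    left_join(sample_sheet, by = "cell_id")
  ok <- !is.na(measurements$soma_mean) & measurements$soma_mean > 0
  measurements$ratio <- ifelse(ok, measurements$ais_mean / measurements$soma_mean,
                               NA_real_)
  list(measurements = measurements, traces = bind_rows(trace_rows))
}
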