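# Independent oracles: deliberately naive implementations (loops, direct
# enumeration, first-principles formulas) used to validate the package's
# vectorised code paths.

# O(N^2) discrete Fourier transform by direct summation.
brute_dft <- function(x) {
  N <- length(x)
  vapply(0:(N - 1), function(k) {
    s <- 0 + 0i
    for (n in 0:(N - 1)) s <- s + x[n + 1] * exp(-2i * pi * k * n / N)
    s
  }, complex(1))
}

# Loop-based mean over a logical mask.
loop_mean <- function(image, roi) {
  tot <- 0; cnt <- 0
  for (r in seq_len(nrow(image))) for (c in seq_len(ncol(image))) {
    if (roi[r, c]) { tot <- tot + image[r, c]; cnt <- cnt + 1 }
  }
  tot / cnt
}

# Pair-enumeration GLCM oracle (symmetric, normalised).
oracle_glcm <- function(q, n_bins, distance, directions) {
  offs <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
               `135` = c(-1, -1))
  P <- matrix(0, n_bins, n_bins)
  nr <- nrow(q); nc <- ncol(q)
  for (d in directions) {
    o <- offs[[d]] * distance
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      r2 <- r + o[1]; c2 <- c + o[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      a <- q[r, c]; b <- q[r2, c2]
      if (is.na(a) || is.na(b)) next
      P[a, b] <- P[a, b] + 1
      P[b, a] <- P[b, a] + 1
    }
  }
  P / sum(P)
}

# Neighbour-count GLDM oracle.
oracle_gldm <- function(q, n_bins, alpha, distance) {
  nr <- nrow(q); nc <- ncol(q)
  max_dep <- (2 * distance + 1)^2 - 1
  M <- matrix(0, n_bins, max_dep + 1,
              dimnames = list(NULL, as.character(0:max_dep)))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (is.na(q[r, c])) next
    d <- 0
    for (dr in -distance:distance) for (dc in -distance:distance) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (!is.na(q[r2, c2]) && abs(q[r2, c2] - q[r, c]) <= alpha) d <- d + 1
    }
    M[q[r, c], d + 1] <- M[q[r, c], d + 1] + 1
  }
  last <- max(c(1L, which(colSums(M) > 0)))
  M[, seq_len(last), drop = FALSE]
}

# GLSZM oracle: 8-connected zones by iterative label propagation (a different
# algorithm from the package's BFS flood fill).
oracle_glszm <- function(q, n_bins) {
  nr <- nrow(q); nc <- ncol(q)
  sizes <- list()
  for (lvl in sort(unique(q[!is.na(q)]))) {
    mask <- !is.na(q) & q == lvl
    lab <- matrix(0, nr, nc)
    lab[mask] <- seq_len(sum(mask))
    repeat {
      new_lab <- lab
      for (r in seq_len(nr)) for (c in seq_len(nc)) {
        if (!mask[r, c]) next
        for (dr in -1:1) for (dc in -1:1) {
          r2 <- r + dr; c2 <- c + dc
          if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
          if (mask[r2, c2] && new_lab[r2, c2] > new_lab[r, c]) {
            new_lab[r, c] <- new_lab[r2, c2]
          }
        }
      }
      if (identical(new_lab, lab)) break
      lab <- new_lab
    }
    for (s in table(lab[lab > 0])) {
      sizes[[length(sizes) + 1]] <- c(level = lvl, size = as.integer(s))
    }
  }
  zones <- do.call(rbind, sizes)
  max_s <- max(zones[, "size"])
  Z <- matrix(0, n_bins, max_s,
              dimnames = list(NULL, as.character(seq_len(max_s))))
  for (k in seq_len(nrow(zones))) {
    Z[zones[k, "level"], zones[k, "size"]] <-
      Z[zones[k, "level"], zones[k, "size"]] + 1
  }
  Z
}

# First-principles split-plot sums of squares for a balanced design:
# a groups x n subjects/group x b treatments, one value per cell mean.
# Returns F statistics for group, treatment, interaction.
oracle_split_plot_F <- function(df) {
  # df: columns value, between, within, subject (one row per subject x within)
  a <- length(unique(df$between))
  b <- length(unique(df$within))
  n <- length(unique(df$subject)) / a
  grand <- mean(df$value)
  g_means <- tapply(df$value, df$between, mean)
  t_means <- tapply(df$value, df$within, mean)
  gs_means <- tapply(df$value, df$subject, mean)
  gt_means <- tapply(df$value, list(df$between, df$within), mean)
  subj_group <- tapply(df$between, df$subject, function(x) x[1])
  ss_g <- n * b * sum((g_means - grand)^2)
  ss_subj <- b * sum((gs_means - g_means[subj_group])^2)
  ss_t <- a * n * sum((t_means - grand)^2)
  ss_gt <- 0
  for (g in names(g_means)) for (tt in names(t_means)) {
    ss_gt <- ss_gt + n * (gt_means[g, tt] - g_means[g] - t_means[tt] + grand)^2
  }
  ss_tot <- sum((df$value - grand)^2)
  ss_err <- ss_tot - ss_g - ss_subj - ss_t - ss_gt
  ms_g <- ss_g / (a - 1)
  ms_subj <- ss_subj / (a * (n - 1))
  ms_t <- ss_t / (b - 1)
  ms_gt <- ss_gt / ((a - 1) * (b - 1))
  ms_err <- ss_err / (a * (n - 1) * (b - 1))
  c(group = unname(ms_g / ms_subj), treatment = unname(ms_t / ms_err),
    interaction = unname(ms_gt / ms_err))
}

# Random quantized grid with a random mask, as input for texture oracles.
random_quantized <- function(nr = 16, nc = 16, n_bins = 4, p_roi = 0.85) {
  img <- matrix(runif(nr * nc, 0, 100), nr, nc)
  roi <- matrix(runif(nr * nc) < p_roi, nr, nc)
  if (!any(roi)) roi[1, 1] <- TRUE
  quantize_gray_levels(img, roi, n_bins)
}
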