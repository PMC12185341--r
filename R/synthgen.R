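#' Group-level generative parameters for a two-diagnosis postmortem design
#'
#' Convenience builders for the `groups` table of [synth_config()]. Each row is
#' one diagnosis x treatment condition with its generative parameters: the mean
#' AIS profile amplitude (a.u. above baseline), the mean soma intensity, the
#' soma texture correlation length (px) and a multiplicative factor on the
#' profile decay length (a proxy for AIS length effects).
#'
#' `postmortem_groups()` encodes a healthy-control vs schizophrenia contrast:
#' reduced AIS amplitude in SCZ, equal soma intensity, and a shorter soma
#' texture correlation length in SCZ (a less organised somatic pattern).
#' `ipsc_groups()` encodes a diagnosis x treatment grid (vehicle, GSK3
#' inhibitor, AKT inhibitor) in which kinase inhibition raises AIS intensity in
#' control lines but not in patient lines, and AKT inhibition lengthens the
#' control AIS.
#'
#' @param a_hc,a_scz Mean AIS amplitude (a.u.) for the HC and SCZ groups.
#' @param soma_level Mean soma intensity (a.u.), shared by both groups.
#' @param corr_hc,corr_scz Soma texture correlation length (px) per group.
#' @return A tibble with columns `diagnosis`, `treatment`, `ais_amplitude`,
#'   `soma_amplitude`, `texture_corr_px`, `length_factor`.
#' @export
postmortem_groups <- function(a_hc = 100, a_scz = 80, soma_level = 150,
                              corr_hc = 4, corr_scz = 1.5) {
  tibble(
    diagnosis = c("HC", "SCZ"),
    treatment = "none",
    ais_amplitude = c(a_hc, a_scz),
    soma_amplitude = soma_level,
    texture_corr_px = c(corr_hc, corr_scz),
    length_factor = 1
  )
}

#' @rdname postmortem_groups
#' @param a_dmso_hc,a_dmso_scz Vehicle-condition AIS amplitudes per diagnosis.
#' @param inhibitor_gain Multiplicative effect of kinase inhibition on the HC
#'   AIS amplitude (blunted to 1 in SCZ).
#' @param akt_length_gain Multiplicative effect of AKT inhibition on the HC
#'   profile decay length.
#' @export
ipsc_groups <- function(a_dmso_hc = 100, a_dmso_scz = 80,
                        inhibitor_gain = 1.2, akt_length_gain = 1.2,
                        soma_level = 150, corr_hc = 4, corr_scz = 1.5) {
  grid <- tidyr::expand_grid(
    diagnosis = c("HC", "SCZ"),
    treatment = c("DMSO", "GSK3i", "AKTi")
  )
  grid %>%
    mutate(
      ais_amplitude = ifelse(.data$diagnosis == "HC", a_dmso_hc, a_dmso_scz) *
        ifelse(.data$diagnosis == "HC" & .data$treatment != "DMSO",
               inhibitor_gain, 1),
      soma_amplitude = soma_level,
      texture_corr_px = ifelse(.data$diagnosis == "HC", corr_hc, corr_scz),
      length_factor = ifelse(.data$diagnosis == "HC" & .data$treatment == "AKTi",
                             akt_length_gain, 1)
    )
}

#' Configure a synthetic imaging cohort
#'
#' Bundles every generative parameter of the synthetic cohort: the subject and
#' cell counts, the diagnosis x treatment condition table, the AIS profile
#' shape, the hierarchical noise structure (subject-level random intercepts and
#' cell-level scatter), the soma image geometry and the seed. The configuration
#' is the single source of truth for [generate_cohort()]; identical
#' configurations yield identical cohorts.
#'
#' @param n_subjects_per_group Subjects per diagnosis group.
#' @param cells_per_subject Cells contributed by each subject under each
#'   treatment; a single count or a `c(min, max)` range sampled per
#'   subject-condition.
#' @param groups Condition table as built by [postmortem_groups()] or
#'   [ipsc_groups()].
#' @param trace_length_px Nominal post-anchor trace length (samples at 1 px).
#' @param baseline_intensity Background fluorescence level (a.u.).
#' @param profile_rise_px,profile_decay_px Shape of the AIS profile: linear
#'   rise over `profile_rise_px` samples to the peak, then exponential decay
#'   with length constant `profile_decay_px`.
#' @param subject_sd SD (a.u.) of the subject-level random intercept shared by
#'   all cells of a subject.
#' @param cell_noise_sd SD (a.u.) of the cell-level amplitude scatter.
#' @param trace_noise_sd SD (a.u.) of per-sample measurement noise.
#' @param lead_px Maximum baseline-only lead-in before the profile anchor
#'   (sampled uniformly per cell), emulating traces that start slightly
#'   proximal to the AIS.
#' @param length_jitter_px Maximum extra post-anchor samples (sampled uniformly
#'   per cell), so raw traces differ in length and require calibration.
#' @param soma_size_px Major axis (px) of the elliptical soma mask.
#' @param soma_texture_amp SD (a.u.) of the stationary textured component
#'   inside the soma mask.
#' @param pixel_size_um Physical pixel size (micrometres).
#' @param seed Integer seed; all cohort randomness derives from it.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_subjects_per_group = 6,
                         cells_per_subject = 20,
                         groups = postmortem_groups(),
                         trace_length_px = 100,
                         baseline_intensity = 100,
                         profile_rise_px = 10,
                         profile_decay_px = 30,
                         subject_sd = 8,
                         cell_noise_sd = 10,
                         trace_noise_sd = 3,
                         lead_px = 6,
                         length_jitter_px = 8,
                         soma_size_px = 32,
                         soma_texture_amp = 15,
                         pixel_size_um = 0.1,
                         seed = 1L) {
  check_number(n_subjects_per_group, "n_subjects_per_group", min = 1, integer = TRUE)
  if (!length(cells_per_subject) %in% 1:2) {
    abort("`cells_per_subject` must be a count or a c(min, max) range.")
  }
  for (v in cells_per_subject) check_number(v, "cells_per_subject", min = 1, integer = TRUE)
  if (length(cells_per_subject) == 2 && diff(cells_per_subject) < 0) {
    abort("`cells_per_subject` range must be non-decreasing.")
  }
  stopifnot(is.data.frame(groups))
  needed <- c("diagnosis", "treatment", "ais_amplitude", "soma_amplitude",
              "texture_corr_px", "length_factor")
  if (!all(needed %in% names(groups))) {
    abort(paste("`groups` must have columns:", paste(needed, collapse = ", ")))
  }
  check_number(trace_length_px, "trace_length_px", min = 16, integer = TRUE)
  check_number(baseline_intensity, "baseline_intensity", min = 0)
  check_number(profile_rise_px, "profile_rise_px", min = 0)
  check_number(profile_decay_px, "profile_decay_px", min = 1e-6)
  check_number(subject_sd, "subject_sd", min = 0)
  check_number(cell_noise_sd, "cell_noise_sd", min = 0)
  check_number(trace_noise_sd, "trace_noise_sd", min = 0)
  check_number(lead_px, "lead_px", min = 0, integer = TRUE)
  check_number(length_jitter_px, "length_jitter_px", min = 0, integer = TRUE)
  check_number(soma_size_px, "soma_size_px", min = 8, integer = TRUE)
  check_number(soma_texture_amp, "soma_texture_amp", min = 0)
  check_number(pixel_size_um, "pixel_size_um", min = 1e-9)
  check_number(seed, "seed", integer = TRUE)
  structure(
    list(
      n_subjects_per_group = as.integer(n_subjects_per_group),
      cells_per_subject = as.integer(cells_per_subject),
      groups = as_tibble(groups),
      trace_length_px = as.integer(trace_length_px),
      baseline_intensity = baseline_intensity,
      profile_rise_px = profile_rise_px,
      profile_decay_px = profile_decay_px,
      subject_sd = subject_sd,
      cell_noise_sd = cell_noise_sd,
      trace_noise_sd = trace_noise_sd,
      lead_px = as.integer(lead_px),
      length_jitter_px = as.integer(length_jitter_px),
      soma_size_px = as.integer(soma_size_px),
      soma_texture_amp = soma_texture_amp,
      pixel_size_um = pixel_size_um,
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# Normalized AIS profile shape: linear rise over `rise` px to 1, then
# exponential decay with length constant `decay`; max is exactly 1 at x = rise.
profile_shape <- function(length_px, rise_px, decay_px) {
  x <- seq_len(length_px) - 1
  ifelse(x <= rise_px,
         if (rise_px > 0) x / rise_px else 1,
         exp(-(x - rise_px) / decay_px))
}

#' Generate a single AIS-like intensity trace
#'
#' Renders one rise-and-decay fluorescence profile: a baseline-only lead-in of
#' `lead_px` samples, then `amplitude * f(x)` on top of the baseline, where
#' `f` rises linearly over `rise_px` samples and decays exponentially with
#' length constant `decay_px` (normalised so `max(f) = 1`). Gaussian sample
#' noise is drawn from the current RNG state.
#'
#' @param amplitude Peak amplitude above baseline (a.u.); must be >= 0.
#' @param length_px Post-anchor trace length in samples.
#' @param rise_px,decay_px Profile shape parameters (see above).
#' @param baseline Baseline intensity (a.u.).
#' @param noise_sd Per-sample Gaussian noise SD (a.u.).
#' @param lead_px Baseline-only samples before the anchor.
#' @return A tibble with columns `position_px` (0-based) and `intensity`,
#'   with attribute `anchor_index` marking the profile start.
#' @export
generate_trace <- function(amplitude, length_px, rise_px = 10, decay_px = 30,
                           baseline = 0, noise_sd = 0, lead_px = 0L) {
  check_number(amplitude, "amplitude", min = 0)
  check_number(length_px, "length_px", min = rise_px + 1, integer = TRUE)
  f <- profile_shape(length_px, rise_px, decay_px)
  values <- c(rep(baseline, lead_px), baseline + amplitude * f)
  if (noise_sd > 0) values <- values + rnorm(length(values), 0, noise_sd)
  values <- pmax(values, 0)
  out <- tibble(position_px = seq_along(values) - 1L, intensity = values)
  attr(out, "anchor_index") <- as.integer(lead_px)
  out
}

# Separable Gaussian smoothing with edge replication; sigma in px.
gauss_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad_conv <- function(v) {
    padded <- c(rep(v[1], r), v, rep(v[length(v)], r))
    out <- stats::filter(padded, k, sides = 2)
    as.numeric(out[(r + 1):(r + length(v))])
  }
  mat <- apply(mat, 2, pad_conv)
  t(apply(mat, 1, pad_conv))
}

#' Generate a textured synthetic soma image with its mask
#'
#' Builds a square image containing an elliptical soma on a dim background.
#' Inside the mask the intensity is `soma_level` plus a stationary Gaussian
#' random field obtained by smoothing white noise with a Gaussian kernel of
#' width `texture_corr_px` and rescaling to SD `texture_amp` — the correlation
#' length is the single knob controlling how organised the somatic texture
#' looks. Randomness comes from the current RNG state.
#'
#' @param soma_size_px Major axis of the elliptical mask (px); image side is
#'   `soma_size_px + 2 * margin`.
#' @param texture_corr_px Correlation length (px) of the textured component.
#' @param soma_level Mean intensity inside the mask (a.u.).
#' @param texture_amp SD (a.u.) of the textured component; 0 gives a constant
#'   soma.
#' @param background Background intensity outside the mask (a.u.).
#' @param background_noise_sd Gaussian noise SD outside the mask.
#' @param margin Background margin (px) around the mask.
#' @return A list with `image` (numeric matrix) and `mask` (logical matrix).
#' @export
generate_soma_image <- function(soma_size_px, texture_corr_px = 2,
                                soma_level = 150, texture_amp = 15,
                                background = 10, background_noise_sd = 1,
                                margin = 8L) {
  check_number(soma_size_px, "soma_size_px", min = 8, integer = TRUE)
  check_number(texture_corr_px, "texture_corr_px", min = 0)
  n <- soma_size_px + 2L * margin
  ctr <- (n + 1) / 2
  a <- soma_size_px / 2
  b <- 0.8 * a
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  mask <- ((rows - ctr) / b)^2 + ((cols - ctr) / a)^2 <= 1
  image <- matrix(background, n, n)
  if (background_noise_sd > 0) {
    image <- image + matrix(rnorm(n * n, 0, background_noise_sd), n, n)
  }
  field <- matrix(0, n, n)
  if (texture_amp > 0) {
    white <- matrix(rnorm(n * n), n, n)
    field <- gauss_smooth(white, texture_corr_px)
    s <- sd(as.numeric(field))
    if (s > 0) field <- field / s * texture_amp
  }
  image[mask] <- soma_level + field[mask]
  image <- pmax(image, 0)
  list(image = image, mask = mask)
}

#' Generate a full synthetic cohort
#'
#' Draws a hierarchical cohort under `config`: per subject a Gaussian random
#' intercept `s_j ~ N(0, subject_sd)`; per cell an amplitude
#' `A = ais_amplitude(group) + s_j + e_c` with `e_c ~ N(0, cell_noise_sd)`;
#' per cell an AIS-like trace via [generate_trace()] and (optionally) a
#' textured soma image via [generate_soma_image()]. All randomness derives
#' from `config$seed`, so identical configurations give identical cohorts.
#'
#' @param config A [synth_config()].
#' @param components Which per-cell artefacts to generate: `"traces"`,
#'   `"soma"`, or both. Trace-only cohorts are much lighter for large
#'   classification runs.
#' @return An object of class `synthetic_cohort`: a list with `traces` (long
#'   tibble: cell_id, subject_id, diagnosis, treatment, compartment,
#'   position_px, intensity, anchor_index), `soma_images` (named list of
#'   image/mask pairs, possibly empty), `sample_sheet` (one row per cell),
#'   `truth` (the generative parameters actually drawn per cell) and the
#'   `config` echo.
#' @export
generate_cohort <- function(config, components = c("traces", "soma")) {
  stopifnot(inherits(config, "synth_config"))
  components <- match.arg(components, several.ok = TRUE)
  with_seed(config$seed, generate_cohort_impl(config, components))
}

generate_cohort_impl <- function(config, components) {
  diagnoses <- unique(config$groups$diagnosis)
  subjects <- tidyr::expand_grid(
    diagnosis = diagnoses,
    subject_rank = seq_len(config$n_subjects_per_group)
  ) %>%
    mutate(
      subject_id = sprintf("%s_s%02d", .data$diagnosis, .data$subject_rank),
      subject_effect = rnorm(dplyr::n(), 0, config$subject_sd)
    )

  conditions <- config$groups %>%
    left_join(subjects, by = "diagnosis", relationship = "many-to-many")

  # Cell counts per subject x condition (fixed or sampled from a range).
  rng <- config$cells_per_subject
  n_cells <- if (length(rng) == 1) {
    rep(rng, nrow(conditions))
  } else {
    sample(seq(rng[1], rng[2]), nrow(conditions), replace = TRUE)
  }
  cells <- conditions[rep(seq_len(nrow(conditions)), n_cells), ] %>%
    mutate(
      cell_rank = stats::ave(rep(1, dplyr::n()), .data$subject_id,
                             .data$treatment, FUN = seq_along),
      cell_id = sprintf("%s_%s_c%03d", .data$subject_id, .data$treatment,
                        .data$cell_rank),
      amplitude = pmax(.data$ais_amplitude + .data$subject_effect +
                         rnorm(dplyr::n(), 0, config$cell_noise_sd), 0),
      soma_true = pmax(.data$soma_amplitude + .data$subject_effect +
                         rnorm(dplyr::n(), 0, config$cell_noise_sd), 1e-6),
      lead = sample(0:config$lead_px, dplyr::n(), replace = TRUE),
      extra = sample(0:config$length_jitter_px, dplyr::n(), replace = TRUE)
    )

  traces <- NULL
  if ("traces" %in% components) {
    traces <- purrr::pmap(
      list(cells$amplitude, cells$extra, cells$length_factor, cells$lead,
           cells$cell_id),
      function(amp, extra, lenf, lead, id) {
        tr <- generate_trace(
          amplitude = amp,
          length_px = config$trace_length_px + extra,
          rise_px = config$profile_rise_px,
          decay_px = config$profile_decay_px * lenf,
          baseline = config$baseline_intensity,
          noise_sd = config$trace_noise_sd,
          lead_px = lead
        )
        tr$cell_id <- id
        tr$anchor_index <- attr(tr, "anchor_index")
        tr
      }
    ) %>%
      bind_rows() %>%
      left_join(
        cells %>%
          select("cell_id", "subject_id", "diagnosis", "treatment"),
        by = "cell_id"
      ) %>%
      mutate(compartment = "AIS") %>%
      select("cell_id", "subject_id", "diagnosis", "treatment", "compartment",
             "position_px", "intensity", "anchor_index")
  }

  soma_images <- list()
  if ("soma" %in% components) {
    soma_images <- purrr::map2(
      cells$soma_true, cells$texture_corr_px,
      function(level, corr) {
        generate_soma_image(
          soma_size_px = config$soma_size_px,
          texture_corr_px = corr,
          soma_level = level,
          texture_amp = config$soma_texture_amp
        )
      }
    )
    names(soma_images) <- cells$cell_id
  }

  f_mean <- function(len, lenf) {
    mean(profile_shape(len, config$profile_rise_px,
                       config$profile_decay_px * lenf))
  }
  truth <- cells %>%
    mutate(
      ais_mean_true = config$baseline_intensity + .data$amplitude *
        purrr::map2_dbl(config$trace_length_px + .data$extra,
                        .data$length_factor, f_mean),
      anchor_index = .data$lead,
      trace_length = config$trace_length_px + .data$extra
    ) %>%
    select("cell_id", "subject_id", "diagnosis", "treatment",
           "subject_effect", "amplitude", "soma_true", "ais_mean_true",
           "length_factor", "anchor_index", "trace_length")

  sheet <- cells %>%
    mutate(compartment = "AIS") %>%
    select("cell_id", "subject_id", "diagnosis", "treatment", "compartment")

  structure(
    list(traces = traces, soma_images = soma_images, sample_sheet = sheet,
         truth = truth, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n")
  cat("  cells:   ", nrow(x$sample_sheet), "\n")
  cat("  subjects:", length(unique(x$sample_sheet$subject_id)), "\n")
  cat("  groups:  ", paste(unique(paste(x$sample_sheet$diagnosis,
                                        x$sample_sheet$treatment)),
                           collapse = ", "), "\n")
  cat("  traces:  ", if (is.null(x$traces)) "none" else
    paste0(length(unique(x$traces$cell_id)), " cells"), "\n")
  cat("  soma imgs:", length(x$soma_images), "\n")
  invisible(x)
}

#' Simulate cell-level measurements without rendering images
#'
#' Draws scalar per-cell measurements directly from the hierarchical model
#' (group mean + subject random intercept + cell noise), bypassing trace and
#' image rendering. This is the fast path for statistical calibration studies
#' that need thousands of replicate cohorts.
#'
#' @param group_means Tibble with columns `diagnosis`, `treatment`, `mean`.
#' @param n_subjects_per_group Subjects per diagnosis.
#' @param cells_per_subject Cells per subject x condition.
#' @param subject_sd,cell_sd SDs of the subject intercept and cell noise.
#' @param seed Integer seed.
#' @return Tibble: `cell_id`, `subject_id`, `diagnosis`, `treatment`, `value`.
#' @export
simulate_measurements <- function(group_means, n_subjects_per_group = 6,
                                  cells_per_subject = 20, subject_sd = 8,
                                  cell_sd = 10, seed = 1L) {
  stopifnot(all(c("diagnosis", "treatment", "mean") %in% names(group_means)))
  with_seed(seed, {
    diagnoses <- unique(group_means$diagnosis)
    subjects <- tidyr::expand_grid(
      diagnosis = diagnoses,
      subject_rank = seq_len(n_subjects_per_group)
    ) %>%
      mutate(subject_id = sprintf("%s_s%02d", .data$diagnosis, .data$subject_rank),
             subject_effect = rnorm(dplyr::n(), 0, subject_sd))
    df <- group_means %>%
      left_join(subjects, by = "diagnosis", relationship = "many-to-many")
    df <- df[rep(seq_len(nrow(df)), cells_per_subject), ]
    df %>%
      mutate(
        cell_rank = stats::ave(rep(1, dplyr::n()), .data$subject_id,
                               .data$treatment, FUN = seq_along),
        cell_id = sprintf("%s_%s_c%03d", .data$subject_id, .data$treatment,
                          .data$cell_rank),
        value = .data$mean + .data$subject_effect + rnorm(dplyr::n(), 0, cell_sd)
      ) %>%
      select("cell_id", "subject_id", "diagnosis", "treatment", "value")
  })
}
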