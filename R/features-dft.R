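#' Calibrate traces to a common anatomical start and length
#'
#' Re-indexes every trace to begin at its anchor (the annotated start of the
#' AIS or neurite) and truncates all traces to the shortest post-anchor length
#' so that spectral features are computed over identical spatial supports.
#' Traces whose post-anchor length falls below `min_length` are dropped and
#' recorded with a reason.
#'
#' @param traces Long tibble with columns `cell_id`, `position_px`,
#'   `intensity`, `anchor_index` (constant within cell) and any metadata
#'   columns, as produced by [generate_cohort()] or [quantify_images()].
#' @param min_length Minimum admissible post-anchor length (samples).
#' @return A long tibble of calibrated traces, all exactly the same length,
#'   with `position_px` re-indexed from 0 at the anchor. Dropped cells are
#'   listed in the `dropped` attribute (tibble: `cell_id`, `reason`) and
#'   reported via a message.
#' @export
calibrate_traces <- function(traces, min_length = 16L) {
  stopifnot(all(c("cell_id", "position_px", "intensity", "anchor_index") %in%
                  names(traces)))
  post <- traces %>%
    filter(.data$position_px >= .data$anchor_index) %>%
    group_by(.data$cell_id) %>%
    mutate(position_px = .data$position_px - .data$anchor_index) %>%
    ungroup()
  lens <- post %>% count(.data$cell_id, name = "len")
  short <- lens %>% filter(.data$len < min_length)
  dropped <- tibble(cell_id = short$cell_id,
                    reason = sprintf("post-anchor length %d < %d",
                                     short$len, as.integer(min_length)))
  if (nrow(dropped) > 0) {
    inform(sprintf("calibrate_traces: dropped %d trace(s) shorter than %d samples.",
                   nrow(dropped), as.integer(min_length)))
    post <- post %>% filter(!.data$cell_id %in% dropped$cell_id)
  }
  if (nrow(post) == 0) abort("No traces remain after calibration.")
  L <- min(lens$len[!lens$cell_id %in% dropped$cell_id])
  out <- post %>% filter(.data$position_px < L)
  attr(out, "dropped") <- dropped
  attr(out, "calibrated_length") <- as.integer(L)
  out
}

# Wide matrix (positions x cells) from a calibrated long trace table.
trace_matrix <- function(traces) {
  lens <- table(traces$cell_id)
  if (length(unique(as.integer(lens))) != 1) {
    abort("Traces have unequal lengths; run `calibrate_traces()` first.")
  }
  wide <- traces %>%
    arrange(.data$cell_id, .data$position_px) %>%
    select("cell_id", "position_px", "intensity") %>%
    tidyr::pivot_wider(names_from = "cell_id", values_from = "intensity") %>%
    arrange(.data$position_px)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$position_px
  m
}

#' Discrete-Fourier-transform descriptors of calibrated traces
#'
#' Computes, per cell, the magnitudes of the first `n_coeff` DFT coefficients
#' of the intensity trace: `X[k] = sum_n x[n] exp(-2*pi*i*k*n/N)`. The DC term
#' is reported as `|X[0]|/N` (the trace mean); higher coefficients as raw
#' magnitudes `|X[k]|`. Magnitudes discard phase, making the descriptors
#' insensitive to residual alignment shifts left over after calibration.
#'
#' @param traces Calibrated long trace tibble (equal lengths; see
#'   [calibrate_traces()]).
#' @param n_coeff Number of coefficients to keep (including DC); must not
#'   exceed the trace length.
#' @return A tibble with one row per cell: metadata columns (`cell_id` plus
#'   any of `subject_id`, `diagnosis`, `treatment`, `compartment` present)
#'   followed by feature columns `dft_00` ... `dft_<n_coeff-1>`.
#' @export
dft_features <- function(traces, n_coeff = 20L) {
  check_number(n_coeff, "n_coeff", min = 1, integer = TRUE)
  m <- trace_matrix(traces)
  N <- nrow(m)
  if (n_coeff > N) abort("`n_coeff` exceeds the calibrated trace length.")
  spec <- Mod(stats::mvfft(m))
  feats <- t(spec[seq_len(n_coeff), , drop = FALSE])
  feats[, 1] <- feats[, 1] / N
  colnames(feats) <- sprintf("dft_%02d", seq_len(n_coeff) - 1)
  meta_cols <- intersect(
    c("cell_id", "subject_id", "diagnosis", "treatment", "compartment"),
    names(traces))
  meta <- traces %>% distinct(across(all_of(meta_cols)))
  tibble(cell_id = colnames(m)) %>%
    left_join(meta, by = "cell_id") %>%
    dplyr::bind_cols(as_tibble(feats))
}
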