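# broom-style tidiers for the package's fitted objects.

#' @exportS3Method generics::tidy
tidy.rf_report <- function(x, ...) {
  x$per_repeat
}

#' @exportS3Method generics::glance
glance.rf_report <- function(x, ...) {
  tibble(
    task = if (is.null(x$task)) NA_character_ else x$task,
    subset = if (is.null(x$subset)) NA_character_ else
      paste(names(x$subset), x$subset, sep = "=", collapse = ","),
    mean_accuracy = x$mean_accuracy,
    sd_accuracy = x$sd_accuracy,
    n_repeats = nrow(x$per_repeat),
    n_cells = x$n_cells,
    n_classes = length(x$classes),
    group_aware = x$scheme$group_aware
  )
}

#' @exportS3Method generics::tidy
tidy.nested_t <- function(x, ...) {
  tibble(
    term = paste(x$groups[1], "-", x$groups[2]),
    estimate = x$estimate,
    statistic = x$statistic,
    df = x$df,
    p.value = x$p_value
  )
}

#' @exportS3Method generics::glance
glance.nested_t <- function(x, ...) {
  tibble(method = x$method, statistic = x$statistic, df = x$df,
         p.value = x$p_value, n_subjects = nrow(x$subject_means))
}

#' @exportS3Method generics::tidy
tidy.mixed_anova <- function(x, ...) {
  x$table
}

#' @exportS3Method generics::glance
glance.mixed_anova <- function(x, ...) {
  eff <- x$table %>% filter(!.data$term %in% "Residuals")
  tibble(method = x$method,
         n_subjects = length(unique(x$aggregated$subject)),
         n_terms = nrow(eff),
         min_p = suppressWarnings(min(eff$p.value, na.rm = TRUE)))
}

#' @exportS3Method generics::tidy
tidy.dunnett_result <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @exportS3Method generics::tidy
tidy.sidak_result <- function(x, ...) {
  as_tibble(unclass(x))
}
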