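#' Nested t-test: two groups of subjects, many cells per subject
#'
#' Cells are not independent — they are nested in subjects — so the comparison
#' first aggregates to per-subject means and then applies a two-tailed,
#' equal-variance two-sample t-test on those means, with
#' `df = n_subjects - 2`. This makes subjects, not cells, the units of
#' inference and keeps the type-I error calibrated when subjects differ
#' systematically (pseudoreplication control). A weighted variant weights
#' subject means by their cell counts.
#'
#' @param table Tibble with one row per cell.
#' @param value Name of the measurement column.
#' @param group Name of the (two-level) group column.
#' @param subject Name of the subject identifier column.
#' @param weighted Weight subject means by cell count (for unbalanced
#'   designs); default unweighted.
#' @return An object of class `nested_t` with `statistic`, `df`, `p_value`,
#'   the group means and the subject-mean table. Works with [glance()] and
#'   [tidy()].
#' @export
nested_t_test <- function(table, value = "value", group = "diagnosis",
                          subject = "subject_id", weighted = FALSE) {
  stopifnot(all(c(value, group, subject) %in% names(table)))
  df <- tibble(
    value = table[[value]], group = as.character(table[[group]]),
    subject = as.character(table[[subject]])
  )
  if (anyNA(df$value)) {
    warn("Dropping cells with missing values.")
    df <- df[!is.na(df$value), ]
  }
  groups <- sort(unique(df$group))
  if (length(groups) != 2) abort("Nested t-test needs exactly 2 groups.")
  sm <- df %>%
    group_by(.data$subject, .data$group) %>%
    summarise(mean = mean(.data$value), n_cells = dplyr::n(), .groups = "drop")
  if (any(table(sm$subject) > 1)) {
    abort("Each subject must belong to exactly one group.")
  }
  n_per <- table(sm$group)
  if (any(n_per < 2)) abort("Need at least 2 subjects per group.")
  if (weighted) {
    fit <- stats::lm(mean ~ group, data = sm, weights = sm$n_cells)
    co <- summary(fit)$coefficients
    statistic <- co[2, "t value"]
    p <- co[2, "Pr(>|t|)"]
    dof <- fit$df.residual
  } else {
    tt <- t.test(mean ~ group, data = sm, var.equal = TRUE)
    statistic <- unname(tt$statistic)
    p <- tt$p.value
    dof <- unname(tt$parameter)
  }
  means <- tapply(sm$mean, sm$group, mean)
  structure(
    list(method = if (weighted) "nested t-test (weighted)" else "nested t-test",
         statistic = statistic, df = dof, p_value = p,
         group_means = means, groups = groups,
         estimate = unname(means[1] - means[2]),
         subject_means = sm),
    class = "nested_t"
  )
}

#' @export
print.nested_t <- function(x, ...) {
  cat(sprintf("%s: t(%d) = %.3f, p = %.4g\n", x$method, as.integer(x$df),
              x$statistic, x$p_value))
  cat(sprintf("  group means: %s = %.3f, %s = %.3f\n", x$groups[1],
              x$group_means[1], x$groups[2], x$group_means[2]))
  invisible(x)
}

# Aggregate cells to subject x treatment means; subjects missing a level are
# dropped (with a warning) so the split-plot strata stay balanced.
aggregate_subject_treatment <- function(table, value, between, within, subject) {
  df <- tibble(
    value = table[[value]], between = as.character(table[[between]]),
    within = as.character(table[[within]]),
    subject = as.character(table[[subject]])
  )
  agg <- df %>%
    group_by(.data$subject, .data$between, .data$within) %>%
    summarise(value = mean(.data$value), n_cells = dplyr::n(), .groups = "drop")
  n_levels <- length(unique(agg$within))
  per_subj <- agg %>% count(.data$subject)
  incomplete <- per_subj$subject[per_subj$n < n_levels]
  if (length(incomplete) > 0) {
    warn(sprintf("Dropping %d subject(s) without all %d within-subject levels: %s",
                 length(incomplete), n_levels,
                 paste(incomplete, collapse = ", ")))
    agg <- agg %>% filter(!.data$subject %in% incomplete)
  }
  agg
}

#' Two-way mixed-model (split-plot) ANOVA
#'
#' Diagnosis is a between-subject factor, treatment a within-subject factor,
#' and subject the random effect. Cells are first aggregated to subject x
#' treatment means, then a split-plot ANOVA is fit with subjects as the
#' between-unit error stratum: the diagnosis F uses the subject-within-
#' diagnosis mean square, while treatment and the diagnosis x treatment
#' interaction use the subject x treatment residual. Aggregation keeps the
#' computation fully specified and exactly checkable against first-principles
#' sums of squares in the balanced case (it is an approximation under severe
#' cell-count imbalance).
#'
#' @inheritParams nested_t_test
#' @param between Between-subject factor column (e.g. diagnosis).
#' @param within Within-subject factor column (e.g. treatment).
#' @return An object of class `mixed_anova`; [tidy()] returns the ANOVA
#'   table (term, stratum, df, sumsq, meansq, statistic, p.value).
#' @export
mixed_two_way_anova <- function(table, value = "value", between = "diagnosis",
                                within = "treatment", subject = "subject_id") {
  stopifnot(all(c(value, between, within, subject) %in% names(table)))
  agg <- aggregate_subject_treatment(table, value, between, within, subject)
  if (length(unique(agg$within)) < 2) {
    abort("Need at least 2 within-subject levels.")
  }
  agg_f <- agg %>%
    mutate(between = factor(.data$between), within = factor(.data$within),
           subject = factor(.data$subject))
  fit <- aov(value ~ between * within + Error(subject), data = agg_f)
  sm <- summary(fit)
  grab <- function(stratum_tab, stratum_name) {
    tab <- as.data.frame(stratum_tab[[1]])
    terms <- trimws(rownames(tab))
    tibble(term = terms, stratum = stratum_name,
           df = tab$Df, sumsq = tab$`Sum Sq`, meansq = tab$`Mean Sq`,
           statistic = if ("F value" %in% names(tab)) tab$`F value` else NA_real_,
           p.value = if ("Pr(>F)" %in% names(tab)) tab$`Pr(>F)` else NA_real_)
  }
  tab <- bind_rows(
    grab(sm[["Error: subject"]], "between-subjects"),
    grab(sm[["Error: Within"]], "within-subjects")
  ) %>%
    mutate(term = dplyr::recode(.data$term,
                                "between" = between, "within" = within,
                                "between:within" = paste0(between, ":", within)))
  structure(
    list(table = tab, aggregated = agg_f, fit = fit,
         factors = c(between = between, within = within, subject = subject),
         method = "two-way mixed-model ANOVA (split-plot on subject x treatment means)"),
    class = "mixed_anova"
  )
}

#' @export
print.mixed_anova <- function(x, ...) {
  cat(x$method, "\n")
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Dunnett many-to-one comparisons against a control treatment
#'
#' Within each between-subject group, compares every treatment to the control
#' on subject x treatment means, using the within-subject (subject x
#' treatment) error stratum of that group. Adjusted p-values come from the
#' exact many-to-one multivariate-t distribution (pairwise correlation 1/2 in
#' the balanced case) via `mvtnorm`; with a single comparison this reduces to
#' the plain paired t-test.
#'
#' @inheritParams mixed_two_way_anova
#' @param control Label of the control level of `within` (e.g. `"DMSO"`).
#' @return A tibble of class `dunnett_result`: one row per group x
#'   comparison with `estimate`, `statistic`, `df`, `p.value`,
#'   `adj.p.value`.
#' @export
dunnett_comparisons <- function(table, control, value = "value",
                                between = "diagnosis", within = "treatment",
                                subject = "subject_id") {
  stopifnot(all(c(value, between, within, subject) %in% names(table)))
  agg <- aggregate_subject_treatment(table, value, between, within, subject)
  if (!control %in% agg$within) {
    abort(sprintf("Control label `%s` not found in `%s`.", control, within))
  }
  out <- list()
  for (g in sort(unique(agg$between))) {
    sub <- agg %>% filter(.data$between == g)
    treatments <- sort(unique(sub$within))
    others <- setdiff(treatments, control)
    if (length(others) == 0) next
    n_subj <- length(unique(sub$subject))
    n_trt <- length(treatments)
    if (n_subj < 2) abort(sprintf("Group `%s` has fewer than 2 subjects.", g))
    fitg <- aov(value ~ within + Error(subject),
                data = sub %>% mutate(within = factor(.data$within),
                                      subject = factor(.data$subject)))
    wtab <- as.data.frame(summary(fitg)[["Error: Within"]][[1]])
    mse <- wtab["Residuals", "Mean Sq"]
    dof <- wtab["Residuals", "Df"]
    se <- sqrt(2 * mse / n_subj)
    means <- tapply(sub$value, sub$within, mean)
    m <- length(others)
    corr <- matrix(0.5, m, m); diag(corr) <- 1
    for (trt in others) {
      est <- unname(means[trt] - means[control])
      tstat <- est / se
      p_raw <- 2 * pt(-abs(tstat), dof)
      p_adj <- if (m == 1) {
        p_raw
      } else {
        # quasi-MC integration under a fixed local seed: reproducible to
        # well below the 1e-5 tolerance
        alg <- mvtnorm::GenzBretz(abseps = 1e-5, maxpts = 50000L)
        1 - with_seed(1L, as.numeric(
          mvtnorm::pmvt(lower = rep(-abs(tstat), m), upper = rep(abs(tstat), m),
                        df = as.integer(dof), corr = corr, algorithm = alg)))
      }
      out[[length(out) + 1]] <- tibble(
        group = g, comparison = paste(trt, "vs", control),
        estimate = est, statistic = tstat, df = dof,
        p.value = p_raw, adj.p.value = min(max(p_adj, p_raw), 1)
      )
    }
  }
  res <- bind_rows(out)
  class(res) <- c("dunnett_result", class(res))
  res
}

#' Sidak adjustment for m independent comparisons
#'
#' `p_adj = 1 - (1 - p)^m`, capped at 1 — the standard correction for a
#' family of `m` comparisons under independence.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param m Family size (>= 1).
#' @return Adjusted p-values, same length as `p`.
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(is.numeric(p), all(p >= 0 & p <= 1))
  check_number(m, "m", min = 1, integer = TRUE)
  pmin(1, 1 - (1 - p)^m)
}

#' Between-group comparisons at each treatment with Sidak adjustment
#'
#' Runs a nested t-test (subject means) between the two diagnosis groups
#' within each treatment level and adjusts the resulting p-values with
#' [sidak_adjust()] over the number of treatments.
#'
#' @inheritParams mixed_two_way_anova
#' @return A tibble: one row per treatment with the nested-t statistic, raw
#'   and adjusted p-values.
#' @export
sidak_comparisons <- function(table, value = "value", between = "diagnosis",
                              within = "treatment", subject = "subject_id") {
  treatments <- sort(unique(as.character(table[[within]])))
  rows <- purrr::map(treatments, function(trt) {
    sub <- table[table[[within]] == trt, , drop = FALSE]
    nt <- nested_t_test(sub, value = value, group = between, subject = subject)
    tibble(treatment = trt, estimate = nt$estimate, statistic = nt$statistic,
           df = nt$df, p.value = nt$p_value)
  }) %>% bind_rows()
  rows$adj.p.value <- sidak_adjust(rows$p.value, length(treatments))
  class(rows) <- c("sidak_result", class(rows))
  rows
}

#' Assess skew and log-transform when warranted
#'
#' Mirrors a normality pre-check: if the sample skewness exceeds
#' `skew_threshold` (default 1, a conventional cut for marked right skew) the
#' values are natural-log transformed; non-positive values under a triggered
#' transform are handled by a recorded additive offset. The decision is
#' returned alongside the (possibly transformed) values.
#'
#' @param values Numeric vector.
#' @param skew_threshold Skewness above which the transform fires.
#' @return A list of class `transform_decision`: `values`, `transformed`,
#'   `skewness`, `offset`, `threshold`.
#' @export
qq_log_transform <- function(values, skew_threshold = 1) {
  stopifnot(is.numeric(values), length(values) > 2)
  sk <- sample_skewness(values)
  transformed <- is.finite(sk) && sk > skew_threshold
  offset <- 0
  out <- values
  if (transformed) {
    if (any(values <= 0)) {
      offset <- -min(values) + 1
      warn(sprintf("Non-positive values: applying offset %.3g before log.", offset))
    }
    out <- log(values + offset)
  }
  structure(
    list(values = out, transformed = transformed, skewness = sk,
         offset = offset, threshold = skew_threshold),
    class = "transform_decision"
  )
}
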