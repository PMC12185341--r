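nested_tbl <- function(subject_means, cells_per_subject = 4, noise = 0) {
  # subject_means: named list group -> vector of subject means
  rows <- list()
  for (g in names(subject_means)) {
    for (s in seq_along(subject_means[[g]])) {
      rows[[paste(g, s)]] <- tibble::tibble(
        value = subject_means[[g]][s] + noise * rnorm(cells_per_subject),
        diagnosis = g,
        subject_id = paste0(g, "_", s)
      )
    }
  }
  dplyr::bind_rows(rows)
}

test_that("nested t-test on identical subject means gives t = 0", {
  tb <- nested_tbl(list(HC = c(10, 12), SCZ = c(10, 12)))
  res <- nested_t_test(tb)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 2)
})

test_that("nested t-test equals a t-test on subject means and is duplication invariant", {
  set.seed(12)
  tb <- nested_tbl(list(HC = rnorm(5, 12), SCZ = rnorm(6, 10)),
                   cells_per_subject = 6, noise = 1)
  res <- nested_t_test(tb)
  sm <- tapply(tb$value, tb$subject_id, mean)
  grp <- substr(names(sm), 1, 2) == "HC"
  ref <- t.test(sm[grp], sm[!grp], var.equal = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$df, 9)

  # duplicating every cell leaves subject means, hence the test, unchanged
  dup <- dplyr::bind_rows(tb, tb)
  res2 <- nested_t_test(dup)
  expect_equal(res2$statistic, res$statistic)
  expect_equal(res2$p_value, res$p_value)

  expect_error(nested_t_test(nested_tbl(list(A = 1, B = c(1, 2)))), "2 subjects")
  g <- glance(res)
  expect_equal(g$p.value, res$p_value)
})

test_that("mixed ANOVA: zero-signal data has zero effect sums of squares", {
  tb <- tidyr::expand_grid(subject_id = paste0("s", 1:6),
                           treatment = c("DMSO", "GSK3i")) |>
    dplyr::mutate(diagnosis = ifelse(subject_id %in% paste0("s", 1:3),
                                     "HC", "SCZ"),
                  value = 5)
  res <- mixed_two_way_anova(tb)
  tab <- tidy(res)
  eff <- tab[!grepl("Residuals", tab$term), ]
  expect_equal(eff$sumsq, rep(0, 3))
})

test_that("mixed ANOVA separates a pure diagnosis offset from interaction", {
  set.seed(13)
  tb <- tidyr::expand_grid(subject_id = paste0("s", 1:8),
                           treatment = c("DMSO", "GSK3i", "AKTi")) |>
    dplyr::mutate(diagnosis = ifelse(subject_id %in% paste0("s", 1:4),
                                     "HC", "SCZ"),
                  value = 100 + 20 * (diagnosis == "SCZ") +
                    5 * (treatment == "GSK3i") + rnorm(dplyr::n(), 0, 0.01))
  tab <- tidy(mixed_two_way_anova(tb))
  f_dx <- tab$statistic[tab$term == "diagnosis"]
  f_int <- tab$statistic[tab$term == "diagnosis:treatment"]
  expect_gt(f_dx, 1e4)
  expect_lt(f_int, 10)
})

test_that("mixed ANOVA F statistics match first-principles sums of squares", {
  set.seed(14)
  for (i in 1:5) {
    df <- tidyr::expand_grid(subject_id = paste0("s", 1:10),
                             within = c("a", "b", "c")) |>
      dplyr::mutate(between = ifelse(subject_id %in% paste0("s", 1:5),
                                     "G1", "G2"),
                    value = rnorm(dplyr::n(), 100, 10))
    res <- mixed_two_way_anova(df, value = "value", between = "between",
                               within = "within", subject = "subject_id")
    tab <- tidy(res)
    oracle <- oracle_split_plot_F(data.frame(value = df$value,
                                             between = df$between,
                                             within = df$within,
                                             subject = df$subject_id))
    expect_equal(tab$statistic[tab$term == "between"],
                 unname(oracle["group"]), tolerance = 1e-8)
    expect_equal(tab$statistic[tab$term == "within"],
                 unname(oracle["treatment"]), tolerance = 1e-8)
    expect_equal(tab$statistic[tab$term == "between:within"],
                 unname(oracle["interaction"]), tolerance = 1e-8)
  }
})

test_that("ANOVA F statistics are shift invariant", {
  set.seed(15)
  df <- tidyr::expand_grid(subject_id = paste0("s", 1:6),
                           treatment = c("DMSO", "GSK3i")) |>
    dplyr::mutate(diagnosis = ifelse(subject_id %in% paste0("s", 1:3),
                                     "HC", "SCZ"),
                  value = rnorm(dplyr::n(), 50, 5))
  a <- tidy(mixed_two_way_anova(df))
  b <- tidy(mixed_two_way_anova(dplyr::mutate(df, value = value + 1000)))
  expect_equal(a$statistic, b$statistic, tolerance = 1e-8)
})

test_that("Dunnett comparisons reduce to the paired t-test for one contrast", {
  set.seed(16)
  tb <- tidyr::expand_grid(subject_id = paste0("s", 1:6),
                           treatment = c("DMSO", "GSK3i")) |>
    dplyr::mutate(diagnosis = "HC", value = rnorm(dplyr::n(), 100, 8) +
                    3 * (treatment == "GSK3i"))
  res <- dunnett_comparisons(tb, control = "DMSO")
  expect_equal(nrow(res), 1)
  wide <- tapply(tb$value, list(tb$subject_id, tb$treatment), mean)
  ref <- t.test(wide[, "GSK3i"], wide[, "DMSO"], paired = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(res$adj.p.value, ref$p.value, tolerance = 1e-8)
  expect_equal(res$p.value, res$adj.p.value)
})

test_that("Dunnett adjusted p-values exceed raw ones and flag a null treatment", {
  set.seed(17)
  tb <- tidyr::expand_grid(subject_id = paste0("s", 1:8),
                           treatment = c("DMSO", "T1", "T2")) |>
    dplyr::mutate(diagnosis = "HC",
                  value = rnorm(dplyr::n(), 100, 5) + 25 * (treatment == "T2"))
  res <- dunnett_comparisons(tb, control = "DMSO")
  expect_equal(nrow(res), 2)
  expect_true(all(res$adj.p.value >= res$p.value - 1e-12))
  expect_gt(res$adj.p.value[res$comparison == "T1 vs DMSO"], 0.2)
  expect_lt(res$adj.p.value[res$comparison == "T2 vs DMSO"], 0.01)
  expect_error(dunnett_comparisons(tb, control = "missing"), "Control label")
})

test_that("Sidak adjustment follows its closed form and is monotone", {
  expect_equal(sidak_adjust(0.05, 1), 0.05)
  expect_equal(sidak_adjust(0.01, 3), 1 - 0.99^3)
  set.seed(18)
  p <- runif(50)
  for (m in c(1, 2, 5)) {
    expect_equal(sidak_adjust(p, m), pmin(1, 1 - (1 - p)^m))
  }
  # monotone in p and m, and bounded by [p, 1]
  ps <- sort(runif(10))
  expect_true(all(diff(sidak_adjust(ps, 3)) >= 0))
  expect_true(all(sidak_adjust(ps, 4) >= sidak_adjust(ps, 2)))
  expect_true(all(sidak_adjust(ps, 6) >= ps))
})

test_that("Sidak between-group comparisons run per treatment", {
  set.seed(19)
  tb <- tidyr::expand_grid(subject_id = paste0("s", 1:10),
                           treatment = c("DMSO", "GSK3i")) |>
    dplyr::mutate(diagnosis = ifelse(subject_id %in% paste0("s", 1:5),
                                     "HC", "SCZ"),
                  value = rnorm(dplyr::n(), 100, 3) -
                    15 * (diagnosis == "SCZ" & treatment == "GSK3i"))
  res <- sidak_comparisons(tb)
  expect_equal(nrow(res), 2)
  expect_lt(res$adj.p.value[res$treatment == "GSK3i"], 0.05)
  expect_equal(res$adj.p.value, sidak_adjust(res$p.value, 2))
})

test_that("log-transform decision fires on skewed data only", {
  sym <- qq_log_transform(rnorm(200))
  expect_false(sym$transformed)
  expect_equal(qq_log_transform(rep(5, 10))$skewness, 0)

  set.seed(20)
  fired <- sapply(1:200, function(i) {
    qq_log_transform(rlnorm(100, 0, 1))$transformed
  })
  expect_gt(mean(fired), 0.9)

  # non-positive values under a triggered transform use a recorded offset
  x <- c(rlnorm(100, 0, 1.5) - 0.5)
  expect_warning(res <- qq_log_transform(x), "offset")
  expect_true(res$offset > 0)
  expect_true(all(is.finite(res$values)))
})
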