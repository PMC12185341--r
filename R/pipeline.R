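#' Write a synthetic cohort to disk
#'
#' Persists the cohort in exchange formats: traces as long CSV, sample sheet
#' and truth tables as CSV, the configuration echo as JSON, and soma
#' image/mask pairs as 16-bit grayscale TIFFs under `soma/`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if missing).
#' @param max_intensity Intensity mapped to the top of the 16-bit range.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, max_intensity = 1000) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cohort$traces)) {
    readr::write_csv(cohort$traces, file.path(dir, "traces.csv"))
  }
  readr::write_csv(cohort$sample_sheet, file.path(dir, "sample_sheet.csv"))
  readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  cfg <- unclass(cohort$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(cohort$soma_images) > 0) {
    soma_dir <- file.path(dir, "soma")
    dir.create(soma_dir, showWarnings = FALSE)
    for (id in names(cohort$soma_images)) {
      sm <- cohort$soma_images[[id]]
      img01 <- pmin(sm$image / max_intensity, 1)
      tiff::writeTIFF(img01, file.path(soma_dir, paste0(id, ".tif")),
                      bits.per.sample = 16)
      tiff::writeTIFF(sm$mask * 1, file.path(soma_dir, paste0(id, "_mask.tif")),
                      bits.per.sample = 16)
    }
  }
  invisible(dir)
}

#' Configure a figure-shaped experiment
#'
#' Bundles everything one end-to-end run needs: the scenario (which task grid
#' to reproduce), the synthetic cohort configuration, feature settings and the
#' split scheme.
#'
#' Scenarios:
#' * `postmortem_diagnosis` — two diagnosis groups, one condition; tasks:
#'   diagnosis from AIS spectral features and from soma texture features;
#'   statistics: nested t-tests on AIS mean, soma mean and the AIS/soma ratio.
#' * `ipsc_diagnosis_treatment` — diagnosis x treatment grid; tasks:
#'   diagnosis within each treatment and treatment within each diagnosis
#'   (spectral features); statistics: split-plot mixed ANOVA, Dunnett
#'   within-group comparisons against vehicle, Sidak between-group
#'   comparisons per treatment.
#'
#' @param scenario `"postmortem_diagnosis"` or `"ipsc_diagnosis_treatment"`.
#' @param synth A [synth_config()]; a scenario-appropriate default is built
#'   when omitted.
#' @param n_coeff DFT coefficients kept as features.
#' @param n_bins Gray levels for texture quantization.
#' @param scheme A [split_scheme()].
#' @param frac_of_peak Threshold fraction for AIS length.
#' @param with_soma Generate and analyse soma images (postmortem scenario).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(scenario = c("postmortem_diagnosis",
                                           "ipsc_diagnosis_treatment"),
                              synth = NULL, n_coeff = 20L, n_bins = 32L,
                              scheme = split_scheme(), frac_of_peak = 0.33,
                              with_soma = NULL) {
  scenario <- match.arg(scenario)
  if (is.null(synth)) {
    synth <- switch(scenario,
      postmortem_diagnosis = synth_config(groups = postmortem_groups()),
      ipsc_diagnosis_treatment = synth_config(groups = ipsc_groups(),
                                              n_subjects_per_group = 4,
                                              cells_per_subject = 15)
    )
  }
  stopifnot(inherits(synth, "synth_config"), inherits(scheme, "split_scheme"))
  if (is.null(with_soma)) with_soma <- scenario == "postmortem_diagnosis"
  structure(
    list(scenario = scenario, synth = synth, n_coeff = as.integer(n_coeff),
         n_bins = as.integer(n_bins), scheme = scheme,
         frac_of_peak = frac_of_peak, with_soma = isTRUE(with_soma)),
    class = "experiment_config"
  )
}

rf_report_to_list <- function(report) {
  list(
    task = report$task, subset = as.list(report$subset),
    per_repeat_accuracy = report$per_repeat$accuracy,
    mean_accuracy = report$mean_accuracy, sd_accuracy = report$sd_accuracy,
    classes = report$classes, n_cells = report$n_cells,
    confusion = lapply(report$confusion, function(cm) {
      list(truth = rownames(cm), predicted = colnames(cm),
           counts = unclass(as.matrix(cm)))
    }),
    importance = report$importance,
    scheme = unclass(report$scheme),
    model_params = report$model_params
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage `%s` failed: %s", stage, conditionMessage(e)))
  })
}

#' Run a full figure-shaped experiment
#'
#' Executes simulate -> quantify -> features -> classify -> statistics from a
#' single [experiment_config()], writing every stage product plus a run
#' manifest under `out_dir`. The run is a pure function of the configuration:
#' identical configs give byte-identical CSV/JSON outputs (the manifest's
#' timestamp aside).
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory.
#' @return An object of class `experiment_result`: the in-memory bundle
#'   (cohort, measurements, feature tables, `rf_report`s, statistics,
#'   summary table) plus output paths.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  components <- if (config$with_soma) c("traces", "soma") else "traces"
  cohort <- run_stage("simulate", generate_cohort(config$synth, components))
  run_stage("simulate", write_cohort(cohort, file.path(out_dir, "cohort")))

  measurements <- run_stage("quantify",
                            quantify_cohort(cohort, config$frac_of_peak))
  readr::write_csv(measurements, file.path(out_dir, "measurements.csv"))

  calibrated <- run_stage("features", calibrate_traces(cohort$traces))
  feats_dft <- run_stage("features", dft_features(calibrated, config$n_coeff))
  readr::write_csv(feats_dft, file.path(out_dir, "features_dft.csv"))
  feats_tex <- NULL
  if (config$with_soma) {
    feats_tex <- run_stage("features",
                           texture_features_cohort(cohort, n_bins = config$n_bins))
    readr::write_csv(feats_tex, file.path(out_dir, "features_texture.csv"))
  }
  manifest_features <- list(
    dft = list(n_coeff = config$n_coeff,
               trace_length = attr(calibrated, "calibrated_length"),
               dropped = attr(calibrated, "dropped")$cell_id),
    texture = if (config$with_soma) list(n_bins = config$n_bins, distance = 1,
                                         alpha = 0) else NULL
  )

  reports <- run_stage("classify", switch(
    config$scenario,
    postmortem_diagnosis = {
      r <- list(ais_diagnosis = run_task(feats_dft, "diagnosis",
                                         scheme = config$scheme))
      if (!is.null(feats_tex)) {
        r$soma_diagnosis <- run_task(feats_tex, "diagnosis",
                                     scheme = config$scheme)
      }
      r
    },
    ipsc_diagnosis_treatment = {
      r <- list()
      for (trt in unique(feats_dft$treatment)) {
        r[[paste0("diagnosis_within_", trt)]] <-
          run_task(feats_dft, "diagnosis", filters = c(treatment = trt),
                   scheme = config$scheme)
      }
      for (dx in unique(feats_dft$diagnosis)) {
        r[[paste0("treatment_within_", dx)]] <-
          run_task(feats_dft, "treatment", filters = c(diagnosis = dx),
                   scheme = config$scheme)
      }
      r
    }
  ))
  jsonlite::write_json(lapply(reports, rf_report_to_list),
                       file.path(out_dir, "classification.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  stats_res <- run_stage("stats", switch(
    config$scenario,
    postmortem_diagnosis = {
      measures <- intersect(c("ais_mean", "soma_mean", "ratio"),
                            names(measurements))
      setNames(lapply(measures, function(mcol) {
        glance(nested_t_test(measurements, value = mcol))
      }), measures)
    },
    ipsc_diagnosis_treatment = {
      list(
        mixed_anova_ais = tidy(mixed_two_way_anova(measurements,
                                                   value = "ais_mean")),
        dunnett_ais = tidy(dunnett_comparisons(measurements, control = "DMSO",
                                               value = "ais_mean")),
        sidak_ais = tidy(sidak_comparisons(measurements, value = "ais_mean")),
        mixed_anova_length = tidy(mixed_two_way_anova(measurements,
                                                      value = "ais_length_um"))
      )
    }
  ))
  jsonlite::write_json(stats_res, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  summary_tab <- purrr::imap(reports, function(rep, nm) {
    glance(rep) %>% mutate(task_label = nm, .before = 1)
  }) %>% bind_rows()
  readr::write_csv(summary_tab, file.path(out_dir, "summary.csv"))

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[!grepl("manifest\\.json$", outputs)]
  manifest <- list(
    scenario = config$scenario,
    config = list(synth = unclass(config$synth)[setdiff(names(unclass(config$synth)), "groups")],
                  groups = config$synth$groups,
                  scheme = unclass(config$scheme),
                  n_coeff = config$n_coeff, n_bins = config$n_bins,
                  frac_of_peak = config$frac_of_peak,
                  with_soma = config$with_soma),
    seeds = list(synth = config$synth$seed, scheme = config$scheme$seed),
    features = manifest_features,
    versions = list(package = as.character(utils::packageVersion("aisquant")),
                    r = R.version.string),
    output_hashes = as.list(setNames(unname(tools::md5sum(outputs)),
                                     sub(paste0("^", out_dir, "/?"), "", outputs))),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(
    list(dir = out_dir, config = config, cohort = cohort,
         measurements = measurements, calibrated_traces = calibrated,
         features = list(dft = feats_dft, texture = feats_tex),
         reports = reports, stats = stats_res, summary = summary_tab,
         manifest = manifest),
    class = "experiment_result"
  )
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result>", x$config$scenario, "\n")
  cat("  output:", x$dir, "\n")
  print(x$summary %>%
          select("task_label", "mean_accuracy", "sd_accuracy", "n_cells"),
        n = Inf)
  invisible(x)
}

#' Build a report from an experiment bundle
#'
#' Collates the figure-style deliverables of a run: the accuracy summary
#' table, the statistics tables, a group-mean calibrated-trace plot with
#' dispersion bands, and an accuracy bar plot.
#'
#' @param bundle An `experiment_result`.
#' @return A list of class `experiment_report` with elements `summary`,
#'   `stats`, `trace_plot`, `accuracy_plot`.
#' @export
make_report <- function(bundle) {
  stopifnot(inherits(bundle, "experiment_result"))
  facet <- if (bundle$config$scenario == "ipsc_diagnosis_treatment")
    "treatment" else NULL
  trace_plot <- plot_mean_traces(bundle$calibrated_traces, facet_by = facet)
  accuracy_plot <- if (nrow(bundle$summary) > 0)
    plot_accuracy_table(bundle$summary) else NULL
  structure(
    list(summary = bundle$summary, stats = bundle$stats,
         trace_plot = trace_plot, accuracy_plot = accuracy_plot),
    class = "experiment_report"
  )
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  if (nrow(x$summary) > 0) {
    print(x$summary %>%
            select("task_label", "mean_accuracy", "sd_accuracy"), n = Inf)
  } else {
    cat("  no classification tasks; cohort description only\n")
  }
  invisible(x)
}
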