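#' Configuration of a full simulated study
#'
#' Bundles everything needed to regenerate a complete three-configuration
#' study: presets, indentation geometry, acquisition parameters, pipeline
#' settings and the global seed. Per-sample seeds are fanned out from the
#' global seed with a counter-based scheme (configuration index, sample
#' index), so adding samples or configurations never perturbs existing ones.
#'
#' @param presets Preset tibble, default [grade_presets()].
#' @param geometry An [indentation_geometry()].
#' @param acquisition An [acquisition_params()].
#' @param settings A [pipeline_settings()].
#' @param seed Global integer seed.
#' @param configs Imaging configurations to simulate.
#' @return An object of class `study_config`.
#' @export
study_config <- function(presets = grade_presets(),
                         geometry = indentation_geometry(),
                         acquisition = acquisition_params(),
                         settings = pipeline_settings(),
                         seed = 1L,
                         configs = psoct_configs()) {
  configs <- match.arg(configs, psoct_configs(), several.ok = TRUE)
  structure(
    list(presets = presets, geometry = geometry, acquisition = acquisition,
         settings = settings, seed = as.integer(seed), configs = configs),
    class = "study_config"
  )
}

#' Simulate and analyse one specimen
#'
#' Generates the tissue model for one (grade, configuration, sample) cell,
#' renders the B-scan stack and runs the BRC pipeline at the default
#' analysis column.
#'
#' @param preset One row of a preset tibble.
#' @param config A [study_config()].
#' @param sample_index Specimen index within its group.
#' @return A one-row tibble: `sample_id`, `grade`, `config`, `brc`,
#'   `truth_brc`, `center_ascan`, and the per-B-scan values nested in
#'   `per_bscan`.
#' @export
simulate_sample <- function(preset, config = study_config(), sample_index = 1L) {
  cfg_idx <- match(preset$config, psoct_configs())
  grade_idx <- match(preset$grade, psoct_grades())
  seed <- derive_seed(config$seed, cfg_idx, grade_idx * 100L + sample_index)
  tissue <- make_tissue(preset, config$geometry,
                        sample_index = sample_index, seed = seed,
                        refractive_index = config$settings$refractive_index)
  volume <- simulate_volume(tissue, config$acquisition,
                            n_bscans = config$settings$n_bscans, seed = seed)
  center <- default_center_ascan(tissue, config$acquisition)
  res <- compute_sample_brc(volume, center, config$settings)
  tibble::tibble(
    sample_id = sprintf("%s_%s_%02d", preset$grade, preset$config, sample_index),
    grade = preset$grade, config = preset$config,
    brc = res$brc, truth_brc = tissue$truth_brc,
    center_ascan = center,
    per_bscan = list(res$per_bscan)
  )
}

#' Replicate the full indentation study in silico
#'
#' Simulates the complete study design -- 10 healthy (G0), 8 mildly (G1) and
#' 8 moderately (G2) degenerate specimens, each imaged in the indented XZ
#' plane, the non-indented XZ plane and the XY side plane -- runs the BRC
#' pipeline on every volume, and applies the group statistics (one-way ANOVA
#' and Tukey post-hoc per configuration). Fully reproducible from the
#' config and its seed.
#'
#' @param config A [study_config()].
#' @param out_dir Optional directory: if given, the per-sample table, the
#'   formatted summary table and the echoed run configuration are written
#'   there as plain-text files.
#' @return An object of class `brc_study`: list with `samples` (tibble, one
#'   row per specimen x configuration), `summary` (a [summarize_study()]
#'   result) and `config`.
#' @export
replicate_study <- function(config = study_config(), out_dir = NULL) {
  rows <- config$presets |>
    dplyr::filter(.data$config %in% !!config$configs)
  samples <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
    preset <- rows[i, ]
    purrr::map_dfr(seq_len(preset$n_samples), function(s) {
      simulate_sample(preset, config, sample_index = s)
    })
  })
  summary <- if (setequal(config$configs, psoct_configs())) {
    summarize_study(samples)
  } else {
    NULL
  }
  out <- structure(list(samples = samples, summary = summary, config = config),
                   class = "brc_study")
  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

#' @export
print.brc_study <- function(x, ...) {
  cat(sprintf("<brc_study> %d specimens x %d configuration(s), seed %d\n\n",
              length(unique(sub("^(G\\d)_.*_(\\d+)$", "\\1\\2", x$samples$sample_id))),
              length(unique(x$samples$config)), x$config$seed))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
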