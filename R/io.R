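#' Persist and reload simulated volumes
#'
#' A volume is stored as a single JSON document holding, per B-scan, the two
#' channel amplitude images (vertical page first, horizontal second), plus a
#' sidecar block with the acquisition parameters and the simulation truth.
#' The reader validates that the two pages of every B-scan agree in shape.
#' (The installed R stack has no TIFF codec, so JSON plays the role of the
#' interchange container; the page/sidecar content contract is unchanged.)
#'
#' @param volume A `psoct_volume`.
#' @param path Output file path (".json").
#' @return `write_volume()` returns `path` invisibly; `read_volume()`
#'   returns a `psoct_volume`.
#' @export
write_volume <- function(volume, path) {
  pairs <- purrr::map(volume, function(p) {
    list(Av = p$Av, Ah = p$Ah)
  })
  doc <- list(
    pages = pairs,
    params = unclass(volume[[1]]$params),
    truth_brc = attr(volume, "truth_brc", exact = TRUE),
    grade = attr(volume, "grade", exact = TRUE),
    config = attr(volume, "config", exact = TRUE)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  params <- do.call(acquisition_params, as.list(doc$params))
  tissue_stub <- list(truth_brc = doc$truth_brc, grade = doc$grade,
                      config = doc$config)
  pairs <- purrr::map(doc$pages, function(page) {
    av <- as.matrix(page$Av); ah <- as.matrix(page$Ah)
    if (!identical(dim(av), dim(ah))) {
      stop_psoct("channel pages disagree in shape", "psoct_structural_error")
    }
    new_bscan_pair(av, ah, params, tissue_stub)
  })
  structure(pairs, class = "psoct_volume",
            truth_brc = doc$truth_brc, grade = doc$grade, config = doc$config)
}

#' Write a study manifest
#'
#' One row per specimen: sample id, grade, configuration, volume path,
#' analysis column and seed. Round-trips through [read_manifest()].
#'
#' @param manifest A data frame with columns `sample_id`, `grade`, `config`,
#'   `path`, `center_ascan`, `seed`.
#' @param path CSV file path.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("sample_id", "grade", "config", "path", "center_ascan", "seed")
  if (!all(need %in% names(manifest))) {
    stop_psoct(paste0("manifest needs columns: ", paste(need, collapse = ", ")),
               "psoct_structural_error")
  }
  if (anyDuplicated(manifest$sample_id)) {
    stop_psoct("sample ids must be unique", "psoct_structural_error")
  }
  if (!all(manifest$grade %in% psoct_grades()) ||
      !all(manifest$config %in% psoct_configs())) {
    stop_psoct("unknown grade or config label in manifest", "psoct_structural_error")
  }
  write.csv(manifest[, need], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  out <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  out$center_ascan <- as.integer(out$center_ascan)
  out$seed <- as.integer(out$seed)
  out
}

#' Write the artefacts of a completed study
#'
#' Writes `samples.csv` (per-specimen results), `table1.txt` (the formatted
#' summary table), `anova.csv`, `tukey.csv` and `config.txt` (the echoed run
#' configuration) into `dir`.
#'
#' @param study A `brc_study` from [replicate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- dplyr::mutate(
    study$samples,
    per_bscan = vapply(.data$per_bscan, function(v) paste(v, collapse = ";"), "")
  )
  write.csv(flat, file.path(dir, "samples.csv"), row.names = FALSE)
  if (!is.null(study$summary)) {
    con <- file(file.path(dir, "table1.txt"), "w")
    sink(con); print(study$summary); sink()
    close(con)
    write.csv(study$summary$anova, file.path(dir, "anova.csv"), row.names = FALSE)
    write.csv(study$summary$tukey, file.path(dir, "tukey.csv"), row.names = FALSE)
  }
  write_run_config(study$config, file.path(dir, "config.txt"))
  invisible(dir)
}

#' Flat key/value serialisation of a run configuration
#'
#' YAML-style `key: value` lines covering the acquisition parameters,
#' pipeline settings, geometry and seed; presets are written alongside via
#' [write_preset_config()] conventions.
#'
#' @param config A [study_config()].
#' @param path Output text file.
#' @export
write_run_config <- function(config, path) {
  num <- function(x) format(x, digits = 15)
  lines <- c(
    paste0("seed: ", config$seed),
    paste0("configs: ", paste(config$configs, collapse = ",")),
    paste0("geometry.", names(config$geometry), ": ",
           vapply(config$geometry, num, "")),
    paste0("acquisition.", names(unclass(config$acquisition)), ": ",
           vapply(unclass(config$acquisition), num, "")),
    paste0("settings.", names(unclass(config$settings)), ": ",
           vapply(unclass(config$settings), num, "")),
    "presets:",
    vapply(seq_len(nrow(config$presets)), function(i) {
      p <- config$presets[i, ]
      sprintf("  %s %s %s %s %d %s", p$grade, p$config, num(p$brc_mean),
              num(p$brc_sd), p$n_samples, num(p$banding_asymmetry))
    }, "")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  preset_at <- which(lines == "presets:")
  kv_lines <- lines[seq_len(preset_at - 1)]
  kv <- strsplit(kv_lines, ":\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ":"), "")
  get <- function(prefix) {
    sel <- startsWith(keys, paste0(prefix, "."))
    setNames(vals[sel], sub(paste0("^", prefix, "\\."), "", keys[sel]))
  }
  as_args <- function(x) lapply(as.list(x), function(v) {
    suppressWarnings(n <- as.numeric(v)); if (is.na(n)) v else n
  })
  geom <- do.call(indentation_geometry, as_args(get("geometry")))
  acq <- do.call(acquisition_params, as_args(get("acquisition")))
  set <- do.call(pipeline_settings, as_args(get("settings")))
  pl <- lines[(preset_at + 1):length(lines)]
  pl <- trimws(pl[nzchar(trimws(pl))])
  parts <- strsplit(pl, "\\s+")
  presets <- tibble::tibble(
    grade = vapply(parts, `[`, "", 1),
    config = vapply(parts, `[`, "", 2),
    brc_mean = as.numeric(vapply(parts, `[`, "", 3)),
    brc_sd = as.numeric(vapply(parts, `[`, "", 4)),
    n_samples = as.integer(vapply(parts, `[`, "", 5)),
    banding_asymmetry = as.numeric(vapply(parts, `[`, "", 6))
  )
  study_config(
    presets = presets, geometry = geom, acquisition = acq, settings = set,
    seed = as.integer(as.numeric(vals[keys == "seed"])),
    configs = strsplit(vals[keys == "configs"], ",")[[1]]
  )
}
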