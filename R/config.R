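config_defaults <- function() {
  list(
    strategies = c("current", "A", "B", "C", "D"),
    sexes = c("male", "female"),
    n_donors = 10000,
    horizon_weeks = 78,
    seed = 1,
    psa_samples = 500,
    weights_grid = c(10, 20, 40),
    out_dir = "results",
    params = list(),                # optional keys: hb, attendance, probs (paths)
    costs = list(base = 26.20)      # optional keys: onsession_test, low_hb_deferral
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration, fills defaults (10,000 donors,
#' 78-week horizon, 500 PSA samples, weight grid \{10, 20, 40\}) and rejects
#' unknown keys, naming the offending key. Parameter-bundle paths, when
#' given, must exist.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` configuration file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    stop_config("unknown configuration key: %s", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, raw)
  if (!all(cfg$strategies %in% c("current", "A", "B", "C", "D", "custom"))) {
    stop_config("strategies must be among current/A/B/C/D/custom")
  }
  if (!all(cfg$sexes %in% c("male", "female"))) stop_config("sexes must be male/female")
  if (!is.numeric(cfg$n_donors) || cfg$n_donors < 1) stop_config("n_donors must be >= 1")
  if (!is.numeric(cfg$horizon_weeks) || cfg$horizon_weeks <= 0) stop_config("horizon_weeks must be > 0")
  if (!is.numeric(cfg$seed) || cfg$seed != floor(cfg$seed)) stop_config("seed must be an integer")
  if (!is.numeric(cfg$psa_samples) || cfg$psa_samples < 2) stop_config("psa_samples must be >= 2")
  for (p in unlist(cfg$params)) {
    if (!is.null(p) && !file.exists(p)) stop_config("parameter bundle not found: %s", p)
  }
  structure(cfg, class = "run_config")
}

#' Write a configuration back to YAML
#'
#' @param cfg A `run_config` (or plain list of valid keys).
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write result tables with a reproducibility manifest
#'
#' Writes each element of `results` under `out_dir` (`data.frame`s as CSV,
#' anything else as JSON) and a `manifest.json` recording file content
#' hashes, the resolved configuration and the package version. Identical
#' inputs produce byte-identical CSVs.
#'
#' @param results Named list of `data.frame`s and/or lists.
#' @param out_dir Output directory (created if needed).
#' @param config Optional resolved configuration to embed in the manifest.
#' @return The manifest, invisibly.
#' @export
write_results <- function(results, out_dir, config = NULL) {
  if (length(results) && is.null(names(results))) stop_config("results must be named")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_config("cannot create output directory: %s", out_dir)
  artifacts <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      utils::write.csv(x, f, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
    } else {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, null = "null")
    }
    artifacts[[nm]] <- list(file = basename(f), md5 = unname(tools::md5sum(f)))
  }
  manifest <- list(
    package = "pdtsim",
    version = as.character(utils::packageVersion("pdtsim")),
    config = if (!is.null(config)) unclass(config) else NULL,
    artifacts = artifacts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(manifest)
}
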