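#' Configuration for a full catalog-to-panel run
#'
#' Collects every tunable of the end-to-end workflow in one serializable
#' object so a saved configuration re-runs bit-identically for the
#' deterministic stages. All randomness (model-check sampling) flows from
#' the single \code{seed}; per-stage child seeds are derived from it.
#'
#' @param catalog path to a hairpin FASTA file, or a
#'   \code{\link{hairpin_catalog}}.
#' @param out_dir output directory for all artifacts.
#' @param species_prefix identifier prefix filter for FASTA input.
#' @param params an \code{\link{alignment_params}}.
#' @param families candidate distribution families to fit.
#' @param bandwidth KDE bandwidth (numeric or \code{"auto"}).
#' @param n_check KS check sample size.
#' @param seed master integer seed.
#' @param quantile_qs percents for the quantile table.
#' @param threshold_p optional similarity threshold percentile.
#' @param panels named list of biomarker panels (character vectors of
#'   names, or paths to panel text files).
#' @param name_map optional path to a name-map TSV or a named character
#'   vector.
#' @return An object of class \code{run_config}.
#' @export
run_config <- function(catalog, out_dir,
                       species_prefix = "hsa-",
                       params = alignment_params(),
                       families = c("kde", "ecdf", "normal",
                                    "exponential"),
                       bandwidth = reference_bandwidth(),
                       n_check = 66L, seed = 1L,
                       quantile_qs = seq(5, 100, by = 5),
                       threshold_p = NULL, panels = list(),
                       name_map = NULL) {
  stopifnot(inherits(params, "alignment_params"), n_check >= 1)
  structure(list(catalog = catalog, out_dir = out_dir,
                 species_prefix = species_prefix, params = params,
                 families = families, bandwidth = bandwidth,
                 n_check = as.integer(n_check), seed = as.integer(seed),
                 quantile_qs = quantile_qs, threshold_p = threshold_p,
                 panels = panels, name_map = name_map),
            class = "run_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  serial <- config
  if (inherits(serial$catalog, "hairpin_catalog"))
    serial$catalog <- serial$catalog$records
  writeLines(toJSON(serial, auto_unbox = TRUE, digits = NA,
                    force = TRUE), f)
  unname(md5sum(f))
}

#' Run the full catalog-to-panel flowchart
#'
#' Executes, in order: catalog loading, all-pairs distance computation
#' (cached in \code{out_dir/distances.tsv} and reused on re-runs with an
#' unchanged catalog and scoring), fitting of every candidate family,
#' Kolmogorov-Smirnov model selection, percentile tabulation from the
#' selected model, and scoring of any configured biomarker panels. Every
#' artifact carries the configuration hash so outputs can be traced to
#' their settings; errors are reported with the failing stage's name.
#'
#' @param config a \code{\link{run_config}}.
#' @param verbose log stage progress.
#' @return Invisibly, a list with the loaded \code{catalog}, the
#'   \code{distances}, the model \code{selection}, the selected
#'   \code{model}, the \code{quantiles} table, the list of panel
#'   \code{reports}, and \code{artifacts} (paths of everything written).
#' @export
run_flowchart <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  say <- function(...) if (verbose) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop2("stage '", name, "' failed: ", conditionMessage(e)))
  }
  artifacts <- character(0)

  say("stage: catalog")
  catalog <- stage("catalog", {
    if (inherits(config$catalog, "hairpin_catalog")) config$catalog
    else read_hairpin_fasta(config$catalog,
                            species_prefix = config$species_prefix)
  })
  say(sprintf("  %d records", length(catalog)))

  say("stage: distances")
  dist_path <- file.path(config$out_dir, "distances.tsv")
  distances <- stage("distances",
    pairwise_distances(catalog, config$params, cache = dist_path,
                       verbose = verbose))
  artifacts <- c(artifacts, dist_path)

  say("stage: fit + model selection")
  selection <- stage("model-selection",
    select_model(distances, families = config$families,
                 n_check = config$n_check, seed = config$seed,
                 bandwidth = config$bandwidth))
  for (fam in names(selection$fits)) {
    p <- file.path(config$out_dir, sprintf("model_%s.json", fam))
    write_model(selection$fits[[fam]], p, config_hash = hash)
    artifacts <- c(artifacts, p)
  }
  sel_path <- file.path(config$out_dir, "selection.tsv")
  write_tsv_artifact(selection$table, sel_path, hash)
  artifacts <- c(artifacts, sel_path)
  model <- selected_model(selection)
  say(sprintf("  selected family: %s", model$family))

  say("stage: quantile table")
  qt <- stage("quantiles", quantile_table(model, config$quantile_qs))
  qt_path <- file.path(config$out_dir, "quantiles.tsv")
  write_tsv_artifact(as.data.frame(qt), qt_path, hash)
  artifacts <- c(artifacts, qt_path)

  reports <- list()
  if (length(config$panels) > 0) {
    say("stage: panels")
    nm_map <- config$name_map
    if (is.character(nm_map) && length(nm_map) == 1L &&
        file.exists(nm_map)) nm_map <- read_name_map(nm_map)
    for (i in seq_along(config$panels)) {
      pnl <- config$panels[[i]]
      if (length(pnl) == 1L && file.exists(pnl))
        pnl <- read_panel_names(pnl)
      label <- names(config$panels)[i]
      if (is.null(label) || is.na(label) || !nzchar(label))
        label <- sprintf("panel_%02d", i)
      rep_i <- stage(paste0("panel:", label),
        analyze_panel(pnl, catalog, model, params = config$params,
                      species_prefix = config$species_prefix,
                      name_map = nm_map,
                      threshold_p = config$threshold_p))
      p <- file.path(config$out_dir, paste0(label, ".json"))
      write_panel_report(rep_i, p, config_hash = hash)
      artifacts <- c(artifacts, p)
      reports[[label]] <- rep_i
    }
  }

  cfg_path <- file.path(config$out_dir, "config.json")
  cfg <- config
  if (inherits(cfg$catalog, "hairpin_catalog"))
    cfg$catalog <- "<in-memory catalog>"
  write_json(c(list(tool = "premirdist",
                    version = as.character(packageVersion("premirdist")),
                    config_hash = hash), unclass(cfg)),
             cfg_path, auto_unbox = TRUE, digits = NA, force = TRUE,
             null = "null")
  artifacts <- c(artifacts, cfg_path)
  say(sprintf("run complete (config %s); %d artifact(s) in %s",
              substr(hash, 1, 8), length(artifacts), config$out_dir))
  invisible(list(catalog = catalog, distances = distances,
                 selection = selection, model = model, quantiles = qt,
                 reports = reports, artifacts = artifacts,
                 config_hash = hash))
}

write_tsv_artifact <- function(df, path, config_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# premirdist %s",
                       as.character(packageVersion("premirdist"))),
               sprintf("# config: %s", config_hash)), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Write / read a fitted model as JSON
#'
#' Serializes a \code{dist_fit} to a JSON sidecar (family, parameters,
#' and - for the data-backed families - the data itself) such that
#' \code{read_model} reconstructs an equivalent fit.
#'
#' @param fit a \code{dist_fit}.
#' @param path file path.
#' @param config_hash optional provenance string stored in the file.
#' @return \code{path} (write) / a \code{dist_fit} (read).
#' @export
write_model <- function(fit, path, config_hash = NULL) {
  stopifnot(inherits(fit, "dist_fit"))
  payload <- list(tool = "premirdist",
                  version = as.character(packageVersion("premirdist")),
                  config_hash = config_hash,
                  family = fit$family, n = fit$n,
                  data_min = fit$data_min, data_max = fit$data_max)
  payload <- c(payload, switch(fit$family,
    normal = list(mu = fit$mu, sigma = fit$sigma),
    exponential = list(mean = fit$mean),
    ecdf = list(data = fit$data),
    kde = list(bandwidth = fit$bandwidth, data = fit$data)))
  write_json(payload, path, auto_unbox = TRUE, digits = NA,
             null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop2("model file not found: ", path)
  p <- read_json(path, simplifyVector = TRUE)
  if (!identical(p$tool, "premirdist"))
    stop2("not a premirdist model file: ", path)
  switch(p$family,
    normal = ,
    exponential = {
      fit <- c(list(family = p$family, n = p$n, data_min = p$data_min,
                    data_max = p$data_max),
               if (p$family == "normal") list(mu = p$mu, sigma = p$sigma)
               else list(mean = p$mean))
      structure(fit, class = c(paste0(p$family, "_fit"), "dist_fit"))
    },
    ecdf = fit_distance_distribution(p$data, "ecdf"),
    kde = fit_distance_distribution(p$data, "kde",
                                    bandwidth = p$bandwidth),
    stop2("unknown model family in ", path))
}

write_panel_report <- function(report, path, config_hash = NULL) {
  payload <- list(tool = "premirdist",
                  version = as.character(packageVersion("premirdist")),
                  config_hash = config_hash,
                  queries = report$queries,
                  resolved = report$resolved,
                  m = report$m, pair_count = report$pair_count,
                  distances = report$distances$values,
                  saturated_excluded = report$n_saturated,
                  mean = report$mean, range = report$range,
                  percentile_of_mean = report$percentile_of_mean,
                  threshold_p = report$threshold_p,
                  similar = report$similar)
  write_json(payload, path, auto_unbox = TRUE, digits = NA,
             null = "null", force = TRUE)
  invisible(path)
}
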