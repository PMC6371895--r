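#' Pipeline configuration
#'
#' Assembles and validates the configuration of an end-to-end run. All
#' randomness flows from the single global `seed` through fixed per-layer
#' offsets, so enabling or disabling one layer does not change another's
#' output.
#'
#' @param seed global integer seed (mandatory)
#' @param outdir output directory (created if absent)
#' @param layers layers to run, a subset of
#'   `c("size_gradient", "bifurcation", "hydrology", "temperature",
#'   "confinement")`
#' @param generator list of [generator_config()] arguments (without `seed`);
#'   ignored when `reach_table`/`fromto` paths are given
#' @param reach_table,fromto optional CSV paths of an existing network
#'   (read with [read_network()]); when `NULL` a network is generated
#' @param discharge_unit unit of the discharge column when reading
#'   (`"m3s"` or `"cfs"`)
#' @param hydrology list: `n_sites`, `k_clusters`, `separation`,
#'   `missing_frac`, `k_list`
#' @param temperature list: `n_sites`, `noise_sd`, `thresholds` (`"default"`
#'   for the packaged bins, or `"jenks"` to derive breaks from the predicted
#'   temperatures), `jenks_range`
#' @param regions optional data.frame `COMID, region` used to split output
#'   files by region
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(seed, outdir,
                            layers = c("size_gradient", "bifurcation",
                                       "hydrology", "temperature",
                                       "confinement"),
                            generator = list(n_reaches = 500),
                            reach_table = NULL, fromto = NULL,
                            discharge_unit = "m3s",
                            hydrology = list(),
                            temperature = list(),
                            regions = NULL) {
  if (missing(seed)) stop("config error: seed is mandatory", call. = FALSE)
  known <- c("size_gradient", "bifurcation", "hydrology", "temperature",
             "confinement")
  bad <- setdiff(layers, known)
  if (length(bad))
    stop("config error: unknown layer(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  hyd <- utils::modifyList(list(n_sites = 200, k_clusters = 4, separation = 6,
                                missing_frac = 0, k_list = c(2, 4)),
                           hydrology)
  tmp <- utils::modifyList(list(n_sites = 800, noise_sd = 1,
                                thresholds = "default", jenks_range = 2:8),
                           temperature)
  structure(list(seed = as.integer(seed), outdir = outdir, layers = layers,
                 generator = generator, reach_table = reach_table,
                 fromto = fromto, discharge_unit = discharge_unit,
                 hydrology = hyd, temperature = tmp, regions = regions),
            class = "pipeline_config")
}

# fixed per-layer seed offsets (named substreams of the global seed)
layer_seed <- function(seed, layer) {
  seed + switch(layer, generate = 0L, hydrology = 1000L,
                temperature = 2000L, confinement = 3000L,
                stop("unknown seed substream: ", layer))
}

#' Run the full classification pipeline
#'
#' Generates (or reads) a reach network, runs the enabled layers, and writes
#' one CSV per layer keyed by COMID plus a run manifest (seed, config hash,
#' per-layer unclassified counts) into the output directory. Reruns with the
#' same configuration are byte-identical. A failing layer leaves earlier
#' outputs in place and raises an error naming the layer.
#'
#' @param config a [pipeline_config()]
#' @return invisibly, the manifest list
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  manifest <- list(seed = seed,
                   config_hash = config_hash(config),
                   layers = list())

  in_layer <- function(layer, expr) {
    tryCatch(expr, error = function(e)
      stop("layer '", layer, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  if (!is.null(config$reach_table)) {
    net <- read_network(config$reach_table, config$fromto,
                        list(discharge_unit = config$discharge_unit))
  } else {
    gcfg <- do.call(generator_config,
                    c(config$generator, list(seed = layer_seed(seed, "generate"))))
    net <- generate_dendritic_network(gcfg)
    net <- attach_physical_attributes(net, gcfg)
  }
  manifest$n_reaches <- nrow(net$reaches)

  outputs <- list()

  if ("size_gradient" %in% config$layers) {
    tab <- in_layer("size_gradient", size_gradient_table(net))
    outputs$size_gradient <- tab
    manifest$layers$size_gradient <-
      list(unclassified = sum(tab$size_class == "unclassified" |
                                tab$gradient_class == "unclassified"))
  } else manifest$layers$size_gradient <- list(skipped = TRUE)

  if ("bifurcation" %in% config$layers) {
    tab <- in_layer("bifurcation", {
      cls <- assign_bifurcation_classes(net)
      correct_split_reaches(net, cls)
    })
    outputs$bifurcation <- tab
    manifest$layers$bifurcation <- list(unclassified = 0L,
                                        n_classes = length(unique(tab$bif_class)))
  } else manifest$layers$bifurcation <- list(skipped = TRUE)

  if ("hydrology" %in% config$layers) {
    tab <- in_layer("hydrology", {
      h <- config$hydrology
      hseed <- layer_seed(seed, "hydrology")
      panel <- generate_gage_panel(net, n_sites = h$n_sites,
                                   k_clusters = h$k_clusters,
                                   separation = h$separation,
                                   missing_frac = h$missing_frac, seed = hseed)
      if (h$missing_frac > 0)
        panel <- impute_missing(panel, seed = hseed + 1L)
      ward <- cluster_ward(as.matrix(panel$sites[panel$feature_cols]),
                           h$k_list)
      out <- data.frame(COMID = net$reaches$comid)
      assignments <- list()
      for (k in h$k_list) {
        mod <- fit_class_extrapolator(panel, labels = ward$labels[[paste0("k", k)]],
                                      seed = hseed + k)
        a <- predict_class_membership(mod, panel$network)
        assignments[[paste0("W", k)]] <- a
        out[[paste0("W", k)]] <- a$label
        out[[paste0("W", k, "_prob")]] <- a$predominant_prob
      }
      attr(out, "diagnostics") <- summarize_assignment_probabilities(assignments)
      out
    })
    outputs$hydrology <- tab
    manifest$layers$hydrology <- list(
      unclassified = sum(tab[[2]] == "unclassified"),
      diagnostics = attr(tab, "diagnostics"))
  } else manifest$layers$hydrology <- list(skipped = TRUE)

  if ("temperature" %in% config$layers) {
    tab <- in_layer("temperature", {
      tc <- config$temperature
      tseed <- layer_seed(seed, "temperature")
      sites <- generate_temperature_sites(net, n_sites = tc$n_sites,
                                          noise_sd = tc$noise_sd, seed = tseed)
      ref <- screen_reference_sites(sites)
      mod <- fit_temperature_regressor(ref, seed = tseed + 1L)
      pred <- predict_temperature(mod, net)
      if (identical(tc$thresholds, "jenks")) {
        k <- select_parsimonious_k(unname(pred[!is.na(pred)]), tc$jenks_range)
        jb <- jenks_breaks(unname(pred[!is.na(pred)]), as.integer(k))
        labels <- paste0("T", seq_len(jb$k))
        cls <- assign_interval_classes(pred, jb$breaks, labels)
      } else {
        def <- default_thresholds()$temperature
        cls <- assign_interval_classes(pred, def$breaks, def$labels)
      }
      data.frame(COMID = net$reaches$comid,
                 predicted_ja_temp = unname(pred),
                 temp_class = cls)
    })
    outputs$temperature <- tab
    manifest$layers$temperature <-
      list(unclassified = sum(tab$temp_class == "unclassified"))
  } else manifest$layers$temperature <- list(skipped = TRUE)

  if ("confinement" %in% config$layers) {
    tab <- in_layer("confinement", {
      inputs <- generate_valley_inputs(net, seed = layer_seed(seed, "confinement"))
      confinement_table(inputs)
    })
    outputs$confinement <- tab
    manifest$layers$confinement <-
      list(unclassified = sum(tab$conf_class == "unclassified"))
  } else manifest$layers$confinement <- list(skipped = TRUE)

  write_outputs(outputs, config$outdir, regions = config$regions)
  manifest$outputs <- sort(names(outputs))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(manifest)
}

# stable hash of the scientific configuration (seed included; the run
# location and region split are presentation, not content)
config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  keep <- setdiff(names(config), c("regions", "outdir"))
  writeLines(yaml::as.yaml(unclass(config)[keep]), tf)
  unname(tools::md5sum(tf))
}

#' Write per-layer output CSVs
#'
#' Writes each assignment table as `<layer>.csv` under `outdir`; when a
#' region table is supplied, one file per region is written instead
#' (`<layer>_<region>.csv`). Unclassified reaches are kept with their
#' explicit label, never dropped.
#'
#' @param outputs named list of data.frames, each keyed by a `COMID` column
#' @param outdir output directory
#' @param regions optional data.frame with columns `COMID` and `region`
#' @return invisibly, the written file paths
#' @export
write_outputs <- function(outputs, outdir, regions = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (layer in names(outputs)) {
    tab <- outputs[[layer]]
    if (!"COMID" %in% names(tab))
      stop("integrity error: layer '", layer, "' lacks a COMID column",
           call. = FALSE)
    if (anyDuplicated(tab$COMID))
      stop("integrity error: duplicate COMID in layer '", layer, "'",
           call. = FALSE)
    if (is.null(regions)) {
      p <- file.path(outdir, paste0(layer, ".csv"))
      utils::write.csv(tab, p, row.names = FALSE)
      paths <- c(paths, p)
    } else {
      reg <- regions$region[match(tab$COMID, regions$COMID)]
      for (r in sort(unique(reg))) {
        p <- file.path(outdir, paste0(layer, "_", r, ".csv"))
        utils::write.csv(tab[!is.na(reg) & reg == r, , drop = FALSE], p,
                         row.names = FALSE)
        paths <- c(paths, p)
      }
    }
  }
  invisible(paths)
}
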