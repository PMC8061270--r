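#' Build and validate a run configuration
#'
#' A configuration is a plain list (or YAML file) describing either a
#' synthetic scenario or input paths, the stages to run, and per-stage
#' parameters. Every seed is explicit: all stochastic stages derive their
#' streams from `seed`. Validation is fail-fast: missing input files for
#' enabled stages abort before any computation.
#'
#' @param config list or YAML path. Recognized fields:
#'   * `scenario`: list of [syn_scenario()] arguments (synthetic input), or
#'   * `genotypes`, `locales`: paths to a locale-labelled SNP CSV and
#'     locale CSV; `ploidy` for the CSV dialect;
#'   * `rasters`: named list of `list(path =, kind =)` raster inputs (ESRI
#'     ASCII grids) or in-memory `raster_layer`s;
#'   * `stages`: character subset of c("stats", "fst", "popgraph",
#'     "netmetrics", "landscape", "mlpe") (default: all whose inputs
#'     exist);
#'   * `alpha`, `n_perm`, `seed`, `null_model`, `tail`, `out_dir`.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- list(
    scenario = config$scenario,
    genotypes = config$genotypes, locales = config$locales,
    ploidy = config$ploidy %||% 1L,
    rasters = config$rasters %||% list(),
    stages = config$stages %||% c("stats", "fst", "popgraph", "netmetrics",
                                  "landscape", "mlpe"),
    alpha = config$alpha %||% 0.05,
    n_perm = as.integer(config$n_perm %||% 1000L),
    seed = as.integer(config$seed %||% 1L),
    null_model = config$null_model %||% "degree_preserving",
    tail = config$tail %||% "two-sided",
    out_dir = config$out_dir %||% "popland_run"
  )
  known <- c("stats", "fst", "popgraph", "netmetrics", "landscape", "mlpe")
  bad <- setdiff(cfg$stages, known)
  if (length(bad)) stop_popland("unknown stages: %s", paste(bad, collapse = ", "))
  if (is.null(cfg$scenario) && (is.null(cfg$genotypes) || is.null(cfg$locales)))
    stop_popland("config needs either a synthetic scenario or genotype + locale paths")
  for (p in c(cfg$genotypes, cfg$locales))
    if (!is.null(p) && !file.exists(p)) stop_popland("input path not found: %s", p)
  if ("landscape" %in% cfg$stages) {
    if (!length(cfg$rasters))
      stop_popland("landscape stage enabled but no rasters configured")
    for (nm in names(cfg$rasters)) {
      r <- cfg$rasters[[nm]]
      if (!inherits(r, "raster_layer") && !is.null(r$path) && !file.exists(r$path))
        stop_popland("raster path not found: %s", r$path)
    }
  }
  structure(cfg, class = "run_config")
}

load_config_raster <- function(r) {
  if (inherits(r, "raster_layer")) r
  else read_ascii_grid(r$path, kind = r$kind %||% "continuous")
}

#' Run the full connectivity pipeline
#'
#' Executes the enabled stages in dependency order (diversity stats ->
#' FST -> population graph -> network metrics -> landscape tests -> MLPE),
#' writing every artifact under `out_dir` together with a machine-readable
#' run manifest (package version, seeds, parameters, stage timings,
#' collected warnings, and md5 hashes of every written file). The first
#' failing stage aborts with a stage-qualified error; artifacts already
#' written are retained.
#'
#' @param config a `run_config` (or anything [run_config()] accepts).
#' @return (invisibly) list of stage results plus `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()
  manifest <- list(package = "popland",
                   version = as.character(utils::packageVersion("popland")),
                   r_version = R.version.string,
                   seed = cfg$seed, alpha = cfg$alpha, n_perm = cfg$n_perm,
                   null_model = cfg$null_model, tail = cfg$tail,
                   stages = cfg$stages, timings = list(), warnings = list())
  notes <- character()
  run_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop_popland("stage '%s' failed: %s", name, conditionMessage(e))),
      warning = function(w) {
        notes <<- c(notes, sprintf("[%s] %s", name, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  # inputs
  inp <- run_stage("input", {
    if (!is.null(cfg$scenario)) {
      sc <- do.call(syn_scenario, modifyList(cfg$scenario,
                                             list(seed = cfg$scenario$seed %||% cfg$seed)))
      sim <- simulate_snp_dataset(sc)
      write_snp_csv(sim$dataset, file.path(cfg$out_dir, "genotypes.csv"))
      write_vcf(sim$dataset, file.path(cfg$out_dir, "genotypes.vcf"))
      write_locales_csv(sim$locales, file.path(cfg$out_dir, "locales.csv"))
      write_scenario_yaml(sc, file.path(cfg$out_dir, "scenario.yaml"))
      c(sim, list(scenario = sc))
    } else {
      list(dataset = read_snp_csv(cfg$genotypes, ploidy = cfg$ploidy),
           locales = read_locales_csv(cfg$locales))
    }
  })
  dataset <- inp$dataset; locales <- inp$locales
  results$input <- inp
  if ("stats" %in% cfg$stages) {
    results$stats <- run_stage("stats", {
      st <- diversity_stats(dataset)
      utils::write.csv(st, file.path(cfg$out_dir, "diversity_stats.csv"),
                       row.names = FALSE)
      st
    })
  }
  if (any(c("fst", "mlpe") %in% cfg$stages)) {
    results$fst <- run_stage("fst", {
      m <- pairwise_fst_matrix(dataset)
      write_pairwise_csv(m, file.path(cfg$out_dir, "fst_matrix.csv"))
      pm <- panmixia_permutation(dataset, n_perm = cfg$n_perm, seed = cfg$seed)
      jsonlite::write_json(
        list(global_fst = attr(m, "global"), global_p = pm$global_p,
             n_perm = pm$n_perm, seed = pm$seed,
             pair_p_le_05 = sum(pm$p_value[upper.tri(pm$p_value)] <= 0.05)),
        file.path(cfg$out_dir, "panmixia_test.json"),
        auto_unbox = TRUE, digits = NA)
      list(matrix = m, global = attr(m, "global"), panmixia = pm)
    })
  }
  graph <- NULL
  if (any(c("popgraph", "netmetrics", "landscape") %in% cfg$stages)) {
    results$popgraph <- run_stage("popgraph", {
      pg <- build_popgraph(dataset, locales, alpha = cfg$alpha)
      write_popgraph_graphml(pg$graph, file.path(cfg$out_dir, "popgraph.graphml"))
      write_edgelist_csv(pg$graph, file.path(cfg$out_dir, "popgraph_edges.csv"))
      cgd <- cgd_matrix(pg$graph)
      write_pairwise_csv(cgd, file.path(cfg$out_dir, "cgd_matrix.csv"))
      list(graph = pg$graph, cov = pg$cov, cgd = cgd,
           isolated = isolated_nodes(pg$graph))
    })
    graph <- results$popgraph$graph
  }
  if ("netmetrics" %in% cfg$stages) {
    results$netmetrics <- run_stage("netmetrics", {
      nm <- node_metrics(graph)
      write_node_metrics_csv(nm, file.path(cfg$out_dir, "node_metrics.csv"))
      tests <- list()
      if (igraph::ecount(graph) >= 2) {
        for (metric in c("closeness", "betweenness", "eigenvector")) {
          tests[[metric]] <- metric_permutation_test(
            graph, metric, n_perm = cfg$n_perm,
            seed = derive_seed(cfg$seed, 20L + match(metric, c("closeness", "betweenness", "eigenvector"))),
            null_model = cfg$null_model, tail = cfg$tail)
          write_perm_result(tests[[metric]],
                            file.path(cfg$out_dir, sprintf("metric_test_%s.json", metric)),
                            keep_null = FALSE)
        }
      }
      list(metrics = nm, tests = tests)
    })
  }
  if ("landscape" %in% cfg$stages) {
    results$landscape <- run_stage("landscape", {
      out <- list()
      geo <- geographic_distance_matrix(locales)
      write_pairwise_csv(geo, file.path(cfg$out_dir, "geo_distance.csv"))
      out$geo <- geo
      out$tests <- list()
      out$summaries <- list()
      for (nm in names(cfg$rasters)) {
        r <- load_config_raster(cfg$rasters[[nm]])
        stat <- if (r$kind == "categorical") {
          vals <- r$values[r$values != r$nodata]
          paste0("category:", sort(unique(as.integer(vals)))[1])
        } else "mean"
        if (r$kind == "continuous" && igraph::ecount(graph) >= 1) {
          es <- edge_resistance_summary(r, graph, locales)
          utils::write.csv(es, file.path(cfg$out_dir, sprintf("edges_%s.csv", nm)),
                           row.names = FALSE)
          out$summaries[[nm]] <- es
        }
        if (igraph::ecount(graph) >= 2) {
          tst <- landscape_permutation_test(graph, r, locales, statistic = stat,
                                            n_perm = cfg$n_perm,
                                            seed = derive_seed(cfg$seed, 30L),
                                            tail = cfg$tail)
          write_perm_result(tst, file.path(cfg$out_dir, sprintf("landscape_test_%s.json", nm)),
                            keep_null = FALSE)
          out$tests[[nm]] <- tst
        }
      }
      out
    })
  }
  if ("mlpe" %in% cfg$stages) {
    results$mlpe <- run_stage("mlpe", {
      geo <- geographic_distance_matrix(locales)
      layers <- list()
      for (nm in names(cfg$rasters)) {
        r <- load_config_raster(cfg$rasters[[nm]])
        if (r$kind == "continuous")
          layers[[paste0(nm, "_mean")]] <- pair_stat_matrix(r, locales, "mean")
      }
      tab <- build_pair_table(results$fst$matrix, geo, layers)
      fits <- list(geo_only = fit_mlpe(tab, "geo"))
      if (length(layers))
        fits$full <- fit_mlpe(tab)
      ranking <- compare_models_aic(fits)
      utils::write.csv(ranking, file.path(cfg$out_dir, "mlpe_ranking.csv"),
                       row.names = FALSE)
      list(table = tab, fits = fits, ranking = ranking)
    })
  }
  manifest$warnings <- notes
  files <- setdiff(list.files(cfg$out_dir, full.names = TRUE),
                   file.path(cfg$out_dir, c("manifest.json", "report.json",
                                            "report.txt")))
  manifest$file_hashes <- as.list(tools::md5sum(files))
  names(manifest$file_hashes) <- basename(files)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  write_report(results, cfg$out_dir)
  invisible(results)
}

#' Aggregate a run into a report
#'
#' One JSON aggregating diversity statistics, global/pairwise FST summary,
#' graph summary (node/edge counts, isolated locales), metric and
#' landscape permutation p-values, and the MLPE ranking; plus a short
#' human-readable text summary. Stage keys are present (null-valued) even
#' when a stage was skipped.
#'
#' @param results stage results list from [run_pipeline()].
#' @param out_dir output directory.
#' @return (invisibly) the report list.
#' @export
write_report <- function(results, out_dir) {
  if (!length(results)) stop_popland("no stage outputs to report")
  rep <- list(
    diversity = if (!is.null(results$stats)) results$stats else NULL,
    fst = if (!is.null(results$fst))
      list(global = results$fst$global,
           global_p = results$fst$panmixia$global_p,
           n_pairs = sum(upper.tri(results$fst$matrix)),
           pairs_p_le_05 = sum(results$fst$panmixia$p_value[
             upper.tri(results$fst$panmixia$p_value)] <= 0.05)) else NULL,
    popgraph = if (!is.null(results$popgraph))
      list(n_nodes = igraph::vcount(results$popgraph$graph),
           n_edges = igraph::ecount(results$popgraph$graph),
           isolated = results$popgraph$isolated,
           shrinkage = igraph::graph_attr(results$popgraph$graph, "shrinkage")) else NULL,
    netmetrics = if (!is.null(results$netmetrics))
      lapply(results$netmetrics$tests, function(t)
        list(observed = t$observed, p = t$p_value)) else NULL,
    landscape = if (!is.null(results$landscape))
      lapply(results$landscape$tests, function(t)
        list(observed = t$observed, p = t$p_value)) else NULL,
    mlpe = if (!is.null(results$mlpe)) results$mlpe$ranking else NULL
  )
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE, null = "null",
                       always_decimal = FALSE)
  lines <- c("popland run report", "==================")
  if (!is.null(rep$fst))
    lines <- c(lines, sprintf("global FST %.4f (panmixia p = %.4g)",
                              rep$fst$global, rep$fst$global_p))
  if (!is.null(rep$popgraph))
    lines <- c(lines, sprintf("popgraph: %d nodes, %d edges, %d isolated",
                              rep$popgraph$n_nodes, rep$popgraph$n_edges,
                              length(rep$popgraph$isolated)))
  if (!is.null(rep$mlpe))
    lines <- c(lines, sprintf("best MLPE model: %s (AIC %.2f)",
                              rep$mlpe$model[1], rep$mlpe$aic[1]))
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(rep)
}
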