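#' Validate and normalize a pipeline configuration
#'
#' Accepts a YAML path or a plain list. Unknown keys are rejected, missing
#' keys are filled with defaults (notably `tau = 0.05`, `split = 0.7`,
#' `seed = 1`), field types are checked with errors naming the offending
#' field, and the normalized configuration is echoed to the log.
#'
#' @param config path to a YAML file, or a named list.
#' @return A normalized `pipeline_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stopf("config must be a list or a YAML path")
  # YAML 1.1 parses a bare `n` key as boolean FALSE; map it back
  if ("FALSE" %in% names(config) && is.null(config$n)) {
    config$n <- config[["FALSE"]]
    config[["FALSE"]] <- NULL
  }
  known <- c("data", "label", "preset", "n", "seed", "tau", "split",
             "out_dir", "truth", "model", "graph", "edges", "params",
             "report", "capsnet", "log_level", "threshold")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    stopf("validation error: unknown config key(s): %s",
          paste(unknown, collapse = ", "))
  defaults <- list(label = "disease", n = 1000L, seed = 1L,
                   split = 0.7, out_dir = ".", log_level = "info",
                   threshold = 0.5)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config$tau)) {
    config$tau <- 0.05
    cc_log("validate_config: tau not set, using default 0.05")
  }
  chk_num <- function(field, lo, hi, integer = FALSE) {
    v <- config[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) ||
        v < lo || v > hi || (integer && v != round(v)))
      stopf("validation error: field %s must be %s in [%s, %s]",
            sQuote(field), if (integer) "an integer" else "a number",
            format(lo), format(hi))
  }
  chk_num("split", 1e-9, 1 - 1e-9)
  if (config$split <= 0 || config$split >= 1)
    stopf("validation error: field %s must lie in (0, 1)", sQuote("split"))
  chk_num("seed", 0, .Machine$integer.max, integer = TRUE)
  chk_num("n", 1, Inf, integer = TRUE)
  chk_num("tau", 0, Inf)
  chk_num("threshold", 0, 1)
  if (!is.character(config$label) || length(config$label) != 1L)
    stopf("validation error: field %s must be a string", sQuote("label"))
  if (!is.null(config$preset) && !config$preset %in%
        c("chain5", "hub10", "clinic37"))
    stopf("validation error: field %s must be one of chain5, hub10, clinic37",
          sQuote("preset"))
  if (is.null(config$preset) && is.null(config$data))
    stopf("validation error: either %s or %s is required",
          sQuote("preset"), sQuote("data"))
  caps_args <- config$capsnet %||% list()
  if (!is.list(caps_args))
    stopf("validation error: field %s must be a mapping", sQuote("capsnet"))
  bad <- setdiff(names(caps_args), names(formals(caps_config)))
  if (length(bad) > 0)
    stopf("validation error: unknown capsnet key(s): %s",
          paste(bad, collapse = ", "))
  if (is.null(caps_args$seed)) caps_args$seed <- config$seed
  config$capsnet <- do.call(caps_config, caps_args)
  art <- function(field, default)
    config[[field]] %||% file.path(config$out_dir, default)
  config$data_out <- art("data", "data.csv")
  config$truth <- art("truth", "truth.json")
  config$model <- art("model", "model.json")
  config$graph <- art("graph", "graph.graphml")
  config$edges <- art("edges", "graph_edges.csv")
  config$params <- art("params", "params.json")
  config$report <- art("report", "report.json")
  class(config) <- "pipeline_config"
  cc_log("validate_config: preset=%s n=%d seed=%d tau=%.3g split=%.2f",
         config$preset %||% "(file)", config$n, config$seed, config$tau,
         config$split)
  config
}

run_stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stopf("pipeline stage %s failed: %s", sQuote(name), conditionMessage(e)))
  cc_log("stage %-9s done in %.2fs", name,
         as.numeric(difftime(Sys.time(), t0, units = "secs")))
  res
}

#' Run the full simulate -> discover -> train -> evaluate pipeline
#'
#' Executes every stage in order, writing each intermediate artifact
#' (simulated CSV and ground truth, causal model JSON, causal graph
#' GraphML + edge CSV, capsule-network parameters JSON, metrics report
#' JSON). Causal discovery and classifier training use only the training
#' portion of the seeded split; the report is computed on the held-out
#' portion. Identical configuration and seed reproduce identical
#' artifacts.
#'
#' @param config a `pipeline_config`, YAML path, or plain list (passed
#'   through [validate_config()]).
#' @return Invisibly, a list with the fitted `model` (lingam), `fit`
#'   (capsnet), `report` (metrics), and artifact `paths`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  old <- options(causalcaps.log_level = config$log_level)
  on.exit(options(old))

  table <- run_stage("simulate", {
    if (!is.null(config$preset)) {
      spec <- preset_spec(config$preset)
      tab <- make_dataset(spec, config$n, config$seed)
      write_clinical_table(tab, config$data_out)
      write_truth(attr(tab, "truth"), config$truth)
      tab
    } else {
      read_clinical_table(config$data, config$label)
    }
  })

  table <- standardize(table)
  sp <- train_test_split(nrow(table$X), config$split, config$seed)
  train_tab <- subset_table(table, sp$train)

  model <- run_stage("discover", {
    m <- lingam(train_tab, tau = config$tau)
    write_causal_model(m, config$model)
    write_causal_graph(m$graph, config$graph, edge_csv = config$edges)
    m
  })

  fit <- run_stage("train", {
    f <- capsnet(model$graph, train_tab, config$capsnet)
    write_capsnet(f, config$params)
    f
  })

  report <- run_stage("evaluate", {
    test_tab <- subset_table(table, sp$test)
    scores <- predict(fit, test_tab)
    rep <- metrics_report(test_tab$y_raw, scores, config$threshold)
    write_metrics_report(rep, config$report)
    rep
  })

  invisible(list(model = model, fit = fit, report = report,
                 paths = config[c("data_out", "truth", "model", "graph",
                                  "edges", "params", "report")]))
}
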