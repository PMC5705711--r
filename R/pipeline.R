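#' Default pipeline configuration
#'
#' A complete demo configuration wiring every stage together at modest
#' problem sizes: generate a synthetic study, run stepwise model selection,
#' tabulate minimum visits, evaluate a small design grid, draw power curves
#' and the required-sites planning table. All scalar defaults mirror the
#' default [study_config()] design (143 sites in three zones, alpha = 0.1).
#'
#' @return A nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    generate = list(),
    select = list(p_candidates = c("observer_experience", "time_after_dusk"),
                  psi_candidates = c("zone", "elevation", "bromeliad_size"),
                  n_starts = 3),
    design_k = list(p = c(0.38, 0.56, 0.61), p_star = c(0.8, 0.9, 0.95)),
    design_grid = list(psi = 0.3, p = 0.56, sites = c(50, 123, 150),
                       occasions = c(2, 3, 4), n_iter = 200),
    power = list(psi1 = 0.49, p = 0.61, occasions = 20,
                 sites = c(50, 143, 300), effects = c(0.15, 0.2, 0.3),
                 alpha = 0.1, convention = "proportional"),
    sites = list(psi1 = 0.49, effect = 0.15, p = 0.61, occasions = 20,
                 alphas = c(0.05, 0.1, 0.2), powers = c(0.8, 0.9, 0.95),
                 convention = "proportional")
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  config
}

#' Run the full monitoring-design pipeline
#'
#' Executes the requested stages in dependency order — generate, fit/select,
#' design-K, design grid, power curves, required sites — and writes
#' deterministic artifacts plus a manifest (inputs, seed, package version)
#' to `outdir`. Every artifact is a pure function of (config, seed,
#' version).
#'
#' @param config A config list, or a path to a YAML/JSON file; see
#'   [default_pipeline_config()] for the shape. Stages absent from the
#'   config are skipped.
#' @param outdir Output directory.
#' @param seed Overrides `config$seed` when non-`NULL`.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         outdir = "occudesign_report", seed = NULL) {
  config <- read_pipeline_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1
  master <- as.integer(config$seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  summary_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message("[occudesign] ", msg)
    summary_lines <<- c(summary_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  study <- NULL
  if (!is.null(config$generate)) {
    study <- stage("generate", {
      cfg <- do.call(study_config, config$generate)
      st <- generate_study(cfg, seed = master)
      write_study(st, file.path(outdir, "data"))
      st
    })
    note("generated %d sites x %d occasions (naive occupancy %.3f)",
         nrow(study$history$matrix), ncol(study$history$matrix),
         naive_occupancy(study$history))
    results$study <- study
  }

  if (!is.null(config$select)) {
    if (is.null(study)) stop("pipeline stage 'select' needs the generate stage")
    sel <- stage("select", do.call(stepwise_select, c(
      list(history = study$history, site_covs = study$site_covs,
           survey_covs = study$survey_covs, seed = master),
      config$select)))
    tab <- sel$table
    utils::write.csv(format(as.data.frame(tab), digits = 8),
                     file.path(outdir, "selection_table.csv"), row.names = FALSE,
                     quote = FALSE)
    note("best model: %s (AIC %.2f, weight %.3f)",
         tab$model[1], tab$aic[1], tab$weight[1])
    results$selection <- sel
  }

  if (!is.null(config$design_k)) {
    dk <- stage("design_k", {
      g <- expand.grid(p = config$design_k$p, p_star = config$design_k$p_star)
      g$min_occasions <- min_occasions(g$p, g$p_star)
      g
    })
    utils::write.csv(dk, file.path(outdir, "design_k.csv"), row.names = FALSE,
                     quote = FALSE)
    note("minimum visits over %d (p, p*) combinations: %d to %d",
         nrow(dk), min(dk$min_occasions), max(dk$min_occasions))
    results$design_k <- dk
  }

  if (!is.null(config$design_grid)) {
    dg <- stage("design_grid", with(config$design_grid,
      evaluate_design_grid(psi, p, sites, occasions,
                           n_iter = n_iter, seed = master)))
    utils::write.csv(format(dg, digits = 6),
                     file.path(outdir, "design_grid.csv"),
                     row.names = FALSE, quote = FALSE)
    note("design grid: %d cells x %d iterations", nrow(dg), dg$n_iter[1])
    results$design_grid <- dg
  }

  if (!is.null(config$power)) {
    pw <- config$power
    curves <- stage("power", power_curves(
      pw$psi1, pw$effects, convention = pw$convention,
      p_grid = pw$p, K_grid = pw$occasions, S_grid = pw$sites,
      alpha = pw$alpha))
    utils::write.csv(format(curves, digits = 6),
                     file.path(outdir, "power_curves.csv"),
                     row.names = FALSE, quote = FALSE)
    note("power curves: %d cells; e.g. effect %.2f at S = %d: power %.3f",
         nrow(curves), curves$effect[1], curves$S[1], curves$power[1])
    results$power_curves <- curves
  }

  if (!is.null(config$sites)) {
    st <- config$sites
    sites_tab <- stage("sites", required_sites_table(
      st$psi1, st$effect, convention = st$convention, p = st$p,
      K = st$occasions, alphas = st$alphas, powers = st$powers))
    utils::write.csv(sites_tab, file.path(outdir, "required_sites.csv"),
                     row.names = FALSE, quote = FALSE)
    note("required sites for effect %.2f range %d-%d over the alpha x power grid",
         st$effect, min(sites_tab$required_sites), max(sites_tab$required_sites))
    results$required_sites <- sites_tab
  }

  manifest <- list(
    package = "occudesign",
    version = as.character(utils::packageVersion("occudesign")),
    seed = master,
    config = config[setdiff(names(config), "seed")],
    artifacts = list.files(outdir, recursive = TRUE)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(summary_lines, file.path(outdir, "summary.txt"))
  invisible(results)
}
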