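# End-to-end pipeline orchestration from a single configuration object.
# Every stochastic stage carries an explicit seed; outputs embed the config
# hash so any result file can be traced to the configuration that made it.

#' Default pipeline configuration
#'
#' @param seed master seed; per-stage seeds derive from it deterministically.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  list(
    simulate = list(enabled = TRUE, seed = seed),
    input = list(matrix = NULL, samples = NULL, metabolites = NULL),
    preprocess = list(min_frac = 0.5, impute = "half_min",
                      transform = "log", scaling = "uv"),
    univariate = list(alpha = 0.05, p_adjust = "none"),
    model = list(a_pred = 2, a_orth = 1, folds = 7, cv_seed = seed + 101L),
    panel = list(k = 8, k_min = 2, k_max = 20, n_boot = 500,
                 boot_seed = seed + 211L,
                 clinical = c("edss", "ocb", "protein")),
    sus = list(c_contrib = 0.3, c_axis = 0.1, c_diag = 0.1, a_orth = 1,
               kmeans_k = 2, kmeans_seed = seed + 307L),
    network = list(cutoff = 0.7, alpha = 0.05))
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Values absent from the file fall back to [default_config()] defaults;
#' the master seed must be given as `simulate$seed`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return validated configuration list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  user <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
          else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
          else stop("unrecognised config extension: .", ext)
  if (is.null(user$simulate$seed))
    stop("config must set simulate$seed (every stochastic stage needs a seed)")
  cfg <- default_config(as.integer(user$simulate$seed))
  for (sec in names(user))
    for (key in names(user[[sec]]))
      cfg[[sec]][[key]] <- user[[sec]][[key]]
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Every stage section must be present and every stochastic stage must have
#' an explicit seed.
#'
#' @param cfg configuration list.
#' @return the configuration, invisibly.
#' @export
validate_config <- function(cfg) {
  for (s in c("simulate", "preprocess", "univariate", "model", "panel",
              "sus", "network"))
    if (is.null(cfg[[s]])) stop("config section missing: ", s)
  seeds <- list(simulate = cfg$simulate$seed, model = cfg$model$cv_seed,
                panel = cfg$panel$boot_seed, sus = cfg$sus$kmeans_seed)
  bad <- names(seeds)[vapply(seeds, function(x)
    is.null(x) || length(x) != 1 || is.na(x), NA)]
  if (length(bad)) stop("missing seed(s) for stage(s): ", paste(bad, collapse = ", "))
  invisible(cfg)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> preprocess -> univariate -> latent models
#' -> biomarker panel -> SUS/relapse screen -> network -> pathway analysis,
#' writing every stage output plus a provenance record into `out_dir`.
#' Deterministic (and hence idempotent on its numeric outputs) for a fixed
#' configuration.
#'
#' @param config configuration list from [default_config()] or
#'   [read_config()], or a path to a config file.
#' @param out_dir output directory.
#' @return invisibly, a result bundle (list of the main stage objects).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile("metidd_run_")) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  data <- stage("simulate", {
    if (isTRUE(config$simulate$enabled)) {
      generate_cohort(reference_design(seed = config$simulate$seed))
    } else {
      read_dataset(config$input$matrix, config$input$samples,
                   config$input$metabolites)
    }
  })
  write_dataset(data, file.path(out_dir, "dataset"))

  pp <- stage("preprocess", {
    norm <- sum_normalize(data$matrix)
    filt <- occurrence_filter(norm, data$samples, config$preprocess$min_frac)
    imp <- impute_missing(filt, config$preprocess$impute)
    sc <- autoscale(imp, transform = config$preprocess$transform,
                    scaling = config$preprocess$scaling)
    list(normalized = filt, imputed = imp, scaled = sc$matrix, state = sc$state)
  })

  uni <- stage("univariate", {
    contrasts <- list(MS = "MS", NMOSD = "NMOSD", ITM = "ITM", ALL = DISEASES)
    res <- lapply(contrasts, function(cs)
      contrast_stats(pp$normalized, data$samples, "CTRL", cs,
                     alpha = config$univariate$alpha,
                     p_adjust = config$univariate$p_adjust))
    tab <- do.call(rbind, lapply(names(res), function(nm)
      cbind(contrast = nm, as.data.frame(res[[nm]]))))
    write_tsv(tab, file.path(out_dir, "univariate.tsv"))
    res
  })

  labels <- data$samples$group[match(rownames(pp$scaled), data$samples$sample_id)]
  models <- stage("model", {
    pls <- fit_plsda(pp$scaled, labels, a_pred = config$model$a_pred)
    opls <- fit_opls(pp$scaled, labels, a_pred = config$model$a_pred,
                     a_orth = config$model$a_orth)
    q2_pls <- q2_cv(unclass(pp$imputed), labels, a_pred = config$model$a_pred,
                    folds = config$model$folds, seed = config$model$cv_seed,
                    transform = config$preprocess$transform,
                    scaling = config$preprocess$scaling)
    q2_opls <- q2_cv(unclass(pp$imputed), labels, a_pred = config$model$a_pred,
                     a_orth = config$model$a_orth, folds = config$model$folds,
                     seed = config$model$cv_seed,
                     transform = config$preprocess$transform,
                     scaling = config$preprocess$scaling)
    v <- vip(pls)
    write_tsv(data.frame(sample_id = rownames(pp$scaled), group = labels,
                         t1 = opls$T[, 1],
                         t2 = if (config$model$a_pred > 1) opls$T[, 2] else
                           opls$T_o[, 1]),
              file.path(out_dir, "scores.tsv"))
    write_tsv(data.frame(metabolite = names(v), vip = unname(v)),
              file.path(out_dir, "vip.tsv"))
    list(pls = pls, opls = opls, q2_pls = q2_pls, q2_opls = q2_opls, vip = v)
  })

  panel <- stage("panel", {
    vip_order <- vip_ranking(pp$scaled, labels, a_pred = config$model$a_pred)
    sweep <- sweep_panel_size(pp$scaled, labels, vip_order,
                              k_min = config$panel$k_min,
                              k_max = min(config$panel$k_max, ncol(pp$scaled)))
    met_panel <- build_panel(pp$scaled, labels,
                             vip_order[seq_len(config$panel$k)],
                             n_boot = config$panel$n_boot,
                             seed = config$panel$boot_seed)
    joint <- joint_panel(pp$scaled, data$samples, labels,
                         clinical = config$panel$clinical,
                         n_boot = config$panel$n_boot,
                         seed = config$panel$boot_seed)
    write_tsv(sweep$table, file.path(out_dir, "panel_sweep.tsv"))
    panel_report <- list(
      config_hash = cfg_hash,
      features = met_panel$features,
      auc = lapply(met_panel$roc, function(r)
        list(auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high)),
      joint_features = joint$features,
      joint_auc = lapply(joint$roc, function(r)
        list(auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high)),
      k_best = sweep$k_best, plateau = sweep$plateau)
    jsonlite::write_json(panel_report, file.path(out_dir, "panel.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(vip_order = vip_order, sweep = sweep, metabolite = met_panel,
         joint = joint)
  })

  sus <- stage("sus", {
    hits <- merged_gradual_screen(pp$imputed, data$samples,
                                  alpha = config$univariate$alpha,
                                  c_contrib = config$sus$c_contrib,
                                  c_axis = config$sus$c_axis,
                                  c_diag = config$sus$c_diag,
                                  a_orth = config$sus$a_orth)
    coords <- attr(hits, "coordinates")
    write_tsv(coords, file.path(out_dir, "sus_coordinates.tsv"))
    km <- if (length(hits) >= max(2, config$sus$kmeans_k))
      kmeans_confirm(pp$imputed, data$samples, hits,
                     k = config$sus$kmeans_k, seed = config$sus$kmeans_seed)
    else NULL
    list(hits = as.character(hits), coords = coords, kmeans = km)
  })

  net <- stage("network", {
    nw <- build_network(data$metabolites, cutoff = config$network$cutoff)
    nw <- annotate_nodes(nw, uni$ALL, alpha = config$network$alpha)
    export_sif(nw, file.path(out_dir, "network.sif"))
    nw
  })

  pw <- stage("pathway", {
    enr <- pathway_enrich(sus$hits, data$metabolites)
    write_tsv(as.data.frame(enr), file.path(out_dir, "pathway_enrichment.tsv"))
    enr
  })

  provenance <- list(
    package = "metidd",
    version = as.character(utils::packageVersion("metidd")),
    config_hash = cfg_hash,
    config = config,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(data = data, preprocess = pp, univariate = uni,
                 models = models, panel = panel, sus = sus, network = net,
                 pathways = pw, out_dir = out_dir, config_hash = cfg_hash))
}
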