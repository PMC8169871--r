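#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()],
#' with the bundled demo settings: the pedagogical cholesterol network,
#' simulated expression with planted differential genes, and the
#' two-cohort metabolomics simulation.
#'
#' @param seed Master seed recorded in the config.
#' @param out_dir Output directory.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 7, out_dir = tempfile("sterolflux_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    stages = c("simulate", "imat", "compare", "metabolites"),
    network = list(source = "mini_cholesterol", model_path = NULL),
    expression = list(n_per_group = 20, planted_genes = c("CYP46A1", "HSD3B7"),
                      delta = -5, noise_sd = 0.3,
                      groups = c("CN", "AD")),
    imat = list(epsilon = 1, tol = 1e-6, quantile_mode = "global",
                residualize = c("sex", "age"),
                media = list()),
    compare = list(alpha = 0.05, group_order = c("AD", "CN"),
                   reactions = NULL),
    metabolites = list(rho = 0.5, sigma = 0.45, lod_quantile = 0.05,
                       missing_fraction = 0.02, max_missing_fraction = 0.30,
                       predictors = c("group", "cerad", "braak"))
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested stages in order: `simulate` (network,
#' expression, metabolomics), `imat` (per-sample activity prediction),
#' `compare` (Fisher-exact reaction comparison), and `metabolites`
#' (cohort statistics with convergence pooling and pathway-cluster FDR).
#' All outputs are TSV/JSON files in the configured output directory,
#' together with a manifest capturing the configuration, seeds and
#' package version; re-running an identical configuration reproduces
#' identical result tables.
#'
#' @param config A configuration list (see [default_config()]), or the
#'   path of a YAML file holding one. Partial configs are completed with
#'   the defaults.
#' @return Invisibly, a list of output file paths and in-memory results.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  config <- merge_config(default_config(), config)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  paths <- list()
  results <- list()
  seed <- as.integer(config$seed)

  model <- switch(config$network$source,
                  mini_cholesterol = mini_cholesterol_fixture(),
                  file = read_model(config$network$model_path),
                  stop("unknown network source: ", config$network$source,
                       call. = FALSE))
  media <- unlist(config$imat$media)
  if (length(media)) model <- apply_media_constraints(model, media)

  if ("simulate" %in% stages) {
    ecfg <- config$expression
    sim <- simulate_expression(model,
                               n_per_group = ecfg$n_per_group,
                               planted_genes = ecfg$planted_genes,
                               delta = ecfg$delta, noise_sd = ecfg$noise_sd,
                               groups = ecfg$groups, seed = seed)
    results$expr <- sim$expr
    results$expr_truth <- sim$truth
    paths$expression <- file.path(out_dir, "expression.tsv")
    paths$metadata <- file.path(out_dir, "sample_metadata.tsv")
    write_expression(sim$expr, paths$expression, paths$metadata)
    paths$model <- file.path(out_dir, "model.json")
    write_model(model, paths$model, format = "json")

    mcfg <- config$metabolites
    msim <- simulate_metabolomics(rho = mcfg$rho, sigma = mcfg$sigma,
                                  lod_quantile = mcfg$lod_quantile,
                                  missing_fraction = mcfg$missing_fraction,
                                  seed = seed + 1L)
    results$metab <- msim$table
    results$metab_truth <- msim$truth
    paths$metabolites <- file.path(out_dir, "metabolites.tsv")
    write_metabolites(msim$table, paths$metabolites)
  }

  if ("imat" %in% stages) {
    if (is.null(results$expr)) {
      stop("stage 'imat' requires the simulate stage (or preloaded expression)",
           call. = FALSE)
    }
    act <- predict_activity(model, results$expr,
                            epsilon = config$imat$epsilon,
                            tol = config$imat$tol,
                            residualize = config$imat$residualize,
                            quantile_mode = config$imat$quantile_mode)
    results$activity <- act
    paths$activity <- file.path(out_dir, "activity.tsv")
    write_activity(act, paths$activity)

    de <- differential_expression(results$expr, group = "group",
                                  covariates = c("sex", "age", "batch"),
                                  reference = config$expression$groups[1])
    results$de <- de
    paths$de <- file.path(out_dir, "de_results.tsv")
    utils::write.table(de, paths$de, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  if ("compare" %in% stages) {
    if (is.null(results$activity)) {
      stop("stage 'compare' requires the imat stage", call. = FALSE)
    }
    labels <- stats::setNames(results$expr$metadata$group,
                              results$expr$metadata$sample)
    cmp <- compare_groups(results$activity, labels,
                          reactions = config$compare$reactions,
                          alpha = config$compare$alpha,
                          group_order = config$compare$group_order,
                          model = model)
    results$comparison <- cmp
    paths$comparison <- file.path(out_dir, "reaction_comparison.tsv")
    utils::write.table(cmp, paths$comparison, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  if ("metabolites" %in% stages) {
    if (is.null(results$metab)) {
      stop("stage 'metabolites' requires the simulate stage", call. = FALSE)
    }
    mcfg <- config$metabolites
    tab <- impute_lod(qc_filter(results$metab,
                                max_missing_fraction = mcfg$max_missing_fraction))
    cohorts <- unique(as.character(tab$cohort))
    all_rows <- list()
    for (pred in mcfg$predictors) {
      res_by_cohort <- lapply(cohorts, function(ch) {
        fit_metabolite_models(
          metabolite_table(tab[tab$cohort == ch, , drop = FALSE]),
          predictor = pred)
      })
      pooled <- convergence_pool(res_by_cohort[[1]], res_by_cohort[[2]],
                                 tab, predictor = pred)
      prim <- pooled$pooled
      if (nrow(prim)) {
        prim$q <- NA_real_
        prim$cluster <- default_cluster_map()$cluster[
          match(prim$metabolite, default_cluster_map()$metabolite)]
        prim$significant <- prim$p < 0.05
        prim$only_one_cohort <- FALSE
      }
      sec <- cluster_fdr(pooled$cohort_specific, default_cluster_map())
      all_rows[[pred]] <- rbind(
        prim[, intersect(names(prim), c("metabolite", "cluster", "region",
                                        "predictor", "beta", "se", "p", "q",
                                        "scope", "significant")), drop = FALSE],
        sec[, intersect(names(sec), c("metabolite", "cluster", "region",
                                      "predictor", "beta", "se", "p", "q",
                                      "scope", "significant")), drop = FALSE])
    }
    mres <- do.call(rbind, all_rows)
    rownames(mres) <- NULL
    results$metabolite_results <- mres
    paths$metabolite_results <- file.path(out_dir, "metabolite_results.tsv")
    utils::write.table(mres, paths$metabolite_results, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  manifest <- list(package = "sterolflux",
                   version = as.character(utils::packageVersion("sterolflux")),
                   config = config)
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(paths = paths, results = results, config = config))
}
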