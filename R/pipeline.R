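#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()].  With
#' `paths = NULL` the pipeline runs on synthetic data generated from
#' [sim_config()]; otherwise `paths` must name `records`, `traits` and
#' `trees` files (plus optionally `hominin_tree` and `hominin_traits` for
#' the fossil stage).
#'
#' @param out_dir Output directory.
#' @param responses Responses to analyze.
#' @param include_humans `"both"`, `"with"` or `"without"` — whether the
#'   hypothesis fits are repeated excluding the focal species.
#' @param focal_species Species used for exclusion runs and the outlier
#'   test.
#' @param n_trees Number of trees used in the battery stage.
#' @param chains,iter,warmup Sampler settings.
#' @param seed Master seed; all stage seeds derive from it.
#' @param battery Path to the hypothesis battery YAML (default: shipped
#'   battery).
#' @param paths Optional named list of input files.
#' @param sim Optional [sim_config()] overriding the synthetic defaults.
#' @return Configuration list.
#' @export
pipeline_config <- function(out_dir = tempfile("phylohand_run_"),
                            responses = "MHI",
                            include_humans = "both",
                            focal_species = NULL,
                            n_trees = 5, chains = 2, iter = 2000,
                            warmup = 500, seed = 1,
                            battery = NULL, paths = NULL, sim = NULL) {
  list(out_dir = out_dir, responses = responses,
       include_humans = include_humans, focal_species = focal_species,
       n_trees = n_trees, chains = chains, iter = iter, warmup = warmup,
       seed = seed, battery = battery, paths = paths, sim = sim)
}

.stage <- function(name, expr) {
  message("[", name, "] ", appendLF = FALSE)
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(format(round(as.numeric(difftime(Sys.time(), t0, units = "secs")),
                       1)), "s")
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage over one or two responses: covariate
#' imputation, the hypothesis battery across the tree set with averaged
#' summaries and PSIS-LOO comparison, iterative model reduction of the
#' union of credible predictors, the phylogenetic outlier test on the
#' focal species, and fossil prediction when a grafted tree and fossil
#' covariates are supplied.  All outputs are written as CSV/JSON under
#' `config$out_dir` together with a manifest sufficient to rerun the
#' analysis.
#'
#' @param config List from [pipeline_config()], or a path to a YAML file
#'   with the same fields.
#' @return Invisibly, a list of in-memory results per response; side
#'   effect: files under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)

  if (is.null(config$paths)) {
    cfg <- config$sim
    if (is.null(cfg)) cfg <- sim_config(seed = seed,
                                        n_trees = config$n_trees)
    trees <- .stage("simulate", simulate_trees(cfg))
    simdat <- simulate_dataset(cfg, trees[[1]])
    records <- simdat$records
    traits <- make_missing(simdat$traits, cfg)$traits
    truth <- simdat$truth
  } else {
    dat <- .stage("load", load_dataset(config$paths$records,
                                       config$paths$traits))
    records <- dat$records
    traits <- dat$traits
    trees <- .stage("trees", read_trees(config$paths$trees))
    truth <- NULL
  }
  trees <- trees[seq_len(min(length(trees), config$n_trees))]
  mcc <- mcc_tree(trees)

  traits <- .stage("impute", {
    imp <- impute_traits(traits, mcc)
    write.csv(imp$report, file.path(config$out_dir, "imputation_report.csv"),
              row.names = FALSE)
    imp$traits
  })

  battery <- load_battery(config$battery %||%
                            system.file("extdata", "battery.yaml",
                                        package = "phylohand"))
  battery <- Filter(function(h) all(h$covariates %in% names(traits)), battery)

  excl_sets <- switch(config$include_humans,
                      with = list(NULL),
                      without = list(config$focal_species),
                      both = list(NULL, config$focal_species))
  excl_sets <- unique(excl_sets)

  results <- list()
  for (resp in config$responses) {
    resp_res <- list()
    for (excl in excl_sets) {
      tag <- paste0(resp, if (is.null(excl)) "_all" else "_excl")
      bat <- .stage(paste0("battery:", tag),
                    run_battery(records, traits, trees, battery, resp,
                                exclude_species = excl, seed = seed,
                                chains = config$chains, iter = config$iter,
                                warmup = config$warmup))
      if (!is.null(bat$comparison))
        write.csv(as.data.frame(bat$comparison),
                  file.path(config$out_dir,
                            paste0("battery_comparison_", tag, ".csv")),
                  row.names = FALSE)

      cred_covs <- unique(unlist(lapply(names(bat$summaries), function(nm) {
        s <- bat$summaries[[nm]]
        grp <- battery[[nm]]$covariates
        fx <- s$parameter[s$credible &
                            !s$parameter %in% c("(Intercept)", "sigma_p",
                                                "sigma_s", "tau", "h2",
                                                "R2_fixed", "R2_conditional")]
        grp[vapply(grp, function(g) any(startsWith(fx, g)), TRUE)]
      })))
      red <- .stage(paste0("reduce:", tag),
                    reduce_model(records, traits, resp,
                                 covariates = cred_covs, C = phylo_corr(mcc),
                                 exclude_species = excl, seed = seed + 1L,
                                 chains = config$chains, iter = config$iter,
                                 warmup = config$warmup))
      rs <- summary(red$fit)
      write.csv(as.data.frame(rs),
                file.path(config$out_dir,
                          paste0("reduced_coefficients_", tag, ".csv")),
                row.names = FALSE)
      write.csv(species_estimates(red$fit),
                file.path(config$out_dir,
                          paste0("species_estimates_", tag, ".csv")),
                row.names = FALSE)
      resp_res[[tag]] <- list(battery = bat, reduced = red)

      # outlier test: refit without the focal species on the reduced set
      focal <- config$focal_species
      if (!is.null(focal) && is.null(excl) &&
          normalize_labels(focal) %in% normalize_labels(records$species)) {
        ot <- .stage(paste0("outlier:", tag), {
          fr_wo <- build_model_frame(records, traits, resp,
                                     red$covariates,
                                     exclude_species = focal)
          fit_wo <- fit_phylo_meta(fr_wo, phylo_corr(mcc),
                                   seed = seed + 2L,
                                   chains = config$chains,
                                   iter = config$iter,
                                   warmup = config$warmup)
          fs <- normalize_labels(focal)
          obs_rec <- records[normalize_labels(records$species) == fs &
                               records$response == resp, ]
          obs_val <- sum(obs_rec$effect / obs_rec$se^2) /
            sum(1 / obs_rec$se^2)
          phylo_outlier_test(fit_wo, mcc, focal,
                             traits[normalize_labels(traits$species) == fs,
                                    setdiff(names(traits), "species")],
                             se_target = pooled_se(records, focal, resp),
                             observed = obs_val)
        })
        write.csv(data.frame(taxon = ot$taxon, mean = ot$mean,
                             lower = ot$lower, upper = ot$upper,
                             observed = ot$observed,
                             percentile = ot$percentile_of_observed,
                             outlier = ot$outlier),
                  file.path(config$out_dir, paste0("outlier_", tag, ".csv")),
                  row.names = FALSE)
        resp_res[[tag]]$outlier <- ot
      }

      # fossil prediction stage (needs a grafted tree + fossil covariates)
      if (!is.null(config$paths$hominin_tree) &&
          !is.null(config$paths$hominin_traits) && is.null(excl)) {
        fp <- .stage(paste0("fossils:", tag), {
          homin <- read_trees(config$paths$hominin_tree)[[1]]
          ftr <- read.csv(config$paths$hominin_traits,
                          stringsAsFactors = FALSE)
          shared <- intersect(normalize_labels(homin$tip.label),
                              normalize_labels(mcc$tip.label))
          grafted <- graft_clade(mcc, homin, shared)
          ftr <- ftr[!normalize_labels(ftr$species) %in%
                       red$fit$frame$species_levels, ]
          predict_fossils(red$fit, grafted, ftr,
                          se_assumption = pooled_se(records,
                                                    config$focal_species,
                                                    resp))
        })
        write.csv(attr(fp, "table"),
                  file.path(config$out_dir,
                            paste0("fossil_predictions_", tag, ".csv")),
                  row.names = FALSE)
        resp_res[[tag]]$fossils <- fp
      }
    }
    results[[resp]] <- resp_res
  }

  manifest <- list(config = config[setdiff(names(config), "sim")],
                   seed = seed,
                   n_records = nrow(records),
                   n_species = length(unique(records$species)),
                   n_trees = length(trees),
                   synthetic = is.null(config$paths),
                   package_version = as.character(
                     utils::packageVersion("phylohand")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$truth <- truth
  invisible(results)
}
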