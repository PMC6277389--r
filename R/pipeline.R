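#' Full-run configuration
#'
#' Bundles the scenario (generator) configuration with every analysis-stage
#' parameter. Defaults follow the screening protocol throughout: 0.2 Hz
#' high-pass, mean + 2 SD transient threshold, 15.21 um^2 ROIs, n = 5
#' replicates, 20 principal components, 1000 consensus resamples with the
#' < 1% AUC-CDF rule, alpha = 0.05 for the hypergeometric tests, and a
#' 100-tree random forest.
#'
#' @param scenario a [scenario_config()].
#' @param k_range candidate cluster numbers.
#' @param n_iterations consensus resampling iterations.
#' @param subsample_frac consensus subsample fraction.
#' @param n_components Pheno-Print dimensionality.
#' @param rel_increase_threshold AUC-CDF rule threshold.
#' @param alpha hypergeometric significance level.
#' @param n_trees random-forest ensemble size.
#' @param seed master seed; per-stage seeds are derived from it by stage name.
#' @param stages stages to execute, in order.
#' @return A list of class `run_config`.
#' @export
run_config <- function(scenario = scenario_config(),
                       k_range = 2:15,
                       n_iterations = 1000L,
                       subsample_frac = 0.8,
                       n_components = 20L,
                       rel_increase_threshold = 0.01,
                       alpha = 0.05,
                       n_trees = 100L,
                       seed = 1L,
                       stages = c("simulate", "bam", "tscore", "phenoprint",
                                  "cluster", "associate", "predict",
                                  "report")) {
  cfg <- list(scenario = scenario, k_range = as.integer(k_range),
              n_iterations = as.integer(n_iterations),
              subsample_frac = subsample_frac,
              n_components = as.integer(n_components),
              rel_increase_threshold = rel_increase_threshold,
              alpha = alpha, n_trees = as.integer(n_trees),
              seed = as.integer(seed), stages = stages)
  known <- c("simulate", "bam", "tscore", "phenoprint", "cluster",
             "associate", "predict", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `load_run_config()` returns a `run_config`; `save_run_config()`
#'   returns the path invisibly.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sc <- do.call(scenario_config, raw$scenario)
  raw$scenario <- sc
  do.call(run_config, raw)
}

#' @rdname load_run_config
#' @param config a [run_config()].
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  out <- unclass(config)
  out$scenario <- unclass(config$scenario)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full screening pipeline on a synthetic scenario
#'
#' Executes the enabled stages in order: simulate the BAM library, assemble
#' replicate BAM stacks, compute T-score BAMs, fit the training PC model and
#' project Pheno-Prints, consensus-cluster the training set and select k,
#' test cluster/ATC associations, train the random forest and rank test
#' compounds, and (when an output directory is given) render the report
#' bundle. Any stage failure aborts with the failing stage named; outputs of
#' completed stages are retained in the returned object with the manifest
#' marking incompleteness.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory; when given, stage outputs are
#'   written as CSV/JSON/PNG and hashed into the manifest.
#' @return A list of class `bam_run`: stage outputs (`library`, `tscores`,
#'   `pc_model`, `phenoprints`, `consensus`, `k_selected`, `assignment`,
#'   `coherence`, `association`, `forest`, `test_assignments`,
#'   `predictions`) plus `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  run <- list(config = config)
  manifest <- list(seed = config$seed, started = format(Sys.time(), tz = "UTC"),
                   stages = list(), complete = FALSE)
  record <- function(stage, params, files = character(0)) {
    manifest$stages[[stage]] <<- list(
      params = params,
      seed = derive_seed(config$seed, stage),
      outputs = if (length(files)) {
        stats::setNames(as.vector(tools::md5sum(files)), basename(files))
      } else {
        NULL
      },
      timestamp = format(Sys.time(), tz = "UTC"))
  }
  out_file <- function(name) if (is.null(out_dir)) NULL else file.path(out_dir, name)
  enabled <- function(stage) stage %in% config$stages

  run_stage <- function(stage, fn) {
    if (!enabled(stage)) return(invisible(NULL))
    tryCatch(fn(), error = function(e) {
      manifest$complete <<- FALSE
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sc <- config$scenario
  sc$seed <- derive_seed(config$seed, "simulate")

  run_stage("simulate", function() {
    run$library <<- simulate_bam_library(sc)
    files <- character(0)
    if (!is.null(out_dir)) {
      f <- out_file("drug_table.csv")
      utils::write.csv(run$library$drug_table, f, row.names = FALSE)
      g <- out_file("ground_truth.json")
      gt <- run$library$ground_truth
      jsonlite::write_json(list(clusters = as.list(gt$clusters),
                                linked_atc = as.list(gt$linked_atc)),
                           g, auto_unbox = TRUE)
      files <- c(f, g)
    }
    record("simulate", unclass(sc), files)
  })

  run_stage("bam", function() {
    if (is.null(run$library)) {
      stop("no BAM library available (simulate stage disabled and no inputs)")
    }
    # BAM stacks come straight from the generator here; with raw movies this
    # stage would run movie_to_bam() per replicate.
    n_bams <- sum(lengths(run$library$bams))
    record("bam", list(n_bams = n_bams))
  })

  run_stage("tscore", function() {
    run$tscores <<- tscore_library(run$library)
    record("tscore", list(n = sc$n_replicates))
  })

  run_stage("phenoprint", function() {
    train_ids <- run$library$drug_table$compound_id[
      run$library$drug_table$set == "training"]
    test_ids <- run$library$drug_table$compound_id[
      run$library$drug_table$set == "test"]
    run$pc_model <<- fit_pca(run$tscores[train_ids],
                             n_components = config$n_components)
    run$phenoprints <<- project_library(run$tscores[train_ids], run$pc_model)
    run$test_phenoprints <<- project_library(run$tscores[test_ids],
                                             run$pc_model)
    files <- character(0)
    if (!is.null(out_dir)) {
      f <- out_file("phenoprints.csv")
      pp <- rbind(run$phenoprints, run$test_phenoprints)
      utils::write.csv(data.frame(compound_id = rownames(pp), pp,
                                  row.names = NULL), f, row.names = FALSE)
      files <- f
    }
    record("phenoprint",
           list(n_components = config$n_components,
                evr_top = sum(run$pc_model$evr)), files)
  })

  run_stage("cluster", function() {
    run$consensus <<- consensus_cluster(
      run$phenoprints, k_range = config$k_range,
      n_iterations = config$n_iterations,
      subsample_frac = config$subsample_frac,
      seed = derive_seed(config$seed, "cluster"))
    run$k_selected <<- select_k(run$consensus, config$rel_increase_threshold)
    train_ids <- rownames(run$phenoprints)
    run$assignment <<- cut_clusters(run$consensus, run$k_selected,
                                    tscore_bams = run$tscores[train_ids])
    run$coherence <<- coherence_tests(run$consensus, run$assignment,
                                      phenoprints = run$phenoprints)
    files <- character(0)
    if (!is.null(out_dir)) {
      f <- out_file("cluster_labels.csv")
      utils::write.csv(data.frame(compound_id = names(run$assignment$labels),
                                  cluster = as.integer(run$assignment$labels),
                                  row.names = NULL), f, row.names = FALSE)
      g <- out_file("coherence.csv")
      utils::write.csv(run$coherence, g, row.names = FALSE)
      files <- c(f, g)
    }
    record("cluster", list(k_range = config$k_range,
                           n_iterations = config$n_iterations,
                           subsample_frac = config$subsample_frac,
                           k_selected = run$k_selected), files)
  })

  run_stage("associate", function() {
    run$association <<- hypergeom_overrep(run$assignment,
                                          run$library$drug_table,
                                          alpha = config$alpha,
                                          phenoprints = run$phenoprints)
    files <- character(0)
    if (!is.null(out_dir)) {
      f <- out_file("association.csv")
      utils::write.csv(run$association$table, f, row.names = FALSE)
      files <- f
    }
    record("associate",
           list(alpha = config$alpha,
                n_significant = sum(run$association$table$significant)), files)
  })

  run_stage("predict", function() {
    run$forest <<- train_forest(run$phenoprints, run$assignment,
                                n_trees = config$n_trees,
                                seed = derive_seed(config$seed, "predict"))
    run$test_assignments <<- classify_compounds(run$forest,
                                                run$test_phenoprints)
    run$predictions <<- rank_candidates(run$test_assignments,
                                        run$test_phenoprints,
                                        run$association)
    files <- character(0)
    if (!is.null(out_dir)) {
      f <- out_file("predictions.csv")
      utils::write.csv(run$predictions, f, row.names = FALSE)
      files <- f
    }
    record("predict", list(n_trees = config$n_trees,
                           oob_accuracy = run$forest$oob_accuracy), files)
  })

  run_stage("report", function() {
    files <- character(0)
    if (!is.null(out_dir)) {
      files <- render_report(run, out_dir)
    }
    record("report", list(rendered = !is.null(out_dir)), files)
  })

  manifest$complete <- TRUE
  manifest$finished <- format(Sys.time(), tz = "UTC")
  run$manifest <- manifest
  if (!is.null(out_dir)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  class(run) <- "bam_run"
  run
}

#' @export
print.bam_run <- function(x, ...) {
  cat("bamscope pipeline run\n")
  cat("  stages:", paste(names(x$manifest$stages), collapse = ", "), "\n")
  if (!is.null(x$k_selected)) cat("  selected k:", x$k_selected, "\n")
  if (!is.null(x$association)) {
    cat("  significant cluster/ATC pairs:",
        sum(x$association$table$significant), "\n")
  }
  if (!is.null(x$predictions)) {
    cat("  ranked test compounds:", sum(!is.na(x$predictions$r)), "of",
        nrow(x$predictions), "\n")
  }
  invisible(x)
}
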