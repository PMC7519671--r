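# Reproducible end-to-end runs: a single validated config drives optional
# target scoring, data generation or loading, phenotyping, ensemble fitting
# and recommendation; every artifact is written with a content hash into a
# run manifest. All randomness flows from config$seed via named substreams.

pipeline_defaults <- function() list(
  seed = 1,
  out_dir = NULL,
  synthetic = TRUE,
  n_strains = 250,
  n_reps = 3,
  cv = 0.043,
  defect_rates = list(correct = 0.82, cured = 0.92, duplicate = 0.037),
  reads_path = NULL, map_path = NULL, metadata_path = NULL,
  model_path = NULL,
  fractions = default_fraction_grid(),
  pseudo_flux = 1e-4,
  window = c(0.075, 0.150),
  estimator = "endpoint",
  outlier_filter = "percentile",
  outlier_fraction = 0.01,
  mad_cutoff = 3,
  folds = 10,
  run_cv = FALSE,
  mcmc = list(chains = 4, draws = 5000, burn = 1000),
  n_recommend = 30,
  mode = "exploit")

#' Build and validate a pipeline run configuration
#'
#' Unknown keys are rejected (a typo must fail before any stage runs), all
#' seeds are explicit, and a provenance block (config hash, package
#' version) is attached.
#'
#' @param ... named overrides of the defaults: `seed`, `out_dir`,
#'   `synthetic`, `n_strains`, `n_reps`, `cv`, `defect_rates`,
#'   `reads_path`/`map_path`/`metadata_path` (for non-synthetic runs),
#'   `model_path` (enables the target-scoring stage), `fractions`,
#'   `pseudo_flux`, `window`, `estimator` ("endpoint"/"slope"),
#'   `outlier_filter` ("percentile"/"robust"/"none"), `outlier_fraction`,
#'   `mad_cutoff`, `folds`, `run_cv`, `mcmc` (chains/draws/burn),
#'   `n_recommend`, `mode` ("exploit"/"explore").
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(names(over)) && length(over)) stop("config values must be named")
  cfg[names(over)] <- over
  stopifnot(cfg$estimator %in% c("endpoint", "slope"),
            cfg$outlier_filter %in% c("percentile", "robust", "none"),
            cfg$mode %in% c("exploit", "explore"),
            is.numeric(cfg$seed), length(cfg$window) == 2)
  if (!cfg$synthetic &&
      (is.null(cfg$reads_path) || is.null(cfg$map_path) ||
       is.null(cfg$metadata_path)))
    stop("non-synthetic runs need reads_path, map_path and metadata_path")
  cfg$provenance <- list(
    package_version = as.character(utils::packageVersion("trpdesign")),
    config_hash = config_hash(cfg))
  class(cfg) <- "run_config"
  cfg
}

config_hash <- function(cfg) {
  cfg$provenance <- NULL
  cfg$out_dir <- NULL       # the output location is not part of the science
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  md5_file(tmp)
}

#' Execute the full design-build-test-learn pipeline
#'
#' Stages: optional gene-target scoring (when `model_path` is set), data
#' generation (synthetic) or loading, phenotyping with QC and outlier
#' filtering, ensemble fitting, and design recommendation. Each written
#' artifact gets an md5 content hash in the returned manifest; rerunning
#' an identical config reproduces the hashes of all deterministic stages.
#'
#' @param config a [run_config].
#' @return the run manifest (invisibly if `out_dir` is set): per-stage
#'   outputs, artifact hashes, timings and warnings, plus the in-memory
#'   stage results in `$results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), stages = list())
  results <- list()
  emit <- function(df, name) {
    if (is.null(out_dir)) return(NULL)
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    list(path = path, md5 = md5_file(path))
  }
  stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- c(list(status = "ok",
                                       seconds = round(proc.time()[["elapsed"]] - t0, 2)),
                                  res$meta)
    results[[name]] <<- res$value
    res$value
  }

  if (!is.null(config$model_path)) {
    stage("score_targets", function() {
      model <- read_model_json(config$model_path)
      sc <- score_targets(model, config$fractions, config$pseudo_flux)
      art <- emit(sc$gene_scores, "gene_scores.csv")
      list(value = sc, meta = list(artifact = art,
                                   n_genes = nrow(sc$gene_scores)))
    })
  }

  data <- stage("data", function() {
    if (config$synthetic) {
      study <- generate_mock_study(config$n_strains, config$n_reps,
                                   seed = substream_seed(config$seed, "study"),
                                   cv = config$cv,
                                   defect_rates = config$defect_rates)
      arts <- list(emit(study$reads, "reads.csv"), emit(study$map, "map.csv"),
                   emit(study$metadata, "metadata.csv"),
                   emit(study$strains, "genotypes.csv"))
      list(value = study, meta = list(artifacts = arts, synthetic = TRUE))
    } else {
      study <- list(reads = utils::read.csv(config$reads_path),
                    map = utils::read.csv(config$map_path),
                    metadata = utils::read.csv(config$metadata_path),
                    catalog = default_catalog())
      list(value = study, meta = list(synthetic = FALSE))
    }
  })

  phen <- stage("phenotype", function() {
    ph <- phenotype_plates(data$reads, data$map, data$metadata,
                           window = config$window,
                           estimator = config$estimator)
    reps <- attr(ph, "replicates")
    keep <- ph$strain[ph$qc_pass & ph$n >= 2]
    reps <- reps[reps$strain %in% keep & is.finite(reps$rate), ]
    removed <- character(0)
    if (config$outlier_filter == "percentile" && length(unique(reps$strain)) >= 2) {
      fl <- outlier_filter_percentile(reps, config$outlier_fraction)
      reps <- fl$kept; removed <- fl$removed_strains
    } else if (config$outlier_filter == "robust" && nrow(reps)) {
      fl <- outlier_filter_robust(reps, config$mad_cutoff)
      reps <- fl$kept; removed <- fl$removed_strains
    }
    ph2 <- ph[ph$strain %in% unique(reps$strain), , drop = FALSE]
    art <- emit(ph2, "phenotypes.csv")
    list(value = list(phenotypes = ph2, replicates = reps,
                      outliers_removed = removed),
         meta = list(artifact = art, n_strains = nrow(ph2),
                     n_outlier_strains = length(removed),
                     estimator = config$estimator))
  })

  fit <- stage("fit", function() {
    ph <- phen$phenotypes
    geno <- data$strains
    idx <- match(ph$strain, geno$strain)
    ok <- !is.na(idx)
    mc <- do.call(mcmc_control, config$mcmc)
    fit <- trp_ensemble(geno$key[idx[ok]], ph$rate_mean[ok],
                        catalog = data$catalog, mcmc = mc,
                        seed = substream_seed(config$seed, "fit"))
    meta <- list(n_train = sum(ok),
                 weights = stats::setNames(round(coef(fit), 4),
                                           fit$learner_names),
                 accept = round(fit$accept, 3))
    if (isTRUE(config$run_cv)) {
      cv <- cross_validate(geno$key[idx[ok]], ph$rate_mean[ok],
                           catalog = data$catalog,
                           k = min(config$folds, sum(ok)), mcmc = mc,
                           seed = substream_seed(config$seed, "cv"))
      meta$test_mae <- cv$mae
    }
    list(value = fit, meta = meta)
  })

  stage("recommend", function() {
    rec <- recommend_designs(fit, n = config$n_recommend, mode = config$mode)
    art <- emit(as.data.frame(rec), "recommendations.csv")
    list(value = rec, meta = list(artifact = art, mode = config$mode))
  })

  manifest$results <- results
  if (!is.null(out_dir)) {
    mpath <- file.path(out_dir, "manifest.json")
    m <- manifest[c("config", "stages")]
    jsonlite::write_json(m, mpath, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE, pretty = TRUE)
    manifest$manifest_path <- mpath
    return(invisible(manifest))
  }
  manifest
}
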