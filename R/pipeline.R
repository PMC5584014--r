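#' Pipeline configuration
#'
#' Collects every knob of the end-to-end experiment: data source (synthetic
#' generation sizes or CSV paths), preprocessing chain, partitioning method
#' and fraction, per-method variable-selection parameters, the property list,
#' and the master seed from which all stage-level seeds are derived.
#'
#' @param properties character vector of reference properties to calibrate.
#' @param preprocess a [preprocess_config()].
#' @param partition_method `"spxy"`, `"kennard_stone"` or `"random"`.
#' @param validation_fraction fraction of samples held out for validation.
#' @param max_factors PLS factor cap (the parsimony rule of
#'   [select_factors()] picks the working count below it).
#' @param n_sweet,n_biomass synthetic population sizes, used when no data is
#'   passed to the run functions.
#' @param noise a [noise_model()] for synthetic generation.
#' @param cars_runs CARS Monte Carlo run count.
#' @param mc_uve_models MC-UVE submodel count.
#' @param sr_alpha selectivity-ratio F-test level.
#' @param vip_threshold VIP cutoff.
#' @param max_pcs component cap for the qualitative rate curve.
#' @param seed master seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(properties = REFERENCE_PROPERTIES,
                            preprocess = preprocess_config(),
                            partition_method = "spxy",
                            validation_fraction = 0.25,
                            max_factors = 15,
                            n_sweet = 70, n_biomass = 77,
                            noise = noise_model(),
                            cars_runs = 50,
                            mc_uve_models = 500,
                            sr_alpha = 0.05,
                            vip_threshold = 1,
                            max_pcs = 40,
                            seed = 1) {
  bad <- setdiff(properties, REFERENCE_PROPERTIES)
  if (length(bad)) stop("unknown properties: ", paste(bad, collapse = ", "))
  structure(list(properties = properties, preprocess = preprocess,
                 partition_method = partition_method,
                 validation_fraction = validation_fraction,
                 max_factors = max_factors,
                 n_sweet = n_sweet, n_biomass = n_biomass, noise = noise,
                 cars_runs = cars_runs, mc_uve_models = mc_uve_models,
                 sr_alpha = sr_alpha, vip_threshold = vip_threshold,
                 max_pcs = max_pcs, seed = seed),
            class = "pipeline_config")
}

# independent, reproducible substream seed per (stage, index); keeps every
# derived seed a valid 32-bit integer
derive_seed <- function(seed, stage, index = 0L) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h * 131 + index) %% 2147483647)
}

#' Generate the default synthetic dataset
#'
#' Convenience wrapper: draws the two-class composition table and its spectra
#' under one master seed.
#'
#' @param config a [pipeline_config()].
#' @param noise optional [noise_model()] overriding the config's.
#' @return List with `spectra` ([spectra_set()]) and `reference`
#'   ([reference_table()]).
#' @export
synthetic_dataset <- function(config = pipeline_config(), noise = NULL) {
  if (is.null(noise)) noise <- config$noise
  reference <- generate_composition(config$n_sweet, config$n_biomass,
                                    seed = derive_seed(config$seed, "composition"))
  spectra <- generate_spectra(reference, noise = noise,
                              seed = derive_seed(config$seed, "spectra"))
  list(spectra = spectra, reference = reference)
}

# fit + evaluate one (property, variable subset) model; shared by the
# full-spectrum control and the five dual-optimized strategies
calibrate_subset <- function(strategy, property, Xcal, ycal, Xval, yval,
                             vars, max_factors, y_range) {
  Xc <- Xcal[, vars, drop = FALSE]
  Xv <- Xval[, vars, drop = FALSE]
  cv <- loo_cv(Xc, ycal, max_factors)
  k <- select_factors(cv, max = max_factors)
  fit <- fit_pls(Xc, ycal, k)
  metrics <- evaluate_model(fit, Xc, ycal, Xv, yval, cv,
                            n_factors = fit$n_factors, y_range = y_range)
  list(strategy = strategy, property = property,
       n_factors = fit$n_factors, n_variables = length(vars),
       metrics = unclass(metrics))
}

pipeline_log <- function(verbose, stage, property, detail) {
  if (verbose)
    message(sprintf("[%s] %s: %s", stage, property, detail))
}

#' Run the full quantitative calibration comparison
#'
#' The complete dual-optimization experiment. For every property:
#' SPXY partitioning of the preprocessed spectra, removal of calibration
#' outliers, a full-spectrum PLS control (the partial-optimized model), the
#' five variable-selection algorithms on the calibration subset, a refitted
#' PLS per selected subset (the dual-optimized models), and the consensus
#' categorization of the five selections. With the default six properties
#' this produces 36 model records (6 controls + 30 dual-optimized).
#'
#' One SPXY partition and one outlier-cleaned calibration set are shared by
#' all six strategies of a property, so strategy comparisons are paired.
#'
#' @param spectra a [spectra_set()]; `NULL` generates synthetic data from the
#'   config.
#' @param reference a [reference_table()] aligned by id with `spectra`.
#' @param config a [pipeline_config()].
#' @param verbose emit stage-level progress messages.
#' @return A report list with `records` (one per strategy x property),
#'   `consensus` (per-property summaries), `partitions`, `outliers` and
#'   `config_summary`.
#' @export
run_quantitative <- function(spectra = NULL, reference = NULL,
                             config = pipeline_config(), verbose = FALSE) {
  if (is.null(spectra) != is.null(reference))
    stop("supply both spectra and reference, or neither")
  if (is.null(spectra)) {
    ds <- synthetic_dataset(config)
    spectra <- ds$spectra
    reference <- ds$reference
  }
  aligned <- align_samples(spectra, reference)
  reference <- aligned$reference
  sp <- preprocess(spectra, config$preprocess)
  X <- sp$absorbance
  records <- list()
  consensus <- list()
  partitions <- list()
  outliers <- list()
  for (pi in seq_along(config$properties)) {
    property <- config$properties[pi]
    y <- reference[[property]]
    part <- make_partition(sp, reference, property,
                           method = config$partition_method,
                           validation_fraction = config$validation_fraction,
                           seed = derive_seed(config$seed, "partition", pi))
    Xcal0 <- X[part$calibration, , drop = FALSE]
    ycal0 <- y[part$calibration]
    Xval <- X[part$validation, , drop = FALSE]
    yval <- y[part$validation]
    y_range <- range(y)
    # factor count for the outlier screen, then the shared clean set
    cv0 <- loo_cv(Xcal0, ycal0, config$max_factors)
    k0 <- select_factors(cv0, max = config$max_factors)
    out <- remove_outliers(Xcal0, ycal0, k0)
    Xcal <- Xcal0[out$retained, , drop = FALSE]
    ycal <- ycal0[out$retained]
    pipeline_log(verbose, "partition", property,
                 sprintf("%d cal (%d after outlier removal) / %d val",
                         length(ycal0), length(ycal), length(yval)))
    recs <- list(calibrate_subset("full_spectrum", property, Xcal, ycal,
                                  Xval, yval, seq_len(ncol(Xcal)),
                                  config$max_factors, y_range))
    k_full <- recs[[1]]$n_factors
    pipeline_log(verbose, "control", property,
                 sprintf("k=%d R2V=%.3f", k_full, recs[[1]]$metrics$r2v))
    sels <- list(
      CARS = cars(Xcal, ycal, n_runs = config$cars_runs,
                  max_factors = config$max_factors,
                  seed = derive_seed(config$seed, "cars", pi)),
      SR = selectivity_ratio(Xcal, ycal, k_full, alpha = config$sr_alpha),
      VIP = vip(Xcal, ycal, k_full, threshold = config$vip_threshold),
      UVE = uve(Xcal, ycal, k_full,
                seed = derive_seed(config$seed, "uve", pi)),
      MC_UVE = mc_uve(Xcal, ycal, k_full, n_models = config$mc_uve_models,
                      seed = derive_seed(config$seed, "mcuve", pi)))
    for (m in names(sels)) {
      vars <- sels[[m]]$selected
      if (length(vars) < 2) {
        # degenerate selection: fall back to the two top-scoring variables so
        # the comparison record still exists, flagged by n_variables
        ord <- order(abs(sels[[m]]$scores), decreasing = TRUE)
        vars <- sort(ord[seq_len(2)])
      }
      recs[[m]] <- calibrate_subset(m, property, Xcal, ycal, Xval, yval,
                                    vars, config$max_factors, y_range)
      pipeline_log(verbose, "dual", property,
                   sprintf("%s: %d vars, k=%d, R2V=%.3f", m,
                           recs[[m]]$n_variables, recs[[m]]$n_factors,
                           recs[[m]]$metrics$r2v))
    }
    records <- c(records, unname(recs))
    cm <- categorize_consensus(unname(sels), ncol(Xcal))
    consensus[[property]] <- cm$summary
    partitions[[property]] <- list(
      calibration = spectra$sample_ids[part$calibration],
      validation = spectra$sample_ids[part$validation])
    outliers[[property]] <- list(
      removed = spectra$sample_ids[part$calibration][out$removed],
      flagged = out$flagged)
  }
  list(records = records, consensus = consensus, partitions = partitions,
       outliers = outliers,
       config_summary = list(properties = config$properties,
                             partition_method = config$partition_method,
                             validation_fraction = config$validation_fraction,
                             max_factors = config$max_factors,
                             seed = config$seed))
}

#' Run the qualitative classification branch
#'
#' Preprocesses the spectra, computes the PCA score cloud, the
#' correct-classification-rate curve up to `max_pcs` components, and the
#' per-sample Mahalanobis distances and class assignments at the best
#' component count.
#'
#' @inheritParams run_quantitative
#' @return A list with `rate_curve` (data frame), `best_n_pcs`, `rate_at_best`,
#'   `scores3d` (first three PC scores), `assignments` (per-sample assigned
#'   class and distances at `best_n_pcs`) and `n_pcs_evaluated`.
#' @export
run_qualitative <- function(spectra = NULL, reference = NULL,
                            config = pipeline_config(), verbose = FALSE) {
  if (is.null(spectra) != is.null(reference))
    stop("supply both spectra and reference, or neither")
  if (is.null(spectra)) {
    ds <- synthetic_dataset(config)
    spectra <- ds$spectra
    reference <- ds$reference
  }
  aligned <- align_samples(spectra, reference)
  reference <- aligned$reference
  labels <- reference$class
  if (length(unique(labels)) < 2)
    stop("qualitative classification requires two classes; got only '",
         unique(labels), "'")
  sp <- preprocess(spectra, config$preprocess)
  curve <- rate_curve(sp, labels, max_pcs = config$max_pcs)
  best <- which.max(curve$rate)
  pca <- fit_pca(sp$absorbance, max(3, best))
  cls <- mahalanobis_classify(pca$scores[, seq_len(best), drop = FALSE],
                              labels)
  pipeline_log(verbose, "classify", "all",
               sprintf("best rate %.1f%% at %d PCs", curve$rate[best], best))
  list(rate_curve = curve,
       best_n_pcs = best,
       rate_at_best = curve$rate[best],
       scores3d = pca$scores[, seq_len(min(3, ncol(pca$scores))), drop = FALSE],
       assignments = data.frame(sample_id = spectra$sample_ids,
                                class = labels,
                                assigned = cls$labels,
                                stringsAsFactors = FALSE),
       distances = cls$distances,
       n_pcs_evaluated = nrow(curve))
}
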