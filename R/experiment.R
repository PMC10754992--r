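#' Validate an experiment configuration
#'
#' A configuration is a named list (or a YAML file loaded into one) with
#' sections `generator` (`type` `"pheno"` or `"circuit"` plus that
#' generator's parameters), `dataset` (`n_groups`, `neurons_per_group`,
#' `duration`), `split` (`train_frac`, `stratified`), `detector` (`arch`,
#' `widths_scale`), `train` ([train_config()] fields), optional `noise`
#' (list of `{mu, sigma}` settings) and `device` ([device_model()] fields),
#' and a master `seed`. Every source of randomness in the pipeline draws
#' from a named child stream of the master seed, so any stage is
#' independently reproducible. Errors name the offending field.
#'
#' @param cfg named list, or path to a YAML file.
#' @return the normalized configuration list, invisibly usable downstream.
#' @export
experiment_config <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  if (!is.list(cfg)) stop_field("(root)", "must be a list or YAML path")
  cfg$name <- cfg$name %||% "experiment"
  if (is.null(cfg$seed)) stop_field("seed", "is required")
  if (!is.numeric(cfg$seed)) stop_field("seed", "must be numeric")
  gen <- cfg$generator %||% list()
  gen$type <- gen$type %||% "pheno"
  if (!gen$type %in% c("pheno", "circuit"))
    stop_field("generator.type", "must be 'pheno' or 'circuit'")
  cfg$generator <- gen
  dsec <- cfg$dataset %||% list()
  dsec$n_groups <- dsec$n_groups %||% 100
  dsec$neurons_per_group <- dsec$neurons_per_group %||% 10
  dsec$duration <- dsec$duration %||% 2500
  if (dsec$n_groups < 1) stop_field("dataset.n_groups", "must be >= 1")
  if (dsec$neurons_per_group < 1)
    stop_field("dataset.neurons_per_group", "must be >= 1")
  cfg$dataset <- dsec
  sp <- cfg$split %||% list()
  sp$train_frac <- sp$train_frac %||% 0.75
  sp$stratified <- sp$stratified %||% TRUE
  if (sp$train_frac <= 0 || sp$train_frac >= 1)
    stop_field("split.train_frac", "must lie in (0, 1)")
  cfg$split <- sp
  det <- cfg$detector %||% list()
  det$arch <- det$arch %||% "slstm8"
  if (!det$arch %in% c("slstm8", "slstm7", "snn7"))
    stop_field("detector.arch", "must be one of slstm8, slstm7, snn7")
  det$widths_scale <- det$widths_scale %||% 1
  cfg$detector <- det
  tr <- cfg$train %||% list()
  cfg$train_config <- tryCatch(
    do.call(train_config,
            c(tr[intersect(names(tr),
                           names(formals(train_config)))],
              list(seed = derive_seed(cfg$seed, "train")))),
    error = function(e) stop_field("train", conditionMessage(e)))
  if (!is.null(cfg$noise)) {
    for (i in seq_along(cfg$noise)) {
      ns <- cfg$noise[[i]]
      if (is.null(ns$mu) || is.null(ns$sigma))
        stop_field(sprintf("noise[%d]", i), "needs mu and sigma")
    }
  }
  if (!is.null(cfg$device)) {
    cfg$device_model <- tryCatch(
      do.call(device_model,
              cfg$device[intersect(names(cfg$device),
                                   names(formals(device_model)))]),
      error = function(e) stop_field("device", conditionMessage(e)))
  }
  cfg
}

#' Run a full experiment from a configuration
#'
#' Generates the dataset, splits it, trains the configured detector,
#' evaluates it clean, optionally retrains/evaluates under each timing-noise
#' setting and runs crossbar inference, and writes every artifact (dataset
#' CSV + manifest, weight archive, per-stage metrics CSVs, machine-readable
#' `summary.json`) into `out_dir`. Re-running with the same configuration
#' and seed reproduces the summary bit for bit.
#'
#' @param cfg configuration list or YAML path (see [experiment_config()]).
#' @param out_dir output directory; created if missing. Defaults to
#'   `cfg$out_dir`.
#' @param verbose log one line per stage.
#' @return the summary list, invisibly.
#' @export
run_experiment <- function(cfg, out_dir = NULL, verbose = TRUE) {
  cfg <- experiment_config(cfg)
  out_dir <- out_dir %||% cfg$out_dir %||% stop_field("out_dir", "is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  say("[%s] generating dataset (%s)", cfg$name, cfg$generator$type)
  if (cfg$generator$type == "pheno") {
    gp <- do.call(pheno_params,
                  c(cfg$generator$params %||% list(),
                    list(seed = derive_seed(cfg$seed, "generate"))))
    ds <- generate_dataset(gp, cfg$dataset$n_groups,
                           cfg$dataset$neurons_per_group,
                           cfg$dataset$duration)
  } else {
    ds <- circuit_dataset(cfg$dataset$n_groups,
                          region_size = cfg$dataset$neurons_per_group,
                          duration = cfg$dataset$duration,
                          seed = derive_seed(cfg$seed, "generate"))
  }
  write_dataset(ds, file.path(out_dir, "dataset.csv"))

  parts <- split_dataset(ds, cfg$split$train_frac,
                         stratified = isTRUE(cfg$split$stratified),
                         seed = derive_seed(cfg$seed, "split"))
  say("[%s] split: %d train / %d val", cfg$name,
      nrow(parts$train$times), nrow(parts$val$times))

  spec <- build_detector(cfg$detector$arch, L_max = ds$L_max,
                         widths_scale = cfg$detector$widths_scale)
  say("[%s] training %s for %d epochs", cfg$name, cfg$detector$arch,
      cfg$train_config$epochs)
  det <- train_detector(spec, parts$train, parts$val, cfg$train_config)
  export_weights(det, file.path(out_dir, "weights.json"))
  utils::write.csv(det$history, file.path(out_dir, "history.csv"),
                   row.names = FALSE)

  clean <- evaluate(det, parts$val)
  utils::write.csv(as.data.frame(clean),
                   file.path(out_dir, "metrics_clean.csv"), row.names = FALSE)
  summary <- list(
    name = cfg$name, seed = cfg$seed, arch = cfg$detector$arch,
    n_samples = nrow(ds$times),
    n_train = nrow(parts$train$times), n_val = nrow(parts$val$times),
    clean = as.data.frame(clean))

  if (!is.null(cfg$noise)) {
    noise_rows <- list()
    for (i in seq_along(cfg$noise)) {
      ns <- cfg$noise[[i]]
      say("[%s] noise setting mu=%g sigma=%g", cfg$name, ns$mu, ns$sigma)
      tr <- add_timing_noise(parts$train,
              noise_spec(ns$mu, ns$sigma,
                         seed = derive_seed(cfg$seed, sprintf("noise-tr-%d", i))))
      va <- add_timing_noise(parts$val,
              noise_spec(ns$mu, ns$sigma,
                         seed = derive_seed(cfg$seed, sprintf("noise-va-%d", i))))
      ncfg <- cfg$train_config
      ncfg$seed <- derive_seed(cfg$seed, sprintf("noise-train-%d", i))
      ndet <- train_detector(spec, tr, cfg = ncfg)
      noise_rows[[i]] <- cbind(data.frame(mu = ns$mu, sigma = ns$sigma),
                               as.data.frame(evaluate(ndet, va)))
    }
    noise_df <- do.call(rbind, noise_rows)
    utils::write.csv(noise_df, file.path(out_dir, "metrics_noise.csv"),
                     row.names = FALSE)
    summary$noise <- noise_df
  }

  if (!is.null(cfg$device_model)) {
    say("[%s] crossbar inference", cfg$name)
    xb_pred <- crossbar_predict(det, parts$val, cfg$device_model)
    xb <- metrics_from_confusion(confusion(parts$val$label, xb_pred))
    utils::write.csv(as.data.frame(xb),
                     file.path(out_dir, "metrics_xbar.csv"), row.names = FALSE)
    summary$xbar <- as.data.frame(xb)
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(summary)
}
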