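# Pipeline orchestration: the two end-to-end studies (discrimination and
# quantification) driven by a single config, with all file I/O, logging and
# seed fan-out in one place.

#' Build a run configuration
#'
#' @param spectra path to a wide spectra CSV, or `"synthetic"` to generate.
#' @param labels path to a labels CSV (ignored when synthetic).
#' @param concentrations path to a concentration CSV, or `"synthetic"`.
#' @param design an [experiment_design()] (used when synthetic).
#' @param chains pretreatment chain specs to compare.
#' @param band quantification band, `c(upper, lower)` cm^-1.
#' @param plsda_fractions,cnn_fractions Kennard-Stone split fractions.
#' @param image_size CNN raster side (default 64 to keep CPU time low;
#'   rendering for figures defaults to 224 elsewhere).
#' @param epochs,batch_size,lr CNN hyperparameters.
#' @param max_components,cv_folds latent-model controls.
#' @param seed mandatory integer seed; every stochastic stage derives its
#'   own stream from it via [stage_seed()].
#' @param out_dir output directory root.
#' @return a `run_config` list.
#' @export
run_config <- function(spectra = "synthetic", labels = NULL,
                       concentrations = "synthetic",
                       design = experiment_design(),
                       chains = standard_chains(),
                       band = c(1800, 1200),
                       plsda_fractions = c(calibration = 0.7, test = 0.3),
                       cnn_fractions = c(train = 0.6, test = 0.3,
                                         external = 0.1),
                       image_size = 64, epochs = 30, batch_size = 8,
                       lr = 2e-3, max_components = 10, cv_folds = 7,
                       seed = NULL, out_dir = tempfile("dryspec_run_")) {
  if (is.null(seed)) stop("seed is mandatory in a run config")
  for (p in c(spectra, labels, concentrations)) {
    if (!is.null(p) && !identical(p, "synthetic") && !file.exists(p))
      stop("config validation: file not found: ", p)
  }
  structure(list(spectra = spectra, labels = labels,
                 concentrations = concentrations, design = design,
                 chains = chains, band = band,
                 plsda_fractions = plsda_fractions,
                 cnn_fractions = cnn_fractions, image_size = image_size,
                 epochs = epochs, batch_size = batch_size, lr = lr,
                 max_components = max_components, cv_folds = cv_folds,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (!is.null(raw$design)) raw$design <- do.call(experiment_design, raw$design)
  for (nm in c("plsda_fractions", "cnn_fractions"))
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  do.call(run_config, raw)
}

run_dir <- function(config, stamp = TRUE) {
  d <- if (stamp)
    file.path(config$out_dir, format(Sys.time(), "run_%Y%m%d_%H%M%S"))
  else config$out_dir
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

log_stage <- function(dir, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), msg)
  message(line)
  cat(line, "\n", file = file.path(dir, "run.log"), append = TRUE)
}

load_or_generate_spectra <- function(config) {
  if (identical(config$spectra, "synthetic")) {
    d <- config$design
    d$seed <- config$seed
    generate_spectra(d)
  } else read_spectra(config$spectra, config$labels)
}

#' Run the discrimination study
#'
#' Generate/load spectra, fit a PLS-DA per pretreatment chain on a
#' Kennard-Stone 70/30 split, build per-sample synchronous 2DCOS images,
#' split 60/30/10, train and evaluate the residual CNN on the external
#' partition. Every artifact lands under a timestamped run directory with
#' the config echoed.
#'
#' @param config a [run_config()].
#' @return list: `plsda_table` (one row per chain), `best_chain`,
#'   `cnn_history`, `cnn_external` (counts, metrics, accuracy), `dir`.
#' @export
run_discrimination <- function(config) {
  dir <- run_dir(config)
  jsonlite::write_json(config[setdiff(names(config), "design")],
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       force = TRUE)
  log_stage(dir, "stage spectra: load/generate")
  spectra <- tryCatch(load_or_generate_spectra(config),
                      error = function(e) stop("stage spectra: ", conditionMessage(e)))
  if (is.null(spectra$labels)) stop("stage spectra: class labels required")
  write_spectra(spectra, file.path(dir, "spectra.csv"))

  log_stage(dir, "stage plsda: Kennard-Stone 70/30 + chain table")
  split70 <- ks_split(spectra, config$plsda_fractions)
  write_split(split70, spectra$sample_ids, file.path(dir, "split_plsda.csv"))
  cs <- tryCatch(
    chain_search(spectra, spectra$labels, config$chains, split70,
                 max_components = config$max_components,
                 cv_folds = config$cv_folds),
    error = function(e) stop("stage plsda: ", conditionMessage(e)))
  write.csv(cs$table, file.path(dir, "plsda_chains.csv"), row.names = FALSE)

  log_stage(dir, "stage twodcos: per-sample synchronous maps")
  images <- sample_map_images(spectra, size = config$image_size)
  manifest <- data.frame(sample_id = spectra$sample_ids,
                         class = as.character(spectra$labels))
  write.csv(manifest, file.path(dir, "image_manifest.csv"),
            row.names = FALSE)

  log_stage(dir, "stage split: Kennard-Stone 60/30/10 on raw spectra (per class)")
  # stratified: every temperature class is represented in every partition,
  # so external-set SEN/SPE are defined for all classes
  split631 <- ks_split(spectra, config$cnn_fractions,
                       per_class = spectra$labels)
  write_split(split631, spectra$sample_ids, file.path(dir, "split_cnn.csv"))

  log_stage(dir, sprintf("stage cnn: train residual net (%d epochs)",
                         config$epochs))
  model <- build_resnet(config$image_size, nlevels(spectra$labels),
                        seed = config$seed)
  tr <- tryCatch(
    cnn_train(model, images, spectra$labels, split631,
              epochs = config$epochs, batch_size = config$batch_size,
              lr = config$lr, seed = config$seed),
    error = function(e) stop("stage cnn: ", conditionMessage(e)))
  write.csv(tr$history, file.path(dir, "cnn_history.csv"), row.names = FALSE)

  log_stage(dir, "stage evaluate: external validation")
  ext <- split631[["external"]]
  ev <- cnn_evaluate(tr$model, images[ext, , , , drop = FALSE],
                     spectra$labels[ext], levels = tr$levels)
  met <- classification_metrics(ev$counts)
  write.csv(ev$counts, file.path(dir, "cnn_confusion.csv"), row.names = FALSE)
  metrics <- list(external_accuracy = ev$accuracy,
                  per_class = met,
                  macro_SEN = mean(met$SEN, na.rm = TRUE),
                  macro_SPE = mean(met$SPE, na.rm = TRUE),
                  macro_EFF = mean(met$EFF, na.rm = TRUE))
  jsonlite::write_json(metrics, file.path(dir, "cnn_metrics.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  log_stage(dir, "done")
  list(plsda_table = cs$table, best_chain = cs$best,
       cnn_history = tr$history,
       cnn_external = list(counts = ev$counts, metrics = met,
                           accuracy = ev$accuracy),
       split_plsda = split70, split_cnn = split631, dir = dir)
}

#' Run the quantification study
#'
#' Restrict spectra to the fingerprint band, split 70/30 by Kennard-Stone,
#' and run the pretreatment chain search per compound; the report has one
#' row per compound (best chain, R2c, R2p, RMSEP, RPD).
#'
#' @param config a [run_config()].
#' @param compounds compound subset (default all in the table).
#' @return list: `table` (per-compound best-model rows), `chain_tables`
#'   (full per-chain metrics per compound), `dir`.
#' @export
run_quantification <- function(config, compounds = NULL) {
  dir <- run_dir(config)
  log_stage(dir, "stage spectra: load/generate")
  spectra <- load_or_generate_spectra(config)
  conc <- if (identical(config$concentrations, "synthetic"))
    generate_concentrations(spectra, seed = config$seed)
  else read_concentrations(config$concentrations)
  if (is.null(compounds)) compounds <- conc$compound_names
  if (length(compounds) == 0) stop("empty compound list")
  missing <- setdiff(compounds, conc$compound_names)
  if (length(missing))
    stop("compound absent from table: ", paste(missing, collapse = ", "))

  non_default <- !isTRUE(all.equal(sort(config$band),
                                   sort(c(1800, 1200))))
  log_stage(dir, sprintf("stage band: restrict X to %.0f-%.0f cm-1%s",
                         max(config$band), min(config$band),
                         if (non_default) " (non-default band)" else ""))
  xband <- band_window(spectra, max(config$band), min(config$band))

  log_stage(dir, "stage split: Kennard-Stone 70/30")
  split70 <- ks_split(xband, config$plsda_fractions)
  write_split(split70, spectra$sample_ids, file.path(dir, "split_plsr.csv"))

  log_stage(dir, "stage plsr: chain search per compound")
  rows <- list(); chain_tables <- list()
  for (cp in compounds) {
    y <- conc$values[, cp]
    cs <- chain_search(xband, y, config$chains, split70,
                       max_components = config$max_components,
                       cv_folds = config$cv_folds)
    best <- cs$table[cs$best_index, ]
    rows[[cp]] <- data.frame(compound = cp, best_chain = best$chain,
                             R2c = best$R2c, R2p = best$R2p,
                             RMSEP = best$RMSEP, RPD = best$RPD)
    chain_tables[[cp]] <- cs$table
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (non_default) attr(tab, "band") <- config$band
  write.csv(tab, file.path(dir, "plsr_compounds.csv"), row.names = FALSE)
  log_stage(dir, "done")
  list(table = tab, chain_tables = chain_tables, split = split70, dir = dir)
}
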