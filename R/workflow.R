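# Command-line entry points and run configuration tying the modules into the
# experimental protocol: simulate -> features -> train -> predict -> evaluate.
# Exit codes: 0 success, 2 config error, 3 data error.

#' Read a plain key=value run configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are kept as
#' strings; callers coerce.
#'
#' @param path file path.
#' @return Named list of strings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) tmc_config_error(sprintf("config file not found: %s", path))
  lines <- trimws(sub("#.*$", "", readLines(path, warn = FALSE)))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2
  if (any(bad)) tmc_config_error(sprintf("malformed config line: %s", lines[bad][1]))
  vals <- lapply(kv, function(p) trimws(paste(p[-1], collapse = "=")))
  names(vals) <- trimws(vapply(kv, `[[`, "", 1))
  vals
}

write_run_log <- function(dir, cmd, opts) {
  lines <- c(sprintf("command: %s", cmd),
             sprintf("package_version: %s",
                     as.character(utils::packageVersion("tmcontact"))),
             sprintf("%s: %s", names(opts), vapply(opts, function(x)
               paste(format(x), collapse = ","), "")))
  lines <- c(lines, sprintf("config_hash: %s", text_hash(lines)))
  writeLines(lines, file.path(dir, sprintf("%s_run.log", cmd)))
}

#' Simulate a paired synthetic benchmark to disk
#'
#' Writes, per sequence, experimental and predicted PDB files and the
#' annotation file, plus a `manifest.tsv` listing them, in the formats the
#' rest of the pipeline consumes.
#'
#' @param out_dir output directory (created if missing).
#' @param n_sequences,sigma,seed forwarded to [make_benchmark()].
#' @param ... further arguments to [make_benchmark()].
#' @return The manifest data.frame, invisibly.
#' @export
cmd_simulate <- function(out_dir, n_sequences = 10L, sigma = 0.5, seed = 1L, ...) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    tmc_config_error(sprintf("cannot create output directory %s", out_dir))
  ds <- make_benchmark(n_sequences = n_sequences,
                       noise = noise_spec(sigma, seed), seed = seed, ...)
  rows <- lapply(ds, function(e) {
    exp_p <- sprintf("%s_exp.pdb", e$id); pred_p <- sprintf("%s_pred.pdb", e$id)
    ann_p <- sprintf("%s_ann.txt", e$id)
    write_pdb(e$experimental, file.path(out_dir, exp_p))
    write_pdb(e$predicted, file.path(out_dir, pred_p))
    write_helix_annotation(e$annotation, file.path(out_dir, ann_p))
    data.frame(id = e$id, experimental = exp_p, predicted = pred_p,
               annotation = ann_p)
  })
  manifest <- do.call(rbind, rows)
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_run_log(out_dir, "simulate",
                list(n_sequences = n_sequences, sigma = sigma, seed = seed))
  invisible(manifest)
}

load_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path))
    tmc_data_error(sprintf("manifest not found: %s", manifest_path))
  read.table(manifest_path, header = TRUE, sep = "\t",
             colClasses = "character")
}

#' Extract features and labels for every sequence of a manifest
#'
#' For each sequence the experimental and predicted structures are
#' reconciled (offset 0 for simulated data), candidate pairs are enumerated on
#' the experimental annotation, ground-truth labels always come from the
#' experimental coordinates, and feature matrices are built from the requested
#' source. For `source = "predicted"` the structure's own binary contact
#' annotation is also written (the baseline a predicted structure implies).
#'
#' @param manifest_path path to a `manifest.tsv` from [cmd_simulate()] (paths
#'   are resolved relative to it).
#' @param out_dir output directory.
#' @param feature_kind `"SDF"` or `"CF"`.
#' @param source `"experimental"` or `"predicted"`.
#' @param chain_id chain to read from the PDB files.
#' @param offset author-numbering offset between the members.
#' @param min_separation sequence-separation filter.
#' @return Invisible data.frame of written files and skip counts.
#' @export
cmd_features <- function(manifest_path, out_dir, feature_kind = c("SDF", "CF"),
                         source = c("experimental", "predicted"),
                         chain_id = "A", offset = 0L, min_separation = 5L) {
  feature_kind <- match.arg(toupper(feature_kind), c("SDF", "CF"))
  source <- match.arg(source)
  manifest <- load_manifest(manifest_path)
  base <- dirname(manifest_path)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  out <- list()
  for (r in seq_len(nrow(manifest))) {
    id <- manifest$id[r]
    res <- tryCatch({
      ch_exp <- read_pdb(file.path(base, manifest$experimental[r]), chain_id,
                         "experimental")
      ch_pred <- read_pdb(file.path(base, manifest$predicted[r]), chain_id,
                          "predicted")
      ann <- read_helix_annotation(file.path(base, manifest$annotation[r]))
      paired <- reconcile_pair(ch_exp, ch_pred, offset, ann)
      pairs <- candidate_pairs(ch_exp, ann, min_separation)
      truth <- label_contacts(ch_exp, pairs)
      write_contact_map(truth, file.path(out_dir, sprintf("%s_labels.tsv", id)))
      if (source == "experimental") {
        fm <- build_feature_matrix(ch_exp, ann, pairs, feature_kind, id)
      } else {
        ppairs <- translate_pairs(paired, pairs)
        fm <- build_feature_matrix(ch_pred, translate_annotation(paired),
                                   ppairs, feature_kind, id)
        # report rows in the experimental index frame so sources align
        fm$pairs <- pairs[fm$kept, , drop = FALSE]
        pred_ann <- label_contacts(ch_pred, ppairs)
        pred_ann$pairs <- pairs
        write_contact_map(pred_ann,
                          file.path(out_dir, sprintf("%s_pred_annotation.tsv", id)))
      }
      fpath <- sprintf("%s_%s_%s.features.tsv", id, feature_kind, source)
      write_feature_matrix(fm, file.path(out_dir, fpath))
      data.frame(id = id, file = fpath, n_pairs = nrow(fm$x),
                 n_skipped = fm$n_skipped, error = NA_character_)
    }, error = function(e) {
      message(sprintf("sequence %s failed: %s", id, conditionMessage(e)))
      data.frame(id = id, file = NA_character_, n_pairs = 0L,
                 n_skipped = NA_integer_, error = conditionMessage(e))
    })
    out[[r]] <- res
  }
  summary <- do.call(rbind, out)
  write_run_log(out_dir, sprintf("features_%s_%s", feature_kind, source),
                list(manifest = manifest_path, kind = feature_kind,
                     source = source,
                     skipped = sum(summary$n_skipped, na.rm = TRUE)))
  invisible(summary)
}

# read one sequence's features (+ optional predicted-source features) and
# labels aligned to the featurized pair set
load_sequence_entry <- function(dir, id, kind, with_predicted = TRUE) {
  fexp <- file.path(dir, sprintf("%s_%s_experimental.features.tsv", id, kind))
  if (!file.exists(fexp)) tmc_data_error(sprintf("missing feature file %s", fexp))
  fm <- read_feature_matrix(fexp)
  fm$kind <- kind
  lab_path <- file.path(dir, sprintf("%s_labels.tsv", id))
  if (!file.exists(lab_path)) tmc_data_error(sprintf("missing label file %s", lab_path))
  labcm <- read_contact_map(lab_path)
  key <- function(p) paste(p$i, p$j)
  labmap <- structure(labcm$labels, names = key(labcm$pairs))
  entry <- list(id = id, features = fm,
                labels = unname(labmap[key(fm$pairs)]))
  if (anyNA(entry$labels)) tmc_data_error(sprintf("labels missing for pairs of %s", id))
  fpred <- file.path(dir, sprintf("%s_%s_predicted.features.tsv", id, kind))
  if (with_predicted && file.exists(fpred)) {
    fmp <- read_feature_matrix(fpred)
    fmp$kind <- kind
    # keep the pair set common to both sources so the scored sets coincide
    common <- intersect(key(fm$pairs), key(fmp$pairs))
    sel_e <- key(fm$pairs) %in% common
    sel_p <- key(fmp$pairs) %in% common
    entry$features$x <- fm$x[sel_e, , drop = FALSE]
    entry$features$pairs <- fm$pairs[sel_e, , drop = FALSE]
    entry$labels <- entry$labels[sel_e]
    fmp$x <- fmp$x[sel_p, , drop = FALSE]
    fmp$pairs <- fmp$pairs[sel_p, , drop = FALSE]
    entry$features_test <- fmp
  }
  pred_ann <- file.path(dir, sprintf("%s_pred_annotation.tsv", id))
  if (file.exists(pred_ann)) {
    pa <- read_contact_map(pred_ann)
    pamap <- structure(pa$labels, names = key(pa$pairs))
    entry$pred_labels <- unname(pamap[key(entry$features$pairs)])
  }
  entry
}

#' Assemble the per-sequence dataset from a features directory
#'
#' @param dir directory written by [cmd_features()].
#' @param kind `"SDF"` or `"CF"`.
#' @param with_predicted attach predicted-source feature matrices when found.
#' @return list of dataset entries for [cross_validate()].
#' @export
load_feature_dataset <- function(dir, kind = "SDF", with_predicted = TRUE) {
  files <- list.files(dir, sprintf("_%s_experimental\\.features\\.tsv$", kind))
  if (!length(files)) tmc_data_error(sprintf("no %s feature files in %s", kind, dir))
  ids <- sub(sprintf("_%s_experimental\\.features\\.tsv$", kind), "", files)
  lapply(sort(ids), function(id) load_sequence_entry(dir, id, kind, with_predicted))
}

#' Train a classifier on the pooled experimental features of a dataset
#'
#' @param features_dir directory written by [cmd_features()].
#' @param model_path output checkpoint path.
#' @param feature_kind `"SDF"` or `"CF"`.
#' @param config a [model_config()].
#' @return The trained model, invisibly.
#' @export
cmd_train <- function(features_dir, model_path, feature_kind = "SDF",
                      config = model_config()) {
  ds <- load_feature_dataset(features_dir, feature_kind, with_predicted = FALSE)
  pool_x <- do.call(rbind, lapply(ds, function(d) d$features$x))
  pool_y <- unlist(lapply(ds, function(d) d$labels))
  scaler <- fit_scaler(pool_x); scaler$kind <- feature_kind
  fm <- structure(list(x = pool_x, pairs = NULL, kind = feature_kind,
                       sequence_id = "pool", n_skipped = 0L, scaled = FALSE),
                  class = "FeatureMatrix")
  model <- train_model(fm, pool_y, config, scaler = scaler)
  save_model(model, model_path)
  write_run_log(dirname(model_path), "train",
                list(features_dir = features_dir, kind = feature_kind,
                     seed = config$seed, epochs = config$epochs))
  invisible(model)
}

#' Score feature files with a trained model
#'
#' @param model_path checkpoint from [cmd_train()].
#' @param features_dir directory with feature files.
#' @param out_dir output directory for scored contact maps.
#' @param source which source's features to score.
#' @return Invisible character vector of written files.
#' @export
cmd_predict <- function(model_path, features_dir, out_dir,
                        source = c("predicted", "experimental")) {
  source <- match.arg(source)
  if (!file.exists(model_path)) tmc_data_error(sprintf("missing model %s", model_path))
  model <- load_model(model_path)
  kind <- model$input_kind
  files <- list.files(features_dir, sprintf("_%s_%s\\.features\\.tsv$", kind, source))
  if (!length(files))
    tmc_data_error(sprintf("no %s/%s feature files in %s", kind, source, features_dir))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  for (f in files) {
    fm <- read_feature_matrix(file.path(features_dir, f))
    fm$kind <- kind
    id <- sub(sprintf("_%s_%s\\.features\\.tsv$", kind, source), "", f)
    lab <- read_contact_map(file.path(features_dir, sprintf("%s_labels.tsv", id)))
    key <- paste(lab$pairs$i, lab$pairs$j)
    labels <- structure(lab$labels, names = key)[paste(fm$pairs$i, fm$pairs$j)]
    cm <- contact_map(fm$pairs, unname(labels), predict_scores(model, fm))
    out <- file.path(out_dir, sprintf("%s_%s_%s.scores.tsv", id, kind, source))
    write_contact_map(cm, out)
    written <- c(written, out)
  }
  write_run_log(out_dir, "predict", list(model = model_path, source = source))
  invisible(written)
}

#' Cross-validated evaluation report
#'
#' Runs sequence-grouped cross-validation for each requested feature kind,
#' scoring held-out sequences on the experimental features (upper bound) and,
#' when available, the predicted-structure features, and appends the
#' predicted-structure binary-annotation baseline row.
#'
#' @param features_dir directory with feature/label files for one or both
#'   kinds.
#' @param out_path report TSV path.
#' @param kinds feature kinds to evaluate.
#' @param config a [model_config()].
#' @param k,repeats,seed cross-validation settings.
#' @return list of `MetricsReport`s plus the summary table, invisibly.
#' @export
cmd_evaluate <- function(features_dir, out_path, kinds = c("SDF", "CF"),
                         config = model_config(), k = 5L, repeats = 5L,
                         seed = 1L) {
  rows <- list(); reports <- list()
  for (kind in kinds) {
    ds <- tryCatch(load_feature_dataset(features_dir, kind),
                   tmc_data_error = function(e) NULL)
    if (is.null(ds)) next
    has_pred <- all(vapply(ds, function(d) !is.null(d$features_test), TRUE))
    rep_exp <- cross_validate(lapply(ds, function(d)
      list(id = d$id, features = d$features, labels = d$labels)),
      config, k, repeats, seed)
    reports[[paste0(kind, "_experimental")]] <- rep_exp
    rows[[length(rows) + 1L]] <- data.frame(
      classifier = "NN", source = "experimental", kind = kind,
      ap = mean(rep_exp$repeat_means$ap), ap_sd = sd_or_zero(rep_exp$repeat_means$ap),
      auc = mean(rep_exp$repeat_means$auc), auc_sd = sd_or_zero(rep_exp$repeat_means$auc))
    if (has_pred) {
      rep_pred <- cross_validate(ds, config, k, repeats, seed)
      reports[[paste0(kind, "_predicted")]] <- rep_pred
      rows[[length(rows) + 1L]] <- data.frame(
        classifier = "NN", source = "predicted", kind = kind,
        ap = mean(rep_pred$repeat_means$ap), ap_sd = sd_or_zero(rep_pred$repeat_means$ap),
        auc = mean(rep_pred$repeat_means$auc), auc_sd = sd_or_zero(rep_pred$repeat_means$auc))
    }
  }
  if (!length(rows)) tmc_data_error("no feature files found to evaluate")
  base_ds <- tryCatch(load_feature_dataset(features_dir, kinds[1]),
                      tmc_data_error = function(e) NULL)
  if (!is.null(base_ds) &&
      all(vapply(base_ds, function(d) !is.null(d$pred_labels), TRUE))) {
    base_rep <- annotation_baseline_report(base_ds)
    reports[["annotation_baseline"]] <- base_rep
    rows[[length(rows) + 1L]] <- data.frame(
      classifier = "structure annotation", source = "predicted", kind = "-",
      ap = base_rep$mean_ap, ap_sd = 0, auc = base_rep$mean_auc, auc_sd = 0)
  }
  summary <- do.call(rbind, rows)
  write.table(summary, out_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_log(dirname(out_path), "evaluate",
                list(features_dir = features_dir, k = k, repeats = repeats,
                     seed = seed))
  invisible(list(summary = summary, reports = reports))
}

cli_opts <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      tmc_config_error(sprintf("unexpected argument '%s'", args[i]))
    key <- gsub("-", "_", substring(args[i], 3))
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      tmc_config_error(sprintf("flag --%s needs a value", key))
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command line interface
#'
#' Subcommands `simulate`, `features`, `train`, `predict`, `evaluate` with
#' `--key value` flags; `--config file` supplies defaults that flags override.
#' See the package README for the flag list per subcommand.
#'
#' @param args character vector (defaults to the command line).
#' @return Integer exit code: 0 success, 2 config error, 3 data error.
#' @export
tmc_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  run <- function() {
    if (!length(args)) tmc_config_error(
      "usage: tmcontact <simulate|features|train|predict|evaluate> [--flags]")
    cmd <- args[1]
    opts <- cli_opts(args[-1])
    if (!is.null(opts$config)) {
      base <- read_run_config(opts$config)
      opts <- utils::modifyList(base, opts[names(opts) != "config"])
    }
    num <- function(key, default) as.numeric(opts[[key]] %||% default)
    cfg <- model_config(
      learning_rate = num("learning_rate", 1e-4),
      batch_size = num("batch_size", 256), epochs = num("epochs", 400),
      seed = num("seed", 42), projection_seed = num("projection_seed", 7))
    kindopt <- toupper(opts$feature_kind %||% "SDF")
    switch(cmd,
      simulate = cmd_simulate(opts$out %||% tmc_config_error("--out required"),
                              n_sequences = num("n_sequences", 10),
                              sigma = num("sigma", 0.5), seed = num("seed", 1)),
      features = cmd_features(opts$manifest %||% tmc_config_error("--manifest required"),
                              opts$out %||% tmc_config_error("--out required"),
                              kindopt, opts$source %||% "experimental",
                              min_separation = num("min_separation", 5)),
      train = cmd_train(opts$features_dir %||% tmc_config_error("--features-dir required"),
                        opts$out %||% tmc_config_error("--out required"),
                        kindopt, cfg),
      predict = cmd_predict(opts$model %||% tmc_config_error("--model required"),
                            opts$features_dir %||% tmc_config_error("--features-dir required"),
                            opts$out %||% tmc_config_error("--out required"),
                            opts$source %||% "predicted"),
      evaluate = cmd_evaluate(opts$features_dir %||% tmc_config_error("--features-dir required"),
                              opts$out %||% tmc_config_error("--out required"),
                              kinds = if (kindopt == "BOTH") c("SDF", "CF") else kindopt,
                              config = cfg, k = num("k", 5),
                              repeats = num("repeats", 5), seed = num("seed", 1)),
      tmc_config_error(sprintf("unknown subcommand '%s'", cmd)))
    0L
  }
  tryCatch(run(),
           tmc_config_error = function(e) { message("config error: ", conditionMessage(e)); 2L },
           tmc_data_error = function(e) { message("data error: ", conditionMessage(e)); 3L },
           error = function(e) { message("error: ", conditionMessage(e)); 1L })
}
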