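# Reproducible experiment pipeline: synth -> preprocess -> train -> predict
# -> evaluate, driven by one config with a single root seed from which every
# stage's randomness is derived.

#' Default experiment configuration
#'
#' @param seed root seed; per-stage seeds are derived from it.
#' @param synth named list of [synth_config()] overrides.
#' @param val_fraction fraction of documents held out for validation.
#' @param keep_neg fraction of training negatives kept by
#'   [subsample_negatives()] (validation is never subsampled).
#' @param model named list of [model_config()] overrides; `dims` may be a
#'   named list of [feature_dims()] overrides.
#' @param train named list of [train_config()] overrides; `n_seeds` controls
#'   how many random initializations [multi_seed_select()] tries.
#' @param vocab_k dictionary size cap.
#' @param embeddings optional path to a word2vec text file.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(seed = 1L, synth = list(), val_fraction = 0.3,
                              keep_neg = 1.0, model = list(), train = list(),
                              vocab_k = 100000L, embeddings = NULL) {
  structure(list(seed = seed, synth = synth, val_fraction = val_fraction,
                 keep_neg = keep_neg, model = model, train = train,
                 vocab_k = vocab_k, embeddings = embeddings),
            class = "experiment_config")
}

apply_overrides <- function(defaults, overrides) {
  for (k in names(overrides)) defaults[[k]] <- overrides[[k]]
  defaults
}

build_model_config <- function(model_over) {
  dims <- do.call(feature_dims, model_over$dims %||% list())
  model_over$dims <- NULL
  do.call(model_config, c(list(dims = dims), model_over))
}

#' Run a full experiment
#'
#' Generates a synthetic corpus, splits it into training and validation
#' documents, builds candidate instances, trains the classifier under
#' multiple random initializations, predicts the validation split and
#' evaluates both at instance level and at relation level (against the gold
#' `.a2` relations, intersentence gold counting as false negatives). All
#' stage seeds derive from the root seed, so two runs of the same config
#' produce identical metrics.
#'
#' @param config an [experiment_config()], a named list of its arguments, or
#'   the path of a YAML file holding them.
#' @param out_dir optional directory: the corpus, predictions, metrics and
#'   run manifest are written there.
#' @param quiet suppress progress messages.
#' @return list with `metrics` (instance- and relation-level), `model`,
#'   `manifest` (config hash, seeds, stage durations, counts) and the
#'   instance sets.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL,
                           quiet = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "experiment_config"))
    config <- do.call(experiment_config, config)
  t0 <- proc.time()[["elapsed"]]
  stage_t <- c()
  tick <- function(name) {
    t1 <- proc.time()[["elapsed"]]
    stage_t[[name]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  scfg <- do.call(synth_config, apply_overrides(list(seed = config$seed),
                                                config$synth))
  corpus <- generate_corpus(scfg)
  task <- corpus$task
  docs <- corpus$documents
  n_val <- max(1L, round(config$val_fraction * length(docs)))
  val_ids <- withr::with_seed(config$seed + 101L,
                              sample(names(docs), n_val))
  train_docs <- docs[setdiff(names(docs), val_ids)]
  val_docs <- docs[val_ids]
  tick("synth")

  enumerate_all <- function(dd) {
    insts <- unlist(lapply(dd, enumerate_candidates, rules = task),
                    recursive = FALSE)
    filter_no_path(insts, quiet = TRUE)
  }
  train_inst <- enumerate_all(train_docs)
  train_inst <- subsample_negatives(train_inst, config$keep_neg,
                                    seed = config$seed + 202L)
  val_inst <- enumerate_all(val_docs)
  if (!quiet)
    message(sprintf("instances: %d train (%d pos), %d val (%d pos)",
                    length(train_inst), corpus_statistics(train_inst)$positives,
                    length(val_inst), corpus_statistics(val_inst)$positives))
  tick("preprocess")

  mcfg <- build_model_config(config$model)
  emb <- if (!is.null(config$embeddings)) read_word2vec(config$embeddings)
  vt <- build_vocabulary(train_inst, task$entity_types, k = config$vocab_k,
                         embeddings = emb, dims = mcfg$dims,
                         seed = config$seed + 303L)
  cats <- task$category_names
  train_enc <- lapply(train_inst, encode_instance, vocab = vt$vocab,
                      categories = cats)
  val_enc <- lapply(val_inst, encode_instance, vocab = vt$vocab,
                    categories = cats)
  tr_over <- config$train
  n_seeds <- tr_over$n_seeds %||% 3L
  tr_over$n_seeds <- NULL
  tcfg <- do.call(train_config,
                  apply_overrides(list(seeds = config$seed + seq_len(n_seeds)),
                                  tr_over))
  model <- multi_seed_select(train_enc, val_enc, vt$vocab, vt$tables, cats,
                             mcfg, tcfg, quiet = quiet)
  tick("train")

  pred_labels <- attr(predict(model, val_enc), "label")
  predicted <- predictions_to_relations(val_inst, pred_labels)
  tick("predict")

  gold <- gold_relations(val_docs)
  rel_report <- score(predicted, gold)
  gold_inst <- cats[vapply(val_enc, `[[`, integer(1), "label_idx")]
  inst_metrics <- instance_micro_f1(pred_labels, gold_inst)
  metrics <- list(
    val_f1 = model$val_f1,
    seed_summary = model$seed_summary,
    instance = inst_metrics,
    relation = list(overall = rel_report$overall, intra = rel_report$intra)
  )
  tick("evaluate")

  manifest <- list(
    config_hash = fnv1a_hash(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                              null = "null", digits = NA)),
    seed = config$seed, train_seeds = tcfg$seeds,
    package_version = as.character(utils::packageVersion("biorel")),
    corpus = corpus$manifest,
    n_train_instances = length(train_inst),
    n_val_instances = length(val_inst),
    stage_seconds = as.list(stage_t)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_corpus_dir(docs, file.path(out_dir, "corpus"), rules = task)
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    pred_dir <- file.path(out_dir, "predictions")
    dir.create(pred_dir, showWarnings = FALSE)
    for (id in names(val_docs)) {
      rows <- predicted[predicted$doc_id == id, , drop = FALSE]
      names(rows)[names(rows) == "e1"] <- "arg1"
      names(rows)[names(rows) == "e2"] <- "arg2"
      write_file(write_predictions(val_docs[[id]], rows, task),
                 file.path(pred_dir, paste0(id, ".a2")))
    }
  }
  list(metrics = metrics, model = model, manifest = manifest,
       task = task, train_instances = train_inst, val_instances = val_inst,
       val_docs = val_docs, report = rel_report)
}

#' Run the encoder ablation grid
#'
#' Trains the configured experiment once per encoder variant and reports the
#' min/max/mean/SD of validation F1 across random initializations for each —
#' the shape of the sentence-encoder and SDP-encoder comparison tables.
#'
#' @param config an [experiment_config()] (or overrides list / YAML path).
#' @param encoders sentence-encoder variants to try.
#' @param sdp_encoders SDP-encoder variants to try (crossed with the default
#'   sentence encoder).
#' @param quiet suppress progress messages.
#' @return data.frame: `encoder`, `sdp_encoder`, `min`, `max`, `mean`, `sd`
#'   of validation F1 (0-1 scale).
#' @export
run_ablation <- function(config = experiment_config(),
                         encoders = c("mha"),
                         sdp_encoders = c("cnn", "lstm", "none"),
                         quiet = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "experiment_config"))
    config <- do.call(experiment_config, config)
  grid <- rbind(
    expand.grid(encoder = encoders, sdp_encoder = "cnn",
                stringsAsFactors = FALSE),
    expand.grid(encoder = "mha", sdp_encoder = setdiff(sdp_encoders, "cnn"),
                stringsAsFactors = FALSE)
  )
  grid <- grid[!duplicated(grid), , drop = FALSE]
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$model$encoder <- grid$encoder[i]
    cfg$model$sdp_encoder <- grid$sdp_encoder[i]
    if (!quiet)
      message(sprintf("ablation: encoder=%s sdp=%s", grid$encoder[i],
                      grid$sdp_encoder[i]))
    res <- run_experiment(cfg, quiet = quiet)
    ss <- res$metrics$seed_summary
    data.frame(encoder = grid$encoder[i], sdp_encoder = grid$sdp_encoder[i],
               min = ss$min, max = ss$max, mean = ss$mean, sd = ss$sd)
  })
  do.call(rbind, rows)
}
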