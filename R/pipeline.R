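# End-to-end workflow: simulate? -> filter -> train -> embed -> specificity
# -> classify -> aggregate -> evaluate (+ transcriptomic baselines,
# + donor-invariance ablation). Driven by a nested run config validated
# against a fixed schema; the resolved config, a plain-text log and
# machine-readable metrics are written alongside the outputs.

RUN_CONFIG_SCHEMA <- list(
  seed = NULL, out_dir = NULL, ablation = NULL,
  simulate = c("profile", "overrides"),
  corpus = c("manifest", "image_root"),
  augment = c("crop_size", "hue_jitter", "sat_jitter", "val_jitter",
              "scale_range", "rotation_range"),
  contrastive = c("batch_size", "temperature", "epochs", "learning_rate",
                  "embedding_dim", "channels", "negative_mode",
                  "donor_mask_source", "count_self", "symmetrize"),
  classifier = c("learning_rate", "epochs", "holdout_genes"),
  evaluate = c("expr_dir", "region_map", "truth", "baseline_methods",
               "probe_folds")
)

#' Validate a run configuration
#'
#' Checks the nested config against the published schema: unknown blocks or
#' keys are rejected before any computation.
#'
#' @param config nested named list (e.g. parsed from a YAML file).
#' @return the config, invisibly, on success.
#' @export
validate_run_config <- function(config) {
  bad <- setdiff(names(config), names(RUN_CONFIG_SCHEMA))
  if (length(bad) > 0) stopf("unknown config block(s): %s",
                             paste(bad, collapse = ", "))
  for (blk in names(config)) {
    keys <- RUN_CONFIG_SCHEMA[[blk]]
    if (is.null(keys)) next
    extra <- setdiff(names(config[[blk]]), keys)
    if (length(extra) > 0) {
      stopf("unknown key(s) in config block '%s': %s", blk,
            paste(extra, collapse = ", "))
    }
  }
  invisible(config)
}

#' Desk-scale training protocol
#'
#' The augmentation and contrastive settings used for runs on the synthetic
#' 64x64 corpora: crop 32 (half the image side, mirroring the half-side crop
#' of the full-scale protocol), mild color jitter, +/-45 degree rotation,
#' embedding dimension 32 (keeping the training-image count well above the
#' embedding dimension, the regime in which a linear classifier cannot
#' memorize noisy targets), learning rate 1e-3.
#'
#' @param negative_mode,seed,epochs passed through to
#'   [contrastive_config()].
#' @return an [augment_config()] / [contrastive_config()].
#' @export
desk_augment_config <- function() {
  augment_config(crop_size = 32L, hue_jitter = 0.02, sat_jitter = 0.1,
                 val_jitter = 0.1, scale_range = c(0.9, 1.1),
                 rotation_range = 45)
}

#' @rdname desk_augment_config
#' @export
desk_contrastive_config <- function(negative_mode = "donor_masked",
                                    seed = 1L, epochs = 300L) {
  contrastive_config(batch_size = 150L, temperature = 1.0, epochs = epochs,
                     learning_rate = 1e-3, embedding_dim = 32L,
                     negative_mode = negative_mode, seed = seed)
}

#' Default run configuration
#'
#' A complete config for a self-contained synthetic run: simulate a fixture,
#' train at desk scale (crop 32, 60 epochs), and evaluate against the
#' planted region labels.
#'
#' @param out_dir run output directory.
#' @param profile synthetic profile passed to [make_fixture()].
#' @param seed master seed.
#' @return nested config list.
#' @export
default_run_config <- function(out_dir = tempfile(), profile = "tiny",
                               seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    ablation = FALSE,
    simulate = list(profile = profile),
    augment = list(crop_size = 32L, hue_jitter = 0.02, sat_jitter = 0.1,
                   val_jitter = 0.1, scale_range = c(0.9, 1.1),
                   rotation_range = 45),
    contrastive = list(batch_size = 150L, temperature = 1.0, epochs = 60L,
                       learning_rate = 1e-3, embedding_dim = 32L,
                       negative_mode = "donor_masked"),
    classifier = list(learning_rate = 0.01, epochs = 400L),
    evaluate = list(baseline_methods = c("t_test", "wilcoxon"),
                    probe_folds = 5L)
  )
}

#' Run the full pipeline
#'
#' Executes the staged workflow described by the config and writes versioned
#' outputs under `config$out_dir`: `embeddings.tsv`, `predictions.tsv`
#' (per-gene region probabilities), `auc_summary.tsv`, `roc_points.tsv`,
#' baseline AUC tables, `metrics.json`, a resolved `config.yaml` and
#' `run.log`. With `ablation = TRUE`, encoders are trained under both
#' negative-sampling modes and the donor-probe / planted-class-probe
#' accuracies of both (plus an untrained encoder) are written to
#' `ablation.json`.
#'
#' @param config nested run config (see [default_run_config()]); validated
#'   before any computation.
#' @return (invisibly) a list with the run directory, the key result tibbles
#'   and the trained objects.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir %||% tempfile()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    cat(sprintf("%s  %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                sprintf(...)), file = log_path, append = TRUE)
  }
  metrics <- list()

  # -- simulate / load ------------------------------------------------------
  if (!is.null(config$simulate)) {
    logf("stage simulate: profile=%s", config$simulate$profile %||% "tiny")
    fix <- make_fixture(config$simulate$profile %||% "tiny",
                        out_dir = file.path(out_dir, "sim"), seed = seed,
                        overrides = config$simulate$overrides %||% list())
    manifest <- fix$paths$manifest
    image_root <- fix$paths$dir
    expr_dir <- fix$paths$expr
    region_map_path <- fix$paths$region_map
    truth_path <- fix$paths$truth
  } else {
    manifest <- config$corpus$manifest
    image_root <- config$corpus$image_root %||% dirname(manifest)
    expr_dir <- config$evaluate$expr_dir
    region_map_path <- config$evaluate$region_map
    truth_path <- config$evaluate$truth
  }
  logf("stage corpus: %s", manifest)
  corpus <- filter_corpus(read_manifest(manifest, image_root))
  logf("corpus: %d images, %d genes", nrow(corpus$records),
       length(corpus$gene_partition))

  aug <- do.call(augment_config, config$augment %||% list())
  ccfg_args <- config$contrastive %||% list()
  ccfg_args$seed <- seed
  ccfg <- do.call(contrastive_config, ccfg_args)

  # -- train + embed --------------------------------------------------------
  logf("stage train: mode=%s, epochs=%d", ccfg$negative_mode, ccfg$epochs)
  encoder <- train_contrastive(corpus, ccfg, aug)
  logf("final loss %.4f", tail(encoder$loss_history, 1L))
  embeddings <- embed_corpus(corpus, encoder)
  readr::write_tsv(embeddings, file.path(out_dir, "embeddings.tsv"))

  # -- ablation -------------------------------------------------------------
  if (isTRUE(config$ablation)) {
    logf("stage ablation: retraining with swapped negative mode")
    other <- if (ccfg$negative_mode == "donor_masked") "uniform"
             else "donor_masked"
    ccfg2 <- ccfg; ccfg2$negative_mode <- other
    encoder2 <- train_contrastive(corpus, ccfg2, aug)
    emb2 <- embed_corpus(corpus, encoder2)
    set.seed(derive_seed(seed, "init"))
    enc0 <- init_encoder(aug$crop_size, ccfg$channels, ccfg$embedding_dim)
    emb0 <- embed_corpus(corpus, enc0)
    folds <- config$evaluate$probe_folds %||% 5L
    # planted-class probe labels, when gene-level truth with cell types exists
    class_of <- NULL
    if (!is.null(truth_path) && file.exists(truth_path)) {
      tt <- readr::read_tsv(truth_path, show_col_types = FALSE,
                            progress = FALSE)
      if ("cell_type" %in% names(tt)) {
        class_of <- setNames(tt$cell_type, tt$gene)
      }
    }
    probe_pair <- function(emb) {
      H <- embedding_matrix(emb)
      out <- list(donor_probe = donor_probe(H, emb$donor, folds, seed))
      if (!is.null(class_of)) {
        out$class_probe <- linear_probe(H, class_of[emb$gene], folds, seed)
      }
      out
    }
    abl <- list()
    abl[[ccfg$negative_mode]] <- probe_pair(embeddings)
    abl[[other]] <- probe_pair(emb2)
    abl$untrained <- probe_pair(emb0)
    jsonlite::write_json(abl, file.path(out_dir, "ablation.json"),
                         auto_unbox = TRUE, digits = NA)
    metrics$ablation <- abl
    logf("donor probe: %s=%.3f %s=%.3f untrained=%.3f",
         ccfg$negative_mode, abl[[ccfg$negative_mode]]$donor_probe,
         other, abl[[other]]$donor_probe, abl$untrained$donor_probe)
  }

  # -- specificity + classifier --------------------------------------------
  logf("stage specificity: %s", expr_dir)
  expr <- read_expression_mtx(expr_dir)
  specificity <- build_specificity(mean_expression_by_type(expr))
  holdout <- character(0)
  if (!is.null(config$classifier$holdout_genes)) {
    holdout <- readLines(config$classifier$holdout_genes)
  }
  tr <- match_specificity_targets(embeddings, specificity, holdout)
  clf <- fit_soft_label_classifier(
    tr$H, tr$Y,
    learning_rate = config$classifier$learning_rate %||% 0.01,
    epochs = config$classifier$epochs %||% 1000L
  )
  logf("classifier: %d images, final loss %.4f", nrow(tr$H),
       tail(clf$loss_history, 1L))
  readr::write_tsv(tidyr::pivot_wider(tidy(clf), names_from = "cell_type",
                                      values_from = "weight"),
                   file.path(out_dir, "classifier_weights.tsv"))

  # -- predict + aggregate --------------------------------------------------
  region_map <- read_region_map(region_map_path)
  P <- predict_cell_types(embedding_matrix(embeddings), clf)
  R <- aggregate_to_regions(P, region_map)
  image_regions <- bind_cols(embeddings[, c("image_id", "gene")],
                             as_tibble(R, .name_repair = "minimal"))
  predictions <- gene_level_prediction(image_regions[, -1L])
  readr::write_tsv(predictions, file.path(out_dir, "predictions.tsv"))

  # -- evaluate -------------------------------------------------------------
  truth <- readr::read_tsv(truth_path, show_col_types = FALSE,
                           progress = FALSE)
  roc <- ovr_roc(predictions, truth)
  readr::write_tsv(roc$auc, file.path(out_dir, "auc_summary.tsv"))
  readr::write_tsv(roc$curves, file.path(out_dir, "roc_points.tsv"))
  metrics$mean_region_auc <- mean(roc$auc$auc)
  logf("image pipeline mean region AUC %.4f", metrics$mean_region_auc)

  baselines <- list()
  for (m in config$evaluate$baseline_methods %||% character(0)) {
    bl <- de_baseline_scores(expr, m, region_map)
    broc <- ovr_roc(bl, truth)
    readr::write_tsv(broc$auc,
                     file.path(out_dir, sprintf("auc_baseline_%s.tsv", m)))
    baselines[[m]] <- broc
    metrics[[paste0("mean_region_auc_", m)]] <- mean(broc$auc$auc)
    logf("baseline %s mean region AUC %.4f", m, mean(broc$auc$auc))
  }

  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  logf("done")
  invisible(list(out_dir = out_dir, corpus = corpus, encoder = encoder,
                 embeddings = embeddings, classifier = clf,
                 predictions = predictions, roc = roc, baselines = baselines,
                 metrics = metrics))
}
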