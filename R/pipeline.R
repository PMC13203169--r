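#' Configuration for an end-to-end phantom study run
#'
#' Bundles every stage of the desk-scale pipeline: phantom generation,
#' segmentation training, surface reconstruction, glenohumeral cropping,
#' multi-task classification, metric reports and the simulated rater-panel
#' agreement analysis. All stage seeds derive deterministically from the
#' master `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_train,n_val,n_test Phantom counts per split.
#' @param grid_shape,spacing,noise_sd,label_noise_p Phantom settings, see
#'   [phantom_config()].
#' @param seg Named list of [train_segmentation()] settings (`base_channels`,
#'   `depth`, `lr`, `max_epochs`, `patience`).
#' @param cls Named list of [train_classifier()] settings (`blocks`,
#'   `base_channels`, `projection`, `crop_size_mm`, `lr`, `max_epochs`,
#'   `patience`).
#' @param panel Named list: `n_raters`, `sensitivity_anatomical`,
#'   `sensitivity_reverse`, `bias_reverse`.
#' @param stages Stages to run, in order.
#' @param seed Master seed.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       n_train = 8L, n_val = 2L, n_test = 4L,
                       grid_shape = c(24L, 24L, 24L), spacing = c(2, 2, 2),
                       noise_sd = 0.03, label_noise_p = 0,
                       seg = list(depth = 3L, base_channels = 4L, lr = 2e-2,
                                  max_epochs = 4L, patience = 4L),
                       cls = list(blocks = 3L, base_channels = 4L,
                                  projection = 32L, crop_size_mm = 32,
                                  lr = 1e-2, max_epochs = 6L, patience = 6L),
                       panel = list(n_raters = 6L, sensitivity_anatomical = 0.6,
                                    sensitivity_reverse = 0.7, bias_reverse = 0.1),
                       stages = c("phantoms", "segmentation", "reconstruction",
                                  "classification", "agreement"),
                       seed = 1L) {
  structure(list(out_dir = out_dir, n_train = n_train, n_val = n_val,
                 n_test = n_test, grid_shape = grid_shape, spacing = spacing,
                 noise_sd = noise_sd, label_noise_p = label_noise_p,
                 seg = seg, cls = cls, panel = panel, stages = stages,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, force = TRUE), f)
  unname(tools::md5sum(f))
}

write_manifest <- function(dir, stage, inputs, cfg, seed) {
  jsonlite::write_json(list(stage = stage, inputs = inputs,
                            config_hash = config_hash(cfg), seed = seed),
                       file.path(dir, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

require_artifact <- function(path, stage) {
  if (!file.exists(path)) {
    stop(sprintf("stage '%s': missing artifact '%s' (run the earlier stages first)",
                 stage, path))
  }
  path
}

pipeline_phantom_set <- function(cfg, n, seed0) {
  lapply(seq_len(n), function(i) {
    s <- seed0 + i
    g <- with_seed(s, list(os = sample(0:2, 1), js = sample(0:2, 1),
                           hsa = sample(0:1, 1)))
    generate_phantom(phantom_config(
      grid_shape = cfg$grid_shape, spacing = cfg$spacing,
      os_grade = g$os, js_grade = g$js, hsa_grade = g$hsa,
      noise_sd = cfg$noise_sd, label_noise_p = cfg$label_noise_p, seed = s))
  })
}

#' Run the end-to-end phantom study pipeline
#'
#' Executes the configured stages in order, writing every artifact (NIfTI
#' volumes and masks, STL meshes, prediction CSVs, metric JSON reports,
#' ratings CSV and agreement JSON) plus a per-stage manifest with the inputs,
#' a config hash and the stage seed. Re-running with the same configuration
#' reproduces all CSV/JSON reports bitwise.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the run directory and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list(out_dir = cfg$out_dir)
  seed <- cfg$seed
  dirs <- list()
  for (st in c("phantoms", "segmentation", "reconstruction", "classification",
               "agreement")) {
    dirs[[st]] <- file.path(cfg$out_dir, st)
  }

  if ("phantoms" %in% cfg$stages) {
    dir.create(dirs$phantoms, showWarnings = FALSE)
    sets <- list(train = pipeline_phantom_set(cfg, cfg$n_train, seed * 1000L),
                 val = pipeline_phantom_set(cfg, cfg$n_val, seed * 1000L + 500L),
                 test = pipeline_phantom_set(cfg, cfg$n_test, seed * 1000L + 800L))
    lab_rows <- list()
    for (split in names(sets)) {
      for (i in seq_along(sets[[split]])) {
        cs <- sets[[split]][[i]]
        base <- sprintf("%s_%02d", split, i)
        write_volume(cs$image, file.path(dirs$phantoms, paste0(base, "_image.nii.gz")))
        write_volume(cs$labels, file.path(dirs$phantoms, paste0(base, "_labels.nii.gz")))
        lab_rows[[length(lab_rows) + 1L]] <- data.frame(
          case_id = base, split = split, os = cs$os_grade, js = cs$js_grade,
          hsa = cs$hsa_grade, implant = cs$implant)
      }
    }
    utils::write.csv(do.call(rbind, lab_rows),
                     file.path(dirs$phantoms, "labels.csv"), row.names = FALSE)
    write_manifest(dirs$phantoms, "phantoms", list(),
                   cfg[c("n_train", "n_val", "n_test", "grid_shape", "spacing",
                         "noise_sd", "label_noise_p")], seed)
    res$sets <- sets
  }

  if ("segmentation" %in% cfg$stages) {
    require_artifact(file.path(dirs$phantoms, "labels.csv"), "segmentation")
    dir.create(dirs$segmentation, showWarnings = FALSE)
    sets <- res$sets
    arch <- arch_config(depth = cfg$seg$depth, base_channels = cfg$seg$base_channels)
    fit <- train_segmentation(sets$train, sets$val, arch = arch,
                              lr = cfg$seg$lr, max_epochs = cfg$seg$max_epochs,
                              patience = cfg$seg$patience, seed = seed + 1L)
    save_model(model_from_state(fit$model), file.path(dirs$segmentation, "model.rds"))
    utils::write.csv(fit$history, file.path(dirs$segmentation, "history.csv"),
                     row.names = FALSE)
    seg_rows <- list()
    preds <- list()
    for (i in seq_along(sets$test)) {
      cs <- sets$test[[i]]
      pred <- predict_segmentation(fit, cs)
      preds[[i]] <- pred
      write_volume(pred$labels,
                   file.path(dirs$segmentation, sprintf("test_%02d_pred.nii.gz", i)))
      sm <- segmentation_metrics(pred$labels, cs$labels)
      seg_rows[[i]] <- data.frame(case_id = sprintf("test_%02d", i),
                                  dice = sm$mean_dice, jaccard = sm$mean_jaccard)
    }
    seg_df <- do.call(rbind, seg_rows)
    jsonlite::write_json(list(per_case = seg_df,
                              mean_dice = mean(seg_df$dice),
                              mean_jaccard = mean(seg_df$jaccard)),
                         file.path(dirs$segmentation, "metrics.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    write_manifest(dirs$segmentation, "segmentation",
                   list(phantoms = "phantoms/labels.csv"), cfg$seg, seed + 1L)
    res$seg_fit <- fit
    res$seg_preds <- preds
  }

  if ("reconstruction" %in% cfg$stages) {
    require_artifact(file.path(dirs$segmentation, "metrics.json"), "reconstruction")
    dir.create(dirs$reconstruction, showWarnings = FALSE)
    crops <- list()
    for (i in seq_along(res$seg_preds)) {
      lab <- res$seg_preds[[i]]$labels
      for (cl in c(1L, 2L)) {
        if (!any(as.array(lab) == cl)) next
        mesh <- reconstruct_mesh(lab, cl)
        write_stl(mesh, file.path(dirs$reconstruction,
                                  sprintf("test_%02d_class%d.stl", i, cl)))
      }
      gh <- extract_gh_region(lab, res$sets$test[[i]]$image,
                              crop_size_mm = cfg$cls$crop_size_mm)
      write_volume(gh$image_crop,
                   file.path(dirs$reconstruction, sprintf("test_%02d_gh.nii.gz", i)))
      crops[[i]] <- gh
    }
    write_manifest(dirs$reconstruction, "reconstruction",
                   list(segmentation = "segmentation/metrics.json"),
                   cfg$cls["crop_size_mm"], seed)
    res$gh_crops <- crops
  }

  if ("classification" %in% cfg$stages) {
    require_artifact(file.path(dirs$phantoms, "labels.csv"), "classification")
    dir.create(dirs$classification, showWarnings = FALSE)
    ccfg <- cls_config(blocks = cfg$cls$blocks,
                       base_channels = cfg$cls$base_channels,
                       projection = cfg$cls$projection)
    cases_tr <- c(res$sets$train, res$sets$val)
    fit <- train_classifier(cases_tr, val_cases = NULL, cfg = ccfg,
                            crop_size_mm = cfg$cls$crop_size_mm,
                            lr = cfg$cls$lr, max_epochs = cfg$cls$max_epochs,
                            patience = cfg$cls$patience, seed = seed + 2L)
    save_model(model_from_state(fit$model), file.path(dirs$classification, "model.rds"))
    rows <- list()
    for (i in seq_along(res$sets$test)) {
      cs <- res$sets$test[[i]]
      pr <- predict_classifier(fit, cs, crop_size_mm = cfg$cls$crop_size_mm)
      pred <- attr(pr, "predicted")
      rows[[i]] <- data.frame(case_id = sprintf("test_%02d", i),
                              os = cs$os_grade, js = cs$js_grade,
                              hsa = cs$hsa_grade, implant = cs$implant,
                              os_pred = pred[["OS"]], js_pred = pred[["JS"]],
                              hsa_pred = pred[["HSA"]], implant_pred = pred[["IT"]])
    }
    df <- do.call(rbind, rows)
    utils::write.csv(df, file.path(dirs$classification, "predictions.csv"),
                     row.names = FALSE)
    acc <- vapply(c(os = "os", js = "js", hsa = "hsa", implant = "implant"),
                  function(cl) mean(df[[cl]] == df[[paste0(cl, "_pred")]]),
                  numeric(1))
    jsonlite::write_json(as.list(acc), file.path(dirs$classification, "metrics.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    write_manifest(dirs$classification, "classification",
                   list(phantoms = "phantoms/labels.csv"), cfg$cls, seed + 2L)
    res$cls_fit <- fit
    res$cls_preds <- df
  }

  if ("agreement" %in% cfg$stages) {
    require_artifact(file.path(dirs$classification, "predictions.csv"), "agreement")
    dir.create(dirs$agreement, showWarnings = FALSE)
    test_cases <- res$sets$test
    profiles <- replicate(cfg$panel$n_raters,
                          rater_profile(cfg$panel$sensitivity_anatomical,
                                        cfg$panel$sensitivity_reverse,
                                        cfg$panel$bias_reverse),
                          simplify = FALSE)
    ratings <- generate_rater_panel(test_cases, profiles, seed = seed + 3L)
    write_ratings_csv(ratings, file.path(dirs$agreement, "ratings.csv"))
    counts <- ratings_to_counts(ratings, categories = 0:1)
    kap <- tryCatch(fleiss_kappa(counts), warning = function(w) fleiss_kappa(counts))
    ent <- panel_entropy(ratings)
    truth <- attr(ratings, "truth")
    model_correct <- res$cls_preds$implant == res$cls_preds$implant_pred
    majority <- as.integer(rowSums(ratings == 1L) > ncol(ratings) / 2)
    mcn <- mcnemar_test(model_correct, majority == truth)
    out <- list(kappa = kap$kappa, po = kap$po, pe = kap$pe,
                entropy = ent,
                mcnemar_model_vs_majority = mcn[c("b", "c", "p_value")])
    if (length(unique(truth)) >= 2L && length(truth) >= 10L) {
      vc <- virtual_consensus(ratings, truth, folds = min(5L, floor(length(truth) / 2)),
                              seed = seed + 4L)
      out$virtual_consensus_accuracy <- vc$accuracy
    }
    jsonlite::write_json(out, file.path(dirs$agreement, "agreement.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    write_manifest(dirs$agreement, "agreement",
                   list(classification = "classification/predictions.csv"),
                   cfg$panel, seed + 3L)
    res$agreement <- out
  }

  invisible(res)
}
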