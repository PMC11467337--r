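#' Run the full screening pipeline
#'
#' Executes the stages in order -- simulate (cohort manifest + rendered
#' tomograms), measure (morphometry), stats (group comparison), train
#' (classifier), predict, screen (patient-level ROC) -- writing each stage's
#' artifacts under `cfg$out_dir` together with the configuration and seed.
#' Any stage failure halts with an error naming the stage; artifacts of
#' completed stages are preserved.
#'
#' All randomness derives from `cfg$seed` through named per-stage
#' substreams, so reruns with the same configuration reproduce the
#' manifests, morphometry and statistics tables byte for byte (training is
#' reproducible up to floating-point summation order).
#'
#' @param cfg A [pipeline_config()].
#' @param stages Subset of stages to run (default all, in order).
#' @param verbose Print stage progress.
#' @return Invisible list with the principal artifacts (manifest,
#'   morphometry, comparisons, model, predictions, screening).
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "measure", "stats",
                                         "train", "predict", "screen"),
                         verbose = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  validate_pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  save_config(cfg, file.path(cfg$out_dir, "config.yaml"))
  say <- function(...) if (verbose) message("[holoblast] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  art <- list()

  wt <- do.call(group_params, c(list("WT"), cfg$wt_overrides))
  mut <- do.call(group_params, c(list("MUT"), cfg$mut_overrides))
  if (!is.null(cfg$n_images_per_group)) {
    wt$image_count <- as.integer(cfg$n_images_per_group$WT)
    mut$image_count <- as.integer(cfg$n_images_per_group$MUT)
  }
  if (!is.null(cfg$n_patients)) {
    wt$patient_count <- as.integer(cfg$n_patients$WT)
    mut$patient_count <- as.integer(cfg$n_patients$MUT)
  }

  if ("simulate" %in% stages) {
    say("simulate: cohort manifest and tomograms")
    art$cohort <- stage("simulate", {
      n_val_img <- max(2L, round(333 / 2073 *
                                   (wt$image_count + mut$image_count)))
      n_val_pat <- max(1L, min(4L, wt$patient_count - 1L,
                               mut$patient_count - 1L))
      cohort <- generate_cohort(wt, mut, seed = cfg$seed,
                                n_validation_patients = n_val_pat,
                                n_validation_images = n_val_img)
      manifest <- render_cohort(cohort, file.path(cfg$out_dir, "tomograms"),
                                seed = cfg$seed, grid_dim = cfg$grid_dim,
                                voxel_spacing = cfg$voxel_spacing,
                                medium_ri = cfg$medium_ri,
                                noise_sd = cfg$noise_sd)
      write_manifest(manifest, file.path(cfg$out_dir, "manifest.csv"))
      list(manifest = manifest, specs = cohort$specs)
    })
  }

  if ("measure" %in% stages) {
    say("measure: morphometry per cell")
    art$morpho <- stage("measure", {
      manifest <- art$cohort$manifest %||%
        read_manifest(file.path(cfg$out_dir, "manifest.csv"))
      rows <- lapply(seq_len(nrow(manifest)), function(i) {
        td <- read_tomogram(manifest$image_path[i], with_mask = TRUE)
        msk <- td$mask %||%
          segment_rule_based(td$tomogram,
                             segment_params(noise_sd = cfg$noise_sd))
        dplyr::bind_cols(
          tibble::tibble(image_id = manifest$image_id[i]),
          measure_cell(td$tomogram, msk, alpha = cfg$alpha))
      })
      morpho <- dplyr::bind_rows(rows)
      readr::write_csv(morpho, file.path(cfg$out_dir, "morphometry.csv"))
      morpho
    })
  }

  if ("stats" %in% stages) {
    say("stats: group comparisons")
    art$comparisons <- stage("stats", {
      manifest <- art$cohort$manifest %||%
        read_manifest(file.path(cfg$out_dir, "manifest.csv"))
      morpho <- art$morpho %||%
        readr::read_csv(file.path(cfg$out_dir, "morphometry.csv"),
                        show_col_types = FALSE)
      joined <- dplyr::left_join(
        morpho, dplyr::select(manifest, "image_id", "genotype"),
        by = "image_id")
      cmp <- compare_groups(dplyr::select(joined, -"image_id"),
                            genotype = "genotype")
      readr::write_csv(cmp, file.path(cfg$out_dir, "comparisons.csv"))
      cmp
    })
  }

  model <- NULL
  if ("train" %in% stages) {
    say("train: classifier")
    art$model <- model <- stage("train", {
      manifest <- art$cohort$manifest %||%
        read_manifest(file.path(cfg$out_dir, "manifest.csv"))
      trn <- manifest[manifest$split %in% c("optimization",
                                            "generalization"), ]
      vols <- lapply(stats::setNames(trn$image_path, trn$image_id),
                     function(p) read_tomogram(p)$ri)
      tc <- do.call(train_config,
                    c(list(seed = derive_seed(cfg$seed, "train")),
                      cfg$train))
      arch <- if (cfg$arch_preset == "tiny")
        arch_tiny(input_shape = cfg$grid_dim)
      else arch_config(input_shape = cfg$grid_dim)
      m <- train_classifier(vols,
                            stats::setNames(trn$genotype, trn$image_id),
                            stats::setNames(trn$split, trn$image_id),
                            arch, tc, normalize = TRUE,
                            medium_ri = cfg$medium_ri)
      saveRDS(m, file.path(cfg$out_dir, "model.rds"))
      readr::write_csv(m$history, file.path(cfg$out_dir,
                                            "training_history.csv"))
      m
    })
  }

  if ("predict" %in% stages) {
    say("predict: single-cell genotype calls")
    art$predictions <- stage("predict", {
      manifest <- art$cohort$manifest %||%
        read_manifest(file.path(cfg$out_dir, "manifest.csv"))
      if (is.null(model))
        model <- readRDS(file.path(cfg$out_dir, "model.rds"))
      val <- manifest[manifest$split == "validation", ]
      vols <- lapply(stats::setNames(val$image_path, val$image_id),
                     function(p) read_tomogram(p)$ri)
      preds <- predict_classifier(model, vols, normalize = TRUE,
                                  medium_ri = cfg$medium_ri)
      preds <- dplyr::left_join(
        preds,
        dplyr::select(val, "image_id", "patient_id", "genotype"),
        by = "image_id")
      readr::write_csv(preds, file.path(cfg$out_dir, "predictions.csv"))
      preds
    })
  }

  if ("screen" %in% stages) {
    say("screen: patient-level ROC")
    art$screening <- stage("screen", {
      preds <- art$predictions %||%
        readr::read_csv(file.path(cfg$out_dir, "predictions.csv"),
                        show_col_types = FALSE)
      sc <- screen_patients(preds)
      readr::write_csv(sc$patients, file.path(cfg$out_dir, "patients.csv"))
      readr::write_csv(sc$roc$points, file.path(cfg$out_dir,
                                                "roc_points.csv"))
      jsonlite::write_json(
        list(auc = sc$roc$auc,
             tpr_at_zero_fpr = sc$operating_points$tpr_at_zero_fpr,
             fpr_at_full_tpr = sc$operating_points$fpr_at_full_tpr),
        file.path(cfg$out_dir, "screening.json"), auto_unbox = TRUE,
        digits = NA)
      sc
    })
  }
  say("done")
  invisible(art)
}
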