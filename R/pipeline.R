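#' Configuration for a full texture-analysis run
#'
#' Bundles every stage's settings. All stochastic stages draw their seeds
#' deterministically from `master_seed`, so a run is reproducible end to end
#' from the config alone.
#'
#' @param input_mode `"synthetic"` (generate micrographs) or `"directory"`
#'   (read rasters from disk).
#' @param n_per_group,grades,params Synthetic-mode settings; see
#'   [generate_micrograph_set()]. The default generates 500 images per group
#'   at the 300-pixel ROI size for the native-versus-fully-decellularized
#'   contrast.
#' @param input_dir,labels_csv Directory-mode settings: a folder of
#'   PNG/TIFF/BMP rasters and a CSV with columns `file`, `label`.
#' @param rois_per_image Number of ROIs drawn per image (default 1).
#' @param roi_size ROI side length; `NULL` (default) uses each full image as
#'   one ROI.
#' @param allow_overlap May ROIs from one image overlap? Default `TRUE`.
#' @param bits,offset,symmetric,wavelet Feature settings; see
#'   [texture_features()].
#' @param comparisons,control,adjust Group-statistics settings; see
#'   [kw_dunn_test()].
#' @param models,positive,train_fraction,folds,hyperparams Classifier
#'   settings; see [evaluate_classifiers()]. Classification runs only when
#'   exactly two groups are present.
#' @param master_seed Integer master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input_mode = c("synthetic", "directory"),
                            n_per_group = 500L,
                            grades = c("native", "g4"),
                            params = stroma_params(size = 300L),
                            input_dir = NULL,
                            labels_csv = NULL,
                            rois_per_image = 1L,
                            roi_size = NULL,
                            allow_overlap = TRUE,
                            bits = 8L,
                            offset = c(0L, 1L),
                            symmetric = FALSE,
                            wavelet = "haar",
                            comparisons = "all",
                            control = "native",
                            adjust = "bonferroni",
                            models = c("rf", "svm"),
                            positive = NULL,
                            train_fraction = 0.8,
                            folds = 5L,
                            hyperparams = list(),
                            master_seed = 1L) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "directory" && (is.null(input_dir) || is.null(labels_csv))) {
    abort_validation("Directory mode needs `input_dir` and `labels_csv`.")
  }
  structure(
    list(
      input_mode = input_mode, n_per_group = as.integer(n_per_group),
      grades = grades, params = params, input_dir = input_dir,
      labels_csv = labels_csv, rois_per_image = as.integer(rois_per_image),
      roi_size = if (is.null(roi_size)) NULL else as.integer(roi_size),
      allow_overlap = allow_overlap, bits = as.integer(bits),
      offset = as.integer(offset), symmetric = symmetric, wavelet = wavelet,
      comparisons = comparisons, control = control, adjust = adjust,
      models = models, positive = positive,
      train_fraction = train_fraction, folds = as.integer(folds),
      hyperparams = hyperparams, master_seed = as.integer(master_seed)
    ),
    class = "pipeline_config"
  )
}

load_image_directory <- function(input_dir, labels_csv) {
  if (!dir.exists(input_dir)) abort_io(sprintf("Input directory not found: '%s'.", input_dir))
  if (!file.exists(labels_csv)) abort_io(sprintf("Labels CSV not found: '%s'.", labels_csv))
  labels <- readr::read_csv(labels_csv, show_col_types = FALSE)
  if (!all(c("file", "label") %in% names(labels))) {
    abort_validation("Labels CSV must have columns 'file' and 'label'.")
  }
  tibble::tibble(
    image_id = tools::file_path_sans_ext(basename(labels$file)),
    label = as.character(labels$label),
    image = purrr::map(file.path(input_dir, labels$file), read_micrograph)
  )
}

stats_report_list <- function(tests) {
  purrr::pmap(tests, function(feature, statistic, df, p.value, n, pairwise) {
    list(
      feature = feature, H = statistic, df = df, p = p.value, n = n,
      pairwise = purrr::pmap(pairwise, function(group1, group2, z, p, p_adj) {
        list(pair = paste(group1, group2, sep = " vs "), z = z, p = p, p_adj = p_adj)
      })
    )
  })
}

#' Run the full texture-analysis pipeline
#'
#' Executes, in order: image acquisition (synthetic generation or directory
#' ingestion), ROI extraction, per-ROI feature computation, per-feature
#' group statistics, and (for two-group data) classifier training and
#' evaluation. Writes `features.csv`, `stats.json`, one
#' `report_<model>.json` and `roc_<model>.csv` per classifier, and
#' `manifest.json` with the config snapshot, stage counts and MD5 checksums
#' of every output. Identical configs reproduce identical checksums.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Writable output directory (created if missing).
#' @return The run manifest, invisibly (class `run_manifest`).
#' @export
run_texture_pipeline <- function(config, output_dir) {
  if (!inherits(config, "pipeline_config")) {
    abort_validation("`config` must be created with pipeline_config().")
  }
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seed_images <- derive_seed(config$master_seed, 1L)
  seed_rois <- derive_seed(config$master_seed, 2L)
  seed_ml <- derive_seed(config$master_seed, 3L)

  images <- if (config$input_mode == "synthetic") {
    rlang::inform(sprintf(
      "[images] generating %d synthetic micrographs per grade (%s), size %d",
      config$n_per_group, paste(config$grades, collapse = ", "), config$params$size
    ))
    generate_micrograph_set(config$n_per_group, config$grades,
                            config$params, seed = seed_images)
  } else {
    rlang::inform(sprintf("[images] reading rasters from '%s'", config$input_dir))
    load_image_directory(config$input_dir, config$labels_csv)
  }

  rois <- if (is.null(config$roi_size)) {
    NULL  # one full-frame ROI per image
  } else {
    purrr::imap_dfr(images$image, function(img, i) {
      extract_rois(img, n = config$rois_per_image, size = config$roi_size,
                   seed = derive_seed(seed_rois, i),
                   allow_overlap = config$allow_overlap,
                   image_id = images$image_id[i], label = images$label[i])
    })
  }
  n_rois <- if (is.null(rois)) nrow(images) else nrow(rois)
  rlang::inform(sprintf("[rois] %d regions of interest", n_rois))

  features <- compute_feature_table(
    images, rois = if (is.null(rois)) NULL else rois[, c("image_id", "row0", "col0", "size")],
    bits = config$bits, offset = config$offset,
    symmetric = config$symmetric, wavelet = config$wavelet
  )
  dropped <- n_rois - nrow(features)
  features_path <- file.path(output_dir, "features.csv")
  readr::write_csv(features, features_path)
  rlang::inform(sprintf("[features] %d rows written (%d dropped)", nrow(features), dropped))

  outputs <- c(features = features_path)
  n_groups <- length(unique(features$label))

  if (n_groups >= 2L) {
    tests <- feature_group_tests(
      features, group = "label", comparisons = config$comparisons,
      control = if (config$comparisons == "versus-control") config$control else NULL,
      adjust = config$adjust
    )
    stats_path <- file.path(output_dir, "stats.json")
    jsonlite::write_json(stats_report_list(tests), stats_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- c(outputs, stats = stats_path)
    rlang::inform(sprintf("[stats] %d features tested across %d groups", nrow(tests), n_groups))
  }

  if (n_groups == 2L) {
    report <- evaluate_classifiers(
      features, models = config$models, positive = config$positive,
      train_fraction = config$train_fraction, folds = config$folds,
      seed = seed_ml, hyperparams = config$hyperparams
    )
    for (m in report$models) {
      rp <- file.path(output_dir, sprintf("report_%s.json", m$model_name))
      jsonlite::write_json(
        list(model = m$model_name, test_accuracy = m$test_accuracy,
             cv_accuracy = m$cv_accuracy, auc = m$auc,
             roc = purrr::pmap(m$roc, function(threshold, fpr, tpr) {
               list(fpr = fpr, tpr = tpr)
             }),
             hyperparams = m$hyperparams, seed = report$seed),
        rp, auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      rc <- file.path(output_dir, sprintf("roc_%s.csv", m$model_name))
      readr::write_csv(m$roc, rc)
      outputs <- c(outputs, stats::setNames(c(rp, rc), paste0(c("report_", "roc_"), m$model_name)))
      rlang::inform(sprintf(
        "[ml] %s: test accuracy %.3f, CV accuracy %.3f, AUC %.3f",
        toupper(m$model_name), m$test_accuracy, m$cv_accuracy, m$auc
      ))
    }
  }

  manifest <- list(
    tool = "stromatex",
    version = as.character(utils::packageVersion("stromatex")),
    config = config_snapshot(config),
    counts = list(images = nrow(images), rois = n_rois,
                  feature_rows = nrow(features), dropped_rois = dropped,
                  groups = n_groups),
    outputs = lapply(stats::setNames(nm = names(outputs)), function(k) {
      list(path = basename(outputs[[k]]),
           md5 = unname(tools::md5sum(outputs[[k]])))
    })
  )
  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(structure(manifest, class = "run_manifest"))
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$params <- unclass(snap$params)
  snap[!vapply(snap, is.null, logical(1))]
}

#' Re-run the group statistics on an existing feature CSV
#'
#' @param features_csv Path to a `features.csv` written by
#'   [run_texture_pipeline()] (or any CSV with a `label` column and at least
#'   one texture feature column).
#' @param output_path Where to write the JSON report (default: next to the
#'   input as `stats.json`).
#' @param comparisons,control,adjust See [kw_dunn_test()].
#' @return The output path, invisibly.
#' @export
run_stats_only <- function(features_csv,
                           output_path = file.path(dirname(features_csv), "stats.json"),
                           comparisons = "all", control = NULL,
                           adjust = "bonferroni") {
  if (!file.exists(features_csv)) {
    abort_io(sprintf("Feature CSV not found: '%s'.", features_csv))
  }
  features <- readr::read_csv(features_csv, show_col_types = FALSE)
  feats <- intersect(texture_feature_names(), names(features))
  if (!"label" %in% names(features) || length(feats) == 0L) {
    abort_validation(sprintf(
      "Feature CSV must have a 'label' column and feature columns among: %s.",
      paste(texture_feature_names(), collapse = ", ")
    ))
  }
  if (length(unique(features$label)) < 2L) {
    abort_validation("Feature CSV must contain at least two groups.")
  }
  tests <- feature_group_tests(features, features = feats, group = "label",
                               comparisons = comparisons, control = control,
                               adjust = adjust)
  jsonlite::write_json(stats_report_list(tests), output_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_path)
}
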