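#' Pipeline configuration
#'
#' One validated object holds every tunable the convert -> reduce -> detect
#' -> evaluate chain uses. The detector-training hyperparameters
#' (`batch_size`, `learning_rate`, `training_steps`) are recorded for
#' provenance only; network training is outside this package and they are
#' never exercised.
#'
#' @param modality `"wli"` or `"nbi"`.
#' @param representation what the scorer consumes: `"rgb"`, `"spectrum"`,
#'   or `"pca"`.
#' @param degree,ridge,transfer conversion-fit settings
#'   (see [spectral_calibration()]).
#' @param pca_k components kept by the reduction (default 3).
#' @param match_threshold IoU threshold for box matching (default 0.5).
#' @param nms_threshold per-stage NMS threshold (default 0.45).
#' @param score_floor image-level call floor (default 0.5).
#' @param alpha multibox-loss localization weight (default 1).
#' @param seed RNG seed for the synthetic inputs and the scorer.
#' @param n_per_stage synthetic test-set size per stage (default 5).
#' @param scene_size synthetic scene side length in pixels (default 48).
#' @param confusion_rate stub-scorer mislabel probability (default 0).
#' @param batch_size,learning_rate,training_steps recorded training
#'   defaults (32, 5e-4, 80000); not used by any computation here.
#' @return object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(modality = c("wli", "nbi"),
                            representation = c("spectrum", "rgb", "pca"),
                            degree = 3, ridge = 1e-6, transfer = "srgb",
                            pca_k = 3, match_threshold = 0.5,
                            nms_threshold = 0.45, score_floor = 0.5,
                            alpha = 1, seed = 1, n_per_stage = 5,
                            scene_size = 48, confusion_rate = 0,
                            batch_size = 32, learning_rate = 5e-4,
                            training_steps = 80000) {
  modality <- match.arg(modality)
  representation <- match.arg(representation)
  bad <- character(0)
  chk <- function(ok, field) if (!ok) bad <<- c(bad, field)
  chk(match_threshold > 0 && match_threshold < 1, "match_threshold")
  chk(nms_threshold > 0 && nms_threshold < 1, "nms_threshold")
  chk(score_floor >= 0 && score_floor <= 1, "score_floor")
  chk(alpha >= 0, "alpha")
  chk(degree >= 1, "degree")
  chk(ridge >= 0, "ridge")
  chk(pca_k >= 1, "pca_k")
  chk(n_per_stage >= 1, "n_per_stage")
  chk(scene_size >= 8, "scene_size")
  chk(confusion_rate >= 0 && confusion_rate <= 1, "confusion_rate")
  if (length(bad)) {
    stop("invalid pipeline config field(s): ", paste(bad, collapse = ", "))
  }
  structure(list(modality = modality, representation = representation,
                 degree = degree, ridge = ridge, transfer = transfer,
                 pca_k = pca_k, match_threshold = match_threshold,
                 nms_threshold = nms_threshold, score_floor = score_floor,
                 alpha = alpha, seed = seed, n_per_stage = n_per_stage,
                 scene_size = scene_size, confusion_rate = confusion_rate,
                 batch_size = batch_size, learning_rate = learning_rate,
                 training_steps = training_steps),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("pipeline config: %s / %s, degree %d, seed %s (hash %s)\n",
              toupper(x$modality), x$representation, x$degree,
              format(x$seed), config_hash(x)))
  invisible(x)
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @return `config_hash()`: md5 of the configuration.
#' @export
config_hash <- function(config) object_hash(unclass(config))

#' Run the full synthetic evaluation pipeline
#'
#' Generates a balanced synthetic test set, fits the RGB -> spectrum
#' conversion on the synthetic color target seen through the configured
#' camera, reconstructs the scene spectra, fits the principal-component
#' basis on them, scores every image (ground-truth stub by default),
#' and evaluates the image-level calls against the truth. Deterministic:
#' the same config yields bit-identical metrics.
#'
#' @param config a [pipeline_config()].
#' @param testset optional pre-built [make_test_set()] set (default:
#'   generated from the config).
#' @param scorer optional scorer function (default: [stub_scorer()] with the
#'   config's `confusion_rate` and seed).
#' @return list of class `"pipeline_result"`: `config`, `config_hash`,
#'   `calibration`, `pca`, `calls` (per-image truth/predicted),
#'   `confusion`, `metrics`, `reconstruction_rmse` (median per-pixel RMSE
#'   of the first scene, truth vs reconstruction).
#' @export
run_pipeline <- function(config, testset = NULL, scorer = NULL) {
  assert_that(inherits(config, "pipeline_config"), "need a pipeline_config")
  camera <- camera_model(config$modality, transfer = config$transfer)
  tissue <- tissue_spectrum_model(seed = config$seed)
  if (is.null(testset)) {
    testset <- make_test_set(config$n_per_stage, seed = config$seed,
                             camera = camera, tissue = tissue,
                             width = config$scene_size,
                             height = config$scene_size)
  }
  target <- make_color_target(seed = config$seed)
  cal <- spectral_calibration(capture_color_target(target, camera),
                              target, degree = config$degree,
                              ridge = config$ridge,
                              transfer = config$transfer)
  ## reconstruction + reduction on a reference scene (the spectral branch)
  pca <- NULL
  recon_rmse <- NA_real_
  if (config$representation %in% c("spectrum", "pca")) {
    sc <- scene_spec(config$scene_size, config$scene_size,
                     lesions = list(), seed = config$seed)
    truth_scene <- render_scene(sc, tissue, camera)
    recon <- predict(cal, matrix(truth_scene$image,
                                 ncol = 3), modality = config$modality)
    true_sp <- as.matrix(truth_scene$cube)
    ok <- !as.vector(truth_scene$clipped)
    recon_rmse <- median(sqrt(rowMeans((recon[ok, , drop = FALSE] -
                                          true_sp[ok, , drop = FALSE])^2)))
    if (config$representation == "pca") {
      pca <- spectral_pca(true_sp, k = config$pca_k)
    }
  }
  if (is.null(scorer)) {
    scorer <- stub_scorer(confusion_rate = config$confusion_rate,
                          seed = config$seed)
  }
  calls <- detect_images(testset, scorer, score_floor = config$score_floor,
                         nms_threshold = config$nms_threshold)
  confusion <- confusion_from_calls(calls$truth, calls$predicted,
                                    modality = config$modality,
                                    representation = config$representation)
  structure(list(config = config, config_hash = config_hash(config),
                 calibration = cal, pca = pca, calls = calls,
                 confusion = confusion, metrics = metrics_table(confusion),
                 reconstruction_rmse = recon_rmse),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result (config", x$config_hash, ")\n")
  print(x$metrics)
  invisible(x)
}

#' Compare RGB and spectrum representations side by side
#'
#' Puts two evaluations of the same modality — typically RGB images versus
#' reconstructed spectra — next to each other and reports the accuracy and
#' kappa deltas (on the rounded reported values, spectrum minus RGB).
#'
#' @param rgb,spectrum two [staging_confusion] matrices or
#'   [run_pipeline()] results. When results are given, their configs must
#'   differ only in `representation`.
#' @return list of class `"representation_comparison"`: `table` (data.frame
#'   with accuracy/kappa per representation), `accuracy_delta`,
#'   `kappa_delta`.
#' @export
compare_representations <- function(rgb, spectrum) {
  as_conf <- function(x) {
    if (inherits(x, "pipeline_result")) return(x$confusion)
    check_nonempty(x)
    x
  }
  if (inherits(rgb, "pipeline_result") &&
        inherits(spectrum, "pipeline_result")) {
    a <- unclass(rgb$config); b <- unclass(spectrum$config)
    a$representation <- b$representation <- NULL
    if (!identical(a, b)) {
      stop("configs must differ only in their representation")
    }
  }
  ma <- metrics_table(as_conf(rgb))
  mb <- metrics_table(as_conf(spectrum))
  rep_of <- function(m, default) {
    if (is.null(m$representation) || is.na(m$representation)) default
    else m$representation
  }
  tab <- data.frame(
    representation = c(rep_of(ma, "rgb"), rep_of(mb, "spectrum")),
    total = c(ma$total, mb$total),
    accuracy_pct = c(ma$accuracy_pct, mb$accuracy_pct),
    kappa = c(ma$kappa_2dp, mb$kappa_2dp)
  )
  structure(list(table = tab,
                 accuracy_delta = mb$accuracy_pct - ma$accuracy_pct,
                 kappa_delta = round_half_up(mb$kappa_2dp - ma$kappa_2dp, 2),
                 metrics = list(rgb = ma, spectrum = mb)),
            class = "representation_comparison")
}

#' @export
print.representation_comparison <- function(x, ...) {
  cat("representation comparison\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("accuracy delta: %+d pp   kappa delta: %+.2f\n",
              x$accuracy_delta, x$kappa_delta))
  invisible(x)
}
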