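# End-to-end orchestration: phantom generation (or NIfTI ingest), feature
# extraction, network training, fusion and cross-validated evaluation, with
# digest-keyed stage caching and a run manifest.

#' Pipeline configuration
#'
#' Nested configuration for [runPipeline()].  All stage randomness derives
#' from the single `seed` via per-stage seeds, so a run is reproducible end
#' to end.
#'
#' @param seed master seed.
#' @param out_dir output directory (created if missing).
#' @param synth a [phantomSpec()] describing the dataset.
#' @param filter optional [filterConfig()] applied during preprocessing.
#' @param resize in-plane grid every preprocessed sample is resized to.
#' @param radiomics a [radiomicsConfig()].
#' @param network list with `depth_scale`, `epochs`, `batch_size`, `fc_dim`,
#'   `channels` (stage channel widths).
#' @param classify list with `n_folds` and `kernels`.
#' @return list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1L, out_dir = tempfile("fusionrad_run_"),
                           synth = phantomSpec(n_samples = 50L,
                                               shape = c(32L, 32L),
                                               seed = deriveSeed(seed, "synth")),
                           filter = NULL,
                           resize = c(32L, 32L),
                           radiomics = radiomicsConfig(ng = 16L),
                           network = list(depth_scale = 0.25, epochs = 3L,
                                          batch_size = 10L, fc_dim = 64L,
                                          channels = c(16L, 24L, 32L, 24L, 16L)),
                           classify = list(n_folds = 5L,
                                           kernels = c("linear", "polynomial",
                                                       "rbf"))) {
  structure(list(seed = as.integer(seed), out_dir = out_dir, synth = synth,
                 filter = filter, resize = as.integer(resize),
                 radiomics = radiomics, network = network,
                 classify = classify),
            class = "PipelineConfig")
}

# run one cached stage: key on the stage config + input digests
.stage <- function(name, key_parts, out_dir, manifest, fn) {
  key <- .digestObject(key_parts)
  path <- file.path(out_dir, sprintf("stage_%s_%s.rds", name, key))
  if (file.exists(path)) {
    value <- readRDS(path)
    cached <- TRUE
  } else {
    value <- fn()
    saveRDS(value, path, version = 2)
    cached <- FALSE
  }
  manifest$stages[[name]] <- list(key = key, output_digest = .digestFile(path),
                                  cached = cached,
                                  timestamp = format(Sys.time(), tz = "UTC"))
  list(value = value, manifest = manifest)
}

#' Run the full phantom pipeline
#'
#' Stages: phantom generation, preprocessing, network training on the
#' preprocessed samples, deep-feature extraction, radiomics extraction on
#' the original intensities, fusion, and cross-validated evaluation of the
#' radiomics-only, deep-only and fused feature sets.  Stage outputs are
#' cached in `out_dir` keyed by the digest of their configuration and
#' inputs, so deleting one cached stage output reruns only that stage and
#' (when its output changes) its descendants.
#'
#' @param config a [pipelineConfig()].
#' @return the run manifest (invisibly also written as `manifest.json`),
#'   including the evaluation report written to `metrics.json`.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_digest = .digestObject(unclass(config)),
                   seed = config$seed,
                   package_version = as.character(utils::packageVersion("fusionrad")),
                   stages = list())

  r <- .stage("synth", list(config$synth), config$out_dir, manifest,
              function() generatePhantoms(config$synth))
  phantoms <- r$value; manifest <- r$manifest

  r <- .stage("preprocess", list(config$filter, config$resize,
                                 manifest$stages$synth$output_digest),
              config$out_dir, manifest, function() {
    lapply(phantoms, function(ph)
      preprocessVolume(sampleImage(ph), mask = sampleMask(ph),
                       label = sampleLabel(ph),
                       filter = config$filter,
                       resize = config$resize)$sample)
  })
  prepped <- r$value; manifest <- r$manifest

  r <- .stage("train", list(config$network,
                            manifest$stages$preprocess$output_digest),
              config$out_dir, manifest, function() {
    d <- dim(sampleImage(prepped[[1]]))
    ncfg <- config$network
    plan <- data.frame(blocks = c(6L, 8L, 12L, 8L, 3L),
                       channels = ncfg$channels,
                       change = c("down", "down", "down", "up", "none"))
    net <- buildFusionNet(fusionNetConfig(in_channels = d[1],
                                          stage_plan = plan,
                                          fc_dim = ncfg$fc_dim,
                                          depth_scale = ncfg$depth_scale))
    trainFusionNet(net, prepped,
                   config = trainConfig(max_epochs = ncfg$epochs,
                                        batch_size = ncfg$batch_size,
                                        seed = deriveSeed(config$seed, "train")))
  })
  net <- r$value; manifest <- r$manifest

  r <- .stage("deep_features", list(manifest$stages$train$output_digest),
              config$out_dir, manifest, function() {
    feats <- extractDeepFeatures(net, prepped)
    colnames(feats) <- sprintf("deep_%03d", seq_len(ncol(feats)))
    data.frame(sample_id = sprintf("S%04d", seq_along(prepped)), feats,
               label = sampleLabels(prepped), check.names = FALSE)
  })
  deep_tab <- r$value; manifest <- r$manifest

  r <- .stage("radiomics", list(config$radiomics,
                                manifest$stages$synth$output_digest),
              config$out_dir, manifest,
              function() radiomicsTable(phantoms, config$radiomics))
  rad_tab <- r$value; manifest <- r$manifest

  r <- .stage("evaluate", list(config$classify,
                               manifest$stages$deep_features$output_digest,
                               manifest$stages$radiomics$output_digest),
              config$out_dir, manifest, function() {
    fused <- fuseFeatures(deep_tab, rad_tab)
    seed_cv <- deriveSeed(config$seed, "cv")
    labels <- rad_tab$label
    plan <- cvPlan(labels, config$classify$n_folds, seed_cv)
    list(radiomics = crossValidate(rad_tab, plan = plan,
                                   kernels = config$classify$kernels),
         deep = crossValidate(deep_tab, plan = plan,
                              kernels = config$classify$kernels),
         fused = crossValidate(fused, plan = plan,
                               kernels = config$classify$kernels))
  })
  evals <- r$value; manifest <- r$manifest

  metrics <- lapply(evals, function(e)
    list(mean = as.list(e$aggregate$mean), sd = as.list(e$aggregate$sd),
         selected_kernels = e$selected))
  jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeFeatureTable(rad_tab, file.path(config$out_dir, "radiomics.csv"))
  writeFeatureTable(deep_tab, file.path(config$out_dir, "deep.csv"))
  manifest$metrics <- metrics
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
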