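#' Default run configuration
#'
#' The single nested configuration object behind the command-line entry
#' points: dataset paths, the synthetic federation spec, training
#' hyperparameters and evaluation options. Fully serializable to YAML;
#' replaying an archived config reproduces all deterministic outputs.
#'
#' @param dataRoot dataset directory.
#' @param outDir output directory for checkpoints, histories and reports.
#' @param seed global seed.
#' @return Nested list of class \code{"RunConfig"}.
#' @export
defaultRunConfig <- function(dataRoot = "data", outDir = "out", seed = 1) {
  structure(list(
    paths = list(data_root = dataRoot, out_dir = outDir),
    seed = seed,
    federation = list(n_classes = c(12, 10, 8, 6), samples_per_class = 6,
                      height = 64, width = 128,
                      orientation = "horizontal",
                      contrast_level = c(1, 1, 0.85, 0.7),
                      noise_sd = c(3, 5, 4, 7),
                      illumination_offset = c(0, -10, 6, 0),
                      shared_class_fraction = 0),
    training = list(n_rounds = 15, local_epochs = 2, batch_size = 32,
                    lr = 0.05, momentum = 0.9, margin = 0.4, scale = 16,
                    d = 64, u = 10, h = 0.33, gradient_threshold = 100,
                    prototype_distribution = "all",
                    prototype_sharing = TRUE, quality_adaptive = TRUE),
    evaluation = list(split_ratio = 0.8, far_target = 0.01)),
    class = "RunConfig")
}

#' Read / write a run configuration
#'
#' @param path YAML file path.
#' @param config a \code{"RunConfig"} list.
#' @return \code{readRunConfig} returns the config; \code{writeRunConfig}
#'   returns \code{path} invisibly.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- unclass(defaultRunConfig())
  for (sec in names(base)) {
    if (is.list(base[[sec]]) && !is.null(cfg[[sec]]))
      base[[sec]] <- utils::modifyList(base[[sec]], cfg[[sec]])
    else if (!is.null(cfg[[sec]])) base[[sec]] <- cfg[[sec]]
  }
  structure(base, class = "RunConfig")
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

specFromConfig <- function(config) {
  f <- config$federation
  federationSpec(nClasses = f$n_classes,
                 samplesPerClass = f$samples_per_class,
                 height = f$height, width = f$width,
                 orientation = f$orientation,
                 contrastLevel = f$contrast_level,
                 noiseSd = f$noise_sd,
                 illuminationOffset = f$illumination_offset,
                 sharedClassFraction = f$shared_class_fraction %||% 0,
                 masterSeed = config$seed)
}

trainingConfigFromConfig <- function(config) {
  t <- config$training
  federationConfig(nRounds = t$n_rounds, localEpochs = t$local_epochs,
                   batchSize = t$batch_size, lr = t$lr,
                   momentum = t$momentum, margin = t$margin,
                   scale = t$scale, d = t$d, u = t$u, h = t$h,
                   gradientThreshold = t$gradient_threshold,
                   seed = config$seed,
                   prototypeDistribution = t$prototype_distribution,
                   prototypeSharing = isTRUE(t$prototype_sharing),
                   qualityAdaptive = isTRUE(t$quality_adaptive))
}

#' Generate a synthetic dataset from a run configuration
#'
#' Materializes the configured synthetic federation under
#' \code{paths$data_root} (created if missing) and archives the resolved
#' configuration as \code{manifest.yaml} beside it.
#'
#' @param config a \code{"RunConfig"} or path to a YAML config.
#' @param quiet suppress progress messages.
#' @return The dataset root, invisibly.
#' @export
cmdGenerate <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  fed <- generateFederation(specFromConfig(config))
  root <- config$paths$data_root
  writeDataset(fed, root)
  writeRunConfig(config, file.path(root, "manifest.yaml"))
  if (!quiet)
    message(sprintf("wrote %d clients under %s",
                    length(fed@clients), root))
  invisible(root)
}

#' Train from a run configuration
#'
#' Reads the dataset at \code{paths$data_root}, performs the open-set
#' class split, trains federated (or per-client local baseline), and
#' writes the loss history CSV plus a checkpoint (encoder(s), split
#' assignment, resolved config) into \code{paths$out_dir}.
#'
#' @param config a \code{"RunConfig"} or path to a YAML config.
#' @param mode "federated" or "local" (each client trained independently,
#'   the non-collaborative baseline).
#' @param prototypeSharing,qualityAdaptive ablation switches overriding
#'   the config (set FALSE to disable prototype expansion or the
#'   quality-adaptive margin + enhancement respectively).
#' @param quiet suppress progress messages.
#' @return Path to the checkpoint file, invisibly.
#' @export
cmdTrain <- function(config, mode = c("federated", "local"),
                     prototypeSharing = NULL, qualityAdaptive = NULL,
                     quiet = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  mode <- match.arg(mode)
  fed <- readDataset(config$paths$data_root)
  split <- splitOpenSet(fed, ratio = config$evaluation$split_ratio,
                        seed = config$seed)
  tcfg <- trainingConfigFromConfig(config)
  if (!is.null(prototypeSharing)) tcfg$prototypeSharing <- prototypeSharing
  if (!is.null(qualityAdaptive)) tcfg$qualityAdaptive <- qualityAdaptive
  out <- config$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  run <- if (mode == "federated") runFederation(split$train, tcfg)
         else runLocalBaseline(split$train, tcfg)
  write.csv(run$history, file.path(out, "history.csv"), row.names = FALSE)
  ckpt <- file.path(out, "checkpoint.rds")
  saveRDS(list(format = "fedvein-checkpoint-v1", mode = mode,
               encoder = if (mode == "federated") run$encoder,
               encoders = if (mode == "local") run$encoders,
               assignment = split$assignment,
               trainingConfig = tcfg, runConfig = unclass(config)), ckpt)
  if (!quiet)
    message(sprintf("%s training done (%d rounds); checkpoint at %s",
                    mode, tcfg$nRounds, ckpt))
  invisible(ckpt)
}

#' Evaluate a checkpoint on its open-set test split
#'
#' Re-reads the dataset, reconstructs the archived class split, scores all
#' test pairs per client and writes the per-client metric report (EER,
#' TAR at the configured FAR) with a mean row as CSV. An optional contrast
#' level re-renders the test images at reduced contrast before scoring
#' (the robustness protocol).
#'
#' @param config a \code{"RunConfig"} or path to a YAML config.
#' @param checkpoint checkpoint path (default: the one under
#'   \code{paths$out_dir}).
#' @param contrastLevel optional contrast factor in (0, 1].
#' @param quiet suppress progress messages.
#' @return The metric report data.frame, invisibly.
#' @export
cmdEvaluate <- function(config, checkpoint = NULL, contrastLevel = NULL,
                        quiet = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  checkpoint <- checkpoint %||%
    file.path(config$paths$out_dir, "checkpoint.rds")
  ck <- readRDS(checkpoint)
  if (!identical(ck$format, "fedvein-checkpoint-v1"))
    stop("not a fedvein checkpoint: ", checkpoint)
  fed <- readDataset(config$paths$data_root)
  split <- splitOpenSet(fed, ratio = config$evaluation$split_ratio,
                        seed = ck$runConfig$seed)
  enc <- if (ck$mode == "federated") ck$encoder else ck$encoders
  report <- evaluateOpenSet(enc, split$test,
                            qualityAdaptive = ck$trainingConfig$qualityAdaptive,
                            gradientThreshold = ck$trainingConfig$gradientThreshold,
                            contrastLevel = contrastLevel,
                            farTarget = config$evaluation$far_target)
  out <- config$paths$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write.csv(report, file.path(out, "metrics.csv"), row.names = FALSE)
  if (!quiet) {
    shown <- report
    shown$eer <- round(shown$eer, 2); shown$tar <- round(shown$tar, 2)
    print(shown, row.names = FALSE)
  }
  invisible(report)
}
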