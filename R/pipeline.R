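#' Pipeline run configuration
#'
#' Bundles everything one end-to-end run needs: simulator configurations
#' for a sham and an irradiated sample, a detector-noise configuration,
#' evaluation options, fit options and the output directory. The master
#' seed deterministically derives the per-stage seeds, so a run is fully
#' reproducible from its configuration.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master integer seed.
#' @param sham,irradiated [simConfig()] lists for the two samples.
#' @param noise a [noiseConfig()] list for the detector emulator.
#' @param format annotation file format (\code{"csv"}, \code{"via"},
#'   \code{"coco"}).
#' @param iou_sweep IoU thresholds for the mAP sweep.
#' @param absent_class policy for classes absent from the ground truth
#'   (\code{"exclude"} or \code{"zero"}).
#' @param interpolation AP integration scheme.
#' @param eval_stride evaluate every \code{eval_stride}-th frame in the
#'   per-frame mAP series (12 = hourly at a 5-minute cadence).
#' @param confidence_level confidence level of the growth fits.
#' @param channel count channel fitted (\code{"vital"} or \code{"total"}).
#' @param cgsf_times_h times (hours) at which CGSF is tabulated.
#' @param colony optional list with \code{samples} and \code{controls}
#'   data.frames for [survivalFraction()].
#' @param gating optional data.frame for [gateFractions()].
#' @return A validated list of class \code{"RunConfig"}.
#' @seealso [runPipeline()], [readRunConfig()]
#' @export
runConfig <- function(out_dir = "lifecycle_run", seed = 1L,
                      sham = simConfig(sample_id = "sham"),
                      irradiated = irradiatedConfig(),
                      noise = noiseConfig(),
                      format = c("csv", "via", "coco"),
                      iou_sweep = seq(0.5, 0.95, by = 0.05),
                      absent_class = c("exclude", "zero"),
                      interpolation = c("envelope", "11point"),
                      eval_stride = 12L,
                      confidence_level = 0.63,
                      channel = c("vital", "total"),
                      cgsf_times_h = c(24, 48),
                      colony = NULL, gating = NULL) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), sham = sham,
              irradiated = irradiated, noise = noise,
              format = match.arg(format), iou_sweep = iou_sweep,
              absent_class = match.arg(absent_class),
              interpolation = match.arg(interpolation),
              eval_stride = as.integer(eval_stride),
              confidence_level = confidence_level,
              channel = match.arg(channel),
              cgsf_times_h = cgsf_times_h,
              colony = colony, gating = gating)
  for (s in c("sham", "irradiated")) {
    .validate_sim_config(cfg[[s]])
    if (cfg[[s]]$arrest_h > cfg[[s]]$duration_h)
      stop("invalid ", s, " configuration: arrest_h (", cfg[[s]]$arrest_h,
           " h) exceeds duration_h (", cfg[[s]]$duration_h, " h)")
  }
  .validate_noise_config(cfg$noise)
  if (any(cfg$iou_sweep <= 0 | cfg$iou_sweep > 1))
    stop("iou_sweep thresholds must lie in (0, 1]")
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [runConfig()]; the \code{sham},
#' \code{irradiated} and \code{noise} blocks hold overrides for
#' [simConfig()], [irradiatedConfig()] and [noiseConfig()].
#'
#' @param path YAML file.
#' @return A \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("sham", "irradiated", "noise"))]
  args$sham <- do.call(simConfig, c(list(sample_id = "sham"),
                                    y$sham %||% list()))
  args$irradiated <- do.call(irradiatedConfig, y$irradiated %||% list())
  args$noise <- do.call(noiseConfig, y$noise %||% list())
  do.call(runConfig, args)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.write_with_header <- function(df, path, seed, what) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s; seed=%d; columns documented in the package help",
                     what, seed), con)
  utils::write.csv(format(df, digits = 10, trim = TRUE,
                          scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE, na = "")
}

#' Run the full analysis pipeline
#'
#' simulate -> perturb -> evaluate -> lifecycle -> (optional) survival and
#' gating -> report. Simulates a sham and an irradiated sample, emulates an
#' imperfect detector on both, scores the detections against the ground
#' truth (per-frame mAP series), computes count series, growth fits and the
#' CGSF table, and - when colony or gating tables are supplied - the
#' clonogenic survival and Caspase3/7-Sytox summaries. All outputs are
#' plain CSV/text files in \code{config$out_dir}; every numeric file
#' records the seed in its header and a run log records the configuration
#' hash. Identical configurations produce byte-identical outputs.
#'
#' @param config a [runConfig()] (or [readRunConfig()]) list.
#' @return Invisibly, a list with the in-memory results (videos, count
#'   series, fits, CGSF table, evaluation series, optional survival and
#'   gating results) and \code{files}, the paths written.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  seed <- config$seed
  out <- list()

  sims <- .stage("simulate", {
    sham_cfg <- config$sham; sham_cfg$seed <- seed
    irr_cfg <- config$irradiated; irr_cfg$seed <- seed + 1L
    list(sham = simulatePopulation(sham_cfg),
         irr = simulatePopulation(irr_cfg))
  })
  ext <- c(csv = "csv", via = "json", coco = "json")[config$format]
  # csv annotation files get a seed comment line (readers skip unknown keys)
  write_ann <- function(video, f) {
    writeAnnotations(video, f, config$format)
    if (config$format == "csv")
      writeLines(c(sprintf("# seed=%d", seed), readLines(f)), f)
  }
  for (s in names(sims)) {
    f <- file.path(config$out_dir, sprintf("truth_%s.%s", s, ext))
    write_ann(sims[[s]]$video, f)
    files <- c(files, f)
  }
  out$truth <- lapply(sims, `[[`, "video")
  out$lineage <- lapply(sims, `[[`, "lineage")

  preds <- .stage("perturb", {
    lapply(seq_along(sims), function(i) {
      ncfg <- config$noise; ncfg$seed <- seed + 1L + i
      applyDetectorNoise(sims[[i]]$video, ncfg)
    })
  })
  names(preds) <- names(sims)
  for (s in names(preds)) {
    f <- file.path(config$out_dir, sprintf("pred_%s.%s", s, ext))
    write_ann(preds[[s]], f)
    files <- c(files, f)
  }
  out$pred <- preds

  out$eval <- .stage("evaluate", {
    lapply(names(sims), function(s) {
      gt <- sims[[s]]$video
      keep <- gt@frameIndices[gt@frameIndices %% config$eval_stride == 0 |
                                gt@frameIndices == 1L]
      sub <- function(v) cellVideo(
        v@objects[v@objects$frame %in% keep, , drop = FALSE],
        frameIndices = keep, frameInterval = v@frameInterval,
        imageSize = v@imageSize, sampleMeta = v@sampleMeta)
      ev <- mapScore(sub(gt), sub(preds[[s]]), scope = "frame",
                     thresholds = config$iou_sweep,
                     absent_class = config$absent_class,
                     interpolation = config$interpolation)
      f <- file.path(config$out_dir, sprintf("eval_%s.csv", s))
      .write_with_header(ev, f, seed,
                         sprintf("per-frame detection scores (%s); mAP in percent, time in min", s))
      files <<- c(files, f)
      ev
    })
  })

  out$counts <- .stage("lifecycle", {
    lapply(names(sims), function(s) {
      cs <- countSeries(sims[[s]]$video)
      f <- file.path(config$out_dir, sprintf("counts_%s.csv", s))
      .write_with_header(as.data.frame(cs), f, seed,
                         sprintf("class-count series (%s); counts per frame, normalized to frame 1", s))
      files <<- c(files, f)
      cs
    })
  })
  names(out$counts) <- names(sims)

  out$fits <- .stage("growth fit", {
    fits <- lapply(out$counts, fitGrowth, channel = config$channel,
                   conf_level = config$confidence_level)
    f <- file.path(config$out_dir, "growth_fits.txt")
    txt <- utils::capture.output({
      for (s in names(fits)) {
        cat("==", s, "==\n"); show(fits[[s]])
        cat(sprintf("seed=%d\n\n", seed))
      }
    })
    writeLines(txt, f)
    files <- c(files, f)
    fits
  })

  out$cgsf <- .stage("cgsf", {
    tab <- cgsf(out$fits$irr, out$fits$sham, config$cgsf_times_h)
    f <- file.path(config$out_dir, "cgsf.csv")
    .write_with_header(tab, f, seed,
                       "cell-growth-defined survival fraction (irradiated / sham), 0-1 scale")
    files <- c(files, f)
    tab
  })

  out$divisions <- .stage("division census", {
    lapply(out$lineage, divisionCensus)
  })
  out$death <- .stage("death census", {
    lapply(out$truth, deadCellCensus, window_h = 24)
  })

  if (!is.null(config$colony)) {
    out$survival <- .stage("survival", {
      sf <- survivalFraction(config$colony$samples,
                             config$colony$controls)
      f <- file.path(config$out_dir, "survival.csv")
      .write_with_header(sf, f, seed,
                         "clonogenic survival (PE, SF with propagated errors)")
      files <- c(files, f)
      sf
    })
  }
  if (!is.null(config$gating)) {
    out$gating <- .stage("gating", {
      g <- gateFractions(config$gating)
      f <- file.path(config$out_dir, "gating.csv")
      .write_with_header(g$summary, f, seed,
                         "Caspase3/7-Sytox gating fractions (mean and SEM across samples)")
      files <- c(files, f)
      g
    })
  }

  log_f <- file.path(config$out_dir, "run_log.txt")
  cfg_hash <- .config_hash(config)
  writeLines(c(sprintf("package: LiveCellQuant %s",
                       as.character(utils::packageVersion("LiveCellQuant"))),
               sprintf("R: %s", R.version.string),
               sprintf("seed: %d", seed),
               sprintf("config_hash: %s", cfg_hash),
               sprintf("outputs: %s", paste(basename(files),
                                            collapse = ", "))),
             log_f)
  files <- c(files, log_f)
  out$files <- files
  invisible(out)
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config),
                                    c("colony", "gating"))]), tmp)
  unname(tools::md5sum(tmp))
}
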