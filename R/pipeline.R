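# End-to-end orchestration: simulate (or read) -> preprocess -> spectra /
# connectivity -> graph metrics -> statistics, with a JSON run manifest
# recording the effective configuration, the stage order actually applied,
# every output file with its checksum, and all warnings. Identical config +
# seed reproduces identical checksums.

#' Build a pipeline configuration
#'
#' All knobs of a full run in one serializable list: simulation settings
#' (passed to \code{\link{simConfig}}), preprocessing parameters, the band
#' table selection, Welch segmentation, graph conventions, statistics
#' options, the master seed and the output directory.
#'
#' @param simulation named list of \code{\link{simConfig}} arguments.
#' @param lFreq,hFreq analysis band-pass edges, Hz.
#' @param notch notch stop-band, Hz (NULL disables; disabled automatically
#'   when the sampling rate cannot resolve it).
#' @param rejectUv epoch rejection threshold, uV.
#' @param baseline baseline window (s, relative to onset).
#' @param runICA run ICA ocular removal (default TRUE when EOG present).
#' @param icaThreshold EOG-correlation removal threshold.
#' @param bandTable \code{"canonical"} or \code{"results-section"}.
#' @param bandNames bands to analyze (default: all with planted coupling
#'   plus delta is skipped for speed in reduced runs; NULL = all five).
#' @param segSec,overlap Welch segmentation.
#' @param distance,clusteringVariant graph conventions.
#' @param outputDir output directory.
#' @param seed master seed (overrides \code{simulation$seed}).
#' @return a classed list (\code{"wpliNetConfig"}).
#' @export
pipelineConfig <- function(simulation = list(), lFreq = 0.1, hFreq = 50,
                           notch = c(49, 51), rejectUv = 75,
                           baseline = c(-5, 0), runICA = TRUE,
                           icaThreshold = 0.8,
                           bandTable = c("canonical", "results-section"),
                           bandNames = NULL, segSec = 2, overlap = 0.5,
                           distance = "reciprocal",
                           clusteringVariant = "onnela",
                           outputDir = tempfile("wpliNet-run-"), seed = 1L) {
  bandTable <- match.arg(bandTable)
  cfg <- list(simulation = simulation, lFreq = lFreq, hFreq = hFreq,
              notch = notch, rejectUv = rejectUv, baseline = baseline,
              runICA = runICA, icaThreshold = icaThreshold,
              bandTable = bandTable, bandNames = bandNames,
              segSec = segSec, overlap = overlap, distance = distance,
              clusteringVariant = clusteringVariant,
              outputDir = outputDir, seed = as.integer(seed))
  class(cfg) <- c("wpliNetConfig", "list")
  cfg
}

resolveBands <- function(cfg) {
  bands <- if (cfg$bandTable == "canonical") canonicalBands() else resultsSectionBands()
  if (!is.null(cfg$bandNames)) {
    unknown <- setdiff(cfg$bandNames, bands$name)
    if (length(unknown)) stop("unknown band name(s): ", paste(unknown, collapse = ", "))
    bands <- bands[bands$name %in% cfg$bandNames, , drop = FALSE]
  }
  bands
}

#' Preprocess one recording through the standard chain
#'
#' Applies the prescribed order: band-pass filter, notch, (optional) bad
#' channel interpolation, epoching with baseline correction, ICA ocular
#' removal, linked-mastoid re-referencing, amplitude rejection. Returns the
#' epochs plus the list of applied steps (the provenance is also carried on
#' the object itself).
#'
#' @param rec an \code{\linkS4class{EEGRecording}}.
#' @param cfg a \code{\link{pipelineConfig}}.
#' @param badChannels labels to interpolate (default none).
#' @return list(epochs =, steps =, warnings =).
#' @export
preprocessRecording <- function(rec, cfg, badChannels = character(0)) {
  warnings <- character(0)
  steps <- character(0)
  fs <- rec@fs
  rec <- bandpassFilter(rec, cfg$lFreq, min(cfg$hFreq, fs / 2 - 1e-6 * fs))
  steps <- c(steps, "bandpass")
  if (!is.null(cfg$notch) && cfg$notch[2] < fs / 2) {
    rec <- notchFilter(rec, cfg$notch[1], cfg$notch[2])
    steps <- c(steps, "notch")
  } else if (!is.null(cfg$notch)) {
    warnings <- c(warnings, "notch skipped: stop band at or above Nyquist")
  }
  rec <- interpolateBad(rec, badChannels)
  if (length(badChannels)) steps <- c(steps, "interpolate")
  t1 <- if (!is.null(cfg$trialSec)) cfg$trialSec
        else if (nrow(rec@events) >= 2) min(diff(rec@events$onset)) / fs
        else (ncol(rec@data) - max(rec@events$onset)) / fs
  ep <- epochAndBaseline(rec, t0 = 0, t1 = t1, baseline = cfg$baseline)
  steps <- c(steps, "epoch+baseline")
  if (isTRUE(cfg$runICA) && length(rec@eogLabels)) {
    icares <- removeOcularICA(ep, threshold = cfg$icaThreshold,
                              minSec = min(60, dim(ep@data)[1] * dim(ep@data)[3] / fs))
    ep <- icares$epochs
    steps <- c(steps, "ica")
  } else if (isTRUE(cfg$runICA)) {
    warnings <- c(warnings, "ICA skipped: no EOG channel")
  }
  mast <- try(rereferenceLinkedMastoids(ep), silent = TRUE)
  if (inherits(mast, "try-error")) {
    warnings <- c(warnings, "re-referencing skipped: mastoid channels absent from montage subset")
  } else {
    ep <- mast
    steps <- c(steps, "rereference")
  }
  ep <- rejectAmplitude(ep, cfg$rejectUv)
  steps <- c(steps, "rejectAmplitude")
  list(epochs = ep, steps = steps, warnings = warnings)
}

#' Run the full analysis pipeline
#'
#' Simulates the configured study (behavior and per-subject EEG), runs the
#' preprocessing chain, estimates per-band WPLI matrices and network metrics
#' per subject and music type, computes group means, band powers, and the
#' behavioral and neural statistics, writes everything as tidy CSV/JSON into
#' the output directory, and returns the run manifest.
#'
#' @param cfg a \code{\link{pipelineConfig}}.
#' @return invisibly, the manifest (also written as \code{manifest.json}).
#' @export
runPipeline <- function(cfg) {
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  outFile <- function(...) file.path(cfg$outputDir, paste0(...))
  manifest <- list(package = "wpliNet",
                   version = as.character(packageVersion("wpliNet")),
                   config = cfg[setdiff(names(cfg), "outputDir")],
                   stages = list(), warnings = character(0))
  addStage <- function(name, params = list())
    manifest$stages[[length(manifest$stages) + 1L]] <<- list(stage = name, params = params)

  simArgs <- cfg$simulation
  simArgs$seed <- cfg$seed
  simCfg <- do.call(simConfig, simArgs)
  bands <- resolveBands(cfg)
  jsonlite::write_json(cfg[setdiff(names(cfg), "outputDir")],
                       outFile("config.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")

  # ---- behavioral arm -------------------------------------------------
  behavior <- generateBehavior(simCfg)
  write.csv(behavior, outFile("behavior.csv"), row.names = FALSE)
  addStage("behavior", list(nSubjects = simCfg@nSubjects))

  behStats <- behavioralStats(behavior)
  write.csv(behStats$manipulation, outFile("stats_manipulation.csv"), row.names = FALSE)
  write.csv(behStats$anova, outFile("stats_anova.csv"), row.names = FALSE)
  write.csv(behStats$simpleEffects, outFile("stats_simple_effects.csv"), row.names = FALSE)
  addStage("behavioral-stats")

  # ---- neural arm -----------------------------------------------------
  metricRows <- list()
  meanW <- list()
  groupMats <- list()
  psdRows <- list()
  stepsApplied <- NULL
  cfg2 <- cfg
  cfg2$trialSec <- simCfg@trialSec
  cfg2$baseline <- c(max(cfg$baseline[1], -simCfg@baselineSec), cfg$baseline[2])
  for (s in seq_len(simCfg@nSubjects) - 1L) {
    rec <- makeSubjectRecording(simCfg, s)$recording
    pp <- preprocessRecording(rec, cfg2)
    manifest$warnings <- unique(c(manifest$warnings, pp$warnings))
    stepsApplied <- pp$steps
    ep <- pp$epochs
    for (bi in seq_len(nrow(bands))) {
      for (mt in c("nostalgic", "non-nostalgic")) {
        cm <- tryCatch(
          wpliMatrix(ep, bands[bi, ], segSec = cfg$segSec,
                     overlap = cfg$overlap, musicType = mt,
                     subject = as.character(s)),
          error = function(e) {
            manifest$warnings <<- c(manifest$warnings,
              sprintf("subject %d %s/%s: %s", s, bands$name[bi], mt,
                      conditionMessage(e)))
            NULL
          })
        if (is.null(cm)) next
        key <- paste(bands$name[bi], mt, sep = "|")
        groupMats[[key]] <- c(groupMats[[key]], list(cm))
        nm <- networkSummary(cm, distance = cfg$distance,
                             clusteringVariant = cfg$clusteringVariant)
        row <- metricsRow(nm)
        row$subject <- as.character(s)
        row$condition <- mt
        row$mean_wpli <- meanConnectivity(cm)
        metricRows[[paste(s, key)]] <- row
      }
    }
    # band power per sensory channel under nostalgic stimulation
    for (ct in c("visual", "auditory", "audiovisual")) {
      ps <- tryCatch(
        bandAggregate(welchPSD(ep, segSec = cfg$segSec, overlap = cfg$overlap,
                               musicType = "nostalgic", channelType = ct),
                      bands = resolveBands(cfg)),
        error = function(e) NULL)
      if (is.null(ps)) next
      bt <- bandPowerTable(ps)
      bt$subject <- as.character(s)
      bt$channel_type <- ct
      psdRows[[paste(s, ct)]] <- bt
    }
  }
  addStage("preprocess", list(order = stepsApplied))
  addStage("connectivity", list(bands = bands$name, segSec = cfg$segSec,
                                overlap = cfg$overlap))

  metricsTable <- do.call(rbind, metricRows)
  rownames(metricsTable) <- NULL
  write.csv(metricsTable, outFile("network_metrics.csv"), row.names = FALSE)
  psdTable <- do.call(rbind, psdRows)
  rownames(psdTable) <- NULL
  write.csv(psdTable, outFile("band_power.csv"), row.names = FALSE)

  for (key in names(groupMats)) {
    gm <- groupConnectivity(groupMats[[key]])
    writeConnectivityCSV(gm, outFile("wpli_group_", gsub("\\|", "_", key), ".csv"))
  }
  addStage("group-connectivity", list(n = length(groupMats)))

  # subject-level network comparisons (plus entry-level, clearly labeled)
  neural <- compareNetworkMetrics(metricsTable,
                                  metrics = c("mean_wpli", "strength",
                                              "global_efficiency",
                                              "local_efficiency",
                                              "char_path_length"))
  neural$sampling_unit <- "subject"
  entryRows <- list()
  for (bn in unique(bands$name)) {
    kA <- paste(bn, "nostalgic", sep = "|"); kB <- paste(bn, "non-nostalgic", sep = "|")
    if (is.null(groupMats[[kA]]) || is.null(groupMats[[kB]])) next
    wA <- connMatrix(groupConnectivity(groupMats[[kA]]))
    wB <- connMatrix(groupConnectivity(groupMats[[kB]]))
    tt <- pairedT(wA[upper.tri(wA)], wB[upper.tri(wB)])
    entryRows[[bn]] <- cbind(data.frame(band = bn, metric = "wpli_entries",
                                        stringsAsFactors = FALSE), tt)
  }
  if (length(entryRows)) {
    entry <- do.call(rbind, entryRows)
    entry$sampling_unit <- "matrix-entry"
    common <- intersect(names(neural), names(entry))
    neural <- rbind(neural[, common], entry[, common])
  }
  write.csv(neural, outFile("stats_network.csv"), row.names = FALSE)
  addStage("network-stats")

  files <- list.files(cfg$outputDir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest$files <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, outFile("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", dataframe = "rows")
  invisible(manifest)
}

#' Behavioral statistics bundle
#'
#' The behavioral arm in one call: per-channel manipulation checks (paired t
#' on state nostalgia, nostalgic vs non-nostalgic), the 3 x 2
#' repeated-measures ANOVA with GG correction for each rating scale (after
#' single-pass outlier exclusion on subject-level condition means), and the
#' channel-type simple effects on state nostalgia within each music type.
#'
#' @param behavior per-trial ratings table (see \code{\link{generateBehavior}}).
#' @param outlierK SD multiplier for outlier exclusion (default 3).
#' @return list: \code{manipulation}, \code{anova}, \code{simpleEffects},
#'   \code{outliers}.
#' @export
behavioralStats <- function(behavior, outlierK = 3) {
  scales <- c("nostalgia", "pleasure", "arousal", "dominance")
  manip <- list()
  cm <- cellMeans(behavior, "nostalgia")
  for (ct in unique(cm$channelType)) {
    a <- cm[cm$channelType == ct & cm$musicType == "nostalgic", ]
    b <- cm[cm$channelType == ct & cm$musicType == "non-nostalgic", ]
    a <- a[order(a$subject), ]; b <- b[order(b$subject), ]
    manip[[ct]] <- cbind(data.frame(channelType = ct, stringsAsFactors = FALSE),
                         pairedT(a$value, b$value))
  }
  manip <- do.call(rbind, manip)
  rownames(manip) <- NULL

  anovaRows <- list()
  outliers <- list()
  for (sc in scales) {
    tab <- cellMeans(behavior, sc)
    # single-pass exclusion on subject-level means of the indicator
    subjMeans <- tapply(tab$value, tab$subject, mean)
    ex <- excludeOutliers(as.numeric(subjMeans), outlierK)
    if (length(ex$removed)) {
      drop <- names(subjMeans)[ex$removed]
      tab <- tab[!(tab$subject %in% drop), ]
      outliers[[sc]] <- drop
    }
    res <- rmAnova(tab)
    res$scale <- sc
    anovaRows[[sc]] <- res
  }
  anova <- do.call(rbind, anovaRows)
  rownames(anova) <- NULL

  se <- simpleEffects(cellMeans(behavior, "nostalgia"),
                      factor = "channelType", within = "musicType")
  list(manipulation = manip, anova = anova, simpleEffects = se,
       outliers = outliers)
}
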