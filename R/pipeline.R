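REPORT_SCHEMA <- "trunkentropy-report/1"

defaultPipelineConfig <- function() {
  list(
    markerChannel = "GyrY",
    zeroTol = 2,
    detrend = TRUE,
    m = 2L,
    r = 0.2,
    rMode = "relative",
    rScope = "window",
    nFloor = 200L,
    tStart = 10,
    tEnd = 70,
    step = 2,
    r2Threshold = 0.99,
    slopeThreshold = 0.95,
    blandAltmanI = 28,
    partialChannels = "GyrX"
  )
}

mergeConfig <- function(config) {
  cfg <- defaultPipelineConfig()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(config)] <- config
  cfg
}

# one recording -> per-recording descriptors + partial-SampEn long table
processRecording <- function(rec, cfg) {
  trimmed <- segmentTest(rec, markerChannel = cfg$markerChannel,
                         zeroTol = cfg$zeroTol)
  fs <- samplingRate(rec)
  durationS <- nSamples(trimmed$GyrX) / fs
  ang <- integrateGyro(trimmed$GyrX, detrend = cfg$detrend)
  cyc <- detectCycles(ang)
  sds <- velocitySds(trimmed)
  se <- vapply(IMU_CHANNELS, function(ch) {
    sampEnValue(sampEn(trimmed[[ch]], m = cfg$m, r = cfg$r,
                       rMode = cfg$rMode, nFloor = cfg$nFloor))
  }, numeric(1))
  meta <- imuMeta(rec)
  row <- data.frame(
    participant = meta$participant %||% NA_character_,
    condition = meta$condition %||% NA_character_,
    durationS = durationS,
    nCycles = nCycles(cyc),
    meanAmplitude = meanAmplitude(cyc),
    sdX = unname(sds["sdX"]), sdY = unname(sds["sdY"]),
    sdZ = unname(sds["sdZ"]),
    stringsAsFactors = FALSE
  )
  for (ch in IMU_CHANNELS) row[[paste0("sampen50_", ch)]] <- unname(se[ch])

  partials <- do.call(rbind, lapply(cfg$partialChannels, function(ch) {
    tab <- suppressWarnings(
      sampEnPartials(trimmed[[ch]], m = cfg$m, r = cfg$r, rMode = cfg$rMode,
                     tStart = cfg$tStart, tEnd = cfg$tEnd, step = cfg$step,
                     rScope = cfg$rScope, nFloor = cfg$nFloor))
    data.frame(participant = row$participant, condition = row$condition,
               channel = ch, I = tab$I, sampen = tab$sampen,
               stringsAsFactors = FALSE)
  }))
  list(row = row, partials = partials)
}

loadCohortInput <- function(input) {
  if (is.character(input)) {
    if (!dir.exists(input)) stop("input directory not found: ", input)
    files <- list.files(input, pattern = "\\.csv$", full.names = TRUE)
    if (!length(files)) stop("empty input directory: ", input)
    recs <- lapply(files, readRecording)
  } else if (is.list(input)) {
    recs <- list()
    for (p in input) {
      for (cond in intersect(names(p), c("box", "stool"))) {
        recs[[length(recs) + 1L]] <- p[[cond]]
      }
    }
    if (!length(recs)) stop("input list contains no recordings")
  } else {
    stop("input must be a directory path or a cohort list")
  }
  recs
}

#' Run the full cohort analysis pipeline
#'
#' End-to-end driver over a directory of recording files (or a cohort list
#' from [simulateCohort()]): segments each recording, computes durations,
#' angular amplitudes, angular-velocity SDs, SampEn of all six channels and
#' partial SampEn on growing windows, then aggregates per-condition
#' summaries, paired condition comparisons (Wilcoxon for durations, SDs and
#' SampEn; paired t for amplitudes), cross-condition correlations,
#' per-window through-origin regressions with the shortest-duration
#' selection, and a Bland-Altman comparison between the full-series SampEn
#' and the partial SampEn at `blandAltmanI` seconds.
#'
#' A recording that fails a stage (e.g. no detectable marker) is skipped
#' with a logged reason rather than aborting the cohort; paired statistics
#' use the participants with both conditions available.  The report is
#' deterministic given the inputs and config.
#'
#' @param input directory containing one CSV per recording (see
#'   [readRecording()]) or a list as returned by [simulateCohort()].
#' @param config named list overriding the defaults: `markerChannel`,
#'   `zeroTol`, `detrend`, `m`, `r`, `rMode`, `rScope`, `nFloor`, `tStart`,
#'   `tEnd`, `step`, `r2Threshold`, `slopeThreshold`, `blandAltmanI`,
#'   `partialChannels`.
#' @param verbose log stage progress with [message()] (default `FALSE`).
#' @return a list of class `CohortReport` with elements `schema`,
#'   `participants` (per-recording table), `partials` (long table),
#'   `summary` (per-condition mean/SD), `comparisons`, `crossCondition`,
#'   `convergence` (per condition x channel: per-window regression table,
#'   duration selection, Bland-Altman), `skipped`, `provenance`.
#' @examples
#' coh <- simulateCohort(4, base = participantParams(nCycles = 12), seed = 1)
#' rep <- runPipeline(coh, config = list(tEnd = 24, blandAltmanI = 16))
#' rep$summary
#' @export
runPipeline <- function(input, config = list(), verbose = FALSE) {
  cfg <- mergeConfig(config)
  recs <- loadCohortInput(input)

  fsAll <- vapply(recs, samplingRate, numeric(1))
  if (max(fsAll) - min(fsAll) > 0.01 * stats::median(fsAll)) {
    stop("mixed sampling rates across recordings")
  }

  rows <- list()
  partials <- list()
  skipped <- list()
  for (rec in recs) {
    meta <- imuMeta(rec)
    label <- paste0(meta$participant %||% "?", "/", meta$condition %||% "?")
    if (verbose) message("processing ", label)
    res <- tryCatch(processRecording(rec, cfg), error = function(e) e)
    if (inherits(res, "error")) {
      if (verbose) message("  skipped: ", conditionMessage(res))
      skipped[[length(skipped) + 1L]] <- data.frame(
        participant = meta$participant %||% NA_character_,
        condition = meta$condition %||% NA_character_,
        reason = conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- res$row
    partials[[length(partials) + 1L]] <- res$partials
  }
  if (!length(rows)) stop("no recording could be processed")
  participants <- do.call(rbind, rows)
  partialTab <- do.call(rbind, partials)
  skippedTab <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(participant = character(0), condition = character(0),
               reason = character(0), stringsAsFactors = FALSE)

  numCols <- setdiff(names(participants), c("participant", "condition"))
  summary <- do.call(rbind, lapply(split(participants,
                                         participants$condition),
                                   function(d) {
    out <- data.frame(condition = d$condition[1], n = nrow(d),
                      stringsAsFactors = FALSE)
    for (cn in numCols) {
      out[[paste0(cn, "_mean")]] <- mean(d[[cn]], na.rm = TRUE)
      out[[paste0(cn, "_sd")]] <- stats::sd(d[[cn]], na.rm = TRUE)
    }
    out
  }))
  rownames(summary) <- NULL

  # paired tables: participants with both conditions
  paired <- function(quantity) {
    wide <- merge(
      participants[participants$condition == "box",
                   c("participant", quantity)],
      participants[participants$condition == "stool",
                   c("participant", quantity)],
      by = "participant", suffixes = c("_box", "_stool"))
    wide
  }
  bothConds <- all(c("box", "stool") %in% participants$condition)

  comparisons <- NULL
  crossCondition <- NULL
  if (bothConds) {
    cmp <- function(quantity, test) {
      w <- paired(quantity)
      res <- tryCatch(
        compareConditions(w[[paste0(quantity, "_box")]],
                          w[[paste0(quantity, "_stool")]], test = test),
        error = function(e) list(statistic = NA_real_, pValue = NA_real_,
                                 n = nrow(w), test = test))
      data.frame(quantity = quantity, test = res$test,
                 statistic = res$statistic, pValue = res$pValue, n = res$n,
                 stringsAsFactors = FALSE)
    }
    comparisons <- rbind(
      cmp("durationS", "wilcoxon"),
      cmp("meanAmplitude", "paired_t"),
      cmp("sdX", "wilcoxon"), cmp("sdY", "wilcoxon"), cmp("sdZ", "wilcoxon"),
      do.call(rbind, lapply(IMU_CHANNELS, function(ch) {
        cmp(paste0("sampen50_", ch), "wilcoxon")
      }))
    )
    crossCondition <- do.call(rbind, lapply(IMU_CHANNELS, function(ch) {
      w <- paired(paste0("sampen50_", ch))
      res <- tryCatch(
        crossConditionCorrelation(w[[2]], w[[3]]),
        error = function(e) list(r = NA_real_, pValue = NA_real_,
                                 n = nrow(w)))
      data.frame(channel = ch, r = res$r, pValue = res$pValue, n = res$n,
                 stringsAsFactors = FALSE)
    }))
  }

  # convergence + agreement per condition x partial channel
  convergence <- list()
  for (cond in unique(partialTab$condition)) {
    for (ch in unique(partialTab$channel)) {
      sub <- partialTab[partialTab$condition == cond &
                          partialTab$channel == ch, ]
      if (!nrow(sub)) next
      full <- participants[participants$condition == cond,
                           c("participant", paste0("sampen50_", ch))]
      names(full)[2] <- "sampen50"
      regTab <- do.call(rbind, lapply(sort(unique(sub$I)), function(I) {
        w <- merge(sub[sub$I == I, c("participant", "sampen")], full,
                   by = "participant")
        res <- tryCatch(regressThroughOrigin(w$sampen, w$sampen50),
                        error = function(e) NULL)
        if (is.null(res)) return(NULL)
        data.frame(I = I, k = res$k, rSquared = res$rSquared,
                   pearsonR = res$pearsonR, pValue = res$pValue, n = res$n)
      }))
      if (is.null(regTab) || !nrow(regTab)) next
      sel <- selectDuration(regTab, r2Threshold = cfg$r2Threshold,
                            slopeThreshold = cfg$slopeThreshold)
      baI <- cfg$blandAltmanI
      ba <- NULL
      if (baI %in% sub$I) {
        w <- merge(full, sub[sub$I == baI, c("participant", "sampen")],
                   by = "participant")
        ba <- tryCatch(blandAltman(w$sampen50, w$sampen),
                       error = function(e) NULL)
        if (!is.null(ba)) ba$I <- baI
      }
      convergence[[paste(cond, ch, sep = ".")]] <- list(
        condition = cond, channel = ch,
        regressions = regTab,
        selection = sel[c("optimalI", "qualified", "r2Threshold",
                          "slopeThreshold")],
        blandAltman = ba)
    }
  }

  structure(list(
    schema = REPORT_SCHEMA,
    participants = participants,
    partials = partialTab,
    summary = summary,
    comparisons = comparisons,
    crossCondition = crossCondition,
    convergence = convergence,
    skipped = skippedTab,
    provenance = list(
      package = "trunkentropy",
      version = as.character(utils::packageVersion("trunkentropy")),
      config = cfg,
      nRecordings = length(recs))
  ), class = "CohortReport")
}

#' Write a cohort report to JSON
#'
#' @param report a `CohortReport` from [runPipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCohortReport <- function(report, path) {
  stopifnot(inherits(report, "CohortReport"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a cohort report written by [writeCohortReport()]
#'
#' @param path JSON file path.
#' @return a list of class `CohortReport`.
#' @export
readCohortReport <- function(path) {
  rep <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!identical(rep$schema, REPORT_SCHEMA)) {
    stop("unrecognised report schema: ", rep$schema %||% "<missing>")
  }
  structure(rep, class = "CohortReport")
}

#' @export
print.CohortReport <- function(x, ...) {
  cat("CohortReport (", x$schema, ")\n", sep = "")
  cat("  recordings analysed:", nrow(x$participants),
      " skipped:", nrow(x$skipped), "\n")
  cat("  conditions:", paste(unique(x$participants$condition),
                             collapse = ", "), "\n")
  for (cv in x$convergence) {
    sel <- cv$selection
    cat(sprintf("  %s/%s: optimal I = %s s\n", cv$condition, cv$channel,
                if (isTRUE(sel$qualified)) sel$optimalI else "none"))
  }
  invisible(x)
}
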