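normalizeColname <- function(x) gsub("[^a-z]", "", tolower(x))

#' Write an IMU recording to a delimited text file
#'
#' One row per sample, columns `time, AccX..GyrZ`.  Metadata (participant,
#' condition, sampling rate, notes) is written as a sidecar header block of
#' `#`-prefixed `key: value` lines before the column header.
#'
#' @param rec an [IMURecording-class].
#' @param path output file path.
#' @param delimiter field separator (default `","`).
#' @return `path`, invisibly.
#' @seealso [readRecording()]
#' @export
writeRecording <- function(rec, path, delimiter = ",") {
  stopifnot(is(rec, "IMURecording"))
  m <- rec@meta
  hdr <- c(
    sprintf("# participant: %s", m$participant %||% ""),
    sprintf("# condition: %s", m$condition %||% ""),
    sprintf("# sampling_rate: %.10g", rec@samplingRate),
    sprintf("# notes: %s", m$notes %||% "")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  df <- data.frame(time = rec@time, rec@data, check.names = FALSE)
  utils::write.table(df, con, sep = delimiter, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read an IMU recording from a delimited text file
#'
#' Expects a header row naming the seven columns (`time`, `AccX..GyrZ`;
#' matching is case-insensitive and ignores separators, so `acc_x` or
#' `Gyr.Z` also work).  Other headers are handled through `columnMap`.
#' Rows containing non-finite values are dropped and their count reported
#' with a message (and stored in the metadata as `droppedRows`); the
#' remaining samples are treated as contiguous, which is adequate for
#' isolated sensor glitches.  The sampling rate is inferred from the median
#' time step and checked uniform within 1% (gaps that are integer multiples
#' of the step, left by rejected rows, are not counted as jitter).
#'
#' @param path input file path.
#' @param delimiter field separator (default `","`; use `"\t"` or `";"` for
#'   other dialects).
#' @param columnMap optional named character vector mapping the canonical
#'   names (`time`, `AccX`, ..., `GyrZ`) to the column names used in the
#'   file, for deposits with non-standard headers.
#' @return an [IMURecording-class].
#' @examples
#' rec <- simulateRecording(participantParams(nCycles = 5), seed = 1)
#' f <- tempfile(fileext = ".csv")
#' writeRecording(rec, f)
#' rec2 <- readRecording(f)
#' @export
readRecording <- function(path, delimiter = ",", columnMap = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  isMeta <- grepl("^#", lines)
  metaLines <- lines[isMeta & !cumsum(!isMeta)]  # leading # block only
  body <- lines[!isMeta]
  meta <- list()
  for (ln in metaLines) {
    kv <- sub("^#\\s*", "", ln)
    sep <- regexpr(":", kv, fixed = TRUE)
    if (sep > 0) {
      key <- trimws(substr(kv, 1, sep - 1))
      val <- trimws(substr(kv, sep + 1, nchar(kv)))
      meta[[key]] <- val
    }
  }
  df <- utils::read.table(text = body, header = TRUE, sep = delimiter,
                          dec = ".", stringsAsFactors = FALSE,
                          check.names = FALSE)
  want <- c("time", IMU_CHANNELS)
  if (!is.null(columnMap)) {
    for (canonical in names(columnMap)) {
      hit <- which(names(df) == columnMap[[canonical]])
      if (length(hit)) names(df)[hit[1]] <- canonical
    }
  }
  normWant <- normalizeColname(want)
  normHave <- normalizeColname(names(df))
  idx <- match(normWant, normHave)
  if (anyNA(idx)) {
    stop("missing column(s): ", paste(want[is.na(idx)], collapse = ", "))
  }
  df <- df[, idx]
  names(df) <- want
  for (cn in want) df[[cn]] <- as.numeric(df[[cn]])

  finite <- rowSums(!is.finite(as.matrix(df))) == 0
  nDropped <- sum(!finite)
  if (nDropped > 0) {
    message("dropped ", nDropped, " row(s) with non-finite values")
    df <- df[finite, , drop = FALSE]
  }
  if (nrow(df) < 2L) stop("recording has fewer than 2 usable samples")

  # uniformity check on the kept rows; a step that is an integer multiple of
  # the median step is a gap left by rejected rows, not jitter
  dt <- diff(df$time)
  medDt <- stats::median(dt)
  if (medDt <= 0) stop("time column must be strictly increasing")
  mult <- pmax(1, round(dt / medDt))
  jitter <- max(abs(dt - mult * medDt)) / medDt
  if (jitter > 0.01) {
    stop(sprintf(
      "non-uniform sampling: relative jitter %.3g exceeds the 1%% tolerance",
      jitter))
  }
  fs <- 1 / medDt

  new("IMURecording",
      data = as.matrix(df[IMU_CHANNELS]),
      time = df$time[1] + (seq_len(nrow(df)) - 1L) / fs,
      samplingRate = fs,
      meta = list(
        participant = meta[["participant"]] %||% NA_character_,
        condition = meta[["condition"]] %||% NA_character_,
        notes = meta[["notes"]] %||% "",
        droppedRows = nDropped,
        source = path
      ))
}
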