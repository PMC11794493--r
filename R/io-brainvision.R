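# BrainVision (.vhdr/.vmrk/.eeg) reader and writer. The format is an
# INI-style text header naming a flat binary data file and a text marker
# file; this implementation supports the multiplexed binary layout with
# IEEE_FLOAT_32 or INT_16 samples, the two dialects in common use.

parseIni <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- "_"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- regmatches(ln, regexpr("=", ln), invert = TRUE)[[1]]
      out[[section]][[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  out
}

#' Write a recording as a BrainVision triplet
#'
#' Writes \code{<base>.vhdr} (header), \code{<base>.vmrk} (markers:
#' stimulus events encoded as \code{Stimulus, channelType:musicType} at
#' 1-based sample positions, the format's native convention) and
#' \code{<base>.eeg} (multiplexed binary). The binary dialect is stated in
#' the header: IEEE_FLOAT_32 (default, lossless to single precision) or
#' INT_16 with a 0.1 uV resolution.
#'
#' @param rec an \code{\linkS4class{EEGRecording}}.
#' @param base path prefix (without extension).
#' @param binaryFormat \code{"IEEE_FLOAT_32"} or \code{"INT_16"}.
#' @return invisibly, the three file paths.
#' @export
writeBrainVision <- function(rec, base, binaryFormat = c("IEEE_FLOAT_32", "INT_16")) {
  binaryFormat <- match.arg(binaryFormat)
  stem <- basename(base)
  nCh <- nrow(rec@data)
  res <- if (binaryFormat == "INT_16") 0.1 else 1
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", stem),
    sprintf("MarkerFile=%s.vmrk", stem),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nCh),
    sprintf("SamplingInterval=%.6f", 1e6 / rec@fs),
    sprintf("Reference=%s", rec@reference),
    "[Binary Infos]",
    sprintf("BinaryFormat=%s", binaryFormat),
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%g,uV", seq_len(nCh), rec@channelLabels, res)
  )
  writeLines(hdr, paste0(base, ".vhdr"))

  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    "Codepage=UTF-8",
    sprintf("DataFile=%s.eeg", stem),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0"
  )
  if (nrow(rec@events)) {
    mk <- c(mk, sprintf("Mk%d=Stimulus,%s:%s,%d,1,0",
                        seq_len(nrow(rec@events)) + 1L,
                        rec@events$channelType, rec@events$musicType,
                        rec@events$onset + 1L))
  }
  writeLines(mk, paste0(base, ".vmrk"))

  con <- file(paste0(base, ".eeg"), "wb")
  on.exit(close(con))
  flat <- as.numeric(rec@data)        # column-major = multiplexed (ch fastest)
  if (binaryFormat == "IEEE_FLOAT_32") {
    writeBin(flat, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(pmin(flat / res, 32767), -32768))), con,
             size = 2, endian = "little")
  }
  invisible(paste0(base, c(".vhdr", ".vmrk", ".eeg")))
}

#' Read a BrainVision recording
#'
#' Parses the header triplet, validates units and binary format, scales data
#' to microvolts, and parses Stimulus markers back to 0-based sample onsets
#' (with \code{channelType:musicType} descriptions decoded when present).
#' Channels labeled VEOG/HEOG (or any label containing "EOG") are flagged as
#' EOG channels.
#'
#' @param path path to the \code{.vhdr} header (or base path without
#'   extension).
#' @return an \code{\linkS4class{EEGRecording}}.
#' @export
readBrainVision <- function(path) {
  if (grepl("\\.edf$", path, ignore.case = TRUE))
    stop("EDF input is not supported by this reader; convert to BrainVision ",
         "(.vhdr/.vmrk/.eeg) first")
  if (!grepl("\\.vhdr$", path)) path <- paste0(path, ".vhdr")
  if (!file.exists(path)) stop("header not found: ", path)
  ini <- parseIni(readLines(path, warn = FALSE))
  ci <- ini[["Common Infos"]]
  bi <- ini[["Binary Infos"]]
  chi <- ini[["Channel Infos"]]
  if (is.null(ci$DataFile)) stop("malformed header: no DataFile entry")
  if (!identical(ci$DataFormat, "BINARY"))
    stop("unsupported DataFormat: ", ci$DataFormat)
  if (!is.null(ci$DataOrientation) && ci$DataOrientation != "MULTIPLEXED")
    stop("unsupported DataOrientation: ", ci$DataOrientation)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)
  nCh <- as.integer(ci$NumberOfChannels)
  fmt <- if (is.null(bi$BinaryFormat)) "IEEE_FLOAT_32" else bi$BinaryFormat
  if (!fmt %in% c("IEEE_FLOAT_32", "INT_16"))
    stop("unsupported BinaryFormat: ", fmt)

  labels <- character(nCh)
  resolution <- rep(1, nCh)
  for (i in seq_len(nCh)) {
    entry <- chi[[paste0("Ch", i)]]
    if (is.null(entry)) stop("missing channel info for Ch", i)
    parts <- strsplit(entry, ",")[[1]]
    labels[i] <- parts[1]
    if (length(parts) >= 3 && nzchar(parts[3])) resolution[i] <- as.numeric(parts[3])
    unit <- if (length(parts) >= 4) parts[4] else "uV"
    if (!unit %in% c("uV", "µV", "microvolt", ""))
      stop(sprintf("channel '%s' has unsupported unit '%s' (expected uV)",
                   labels[i], unit))
  }

  eegPath <- file.path(dirname(path), ci$DataFile)
  if (!file.exists(eegPath)) stop("missing binary data file: ", eegPath)
  sz <- file.info(eegPath)$size
  con <- file(eegPath, "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    nVal <- sz %/% 4
    raw <- readBin(con, "numeric", n = nVal, size = 4, endian = "little")
  } else {
    nVal <- sz %/% 2
    raw <- readBin(con, "integer", n = nVal, size = 2, endian = "little")
  }
  nSamp <- length(raw) %/% nCh
  data <- matrix(raw[seq_len(nCh * nSamp)], nrow = nCh)
  data <- data * resolution
  rownames(data) <- labels

  events <- data.frame(onset = integer(0), channelType = character(0),
                       musicType = character(0), stringsAsFactors = FALSE)
  mrkPath <- if (!is.null(ci$MarkerFile)) file.path(dirname(path), ci$MarkerFile) else NULL
  if (!is.null(mrkPath) && file.exists(mrkPath)) {
    mi <- parseIni(readLines(mrkPath, warn = FALSE))[["Marker Infos"]]
    rows <- list()
    for (nm in names(mi)) {
      parts <- strsplit(mi[[nm]], ",")[[1]]
      if (length(parts) < 3 || parts[1] != "Stimulus") next
      desc <- strsplit(parts[2], ":")[[1]]
      rows[[nm]] <- data.frame(
        onset = as.integer(parts[3]) - 1L,          # native 1-based -> 0-based
        channelType = desc[1],
        musicType = if (length(desc) > 1) desc[2] else NA_character_,
        stringsAsFactors = FALSE)
    }
    if (length(rows)) {
      events <- do.call(rbind, rows)
      events <- events[order(events$onset), , drop = FALSE]
      rownames(events) <- NULL
    }
  }

  eog <- labels[grepl("EOG", labels, ignore.case = TRUE)]
  ref <- if (!is.null(ci$Reference) &&
             ci$Reference %in% c("average", "linked-mastoid")) ci$Reference else "other"
  new("EEGRecording", data = data, fs = fs, channelLabels = labels,
      eogLabels = eog, reference = ref, events = events,
      provenance = list(list(op = "read", params = list(path = path, format = fmt))))
}

#' Write a connectivity matrix as CSV
#'
#' Square CSV with a channel-label header, plus (optionally) the tidy
#' long-format pairs table.
#'
#' @param cm a \code{\linkS4class{ConnectivityMatrix}}.
#' @param file output CSV path.
#' @param long if TRUE, write the long format (\code{ch_i, ch_j, wpli}).
#' @return invisibly, \code{file}.
#' @export
writeConnectivityCSV <- function(cm, file, long = FALSE) {
  if (long) {
    W <- cm@W
    idx <- which(upper.tri(W), arr.ind = TRUE)
    df <- data.frame(subject = cm@subject, band = cm@band$name,
                     condition = paste(cm@condition, collapse = "/"),
                     ch_i = rownames(W)[idx[, 1]], ch_j = colnames(W)[idx[, 2]],
                     wpli = W[idx], stringsAsFactors = FALSE)
    write.csv(df, file, row.names = FALSE)
  } else {
    write.csv(as.data.frame(cm@W), file, row.names = TRUE)
  }
  invisible(file)
}
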