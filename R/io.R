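## Epoch persistence: a documented plain-text internal layout (YAML metadata
## + hex-float TSV, lossless) and BrainVision (.vhdr/.vmrk/.eeg, IEEE
## float32 multiplexed) for interoperability with standard EEG tooling.

#' Export epochs in the internal text layout
#'
#' Writes `<stem>.yaml` (sfreq, tmin, lock, channels, trial ids, dimensions)
#' and `<stem>.tsv`, one row per (trial, channel) with samples as C99
#' hex-float literals, so the roundtrip is bit-exact.
#'
#' @param epochs an [EEGEpochs-class]
#' @param stem output path stem (without extension)
#' @return the stem, invisibly
#' @export
exportEpochsText <- function(epochs, stem) {
  d <- epochsData(epochs)
  meta <- list(sfreq = samplingRate(epochs), tmin = epochs@tmin,
               lock = lockType(epochs), channels = channelLabels(epochs),
               trial_ids = trialIds(epochs), dims = dim(d))
  yaml::write_yaml(meta, paste0(stem, ".yaml"))
  m <- matrix(aperm(d, c(3, 2, 1)), nrow = dim(d)[1] * dim(d)[2],
              byrow = TRUE)
  lines <- apply(m, 1L, function(r) paste(sprintf("%a", r), collapse = "\t"))
  writeLines(lines, paste0(stem, ".tsv"))
  invisible(stem)
}

#' Import epochs from the internal text layout
#'
#' @param stem path stem written by [exportEpochsText()]
#' @return [EEGEpochs-class]
#' @export
importEpochsText <- function(stem) {
  yfile <- paste0(stem, ".yaml"); tfile <- paste0(stem, ".tsv")
  if (!file.exists(yfile) || !file.exists(tfile))
    stop("missing internal-layout files at stem: ", stem)
  meta <- yaml::read_yaml(yfile)
  lines <- readLines(tfile)
  dims <- unlist(meta$dims)
  if (length(lines) != dims[1] * dims[2])
    stop("truncated data file: expected ", dims[1] * dims[2], " rows, got ",
         length(lines))
  vals <- lapply(lines, function(l) as.numeric(strsplit(l, "\t")[[1]]))
  if (any(lengths(vals) != dims[3])) stop("truncated row in data file")
  m <- do.call(rbind, vals)
  d <- aperm(array(t(m), c(dims[3], dims[2], dims[1])), c(3, 2, 1))
  newEpochs(d, meta$sfreq, meta$tmin, meta$lock, unlist(meta$channels),
            unlist(meta$trial_ids))
}

#' Export epochs as BrainVision files
#'
#' Writes `<stem>.vhdr`, `<stem>.vmrk` and `<stem>.eeg` (binary IEEE
#' float32, multiplexed, unit microvolts). Epochs are concatenated in the
#' data file with a "New Segment" marker at each epoch onset; the epoch span
#' and lock are recorded in the header comment so the file round-trips.
#'
#' @param epochs an [EEGEpochs-class]
#' @param stem output path stem
#' @return the .vhdr path, invisibly
#' @export
writeBrainVision <- function(epochs, stem) {
  d <- epochsData(epochs)
  nch <- dim(d)[2]; ns <- dim(d)[3]; ntr <- dim(d)[1]
  base <- basename(stem)
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "", "[Common Infos]", "Codepage=UTF-8",
           paste0("DataFile=", base, ".eeg"),
           paste0("MarkerFile=", base, ".vmrk"),
           "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", nch),
           paste0("SamplingInterval=", format(1e6 / samplingRate(epochs))),
           "", "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
           "", "[Channel Infos]",
           sprintf("Ch%d=%s,,1,µV", seq_len(nch), channelLabels(epochs)),
           "", "[Comment]",
           paste0("EpochSamples=", ns),
           paste0("Tmin=", format(epochs@tmin, digits = 17)),
           paste0("Lock=", lockType(epochs)),
           paste0("TrialIds=", paste(trialIds(epochs), collapse = ",")))
  writeLines(hdr, paste0(stem, ".vhdr"))
  mrk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
           "", "[Common Infos]", "Codepage=UTF-8",
           paste0("DataFile=", base, ".eeg"), "", "[Marker Infos]",
           sprintf("Mk%d=New Segment,,%d,1,0", seq_len(ntr),
                   (seq_len(ntr) - 1L) * ns + 1L))
  writeLines(mrk, paste0(stem, ".vmrk"))
  # multiplexed: channel index varies fastest
  flat <- as.vector(aperm(d, c(2, 3, 1)))
  con <- file(paste0(stem, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(flat, con, size = 4L, endian = "little")
  invisible(paste0(stem, ".vhdr"))
}

parseIni <- function(lines) {
  kv <- grep("^[^;#\\[][^=]*=", lines, value = TRUE)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  setNames(vals, keys)
}

#' Import epochs from BrainVision files
#'
#' Supports the layout written by [writeBrainVision()]: binary IEEE float32,
#' multiplexed orientation, microvolt units. A truncated data file raises an
#' error and returns no partial object.
#'
#' @param vhdr path to the .vhdr header
#' @return [EEGEpochs-class]
#' @export
readBrainVision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE)
  ini <- parseIni(lines)
  if (!identical(unname(ini["DataFormat"]), "BINARY") ||
      !identical(unname(ini["BinaryFormat"]), "IEEE_FLOAT_32") ||
      !identical(unname(ini["DataOrientation"]), "MULTIPLEXED"))
    stop("unsupported BrainVision variant (need BINARY IEEE_FLOAT_32 ",
         "MULTIPLEXED)")
  nch <- as.integer(ini["NumberOfChannels"])
  sfreq <- 1e6 / as.numeric(ini["SamplingInterval"])
  ns <- as.integer(ini["EpochSamples"])
  tmin <- as.numeric(ini["Tmin"])
  lock <- unname(ini["Lock"])
  trial_ids <- as.integer(strsplit(unname(ini["TrialIds"]), ",")[[1]])
  ch_keys <- grep("^Ch[0-9]+$", names(ini), value = TRUE)
  ch_keys <- ch_keys[order(as.integer(sub("Ch", "", ch_keys)))]
  channels <- vapply(strsplit(unname(ini[ch_keys]), ","), `[`, "", 1L)
  units <- vapply(strsplit(unname(ini[ch_keys]), ","), function(p)
    if (length(p) >= 4) p[4] else "µV", "")
  bad <- channels[!units %in% c("µV", "uV", "")]
  if (length(bad))
    stop("channels not in microvolts: ", paste(bad, collapse = ", "))
  eeg <- file.path(dirname(vhdr), unname(ini["DataFile"]))
  n_expect <- as.double(nch) * ns * length(trial_ids)
  sz <- file.info(eeg)$size
  if (is.na(sz) || sz < 4 * n_expect)
    stop("truncated or missing data file: ", eeg)
  con <- file(eeg, "rb")
  on.exit(close(con))
  flat <- readBin(con, "numeric", n = n_expect, size = 4L, endian = "little")
  d <- aperm(array(flat, c(nch, ns, length(trial_ids))), c(3, 1, 2))
  newEpochs(d, sfreq, tmin, lock, channels, trial_ids)
}

#' Import epochs from a supported format
#'
#' @param path path stem (internal layout) or .vhdr file (BrainVision)
#' @param format "internal" or "brainvision"
#' @return [EEGEpochs-class]
#' @export
importEpochs <- function(path, format = c("internal", "brainvision")) {
  format <- match.arg(format)
  switch(format,
         internal = importEpochsText(sub("\\.(yaml|tsv)$", "", path)),
         brainvision = readBrainVision(path))
}
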