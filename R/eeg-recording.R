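#' Continuous multichannel EEG recording
#'
#' Lightweight container for a continuous EEG signal: a channels x samples
#' matrix in microvolts, a sampling rate, channel labels (10-20 names, plus
#' optionally one `"EOG"` channel), and an event table marking block onsets,
#' letter onsets, or auditory clicks.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param srate sampling rate in Hz (> 0).
#' @param channels character vector of unique channel labels, one per row of
#'   `data`. The label `"EOG"` marks the ocular reference channel.
#' @param events data frame with columns `sample` (1-based sample index) and
#'   `code` (character), e.g. `"block_on"`, `"block_off"`, `"S1"`, `"S2"`.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, channels, events = empty_events()) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (!is.numeric(srate) || length(srate) != 1L || srate <= 0)
    stop("`srate` must be a single positive number")
  channels <- as.character(channels)
  if (length(channels) != nrow(data))
    stop("need one channel label per row of `data`")
  if (anyDuplicated(channels))
    stop("channel labels must be unique")
  events <- as.data.frame(events)
  if (!all(c("sample", "code") %in% names(events)))
    stop("`events` needs columns `sample` and `code`")
  if (nrow(events) && (any(events$sample < 1) || any(events$sample > ncol(data))))
    stop("event sample indices must lie within the recording")
  rownames(data) <- channels
  structure(
    list(data = data, srate = srate, channels = channels,
         events = events[, c("sample", "code")]),
    class = "eeg_recording"
  )
}

empty_events <- function() data.frame(sample = integer(), code = character())

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate,
              nrow(x$events)))
  cat("  channels:", paste(x$channels, collapse = " "), "\n")
  invisible(x)
}

#' Indices of scalp (non-EOG) channels
#' @param rec an `eeg_recording`.
#' @return integer vector of row indices into `rec$data`.
#' @keywords internal
scalp_idx <- function(rec) which(rec$channels != "EOG")

#' Extract one channel as a numeric vector
#' @param rec an `eeg_recording`.
#' @param channel channel label.
#' @return numeric vector of samples.
#' @export
get_channel <- function(rec, channel) {
  i <- match(channel, rec$channels)
  if (is.na(i)) stop("channel not found: ", channel)
  rec$data[i, ]
}

# ---- BrainVision I/O ---------------------------------------------------
# Minimal writer/reader for the BrainVision triplet (.vhdr/.vmrk/.eeg),
# multiplexed IEEE float32, enough to round-trip recordings produced here.

#' Write a recording as a BrainVision file triplet
#'
#' Emits `<stem>.vhdr` (header), `<stem>.vmrk` (markers) and `<stem>.eeg`
#' (multiplexed little-endian float32, unit microvolt).
#'
#' @param rec an `eeg_recording`.
#' @param stem path without extension.
#' @return `stem`, invisibly.
#' @export
write_brainvision <- function(rec, stem) {
  base <- basename(stem)
  hdr <- c(
    "BrainVision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    sprintf("MarkerFile=%s.vmrk", base),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", nrow(rec$data)),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$srate),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_along(rec$channels), rec$channels)
  )
  writeLines(hdr, paste0(stem, ".vhdr"), useBytes = TRUE)
  mrk <- c(
    "BrainVision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.eeg", base),
    "[Marker Infos]",
    sprintf("Mk%d=Stimulus,%s,%d,1,0", seq_len(nrow(rec$events)),
            rec$events$code, rec$events$sample)
  )
  writeLines(mrk, paste0(stem, ".vmrk"), useBytes = TRUE)
  con <- file(paste0(stem, ".eeg"), "wb")
  on.exit(close(con))
  # multiplexed: sample-major, channel-minor
  writeBin(as.numeric(rec$data), con, size = 4, endian = "little")
  invisible(stem)
}

#' Read a BrainVision file triplet
#'
#' Supports the subset written by [write_brainvision()]: multiplexed
#' IEEE float32 data with stimulus markers.
#'
#' @param vhdr path to the `.vhdr` header file.
#' @return an `eeg_recording`.
#' @export
read_brainvision <- function(vhdr) {
  lines <- readLines(vhdr, warn = FALSE)
  val <- function(key) {
    m <- grep(paste0("^", key, "="), lines, value = TRUE)
    if (!length(m)) stop("missing header field: ", key)
    sub(paste0("^", key, "="), "", m[1])
  }
  nchan <- as.integer(val("NumberOfChannels"))
  srate <- 1e6 / as.numeric(val("SamplingInterval"))
  chl <- grep("^Ch[0-9]+=", lines, value = TRUE)
  channels <- vapply(strsplit(sub("^Ch[0-9]+=", "", chl), ","),
                     `[`, character(1), 1)
  stem <- sub("\\.vhdr$", "", vhdr)
  raw <- readBin(paste0(stem, ".eeg"), "numeric", size = 4,
                 n = file.size(paste0(stem, ".eeg")) / 4, endian = "little")
  data <- matrix(raw, nrow = nchan)
  mlines <- readLines(paste0(stem, ".vmrk"), warn = FALSE)
  mk <- grep("^Mk[0-9]+=", mlines, value = TRUE)
  events <- empty_events()
  if (length(mk)) {
    parts <- strsplit(sub("^Mk[0-9]+=", "", mk), ",")
    events <- data.frame(
      sample = as.integer(vapply(parts, `[`, character(1), 3)),
      code = vapply(parts, `[`, character(1), 2)
    )
  }
  eeg_recording(data, srate, channels, events)
}
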