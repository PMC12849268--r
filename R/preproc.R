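# EEG preprocessing: branch filtering, average reference, Gratton-Coles
# ocular correction, peak-to-peak artifact rejection, and epoching for the
# spectral (block-wise) and ERP (click-locked) branches.

#' Fixed-length epoch container
#'
#' @param data numeric array, epochs x channels x samples, microvolts.
#' @param srate sampling rate, Hz.
#' @param channels channel labels.
#' @param window_ms two-element window bounds in ms relative to the anchor.
#' @param baseline_ms baseline interval in ms, or `NULL`.
#' @param rejected logical rejection mask, one flag per epoch.
#' @param branch `"spectral"` or `"erp"`.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, srate, channels, window_ms, baseline_ms = NULL,
                      rejected = rep(FALSE, dim(data)[1]), branch = "spectral") {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(channels),
            length(rejected) == dim(data)[1])
  expect_len <- round(diff(window_ms) / 1000 * srate)
  if (abs(dim(data)[3] - expect_len) > 1)
    stop("sample count inconsistent with window length and sampling rate")
  structure(list(data = data, srate = srate, channels = channels,
                 window_ms = window_ms, baseline_ms = baseline_ms,
                 rejected = rejected, branch = branch),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set:%s> %d epochs (%d rejected) x %d channels x %d samples @ %g Hz, window [%g, %g] ms\n",
              x$branch, dim(x$data)[1], sum(x$rejected), dim(x$data)[2],
              dim(x$data)[3], x$srate, x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

#' Sample times of an epoch in ms relative to the anchor
#' @param ep an `epoch_set`.
#' @return numeric vector, one time per sample.
#' @export
epoch_times <- function(ep) {
  n <- dim(ep$data)[3]
  ep$window_ms[1] + (seq_len(n) - 1) / ep$srate * 1000
}

# second-order IIR notch (RBJ biquad), returned as an Arma filter
notch_biquad <- function(f0, fs, Q = 35) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  signal::Arma(b / a[1], a / a[1])
}

#' Filter a recording for one analysis branch
#'
#' Applies the zero-phase (forward-backward) filter chain of the requested
#' branch to every channel: the spectral branch is 1 Hz high-pass, 30 Hz
#' low-pass; the ERP branch is 0.1 Hz high-pass, 47 Hz low-pass; both add a
#' 50 Hz notch. High- and low-pass are order-2 Butterworth sections (order 4
#' effective after the forward-backward pass); the notch is a second-order
#' IIR with Q = 35.
#'
#' @param rec an [eeg_recording()].
#' @param branch `"spectral"` or `"erp"`.
#' @param notch_hz line frequency to notch out.
#' @param notch_q notch quality factor.
#' @return the filtered [eeg_recording()].
#' @export
filter_branch <- function(rec, branch = c("spectral", "erp"),
                          notch_hz = 50, notch_q = 35) {
  branch <- match.arg(branch)
  edges <- if (branch == "spectral") c(1, 30) else c(0.1, 47)
  nyq <- rec$srate / 2
  if (nyq <= edges[2]) stop("sampling rate too low for the low-pass edge")
  if (nyq <= notch_hz) stop("sampling rate too low for the notch frequency")
  hp <- signal::butter(2, edges[1] / nyq, type = "high")
  lp <- signal::butter(2, edges[2] / nyq, type = "low")
  nt <- notch_biquad(notch_hz, rec$srate, notch_q)
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ]
    x <- signal::filtfilt(hp, x)
    x <- signal::filtfilt(lp, x)
    x <- signal::filtfilt(nt, x)
    out$data[i, ] <- x
  }
  out
}

#' Re-reference to the average of the scalp electrodes
#'
#' Subtracts, at each sample, the mean over all scalp channels (the EOG
#' channel is excluded from the average and left untouched). The operation
#' is idempotent.
#'
#' @param rec an [eeg_recording()].
#' @return the re-referenced [eeg_recording()].
#' @export
rereference_average <- function(rec) {
  idx <- scalp_idx(rec)
  if (length(idx) < 2) stop("average reference needs at least two scalp channels")
  avg <- colMeans(rec$data[idx, , drop = FALSE])
  rec$data[idx, ] <- sweep(rec$data[idx, , drop = FALSE], 2, avg)
  rec
}

#' Gratton-Coles ocular artifact correction
#'
#' Estimates, for every scalp channel, the ocular propagation factor
#' b = cov(EOG, channel) / var(EOG) on the continuous data and subtracts
#' b x EOG from the channel, removing the blink contribution by regression.
#'
#' @param rec an [eeg_recording()] containing the EOG channel.
#' @param eog_channel label of the ocular reference channel.
#' @return the corrected [eeg_recording()]; the estimated propagation
#'   factors are attached as attribute `"propagation"`.
#' @export
gratton_coles <- function(rec, eog_channel = "EOG") {
  eog <- get_channel(rec, eog_channel)
  v <- stats::var(eog)
  if (v == 0) stop("EOG channel has zero variance; cannot estimate propagation")
  idx <- setdiff(seq_len(nrow(rec$data)), match(eog_channel, rec$channels))
  b <- numeric(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    b[k] <- stats::cov(eog, rec$data[i, ]) / v
    rec$data[i, ] <- rec$data[i, ] - b[k] * eog
  }
  attr(rec, "propagation") <- stats::setNames(b, rec$channels[idx])
  rec
}

# windowed running max/min via the doubling trick, O(n log w)
run_extreme <- function(x, w, max = TRUE) {
  f <- if (max) pmax else pmin
  m <- x
  len <- 1L
  while (len < w) {
    s <- min(len, w - len)
    n <- length(m)
    m <- f(m[seq_len(n - s)], m[(1 + s):n])
    len <- len + s
  }
  m
}

#' Flag epochs containing steep voltage steps
#'
#' An epoch is rejected iff any scalp channel shows a peak-to-peak (max
#' minus min) change exceeding `step_thresh` microvolts within any sliding
#' window of `window_ms` milliseconds. Flags are recorded in the rejection
#' mask; the data are untouched. Re-applying the operation never clears a
#' flag.
#'
#' @param epochs an [epoch_set()].
#' @param step_thresh rejection threshold, microvolt.
#' @param window_ms sliding-window length, ms.
#' @return the [epoch_set()] with an updated rejection mask.
#' @export
reject_artifacts <- function(epochs, step_thresh = 100, window_ms = 100) {
  w <- round(window_ms / 1000 * epochs$srate)
  n_samp <- dim(epochs$data)[3]
  if (w > n_samp) stop("rejection window longer than the epoch")
  w <- max(w, 2L)
  ch_use <- which(epochs$channels != "EOG")
  flag <- epochs$rejected
  for (e in seq_len(dim(epochs$data)[1])) {
    if (flag[e]) next
    for (c in ch_use) {
      x <- epochs$data[e, c, ]
      rng <- run_extreme(x, w, TRUE) - run_extreme(x, w, FALSE)
      if (any(rng > step_thresh)) { flag[e] <- TRUE; break }
    }
  }
  epochs$rejected <- flag
  epochs
}

#' Segment a task recording into overlapping spectral epochs per block
#'
#' Cuts each task block (delimited by `block_on`/`block_off` events) into
#' 2-second epochs whose starts advance by `epoch_s - overlap_s` = 1.8 s.
#' Epochs lie wholly inside their block; rest intervals are never epoched.
#'
#' @param rec a filtered [eeg_recording()] with block events.
#' @param epoch_s epoch length, seconds.
#' @param overlap_s overlap between consecutive epochs, seconds.
#' @return a list of [epoch_set()] objects, one per block.
#' @export
segment_spectral <- function(rec, epoch_s = 2, overlap_s = 0.2) {
  ons <- rec$events$sample[rec$events$code == "block_on"]
  offs <- rec$events$sample[rec$events$code == "block_off"]
  if (!length(ons) || length(ons) != length(offs))
    stop("recording must carry matching block_on/block_off events")
  fs <- rec$srate
  len <- round(epoch_s * fs)
  step <- round((epoch_s - overlap_s) * fs)
  out <- vector("list", length(ons))
  for (b in seq_along(ons)) {
    span <- offs[b] - ons[b] + 1
    if (span < len) stop("block ", b, " is shorter than one epoch")
    n_ep <- floor((span - len) / step) + 1
    arr <- array(0, dim = c(n_ep, nrow(rec$data), len))
    for (e in seq_len(n_ep)) {
      i0 <- ons[b] + (e - 1) * step
      arr[e, , ] <- rec$data[, i0:(i0 + len - 1)]
    }
    out[[b]] <- epoch_set(arr, fs, rec$channels,
                          window_ms = c(0, epoch_s * 1000),
                          branch = "spectral")
  }
  out
}

#' Segment a paired-click recording into baseline-corrected ERP epochs
#'
#' Extracts windows from -150 ms to 450 ms around every event of the
#' requested stimulus and subtracts, per channel and epoch, the mean over
#' the -50 ms to 0 ms baseline. Epochs that would extend past the recording
#' edge are dropped with a message.
#'
#' @param rec a filtered [eeg_recording()] with `S1`/`S2` events.
#' @param stimulus `"S1"` or `"S2"`.
#' @param window_ms epoch bounds relative to click onset, ms.
#' @param baseline_ms baseline interval, ms.
#' @return an [epoch_set()] with branch `"erp"`.
#' @export
segment_erp <- function(rec, stimulus = c("S1", "S2"),
                        window_ms = c(-150, 450), baseline_ms = c(-50, 0)) {
  stimulus <- match.arg(stimulus)
  anchors <- rec$events$sample[rec$events$code == stimulus]
  if (!length(anchors)) stop("no events with code ", stimulus)
  fs <- rec$srate
  i_start <- round(window_ms[1] / 1000 * fs)
  len <- round(diff(window_ms) / 1000 * fs)
  lo <- anchors + i_start
  hi <- lo + len - 1
  keep <- lo >= 1 & hi <= ncol(rec$data)
  if (any(!keep))
    message(sum(!keep), " ", stimulus,
            " epoch(s) dropped: window extends past the recording edge")
  anchors <- anchors[keep]
  if (!length(anchors)) stop("no ", stimulus, " epochs fit inside the recording")
  arr <- array(0, dim = c(length(anchors), nrow(rec$data), len))
  times <- window_ms[1] + (seq_len(len) - 1) / fs * 1000
  base_idx <- which(times >= baseline_ms[1] & times <= baseline_ms[2])
  for (e in seq_along(anchors)) {
    seg <- rec$data[, (anchors[e] + i_start):(anchors[e] + i_start + len - 1),
                    drop = FALSE]
    seg <- seg - rowMeans(seg[, base_idx, drop = FALSE])
    arr[e, , ] <- seg
  }
  epoch_set(arr, fs, rec$channels, window_ms = window_ms,
            baseline_ms = baseline_ms, branch = "erp")
}
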