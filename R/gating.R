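# p50 sensory gating: peak detection on the averaged click-evoked response
# at Cz, the suppression ratio with its degenerate-case rules, and the
# cohort-level exclusion rule.

#' Average the retained epochs of one channel
#'
#' @param epochs an [epoch_set()].
#' @param channel channel label.
#' @return list with `x` (averaged waveform, microvolt), `times_ms`, and
#'   `n_epochs` used.
#' @export
average_erp <- function(epochs, channel = "Cz") {
  i <- match(channel, epochs$channels)
  if (is.na(i)) stop("channel not found: ", channel)
  keep <- which(!epochs$rejected)
  if (!length(keep)) stop("no retained epochs to average")
  mat <- matrix(epochs$data[keep, i, , drop = FALSE], nrow = length(keep))
  list(x = colMeans(mat), times_ms = epoch_times(epochs), n_epochs = length(keep))
}

#' Detect the p50 component on an averaged waveform
#'
#' Finds the largest positive local maximum inside the search window
#' (default 40-80 ms post-stimulus), then the most negative trough between
#' `trough_floor_ms` and that peak. The p50 amplitude is the voltage
#' difference between the peak and the preceding trough. When the search
#' window contains no positive local maximum the component is declared
#' absent (`found = FALSE`); absence is a flag, not an error.
#'
#' @param x averaged waveform (microvolt), typically at Cz.
#' @param times_ms sample times relative to stimulus onset, ms.
#' @param search_ms two-element search window for the positive peak, ms.
#' @param trough_floor_ms lower bound of the preceding-trough search, ms.
#' @return list: `found`, `latency_ms`, `amplitude` (peak minus trough),
#'   `peak_uv`, `trough_uv`, `trough_latency_ms`.
#' @export
detect_p50 <- function(x, times_ms, search_ms = c(40, 80),
                       trough_floor_ms = 20) {
  stopifnot(length(x) == length(times_ms))
  win <- which(times_ms >= search_ms[1] & times_ms <= search_ms[2])
  if (length(win) < 3) stop("search window contains too few samples")
  # local maxima strictly above both neighbours (ties broken to the left)
  cand <- win[win > 1 & win < length(x)]
  is_peak <- x[cand] > x[cand - 1] & x[cand] >= x[cand + 1] & x[cand] > 0
  if (!any(is_peak))
    return(list(found = FALSE, latency_ms = NA_real_, amplitude = NA_real_,
                peak_uv = NA_real_, trough_uv = NA_real_,
                trough_latency_ms = NA_real_))
  peaks <- cand[is_peak]
  ip <- peaks[which.max(x[peaks])]
  tr_win <- which(times_ms >= trough_floor_ms & times_ms <= times_ms[ip])
  it <- tr_win[which.min(x[tr_win])]
  list(found = TRUE,
       latency_ms = times_ms[ip],
       amplitude = x[ip] - x[it],
       peak_uv = x[ip],
       trough_uv = x[it],
       trough_latency_ms = times_ms[it])
}

#' p50 suppression ratio with degenerate-case rules
#'
#' Computes the sensory-gating index (1 - S2/S1) x 100 (higher = stronger
#' gating). When no S2 component was found, its amplitude is substituted
#' with 0.01 microvolt before the ratio is formed; ratios below -200% are
#' clamped to -200%. Both rules set flags.
#'
#' @param s1_amp S1 p50 amplitude, microvolt (> 0).
#' @param s2_amp S2 p50 amplitude, microvolt (ignored when `s2_found` is
#'   `FALSE`).
#' @param s2_found was an S2 component identified?
#' @return list: `ratio` (percent), `s2_used` (amplitude entering the
#'   ratio), `s2_substituted`, `clamped`.
#' @export
suppression_ratio <- function(s1_amp, s2_amp, s2_found = TRUE) {
  if (!is.finite(s1_amp) || s1_amp <= 0)
    stop("S1 amplitude must be positive; an absent S1 is an exclusion, not a ratio")
  substituted <- !isTRUE(s2_found)
  s2_used <- if (substituted) 0.01 else s2_amp
  ratio <- (1 - s2_used / s1_amp) * 100
  clamped <- ratio < -200
  if (clamped) ratio <- -200
  list(ratio = ratio, s2_used = s2_used,
       s2_substituted = substituted, clamped = clamped)
}

#' One gating measurement from a paired-click recording
#'
#' Runs the ERP branch on a single recording: optional branch filtering,
#' ocular correction, and average referencing on the continuous data, then
#' S1/S2 epoching with baseline correction, artifact rejection, averaging
#' at Cz, p50 detection, and the suppression ratio.
#'
#' @param rec an [eeg_recording()] with `S1`/`S2` events.
#' @param do_filter,do_ocular,do_reref toggle the continuous-data steps
#'   (ocular correction requires an `"EOG"` channel).
#' @param search_ms,trough_floor_ms p50 detection windows, see
#'   [detect_p50()].
#' @param step_thresh,reject_window_ms artifact-rejection parameters, see
#'   [reject_artifacts()].
#' @return one-row data frame: S1/S2 amplitudes and latencies, `ratio`,
#'   flags (`s1_found`, `s2_found`, `s2_substituted`, `clamped`), and epoch
#'   counts.
#' @export
measure_gating <- function(rec, do_filter = TRUE, do_ocular = TRUE,
                           do_reref = TRUE, search_ms = c(40, 80),
                           trough_floor_ms = 20, step_thresh = 100,
                           reject_window_ms = 100) {
  if (do_filter) rec <- filter_branch(rec, "erp")
  if (do_ocular && "EOG" %in% rec$channels) rec <- gratton_coles(rec)
  if (do_reref) rec <- rereference_average(rec)
  amps <- lapply(c("S1", "S2"), function(stim) {
    ep <- segment_erp(rec, stim)
    ep <- reject_artifacts(ep, step_thresh, reject_window_ms)
    avg <- average_erp(ep, "Cz")
    det <- detect_p50(avg$x, avg$times_ms, search_ms, trough_floor_ms)
    c(det, n_epochs = avg$n_epochs)
  })
  s1 <- amps[[1]]; s2 <- amps[[2]]
  if (!s1$found) {
    return(data.frame(s1_amp = NA_real_, s2_amp = NA_real_,
                      s1_latency = NA_real_, s2_latency = NA_real_,
                      ratio = NA_real_, s1_found = FALSE,
                      s2_found = s2$found, s2_substituted = FALSE,
                      clamped = FALSE, n_epochs_s1 = s1$n_epochs,
                      n_epochs_s2 = s2$n_epochs))
  }
  sr <- suppression_ratio(s1$amplitude, s2$amplitude, s2$found)
  data.frame(s1_amp = s1$amplitude,
             s2_amp = if (s2$found) s2$amplitude else NA_real_,
             s1_latency = s1$latency_ms, s2_latency = s2$latency_ms,
             ratio = sr$ratio, s1_found = TRUE, s2_found = s2$found,
             s2_substituted = sr$s2_substituted, clamped = sr$clamped,
             n_epochs_s1 = s1$n_epochs, n_epochs_s2 = s2$n_epochs)
}

#' Cohort-level p50 inclusion rule
#'
#' A subject is excluded from all p50 analyses iff no S1 p50 component was
#' identifiable at the first gating measurement of the pre-assessment
#' (assessment `"pre"`, time `"begin"`). The exclusion covers every gating
#' measurement of that subject.
#'
#' @param results data frame with columns `subject`, `assessment`, `time`
#'   (`"begin"`/`"end"`), and `s1_found`.
#' @param pre_label,begin_label labels identifying the first measurement.
#' @return data frame `subject`, `included`, `reason`.
#' @export
gating_exclusions <- function(results, pre_label = "pre",
                              begin_label = "begin") {
  stopifnot(all(c("subject", "assessment", "time", "s1_found") %in% names(results)))
  first <- results[results$assessment == pre_label & results$time == begin_label, ]
  subjects <- unique(results$subject)
  excl <- first$subject[!first$s1_found]
  data.frame(
    subject = subjects,
    included = !(subjects %in% excl),
    reason = ifelse(subjects %in% excl,
                    "no identifiable p50 at first pre-assessment measurement", "")
  )
}
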