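# Spectral branch: tapered-FFT power spectra of 2-second epochs and the
# per-block frontal-theta / occipital-alpha fatigue markers.

# split-cosine-bell (Tukey) taper with `prop` of the samples tapered at
# each end; prop = 0.1 reproduces the "10% tapering" convention
split_cosine_taper <- function(n, prop = 0.1) {
  w <- rep(1, n)
  L <- floor(prop * n)
  if (L > 0) {
    i <- seq_len(L) - 1
    ramp <- 0.5 * (1 - cos(pi * i / L))
    w[seq_len(L)] <- ramp
    w[n + 1 - seq_len(L)] <- ramp
  }
  w
}

#' Power spectrum of one 2-second epoch
#'
#' FFT of a single-channel 2-second segment under a split-cosine taper with
#' 10% of the samples tapered at each end, yielding a one-sided power
#' spectrum on an exact 0.5 Hz grid. Powers are corrected for the taper's
#' power gain (mean squared taper), so the spectrum is Parseval-consistent:
#' a noiseless sinusoid of amplitude A concentrates total power A^2/2 around
#' its frequency bin.
#'
#' @param x numeric vector, one channel, exactly 2 seconds of samples.
#' @param srate sampling rate, Hz.
#' @param taper_prop fraction of samples tapered at each end.
#' @return data frame with columns `freq` (Hz, 0.5 Hz spacing) and `power`
#'   (microvolt^2).
#' @export
epoch_spectrum <- function(x, srate, taper_prop = 0.1) {
  n <- length(x)
  if (n != round(2 * srate))
    stop("epoch must be exactly 2 seconds long (got ", n, " samples at ",
         srate, " Hz)")
  w <- split_cosine_taper(n, taper_prop)
  X <- stats::fft(x * w)
  pg <- mean(w^2)                      # taper power gain
  nb <- floor(n / 2) + 1               # one-sided bins incl. DC and Nyquist
  p <- Mod(X[seq_len(nb)])^2 / (n^2 * pg)
  scale2 <- rep(2, nb)
  scale2[1] <- 1
  if (n %% 2 == 0) scale2[nb] <- 1
  data.frame(freq = (seq_len(nb) - 1) / 2, power = p * scale2)
}

#' Band power from a spectrum
#'
#' Total (default) or mean power over all bins with `lo <= f <= hi`, both
#' endpoints inclusive. At 0.5 Hz resolution the theta (4-7.5 Hz) and alpha
#' (8-12 Hz) bands never share a bin. The default total ("sum") aggregation
#' makes a noiseless sinusoid's band power equal its analytic power A^2/2.
#'
#' @param spectrum output of [epoch_spectrum()].
#' @param band two-element numeric, band edges in Hz.
#' @param agg `"sum"` for total band power or `"mean"` for per-bin average.
#' @return band power in microvolt^2.
#' @export
band_power <- function(spectrum, band, agg = c("sum", "mean")) {
  agg <- match.arg(agg)
  if (band[2] < band[1]) stop("band edges out of order")
  if (band[2] > max(spectrum$freq)) stop("band exceeds the Nyquist frequency")
  sel <- spectrum$freq >= band[1] & spectrum$freq <= band[2]
  if (!any(sel)) stop("band contains no frequency bins")
  if (agg == "sum") sum(spectrum$power[sel]) else mean(spectrum$power[sel])
}

#' Per-block fatigue markers: frontal theta and occipital alpha power
#'
#' For each block's epoch set, computes the band power of every retained
#' epoch at the marker electrode and averages across epochs: theta
#' (4-7.5 Hz) at Fz, alpha (8-12 Hz) at POz. Blocks whose epochs were all
#' rejected yield `NA` markers and a message.
#'
#' @param block_sets list of [epoch_set()] objects, one per block (output
#'   of [segment_spectral()], typically after [reject_artifacts()]).
#' @param theta_band,alpha_band band edges in Hz.
#' @param theta_channel,alpha_channel marker electrodes.
#' @param agg band aggregation passed to [band_power()].
#' @return data frame with one row per block: `block`, `theta_fz`,
#'   `alpha_poz`, `n_epochs_used`.
#' @export
block_markers <- function(block_sets, theta_band = c(4, 7.5),
                          alpha_band = c(8, 12), theta_channel = "Fz",
                          alpha_channel = "POz", agg = "sum") {
  rows <- lapply(seq_along(block_sets), function(b) {
    ep <- block_sets[[b]]
    keep <- which(!ep$rejected)
    if (!length(keep)) {
      message("block ", b, ": all epochs rejected; markers set to NA")
      return(data.frame(block = b, theta_fz = NA_real_, alpha_poz = NA_real_,
                        n_epochs_used = 0L))
    }
    i_th <- match(theta_channel, ep$channels)
    i_al <- match(alpha_channel, ep$channels)
    if (is.na(i_th) || is.na(i_al))
      stop("marker channels not present in the epoch set")
    th <- vapply(keep, function(e)
      band_power(epoch_spectrum(ep$data[e, i_th, ], ep$srate), theta_band, agg),
      numeric(1))
    al <- vapply(keep, function(e)
      band_power(epoch_spectrum(ep$data[e, i_al, ], ep$srate), alpha_band, agg),
      numeric(1))
    data.frame(block = b, theta_fz = mean(th), alpha_poz = mean(al),
               n_epochs_used = length(keep))
  })
  do.call(rbind, rows)
}
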