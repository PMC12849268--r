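# Synthetic cohort generation.
#
# Every generator is deterministic given its seed and produces data with
# analytic ground truth: band-limited sinusoidal carriers whose per-block
# amplitude follows a known linear drift, stereotyped p50 templates with
# exact peak-to-trough amplitudes, and bounded VAS series with known drift.

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' generators do not perturb the global random stream.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L) stop("`seed` must be a single number")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}

#' Derive a sub-seed from a master seed
#' @keywords internal
derive_seed <- function(seed, i) as.integer((as.numeric(seed) * 48271 + 7919 * i) %% 2147483629)

#' Standard 23-channel 10-20 montage used by the generators
#' @return character vector of 23 scalp labels.
#' @export
std_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC1", "FC2",
    "T7", "C3", "Cz", "C4", "T8", "P7", "P3", "Pz", "P4", "P8",
    "POz", "O1", "O2", "Oz")
}

#' Study design for the synthetic cohort
#'
#' Captures the cohort layout and effect specification the generators emulate:
#' two stimulation groups of 20, three assessments, an AX-CPT of six blocks of
#' 53 trials with four VAS queries, paired-click blocks of 60 pairs, and a
#' four-day adaptive Go/No-Go. Effect fields give population means and
#' between-subject SDs for the marker amplitudes and their per-block drifts;
#' `alpha_slope_offset` injects a group-by-assessment increment into the
#' occipital alpha amplitude slope (rows `group`, `assessment`, `offset`).
#'
#' @param n_per_group subjects per stimulation group.
#' @param groups group labels.
#' @param assessments assessment labels.
#' @param n_blocks AX-CPT blocks per assessment.
#' @param trials_per_block AX-CPT trials per block.
#' @param n_queries VAS queries per assessment.
#' @param n_pairs click pairs per gating measurement.
#' @param srate EEG sampling rate, Hz.
#' @param channels scalp channel labels (an `"EOG"` channel is appended).
#' @param rest_dur_s rest interval between AX-CPT blocks, seconds.
#' @param stim_dur_s,isi_s AX-CPT letter duration and inter-stimulus interval.
#' @param effects named list overriding any effect-specification default.
#' @param seed master seed; all per-subject seeds derive from it.
#'
#' @return a list of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = 20,
                          groups = c("verum", "sham"),
                          assessments = c("pre", "post", "followup"),
                          n_blocks = 6, trials_per_block = 53,
                          n_queries = 4, n_pairs = 60,
                          srate = 500, channels = std_channels(),
                          rest_dur_s = 120, stim_dur_s = 0.3, isi_s = 1.2,
                          effects = list(), seed = 1L) {
  stopifnot(n_per_group > 0, n_blocks > 0, trials_per_block > 0,
            n_queries >= 2, n_pairs >= 1, srate > 0)
  eff <- list(
    # marker carrier amplitudes (microvolt) and per-block drifts; drift SDs
    # sized so one-sample slope t-tests land near d ~ 0.75
    theta_base = 2.0, theta_base_sd = 0.5,
    theta_slope = 0.15, theta_slope_sd = 0.2,
    alpha_base = 3.0, alpha_base_sd = 0.7,
    alpha_slope = 0.20, alpha_slope_sd = 0.27,
    alpha_slope_offset = NULL,      # data.frame(group, assessment, offset)
    theta_freq = 6, alpha_freq = 10,
    eeg_noise_sd = 10,              # pink background, microvolt
    blink_rate_per_min = 15, blink_amp = 100,
    # paired-click p50 template amplitudes (peak-to-trough, microvolt)
    s1_amp = 2.0, s1_amp_sd = 0.4, gating_ratio = 0.5, gating_ratio_sd = 0.15,
    click_noise_sd = 5,
    # VAS: one fatigue latent, exhaustion drifts up, fitness down
    vas_exh_base = 40, vas_fit_base = 60, vas_base_sd = 10,
    vas_drift = 8, vas_drift_sd = 8, vas_noise_sd = 5,
    # AX-CPT behavior
    acc = 0.92, rt_mean = 450, rt_sd = 100,
    # Go/No-Go agent skill range (threshold of the psychometric curve, ms)
    gng_skill = 600, gng_skill_sd = 80
  )
  eff[names(effects)] <- effects
  if (any(vapply(eff[grep("_sd$", names(eff))], function(x) any(x < 0), FALSE)))
    stop("all SDs must be non-negative")
  structure(list(
    n_per_group = n_per_group, groups = groups, assessments = assessments,
    n_blocks = n_blocks, trials_per_block = trials_per_block,
    n_queries = n_queries, n_pairs = n_pairs, srate = srate,
    channels = channels, rest_dur_s = rest_dur_s,
    stim_dur_s = stim_dur_s, isi_s = isi_s,
    effects = eff, seed = as.integer(seed)
  ), class = "cohort_design")
}

#' Pink (1/f) noise
#'
#' Spectral-synthesis pink noise: white Gaussian noise shaped by 1/sqrt(f)
#' in the frequency domain, rescaled to the requested standard deviation.
#'
#' @param n number of samples.
#' @param sd target standard deviation.
#' @return numeric vector of length `n`.
#' @keywords internal
pink_noise <- function(n, sd = 1) {
  if (sd == 0 || n == 0) return(numeric(n))
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  k <- c(1, seq_len(n - 1))           # avoid the DC bin
  f <- pmin(k, n - k)
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x <- x - mean(x)
  x / stats::sd(x) * sd
}

# blink propagation: fraction of the ocular potential reaching each scalp site
blink_propagation <- function(channels) {
  front2 <- c("Fp1", "Fp2")
  front <- c("F7", "F3", "Fz", "F4", "F8")
  mid <- c("FC1", "FC2", "T7", "C3", "Cz", "C4", "T8")
  coef <- ifelse(channels %in% front2, 0.5,
          ifelse(channels %in% front, 0.3,
          ifelse(channels %in% mid, 0.15, 0.05)))
  coef[channels == "EOG"] <- 1
  stats::setNames(coef, channels)
}

#' Generate one AX-CPT EEG session
#'
#' Produces a continuous recording of pink background noise with a theta
#' carrier at Fz and an alpha carrier at POz whose amplitude is constant
#' within a block and drifts linearly across blocks, plus Gaussian blink
#' pulses shared between a synthetic EOG channel and the scalp (front-weighted
#' propagation). Events mark block onsets/offsets (`block_on`/`block_off`)
#' and letter onsets (`letter`).
#'
#' @param subject_spec list with `theta_base`, `theta_slope`, `alpha_base`,
#'   `alpha_slope` (microvolt, microvolt/block) and optionally `theta_freq`
#'   (must lie in 4-7.5 Hz), `alpha_freq` (8-12 Hz), `noise_sd`,
#'   `blink_rate_per_min`, `blink_amp`.
#' @param design a [cohort_design()].
#' @param seed RNG seed.
#'
#' @return an [eeg_recording()] with `design$channels` plus `"EOG"`.
#' @export
gen_axcpt_eeg <- function(subject_spec, design = cohort_design(), seed = 1L) {
  sp <- subject_spec
  theta_freq <- sp$theta_freq %||% design$effects$theta_freq
  alpha_freq <- sp$alpha_freq %||% design$effects$alpha_freq
  if (theta_freq < 4 || theta_freq > 7.5)
    stop("theta carrier frequency must lie within the 4-7.5 Hz band")
  if (alpha_freq < 8 || alpha_freq > 12)
    stop("alpha carrier frequency must lie within the 8-12 Hz band")
  if (design$n_blocks <= 0) stop("block count must be positive")
  noise_sd <- sp$noise_sd %||% design$effects$eeg_noise_sd
  blink_rate <- sp$blink_rate_per_min %||% design$effects$blink_rate_per_min
  blink_amp <- sp$blink_amp %||% design$effects$blink_amp

  fs <- design$srate
  trial_dur <- design$stim_dur_s + design$isi_s
  block_dur <- design$trials_per_block * trial_dur
  lead <- 1
  block_on_s <- lead + (seq_len(design$n_blocks) - 1) * (block_dur + design$rest_dur_s)
  total_s <- lead + design$n_blocks * block_dur +
    (design$n_blocks - 1) * design$rest_dur_s + 1
  n <- round(total_s * fs)
  t <- (seq_len(n) - 1) / fs
  channels <- c(setdiff(design$channels, "EOG"), "EOG")

  with_seed(seed, {
    data <- matrix(0, nrow = length(channels), ncol = n,
                   dimnames = list(channels, NULL))
    if (noise_sd > 0)
      for (i in seq_along(channels))
        data[i, ] <- pink_noise(n, noise_sd)

    # block-wise amplitude envelopes (zero during rest)
    env_theta <- env_alpha <- numeric(n)
    for (b in seq_len(design$n_blocks)) {
      i0 <- round(block_on_s[b] * fs) + 1
      i1 <- round((block_on_s[b] + block_dur) * fs)
      env_theta[i0:i1] <- sp$theta_base + sp$theta_slope * (b - 1)
      env_alpha[i0:i1] <- sp$alpha_base + sp$alpha_slope * (b - 1)
    }
    data["Fz", ] <- data["Fz", ] + env_theta * sin(2 * pi * theta_freq * t)
    data["POz", ] <- data["POz", ] + env_alpha * sin(2 * pi * alpha_freq * t)

    # blinks: Gaussian pulses on the EOG, propagated to the scalp
    if (blink_rate > 0 && blink_amp > 0) {
      n_blinks <- stats::rpois(1, blink_rate * total_s / 60)
      if (n_blinks > 0) {
        centers <- sort(stats::runif(n_blinks, 0.5, total_s - 0.5))
        blink <- numeric(n)
        for (ct in centers) {
          idx <- which(abs(t - ct) < 0.25)
          blink[idx] <- blink[idx] + blink_amp * exp(-((t[idx] - ct)^2) / (2 * 0.05^2))
        }
        prop <- blink_propagation(channels)
        data <- data + outer(prop, rep(1, n)) * rep(blink, each = length(channels))
      }
    }

    ev <- list()
    for (b in seq_len(design$n_blocks)) {
      on <- round(block_on_s[b] * fs) + 1
      ev[[length(ev) + 1]] <- data.frame(sample = on, code = "block_on")
      letters_at <- on + round((seq_len(design$trials_per_block) - 1) * trial_dur * fs)
      ev[[length(ev) + 1]] <- data.frame(sample = letters_at, code = "letter")
      ev[[length(ev) + 1]] <- data.frame(sample = round((block_on_s[b] + block_dur) * fs),
                                         code = "block_off")
    }
    eeg_recording(data, fs, channels, do.call(rbind, ev))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Unit p50 template (peak-to-trough = 1)
#'
#' Biphasic waveform: negative trough near 35 ms, positive peak near 55 ms
#' post-click, normalized on the sample grid so its peak-to-trough distance
#' is exactly 1.
#' @keywords internal
p50_template <- function(srate, dur_s = 0.15) {
  tt <- seq(0, dur_s, by = 1 / srate)
  raw <- -0.5 * exp(-((tt - 0.035)^2) / (2 * 0.006^2)) +
          0.5 * exp(-((tt - 0.055)^2) / (2 * 0.007^2))
  raw / (max(raw) - min(raw))
}

#' Generate a paired-click recording
#'
#' Sixty pairs (by default) of click-evoked p50-like responses at Cz: within
#' a pair S2 follows S1 after exactly 500 ms; pairs are separated by a gap
#' drawn uniformly from 8-11 s. The evoked template has the requested
#' peak-to-trough amplitude (microvolt) and sits in pink noise.
#'
#' @param s1_amp,s2_amp peak-to-trough template amplitudes (>= 0).
#' @param noise_sd pink-noise SD, microvolt.
#' @param n_pairs number of click pairs.
#' @param seed RNG seed.
#' @param srate sampling rate, Hz.
#' @param channels channel labels; the template is placed on `"Cz"`.
#'
#' @return an [eeg_recording()] with `S1`/`S2` events.
#' @export
gen_paired_click <- function(s1_amp, s2_amp, noise_sd = 0, n_pairs = 60,
                             seed = 1L, srate = 500,
                             channels = c("Fz", "Cz", "POz", "EOG")) {
  if (s1_amp < 0 || s2_amp < 0) stop("click amplitudes must be non-negative")
  if (n_pairs < 1) stop("need at least one click pair")
  with_seed(seed, {
    gaps <- stats::runif(n_pairs, 8, 11)
    s1_times <- 1 + cumsum(c(0, gaps[-n_pairs]))
    s1_idx <- round(s1_times * srate) + 1
    s2_idx <- s1_idx + round(0.5 * srate)
    n <- max(s2_idx) + round(1 * srate)
    data <- matrix(0, nrow = length(channels), ncol = n,
                   dimnames = list(channels, NULL))
    if (noise_sd > 0)
      for (i in seq_along(channels))
        data[i, ] <- pink_noise(n, noise_sd)
    tmpl <- p50_template(srate)
    cz <- match("Cz", channels)
    if (is.na(cz)) stop("channel set must include Cz")
    for (k in seq_len(n_pairs)) {
      i1 <- s1_idx[k]; i2 <- s2_idx[k]
      span1 <- i1:(i1 + length(tmpl) - 1)
      span2 <- i2:(i2 + length(tmpl) - 1)
      data[cz, span1] <- data[cz, span1] + s1_amp * tmpl
      data[cz, span2] <- data[cz, span2] + s2_amp * tmpl
    }
    events <- rbind(
      data.frame(sample = s1_idx, code = "S1"),
      data.frame(sample = s2_idx, code = "S2")
    )
    events <- events[order(events$sample), ]
    eeg_recording(data, srate, channels, events)
  })
}

#' Generate a VAS rating series
#'
#' One visual-analogue scale (0-100) over `n_queries` queries with linear
#' drift and truncated-normal noise; values never leave the scale bounds.
#'
#' @param baseline value at the first query (0-100).
#' @param drift_per_query change per query, scale points.
#' @param noise_sd truncated-normal noise SD; `0` gives a deterministic
#'   clipped series.
#' @param n_queries number of queries.
#' @param seed RNG seed.
#' @return numeric vector of length `n_queries` in `[0, 100]`.
#' @export
gen_vas <- function(baseline, drift_per_query, noise_sd = 0, n_queries = 4,
                    seed = 1L) {
  if (baseline < 0 || baseline > 100) stop("baseline must lie in [0, 100]")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  mu <- baseline + drift_per_query * (seq_len(n_queries) - 1)
  if (noise_sd == 0) return(pmin(100, pmax(0, mu)))
  with_seed(seed, {
    mu_c <- pmin(100, pmax(0, mu))
    lo <- stats::pnorm(0, mu_c, noise_sd)
    hi <- stats::pnorm(100, mu_c, noise_sd)
    stats::qnorm(stats::runif(n_queries, lo, hi), mu_c, noise_sd)
  })
}

#' Generate an AX-CPT behavioral trial log
#'
#' Trials follow the classic AX-CPT mix (70% AX targets, 10% each AY/BX/BY);
#' correctness is Bernoulli at the requested accuracy and response times are
#' lognormal with the requested mean and SD. Error trials are flagged invalid
#' (excluded downstream from RT summaries, not from accuracy).
#'
#' @param acc per-trial probability of a correct response, in (0, 1].
#' @param rt_mean,rt_sd response-time mean and SD, ms.
#' @param design a [cohort_design()].
#' @param seed RNG seed.
#' @return data frame with one row per trial: `block`, `trial`, `cue`,
#'   `probe`, `is_target`, `correct`, `invalid`, `rt_ms`.
#' @export
gen_axcpt_behavior <- function(acc, rt_mean, rt_sd, design = cohort_design(),
                               seed = 1L) {
  if (acc <= 0 || acc > 1) stop("`acc` must lie in (0, 1]")
  n <- design$n_blocks * design$trials_per_block
  with_seed(seed, {
    type <- sample(c("AX", "AY", "BX", "BY"), n, replace = TRUE,
                   prob = c(0.7, 0.1, 0.1, 0.1))
    cue <- substr(type, 1, 1)
    probe <- substr(type, 2, 2)
    correct <- stats::runif(n) < acc
    sdlog <- sqrt(log(1 + (rt_sd / rt_mean)^2))
    meanlog <- log(rt_mean) - sdlog^2 / 2
    rt <- stats::rlnorm(n, meanlog, sdlog)
    data.frame(
      block = rep(seq_len(design$n_blocks), each = design$trials_per_block),
      trial = rep(seq_len(design$trials_per_block), design$n_blocks),
      cue = cue, probe = probe,
      is_target = type == "AX",
      correct = correct,
      invalid = !correct,
      rt_ms = rt
    )
  })
}

#' Simulate a slope table directly
#'
#' Draws per-subject time-on-task slopes from the mixed-model data-generating
#' process the inference stage assumes: slope = grand mean + cell offset +
#' subject random intercept + residual. Used for calibration and power
#' studies without simulating EEG.
#'
#' @param n_per_group subjects per group.
#' @param groups,assessments factor labels.
#' @param grand_mean population mean slope.
#' @param sd_between between-subject SD (random intercept).
#' @param sd_resid residual SD.
#' @param offsets `NULL` (null design) or a data frame with columns `group`,
#'   `assessment`, `offset` giving cell-mean increments.
#' @param seed RNG seed.
#' @return data frame `subject`, `group`, `assessment`, `slope`.
#' @export
gen_slope_table <- function(n_per_group = 20, groups = c("verum", "sham"),
                            assessments = c("pre", "post", "followup"),
                            grand_mean = 0, sd_between = sqrt(0.5),
                            sd_resid = sqrt(0.5), offsets = NULL, seed = 1L) {
  with_seed(seed, {
    subjects <- paste0("S", sprintf("%03d", seq_len(n_per_group * length(groups))))
    grp <- rep(groups, each = n_per_group)
    u <- stats::rnorm(length(subjects), 0, sd_between)
    rows <- expand.grid(subject = subjects, assessment = assessments,
                        stringsAsFactors = FALSE)
    rows$group <- grp[match(rows$subject, subjects)]
    rows$slope <- grand_mean + u[match(rows$subject, subjects)] +
      stats::rnorm(nrow(rows), 0, sd_resid)
    if (!is.null(offsets)) {
      for (k in seq_len(nrow(offsets))) {
        sel <- rows$group == offsets$group[k] & rows$assessment == offsets$assessment[k]
        rows$slope[sel] <- rows$slope[sel] + offsets$offset[k]
      }
    }
    rows[, c("subject", "group", "assessment", "slope")]
  })
}

#' Generate a full synthetic cohort
#'
#' Draws per-subject marker levels and drifts from the design's effect
#' specification and generates, for every subject and assessment, the AX-CPT
#' EEG session, begin/end paired-click recordings, VAS series for both
#' scales, and the behavioral trial log; plus one four-day Go/No-Go run per
#' subject. All seeds derive from `design$seed`, so the cohort is fully
#' reproducible. When `out_dir` is given, EEG goes out as BrainVision
#' triplets, tabular data as TSV, and a JSON manifest lists every file with
#' the seed that produced it.
#'
#' @param design a [cohort_design()].
#' @param out_dir optional output directory.
#' @param gen_eeg generate the (large) AX-CPT EEG sessions; disable to keep
#'   only click, VAS, behavioral and Go/No-Go data.
#' @return a list with elements `design`, `subjects` (per-subject metadata),
#'   and `sessions` (nested per subject x assessment), invisibly also
#'   written to `out_dir` if requested.
#' @export
gen_cohort <- function(design = cohort_design(), out_dir = NULL,
                       gen_eeg = TRUE) {
  eff <- design$effects
  n_sub <- design$n_per_group * length(design$groups)
  subjects <- paste0("S", sprintf("%03d", seq_len(n_sub)))
  grp <- rep(design$groups, each = design$n_per_group)

  manifest <- list()
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(list.files(out_dir)))
      stop("output directory exists and is not empty: ", out_dir)
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }

  sub_meta <- with_seed(design$seed, data.frame(
    subject = subjects, group = grp,
    theta_base = stats::rnorm(n_sub, eff$theta_base, eff$theta_base_sd),
    theta_slope = stats::rnorm(n_sub, eff$theta_slope, eff$theta_slope_sd),
    alpha_base = stats::rnorm(n_sub, eff$alpha_base, eff$alpha_base_sd),
    alpha_slope = stats::rnorm(n_sub, eff$alpha_slope, eff$alpha_slope_sd),
    s1_amp = pmax(0.2, stats::rnorm(n_sub, eff$s1_amp, eff$s1_amp_sd)),
    gating_ratio = pmin(0.95, pmax(0.05,
      stats::rnorm(n_sub, eff$gating_ratio, eff$gating_ratio_sd))),
    vas_exh_base = stats::rnorm(n_sub, eff$vas_exh_base, eff$vas_base_sd),
    vas_fit_base = stats::rnorm(n_sub, eff$vas_fit_base, eff$vas_base_sd),
    vas_drift = stats::rnorm(n_sub, eff$vas_drift, eff$vas_drift_sd),
    gng_skill = stats::rnorm(n_sub, eff$gng_skill, eff$gng_skill_sd)
  ))
  sub_meta$theta_base <- pmax(0.1, sub_meta$theta_base)
  sub_meta$alpha_base <- pmax(0.1, sub_meta$alpha_base)
  sub_meta$vas_exh_base <- pmin(100, pmax(0, sub_meta$vas_exh_base))
  sub_meta$vas_fit_base <- pmin(100, pmax(0, sub_meta$vas_fit_base))

  sessions <- list()
  for (i in seq_len(n_sub)) {
    sid <- subjects[i]
    sessions[[sid]] <- list()
    for (a_i in seq_along(design$assessments)) {
      a <- design$assessments[a_i]
      sseed <- derive_seed(design$seed, i * 101 + a_i)
      alpha_slope_i <- sub_meta$alpha_slope[i]
      off <- eff$alpha_slope_offset
      if (!is.null(off)) {
        sel <- off$group == grp[i] & off$assessment == a
        if (any(sel)) alpha_slope_i <- alpha_slope_i + sum(off$offset[sel])
      }
      spec <- list(theta_base = sub_meta$theta_base[i],
                   theta_slope = sub_meta$theta_slope[i],
                   alpha_base = sub_meta$alpha_base[i],
                   alpha_slope = alpha_slope_i)
      sess <- list()
      if (gen_eeg)
        sess$eeg <- gen_axcpt_eeg(spec, design, seed = sseed)
      # sensory gating weakens slightly (s2 rises) after the fatiguing task
      s1 <- sub_meta$s1_amp[i]
      r <- sub_meta$gating_ratio[i]
      sess$click_begin <- gen_paired_click(s1, s1 * r, eff$click_noise_sd,
                                           design$n_pairs, derive_seed(sseed, 1),
                                           design$srate)
      sess$click_end <- gen_paired_click(s1, min(s1, s1 * (r + 0.1)),
                                         eff$click_noise_sd, design$n_pairs,
                                         derive_seed(sseed, 2), design$srate)
      sess$vas <- data.frame(
        query = seq_len(design$n_queries),
        exhaustion = gen_vas(sub_meta$vas_exh_base[i], sub_meta$vas_drift[i],
                             eff$vas_noise_sd, design$n_queries,
                             derive_seed(sseed, 3)),
        fitness = gen_vas(sub_meta$vas_fit_base[i], -sub_meta$vas_drift[i],
                          eff$vas_noise_sd, design$n_queries,
                          derive_seed(sseed, 4))
      )
      sess$behavior <- gen_axcpt_behavior(eff$acc, eff$rt_mean, eff$rt_sd,
                                          design, derive_seed(sseed, 5))
      sess$seed <- sseed
      sessions[[sid]][[a]] <- sess

      if (!is.null(out_dir)) {
        stem <- file.path(out_dir, sprintf("%s_%s", sid, a))
        if (gen_eeg) {
          write_brainvision(sess$eeg, paste0(stem, "_axcpt"))
          manifest[[length(manifest) + 1]] <- list(
            file = paste0(basename(stem), "_axcpt.vhdr"), subject = sid,
            assessment = a, kind = "axcpt_eeg", seed = sseed)
        }
        write_brainvision(sess$click_begin, paste0(stem, "_click_begin"))
        write_brainvision(sess$click_end, paste0(stem, "_click_end"))
        utils::write.table(sess$vas, paste0(stem, "_vas.tsv"), sep = "\t",
                           row.names = FALSE, quote = FALSE)
        utils::write.table(sess$behavior, paste0(stem, "_behavior.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
        manifest[[length(manifest) + 1]] <- list(
          file = paste0(basename(stem), "_vas.tsv"), subject = sid,
          assessment = a, kind = "vas", seed = sseed)
      }
    }
    gng_seed <- derive_seed(design$seed, 90000 + i)
    agent <- make_agent(threshold = sub_meta$gng_skill[i])
    sessions[[sid]]$gonogo <- simulate_participant(agent, days = 4,
                                                   seed = gng_seed)
    if (!is.null(out_dir)) {
      gf <- file.path(out_dir, sprintf("%s_gonogo.tsv", sid))
      utils::write.table(gonogo_trials(sessions[[sid]]$gonogo), gf,
                         sep = "\t", row.names = FALSE, quote = FALSE)
      manifest[[length(manifest) + 1]] <- list(
        file = basename(gf), subject = sid, kind = "gonogo", seed = gng_seed)
    }
  }

  out <- list(design = design, subjects = sub_meta, sessions = sessions)
  if (!is.null(out_dir)) {
    jsonlite::write_json(list(seed = design$seed, files = manifest),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
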