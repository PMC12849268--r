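# Pipeline orchestration: a single config object carrying every analysis
# constant, and a runner that chains synthesis -> preprocessing ->
# spectral/gating -> slope statistics -> mixed-model inference, writing
# tabular results plus a JSON manifest.

#' Default pipeline configuration
#'
#' All analysis constants in one place: filter edges per branch, band
#' definitions, p50 windows, the artifact-rejection rule, winsorization
#' threshold, staircase schedule, statistics options (denominator-df
#' method, FDR method, per-test continuity flags), and the synthetic-cohort
#' design. Values can be overridden individually via [load_config()].
#'
#' @return nested list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    design = list(
      n_per_group = 20, n_blocks = 6, trials_per_block = 53,
      n_queries = 4, n_pairs = 60, srate = 500, rest_dur_s = 120,
      channels = std_channels(), seed = 1L
    ),
    preproc = list(
      spectral_edges_hz = c(1, 30), erp_edges_hz = c(0.1, 47),
      notch_hz = 50, notch_q = 35,
      reject_step_uv = 100, reject_window_ms = 100,
      epoch_s = 2, overlap_s = 0.2,
      erp_window_ms = c(-150, 450), erp_baseline_ms = c(-50, 0)
    ),
    spectral = list(
      theta_band = c(4, 7.5), alpha_band = c(8, 12),
      theta_channel = "Fz", alpha_channel = "POz", taper_prop = 0.1
    ),
    gating = list(
      search_ms = c(40, 80), trough_floor_ms = 20,
      s2_substitute_uv = 0.01, ratio_floor_pct = -200
    ),
    stats = list(
      winsor_z = 2.5, ddf_method = "Satterthwaite", fdr_method = "BH",
      blinding_continuity = FALSE, gender_continuity = TRUE
    ),
    gonogo = list(
      initial_ms = 909, step_ms = 47, floor_ms = 345,
      up_threshold = 0.90, down_threshold = 0.65,
      n_blocks = 10, n_go = 60, n_nogo = 30, days = 4
    )
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it onto [default_config()]: any field
#' present in the file overrides the default, everything else keeps its
#' pinned value. The merged config is validated.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return a validated `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
  cfg
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Validate a pipeline configuration
#' @param cfg a `pipeline_config`.
#' @return `cfg`, invisibly; stops on an invalid field.
#' @export
validate_config <- function(cfg) {
  d <- cfg$design
  stopifnot(d$n_per_group > 0, d$n_blocks > 0, d$trials_per_block > 0,
            d$srate > 0, d$n_pairs >= 1)
  stopifnot(cfg$preproc$spectral_edges_hz[1] < cfg$preproc$spectral_edges_hz[2],
            cfg$preproc$erp_edges_hz[1] < cfg$preproc$erp_edges_hz[2],
            d$srate / 2 > cfg$preproc$spectral_edges_hz[2],
            d$srate / 2 > cfg$preproc$erp_edges_hz[2])
  stopifnot(cfg$spectral$theta_band[1] < cfg$spectral$theta_band[2],
            cfg$spectral$alpha_band[1] < cfg$spectral$alpha_band[2])
  stopifnot(cfg$stats$winsor_z > 0)
  stopifnot(cfg$gonogo$floor_ms <= cfg$gonogo$initial_ms)
  invisible(cfg)
}

#' Stable hash of a configuration
#' @param cfg a `pipeline_config`.
#' @return md5 hex string of the serialized config.
#' @export
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2)
  unname(tools::md5sum(f))
}

#' Spectral branch for one AX-CPT session
#'
#' Filter (spectral edges), Gratton-Coles ocular correction, average
#' reference, block-wise overlapping epoching, artifact rejection, and the
#' per-block theta/alpha markers.
#'
#' @param rec an [eeg_recording()] with block events.
#' @param cfg a `pipeline_config`.
#' @return data frame from [block_markers()].
#' @export
process_session_spectral <- function(rec, cfg = default_config()) {
  rec <- filter_branch(rec, "spectral", cfg$preproc$notch_hz, cfg$preproc$notch_q)
  if ("EOG" %in% rec$channels) rec <- gratton_coles(rec)
  rec <- rereference_average(rec)
  sets <- segment_spectral(rec, cfg$preproc$epoch_s, cfg$preproc$overlap_s)
  sets <- lapply(sets, reject_artifacts, step_thresh = cfg$preproc$reject_step_uv,
                 window_ms = cfg$preproc$reject_window_ms)
  block_markers(sets, cfg$spectral$theta_band, cfg$spectral$alpha_band,
                cfg$spectral$theta_channel, cfg$spectral$alpha_channel)
}

# per-block behavioral summaries; error trials are invalid for RT summaries
# only, accuracy is computed over all trials
behavior_blocks <- function(beh) {
  blocks <- sort(unique(beh$block))
  do.call(rbind, lapply(blocks, function(b) {
    d <- beh[beh$block == b, ]
    valid_rt <- d$rt_ms[!d$invalid]
    data.frame(block = b, accuracy = mean(d$correct),
               rt = if (length(valid_rt)) mean(valid_rt) else NA_real_,
               rt_sd = if (length(valid_rt) > 1) stats::sd(valid_rt) else NA_real_)
  }))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Generates the cohort, runs the spectral and gating branches on every
#' session, assembles long marker tables, winsorizes each variable within
#' block-by-assessment cells (pooled across groups), computes per-subject
#' time-on-task slopes, tests pre-assessment slopes against zero per group,
#' fits the slope mixed models (group x assessment) with Type-III ANOVAs
#' and BH-corrected post hoc contrasts, and analyzes the gating ratios with
#' the additional begin/end factor after applying the p50 exclusion rule.
#'
#' @param cfg a `pipeline_config`; `cfg$design` controls the cohort.
#' @param out_dir optional directory for TSV/JSON outputs and the manifest.
#' @param gen_eeg simulate and analyze the EEG branches (the expensive
#'   part); when `FALSE`, only VAS and behavior are analyzed.
#' @param effects effect overrides passed to [cohort_design()].
#' @return list: `markers` (long per-block/per-query table), `slopes`,
#'   `pre_tests`, `lmm` (per-variable ANOVA tables), `posthoc`, `gating`
#'   (results, exclusions, model), `config_hash`.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir = NULL,
                         gen_eeg = TRUE, effects = list()) {
  validate_config(cfg)
  d <- cfg$design
  design <- cohort_design(
    n_per_group = d$n_per_group, n_blocks = d$n_blocks,
    trials_per_block = d$trials_per_block, n_queries = d$n_queries,
    n_pairs = d$n_pairs, srate = d$srate, channels = d$channels,
    rest_dur_s = d$rest_dur_s, effects = effects, seed = d$seed
  )
  cohort <- gen_cohort(design, gen_eeg = gen_eeg)

  long <- list()
  gating_rows <- list()
  for (sid in names(cohort$sessions)) {
    grp <- cohort$subjects$group[cohort$subjects$subject == sid]
    for (a in design$assessments) {
      sess <- cohort$sessions[[sid]][[a]]
      base <- data.frame(subject = sid, group = grp, assessment = a)
      if (gen_eeg && !is.null(sess$eeg)) {
        mk <- process_session_spectral(sess$eeg, cfg)
        long[[length(long) + 1]] <- cbind(base, x = mk$block,
                                          variable = "theta_fz", value = mk$theta_fz)
        long[[length(long) + 1]] <- cbind(base, x = mk$block,
                                          variable = "alpha_poz", value = mk$alpha_poz)
      }
      bb <- behavior_blocks(sess$behavior)
      for (v in c("accuracy", "rt", "rt_sd"))
        long[[length(long) + 1]] <- cbind(base, x = bb$block, variable = v,
                                          value = bb[[v]])
      long[[length(long) + 1]] <- cbind(base, x = sess$vas$query,
                                        variable = "vas_exhaustion",
                                        value = sess$vas$exhaustion)
      long[[length(long) + 1]] <- cbind(base, x = sess$vas$query,
                                        variable = "vas_fitness",
                                        value = sess$vas$fitness)
      if (gen_eeg) {
        for (tm in c("begin", "end")) {
          rec <- if (tm == "begin") sess$click_begin else sess$click_end
          g <- measure_gating(rec, search_ms = cfg$gating$search_ms,
                              trough_floor_ms = cfg$gating$trough_floor_ms,
                              step_thresh = cfg$preproc$reject_step_uv,
                              reject_window_ms = cfg$preproc$reject_window_ms)
          gating_rows[[length(gating_rows) + 1]] <- cbind(base, time = tm, g)
        }
      }
      cohort$sessions[[sid]][[a]]$eeg <- NULL   # free memory as we go
    }
  }
  markers <- do.call(rbind, long)

  # winsorize within measurement-point x assessment cells, pooled over groups
  win <- do.call(rbind, lapply(split(markers, markers$variable), function(dd)
    winsorize_cells(dd, "value", c("x", "assessment"), cfg$stats$winsor_z)))
  rownames(win) <- NULL

  slopes <- do.call(rbind, lapply(split(win, win$variable), function(dd) {
    s <- compute_slopes(dd, "x", "value", c("subject", "group", "assessment"))
    s$variable <- dd$variable[1]
    s
  }))
  rownames(slopes) <- NULL

  pre <- slopes[slopes$assessment == "pre", ]
  pre_tests <- do.call(rbind, lapply(split(pre, list(pre$variable, pre$group),
                                           drop = TRUE), function(dd) {
    tt <- one_sample_t(dd$slope)
    data.frame(variable = dd$variable[1], group = dd$group[1],
               t = tt$statistic, df = tt$df, p = tt$p, d = tt$d,
               d_lower = tt$d_lower, d_upper = tt$d_upper)
  }))
  rownames(pre_tests) <- NULL

  lmm <- list(); posthoc <- list()
  for (v in unique(slopes$variable)) {
    sv <- slopes[slopes$variable == v, ]
    fit <- fit_slope_lmm(sv, dv = "slope", fixed = c("group", "assessment"))
    lmm[[v]] <- fit$anova
    ph <- try(posthoc_contrasts(fit, ~ group | assessment), silent = TRUE)
    if (!inherits(ph, "try-error")) posthoc[[v]] <- ph
  }

  gating_out <- NULL
  if (length(gating_rows)) {
    gr <- do.call(rbind, gating_rows)
    incl <- gating_exclusions(gr)
    gru <- gr[gr$subject %in% incl$subject[incl$included] & !is.na(gr$ratio), ]
    gmodel <- NULL
    if (length(unique(gru$subject)) >= 4) {
      gfit <- try(fit_slope_lmm(gru, dv = "ratio",
                                fixed = c("group", "assessment", "time")),
                  silent = TRUE)
      if (!inherits(gfit, "try-error")) gmodel <- gfit$anova
    }
    gating_out <- list(results = gr, inclusion = incl, anova = gmodel)
  }

  res <- list(markers = win, slopes = slopes, pre_tests = pre_tests,
              lmm = lmm, posthoc = posthoc, gating = gating_out,
              config_hash = config_hash(cfg))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(win, file.path(out_dir, "markers.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(slopes, file.path(out_dir, "slopes.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(pre_tests, file.path(out_dir, "pre_tests.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (v in names(lmm))
      utils::write.table(lmm[[v]], file.path(out_dir, paste0("anova_", v, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(gating_out)) {
      utils::write.table(gating_out$results, file.path(out_dir, "gating.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(
      list(config_hash = res$config_hash, seed = d$seed,
           r_version = as.character(getRversion()),
           n_subjects = nrow(cohort$subjects),
           variables = unique(slopes$variable)),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  res
}
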