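# Gamified adaptive Go/No-Go: trial generation, the accuracy-driven
# difficulty staircase, multi-day carry-over, an agent-based simulator, and
# session metrics including signal-detection d'.

#' Descent duration for a difficulty level
#'
#' Linear difficulty schedule: 909 ms at level 0, 47 ms faster per level,
#' hard floor at 345 ms (reached at level 12).
#'
#' @param level difficulty level (integer >= 0).
#' @param initial_ms,step_ms,floor_ms schedule parameters.
#' @return descent duration in ms.
#' @export
level_to_duration <- function(level, initial_ms = 909, step_ms = 47,
                              floor_ms = 345) {
  if (any(level < 0)) stop("difficulty level must be non-negative")
  pmax(initial_ms - step_ms * level, floor_ms)
}

#' Update the difficulty staircase after a block
#'
#' Level rises by one when block accuracy exceeds 90%, falls by one (floored
#' at 0) when it drops below 65%, and is unchanged for accuracies between
#' 65% and 90% (inclusive).
#'
#' @param state list with at least `level`.
#' @param block_accuracy proportion correct in the completed block, in
#'   `[0, 1]`.
#' @return the updated state with `level` and `descent_duration`.
#' @export
staircase_update <- function(state, block_accuracy) {
  stopifnot(block_accuracy >= 0, block_accuracy <= 1)
  lvl <- state$level
  if (block_accuracy > 0.90) lvl <- lvl + 1L
  else if (block_accuracy < 0.65) lvl <- max(lvl - 1L, 0L)
  state$level <- lvl
  state$descent_duration <- level_to_duration(lvl)
  state
}

#' Starting level for the next task day
#'
#' Two levels below the highest difficulty achieved on the previous day,
#' floored at 0. Day 1 starts at level 0.
#'
#' @param max_level_prev_day highest level reached on the previous day.
#' @return starting level.
#' @export
next_day_start <- function(max_level_prev_day) {
  max(max_level_prev_day - 2L, 0L)
}

#' Generate the trial list for one block
#'
#' Exactly 60 Go and 30 No-Go trials (fixed 2:1 ratio of 90), apple side
#' drawn left/right with equal probability, order shuffled by the seed.
#'
#' @param level current difficulty level.
#' @param seed RNG seed.
#' @param n_go,n_nogo trial counts.
#' @return data frame `type`, `side`, `level`, `duration_ms`.
#' @export
make_block_trials <- function(level, seed = 1L, n_go = 60, n_nogo = 30) {
  with_seed(seed, {
    n <- n_go + n_nogo
    type <- sample(rep(c("go", "nogo"), c(n_go, n_nogo)))
    data.frame(
      type = type,
      side = sample(c("left", "right"), n, replace = TRUE),
      level = level,
      duration_ms = level_to_duration(level)
    )
  })
}

#' Construct a simulated participant (response agent)
#'
#' The agent's probability of a correct trial outcome is a logistic
#' psychometric function of descent duration with a lapse rate:
#' p(correct) = lapse/2 + (1 - lapse) * plogis((duration - threshold)/slope).
#' Higher thresholds mean the agent needs slower apples; `skill = Inf`
#' effectively never errs. Response times are lognormal, truncated to the
#' descent duration.
#'
#' @param threshold duration (ms) at which performance is halfway between
#'   lapse-limited floor and ceiling.
#' @param slope psychometric slope, ms.
#' @param lapse lapse rate in `[0, 1)`.
#' @param rt_frac median RT as a fraction of the descent duration.
#' @param rt_sdlog lognormal RT spread.
#' @return list of class `gng_agent` with functions `p_correct(duration)`
#'   and `rt(duration, n)`.
#' @export
make_agent <- function(threshold = 600, slope = 80, lapse = 0.02,
                       rt_frac = 0.6, rt_sdlog = 0.25) {
  p_correct <- if (is.infinite(threshold) && threshold < 0) {
    function(duration_ms) rep(1, length(duration_ms))
  } else {
    function(duration_ms)
      lapse / 2 + (1 - lapse) * stats::plogis((duration_ms - threshold) / slope)
  }
  rt <- function(duration_ms, n) {
    lo <- pmin(50, duration_ms * 0.5)
    meanlog <- log(rt_frac * duration_ms)
    plo <- stats::plnorm(lo, meanlog, rt_sdlog)
    phi <- stats::plnorm(duration_ms, meanlog, rt_sdlog)
    stats::qlnorm(stats::runif(n, plo, phi), meanlog, rt_sdlog)
  }
  structure(list(p_correct = p_correct, rt = rt, threshold = threshold,
                 slope = slope, lapse = lapse), class = "gng_agent")
}

#' A deterministic error-free agent
#' @return a `gng_agent` with p(correct) = 1 at every duration.
#' @export
perfect_agent <- function() make_agent(threshold = -Inf)

#' Simulate one Go/No-Go session (10 blocks of 90 trials)
#'
#' Plays the adaptive task: within each block the agent's trial outcomes are
#' Bernoulli draws at its psychometric accuracy for the current descent
#' duration; after each block the staircase adjusts the level. Go errors are
#' split between omissions and wrong-side presses; any press on a No-Go
#' trial is a false alarm. Responses always occur before the apple lands
#' (RT <= descent duration).
#'
#' @param agent a [make_agent()] object.
#' @param start_level starting difficulty level.
#' @param seed RNG seed.
#' @param day day index recorded in the log.
#' @param n_blocks,n_go,n_nogo session layout.
#' @return list of class `gng_session`: `day`, `trials` (one row each:
#'   `block`, `type`, `side`, `level`, `duration_ms`, `response`, `rt_ms`,
#'   `correct`), `staircase` (per-block `level`, `accuracy`), `end_level`,
#'   `max_level`, `metrics` (see [session_metrics()]).
#' @export
simulate_session <- function(agent, start_level = 0, seed = 1L, day = 1L,
                             n_blocks = 10, n_go = 60, n_nogo = 30) {
  with_seed(seed, {
    state <- list(level = as.integer(start_level),
                  descent_duration = level_to_duration(start_level))
    trials <- vector("list", n_blocks)
    stair <- data.frame(block = seq_len(n_blocks), level = NA_integer_,
                        accuracy = NA_real_)
    for (b in seq_len(n_blocks)) {
      tr <- make_block_trials(state$level,
                              seed = stats::runif(1, 1, 2^30), n_go, n_nogo)
      n <- nrow(tr)
      p <- agent$p_correct(tr$duration_ms)
      correct <- stats::runif(n) < p
      response <- rep("none", n)
      rt <- rep(NA_real_, n)
      go <- tr$type == "go"
      # correct go: press the apple's side in time
      hit <- go & correct
      response[hit] <- tr$side[hit]
      rt[hit] <- agent$rt(tr$duration_ms[hit], sum(hit))
      # go errors: half omissions, half wrong-side presses
      gerr <- which(go & !correct)
      if (length(gerr)) {
        press <- gerr[stats::runif(length(gerr)) < 0.5]
        response[press] <- ifelse(tr$side[press] == "left", "right", "left")
        rt[press] <- agent$rt(tr$duration_ms[press], length(press))
      }
      # no-go errors: a press on either side (false alarm)
      ferr <- which(!go & !correct)
      if (length(ferr)) {
        response[ferr] <- sample(c("left", "right"), length(ferr), replace = TRUE)
        rt[ferr] <- agent$rt(tr$duration_ms[ferr], length(ferr))
      }
      tr$response <- response
      tr$rt_ms <- rt
      tr$correct <- correct
      tr$block <- b
      trials[[b]] <- tr
      acc <- mean(correct)
      stair$level[b] <- state$level
      stair$accuracy[b] <- acc
      state <- staircase_update(state, acc)
    }
    trials <- do.call(rbind, trials)
    sess <- list(day = day, trials = trials, staircase = stair,
                 end_level = state$level,
                 max_level = max(c(stair$level, state$level)))
    sess$metrics <- session_metrics(sess)
    structure(sess, class = "gng_session")
  })
}

#' Simulate the staircase trajectory only
#'
#' Identical staircase dynamics to [simulate_session()] but block accuracy
#' is drawn as a single binomial per block instead of logging 90 trials;
#' used for large-scale property checks on level/duration bounds.
#'
#' @inheritParams simulate_session
#' @return data frame `block`, `level`, `duration_ms`, `accuracy`, with
#'   attributes `end_level` and `max_level`.
#' @export
simulate_staircase <- function(agent, start_level = 0, seed = 1L,
                               n_blocks = 10, n_trials = 90) {
  with_seed(seed, {
    state <- list(level = as.integer(start_level),
                  descent_duration = level_to_duration(start_level))
    out <- data.frame(block = seq_len(n_blocks), level = NA_integer_,
                      duration_ms = NA_real_, accuracy = NA_real_)
    for (b in seq_len(n_blocks)) {
      dur <- level_to_duration(state$level)
      acc <- stats::rbinom(1, n_trials, agent$p_correct(dur)) / n_trials
      out$level[b] <- state$level
      out$duration_ms[b] <- dur
      out$accuracy[b] <- acc
      state <- staircase_update(state, acc)
    }
    attr(out, "end_level") <- state$level
    attr(out, "max_level") <- max(c(out$level, state$level))
    out
  })
}

#' Simulate a multi-day Go/No-Go run
#'
#' Day 1 starts at level 0; each later day starts two levels below the
#' previous day's maximum (floored at 0).
#'
#' @param agent a [make_agent()] object.
#' @param days number of daily sessions.
#' @param seed master seed; per-day seeds derive from it.
#' @return list of `gng_session` objects, one per day.
#' @export
simulate_participant <- function(agent, days = 4, seed = 1L) {
  sessions <- vector("list", days)
  start <- 0L
  for (d in seq_len(days)) {
    sessions[[d]] <- simulate_session(agent, start_level = start,
                                      seed = derive_seed(seed, d), day = d)
    start <- next_day_start(sessions[[d]]$max_level)
  }
  sessions
}

#' Bind the trial logs of a multi-day run
#' @param sessions output of [simulate_participant()].
#' @return one data frame with a `day` column.
#' @export
gonogo_trials <- function(sessions) {
  do.call(rbind, lapply(sessions, function(s) cbind(day = s$day, s$trials)))
}

#' Session-level performance metrics
#'
#' Accuracy over all trials; RT mean and SD over correct Go responses;
#' signal-detection d' = z(hit rate) - z(false-alarm rate) with the
#' log-linear correction (+0.5 to both numerators, +1 to both denominators)
#' so extreme rates stay finite; mean difficulty level across blocks. A hit
#' is a correct Go response (wrong-side presses are errors but not false
#' alarms); a false alarm is any press on a No-Go trial.
#'
#' @param session a `gng_session`.
#' @return list: `accuracy`, `rt_mean`, `rt_sd`, `dprime`, `mean_level`,
#'   `hit_rate`, `fa_rate`.
#' @export
session_metrics <- function(session) {
  tr <- session$trials
  go <- tr$type == "go"
  hits <- sum(go & tr$correct)
  fas <- sum(!go & tr$response != "none")
  hr <- (hits + 0.5) / (sum(go) + 1)
  far <- (fas + 0.5) / (sum(!go) + 1)
  rt_ok <- tr$rt_ms[go & tr$correct]
  list(
    accuracy = mean(tr$correct),
    rt_mean = if (length(rt_ok)) mean(rt_ok) else NA_real_,
    rt_sd = if (length(rt_ok) > 1) stats::sd(rt_ok) else NA_real_,
    dprime = stats::qnorm(hr) - stats::qnorm(far),
    mean_level = mean(session$staircase$level),
    hit_rate = hr, fa_rate = far
  )
}
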