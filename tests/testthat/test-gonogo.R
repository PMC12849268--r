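test_that("the level-duration schedule starts at 909 ms and floors at 345 ms", {
  expect_equal(level_to_duration(0), 909)
  lv <- 0:30
  dur <- level_to_duration(lv)
  expect_true(all(dur >= 345))
  # strictly decreasing until the floor is reached
  pre_floor <- dur > 345
  expect_true(all(diff(dur[pre_floor]) < 0))
  expect_error(level_to_duration(-1), "non-negative")
})

test_that("the staircase moves one step on the 90%/65% accuracy rules", {
  st <- list(level = 3L, descent_duration = level_to_duration(3))
  expect_equal(staircase_update(st, 0.92)$level, 4L)
  expect_equal(staircase_update(st, 0.60)$level, 2L)
  expect_equal(staircase_update(st, 0.75)$level, 3L)
  # boundary accuracies leave the level unchanged
  expect_equal(staircase_update(st, 0.90)$level, 3L)
  expect_equal(staircase_update(st, 0.65)$level, 3L)
  # floor at level 0
  st0 <- list(level = 0L, descent_duration = 909)
  expect_equal(staircase_update(st0, 0.3)$level, 0L)
  up <- staircase_update(st, 0.95)
  expect_equal(up$descent_duration, level_to_duration(4))
})

test_that("next-day start is two below the previous maximum, floored at zero", {
  expect_equal(next_day_start(7), 5)
  expect_equal(next_day_start(1), 0)
  expect_equal(next_day_start(2), 0)
})

test_that("block trials keep the fixed 2:1 Go/No-Go ratio under any seed", {
  for (seed in c(1, 99, 12345)) {
    tr <- make_block_trials(2, seed = seed)
    expect_equal(sum(tr$type == "go"), 60)
    expect_equal(sum(tr$type == "nogo"), 30)
    expect_true(all(tr$duration_ms == level_to_duration(2)))
  }
  a <- make_block_trials(0, seed = 1)
  b <- make_block_trials(0, seed = 2)
  expect_false(identical(a$type, b$type))   # different order
  expect_equal(table(a$type), table(b$type))
})

test_that("a perfect agent climbs one level per block to 10 on day one", {
  s <- simulate_session(perfect_agent(), start_level = 0, seed = 5)
  expect_equal(s$staircase$level, 0:9)
  expect_equal(s$end_level, 10L)
  expect_equal(nrow(s$trials), 900)
  expect_identical(simulate_session(perfect_agent(), 0, seed = 5)$trials,
                   s$trials)
})

test_that("a chance-level agent falls to level zero and stays there", {
  hopeless <- make_agent(threshold = 1e6)   # p(correct) ~ lapse/2
  s <- simulate_session(hopeless, start_level = 2, seed = 7)
  expect_true(all(diff(s$staircase$level) <= 0))
  expect_equal(s$end_level, 0L)
  expect_true(all(s$staircase$level[s$staircase$block > 3] == 0))
})

test_that("response times exist iff a response was made, and never exceed the duration", {
  s <- simulate_session(make_agent(threshold = 700), 0, seed = 11)
  tr <- s$trials
  expect_identical(is.na(tr$rt_ms), tr$response == "none")
  ok <- !is.na(tr$rt_ms)
  expect_true(all(tr$rt_ms[ok] <= tr$duration_ms[ok]))
  expect_true(all(tr$duration_ms >= 345 & tr$duration_ms <= 909))
})

test_that("session metrics equal a brute-force recount of the trial log", {
  s <- simulate_session(make_agent(threshold = 650), 1, seed = 13)
  tr <- s$trials
  m <- s$metrics
  expect_equal(m$accuracy, mean(tr$correct))
  go <- tr$type == "go"
  expect_equal(m$rt_mean, mean(tr$rt_ms[go & tr$correct]))
  expect_equal(m$rt_sd, sd(tr$rt_ms[go & tr$correct]))
  hits <- sum(go & tr$correct)
  fas <- sum(!go & tr$response != "none")
  expect_equal(m$dprime,
               qnorm((hits + 0.5) / (sum(go) + 1)) -
               qnorm((fas + 0.5) / (sum(!go) + 1)))
  expect_equal(m$mean_level, mean(s$staircase$level))
})

test_that("d-prime handles extreme and chance-level rates", {
  fake <- function(hits, n_go, fas, n_nogo) {
    tr <- data.frame(
      type = rep(c("go", "nogo"), c(n_go, n_nogo)),
      correct = c(rep(TRUE, hits), rep(FALSE, n_go - hits),
                  rep(TRUE, n_nogo - fas), rep(FALSE, fas)),
      response = c(rep("left", hits), rep("none", n_go - hits),
                   rep("none", n_nogo - fas), rep("left", fas)),
      rt_ms = NA_real_
    )
    session_metrics(list(trials = tr,
                         staircase = data.frame(block = 1, level = 0)))
  }
  perfect <- fake(600, 600, 0, 300)
  expect_true(is.finite(perfect$dprime) && perfect$dprime > 0)
  expect_equal(perfect$hit_rate, 600.5 / 601)
  expect_equal(perfect$fa_rate, 0.5 / 301)
  # hit rate equal to false-alarm rate gives d' = 0
  equal <- fake(300, 600, 150, 300)
  expect_equal(equal$dprime, 0)
})

test_that("replaying logged block accuracies reproduces the level trajectory", {
  s <- simulate_session(make_agent(threshold = 620), 3, seed = 17)
  state <- list(level = 3L, descent_duration = level_to_duration(3))
  for (b in seq_len(nrow(s$staircase))) {
    expect_equal(state$level, s$staircase$level[b])
    state <- staircase_update(state, s$staircase$accuracy[b])
  }
  expect_equal(state$level, s$end_level)
})

test_that("mean level is non-decreasing in agent skill", {
  thresholds <- c(1000, 800, 650, 500, 350)   # lower threshold = more skill
  mean_lv <- vapply(thresholds, function(th) {
    runs <- vapply(1:30, function(i) {
      st <- simulate_staircase(make_agent(threshold = th), 0, seed = 3000 + i)
      mean(st$level)
    }, numeric(1))
    mean(runs)
  }, numeric(1))
  expect_true(all(diff(mean_lv) >= -1e-9))
})

test_that("multi-day runs apply the carry-over rule and keep duration bounds", {
  sessions <- simulate_participant(make_agent(threshold = 600), days = 4,
                                   seed = 23)
  expect_length(sessions, 4)
  expect_equal(sessions[[1]]$staircase$level[1], 0)
  for (d in 2:4) {
    expect_equal(sessions[[d]]$staircase$level[1],
                 next_day_start(sessions[[d - 1]]$max_level))
  }
  tr <- gonogo_trials(sessions)
  expect_equal(nrow(tr), 4 * 900)
  expect_true(all(tr$duration_ms >= 345 & tr$duration_ms <= 909))
  expect_setequal(unique(tr$day), 1:4)
})
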