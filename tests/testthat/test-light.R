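test_that("the documented driver commands serialize bit-exactly", {
  expect_identical(build_command(b = 1000, pulse_ms = 100),
                   '{"pulse":100,"b":1000}')
  expect_identical(build_command(r = 100, ir = 1000),
                   '{"r":100,"ir":1000}')
  # and parse back to their stated meanings
  blue <- parse_command('{"pulse":100,"b":1000}')
  expect_equal(blue$pulse_ms, 100L)
  expect_equal(blue$channels$b, 1000L)
  imaging <- parse_command('{"r":100,"ir":1000}')
  expect_null(imaging$pulse_ms)
  expect_equal(imaging$channels$r, 100L)
  expect_equal(imaging$channels$ir, 1000L)
})

test_that("parse is the inverse of build over the valid command domain", {
  set.seed(51)
  for (i in 1:50) {
    keys <- sample(c("r", "g", "b", "w", "ir"), sample(1:5, 1))
    args <- as.list(setNames(sample(0:1000, length(keys)), keys))
    if (runif(1) < 0.5) args$pulse_ms <- sample(0:5000, 1)
    cmd <- do.call(light_command, args)
    text <- build_command(cmd)
    expect_false(grepl("[[:space:]]", text))
    back <- parse_command(text)
    expect_equal(back$channels, cmd$channels)
    expect_equal(back$pulse_ms, cmd$pulse_ms)
    expect_identical(build_command(back), text)
  }
})

test_that("invalid commands are rejected with the offending key", {
  expect_error(light_command(r = 1500), "r")
  expect_error(light_command(b = -1), "0–1000")
  expect_error(light_command(g = 2.5), "integer")
  expect_error(light_command(), "at least one")
  expect_error(parse_command('{"q":5}'), "unknown")
  expect_error(parse_command('{"r":1001}'), "0–1000")
  expect_error(parse_command('{"r":'), "malformed")
  expect_error(parse_command('{"pulse":-5,"b":1}'), "pulse")
})

test_that("driver state merges channels and restores after pulses", {
  st <- driver_state()
  st <- apply_command(st, light_command(ir = 1000), 0)
  st <- apply_command(st, light_command(r = 100), 10)
  expect_equal(unname(st$intensities[c("r", "ir")]), c(100, 1000))
  expect_equal(unname(st$intensities[c("g", "b", "w")]), c(0, 0, 0))
  # pulse then full restore
  st <- apply_command(st, light_command(b = 1000, pulse_ms = 100), 20)
  expect_equal(unname(driver_intensities(st, 50)[["b"]]), 1000)
  after <- driver_intensities(st, 121)
  expect_equal(unname(after[c("r", "b", "ir")]), c(100, 0, 1000))
  # overlapping pulses rejected
  st2 <- apply_command(driver_state(),
                       light_command(g = 500, pulse_ms = 200), 0)
  expect_error(apply_command(st2, light_command(b = 1, pulse_ms = 10), 50),
               "already active")
  # non-overlapping pulses leave no footprint on the steady state
  st3 <- driver_state()
  st3 <- apply_command(st3, light_command(w = 300), 0)
  st3 <- apply_command(st3, light_command(b = 1000, pulse_ms = 100), 10)
  st3 <- apply_command(st3, light_command(b = 1000, pulse_ms = 100), 500)
  expect_equal(driver_intensities(st3, 1000),
               driver_intensities(apply_command(driver_state(),
                                                light_command(w = 300), 0),
                                  1000))
  # constant commands commute iff their channel sets are disjoint
  ab <- apply_command(apply_command(driver_state(),
                                    light_command(r = 10), 0),
                      light_command(g = 20), 1)
  ba <- apply_command(apply_command(driver_state(),
                                    light_command(g = 20), 0),
                      light_command(r = 10), 1)
  expect_equal(ab$intensities, ba$intensities)
  xy <- apply_command(apply_command(driver_state(),
                                    light_command(r = 10), 0),
                      light_command(r = 99), 1)
  expect_equal(unname(xy$intensities[["r"]]), 99)
})

test_that("schedules map onto frame-aligned stimulus traces", {
  # empty schedule: all dark
  empty <- stimulus_schedule(numeric(0), list(), duration_s = 10)
  tr <- schedule_to_trace(empty, 30, 90)
  expect_true(all(tr[, c("r", "g", "b", "w", "ir")] == 0))
  # one 100 ms pulse at 30 fps: exactly 3 lit frames
  one <- stimulus_schedule(1, list(light_command(b = 1000, pulse_ms = 100)),
                           duration_s = 3)
  tr1 <- schedule_to_trace(one, 30, 90)
  expect_equal(sum(tr1$b > 0), 3)
  # pulses every 10 s over 60 s: 6 lit epochs
  onsets <- seq(0, 50, by = 10)
  cmds <- lapply(onsets, function(o) light_command(b = 1000, pulse_ms = 100))
  six <- stimulus_schedule(onsets, cmds, duration_s = 60)
  tr6 <- schedule_to_trace(six, 30, 60 * 30)
  lit <- tr6$b > 0
  epochs <- sum(diff(c(FALSE, lit)) == 1)
  expect_equal(epochs, 6)
  expect_equal(pulse_onsets(six), onsets)
  # an event past the recording end is ignored with a warning
  late <- stimulus_schedule(c(1, 50), list(light_command(b = 1),
                                           light_command(g = 1)),
                            duration_s = 60)
  expect_warning(schedule_to_trace(late, 30, 60), "ignored")
})

test_that("schedules round-trip through their JSON file format", {
  sched <- stimulus_schedule(
    c(10, 20.5), list(light_command(b = 1000, pulse_ms = 100),
                      light_command(r = 100, ir = 1000)),
    duration_s = 30)
  path <- withr::local_tempfile(fileext = ".json")
  write_schedule_json(sched, path)
  back <- read_schedule_json(path, duration_s = 30)
  expect_equal(back$onsets_s, sched$onsets_s)
  for (i in 1:2) {
    expect_equal(back$commands[[i]]$channels, sched$commands[[i]]$channels)
    expect_equal(back$commands[[i]]$pulse_ms, sched$commands[[i]]$pulse_ms)
  }
  expect_error(stimulus_schedule(c(5, 5), list(light_command(r = 1),
                                               light_command(g = 1))),
               "increasing")
})
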