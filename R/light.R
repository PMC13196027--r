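# LED-driver command protocol and stimulus schedules.
#
# The driver speaks compact JSON objects over serial (115200 baud) or
# MQTT; five channels (r, g, b, w, ir) take integer intensities on a
# 0-1000 PWM duty scale, and an optional "pulse" key flashes the listed
# channels for a duration in milliseconds before restoring the previous
# light state. The physical intensity mapping (duty to uE m-2 s-1) is a
# per-device linear calibration supplied by the caller, not hardcoded.

CHANNELS <- c("r", "g", "b", "w", "ir")

#' Construct an LED driver command
#'
#' @param r,g,b,w,ir optional channel intensities, integers in
#'   `[0, 1000]`.
#' @param pulse_ms optional pulse duration in milliseconds (integer
#'   >= 0); omitted means a constant output.
#' @return an object of class `light_command`.
#' @examples
#' light_command(b = 1000, pulse_ms = 100) # 100 ms full-power blue pulse
#' @export
light_command <- function(r = NULL, g = NULL, b = NULL, w = NULL,
                          ir = NULL, pulse_ms = NULL) {
  vals <- list(r = r, g = g, b = b, w = w, ir = ir)
  vals <- vals[!vapply(vals, is.null, TRUE)]
  if (length(vals) == 0 && is.null(pulse_ms))
    stop_domain("a command needs at least one field")
  for (k in names(vals)) {
    v <- vals[[k]]
    if (!is.numeric(v) || length(v) != 1 || v != round(v) || v < 0 ||
        v > 1000)
      stop_domain(sprintf("`%s` must be an integer in 0–1000", k))
    vals[[k]] <- as.integer(v)
  }
  if (!is.null(pulse_ms)) {
    if (!is.numeric(pulse_ms) || length(pulse_ms) != 1 ||
        pulse_ms != round(pulse_ms) || pulse_ms < 0)
      stop_domain("`pulse` must be an integer >= 0 (ms)")
    pulse_ms <- as.integer(pulse_ms)
  }
  structure(list(channels = vals, pulse_ms = pulse_ms),
            class = "light_command")
}

#' @export
print.light_command <- function(x, ...) {
  cat("<light_command>", build_command(x), "\n")
  invisible(x)
}

#' @export
format.light_command <- function(x, ...) build_command(x)

#' Serialize an LED command to its wire format
#'
#' Produces the compact JSON text the driver expects: no whitespace,
#' only the provided keys, in the order `pulse`, `r`, `g`, `b`, `w`,
#' `ir`. For example a 100 ms full-power blue pulse serializes to
#' `{"pulse":100,"b":1000}`.
#'
#' @param command a [light_command()], or channel values passed through
#'   `...` together with `pulse_ms`.
#' @param ... when `command` is missing: channel intensities (`r`, `g`,
#'   `b`, `w`, `ir`).
#' @param pulse_ms optional pulse duration (ms).
#' @return a single character string.
#' @export
build_command <- function(command, ..., pulse_ms = NULL) {
  if (missing(command)) command <- light_command(..., pulse_ms = pulse_ms)
  stopifnot(inherits(command, "light_command"))
  parts <- character()
  if (!is.null(command$pulse_ms))
    parts <- c(parts, sprintf('"pulse":%d', command$pulse_ms))
  for (k in CHANNELS)
    if (!is.null(command$channels[[k]]))
      parts <- c(parts, sprintf('"%s":%d', k, command$channels[[k]]))
  paste0("{", paste(parts, collapse = ","), "}")
}

#' Parse an LED command from its wire format
#'
#' Strict inverse of [build_command()]: the text must be a JSON object
#' whose keys all belong to `{pulse, r, g, b, w, ir}` with integer
#' values in range. Unknown keys, malformed JSON and non-integer
#' values are rejected.
#'
#' @param text a JSON command string.
#' @return a [light_command()].
#' @export
parse_command <- function(text) {
  obj <- tryCatch(jsonlite::fromJSON(text, simplifyVector = TRUE),
                  error = function(e) stop_domain(
                    paste0("malformed command: ", conditionMessage(e))))
  if (!is.list(obj) || is.null(names(obj)) || any(names(obj) == ""))
    stop_domain("command must be a JSON object")
  unknown <- setdiff(names(obj), c("pulse", CHANNELS))
  if (length(unknown) > 0)
    stop_domain(sprintf("unknown key(s): %s",
                        paste(unknown, collapse = ", ")))
  if (anyDuplicated(names(obj)))
    stop_domain("duplicate keys are not accepted")
  for (k in names(obj)) {
    v <- obj[[k]]
    if (!is.numeric(v) || length(v) != 1 || v != round(v))
      stop_domain(sprintf("`%s` must be an integer", k))
  }
  args <- obj[intersect(CHANNELS, names(obj))]
  do.call(light_command, c(args, list(pulse_ms = obj$pulse)))
}

#' LED driver state machine
#'
#' Tracks the five channel intensities (all 0 at power-on) and the
#' pending restore state during a pulse.
#'
#' @return an object of class `driver_state`.
#' @export
driver_state <- function() {
  structure(list(intensities = setNames(rep(0L, 5), CHANNELS),
                 pulse_until_ms = NA_real_, restore = NULL),
            class = "driver_state")
}

#' @export
print.driver_state <- function(x, ...) {
  cat("<driver_state>",
      paste(sprintf("%s=%d", CHANNELS, x$intensities[CHANNELS]),
            collapse = " "),
      if (!is.na(x$pulse_until_ms))
        sprintf("(pulse active until %g ms)", x$pulse_until_ms) else "",
      "\n")
  invisible(x)
}

settle_state <- function(state, now_ms) {
  if (!is.na(state$pulse_until_ms) && now_ms >= state$pulse_until_ms) {
    state$intensities <- state$restore
    state$pulse_until_ms <- NA_real_
    state$restore <- NULL
  }
  state
}

#' Apply a command to a driver state
#'
#' Without a pulse, the listed channels are set as a constant output
#' and unlisted channels are untouched (last writer wins per channel).
#' With a pulse, the listed channels flash for `pulse_ms` after which
#' the previous light state is restored. A second pulse arriving while
#' one is active is rejected. Constant commands arriving during an
#' active pulse update the state that will be restored.
#'
#' @param state a [driver_state()].
#' @param command a [light_command()].
#' @param now_ms current time in milliseconds.
#' @return the updated `driver_state`.
#' @export
apply_command <- function(state, command, now_ms = 0) {
  stopifnot(inherits(state, "driver_state"),
            inherits(command, "light_command"))
  state <- settle_state(state, now_ms)
  listed <- names(command$channels)
  if (!is.null(command$pulse_ms)) {
    if (!is.na(state$pulse_until_ms))
      stop_domain("a pulse is already active; overlapping pulses rejected")
    state$restore <- state$intensities
    state$intensities[listed] <- unlist(command$channels)
    state$pulse_until_ms <- now_ms + command$pulse_ms
  } else if (!is.na(state$pulse_until_ms)) {
    state$restore[listed] <- unlist(command$channels)
  } else {
    state$intensities[listed] <- unlist(command$channels)
  }
  state
}

#' Channel intensities at a given time
#'
#' @param state a [driver_state()].
#' @param now_ms evaluation time in milliseconds.
#' @return named integer vector of the five channel intensities.
#' @export
driver_intensities <- function(state, now_ms = 0) {
  settle_state(state, now_ms)$intensities
}

#' Stimulus schedule
#'
#' An ordered list of timed LED commands aligned to video time.
#'
#' @param onsets_s numeric vector of event times in seconds, strictly
#'   increasing.
#' @param commands list of [light_command()]s, one per onset.
#' @param duration_s total schedule duration; events must fall within
#'   it.
#' @return an object of class `stimulus_schedule`.
#' @export
stimulus_schedule <- function(onsets_s, commands, duration_s = NULL) {
  if (inherits(commands, "light_command")) commands <- list(commands)
  if (length(onsets_s) != length(commands))
    stop_domain("one command per onset required")
  if (length(onsets_s) > 1 && any(diff(onsets_s) <= 0))
    stop_domain("onsets must be strictly increasing")
  if (!all(vapply(commands, inherits, TRUE, "light_command")))
    stop_domain("`commands` must be light_command objects")
  if (is.null(duration_s))
    duration_s <- if (length(onsets_s) > 0) max(onsets_s) else 0
  if (length(onsets_s) > 0 && max(onsets_s) > duration_s)
    stop_domain("events must lie within the schedule duration")
  structure(list(onsets_s = as.numeric(onsets_s), commands = commands,
                 duration_s = duration_s),
            class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("<stimulus_schedule> %d events over %g s\n",
              length(x$onsets_s), x$duration_s))
  invisible(x)
}

#' Pulse onset times of a schedule
#'
#' @param schedule a [stimulus_schedule()].
#' @return numeric vector of onset times (s) of the events that carry a
#'   pulse.
#' @export
pulse_onsets <- function(schedule) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  has_pulse <- vapply(schedule$commands,
                      function(cmd) !is.null(cmd$pulse_ms), TRUE)
  schedule$onsets_s[has_pulse]
}

#' Write and read stimulus schedules as JSON
#'
#' File format: an array of `{"t": <seconds>, "cmd": {...}}` objects,
#' with each `cmd` in the driver wire format.
#'
#' @param schedule a [stimulus_schedule()].
#' @param path file path.
#' @return `path` invisibly ([write_schedule_json()]); a
#'   [stimulus_schedule()] ([read_schedule_json()]).
#' @export
write_schedule_json <- function(schedule, path) {
  events <- lapply(seq_along(schedule$onsets_s), function(i) {
    cmd <- schedule$commands[[i]]
    obj <- list()
    if (!is.null(cmd$pulse_ms)) obj$pulse <- cmd$pulse_ms
    for (k in CHANNELS)
      if (!is.null(cmd$channels[[k]])) obj[[k]] <- cmd$channels[[k]]
    list(t = schedule$onsets_s[i], cmd = obj)
  })
  jsonlite::write_json(events, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule_json
#' @param duration_s optional total duration override.
#' @export
read_schedule_json <- function(path, duration_s = NULL) {
  events <- jsonlite::read_json(path, simplifyVector = FALSE)
  onsets <- vapply(events, function(e) as.numeric(e$t), 0)
  commands <- lapply(events, function(e) {
    args <- e$cmd[intersect(CHANNELS, names(e$cmd))]
    do.call(light_command, c(args, list(pulse_ms = e$cmd$pulse)))
  })
  stimulus_schedule(onsets, commands, duration_s)
}

#' Per-frame stimulus state of a schedule
#'
#' Simulates [apply_command()] over the recording and evaluates the
#' driver state at each frame time `(i - 1) / frame_rate`, aligning
#' analysis windows with pulses. Events past the recording end are
#' ignored with a warning.
#'
#' @param schedule a [stimulus_schedule()].
#' @param frame_rate frames per second.
#' @param n_frames number of frames.
#' @return `data.frame` with `frame`, `time_s` and the five channel
#'   intensities.
#' @export
schedule_to_trace <- function(schedule, frame_rate, n_frames) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  check_positive(frame_rate = frame_rate, n_frames = n_frames)
  t_end <- (n_frames - 1) / frame_rate
  keep <- schedule$onsets_s <= t_end
  if (any(!keep)) {
    warning(sprintf("%d event(s) past the recording end ignored",
                    sum(!keep)))
  }
  onsets_ms <- schedule$onsets_s[keep] * 1000
  commands <- schedule$commands[keep]
  state <- driver_state()
  trace <- matrix(0L, n_frames, 5, dimnames = list(NULL, CHANNELS))
  ev <- 1L
  for (f in seq_len(n_frames)) {
    t_ms <- (f - 1) / frame_rate * 1000
    while (ev <= length(onsets_ms) && onsets_ms[ev] <= t_ms) {
      state <- apply_command(state, commands[[ev]], onsets_ms[ev])
      ev <- ev + 1L
    }
    trace[f, ] <- driver_intensities(state, t_ms)
  }
  data.frame(frame = seq_len(n_frames),
             time_s = (seq_len(n_frames) - 1) / frame_rate, trace)
}
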