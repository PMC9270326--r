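#' @keywords internal
"_PACKAGE"

#' The four stimulus condition labels
#'
#' The four stimulus configurations decouple event duration, event period
#' and mean display luminance, in the package's canonical order.
#'
#' @format Character vector of length 4.
#' @export
TIMING_CONDITIONS <- c("constant_luminance", "constant_duration",
                       "constant_period", "gaps")

TR_MS <- 2100L          # repetition time of the acquisition
BLOCK_MS <- 117600L     # one condition block: 56 TRs
BLOCK_N_TR <- 56L

#' Event timing of one stimulus step
#'
#' An event timing is a (duration, period) pair in milliseconds. Duration is
#' onset-to-offset time of one visual event; period is onset-to-next-onset
#' time, so `frequency_hz = 1000 / period_ms`. Duration never exceeds period:
#' an event ends no later than the next begins.
#'
#' @param duration_ms Event duration in ms (> 0).
#' @param period_ms Event period in ms (>= duration_ms).
#' @return A one-row data.frame with columns `duration_ms`, `period_ms`,
#'   `frequency_hz`.
#' @examples
#' event_timing(50, 1000)
#' @export
event_timing <- function(duration_ms, period_ms) {
  stopifnot(is.numeric(duration_ms), is.numeric(period_ms),
            length(duration_ms) == length(period_ms))
  if (any(duration_ms <= 0) || any(period_ms <= 0))
    stop("duration_ms and period_ms must be positive")
  if (any(duration_ms > period_ms))
    stop("duration_ms must not exceed period_ms")
  data.frame(duration_ms = as.numeric(duration_ms),
             period_ms = as.numeric(period_ms),
             frequency_hz = 1000 / as.numeric(period_ms))
}

#' Ordered timing steps of one sweep or gaps progression
#'
#' Standard conditions sweep one 20-step progression of timings in 50 ms
#' increments; the gaps condition runs four 10-step progressions that sample
#' duration/period combinations absent from the other conditions.
#'
#' * `constant_luminance`: duration and period equal, 50--1000 ms.
#' * `constant_duration`: duration fixed at 50 ms, period 50--1000 ms.
#' * `constant_period`: period fixed at 1000 ms, duration 50--1000 ms.
#' * `gaps`, segments 1--4: durations 50->500, 50->500, 500->50, 500->50 ms
#'   paired with periods 950->500, 550->1000, 500->950, 1000->550 ms.
#'
#' @param condition One of `"constant_luminance"`, `"constant_duration"`,
#'   `"constant_period"`, `"gaps"`.
#' @param direction `"ascending"` or `"descending"` for the standard
#'   conditions; an integer 1--4 selecting the gaps segment.
#' @return A data.frame of [event_timing()] rows, in presentation order
#'   (20 rows for standard conditions, 10 for a gaps segment).
#' @examples
#' sweep_timings("constant_duration", "ascending")
#' sweep_timings("gaps", 1)
#' @export
sweep_timings <- function(condition, direction = "ascending") {
  condition <- match.arg(condition, TIMING_CONDITIONS)
  steps <- seq(50, 1000, by = 50)
  if (condition == "gaps") {
    seg <- direction
    if (!is.numeric(seg) || length(seg) != 1 || !(seg %in% 1:4))
      stop("for the gaps condition, direction must be a segment index 1..4")
    dur_up <- seq(50, 500, by = 50)
    per <- switch(seg,
      `1` = list(dur = dur_up,      per = seq(950, 500, by = -50)),
      `2` = list(dur = dur_up,      per = seq(550, 1000, by = 50)),
      `3` = list(dur = rev(dur_up), per = seq(500, 950, by = 50)),
      `4` = list(dur = rev(dur_up), per = seq(1000, 550, by = -50)))
    return(event_timing(per$dur, per$per))
  }
  direction <- match.arg(direction, c("ascending", "descending"))
  if (direction == "descending") steps <- rev(steps)
  switch(condition,
    constant_luminance = event_timing(steps, steps),
    constant_duration  = event_timing(rep(50, length(steps)), steps),
    constant_period    = event_timing(steps, rep(1000, length(steps))))
}

# Interval-block event duration: 50 ms in the constant-duration condition,
# 2000 ms in constant-luminance and constant-period (period always 2100 ms).
interval_timing <- function(condition) {
  d <- if (condition == "constant_duration") 50 else 2000
  event_timing(d, 2100)
}

# Expand a condition into its ordered list of timing steps, each with a
# nominal occupancy in ms (sweep steps: one 2100 ms frame; intervals span
# several frames of one event per frame).
condition_steps <- function(condition) {
  condition <- match.arg(condition, TIMING_CONDITIONS)
  one_frame <- function(tw) cbind(tw, nominal_ms = TR_MS)
  if (condition == "gaps") {
    sep <- cbind(event_timing(50, 2100), nominal_ms = 6300)
    fin <- cbind(event_timing(50, 2100), nominal_ms = 14700)
    segs <- lapply(1:4, function(s) one_frame(sweep_timings("gaps", s)))
    out <- rbind(segs[[1]], sep, segs[[2]], sep, segs[[3]], sep,
                 segs[[4]], fin)
  } else {
    iv <- cbind(interval_timing(condition), nominal_ms = 16800)
    out <- rbind(one_frame(sweep_timings(condition, "ascending")), iv,
                 one_frame(sweep_timings(condition, "descending")), iv)
  }
  stopifnot(sum(out$nominal_ms) == BLOCK_MS)
  out
}

#' Assemble one condition block of scheduled events
#'
#' Tiles events contiguously through one 117.6 s (56 TR) condition block.
#' Each sweep timing step nominally occupies one 2100 ms TR frame; because
#' event periods need not divide 2100 ms, the repeat count of each step is
#' chosen greedily from the two integers bracketing the nominal count so the
#' cumulative schedule stays closest to the nominal TR grid (ties toward the
#' smaller count). Timing changes happen at event onsets. Events whose
#' offset would overrun the block end are dropped.
#'
#' @param condition Condition label (see [sweep_timings()]).
#' @return A `condition_schedule`: list with `condition`, `events` (data.frame
#'   with `event_index`, `onset_ms`, `offset_ms`, `duration_ms`, `period_ms`,
#'   `step`), `tr_ms`, `n_tr`, `per_tr_timing` (one timing row per TR) and
#'   `max_drift_ms`, the largest deviation of any step boundary from the
#'   nominal grid.
#' @examples
#' sch <- build_condition_schedule("constant_luminance")
#' sch$n_tr
#' @export
build_condition_schedule <- function(condition) {
  condition <- match.arg(condition, TIMING_CONDITIONS)
  steps <- condition_steps(condition)
  t <- 0
  nominal_end <- cumsum(steps$nominal_ms)
  ev <- vector("list", nrow(steps))
  drift <- numeric(nrow(steps))
  for (k in seq_len(nrow(steps))) {
    p <- steps$period_ms[k]
    n_lo <- floor((nominal_end[k] - t) / p)
    # greedy: whichever of the two bracketing counts lands nearest the grid
    n <- if (abs(t + (n_lo + 1) * p - nominal_end[k]) <
             abs(t + n_lo * p - nominal_end[k])) n_lo + 1L else n_lo
    n <- max(n, 0L)
    onsets <- t + p * (seq_len(n) - 1)
    ev[[k]] <- data.frame(onset_ms = onsets,
                          offset_ms = onsets + steps$duration_ms[k],
                          duration_ms = steps$duration_ms[k],
                          period_ms = p, step = k)
    t <- t + n * p
    drift[k] <- t - nominal_end[k]
  }
  events <- do.call(rbind, ev)
  events <- events[events$offset_ms <= BLOCK_MS, , drop = FALSE]
  events <- cbind(event_index = seq_len(nrow(events)), events)
  rownames(events) <- NULL
  sch <- structure(list(condition = condition, events = events,
                        tr_ms = TR_MS, n_tr = BLOCK_N_TR,
                        max_drift_ms = max(abs(drift))),
                   class = "condition_schedule")
  sch$per_tr_timing <- per_tr_timing(sch)
  sch
}

#' Per-TR stimulus timing labels
#'
#' Labels each TR of a condition block with the event timing whose events
#' occupy the majority of that 2100 ms window (each event occupies its full
#' period). Ties are broken toward the later timing step.
#'
#' @param schedule A `condition_schedule`.
#' @return Data.frame with one row per TR: `tr_index`, `duration_ms`,
#'   `period_ms`, `frequency_hz`.
#' @export
per_tr_timing <- function(schedule) {
  stopifnot(inherits(schedule, "condition_schedule"))
  if (!is.null(schedule$per_tr_timing)) return(schedule$per_tr_timing)
  ev <- schedule$events
  span_end <- pmin(ev$onset_ms + ev$period_ms, BLOCK_MS)
  out <- vector("list", schedule$n_tr)
  for (j in seq_len(schedule$n_tr)) {
    w0 <- (j - 1) * schedule$tr_ms
    w1 <- j * schedule$tr_ms
    ov <- pmin(span_end, w1) - pmax(ev$onset_ms, w0)
    ov[ov < 0] <- 0
    occ <- tapply(ov, ev$step, sum)
    occ <- occ[occ > 0]
    # ties toward the later step: with ties, pick the largest step index
    best <- as.integer(names(occ)[occ >= max(occ) - 1e-9])
    k <- max(best)
    i <- match(k, ev$step)
    out[[j]] <- data.frame(tr_index = j, duration_ms = ev$duration_ms[i],
                           period_ms = ev$period_ms[i],
                           frequency_hz = 1000 / ev$period_ms[i])
  }
  do.call(rbind, out)
}

#' Assemble a full scanning run from the four condition blocks
#'
#' Concatenates the four condition blocks in the given order, shifting onsets
#' by 117.6 s per block: one run is 224 TRs (470.4 s). There are 24 possible
#' run orders; the experiment presents each once.
#'
#' @param order Character vector: a permutation of the four condition labels.
#' @return A `run_schedule`: list with `order`, `blocks` (named list of
#'   `condition_schedule`s in presentation order), `events` (run-relative
#'   onset/offset times with a `block` column), `tr_ms`, `n_tr`.
#' @examples
#' run <- build_run_schedule(c("constant_luminance", "constant_duration",
#'                             "constant_period", "gaps"))
#' run$n_tr
#' @export
build_run_schedule <- function(order = TIMING_CONDITIONS) {
  if (length(order) != 4 || !setequal(order, TIMING_CONDITIONS) ||
      anyDuplicated(order))
    stop("order must be a permutation of the four condition labels")
  blocks <- lapply(order, build_condition_schedule)
  names(blocks) <- order
  ev <- lapply(seq_along(blocks), function(i) {
    e <- blocks[[i]]$events
    e$onset_ms <- e$onset_ms + (i - 1) * BLOCK_MS
    e$offset_ms <- e$offset_ms + (i - 1) * BLOCK_MS
    cbind(block = i, condition = order[i], e)
  })
  structure(list(order = order, blocks = blocks,
                 events = do.call(rbind, ev),
                 tr_ms = TR_MS, n_tr = 4L * BLOCK_N_TR),
            class = "run_schedule")
}

#' Event offset train of a schedule
#'
#' The forward models place the neural response to each event at its offset,
#' when the event's duration and period are fully determined.
#'
#' @param schedule A `condition_schedule` or `run_schedule`.
#' @return Data.frame with one row per event, in order: `offset_ms`,
#'   `duration_ms`, `period_ms`, `frequency_hz`.
#' @export
event_offsets <- function(schedule) {
  ev <- if (inherits(schedule, "run_schedule")) schedule$events
        else if (inherits(schedule, "condition_schedule")) schedule$events
        else stop("schedule must be a condition_schedule or run_schedule")
  data.frame(offset_ms = ev$offset_ms, duration_ms = ev$duration_ms,
             period_ms = ev$period_ms, frequency_hz = 1000 / ev$period_ms)
}

#' Serialize a schedule to TSV
#'
#' Writes one row per event with columns `block`, `condition`, `event_index`,
#' `onset_ms`, `offset_ms`, `duration_ms`, `period_ms`.
#'
#' @param schedule A `condition_schedule` or `run_schedule`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schedule_tsv <- function(schedule, path) {
  if (inherits(schedule, "condition_schedule")) {
    ev <- cbind(block = 1L, condition = schedule$condition, schedule$events)
  } else {
    ev <- schedule$events
  }
  cols <- c("block", "condition", "event_index", "onset_ms", "offset_ms",
            "duration_ms", "period_ms")
  utils::write.table(ev[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Design summary as JSON
#'
#' Per-TR timing table for each condition plus the TR framing constants,
#' written as a JSON design summary.
#'
#' @param path Output file path.
#' @param conditions Conditions to include.
#' @return `path`, invisibly.
#' @export
write_design_json <- function(path, conditions = TIMING_CONDITIONS) {
  per_tr <- lapply(conditions, function(cc)
    build_condition_schedule(cc)$per_tr_timing)
  names(per_tr) <- conditions
  jsonlite::write_json(
    list(tr_ms = TR_MS, block_n_tr = BLOCK_N_TR, run_n_tr = 4L * BLOCK_N_TR,
         per_tr_timing = per_tr),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
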