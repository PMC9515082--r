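#' Sonication session configuration
#'
#' All acoustic, timing and control parameters of one feedback-controlled
#' sonication session. Defaults follow the in vivo protocol: 500 kHz
#' drive, 1 Hz pulse repetition frequency, 10 ms pulses (1% duty cycle),
#' a 5 s dummy sonication at 0.3 MPa to calibrate the baseline, then 180 s
#' of treatment at a target cavitation level (TCL) stated in dB above the
#' baseline SC level.
#'
#' @param f0 Drive center frequency, Hz.
#' @param prf Pulse repetition frequency, Hz.
#' @param pulse_len Pulse length, seconds.
#' @param dummy_pressure Dummy-sonication peak-negative pressure, MPa.
#' @param dummy_duration Dummy-sonication duration, seconds.
#' @param treat_duration Treatment duration, seconds.
#' @param tcl_db Target cavitation level, dB above baseline SC
#'   (protocol values: 0.25, 0.5 or 1).
#' @param tol_db Tolerance half-width of the target range, dB.
#'   Default 0.125 (half the smallest protocol TCL).
#' @param ramp_step Pressure increment per pulse in the ramp-up phase, MPa.
#' @param maintain_step Pressure step in the maintaining phase, MPa.
#' @param p_max Safety pressure cap, MPa.
#' @param p_min Pressure floor, MPa (>= 0).
#' @param ic_event_db IC-event threshold, dB above the baseline IC level.
#'   The protocol fixes this at 1 dB.
#' @param ramp_entry When does ramping stop: `"at_tcl"` (first pulse whose
#'   SC level reaches the TCL, default) or `"in_band"` (first pulse inside
#'   TCL +/- tol).
#' @param ic_action Response to an IC event: `"log"` (record and continue,
#'   default) or `"stop"` (hard stop of the session).
#' @param db_convention dB convention for levels, see [to_db()].
#' @return An object of class `sonication_config`.
#' @export
sonication_config <- function(f0 = 5.0e5, prf = 1, pulse_len = 0.010,
                              dummy_pressure = 0.3, dummy_duration = 5,
                              treat_duration = 180, tcl_db = 0.5,
                              tol_db = 0.125, ramp_step = 0.01,
                              maintain_step = 0.005, p_max = 1.0,
                              p_min = 0, ic_event_db = 1.0,
                              ramp_entry = c("at_tcl", "in_band"),
                              ic_action = c("log", "stop"),
                              db_convention = c("amplitude", "power")) {
  cfg <- structure(list(
    f0 = f0, prf = prf, pulse_len = pulse_len,
    dummy_pressure = dummy_pressure, dummy_duration = dummy_duration,
    treat_duration = treat_duration, tcl_db = tcl_db, tol_db = tol_db,
    ramp_step = ramp_step, maintain_step = maintain_step,
    p_max = p_max, p_min = p_min, ic_event_db = ic_event_db,
    ramp_entry = match.arg(ramp_entry), ic_action = match.arg(ic_action),
    db_convention = match.arg(db_convention)
  ), class = "sonication_config")
  validate_sonication_config(cfg)
  cfg
}

validate_sonication_config <- function(cfg) {
  stopifnot(inherits(cfg, "sonication_config"))
  if (!(cfg$prf > 0)) stop("prf must be positive", call. = FALSE)
  dc <- cfg$pulse_len * cfg$prf
  if (!(dc > 0 && dc <= 1))
    stop("duty cycle pulse_len * prf must lie in (0, 1]", call. = FALSE)
  if (cfg$dummy_pressure > cfg$p_max)
    stop("dummy_pressure must not exceed p_max", call. = FALSE)
  if (!(cfg$tol_db > 0)) stop("tol_db must be positive", call. = FALSE)
  if (!(cfg$ramp_step > 0 && cfg$maintain_step > 0))
    stop("pressure steps must be positive", call. = FALSE)
  if (cfg$p_min < 0 || cfg$p_min > cfg$p_max)
    stop("need 0 <= p_min <= p_max", call. = FALSE)
  invisible(cfg)
}

#' Duty cycle of a pulse scheme
#'
#' @param cfg A `sonication_config`.
#' @return Duty cycle in percent: `100 * pulse_len * prf`.
#' @export
duty_cycle <- function(cfg) {
  if (cfg$prf <= 0) stop("prf must be positive", call. = FALSE)
  100 * cfg$pulse_len * cfg$prf
}

#' Controller step: pressure for the next pulse
#'
#' The two-phase control law. In the ramp-up phase the pressure is
#' increased by `ramp_step` every pulse until the measured SC level
#' reaches the TCL, which switches the controller to the maintaining
#' phase. In the maintaining phase the pressure of the next pulse is
#' decreased (increased) by `maintain_step` when the SC level lies above
#' (below) the target range TCL +/- tol, and kept the same inside it.
#' The output is always clamped to `[p_min, p_max]`; hitting the cap
#' raises a saturation flag on the state instead of aborting.
#'
#' @param state Controller state list with at least `phase`
#'   (`"ramp"`/`"maintain"`), `pressure` (the pressure of the pulse just
#'   measured, MPa) and `saturated` (logical).
#' @param sc_db Measured SC level of the latest pulse, dB re baseline.
#' @param cfg A `sonication_config`.
#' @return Updated state; `state$pressure` is the pressure of the next
#'   pulse.
#' @export
next_pressure <- function(state, sc_db, cfg) {
  stopifnot(state$phase %in% c("ramp", "maintain"))
  p <- state$pressure
  if (state$phase == "ramp") {
    reached <- switch(cfg$ramp_entry,
      at_tcl = sc_db >= cfg$tcl_db,
      in_band = abs(sc_db - cfg$tcl_db) <= cfg$tol_db)
    if (reached) {
      state$phase <- "maintain"
      # fall through: the first maintain pulse is issued by the maintain law
      return(next_pressure(state, sc_db, cfg))
    }
    p <- p + cfg$ramp_step
  } else {
    if (sc_db > cfg$tcl_db + cfg$tol_db) {
      p <- p - cfg$maintain_step
    } else if (sc_db < cfg$tcl_db - cfg$tol_db) {
      p <- p + cfg$maintain_step
    } # else: within the target range, pressure kept the same
  }
  if (p > cfg$p_max) {
    p <- cfg$p_max
    state$saturated <- TRUE
  }
  if (p < cfg$p_min) p <- cfg$p_min
  state$pressure <- p
  state
}

#' Run one closed-loop feedback-controlled sonication
#'
#' Executes the full session against a plant: `dummy_duration * prf`
#' dummy pulses at `dummy_pressure` whose SC/IC levels are averaged into
#' the baseline calibration, then `treat_duration * prf` treatment pulses
#' under the ramp/maintain law of [next_pressure()]. Each pulse is
#' recorded with its phase, drive pressure, linear and dB SC/IC levels,
#' and the derived in-band and IC-event flags.
#'
#' @param plant Either a [plant_params()] object (pulses are synthesized
#'   with [emit_pulse()]) or a function `f(p)` returning a voltage trace
#'   for a pressure `p` in MPa (supply `fs` in that case).
#' @param cfg A `sonication_config`.
#' @param seed Integer seed; the session is fully deterministic given it.
#' @param fs Sampling rate of traces returned by a function plant, Hz.
#'   Ignored for a `plant_params` plant.
#' @param sc,ic SC/IC [band()]s; defaults follow the protocol
#'   (4th harmonic of `cfg$f0`; 2.1 MHz).
#' @param keep_traces Keep the raw dummy/treatment traces in the result
#'   (memory-heavy at full scale). Default `FALSE`.
#' @return An object of class `treatment_log`: list with `config`,
#'   `baseline`, `records` (one data.frame row per pulse), `saturated`,
#'   `stopped_on_ic`, and optionally `traces`.
#' @export
run_treatment <- function(plant, cfg, seed = 1L, fs = NULL,
                          sc = sc_band(cfg$f0), ic = ic_band(),
                          keep_traces = FALSE) {
  validate_sonication_config(cfg)
  if (inherits(plant, "plant_params")) {
    fs <- plant$fs
    emit <- function(p) emit_pulse(p, plant)
  } else if (is.function(plant)) {
    if (is.null(fs)) stop("fs must be given for a function plant", call. = FALSE)
    emit <- plant
  } else stop("plant must be plant_params or a function", call. = FALSE)

  n_dummy <- as.integer(round(cfg$dummy_duration * cfg$prf))
  n_treat <- as.integer(round(cfg$treat_duration * cfg$prf))
  if (n_dummy < 1) stop("dummy phase must contain at least one pulse", call. = FALSE)

  withr::local_seed(as.integer(seed))

  # --- Step 1: dummy sonication and baseline calibration -------------------
  dummy_traces <- lapply(seq_len(n_dummy), function(i) emit(cfg$dummy_pressure))
  baseline <- calibrate_baseline(dummy_traces, fs, sc = sc, ic = ic)

  rec <- function(i, phase, p, lv) {
    data.frame(index = i, phase = phase, pressure_MPa = p,
               sc_linear = lv$sc_linear, ic_linear = lv$ic_linear,
               sc_db = lv$sc_db, ic_db = lv$ic_db,
               in_band = abs(lv$sc_db - cfg$tcl_db) <= cfg$tol_db,
               ic_event = lv$ic_db > cfg$ic_event_db,
               stringsAsFactors = FALSE)
  }
  records <- vector("list", n_dummy + n_treat)
  traces <- if (keep_traces) vector("list", n_dummy + n_treat) else NULL
  for (i in seq_len(n_dummy)) {
    lv <- pulse_levels(dummy_traces[[i]], fs, baseline, sc, ic,
                       cfg$db_convention)
    records[[i]] <- rec(i, "dummy", cfg$dummy_pressure, lv)
    if (keep_traces) traces[[i]] <- dummy_traces[[i]]
  }

  # --- Step 2: ramp-up then maintain ---------------------------------------
  state <- list(phase = "ramp",
                pressure = min(cfg$dummy_pressure + cfg$ramp_step, cfg$p_max),
                saturated = FALSE)
  stopped <- FALSE
  n_done <- 0L
  for (j in seq_len(n_treat)) {
    tr <- emit(state$pressure)
    lv <- pulse_levels(tr, fs, baseline, sc, ic, cfg$db_convention)
    i <- n_dummy + j
    records[[i]] <- rec(i, state$phase, state$pressure, lv)
    if (keep_traces) traces[[i]] <- tr
    n_done <- j
    if (cfg$ic_action == "stop" && lv$ic_db > cfg$ic_event_db) {
      stopped <- TRUE
      break
    }
    state <- next_pressure(state, lv$sc_db, cfg)
  }
  records <- do.call(rbind, records[seq_len(n_dummy + n_done)])
  rownames(records) <- NULL
  structure(list(config = cfg, baseline = baseline, records = records,
                 saturated = state$saturated, stopped_on_ic = stopped,
                 traces = traces, seed = as.integer(seed)),
            class = "treatment_log")
}

maintain_records <- function(log) {
  stopifnot(inherits(log, "treatment_log") || is.data.frame(log))
  rec <- if (is.data.frame(log)) log else log$records
  rec[rec$phase == "maintain", , drop = FALSE]
}

#' Good pulse rate of a session
#'
#' The controller's stability metric: the percentage of maintaining-phase
#' pulses whose SC level lies within the target range TCL +/- tol.
#'
#' @param log A `treatment_log` (or its records data.frame).
#' @return Percentage in `[0, 100]`.
#' @export
good_pulse_rate <- function(log) {
  m <- maintain_records(log)
  if (nrow(m) == 0)
    stop("good pulse rate undefined: no maintaining-phase pulses", call. = FALSE)
  100 * sum(m$in_band) / nrow(m)
}

#' Inertial cavitation probability of a session
#'
#' Percentage of maintaining-phase pulses whose IC level exceeds the
#' baseline IC level by more than the IC-event threshold (1 dB in the
#' protocol).
#'
#' @param log A `treatment_log` (or its records data.frame).
#' @return Percentage in `[0, 100]`.
#' @export
ic_probability <- function(log) {
  m <- maintain_records(log)
  if (nrow(m) == 0)
    stop("IC probability undefined: no maintaining-phase pulses", call. = FALSE)
  100 * sum(m$ic_event) / nrow(m)
}

#' Session summary statistics
#'
#' @param log A `treatment_log`.
#' @return A list: `tcl_db`, `good_pulse_rate_pct`, `ic_probability_pct`,
#'   `n_ramp`, `n_maintain`, `mean_maintain_pressure_MPa`, `saturated`.
#' @export
treatment_summary <- function(log) {
  stopifnot(inherits(log, "treatment_log"))
  m <- maintain_records(log)
  list(
    tcl_db = log$config$tcl_db,
    good_pulse_rate_pct = if (nrow(m) > 0) good_pulse_rate(log) else NA_real_,
    ic_probability_pct = if (nrow(m) > 0) ic_probability(log) else NA_real_,
    n_ramp = sum(log$records$phase == "ramp"),
    n_maintain = nrow(m),
    mean_maintain_pressure_MPa = if (nrow(m) > 0) mean(m$pressure_MPa) else NA_real_,
    saturated = isTRUE(log$saturated)
  )
}

#' @export
print.treatment_log <- function(x, ...) {
  s <- treatment_summary(x)
  cat(sprintf("Feedback-controlled sonication (TCL = %g dB, seed = %d)\n",
              s$tcl_db, x$seed))
  cat(sprintf("  pulses: %d dummy, %d ramp, %d maintain\n",
              sum(x$records$phase == "dummy"), s$n_ramp, s$n_maintain))
  cat(sprintf("  good pulse rate: %.1f %%   IC probability: %.2f %%\n",
              s$good_pulse_rate_pct, s$ic_probability_pct))
  cat(sprintf("  mean maintain pressure: %.4f MPa%s\n",
              s$mean_maintain_pressure_MPa,
              if (s$saturated) "   [saturated at p_max]" else ""))
  invisible(x)
}
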