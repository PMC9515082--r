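#' Synthetic microbubble-emission plant parameters
#'
#' Parameters of the synthetic "plant" that maps an applied peak-negative
#' pressure to a per-pulse passive-cavitation-detector (PCD) voltage trace.
#' The plant emits integer harmonics of the drive frequency whose amplitude
#' grows as a power law of pressure, sub/ultra-harmonics above an onset
#' pressure `p_uh`, and broadband (inertial) noise above `p_ic`, all seen
#' through a band-limited receiver and corrupted by additive electronic
#' noise. It stands in for the in vivo emission source when testing the
#' closed-loop controller.
#'
#' Amplitudes are arbitrary voltage units: the plant carries no absolute
#' voltage calibration, so only ratios and dB quantities are meaningful.
#'
#' @param f0 Drive (fundamental) frequency in Hz. Default 500 kHz.
#' @param fs Sampling rate of the PCD trace in Hz. Default 40 MHz.
#' @param pulse_len Pulse length in seconds. Default 10 ms. `fs * pulse_len`
#'   must be a whole number of samples.
#' @param n_harmonics Number of integer harmonics emitted. Default 8.
#' @param harm_amp Base amplitude coefficient per harmonic (length
#'   `n_harmonics`, arbitrary units). Default `0.5 / (1:n_harmonics)`.
#' @param uh_amp Amplitude coefficients of the sub/ultra-harmonic comb at
#'   `(m - 1/2) * f0`. Default `0.3 * harm_amp`.
#' @param gamma Pressure exponent of harmonic growth (dimensionless).
#'   Harmonic amplitude scales as `p^gamma`. Default 1.5.
#' @param p_uh Sub/ultra-harmonic onset pressure in MPa. Default 0.32.
#' @param p_ic Broadband (inertial cavitation) onset pressure in MPa.
#'   Default 0.45. Must satisfy `p_uh <= p_ic`.
#' @param bb_gain Broadband amplitude slope (a.u. per MPa) above `p_ic`.
#' @param noise_sigma Standard deviation of additive electronic noise.
#' @param amp_sigma Log-normal sigma of the per-pulse multiplicative
#'   variability applied to all harmonic amplitudes (physiological
#'   pulse-to-pulse variability). Default 0 (noiseless amplitudes).
#' @param amp_sigma_exp Exponent of the power-law growth of the
#'   variability sigma with pressure: the effective sigma is
#'   `amp_sigma * (p / p_ref)^amp_sigma_exp`. Emulates the loss of
#'   controllability at higher drive pressures, where microbubble
#'   oscillation becomes increasingly erratic. Default 12.
#' @param p_ref Reference pressure (MPa) at which the variability sigma
#'   equals `amp_sigma`. Default 0.3 (the dummy-sonication pressure).
#' @param rx_center Receiver center frequency in Hz. Default 2.25 MHz.
#' @param rx_bw Receiver -6 dB bandwidth in Hz. Default 600 kHz.
#' @param rx_order Roll-off order of the zero-phase receiver band-pass.
#' @param seed Optional integer seed attached to the parameter set.
#'
#' @return An object of class `plant_params`.
#' @seealso [emit_pulse()], [receiver_filter()], [make_fixture_set()]
#' @export
plant_params <- function(f0 = 5.0e5, fs = 4.0e7, pulse_len = 0.010,
                         n_harmonics = 8L, harm_amp = NULL, uh_amp = NULL,
                         gamma = 1.5, p_uh = 0.32, p_ic = 0.45,
                         bb_gain = 0.05, noise_sigma = 1e-3, amp_sigma = 0,
                         amp_sigma_exp = 12, p_ref = 0.3,
                         rx_center = 2.25e6, rx_bw = 6.0e5, rx_order = 4L,
                         seed = NULL) {
  n_harmonics <- as.integer(n_harmonics)
  if (is.null(harm_amp)) harm_amp <- 0.5 / seq_len(n_harmonics)
  if (is.null(uh_amp)) uh_amp <- 0.3 * harm_amp
  p <- structure(list(
    f0 = f0, fs = fs, pulse_len = pulse_len, n_harmonics = n_harmonics,
    harm_amp = harm_amp, uh_amp = uh_amp, gamma = gamma,
    p_uh = p_uh, p_ic = p_ic, bb_gain = bb_gain,
    noise_sigma = noise_sigma, amp_sigma = amp_sigma,
    amp_sigma_exp = amp_sigma_exp, p_ref = p_ref,
    rx_center = rx_center, rx_bw = rx_bw, rx_order = as.integer(rx_order),
    seed = seed
  ), class = "plant_params")
  validate_plant_params(p)
  p
}

validate_plant_params <- function(p) {
  stopifnot(inherits(p, "plant_params"))
  if (p$f0 <= 0 || p$fs <= 0 || p$pulse_len <= 0)
    stop("f0, fs and pulse_len must be positive", call. = FALSE)
  if (p$fs <= 2 * p$n_harmonics * p$f0)
    stop("fs must exceed twice the highest emitted harmonic (fs > 2*n_harmonics*f0)",
         call. = FALSE)
  n <- p$fs * p$pulse_len
  if (abs(n - round(n)) > 1e-6)
    stop("pulse_len * fs must be an integer sample count", call. = FALSE)
  if (length(p$harm_amp) != p$n_harmonics)
    stop("harm_amp must have length n_harmonics", call. = FALSE)
  if (any(p$harm_amp < 0) || any(p$uh_amp < 0) || p$bb_gain < 0 ||
      p$noise_sigma < 0 || p$amp_sigma < 0)
    stop("all amplitudes must be >= 0", call. = FALSE)
  if (p$p_ref <= 0)
    stop("p_ref must be positive", call. = FALSE)
  if (p$p_uh > p$p_ic)
    stop("p_uh must not exceed p_ic", call. = FALSE)
  if (p$rx_bw >= 2 * p$rx_center)
    stop("receiver bandwidth must be less than twice its center frequency",
         call. = FALSE)
  invisible(p)
}

#' Number of samples in one plant pulse
#' @param params A `plant_params` object.
#' @return Integer sample count `round(fs * pulse_len)`.
#' @export
n_samples <- function(params) {
  as.integer(round(params$fs * params$pulse_len))
}

#' Zero-phase band-limited receiver filter
#'
#' Applies the PCD receiver passband to a voltage trace: a zero-phase
#' band-pass with unit gain at `rx_center` and -6 dB (amplitude 0.5)
#' corners at `rx_center +/- rx_bw/2`. The filter is realized in the
#' frequency domain as a real (zero-phase) Butterworth-style magnitude
#' response `|H(f)| = (1 + 3 * (|f - rx_center| / (rx_bw/2))^(2*order))^(-1/2)`,
#' which hits exactly 0.5 at the stated corners.
#'
#' @param trace Numeric voltage trace sampled at `params$fs`.
#' @param params A `plant_params` object (receiver fields are used).
#' @return Filtered trace of the same length.
#' @export
receiver_filter <- function(trace, params) {
  validate_plant_params(params)
  n <- length(trace)
  if (n < 2) stop("trace must contain at least 2 samples", call. = FALSE)
  f <- (seq_len(n) - 1) * params$fs / n
  f <- pmin(f, params$fs - f)  # fold to [0, fs/2]: conjugate-symmetric H
  x <- abs(f - params$rx_center) / (params$rx_bw / 2)
  h <- 1 / sqrt(1 + 3 * x^(2 * params$rx_order))
  Re(stats::fft(stats::fft(trace) * h, inverse = TRUE)) / n
}

#' Emit one synthetic PCD pulse
#'
#' Maps an applied peak-negative pressure to a band-limited PCD voltage
#' trace. The raw emission is
#' \deqn{\sum_n A_n p^\gamma \sin(2\pi n f_0 t + \phi_n)
#'   + [p \ge p_{uh}] \sum_m U_m (p - p_{uh})^\gamma
#'     \sin(2\pi (m - 1/2) f_0 t + \psi_m)
#'   + [p \ge p_{ic}]\, g\,(p - p_{ic})\, w(t),}
#' passed through [receiver_filter()] with additive electronic noise
#' `noise_sigma * e(t)` appended afterwards. Phases and noise streams are
#' drawn from the R RNG; with `seed` given, the trace is bit-reproducible.
#'
#' @param p Peak-negative pressure in MPa (scalar, `>= 0`).
#' @param params A `plant_params` object.
#' @param seed Optional integer seed. When `NULL`, the current global RNG
#'   stream is consumed (callers such as [run_treatment()] seed once per
#'   session).
#' @return Numeric voltage trace of length `n_samples(params)`.
#' @export
emit_pulse <- function(p, params, seed = NULL) {
  validate_plant_params(params)
  if (!is.numeric(p) || length(p) != 1 || is.na(p))
    stop("pressure must be a single number", call. = FALSE)
  if (p < 0) stop("pressure must be non-negative", call. = FALSE)
  if (!is.null(seed)) {
    return(withr::with_seed(as.integer(seed), emit_pulse(p, params)))
  }
  n <- n_samples(params)
  t <- (seq_len(n) - 1) / params$fs
  sig <- numeric(n)

  # per-pulse physiological variability: one log-normal factor per pulse,
  # with sigma growing as a power law of pressure (harder to control high)
  sig_eff <- if (p > 0)
    params$amp_sigma * (p / params$p_ref)^params$amp_sigma_exp else 0
  amp_fac <- if (sig_eff > 0) exp(stats::rnorm(1L, 0, sig_eff)) else 1

  phi <- stats::runif(params$n_harmonics, 0, 2 * pi)
  if (p > 0) {
    for (k in seq_len(params$n_harmonics)) {
      a <- params$harm_amp[k] * amp_fac * p^params$gamma
      if (a > 0) sig <- sig + a * sin(2 * pi * k * params$f0 * t + phi[k])
    }
  }
  psi <- stats::runif(length(params$uh_amp), 0, 2 * pi)
  if (p > params$p_uh) {
    for (m in seq_along(params$uh_amp)) {
      a <- params$uh_amp[m] * amp_fac * (p - params$p_uh)^params$gamma
      if (a > 0)
        sig <- sig + a * sin(2 * pi * (m - 0.5) * params$f0 * t + psi[m])
    }
  }
  if (p > params$p_ic && params$bb_gain > 0) {
    sig <- sig + params$bb_gain * (p - params$p_ic) * stats::rnorm(n)
  }
  out <- receiver_filter(sig, params)
  if (params$noise_sigma > 0)
    out <- out + params$noise_sigma * stats::rnorm(n)
  out
}

#' Write a seeded fixture archive of plant traces
#'
#' Generates one trace per (pressure, seed) pair and stores them in an
#' HDF5 archive with a full parameter manifest, so the archive can be
#' regenerated bit-identically from its own attributes.
#'
#' @param params A `plant_params` object.
#' @param pressures Non-empty numeric vector of peak-negative pressures (MPa).
#' @param seeds Non-empty integer vector of seeds, recycled against
#'   `pressures` pairwise via expansion: every pressure is generated at
#'   every seed. `(pressure, seed)` keys must be unique.
#' @param path Output HDF5 file path (overwritten).
#' @return Invisibly, a data.frame manifest (dataset name, pressure, seed).
#' @export
make_fixture_set <- function(params, pressures, seeds, path) {
  validate_plant_params(params)
  if (length(pressures) == 0) stop("pressures must be non-empty", call. = FALSE)
  if (length(seeds) == 0) stop("seeds must be non-empty", call. = FALSE)
  grid <- expand.grid(pressure = pressures, seed = as.integer(seeds),
                      KEEP.OUT.ATTRS = FALSE)
  key <- sprintf("p%.6f_s%d", grid$pressure, grid$seed)
  if (anyDuplicated(key))
    stop("duplicate (pressure, seed) keys in fixture request", call. = FALSE)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "traces")
  for (i in seq_len(nrow(grid))) {
    tr <- emit_pulse(grid$pressure[i], params, seed = grid$seed[i])
    ds <- paste0("traces/", key[i])
    rhdf5::h5write(tr, path, ds)
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, ds)
    rhdf5::h5writeAttribute(grid$pressure[i], did, "pressure_MPa")
    rhdf5::h5writeAttribute(grid$seed[i], did, "seed")
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
  }
  # manifest: all scalar plant parameters as root attributes
  fid <- rhdf5::H5Fopen(path)
  for (nm in names(params)) {
    val <- params[[nm]]
    if (!is.null(val)) rhdf5::h5writeAttribute(val, fid, paste0("plant_", nm))
  }
  rhdf5::h5writeAttribute("fuscontrol-fixture-v1", fid, "format")
  rhdf5::H5Fclose(fid)
  invisible(data.frame(dataset = paste0("traces/", key),
                       pressure_MPa = grid$pressure, seed = grid$seed,
                       stringsAsFactors = FALSE))
}

#' Read traces back from a fixture archive
#'
#' @param path HDF5 archive written by [make_fixture_set()].
#' @return A list with `traces` (named list of numeric vectors),
#'   `manifest` (data.frame of pressure/seed per dataset) and `params`
#'   (the stored plant parameters, reconstructed as `plant_params`).
#' @export
read_fixture_set <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  ds <- ls[ls$group == "/traces" & ls$otype == "H5I_DATASET", "name"]
  traces <- list()
  manifest <- data.frame(dataset = character(), pressure_MPa = numeric(),
                         seed = integer(), stringsAsFactors = FALSE)
  for (nm in ds) {
    full <- paste0("traces/", nm)
    traces[[nm]] <- as.numeric(rhdf5::h5read(path, full))
    at <- rhdf5::h5readAttributes(path, full)
    manifest <- rbind(manifest, data.frame(
      dataset = full, pressure_MPa = as.numeric(at$pressure_MPa),
      seed = as.integer(at$seed), stringsAsFactors = FALSE))
  }
  rat <- rhdf5::h5readAttributes(path, "/")
  pp <- rat[grepl("^plant_", names(rat))]
  names(pp) <- sub("^plant_", "", names(pp))
  args <- lapply(pp, function(v) if (is.array(v)) as.vector(v) else v)
  params <- do.call(plant_params, args[names(args) %in%
                                         names(formals(plant_params))])
  list(traces = traces, manifest = manifest, params = params)
}

#' @export
print.plant_params <- function(x, ...) {
  cat("Synthetic microbubble-emission plant\n")
  cat(sprintf("  drive f0: %.0f kHz, fs: %.0f MHz, pulse: %.1f ms (%d samples)\n",
              x$f0 / 1e3, x$fs / 1e6, x$pulse_len * 1e3, n_samples(x)))
  cat(sprintf("  harmonics: %d (gamma = %g), p_uh = %g MPa, p_ic = %g MPa\n",
              x$n_harmonics, x$gamma, x$p_uh, x$p_ic))
  cat(sprintf("  receiver: %.2f MHz center, %.0f kHz (-6 dB) bandwidth, order %d\n",
              x$rx_center / 1e6, x$rx_bw / 1e3, x$rx_order))
  cat(sprintf("  noise_sigma = %g, amp_sigma = %g\n", x$noise_sigma, x$amp_sigma))
  invisible(x)
}
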