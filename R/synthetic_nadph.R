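#' Slow-kinetic trigger-run schedule for NAD(P)H measurements
#'
#' Timing of one NAD(P)H fluorescence measurement: an actinic phase at the
#' light intensity under investigation, a saturating high-light pulse that
#' fully reduces the NAD(P) pool, and a dark relaxation phase in which the
#' pool re-oxidizes. Defaults: 1 s actinic, 0.6 s pulse, 13.4 s darkness
#' (15 s total), sampled at 0.02 s, four replicate runs.
#'
#' @param actinic_phase,pulse_duration,dark_duration seconds, > 0.
#' @param sample_interval sampling step in seconds; must be smaller than the
#'   pulse duration so the pulse is resolved.
#' @param n_replicates number of consecutive replicate runs.
#' @return An object of class `trigger_run`.
#' @export
trigger_run <- function(actinic_phase = 1.0, pulse_duration = 0.6,
                        dark_duration = 13.4, sample_interval = 0.02,
                        n_replicates = 4L) {
  v <- c(actinic_phase, pulse_duration, dark_duration, sample_interval)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all trigger-run durations must be > 0")
  if (sample_interval >= pulse_duration)
    stop("'sample_interval' must be smaller than 'pulse_duration'")
  if (n_replicates < 1) stop("'n_replicates' must be >= 1")
  total <- actinic_phase + pulse_duration + dark_duration
  structure(
    list(actinic_phase = actinic_phase, pulse_duration = pulse_duration,
         dark_duration = dark_duration, sample_interval = sample_interval,
         n_replicates = as.integer(n_replicates), total_duration = total,
         landmarks = c(actinic_end = actinic_phase,
                       pulse_end = actinic_phase + pulse_duration,
                       trace_end = total)),
    class = "trigger_run"
  )
}

#' @export
print.trigger_run <- function(x, ...) {
  cat(sprintf(
    "<trigger_run> %g s actinic + %g s pulse + %g s dark = %g s, dt = %g s, %d replicate(s)\n",
    x$actinic_phase, x$pulse_duration, x$dark_duration, x$total_duration,
    x$sample_interval, x$n_replicates))
  invisible(x)
}

#' Timed NAD(P)H fluorescence trace
#'
#' @param times seconds on a uniform grid starting at 0.
#' @param signal fluorescence signal, same length as `times`.
#' @param landmarks named numeric vector with `actinic_end`, `pulse_end`,
#'   `trace_end` (seconds).
#' @param light_intensity actinic intensity in umol photons m^-2 s^-1
#'   (0 = darkness), or `NA`.
#' @param replicate_id replicate label.
#' @return data.frame of class `nadph_trace` with columns `time_s`, `signal`.
#' @export
nadph_trace <- function(times, signal,
                        landmarks = c(actinic_end = 1, pulse_end = 1.6,
                                      trace_end = 15),
                        light_intensity = NA_real_, replicate_id = NA) {
  if (length(times) != length(signal)) stop("times/signal length mismatch")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  req <- c("actinic_end", "pulse_end", "trace_end")
  if (!all(req %in% names(landmarks))) stop("missing landmarks")
  dt <- if (length(times) > 1) times[2] - times[1] else Inf
  if (times[1] > 0 || max(times) < landmarks[["trace_end"]] - dt - 1e-9)
    stop("'times' must cover [0, trace_end]")
  structure(
    data.frame(time_s = as.numeric(times), signal = as.numeric(signal)),
    landmarks = landmarks[req], light_intensity = light_intensity,
    replicate_id = replicate_id, class = c("nadph_trace", "data.frame")
  )
}

trace_landmarks <- function(trace) attr(trace, "landmarks")

# Noiseless signal model of one trigger run: constant baseline during the
# actinic phase, full reduction to baseline+amplitude during the pulse,
# monoexponential re-oxidation towards steady_offset in darkness.
nadph_model <- function(t, run, baseline, amplitude, oxidation_rate,
                        steady_offset) {
  t1 <- run$landmarks[["actinic_end"]]
  t2 <- run$landmarks[["pulse_end"]]
  peak <- baseline + amplitude
  ifelse(t < t1, baseline,
         ifelse(t < t2, peak,
                steady_offset + (peak - steady_offset) *
                  exp(-oxidation_rate * (t - t2))))
}

#' Simulate replicate NAD(P)H trigger-run traces
#'
#' Generates `run$n_replicates` traces sharing one time grid, each the
#' noiseless trigger-run signal model plus independent Gaussian noise. Ground
#' truth carries the oxidation rate and the analytic photo-reducible level
#' (pulse maximum over pre-pulse level, both after subtracting the dark-end
#' signal).
#'
#' @param run a [trigger_run()].
#' @param baseline pre-pulse signal level during the actinic phase.
#' @param amplitude pulse-induced rise above baseline (>= 0).
#' @param oxidation_rate dark re-oxidation rate constant (s^-1, > 0).
#' @param steady_offset asymptotic dark signal level.
#' @param noise_sd per-sample Gaussian noise SD.
#' @param seed integer RNG seed.
#' @param light_intensity actinic intensity annotation (umol photons m^-2 s^-1).
#' @return List with `traces` (list of [nadph_trace()] replicates) and
#'   `truth` ([ground_truth()]).
#' @export
simulate_nadph_trace <- function(run = trigger_run(), baseline = 2,
                                 amplitude = 1, oxidation_rate = 0.5,
                                 steady_offset = 1.5, noise_sd = 0, seed,
                                 light_intensity = NA_real_) {
  if (!is.finite(amplitude) || amplitude < 0) stop("'amplitude' must be >= 0")
  if (!is.finite(oxidation_rate) || oxidation_rate < 0)
    stop("'oxidation_rate' must be >= 0")
  times <- seq(0, by = run$sample_interval,
               length.out = floor(run$total_duration / run$sample_interval) + 1)
  clean <- nadph_model(times, run, baseline, amplitude, oxidation_rate,
                       steady_offset)
  lm <- run$landmarks
  dark_end <- nadph_model(lm[["trace_end"]], run, baseline, amplitude,
                          oxidation_rate, steady_offset)
  ratio <- (baseline + amplitude - dark_end) / (baseline - dark_end)
  with_seed(seed, {
    traces <- lapply(seq_len(run$n_replicates), function(i) {
      s <- clean + if (noise_sd > 0) rnorm(length(clean), sd = noise_sd) else 0
      nadph_trace(times, s, landmarks = lm,
                  light_intensity = light_intensity, replicate_id = i)
    })
    truth <- ground_truth(
      oxidation_rate_true = if (oxidation_rate > 0) oxidation_rate else NA_real_,
      photoreducible_ratio_true = ratio,
      extra = list(baseline = baseline, amplitude = amplitude,
                   steady_offset = steady_offset, run = run)
    )
    list(traces = traces, truth = truth)
  })
}

#' Simulate a plate-reader absorbance trace
#'
#' A flat OD340 baseline measured for `baseline_minutes`, followed at the
#' substrate-addition time by a linear rise of the given slope for
#' `duration` minutes, plus optional Gaussian noise.
#'
#' @param baseline_minutes baseline length in minutes (default 10).
#' @param slope post-substrate OD340 increase per minute.
#' @param duration post-substrate monitoring time in minutes (default 30).
#' @param noise_sd per-sample Gaussian noise SD (OD units).
#' @param seed integer RNG seed.
#' @param sample_interval_min sampling step in minutes.
#' @param od_baseline baseline OD340 level.
#' @param protein_mass_mg,well_volume_l,path_length_cm assay metadata carried
#'   on the trace; defaults mirror a 200 uL well loaded with 10 ug protein.
#' @return data.frame of class `assay_trace` with columns `time_min`, `od340`
#'   and the assay metadata as attributes (`substrate_added_at`, ...).
#' @export
simulate_assay_trace <- function(baseline_minutes = 10, slope = 0.01,
                                 duration = 30, noise_sd = 0, seed,
                                 sample_interval_min = 0.5, od_baseline = 0.05,
                                 protein_mass_mg = 0.01,
                                 well_volume_l = 200e-6,
                                 path_length_cm = 0.56) {
  if (!is.finite(duration) || duration <= 0) stop("'duration' must be > 0")
  if (baseline_minutes <= 0) stop("'baseline_minutes' must be > 0")
  times <- seq(0, baseline_minutes + duration, by = sample_interval_min)
  od <- od_baseline + pmax(times - baseline_minutes, 0) * slope
  with_seed(seed, {
    if (noise_sd > 0) od <- od + rnorm(length(od), sd = noise_sd)
    assay_trace(times, od, substrate_added_at = baseline_minutes,
                protein_mass_mg = protein_mass_mg,
                well_volume_l = well_volume_l,
                path_length_cm = path_length_cm)
  })
}

#' Plate-reader absorbance trace container
#'
#' @param time_min times in minutes, strictly increasing.
#' @param od340 absorbance values.
#' @param substrate_added_at substrate-addition time in minutes.
#' @param protein_mass_mg,well_volume_l,path_length_cm assay metadata.
#' @return data.frame of class `assay_trace`.
#' @export
assay_trace <- function(time_min, od340, substrate_added_at,
                        protein_mass_mg = 0.01, well_volume_l = 200e-6,
                        path_length_cm = 0.56) {
  if (length(time_min) != length(od340)) stop("time/od length mismatch")
  if (any(diff(time_min) <= 0)) stop("'time_min' must be strictly increasing")
  if (protein_mass_mg <= 0) stop("'protein_mass_mg' must be > 0")
  if (path_length_cm <= 0) stop("'path_length_cm' must be > 0")
  structure(
    data.frame(time_min = as.numeric(time_min), od340 = as.numeric(od340)),
    substrate_added_at = substrate_added_at,
    protein_mass_mg = protein_mass_mg, well_volume_l = well_volume_l,
    path_length_cm = path_length_cm, class = c("assay_trace", "data.frame")
  )
}
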