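#' Dark/light acquisition schedule
#'
#' Timing grid of a live-cell imaging experiment: one frame every
#' `dark_interval` seconds during `dark_duration` seconds of darkness,
#' followed by one frame every `light_interval` seconds for `light_duration`
#' seconds after the illumination is switched back on. Defaults reproduce the
#' standard protocol: 300 s of darkness imaged every 10 s, then 30 s of light
#' imaged every 0.47 s.
#'
#' The dark phase contains `floor(dark_duration/dark_interval) + 1` frames at
#' t = 0, dark_interval, ..., dark_duration. The light phase contains
#' `floor(light_duration/light_interval) + 1` frames; its first frame is
#' taken one interval after the light switch so frame times stay strictly
#' increasing.
#'
#' @param dark_duration,dark_interval,light_duration,light_interval seconds,
#'   all strictly positive.
#' @return An object of class `acquisition_schedule` with the frame time and
#'   illumination vectors precomputed.
#' @export
acquisition_schedule <- function(dark_duration = 300, dark_interval = 10,
                                 light_duration = 30, light_interval = 0.47) {
  v <- c(dark_duration, dark_interval, light_duration, light_interval)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all schedule durations and intervals must be > 0")
  dark_times <- seq(0, by = dark_interval,
                    length.out = floor(dark_duration / dark_interval) + 1)
  n_light <- floor(light_duration / light_interval) + 1
  light_times <- dark_duration + light_interval * seq_len(n_light)
  structure(
    list(dark_duration = dark_duration, dark_interval = dark_interval,
         light_duration = light_duration, light_interval = light_interval,
         frame_times = c(dark_times, light_times),
         illumination = c(rep("dark", length(dark_times)),
                          rep("light", n_light))),
    class = "acquisition_schedule"
  )
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat(sprintf(
    "<acquisition_schedule> dark %g s @ %g s (%d frames), light %g s @ %g s (%d frames)\n",
    x$dark_duration, x$dark_interval, sum(x$illumination == "dark"),
    x$light_duration, x$light_interval, sum(x$illumination == "light")))
  invisible(x)
}

#' Kinetic parameter presets for the two tagged enzymes
#'
#' Default first-order rate constants for the simulated bound-fraction
#' dynamics. GapDH2 is recruited into the CP12 complex faster than PRK, and
#' PRK is released faster upon re-illumination (the sequential binding order
#' of the ternary complex); the presets encode that ordering.
#'
#' @param enzyme `"gapdh2"` or `"prk"`.
#' @return List with `k_assembly` and `k_disassembly` (s^-1).
#' @export
kinetic_preset <- function(enzyme = c("gapdh2", "prk")) {
  switch(match.arg(enzyme),
         gapdh2 = list(k_assembly = 0.030, k_disassembly = 0.06),
         prk    = list(k_assembly = 0.012, k_disassembly = 0.15))
}

# First-order bound-fraction trajectory over a schedule's frame times.
bound_fraction_at <- function(schedule, k_assembly, k_disassembly) {
  t <- schedule$frame_times
  dark <- schedule$illumination == "dark"
  b <- numeric(length(t))
  b[dark] <- 1 - exp(-k_assembly * t[dark])
  b_end <- 1 - exp(-k_assembly * schedule$dark_duration)
  b[!dark] <- b_end * exp(-k_disassembly * (t[!dark] - schedule$dark_duration))
  b
}

#' Simulate a dark/light time-lapse of complex assembly and disassembly
#'
#' Renders a full two-channel time-lapse in which the eYFP bound fraction of
#' every cell follows first-order kinetics: during darkness
#' b(t) = 1 - exp(-k_assembly * t), and after the light switch
#' b(t) = b_dark_end * exp(-k_disassembly * (t - t_switch)). Cell geometry and
#' spot positions are drawn once and held fixed across frames (cells are
#' immobilized on agar); per-frame noise draws are independent.
#'
#' @param schedule an [acquisition_schedule()].
#' @param k_assembly,k_disassembly strictly positive rate constants (s^-1).
#' @param n_cells,spots_per_cell,noise_sd,seed,image_shape,... passed to the
#'   field renderer, see [simulate_cell_field()].
#' @return A list with `stack` ([image_stack()]) and `truth`
#'   ([ground_truth()] carrying b(t) at every frame time).
#' @export
simulate_timelapse <- function(schedule = acquisition_schedule(),
                               k_assembly, k_disassembly,
                               n_cells = 20, spots_per_cell = 3,
                               noise_sd = 0, seed,
                               image_shape = c(512, 512), ...) {
  if (!is.finite(k_assembly) || k_assembly <= 0 ||
      !is.finite(k_disassembly) || k_disassembly <= 0)
    stop("rate constants must be strictly positive")
  b <- bound_fraction_at(schedule, k_assembly, k_disassembly)
  t <- schedule$frame_times
  with_seed(seed, {
    geom <- draw_field_geometry(n_cells, image_shape, spots_per_cell)
    px <- array(0, dim = c(length(t), 2, image_shape[1], image_shape[2]))
    for (f in seq_along(t)) {
      fr <- render_field(geom, b[f], ...)
      if (noise_sd > 0) {
        fr$chl <- pmax(fr$chl + rnorm(length(fr$chl), sd = noise_sd), 0)
        fr$eyfp <- pmax(fr$eyfp + rnorm(length(fr$eyfp), sd = noise_sd), 0)
      }
      px[f, 1, , ] <- fr$chl
      px[f, 2, , ] <- fr$eyfp
    }
    stack <- image_stack(px, frame_times = t,
                         channel_roles = c(chlorophyll = 1L, eyfp = 2L),
                         illumination = schedule$illumination)
    truth <- ground_truth(
      bound_fraction_series = data.frame(time_s = t, bound_fraction = b),
      cells = geom$cells, spots_per_cell = as.integer(spots_per_cell),
      k_assembly = k_assembly, k_disassembly = k_disassembly,
      extra = list(spot_centers = geom$spot_centers,
                   schedule = schedule, image_shape = image_shape)
    )
    list(stack = stack, truth = truth)
  })
}
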