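# Independent brute-force oracles the vectorized implementations are checked
# against, plus small fixture builders. Everything is generated in code.

# per-pixel loop maximum projection
oracle_max_project <- function(stack, channel) {
  ch <- stack$channel_roles[[channel]]
  d <- dim(stack$pixels)
  out <- matrix(-Inf, d[3], d[4])
  for (f in seq_len(d[1]))
    for (r in seq_len(d[3]))
      for (cc in seq_len(d[4]))
        out[r, cc] <- max(out[r, cc], stack$pixels[f, ch, r, cc])
  out
}

# frame-by-frame, cell-by-cell loop over cell_stats
oracle_heterogeneity <- function(stack, mask) {
  rows <- list()
  for (f in seq_len(dim(stack$pixels)[1])) {
    img <- get_plane(stack, f, "eyfp")
    for (id in seq_len(mask$n_cells)) {
      s <- cell_stats(img, mask, id, time = stack$frame_times[f],
                      illumination = stack$illumination[f])
      rows[[length(rows) + 1]] <- data.frame(
        frame = f, time_s = s$time, illumination = s$illumination,
        cell_id = id, mean = s$mean_intensity, sd = s$sd_intensity,
        nsd = s$nsd)
    }
  }
  do.call(rbind, rows)
}

# ordinary least squares via the normal equations
oracle_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(intercept = beta[1], slope = beta[2], r_squared = r2)
}

# random small image stack for oracle-equivalence checks
random_stack <- function(n_frames, nr = 12, nc = 10, seed = 1) {
  set.seed(seed)
  px <- array(runif(n_frames * 2 * nr * nc), dim = c(n_frames, 2, nr, nc))
  image_stack(px, frame_times = seq_len(n_frames),
              channel_roles = c(chlorophyll = 1L, eyfp = 2L),
              illumination = rep("dark", n_frames))
}

# noisy monoexponential nsd trace on a schedule phase grid
synthetic_transition_trace <- function(rate, direction, noise_frac = 0.1,
                                       plateau = 0.5, seed = 1) {
  set.seed(seed)
  if (direction == "assembly") {
    t <- seq(0, 300, by = 10)
    y <- plateau * (1 - exp(-rate * t))
  } else {
    t <- seq(0, 30, by = 0.47)
    y <- plateau * exp(-rate * t)
  }
  data.frame(time_s = t, nsd = pmax(y + rnorm(length(t), sd = noise_frac * plateau), 0))
}

# piecewise-constant NAD(P)H trace with prescribed pre-pulse, pulse-max and
# dark-end levels (dark tail flat so every dark-end convention agrees)
constructed_nadph_trace <- function(prepulse = 0.5, pulse_max = 1.3,
                                    dark_end = 0.1, dt = 0.02) {
  times <- seq(0, 15, by = dt)
  sig <- ifelse(times < 1, prepulse, ifelse(times <= 1.6, pulse_max, dark_end))
  nadph_trace(times, sig)
}
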