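# Brute-force half-time oracle: dense-grid first crossing of half the
# t = 0 value, independent of the package's root-finding path.
oracle_half_time <- function(D, t0, x, dt = 0.01, t_max = 5e4) {
  c_of <- function(t) 1 / sqrt(pi * D * (t + t0)) * exp(-x^2 / (4 * D * (t + t0)))
  target <- c_of(0) / 2
  t <- seq(0, t_max, by = dt)
  v <- c_of(t)
  i <- which(v <= target & t > 0)[1]
  if (is.na(i)) stop("oracle: no crossing below half within t_max")
  t[i]
}

# Small, fast preset for tests that do not need the full 720-frame record.
small_preset <- function(name, n_frames = 60L, seed = 1L) {
  p <- make_preset(name, noise = noise_spec(seed = seed))
  p$n_frames <- as.integer(n_frames)
  p
}
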