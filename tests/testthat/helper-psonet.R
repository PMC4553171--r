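# Shared fixtures, generated in code.

# short Mackey-Glass series for cheap tests
short_mg <- function(horizon = 300) mackey_glass(mg_params(t_horizon = horizon))

# a small forecasting task (embed + split) on a short series
small_task <- function(horizon = 300, sigma = 0, n_train = 200, seed = 1) {
  mg_task(sigma = sigma, params = mg_params(t_horizon = horizon),
          n_train = n_train, noise_seed = seed)
}

# reduced swarm settings for unit tests (full Table-style constants, short loop)
quick_control <- function(k_max = 60, n_particles = 20) {
  pso_control(n_particles = n_particles, k_max = k_max)
}

# hand-rolled forward pass: scalar loops only, independent of the package's
# vectorized/C++ paths
reference_forward <- function(theta, n_in, n_hidden, p) {
  wh <- matrix(theta[seq_len(n_in * n_hidden)], n_hidden, n_in, byrow = TRUE)
  bh <- theta[n_in * n_hidden + seq_len(n_hidden)]
  wo <- theta[n_in * n_hidden + n_hidden + seq_len(n_hidden)]
  bo <- theta[length(theta)]
  out <- bo
  for (j in seq_len(n_hidden)) {
    net <- bh[j]
    for (i in seq_len(n_in)) net <- net + wh[j, i] * p[i]
    out <- out + wo[j] * (exp(net) - exp(-net)) / (exp(net) + exp(-net))
  }
  out
}
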