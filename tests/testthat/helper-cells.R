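# Deterministic seasonal cell built from known constant coefficients with no
# noise: the strongest oracle available, since the data satisfy the fitting
# model exactly.
exact_cell <- function(M = 48, beta = c(0.1, 0.02, 0, 0.001, 0),
                       T0 = 10, P0 = 50) {
  t <- seq_len(M)
  Tv <- T0 + 3 * sin(2 * pi * (t - 1) / 12) + 0.3 * sin(2 * pi * (t - 1) / 7)
  Pv <- P0 + 20 * sin(2 * pi * (t - 1) / 12) + 2 * sin(2 * pi * (t - 1) / 5)
  X <- build_design(Tv, Pv)
  cell_series(drop(X %*% beta), Tv, Pv, cell_id = "exact")
}

# noisy default-condition synthetic cell
noisy_cell <- function(seed = 1, M = 120, sigma = 0.02, ...) {
  make_cell(synthetic_truth(sigma_eps = sigma, seed = seed, ...), M = M)
}
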