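# Small reusable designs built in code.

# Regularly spaced 2D lattice (dense neighbourhoods under the 350 m rule).
lattice_units <- function(nx, ny, spacing = 200, year = 2010) {
  g <- expand.grid(x = seq(0, by = spacing, length.out = nx),
                   y = seq(0, by = spacing, length.out = ny))
  data.frame(plot_id = sprintf("p%05d", seq_len(nrow(g))),
             year = year, x = g$x, y = g$y, stringsAsFactors = FALSE)
}

# Chain of plots along a line (each plot neighbours the next).
chain_units <- function(n, spacing = 200, year = 2010) {
  data.frame(plot_id = sprintf("c%05d", seq_len(n)), year = year,
             x = seq_len(n) * spacing, y = 0, stringsAsFactors = FALSE)
}

# Plots far apart: edgeless adjacency.
scatter_units <- function(n, year = 2010) {
  data.frame(plot_id = sprintf("s%05d", seq_len(n)), year = year,
             x = seq_len(n) * 1000, y = 0, stringsAsFactors = FALSE)
}

# Minimal model_frame around a response and design matrix.
toy_frame <- function(y, X, units) {
  structure(list(y = y, X = X, units = units,
                 terms = colnames(X)[-1], assign = seq_len(ncol(X)) - 1L,
                 references = character()),
            class = "model_frame")
}

# Simulate a binary response from the CAR model on given units.
simulate_car_binary <- function(units, beta, tau, rho, seed,
                                D = build_adjacency(units)) {
  n <- nrow(units)
  set.seed(seed)
  x <- rnorm(n)
  u <- sample_car_effects(tau, rho, D, seed = seed + 77777L)
  y <- rbinom(n, 1, plogis(beta[1] + beta[2] * x + u))
  list(frame = toy_frame(y, cbind("(Intercept)" = 1, x = x), units),
       D = D, x = x, u = u, y = y)
}
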