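# Shared fixtures built in code.

# A triangular 3.5-cycle loading history with configurable coupled channels.
make_history <- function(peak = 7.5, n_q = 50, n_cycles = 3.5, dof = "fe",
                         coupled = NULL, fs = 100) {
  n <- as.integer(round(4 * n_q * n_cycles)) + 1L
  s <- seq_len(n) - 1L
  ph <- (s %% (4 * n_q)) / n_q
  tri <- ifelse(ph < 1, ph, ifelse(ph < 3, 2 - ph, ph - 4))
  m <- matrix(0, n, 3)
  colnames(m) <- ivj_dofs()
  m[, dof] <- peak * tri
  if (!is.null(coupled)) {
    for (d in names(coupled)) m[, d] <- coupled[[d]]
  }
  load_history(s / fs, m, dof)
}

# A small, fast generator configuration (coarse sampling); study conditions
# themselves are exercised in the acceptance tests.
fast_config <- function(seed, ...) {
  generator_config(seed = seed, sample_rate_hz = 5, ...)
}

# zero 6 x 3 matrix with level/DoF dimnames
zmat <- function(fill = 0) {
  matrix(fill, 6, 3, dimnames = list(ivj_levels(), ivj_dofs()))
}

# strip class and solver attributes, keep the 6 x 3 shape
rotmat <- function(x) {
  m <- unclass(x)
  attributes(m) <- list(dim = c(6L, 3L),
                        dimnames = list(ivj_levels(), ivj_dofs()))
  m
}

rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
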